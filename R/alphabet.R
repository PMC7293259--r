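# Integer base coding shared by the hairpin search and context extraction.
# T and U share a code: pairing and motif logic are alphabet-agnostic, only
# rendering differs (DNA prints T, RNA prints U).
.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, U = 4L,
                a = 1L, c = 2L, g = 3L, t = 4L, u = 4L)
.DNA_LETTERS <- c("A", "C", "G", "T")
.RNA_LETTERS <- c("A", "C", "G", "U")

encode_seq <- function(x) {
  unname(.BASE_CODE[strsplit(x, "", fixed = TRUE)[[1]]])
}

#' Reverse complement of DNA/RNA strings
#'
#' Works on plain character vectors; U is complemented to A, and output uses
#' DNA letters unless `rna = TRUE`.
#'
#' @param x character vector of sequences.
#' @param rna logical; render the result with U instead of T.
#' @return character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x, rna = FALSE) {
  comp <- chartr("ACGTUacgtu", if (rna) "UGCAAugcaa" else "TGCAAtgcaa", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Render a DNA-letter string in the requested alphabet.
render_alphabet <- function(x, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "RNA") chartr("Tt", "Uu", x) else chartr("Uu", "Tt", x)
}
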
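#' Coerce a reference to a named character vector of sequences
#'
#' Accepts a named character vector, a `Biostrings::DNAStringSet` (or
#' `RNAStringSet`), or a path to a FASTA file (read with
#' `Biostrings::readDNAStringSet`).
#'
#' @param x reference in any of the supported forms.
#' @return named character vector of uppercase sequences.
#' @export
as_reference <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(toupper(out))
  }
  if (is.character(x)) {
    if (is.null(names(x)) || any(names(x) == ""))
      stop_param("reference sequences must be named")
    return(toupper(x))
  }
  stop_param("unsupported reference type; give a named character vector, an XStringSet, or a FASTA path")
}

#' Write reference sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
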
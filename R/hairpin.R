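#' Hairpin search parameters
#'
#' Bundles the stem-loop model parameters used by [best_hairpin()] and every
#' function that annotates sites with hairpin geometry. The model considers
#' perfect, contiguous stems only (no bulges or internal mismatches): two
#' equal-length arms pair base-by-base around an unpaired loop that contains
#' the query site.
#'
#' @param min_stem minimum stem length in base pairs (default 3).
#' @param max_stem maximum stem length considered (default 12); longer
#'   pairing runs are truncated at the `max_stem` pairs closest to the loop.
#' @param min_loop,max_loop allowed loop lengths in nucleotides (defaults 3
#'   and 11).
#' @param pair_scores named numeric vector of per-pair scores: `GC`, `AT`
#'   (also A:U) and `GU` (wobble, only used when `allow_GU = TRUE`).
#'   Defaults G:C = 3, A:T/U = 2, G:U = 1 — a simple strength proxy in which
#'   stronger stems score higher; not a thermodynamic model.
#' @param allow_GU allow G:U wobble pairs (sensible for RNA; default FALSE).
#' @return a list of class `hairpin_params` with the validated parameters
#'   and a precomputed 4x4 pair-score matrix.
#' @export
hairpin_params <- function(min_stem = 3L, max_stem = 12L,
                           min_loop = 3L, max_loop = 11L,
                           pair_scores = c(GC = 3, AT = 2, GU = 1),
                           allow_GU = FALSE) {
  min_stem <- as.integer(min_stem); max_stem <- as.integer(max_stem)
  min_loop <- as.integer(min_loop); max_loop <- as.integer(max_loop)
  if (min_stem < 1L) stop_param("min_stem must be >= 1")
  if (max_stem < min_stem) stop_param("max_stem must be >= min_stem")
  if (min_loop < 1L) stop_param("min_loop must be >= 1")
  if (max_loop < min_loop) stop_param("max_loop must be >= min_loop")
  for (nm in c("GC", "AT")) {
    if (is.na(pair_scores[nm]) || pair_scores[nm] <= 0)
      stop_param(sprintf("pair score '%s' must be a positive number", nm))
  }
  m <- matrix(0, 4L, 4L)
  m[3L, 2L] <- m[2L, 3L] <- pair_scores[["GC"]]
  m[1L, 4L] <- m[4L, 1L] <- pair_scores[["AT"]]
  if (allow_GU) {
    if (is.na(pair_scores["GU"]) || pair_scores[["GU"]] <= 0)
      stop_param("pair score 'GU' must be a positive number when allow_GU")
    m[3L, 4L] <- m[4L, 3L] <- pair_scores[["GU"]]
  }
  structure(list(min_stem = min_stem, max_stem = max_stem,
                 min_loop = min_loop, max_loop = max_loop,
                 pair_scores = pair_scores, allow_GU = isTRUE(allow_GU),
                 score_mat = m),
            class = "hairpin_params")
}

#' Best stem-loop placement of a site
#'
#' Enumerates every hairpin placement whose loop contains the query site —
#' loop lengths between `min_loop` and `max_loop`, perfect contiguous stems
#' of at least `min_stem` pairs — and returns the placement maximizing
#' stem strength (sum of pair scores over the stem). Ties are broken by the
#' smaller loop, then by the 5'-most arm, so output is deterministic. If no
#' placement qualifies, the site is called structure-free (`stem_length = 0`).
#'
#' @param sequence a single character string (DNA or RNA letters).
#' @param site_position 0-based index of the query nucleotide.
#' @param params a [hairpin_params()] object.
#' @return an object of class `hairpin_call`: `stem_length`, `loop_length`,
#'   `loop_start` (0-based), `site_loop_position` (1-based within the loop,
#'   1 = 5'-most), `stem_strength`, and `arm5_span`/`arm3_span` as 0-based
#'   half-open intervals. For structure-free sites `stem_length` is 0 and
#'   loop fields are `NA`.
#' @examples
#' # A natural DNA hairpin around a TpC site (NUP93-like 21-mer):
#' best_hairpin("GCAAGCTGTTCAGCTTGCTGA", 10)
#' # A structure-free polyA context:
#' best_hairpin("AAAAAAAAATCGGGAAAAAAA", 10)
#' @export
best_hairpin <- function(sequence, site_position, params = hairpin_params()) {
  if (!inherits(params, "hairpin_params")) params <- do.call(hairpin_params, params)
  enc <- encode_seq(sequence)
  n <- length(enc)
  si <- as.integer(site_position) + 1L
  if (si < 1L || si > n) stop_param("site_position outside the sequence")
  sm <- params$score_mat
  best <- NULL
  for (L in params$min_loop:params$max_loop) {
    ls_lo <- max(si - L + 1L, params$min_stem + 1L)
    ls_hi <- min(si, n - L + 1L - params$min_stem)
    if (ls_lo > ls_hi) next
    for (ls in ls_lo:ls_hi) {
      i5 <- ls - 1L              # innermost 5' stem base
      i3 <- ls + L               # innermost 3' stem base
      m <- min(params$max_stem, i5, n - i3 + 1L)
      if (m < params$min_stem) next
      a <- enc[i5:(i5 - m + 1L)]
      b <- enc[i3:(i3 + m - 1L)]
      sc <- sm[cbind(a, b)]
      sc[is.na(sc)] <- 0
      bad <- which(sc == 0)
      k <- if (length(bad)) bad[1L] - 1L else m
      if (k < params$min_stem) next
      strength <- sum(sc[seq_len(k)])
      if (is.null(best) ||
          strength > best$stem_strength ||
          (strength == best$stem_strength &&
           (L < best$loop_length ||
            (L == best$loop_length && (i5 - k) < best$arm5_span[1L])))) {
        best <- list(stem_length = k, loop_length = L,
                     loop_start = ls - 1L,
                     site_loop_position = si - ls + 1L,
                     stem_strength = strength,
                     arm5_span = c(i5 - k, i5),          # 0-based half-open
                     arm3_span = c(i3 - 1L, i3 - 1L + k))
      }
    }
  }
  if (is.null(best)) {
    best <- list(stem_length = 0L, loop_length = NA_integer_,
                 loop_start = NA_integer_, site_loop_position = NA_integer_,
                 stem_strength = 0, arm5_span = NULL, arm3_span = NULL)
  }
  best$site_position <- as.integer(site_position)
  class(best) <- "hairpin_call"
  best
}

#' @export
print.hairpin_call <- function(x, ...) {
  if (x$stem_length == 0L) {
    cat(sprintf("<hairpin_call> site %d: structure-free (no qualifying stem-loop)\n",
                x$site_position))
  } else {
    cat(sprintf(
      "<hairpin_call> site %d: %d-bp stem (strength %.1f), %d-nt loop, site at loop position %d/%d\n",
      x$site_position, x$stem_length, x$stem_strength,
      x$loop_length, x$site_loop_position, x$loop_length))
  }
  invisible(x)
}

#' Stem strength of two paired arms
#'
#' Sums per-pair scores over a perfect stem. `arm5` and `arm3` are both given
#' 5' to 3'; position `i` of `arm5` pairs with position `n + 1 - i` of
#' `arm3`. The score is additive and order-independent.
#'
#' @param arm5,arm3 equal-length character strings (5' to 3').
#' @inheritParams hairpin_params
#' @return numeric score (0 for empty arms).
#' @examples
#' stem_strength("GC", "GC")                 # two G:C pairs -> 6
#' stem_strength("GCAAGCT", "AGCTTGC")       # NUP93 7-bp stem
#' @export
stem_strength <- function(arm5, arm3,
                          pair_scores = c(GC = 3, AT = 2, GU = 1),
                          allow_GU = FALSE) {
  a <- encode_seq(arm5)
  b <- encode_seq(arm3)
  if (length(a) != length(b))
    abort("arms must have equal length", "invalid_stem_error")
  if (length(a) == 0L) return(0)
  p <- hairpin_params(pair_scores = pair_scores, allow_GU = allow_GU)
  sc <- p$score_mat[cbind(a, rev(b))]
  sc[is.na(sc)] <- 0
  if (any(sc == 0))
    abort(sprintf("unpaired stem position(s): %s",
                  paste(which(sc == 0), collapse = ", ")),
          "invalid_stem_error")
  sum(sc)
}

#' Strand-normalized tetranucleotide context of a mutated cytosine
#'
#' Extracts the xTCy window (two 5' bases through one 3' base) around a
#' mutated C, reported on the pyrimidine strand: if the given strand carries
#' a G, the reverse-complement window is used. The 4-mer distinguishes the
#' A3A-preferred YTCA motif (Y = C/T pyrimidine) from the A3B-preferred RTCA
#' motif (R = A/G purine).
#'
#' @param sequence single character string.
#' @param position 0-based index of the mutated base (must be C or G).
#' @param alphabet `"DNA"` or `"RNA"`; controls rendering (T vs U) of the
#'   returned window.
#' @return object of class `site_context`: `position`, `ref_base`,
#'   `strand_normalized` (TRUE when the reverse complement was taken),
#'   `tetranucleotide`, `is_tpc` (base 5' of the C is T/U) and
#'   `character` in `c("YTCA-like", "RTCA-like", "other")`.
#' @examples
#' tetranucleotide_context("AACTCAGG", 4)  # CTCA -> YTCA-like
#' tetranucleotide_context("AAGTCAGG", 4)  # GTCA -> RTCA-like
#' @export
tetranucleotide_context <- function(sequence, position,
                                    alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  n <- nchar(sequence)
  i <- as.integer(position) + 1L
  if (i < 1L || i > n) stop_param("position outside the sequence")
  base <- render_alphabet(toupper(substr(sequence, i, i)), "DNA")
  if (base == "C") {
    if (i - 2L < 1L || i + 1L > n)
      abort("insufficient flank for tetranucleotide context (need 2 nt 5' and 1 nt 3')",
            "context_unavailable_error")
    tet <- toupper(substr(sequence, i - 2L, i + 1L))
    normalized <- FALSE
  } else if (base == "G") {
    if (i - 1L < 1L || i + 2L > n)
      abort("insufficient flank for tetranucleotide context (need 1 nt 5' and 2 nt 3')",
            "context_unavailable_error")
    tet <- revcomp(toupper(substr(sequence, i - 1L, i + 2L)))
    normalized <- TRUE
  } else {
    abort(sprintf("reference base at position %d is '%s'; expected C or G",
                  position, base),
          "invalid_site_error")
  }
  tet_dna <- render_alphabet(tet, "DNA")
  is_tpc <- substr(tet_dna, 2L, 2L) == "T"
  char <- classify_tetranucleotide(tet_dna)
  structure(list(position = as.integer(position), ref_base = base,
                 strand_normalized = normalized,
                 tetranucleotide = render_alphabet(tet_dna, alphabet),
                 is_tpc = is_tpc, character = char),
            class = "site_context")
}

# Vectorized motif classification of xTCy 4-mers (DNA letters).
classify_tetranucleotide <- function(tet) {
  out <- rep("other", length(tet))
  out[grepl("^[CT]TCA$", tet)] <- "YTCA-like"
  out[grepl("^[AG]TCA$", tet)] <- "RTCA-like"
  out[is.na(tet)] <- NA_character_
  out
}

#' @export
print.site_context <- function(x, ...) {
  cat(sprintf("<site_context> pos %d (%s%s): %s, %s%s\n",
              x$position, x$ref_base,
              if (x$strand_normalized) ", strand-normalized" else "",
              x$tetranucleotide, x$character,
              if (x$is_tpc) " [TpC]" else ""))
  invisible(x)
}

#' Annotate sites with hairpin geometry and sequence context
#'
#' For each (sequence, position) pair, runs [best_hairpin()] on a window
#' around the site and [tetranucleotide_context()] at the site, returning a
#' table ready for TSV export (positions 1-based in the output).
#'
#' @param sequences named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param sites data.frame with columns `sequence_id` and `position`
#'   (0-based). If `NULL`, every TpC cytosine (transcript strand) is used.
#' @param params [hairpin_params()].
#' @param window half-width of the sequence window handed to the hairpin
#'   search (default 25 nt each side).
#' @param alphabet `"DNA"` or `"RNA"` for context rendering.
#' @return data.frame: `sequence_id`, `position` (1-based), `loop_length`,
#'   `site_loop_position`, `stem_length`, `stem_strength`,
#'   `tetranucleotide`, `character`.
#' @export
hairpin_annotate <- function(sequences, sites = NULL,
                             params = hairpin_params(), window = 25L,
                             alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  seqs <- as_reference(sequences)
  if (is.null(sites)) {
    sites <- do.call(rbind, lapply(names(seqs), function(id) {
      pos <- tpc_positions_plus(seqs[[id]])
      if (!length(pos)) return(NULL)
      data.frame(sequence_id = id, position = pos, stringsAsFactors = FALSE)
    }))
    if (is.null(sites))
      return(data.frame(sequence_id = character(), position = integer(),
                        loop_length = integer(), site_loop_position = integer(),
                        stem_length = integer(), stem_strength = numeric(),
                        tetranucleotide = character(), character = character(),
                        stringsAsFactors = FALSE))
  }
  missing_seq <- setdiff(unique(sites$sequence_id), names(seqs))
  if (length(missing_seq))
    abort(paste("reference sequence(s) missing:",
                paste(missing_seq, collapse = ", ")),
          "missing_reference_error")
  n <- nrow(sites)
  out <- data.frame(sequence_id = sites$sequence_id,
                    position = sites$position + 1L,
                    loop_length = NA_integer_, site_loop_position = NA_integer_,
                    stem_length = 0L, stem_strength = 0,
                    tetranucleotide = NA_character_, character = NA_character_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    s <- seqs[[sites$sequence_id[r]]]
    pos0 <- sites$position[r]
    hp <- windowed_hairpin(s, pos0, params, window)
    out$loop_length[r] <- hp$loop_length
    out$site_loop_position[r] <- hp$site_loop_position
    out$stem_length[r] <- hp$stem_length
    out$stem_strength[r] <- hp$stem_strength
    ctx <- tryCatch(tetranucleotide_context(s, pos0, alphabet),
                    apobecedit_error = function(e) NULL)
    if (!is.null(ctx)) {
      out$tetranucleotide[r] <- ctx$tetranucleotide
      out$character[r] <- ctx$character
    }
  }
  out
}

# best_hairpin on a +/- window substring around a site (0-based).
windowed_hairpin <- function(sequence, pos0, params, window) {
  n <- nchar(sequence)
  start0 <- max(0L, pos0 - as.integer(window))
  end0 <- min(n - 1L, pos0 + as.integer(window))
  best_hairpin(substr(sequence, start0 + 1L, end0 + 1L), pos0 - start0, params)
}

# 0-based positions of plus-strand TpC cytosines.
tpc_positions_plus <- function(sequence) {
  ch <- strsplit(toupper(render_alphabet(sequence, "DNA")), "", fixed = TRUE)[[1]]
  idx <- which(ch == "C")
  ok <- idx >= 2L
  ok[ok] <- ch[idx[ok] - 1L] == "T"
  idx[ok] - 1L
}

# 0-based positions of minus-strand TpC sites (G on the plus strand with a
# 3' A, i.e. TpC on the reverse complement).
tpc_positions_minus <- function(sequence) {
  ch <- strsplit(toupper(render_alphabet(sequence, "DNA")), "", fixed = TRUE)[[1]]
  idx <- which(ch == "G")
  ok <- idx <= length(ch) - 1L
  ok[ok] <- ch[idx[ok] + 1L] == "A"
  idx[ok] - 1L
}
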
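# Encode a nucleotide string as integer codes A=1, C=2, G=3, T=4, N=0.
# Lowercase input is accepted; any other character is an error.
seq_codes <- function(seq) {
  if (length(seq) != 1L || !is.character(seq)) stop("expected a single string")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  codes <- match(chars, c("A", "C", "G", "T", "N")) - 1L
  if (anyNA(codes))
    stop("sequence contains characters outside {A, C, G, T, N}")
  codes <- ifelse(codes == 4L, 0L, codes + 1L)
  codes
}

#' Reverse complement of a nucleotide string
#'
#' `N` maps to `N`. Vectorized over the input.
#'
#' @param seq character vector of sequences over `A, C, G, T, N`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

# All additive window scores of weight matrix W (width x 4) along integer
# codes, forward strand only. N (code 0) contributes na_value. Returns a
# numeric vector of length L - w + 1.
window_scores <- function(W, codes, na_value = 0) {
  w <- nrow(W)
  nwin <- length(codes) - w + 1L
  if (nwin < 1L) stop("sequence shorter than motif")
  acc <- numeric(nwin)
  for (j in seq_len(w)) {
    lut <- c(na_value, W[j, ])
    acc <- acc + lut[codes[j:(j + nwin - 1L)] + 1L]
  }
  acc
}

# reverse-complement a weight matrix: reverse positions, complement columns
revcomp_matrix <- function(W) W[rev(seq_len(nrow(W))), c(4L, 3L, 2L, 1L), drop = FALSE]

# Window scores on both strands in forward-sequence coordinates.
# Returns list(fwd = ..., rev = ...); rev[o] is the score of the reverse
# complement of the window starting at forward offset o.
both_strand_scores <- function(W, codes, na_value = 0) {
  list(fwd = window_scores(W, codes, na_value),
       rev = window_scores(revcomp_matrix(W), codes, na_value))
}

#' Best-hit score of a sequence
#'
#' The maximum additive log-odds window score over all offsets and both
#' strands. Ties are broken deterministically: the lowest offset wins, and
#' at equal offsets the `+` strand wins. `N` bases contribute weight 0.
#'
#' Offsets are 0-based starts on the input (forward) sequence; a `-` strand
#' hit starts at the forward-strand position of the window whose reverse
#' complement was matched.
#'
#' @param x a `pfm` or `pwm_scoring` object.
#' @param seq a nucleotide string of length at least the motif width.
#' @return A list of class `scan_hit` with `score`, `offset`, `strand`.
#' @export
best_hit <- function(x, seq) {
  sc <- as_scoring(x)
  codes <- seq_codes(seq)
  if (length(codes) < sc$width)
    stop("sequence shorter than motif (", length(codes), " < ", sc$width, ")")
  s <- both_strand_scores(sc$pwm, codes)
  m <- max(s$fwd, s$rev)
  # tie-break: lowest offset first, '+' before '-' at the same offset
  f_off <- which(s$fwd == m)
  r_off <- which(s$rev == m)
  best_f <- if (length(f_off)) min(f_off) else Inf
  best_r <- if (length(r_off)) min(r_off) else Inf
  if (best_f <= best_r) {
    hit <- list(score = m, offset = best_f - 1L, strand = "+")
  } else {
    hit <- list(score = m, offset = best_r - 1L, strand = "-")
  }
  structure(hit, class = "scan_hit")
}

#' @export
print.scan_hit <- function(x, ...) {
  cat(sprintf("<scan_hit> score %.6g at offset %d (%s)\n",
              x$score, x$offset, x$strand))
  invisible(x)
}

#' Sum-occupancy score of a sequence
#'
#' The sum, over all window offsets and both strands, of the emission
#' probability of the window under the pseudocounted PFM (the product of
#' per-position probabilities of the observed bases). `N` bases contribute
#' probability 0.25. Always strictly positive.
#'
#' @inheritParams best_hit
#' @return A single positive number.
#' @export
sum_occupancy <- function(x, seq) {
  sc <- as_scoring(x)
  codes <- seq_codes(seq)
  if (length(codes) < sc$width)
    stop("sequence shorter than motif (", length(codes), " < ", sc$width, ")")
  logp <- log(sc$pfm_pseudo)
  s <- both_strand_scores(logp, codes, na_value = log(0.25))
  sum(exp(s$fwd)) + sum(exp(s$rev))
}

#' Score a read with constant flanks attached
#'
#' Concatenates the last `flank_len` bases of the 5' constant flank and the
#' first `flank_len` bases of the 3' constant flank around the read before
#' applying `scorer`, so that binding sites overhanging the variable insert
#' into the constant library parts can be matched.
#'
#' @param scorer a function taking a single sequence and returning a score
#'   (e.g. a partially applied [best_hit()] or [sum_occupancy()]).
#' @param read the variable insert sequence.
#' @param flank5,flank3 constant flanking sequences adjacent to the insert;
#'   each must provide at least `flank_len` bases.
#' @param flank_len number of flanking bases appended on each side
#'   (default 20).
#' @return The scorer's value for the flank-extended sequence.
#' @export
score_with_flanks <- function(scorer, read, flank5, flank3, flank_len = 20L) {
  if (nchar(flank5) < flank_len)
    stop("5' flank shorter than ", flank_len, " bases")
  if (nchar(flank3) < flank_len)
    stop("3' flank shorter than ", flank_len, " bases")
  ext <- paste0(substr(flank5, nchar(flank5) - flank_len + 1L, nchar(flank5)),
                read,
                substr(flank3, 1L, flank_len))
  scorer(ext)
}

#' Score a set of sequences with a motif model
#'
#' Applies one of the two scanning modes to every sequence and returns a
#' tidy table. When `flank5`/`flank3` are supplied, each sequence is
#' extended by 20 bp of constant flank on both sides before scoring
#' (see [score_with_flanks()]).
#'
#' @param x a `pfm` or `pwm_scoring` object.
#' @param seqs character vector of sequences; names are used as sequence
#'   ids when present.
#' @param mode `"besthit"` (log-odds best window, reports offset/strand) or
#'   `"occupancy"` (sum-occupancy of the pseudocounted PFM).
#' @param flank5,flank3 optional constant flanks (see [score_with_flanks()]).
#' @param flank_len flank length appended on each side (default 20).
#' @return A data.frame with columns `tag`, `seq_id`, `score`, `offset`,
#'   `strand` (`offset`/`strand` are `NA` in occupancy mode).
#' @export
score_sequences <- function(x, seqs, mode = c("besthit", "occupancy"),
                            flank5 = NULL, flank3 = NULL, flank_len = 20L) {
  mode <- match.arg(mode)
  sc <- as_scoring(x)
  ids <- if (!is.null(names(seqs))) names(seqs) else paste0("seq", seq_along(seqs))
  if (!is.null(flank5) || !is.null(flank3)) {
    if (is.null(flank5) || is.null(flank3))
      stop("both flanks must be given, or neither")
    if (nchar(flank5) < flank_len) stop("5' flank shorter than ", flank_len, " bases")
    if (nchar(flank3) < flank_len) stop("3' flank shorter than ", flank_len, " bases")
    seqs <- paste0(substr(flank5, nchar(flank5) - flank_len + 1L, nchar(flank5)),
                   seqs, substr(flank3, 1L, flank_len))
  }
  if (mode == "besthit") {
    hits <- lapply(seqs, function(s) best_hit(sc, s))
    data.frame(tag = sc$tag, seq_id = ids,
               score = vapply(hits, `[[`, numeric(1L), "score"),
               offset = vapply(hits, `[[`, integer(1L), "offset"),
               strand = vapply(hits, `[[`, character(1L), "strand"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(tag = sc$tag, seq_id = ids,
               score = vapply(seqs, function(s) sum_occupancy(sc, s), numeric(1L),
                              USE.NAMES = FALSE),
               offset = NA_integer_, strand = NA_character_,
               stringsAsFactors = FALSE)
  }
}
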
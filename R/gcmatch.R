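#' GC content of sequences
#'
#' Fraction of `G`/`C` bases; `N` bases are excluded from the denominator.
#'
#' @param seqs character vector of nucleotide sequences.
#' @return Numeric vector in `[0, 1]`.
#' @export
gc_content <- function(seqs) {
  x <- Biostrings::DNAStringSet(toupper(seqs))
  gc <- Biostrings::letterFrequency(x, "GC")
  acgt <- Biostrings::letterFrequency(x, "ACGT")
  out <- as.vector(gc) / pmax(as.vector(acgt), 1L)
  out
}

# integer allocation proportional to weights, largest-remainder method
allocate_proportional <- function(weights, total) {
  if (sum(weights) == 0) return(integer(length(weights)))
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' GC-matched sampling
#'
#' Samples candidates so that the GC-content distribution of the sample
#' matches that of a reference set. Sequences are binned by GC fraction
#' (bin width 0.05 by default); the per-bin sample sizes are allocated
#' proportionally to the reference bin frequencies at a total of
#' `ratio * length(reference)`. Bins whose candidate pool is too small
#' borrow the deficit from the nearest non-exhausted bins, with a warning;
#' if the whole pool is smaller than the request, the achievable maximum
#' is returned with a warning.
#'
#' @param candidates candidate sequences (character) or their GC fractions
#'   (numeric in `[0, 1]`).
#' @param reference reference sequences or GC fractions whose distribution
#'   is to be matched.
#' @param ratio sample size as a multiple of the reference size (default 1).
#' @param bin_width GC bin width (default 0.05).
#' @param seed optional RNG seed; `NULL` uses the current RNG state.
#' @return Integer indices into `candidates` (without replacement).
#' @export
gc_match_sample <- function(candidates, reference, ratio = 1,
                            bin_width = 0.05, seed = NULL) {
  if (length(candidates) == 0L) stop("empty candidate set")
  if (length(reference) == 0L) stop("empty reference set")
  if (!is.null(seed)) set.seed(seed)
  gc_c <- if (is.numeric(candidates)) candidates else gc_content(candidates)
  gc_r <- if (is.numeric(reference)) reference else gc_content(reference)
  nb <- as.integer(ceiling(1 / bin_width))
  bin_of <- function(gc) pmin(floor(gc / bin_width) + 1L, nb)
  bc <- bin_of(gc_c)
  br <- bin_of(gc_r)
  total <- round(ratio * length(gc_r))
  if (total > length(gc_c)) {
    warning("candidate pool (", length(gc_c), ") smaller than requested ",
            total, "; returning the achievable maximum")
    total <- length(gc_c)
  }
  ref_counts <- tabulate(br, nb)
  avail <- tabulate(bc, nb)
  target <- allocate_proportional(ref_counts, total)
  # resolve deficits by borrowing from the nearest bins with spare candidates
  deficit <- pmax(target - avail, 0L)
  target <- pmin(target, avail)
  if (any(deficit > 0L)) {
    warning("GC bins with insufficient candidates; borrowing ",
            sum(deficit), " draws from nearest bins")
    for (b in which(deficit > 0L)) {
      need <- deficit[b]
      for (d in seq_len(nb - 1L)) {
        if (need == 0L) break
        for (nb2 in c(b - d, b + d)) {
          if (need == 0L || nb2 < 1L || nb2 > nb) next
          spare <- avail[nb2] - target[nb2]
          take <- min(spare, need)
          if (take > 0L) {
            target[nb2] <- target[nb2] + take
            need <- need - take
          }
        }
      }
    }
  }
  idx <- integer(0)
  for (b in which(target > 0L)) {
    pool <- which(bc == b)
    idx <- c(idx, pool[sample.int(length(pool), target[b])])
  }
  sort(idx)
}
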
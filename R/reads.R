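# Read-based benchmark construction (HT-SELEX and SMiLE-Seq).

#' Deduplicate and disambiguate SELEX reads
#'
#' Applies the leakage-prevention rules for read-based benchmarks:
#' duplicate reads within each cycle are removed; reads appearing in two or
#' more cycles are removed from all of them (ambiguous cycle attribution);
#' and, when read pools of other TFs are supplied, reads present in any of
#' those pools are removed as well (they cannot be unambiguously attributed
#' to one TF). The operation is idempotent and order-invariant.
#'
#' @param cycles named list of character vectors of reads, one element per
#'   SELEX cycle (names are cycle numbers; `"0"` is the input library).
#' @param other_tf_pools optional list of character vectors: read pools of
#'   other TFs.
#' @return Cleaned list with the same names.
#' @export
clean_reads <- function(cycles, other_tf_pools = NULL) {
  stopifnot(is.list(cycles), length(cycles) >= 1L)
  cycles <- lapply(cycles, unique)
  all_reads <- unlist(cycles, use.names = FALSE)
  multi <- unique(all_reads[duplicated(all_reads)])
  if (length(multi))
    cycles <- lapply(cycles, function(x) x[!(x %in% multi)])
  if (!is.null(other_tf_pools)) {
    other <- unique(unlist(other_tf_pools, use.names = FALSE))
    cycles <- lapply(cycles, function(x) x[!(x %in% other)])
  }
  if (all(lengths(cycles) == 0L))
    warning("all reads removed by deduplication")
  cycles
}

#' Sample positive reads per cycle
#'
#' Draws an equal number of reads from every cycle: the per-cycle count is
#' the minimum cycle size, capped at `cap` (100,000 by default, matching
#' the benchmark's per-cycle subset size). Sampling is without replacement;
#' cycle labels are retained for the cycle-regression metric.
#'
#' @param cycles cleaned cycle list (see [clean_reads()]); names must be
#'   parseable as cycle numbers.
#' @param cap per-cycle cap (default 100000).
#' @param seed optional RNG seed.
#' @param tf TF id stored alongside (default `"TF1"`).
#' @return data.frame with `tag`, `seq`, `cycle`, `label = 1`.
#' @export
build_read_positives <- function(cycles, cap = 100000L, seed = NULL,
                                 tf = "TF1") {
  if (length(cycles) == 0L) stop("no cycles given")
  if (is.null(names(cycles))) names(cycles) <- seq_along(cycles)
  if (!is.null(seed)) set.seed(seed)
  n <- min(cap, min(lengths(cycles)))
  if (n == 0L) stop("a cycle has no reads left after cleaning")
  recs <- lapply(names(cycles), function(cy) {
    pool <- cycles[[cy]]
    take <- pool[sample.int(length(pool), n)]
    data.frame(seq = take, cycle = as.integer(cy), label = 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$tag <- sprintf("%s_pos%06d", tf, seq_len(nrow(out)))
  out[, c("tag", "seq", "cycle", "label")]
}

#' Sample GC-matched negative reads
#'
#' Negatives come from the input (zero-cycle) library or from "alien" read
#' pools of non-related TFs. Reads identical to any positive are excluded
#' before sampling; the sample is GC-matched to the positives and sized
#' `ratio` times the positive count (2 for HT-SELEX, 5 for SMiLE-Seq).
#' Negatives carry cycle label 0.
#'
#' @param positives data.frame from [build_read_positives()].
#' @param pool character vector of candidate negative reads.
#' @param ratio negatives per positive (2 = HT-SELEX, 5 = SMiLE-Seq).
#' @param seed optional RNG seed.
#' @param bin_width GC bin width for matching (default 0.05).
#' @param kind negative-set kind stored in tags (`"input"` or `"alien"`).
#' @return data.frame with `tag`, `seq`, `cycle = 0`, `label = 0`.
#' @export
build_read_negatives <- function(positives, pool, ratio = 2, seed = NULL,
                                 bin_width = 0.05, kind = "input") {
  if (!is.null(seed)) set.seed(seed)
  pool <- unique(pool)
  pool <- pool[!(pool %in% positives$seq)]
  if (length(pool) == 0L) stop("no negative candidates remain")
  idx <- gc_match_sample(pool, positives$seq, ratio = ratio,
                         bin_width = bin_width)
  data.frame(tag = sprintf("%s_neg%06d", kind, seq_along(idx)),
             seq = pool[idx], cycle = 0L, label = 0L,
             stringsAsFactors = FALSE)
}
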
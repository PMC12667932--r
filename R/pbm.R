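# Protein-binding microarray normalization and labeling.
#
# A PBM array is a data.frame with columns probe_id, seq, raw_intensity,
# row, col ((row, col) = position on the array grid).

check_pbm <- function(df, need_grid = FALSE) {
  need <- c("probe_id", "seq", "raw_intensity")
  if (need_grid) need <- c(need, "row", "col")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("PBM table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$raw_intensity < 0)) stop("negative probe intensity")
  if (anyDuplicated(df[c("row", "col")]) && need_grid)
    stop("duplicated (row, col) grid coordinates")
  invisible(df)
}

#' Normalize PBM probe intensities
#'
#' Two normalization modes:
#' \describe{
#'   \item{`"QNZS"`}{log10-transform, quantile-normalize across arrays
#'     (all arrays end up with identical sorted value vectors), then
#'     per-probe Z-score with mean and sd taken across arrays. Requires at
#'     least two arrays of identical probe design.}
#'   \item{`"SD"`}{spatial detrending: log10 intensity minus the median of
#'     the 11x11 grid window centered on the probe (windows truncated at
#'     array edges). Removes smooth spatial artifacts of the array surface.
#'     Requires grid coordinates.}
#' }
#'
#' @param arrays list of PBM data.frames (`probe_id`, `seq`,
#'   `raw_intensity`, and for SD mode `row`, `col`).
#' @param mode `"QNZS"` or `"SD"`.
#' @param window SD window side length (default 11; must be odd).
#' @return The input list with a `normalized_value` column added to every
#'   array.
#' @export
normalize_pbm <- function(arrays, mode = c("QNZS", "SD"), window = 11L) {
  mode <- match.arg(mode)
  if (mode == "QNZS") {
    if (length(arrays) < 2L)
      stop("QNZS requires at least two arrays (per-probe Z undefined)")
    lapply(arrays, check_pbm)
    ids <- arrays[[1L]]$probe_id
    for (a in arrays[-1L])
      if (!identical(sort(a$probe_id), sort(ids)))
        stop("QNZS requires arrays of identical probe design")
    mat <- vapply(arrays, function(a)
      log10(a$raw_intensity[match(ids, a$probe_id)]), numeric(length(ids)))
    qn <- limma::normalizeQuantiles(mat)
    mu <- rowMeans(qn)
    sdv <- apply(qn, 1L, stats::sd)
    z <- (qn - mu) / ifelse(sdv > 0, sdv, 1)
    for (k in seq_along(arrays)) {
      ord <- match(arrays[[k]]$probe_id, ids)
      arrays[[k]]$normalized_value <- z[ord, k]
    }
    arrays
  } else {
    if (window %% 2L != 1L) stop("SD window must be odd")
    half <- (window - 1L) %/% 2L
    lapply(arrays, function(a) {
      check_pbm(a, need_grid = TRUE)
      v <- log10(a$raw_intensity)
      nr <- max(a$row); nc <- max(a$col)
      grid <- matrix(NA_real_, nr, nc)
      grid[cbind(a$row, a$col)] <- v
      med <- numeric(nrow(a))
      for (i in seq_len(nrow(a))) {
        r <- a$row[i]; cl <- a$col[i]
        block <- grid[max(1L, r - half):min(nr, r + half),
                      max(1L, cl - half):min(nc, cl + half)]
        med[i] <- stats::median(block, na.rm = TRUE)
      }
      a$normalized_value <- v - med
      a
    })
  }
}

#' Call positive PBM probes
#'
#' In SD mode a probe is positive when its detrended value exceeds the
#' array mean plus 4 standard deviations; in QNZS mode when its Z-score
#' exceeds 4. If fewer than 50 probes pass, the top 50 probes by value are
#' taken instead (ties broken by value then probe id, deterministically).
#'
#' @param array a PBM data.frame with `normalized_value`
#'   (see [normalize_pbm()]).
#' @param mode `"QNZS"` or `"SD"` (determines the threshold rule).
#' @param min_positives minimal positive count (default 50).
#' @return The input data.frame with a logical `positive` column.
#' @export
call_pbm_positives <- function(array, mode = c("QNZS", "SD"),
                               min_positives = 50L) {
  mode <- match.arg(mode)
  if (is.null(array$normalized_value)) stop("normalize the array first")
  v <- array$normalized_value
  if (length(v) < min_positives)
    stop("fewer than ", min_positives, " probes on the array")
  thr <- if (mode == "SD") mean(v) + 4 * stats::sd(v) else 4
  pos <- v > thr
  if (sum(pos) < min_positives) {
    ord <- order(-v, array$probe_id)
    pos <- logical(length(v))
    pos[ord[seq_len(min_positives)]] <- TRUE
  }
  array$positive <- pos
  array
}

#' Sample GC-matched PBM negatives
#'
#' A random GC-matched sample of non-positive probes at `ratio` negatives
#' per positive (default 10).
#'
#' @param array PBM data.frame with a `positive` column
#'   (see [call_pbm_positives()]).
#' @param ratio negatives per positive (default 10).
#' @param seed optional RNG seed.
#' @param bin_width GC bin width (default 0.05).
#' @return The input data.frame with an integer `label` column: 1 for
#'   positives, 0 for sampled negatives, `NA` for unused probes.
#' @export
sample_pbm_negatives <- function(array, ratio = 10, seed = NULL,
                                 bin_width = 0.05) {
  if (is.null(array$positive)) stop("call positives first")
  if (!is.null(seed)) set.seed(seed)
  pos_idx <- which(array$positive)
  cand_idx <- which(!array$positive)
  if (length(cand_idx) == 0L) stop("no negative candidates")
  sel <- gc_match_sample(array$seq[cand_idx], array$seq[pos_idx],
                         ratio = ratio, bin_width = bin_width)
  array$label <- NA_integer_
  array$label[pos_idx] <- 1L
  array$label[cand_idx[sel]] <- 0L
  array
}
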
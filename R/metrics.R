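#' Classification metrics: AUROC and AUPRC
#'
#' AUROC is the probability that a random positive outscores a random
#' negative, counting ties as one half (equivalently the trapezoidal ROC
#' area, computed via the rank-sum identity). AUPRC uses the continuous
#' precision interpolation of Davis & Goadrich: between adjacent score
#' thresholds the false-positive count is interpolated linearly in the
#' true-positive count and the precision integral is evaluated in closed
#' form.
#'
#' @param score numeric prediction scores (higher = more positive).
#' @param label binary labels, 1 = positive, 0 = negative.
#' @return A list with `auroc`, `auprc`, `n_pos`, `n_neg`.
#' @export
classification_scores <- function(score, label) {
  stopifnot(length(score) == length(label))
  if (anyNA(score) || anyNA(label)) stop("missing values in scores or labels")
  label <- as.integer(label)
  n_pos <- sum(label == 1L)
  n_neg <- sum(label == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present (", n_pos, " positives, ",
         n_neg, " negatives)")
  r <- rank(score)
  auroc <- (sum(r[label == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(auroc = auroc, auprc = auprc_dg(score, label),
       n_pos = n_pos, n_neg = n_neg)
}

# Davis-Goadrich continuous AUPRC.
# Walk thresholds from the highest score down; at each distinct score the
# cumulative (TP, FP) gives one PR point. Between points, FP is linear in
# TP and  integral TP/((1+s) TP + c) dTP  has the closed form
# TP/(1+s) - c/(1+s)^2 * log((1+s) TP + c),  s = dFP/dTP, c = FP_a - s TP_a.
auprc_dg <- function(score, label) {
  ord <- order(score, decreasing = TRUE)
  lab <- as.integer(label)[ord]
  sc <- score[ord]
  keep <- !duplicated(sc, fromLast = TRUE)   # last index of each tie group
  tp <- cumsum(lab)[keep]
  fp <- (cumsum(1L - lab))[keep]
  P <- sum(lab)
  tp <- c(0, tp); fp <- c(0, fp)
  area <- 0
  for (i in seq_len(length(tp) - 1L)) {
    dtp <- tp[i + 1L] - tp[i]
    if (dtp == 0) next
    s <- (fp[i + 1L] - fp[i]) / dtp
    cc <- fp[i] - s * tp[i]
    Fv <- function(t) {
      if (abs(cc) < 1e-12) t / (1 + s)
      else t / (1 + s) - cc / (1 + s)^2 * log((1 + s) * t + cc)
    }
    a <- if (tp[i] == 0 && fp[i] == 0 && abs(cc) < 1e-12) {
      # segment from the origin: constant precision dtp/(dtp + dfp)
      dtp * (dtp / (dtp + s * dtp))
    } else if (tp[i] == 0 && abs(cc) >= 1e-12) {
      Fv(tp[i + 1L]) - Fv(0)
    } else {
      Fv(tp[i + 1L]) - Fv(tp[i])
    }
    area <- area + a
  }
  area / P
}

#' Mean top-fraction AUROC and AUPRC
#'
#' For each fraction `f`, the top `ceiling(f * n)` positives and the top
#' `ceiling(f * n)` negatives by score are selected independently and
#' AUROC/AUPRC recomputed on the union; the reported values are the
#' arithmetic means over the fractions. This focuses the comparison on the
#' high-affinity end where in-vitro selection assays are informative.
#'
#' @inheritParams classification_scores
#' @param fractions fractions of each class to keep (default
#'   `c(1, 0.5, 0.25)`).
#' @param tag optional ids used for deterministic tie-breaking when
#'   selecting top records.
#' @return A list with `mauroc`, `mauprc`, `by_fraction` (data.frame),
#'   `n_pos`, `n_neg`.
#' @export
mean_topk_scores <- function(score, label, fractions = c(1, 0.5, 0.25),
                             tag = NULL) {
  label <- as.integer(label)
  if (is.null(tag)) tag <- sprintf("s%09d", seq_along(score))
  pos <- which(label == 1L)
  neg <- which(label == 0L)
  if (length(pos) == 0L || length(neg) == 0L) stop("both classes must be present")
  pos <- pos[order(-score[pos], tag[pos])]
  neg <- neg[order(-score[neg], tag[neg])]
  per <- lapply(fractions, function(f) {
    kp <- ceiling(f * length(pos))
    kn <- ceiling(f * length(neg))
    if (kp == 0L || kn == 0L)
      stop("fraction ", f, " leaves an empty class")
    idx <- c(pos[seq_len(kp)], neg[seq_len(kn)])
    cs <- classification_scores(score[idx], label[idx])
    data.frame(fraction = f, auroc = cs$auroc, auprc = cs$auprc)
  })
  by_fraction <- do.call(rbind, per)
  list(mauroc = mean(by_fraction$auroc), mauprc = mean(by_fraction$auprc),
       by_fraction = by_fraction,
       n_pos = length(pos), n_neg = length(neg))
}

#' Kendall rank correlation with tie correction
#'
#' Tau-b between model scores and SELEX cycle numbers:
#' `(C - D) / sqrt((n0 - n1)(n0 - n2))` with the standard tie terms.
#' Computed on the positive reads (cycles >= 1); when several experimental
#' replicates exist the caller averages per-replicate values.
#'
#' @param score numeric model scores.
#' @param cycle integer cycle labels.
#' @return Tau-b in `[-1, 1]`.
#' @export
kendall_tau_b <- function(score, cycle) {
  stopifnot(length(score) == length(cycle))
  if (length(score) < 2L) stop("need at least two records")
  if (length(unique(cycle)) < 2L)
    stop("tau-b undefined: all cycle labels identical")
  stats::cor(score, cycle, method = "kendall")
}

#' Log2-odds normalized performance score
#'
#' Compares a bounded metric value against a reference value of the same
#' metric on the same data: `log2(m/(1-m)) - log2(r/(1-r))`. Positive
#' values mean the model improves on the reference. Values at the bounds
#' are clamped to `[1e-6, 1 - 1e-6]` so the score stays finite.
#'
#' @param metric metric value(s) in `[0, 1]`.
#' @param reference reference value(s) in `[0, 1]`.
#' @return Numeric vector of normalized scores.
#' @export
normalized_log2_odds <- function(metric, reference) {
  if (anyNA(metric) || anyNA(reference)) stop("missing metric values")
  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  m <- clamp(metric); r <- clamp(reference)
  log2(m / (1 - m)) - log2(r / (1 - r))
}
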
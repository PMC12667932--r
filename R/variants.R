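#' Score a variant with a PWM on both alleles
#'
#' For each allele, the best-hit log-odds score is taken over both strands
#' among the windows overlapping the variant position only (the central
#' `2*width - 1` bp of the context), computed on the integer weight grid.
#' Scores are converted to exact P-values under the uniform background;
#' the predicted allelic preference follows the sign of
#' `effect = log10(p_alt / p_ref)` (positive: the alternative allele scores
#' worse, i.e. binding prefers Ref).
#'
#' @param x a `pfm` or `pwm_scoring` object.
#' @param context sequence centered on the variant (odd length; the variant
#'   base is at the central position). The benchmark convention is 301 bp.
#' @param ref,alt single reference/alternative bases; `context` must carry
#'   `ref` at its center.
#' @param dist optional precomputed [pwm_score_distribution()] (reused
#'   across variants of the same motif).
#' @return A list with `p_ref`, `p_alt`, `selection_score`
#'   (`-log10(min(p_ref, p_alt))`), `effect` (`log10(p_alt / p_ref)`), and
#'   `predicted_pref` (`"Ref"`, `"Alt"`, or `"tie"`).
#' @export
score_variant_pwm <- function(x, context, ref, alt, dist = NULL) {
  sc <- as_scoring(x)
  w <- sc$width
  n <- nchar(context)
  if (n %% 2L == 0L) stop("variant context must have odd length")
  center <- (n + 1L) %/% 2L
  if (toupper(substr(context, center, center)) != toupper(ref))
    stop("reference base mismatch: context has '",
         substr(context, center, center), "', expected '", ref, "'")
  if (center - w < 0L || center + w - 1L > n)
    stop("context too short for motif width ", w)
  if (is.null(dist)) dist <- pwm_score_distribution(sc)

  allele_p <- function(base) {
    s <- context
    substr(s, center, center) <- toupper(base)
    win <- substr(s, center - w + 1L, center + w - 1L)
    codes <- seq_codes(win)
    both <- both_strand_scores(sc$ipwm, codes)
    s_int <- max(both$fwd, both$rev)
    tail_prob(dist, floor(s_int / dist$scale))
  }
  p_ref <- allele_p(ref)
  p_alt <- allele_p(alt)
  effect <- log10(p_alt) - log10(p_ref)
  list(p_ref = p_ref, p_alt = p_alt,
       selection_score = -log10(min(p_ref, p_alt)),
       effect = effect,
       predicted_pref = if (effect > 0) "Ref" else if (effect < 0) "Alt" else "tie")
}

#' Score a table of variants with a PWM
#'
#' Vectorized driver over a variant table; the score distribution is
#' computed once and shared.
#'
#' @param x a `pfm` or `pwm_scoring` object.
#' @param variants data.frame with columns `context`, `ref`, `alt` and
#'   optionally `variant_id` and `observed_pref`.
#' @return The input table with columns `p_ref`, `p_alt`,
#'   `selection_score`, `effect`, `predicted_pref` appended.
#' @export
score_variants <- function(x, variants) {
  sc <- as_scoring(x)
  stopifnot(all(c("context", "ref", "alt") %in% names(variants)))
  dist <- pwm_score_distribution(sc)
  res <- lapply(seq_len(nrow(variants)), function(i)
    score_variant_pwm(sc, variants$context[i], variants$ref[i],
                      variants$alt[i], dist = dist))
  variants$p_ref <- vapply(res, `[[`, numeric(1L), "p_ref")
  variants$p_alt <- vapply(res, `[[`, numeric(1L), "p_alt")
  variants$selection_score <- vapply(res, `[[`, numeric(1L), "selection_score")
  variants$effect <- vapply(res, `[[`, numeric(1L), "effect")
  variants$predicted_pref <- vapply(res, `[[`, character(1L), "predicted_pref")
  variants
}

#' Area under the concordance curve
#'
#' Variants are sorted by decreasing selection score (stable; ties broken
#' by `tag`). For each prefix of the sorted list the concordant fraction is
#' the share of variants whose predicted allelic preference matches the
#' observed one (`"tie"` predictions count one half). The AUC is the
#' trapezoidal integral of the concordant fraction over the hit fraction
#' `k/n` on `(0, 1]`, so it is bounded in `[0, 1]`; 0.5 is the expectation
#' for random predictions and 1 is perfect performance.
#'
#' @param selection_score numeric vector (higher = stronger predicted site).
#' @param predicted_pref,observed_pref character vectors over
#'   `"Ref"`/`"Alt"` (`predicted_pref` may contain `"tie"`).
#' @param tag optional ids used for deterministic tie-breaking.
#' @return A list of class `concordance_result` with `auc`, `n_variants`,
#'   and `curve` (data.frame with `hits`, `hit_fraction`,
#'   `concordant_fraction`).
#' @export
concordance_auc <- function(selection_score, predicted_pref, observed_pref,
                            tag = NULL) {
  n <- length(selection_score)
  if (n == 0L) stop("no variants")
  stopifnot(length(predicted_pref) == n, length(observed_pref) == n)
  if (is.null(tag)) tag <- sprintf("v%09d", seq_len(n))
  ord <- order(-selection_score, tag)
  conc <- ifelse(predicted_pref[ord] == "tie", 0.5,
                 as.numeric(predicted_pref[ord] == observed_pref[ord]))
  y <- cumsum(conc) / seq_len(n)
  # first segment (0, 1/n] as a rectangle at y[1], then trapezoids
  auc <- if (n == 1L) y[1L] else
    (y[1L] + sum((y[-1L] + y[-n]) / 2)) / n
  structure(list(auc = auc, n_variants = n,
                 curve = data.frame(hits = seq_len(n),
                                    hit_fraction = seq_len(n) / n,
                                    concordant_fraction = y)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> AUC %.4f over %d variants\n",
              x$auc, x$n_variants))
  invisible(x)
}

#' Variant-count-weighted mean concordance AUC
#'
#' Global per-team estimate across TFs: the mean of per-TF AUCs weighted by
#' the number of tested variants.
#'
#' @param auc numeric vector of per-TF AUCs.
#' @param n_variants integer vector of per-TF variant counts.
#' @return A single number.
#' @export
weighted_mean_auc <- function(auc, n_variants) {
  stopifnot(length(auc) == length(n_variants))
  if (sum(n_variants) == 0) stop("total variant count is zero")
  sum(auc * n_variants) / sum(n_variants)
}
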
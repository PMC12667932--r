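#' Exact PWM score distribution under the uniform background
#'
#' Computes the full distribution of the additive word score of a PWM for a
#' uniform-random word of the motif width, on the integer weight grid (each
#' weight truncated to 5 decimals and scaled by 1e5). The distribution is
#' built by position-wise convolution over distinct achievable scores, so it
#' is exact on the grid.
#'
#' For wide matrices the number of distinct sums approaches `4^width`; when
#' it would exceed `max_states` the grid is coarsened by powers of 10
#' (weights floored on the coarser grid) to keep the convolution tractable.
#' The result records the grid `scale` actually used.
#'
#' @param x a `pfm` or `pwm_scoring` object.
#' @param max_states upper bound on the number of distinct score states
#'   before grid coarsening kicks in (default `4^12`).
#' @return A list of class `pwm_score_dist` with `scores` (ascending integer
#'   grid scores), `tailp` (`P(S >= scores[i])`), and `scale`.
#' @export
pwm_score_distribution <- function(x, max_states = 4^12) {
  sc <- as_scoring(x)
  iw <- sc$ipwm
  w <- nrow(iw)
  scale <- 1
  # coarsen by 10 until the worst-case state count is acceptable
  n_states_bound <- function(m) {
    # upper bound: product over rows of distinct values, capped at range
    prod_cap <- 1
    for (i in seq_len(nrow(m))) {
      prod_cap <- prod_cap * length(unique(m[i, ]))
      if (prod_cap > max_states) return(Inf)
    }
    prod_cap
  }
  m <- iw
  while (!is.finite(n_states_bound(m)) && scale < 1e6) {
    scale <- scale * 10
    m <- floor(iw / scale)
  }
  scores <- 0
  probs <- 1
  for (i in seq_len(w)) {
    s_new <- rep(scores, times = 4L) + rep(m[i, ], each = length(scores))
    p_new <- rep(probs, times = 4L) * 0.25
    ord <- order(s_new)
    s_o <- s_new[ord]
    p_o <- p_new[ord]
    grp <- cumsum(c(TRUE, diff(s_o) != 0))
    scores <- s_o[!duplicated(grp)]
    probs <- as.vector(rowsum(p_o, grp))
  }
  tailp <- rev(cumsum(rev(probs)))
  structure(list(scores = scores, tailp = tailp, scale = scale, width = w),
            class = "pwm_score_dist")
}

# P(S >= t_grid) for an integer grid score t_grid on the distribution's grid
tail_prob <- function(dist, t_grid) {
  i <- findInterval(t_grid - 0.5, dist$scores) + 1L
  if (i > length(dist$scores)) return(0)
  dist$tailp[i]
}

#' Exact PWM P-value of a score threshold
#'
#' `P(word score >= threshold)` for a uniform-random word of the motif
#' width. The threshold (a real-valued log-odds score) is mapped to the
#' integer weight grid by flooring; the tail probability is exact on that
#' grid.
#'
#' @param x a `pfm` or `pwm_scoring` object, or a precomputed
#'   [pwm_score_distribution()].
#' @param threshold score threshold on the log-odds scale of [best_hit()].
#' @return P-value in `[0, 1]`.
#' @export
pwm_pvalue <- function(x, threshold) {
  dist <- if (inherits(x, "pwm_score_dist")) x else pwm_score_distribution(x)
  if (!is.finite(threshold)) stop("threshold must be finite")
  t_int <- floor(threshold * 1e5 + 1e-9)
  tail_prob(dist, floor(t_int / dist$scale))
}
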
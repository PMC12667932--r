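# Fixture builders and independent brute-force oracles used across tests.

# a PFM putting probability 1 on the given consensus word
consensus_pfm <- function(word, tag = word) {
  bases <- strsplit(word, "")[[1]]
  m <- matrix(0, length(bases), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(bases), match(bases, colnames(m)))] <- 1
  new_pfm(m, tag = tag, normalize = FALSE)
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# exhaustive best-hit oracle: loops over every window and both strands
oracle_best_hit <- function(W, seq) {
  w <- nrow(W)
  chars <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  best <- -Inf
  for (off in 0:(length(chars) - w)) {
    win <- chars[(off + 1):(off + w)]
    rc <- rev(unname(comp[win]))
    sf <- sum(vapply(seq_len(w), function(j)
      if (win[j] == "N") 0 else W[j, win[j]], numeric(1)))
    sr <- sum(vapply(seq_len(w), function(j)
      if (rc[j] == "N") 0 else W[j, rc[j]], numeric(1)))
    best <- max(best, sf, sr)
  }
  best
}

# exhaustive sum-occupancy oracle
oracle_occupancy <- function(P, seq) {
  w <- nrow(P)
  chars <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  tot <- 0
  for (off in 0:(length(chars) - w)) {
    win <- chars[(off + 1):(off + w)]
    rc <- rev(unname(comp[win]))
    pf <- prod(vapply(seq_len(w), function(j)
      if (win[j] == "N") 0.25 else P[j, win[j]], numeric(1)))
    pr <- prod(vapply(seq_len(w), function(j)
      if (rc[j] == "N") 0.25 else P[j, rc[j]], numeric(1)))
    tot <- tot + pf + pr
  }
  tot
}

# enumerate all 4^w words: exact tail probability of the integer-grid score
oracle_pvalue <- function(ipwm, t_grid) {
  w <- nrow(ipwm)
  words <- expand.grid(rep(list(1:4), w))
  scores <- rowSums(vapply(seq_len(w), function(j) ipwm[j, words[[j]]],
                           numeric(nrow(words))))
  mean(scores >= t_grid)
}

# AUROC by pair counting (ties count one half)
oracle_auroc <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# Kendall tau-b by O(n^2) pair counting with tie terms
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# numeric AUPRC oracle: fine subdivision of each TP segment with FP linear
# in TP (independent of the closed-form implementation)
oracle_auprc <- function(score, label, steps = 2000) {
  ord <- order(score, decreasing = TRUE)
  lab <- label[ord]; sc <- score[ord]
  keep <- !duplicated(sc, fromLast = TRUE)
  tp <- c(0, cumsum(lab)[keep])
  fp <- c(0, cumsum(1 - lab)[keep])
  P <- sum(lab)
  area <- 0
  for (i in seq_len(length(tp) - 1)) {
    dtp <- tp[i + 1] - tp[i]
    if (dtp == 0) next
    tt <- seq(tp[i], tp[i + 1], length.out = steps + 1)
    ff <- fp[i] + (tt - tp[i]) / dtp * (fp[i + 1] - fp[i])
    prec <- ifelse(tt + ff > 0, tt / (tt + ff), 1)
    area <- area + sum((prec[-1] + prec[-length(prec)]) / 2 * diff(tt))
  }
  area / P
}

# small deterministic metric table for ranking tests
toy_metric_table <- function(teams = c("alpha", "beta", "gamma"),
                             tfs = c("TF1", "TF2"),
                             platforms = "CHS",
                             metrics = c("auroc", "auprc"),
                             negative_kinds = c("shades", "random"),
                             values = NULL, seed = 1) {
  set.seed(seed)
  g <- expand.grid(team = teams, tf = tfs, platform = platforms,
                   negative_kind = negative_kinds, metric = metrics,
                   stringsAsFactors = FALSE)
  g$submission <- "s1"
  g$value <- if (is.null(values)) round(runif(nrow(g)), 3) else values
  g
}
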
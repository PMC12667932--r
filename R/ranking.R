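# Hierarchical rank aggregation of benchmark results into team rankings.
#
# A metric table is a data.frame with columns team, submission, tf,
# platform, negative_kind, metric, value; (team, submission, tf, platform,
# negative_kind, metric) is unique. A "benchmark" is one negative_kind x
# metric combination for a platform.

#' Rank values with averaged ties
#'
#' Dense 1..N ranks; tied values receive the mean of their positions.
#'
#' @param values numeric vector.
#' @param higher_is_better if `TRUE` (default) the largest value gets
#'   rank 1.
#' @return Numeric vector of ranks.
#' @export
rank_with_ties <- function(values, higher_is_better = TRUE) {
  if (length(values) == 0L) stop("no values to rank")
  if (anyNA(values)) stop("NA/NaN values cannot be ranked")
  if (higher_is_better) rank(-values, ties.method = "average")
  else rank(values, ties.method = "average")
}

#' Log-normalized ranking score
#'
#' The aggregation score `sum(-log(r / (N + 1)))` over a vector of ranks,
#' where `N` is the number of competing solutions. Every term is positive
#' and strictly decreasing in the rank, so improving any single rank
#' strictly increases the score. Natural logarithm (the base only rescales
#' scores and cannot change an ordering).
#'
#' @param ranks numeric ranks in `[1, N]`.
#' @param N total number of competing solutions.
#' @return A single number; larger is better.
#' @export
lognorm_score <- function(ranks, N) {
  if (any(ranks < 1 | ranks > N)) stop("ranks must lie in [1, N]")
  sum(-log(ranks / (N + 1)))
}

#' Hierarchically aggregate a metric table into team ranks
#'
#' Four-level aggregation:
#' \enumerate{
#'   \item submissions are ranked within each (platform, TF, benchmark)
#'     cell, where a benchmark is one negative-set kind x metric pair;
#'   \item per (platform, TF), each submission's ranks are combined with
#'     [lognorm_score()] across that platform's benchmarks and the
#'     submissions re-ranked;
#'   \item per (platform, TF), each team's best submission is identified
#'     and the teams re-ranked;
#'   \item per team, the (platform, TF) ranks are combined with
#'     [lognorm_score()] (equal weight per cell) and re-ranked into the
#'     overall order.
#' }
#' A submission absent from a benchmark it was expected in is assigned the
#' lowest possible rank (`N`, the number of competing submissions) there;
#' rows with `NA` values (e.g. injected by [penalize_missing()]) are
#' treated the same way.
#'
#' @param table metric table (see above). A `submission` column is optional;
#'   a single submission per team is assumed when absent.
#' @return A list of class `mb_ranking` with data.frames `benchmark`,
#'   `experiment_tf`, `team_tf`, and `overall` (each carrying scores and
#'   tie-averaged ranks).
#' @export
hierarchical_aggregate <- function(table) {
  if (is.null(table) || nrow(table) == 0L) stop("empty metric table")
  dt <- data.table::as.data.table(table)
  if (!"submission" %in% names(dt)) dt[, submission := "s1"]
  need <- c("team", "submission", "tf", "platform", "negative_kind",
            "metric", "value")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("metric table missing column(s): ",
                         paste(miss, collapse = ", "))
  dt[, bench := paste(negative_kind, metric, sep = ":")]
  dt[, sol := paste(team, submission, sep = "\r")]
  sols <- unique(dt[, .(sol, team, submission)])
  N <- nrow(sols)
  # complete the (platform, tf, bench) x solution grid; absences rank N
  grid <- unique(dt[, .(platform, tf, bench)])
  full <- grid[, .(sol = sols$sol), by = .(platform, tf, bench)]
  full <- merge(full, sols, by = "sol")
  full <- merge(full, dt[, .(platform, tf, bench, sol, value)],
                by = c("platform", "tf", "bench", "sol"), all.x = TRUE)
  full[, r1 := NA_real_]
  full[!is.na(value),
       r1 := rank(-value, ties.method = "average"),
       by = .(platform, tf, bench)]
  full[is.na(value), r1 := N]
  # level 2: lognorm across benchmarks, re-rank within (platform, tf)
  l2 <- full[, .(score = sum(-log(r1 / (N + 1)))),
             by = .(platform, tf, sol, team, submission)]
  l2[, r2 := rank(-score, ties.method = "average"), by = .(platform, tf)]
  # level 3: best submission per team, re-rank teams within (platform, tf)
  l3 <- l2[, .(score = max(score)), by = .(platform, tf, team)]
  Tn <- length(unique(sols$team))
  l3[, r3 := rank(-score, ties.method = "average"), by = .(platform, tf)]
  # level 4: lognorm across (platform, tf) cells, overall re-rank
  l4 <- l3[, .(score = sum(-log(r3 / (Tn + 1)))), by = .(team)]
  l4[, r4 := rank(-score, ties.method = "average")]
  bench_out <- as.data.frame(
    full[, .(platform, tf, benchmark = bench, team, submission,
             value, rank = r1)])
  structure(list(
    benchmark = bench_out[order(bench_out$platform, bench_out$tf,
                                bench_out$benchmark, bench_out$rank), ],
    experiment_tf = as.data.frame(
      l2[order(platform, tf, r2),
         .(platform, tf, team, submission, score, rank = r2)]),
    team_tf = as.data.frame(
      l3[order(platform, tf, r3), .(platform, tf, team, score, rank = r3)]),
    overall = as.data.frame(l4[order(r4), .(team, score, rank = r4)]),
    n_solutions = N, n_teams = Tn), class = "mb_ranking")
}

#' @export
print.mb_ranking <- function(x, ...) {
  cat("<mb_ranking> ", x$n_teams, " teams, ", x$n_solutions,
      " solutions\noverall:\n", sep = "")
  print(x$overall, row.names = FALSE)
  invisible(x)
}

#' Inject lowest-rank placeholders for missing submissions
#'
#' For every expected (team, tf, platform) cell absent from the table, adds
#' rows with `NA` values for each benchmark observed at that platform, so
#' that [hierarchical_aggregate()] assigns the lowest possible rank there.
#'
#' @param table metric table.
#' @param teams character vector of expected teams.
#' @param expected_cells data.frame with columns `tf`, `platform` listing
#'   the expected cells (defaults to all cells observed in the table).
#' @return The augmented metric table.
#' @export
penalize_missing <- function(table, teams = unique(table$team),
                             expected_cells = NULL) {
  df <- as.data.frame(table)
  if (!"submission" %in% names(df)) df$submission <- "s1"
  if (is.null(expected_cells))
    expected_cells <- unique(df[c("tf", "platform")])
  benches <- unique(df[c("platform", "negative_kind", "metric")])
  add <- list()
  for (tm in teams) {
    for (i in seq_len(nrow(expected_cells))) {
      tf_i <- expected_cells$tf[i]; pl_i <- expected_cells$platform[i]
      present <- any(df$team == tm & df$tf == tf_i & df$platform == pl_i)
      if (!present) {
        b <- benches[benches$platform == pl_i, , drop = FALSE]
        if (nrow(b) == 0L) next
        add[[length(add) + 1L]] <- data.frame(
          team = tm, submission = "s1", tf = tf_i, platform = pl_i,
          negative_kind = b$negative_kind, metric = b$metric,
          value = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  cols <- c("team", "submission", "tf", "platform", "negative_kind",
            "metric", "value")
  if (length(add))
    return(rbind(df[cols], do.call(rbind, add)[cols]))
  df
}

#' Ranking stability under subsampling
#'
#' Re-runs the hierarchical aggregation on `n_reps` random subsamples of
#' the metric table, each dropping every (TF, platform) cell independently
#' with probability `drop_prob` (default 0.25, retaining on average 75% of
#' the pool). Replicates that would retain no cells are re-drawn. Reports
#' the distribution of final ranks per team and the retained-cell fraction
#' per replicate.
#'
#' @param table metric table.
#' @param drop_prob per-cell drop probability (default 0.25).
#' @param n_reps number of subsample replicates (default 1000).
#' @param seed optional RNG seed.
#' @return A list of class `mb_stability` with `rank_freq` (data.frame
#'   `team`, `rank`, `frequency`), `retained_fraction` (numeric per
#'   replicate), and `n_reps`.
#' @export
stability_analysis <- function(table, drop_prob = 0.25, n_reps = 1000L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- data.table::as.data.table(table)
  cells <- unique(dt[, .(tf, platform)])
  n_cells <- nrow(cells)
  if (n_cells < 2L) stop("need at least two (TF, platform) cells")
  cell_key <- paste(dt$tf, dt$platform, sep = "\r")
  cell_ids <- paste(cells$tf, cells$platform, sep = "\r")
  ranks <- vector("list", n_reps)
  retained <- numeric(n_reps)
  for (rep in seq_len(n_reps)) {
    repeat {
      keep <- stats::runif(n_cells) >= drop_prob
      if (any(keep)) break
    }
    retained[rep] <- mean(keep)
    sub <- dt[cell_key %in% cell_ids[keep]]
    agg <- hierarchical_aggregate(sub)
    ranks[[rep]] <- agg$overall[, c("team", "rank")]
  }
  all_r <- do.call(rbind, ranks)
  freq <- as.data.frame(table(team = all_r$team, rank = all_r$rank),
                        stringsAsFactors = FALSE)
  names(freq)[3L] <- "count"
  freq$rank <- as.numeric(freq$rank)
  freq$frequency <- freq$count / n_reps
  structure(list(rank_freq = freq[freq$count > 0, c("team", "rank", "frequency")],
                 retained_fraction = retained, n_reps = n_reps),
            class = "mb_stability")
}

#' @export
print.mb_stability <- function(x, ...) {
  cat(sprintf("<mb_stability> %d replicates, mean retention %.1f%%\n",
              x$n_reps, 100 * mean(x$retained_fraction)))
  invisible(x)
}
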
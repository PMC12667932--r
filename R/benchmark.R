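# End-to-end benchmark orchestration: dataset suites, model scoring,
# metric tables, and ranked reports.

# Library flanks used when scoring reads from in-vitro selection assays:
# the standard Illumina TruSeq / Nextera primer sequences adjacent to the
# variable insert.
selex_flanks <- function(platform) {
  switch(platform,
    HTS = list(flank5 = "ACACTCTTTCCCTACACGACGCTCTTCCGATCT",
               flank3 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"),
    SMS = list(flank5 = "CGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
               flank3 = "CTGTCTCTTATACACATCTCCGAGCCCA"),
    list(flank5 = NULL, flank3 = NULL))
}

#' Metric set of a platform
#'
#' Genomic platforms (CHS, GHTS) and PBM use plain AUROC/AUPRC; the
#' read-based in-vitro platforms (SMS, HTS) use the mean top-fraction
#' variants; HTS adds the cycle-regression tau-b.
#'
#' @param platform one of `"CHS"`, `"GHTS"`, `"HTS"`, `"SMS"`, `"PBM"`.
#' @return Character vector of metric names.
#' @export
platform_metrics <- function(platform) {
  switch(platform,
    CHS = , GHTS = , PBM = c("auroc", "auprc"),
    SMS = c("mauroc", "mauprc"),
    HTS = c("mauroc", "mauprc", "tau_b"),
    stop("unknown platform: ", platform))
}

#' Evaluate prediction scores on a labeled dataset
#'
#' Joins scores to the dataset by tag (every labeled record must be
#' scored; unknown tags are ignored) and computes the platform's metric
#' set. Tau-b is computed on the positive reads against their cycle
#' labels.
#'
#' @param scores data.frame with `tag`, `score`.
#' @param dataset labeled dataset data.frame (`tag`, `seq`, `label`,
#'   optional `cycle`).
#' @param platform platform code (see [platform_metrics()]).
#' @return data.frame with `metric`, `value`, `n_pos`, `n_neg`.
#' @export
evaluate_predictions <- function(scores, dataset, platform) {
  missing <- setdiff(dataset$tag, scores$tag)
  if (length(missing))
    stop("unscored dataset tag(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (and %d more)",
                                           length(missing) - 5L) else "")
  s <- scores$score[match(dataset$tag, scores$tag)]
  lab <- dataset$label
  wanted <- platform_metrics(platform)
  n_pos <- sum(lab == 1L); n_neg <- sum(lab == 0L)
  vals <- numeric(0)
  if (any(c("auroc", "auprc") %in% wanted)) {
    cs <- classification_scores(s, lab)
    vals <- c(vals, auroc = cs$auroc, auprc = cs$auprc)
  }
  if (any(c("mauroc", "mauprc") %in% wanted)) {
    mt <- mean_topk_scores(s, lab, tag = dataset$tag)
    vals <- c(vals, mauroc = mt$mauroc, mauprc = mt$mauprc)
  }
  if ("tau_b" %in% wanted) {
    pos <- lab == 1L
    vals <- c(vals, tau_b = kendall_tau_b(s[pos], dataset$cycle[pos]))
  }
  data.frame(metric = wanted, value = unname(vals[wanted]),
             n_pos = n_pos, n_neg = n_neg, stringsAsFactors = FALSE)
}

#' Score a labeled dataset with a PFM
#'
#' Applies one scanning mode to the dataset sequences, attaching the
#' platform's constant library flanks for the read-based in-vitro
#' platforms (HTS, SMS).
#'
#' @param x a `pfm` or `pwm_scoring` object.
#' @param dataset labeled dataset data.frame.
#' @param platform platform code.
#' @param mode `"besthit"` or `"occupancy"`.
#' @return data.frame with `tag`, `score`.
#' @export
score_dataset <- function(x, dataset, platform,
                          mode = c("besthit", "occupancy")) {
  mode <- match.arg(mode)
  fl <- selex_flanks(platform)
  sc <- score_sequences(x, stats::setNames(dataset$seq, dataset$tag),
                        mode = mode, flank5 = fl$flank5, flank3 = fl$flank3)
  data.frame(tag = sc$seq_id, score = sc$score, stringsAsFactors = FALSE)
}

#' Build the synthetic benchmark suite for one TF
#'
#' Generates planted-motif data for the requested platforms and assembles
#' the labeled test datasets exactly as the real pipeline would: genomic
#' platforms get 301-bp summit-centered positives on even-numbered (test)
#' chromosomes with shade / alien / random negatives; the read platforms
#' get deduplicated cycle-labeled positives with GC-matched input and
#' alien negatives (1:2 for HTS, 1:5 for SMS); PBM gets QNZS-normalized
#' replicate arrays with threshold-called positives and 1:10 GC-matched
#' negatives.
#'
#' @param pfm the true (planted) motif.
#' @param config a [simulation_config()].
#' @param platforms subset of `c("CHS", "GHTS", "HTS", "SMS", "PBM")`.
#' @param tf TF id attached to the datasets.
#' @return A list of dataset entries, each
#'   `list(data, platform, negative_kind, tf)`, plus attribute
#'   `"extras"` holding the raw simulated objects (genome, peaks,
#'   variants, truth tables).
#' @export
build_benchmark_suite <- function(pfm, config = simulation_config(),
                                  platforms = c("CHS", "GHTS", "HTS",
                                                "SMS", "PBM"),
                                  tf = "TF1") {
  set.seed(config$seed)
  suite <- list()
  extras <- list()
  alien <- random_pfm(config$motif_width, config$concentration,
                      tag = "alien_motif")
  add <- function(lst, platform, negative_kind, pos, neg) {
    entry <- list(data = rbind(pos, neg), platform = platform,
                  negative_kind = negative_kind, tf = tf)
    lst[[paste(platform, negative_kind, sep = ".")]] <- entry
    lst
  }
  for (platform in intersect(platforms, c("CHS", "GHTS"))) {
    sim <- simulate_genomic_experiment(
      pfm, n_sites = 60L,
      chrom_lengths = stats::setNames(rep(200000L, 4L), paste0("chr", 1:4)),
      gc = config$gc, n_variants = 30L, min_spacing = 2000L,
      alien_pfm = alien, n_alien_sites = 180L)
    extras[[platform]] <- sim
    pos_iv <- extract_positive_regions(sim$peaks, sim$genome)
    test_pos <- split_by_chromosome(pos_iv)$test
    mk <- function(iv, label)
      data.frame(tag = sprintf("%s_%s_%05d", platform, label, seq_len(nrow(iv))),
                 seq = get_interval_seqs(sim$genome, iv),
                 label = as.integer(label == "positive"), cycle = 0L,
                 stringsAsFactors = FALSE)
    pos <- mk(test_pos, "positive")
    test_chroms <- unique(test_pos$chrom)
    test_peaks <- sim$peaks[sim$peaks$chrom %in% test_chroms, ]
    shades <- build_shades(test_peaks, sim$genome)
    suite <- add(suite, platform, "shades", pos, mk(shades, "shade"))
    alien_test <- sim$alien_peaks[sim$alien_peaks$chrom %in% test_chroms, ]
    aliens <- sample_peak_negatives(
      test_pos, sim$genome, test_peaks, source = "aliens",
      alien_peaks = alien_test, ratio = 2)
    suite <- add(suite, platform, "aliens", pos, mk(aliens, "alien"))
    rand <- sample_peak_negatives(
      test_pos, sim$genome[test_chroms], test_peaks, source = "random",
      ratio = 2)
    suite <- add(suite, platform, "random", pos, mk(rand, "random"))
  }
  for (platform in intersect(platforms, c("HTS", "SMS"))) {
    cycles <- if (platform == "HTS") config$cycles else 1L
    ratio <- if (platform == "HTS") 2 else 5
    sim <- simulate_selex(config$pool_size, pfm, cycles,
                          stringency = config$stringency,
                          read_length = config$read_length)
    alien_sim <- simulate_selex(config$pool_size, alien, cycles,
                                stringency = config$stringency,
                                read_length = config$read_length)
    extras[[platform]] <- list(cycles = sim, alien_cycles = alien_sim)
    clean <- clean_reads(sim[names(sim) != "0"],
                         other_tf_pools = alien_sim[names(alien_sim) != "0"])
    pos <- build_read_positives(clean, cap = config$n_per_class, tf = tf)
    neg_in <- build_read_negatives(pos, sim[["0"]], ratio = ratio,
                                   kind = "input")
    suite <- add(suite, platform, "input", pos, neg_in)
    neg_al <- build_read_negatives(
      pos, unlist(alien_sim[names(alien_sim) != "0"], use.names = FALSE),
      ratio = ratio, kind = "alien")
    suite <- add(suite, platform, "aliens", pos, neg_al)
  }
  if ("PBM" %in% platforms) {
    # plant a twentieth of the probes so the non-positive pool comfortably
    # supports the 1:10 negative ratio
    sim <- simulate_pbm(pfm, noise_sd = config$pbm_noise_sd, gc = config$gc,
                        plant_frac = 0.05)
    extras$PBM <- sim
    arrays <- normalize_pbm(sim$arrays, mode = "QNZS")
    arr <- call_pbm_positives(arrays[[1L]], mode = "QNZS")
    arr <- sample_pbm_negatives(arr, ratio = 10)
    keep <- !is.na(arr$label)
    pbm_data <- data.frame(tag = arr$probe_id[keep], seq = arr$seq[keep],
                           label = arr$label[keep], cycle = 0L,
                           stringsAsFactors = FALSE)
    suite[["PBM.random"]] <- list(data = pbm_data, platform = "PBM",
                                  negative_kind = "random", tf = tf)
  }
  attr(suite, "extras") <- extras
  suite
}

#' Benchmark motif models on a dataset suite
#'
#' Scores every submitted PFM in both scanning modes on every dataset and
#' returns the tidy metric table consumed by [hierarchical_aggregate()].
#' Each (matrix, scanning mode) pair is one scored solution, identified as
#' `"<tag>/<mode>"` in the `submission` column. Arbitrary-model prediction
#' tables can be supplied instead of (or alongside) PFMs.
#'
#' @param suite dataset suite from [build_benchmark_suite()], or any list
#'   of `list(data, platform, negative_kind, tf)` entries.
#' @param teams named list: team name -> list of `pfm` objects (up to four
#'   alternative matrices per TF in the benchmark convention).
#' @param predictions optional named list: team name -> named list keyed by
#'   suite entry name -> data.frame(`tag`, `score`).
#' @return Metric table data.frame (`team`, `submission`, `tf`, `platform`,
#'   `negative_kind`, `metric`, `value`, `n_pos`, `n_neg`).
#' @export
benchmark_models <- function(suite, teams, predictions = NULL) {
  rows <- list()
  for (team in names(teams)) {
    pfms <- teams[[team]]
    if (is_pfm(pfms)) pfms <- list(pfms)
    for (p in pfms) {
      sc <- to_scoring_matrices(p)
      for (entry in suite) {
        for (mode in c("besthit", "occupancy")) {
          scores <- score_dataset(sc, entry$data, entry$platform, mode)
          ev <- evaluate_predictions(scores, entry$data, entry$platform)
          rows[[length(rows) + 1L]] <- data.frame(
            team = team, submission = paste(p$tag, mode, sep = "/"),
            tf = entry$tf, platform = entry$platform,
            negative_kind = entry$negative_kind,
            metric = ev$metric, value = ev$value,
            n_pos = ev$n_pos, n_neg = ev$n_neg, stringsAsFactors = FALSE)
        }
      }
    }
  }
  for (team in names(predictions)) {
    for (key in names(predictions[[team]])) {
      entry <- suite[[key]]
      if (is.null(entry)) stop("predictions refer to unknown dataset: ", key)
      ev <- evaluate_predictions(predictions[[team]][[key]], entry$data,
                                 entry$platform)
      rows[[length(rows) + 1L]] <- data.frame(
        team = team, submission = "predictions", tf = entry$tf,
        platform = entry$platform, negative_kind = entry$negative_kind,
        metric = ev$metric, value = ev$value,
        n_pos = ev$n_pos, n_neg = ev$n_neg, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run a reproducible end-to-end benchmark
#'
#' Generates (or accepts) a dataset suite, scores all submitted models,
#' computes the metric table, aggregates it into team rankings, and
#' optionally writes all outputs (datasets, metric TSV, per-level rank
#' TSVs, and a JSON run log recording the seed and configuration) under
#' `out_dir`. Two runs with the same configuration are identical.
#'
#' @param teams named list: team name -> list of `pfm` objects.
#' @param true_pfm the planted motif used to generate the synthetic suite
#'   (ignored when `suite` is supplied).
#' @param config a [simulation_config()]; its `seed` drives all
#'   randomness.
#' @param platforms platforms to include.
#' @param suite optional pre-built dataset suite.
#' @param predictions optional arbitrary-model predictions (see
#'   [benchmark_models()]).
#' @param out_dir optional output directory.
#' @return A list with `metrics` (metric table), `ranking`
#'   (an `mb_ranking`), and `suite`.
#' @export
run_benchmark <- function(teams, true_pfm = NULL,
                          config = simulation_config(),
                          platforms = c("CHS", "HTS", "SMS", "PBM"),
                          suite = NULL, predictions = NULL, out_dir = NULL) {
  if (is.null(suite)) {
    if (is.null(true_pfm)) stop("either a suite or a true PFM is required")
    suite <- build_benchmark_suite(true_pfm, config, platforms)
  }
  metrics <- benchmark_models(suite, teams, predictions)
  ranking <- hierarchical_aggregate(metrics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (lvl in c("benchmark", "experiment_tf", "team_tf", "overall"))
      utils::write.table(ranking[[lvl]],
                         file.path(out_dir, paste0("ranks_", lvl, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    for (key in names(suite)) {
      entry <- suite[[key]]
      write_labeled_dataset(entry$data,
                            file.path(out_dir, paste0(key, ".fasta")),
                            file.path(out_dir, paste0(key, ".manifest.tsv")),
                            tf = entry$tf, platform = entry$platform,
                            negative_kind = entry$negative_kind)
    }
    jsonlite::write_json(
      list(seed = config$seed, config = unclass(config),
           platforms = platforms, teams = names(teams),
           n_datasets = length(suite)),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  }
  list(metrics = metrics, ranking = ranking, suite = suite)
}
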
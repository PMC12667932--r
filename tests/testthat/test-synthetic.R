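test_that("random PFMs are valid, seed-stable, and sharpen as concentration drops", {
  p <- random_pfm(8, seed = 1)
  expect_true(validate_pfm(p)$ok)
  expect_identical(random_pfm(8, seed = 1)$probs, p$probs)
  sharp <- random_pfm(10, concentration = 0.01, seed = 2)
  flat <- random_pfm(10, concentration = 100, seed = 2)
  expect_gt(mean(apply(sharp$probs, 1, max)), 0.95)
  expect_lt(mean(apply(flat$probs, 1, max)), 0.5)
  expect_error(random_pfm(4), "width")
  expect_error(random_pfm(31), "width")
})

test_that("planted sequences record their truth table faithfully", {
  pfm <- random_pfm(8, 0.05, seed = 3)
  gen <- plant_motif_sequences(pfm, 50, 60, plant_prob = 1, seed = 4)
  expect_true(all(gen$truth$planted))
  for (i in 1:50) {
    tr <- gen$truth[i, ]
    window <- substr(unname(gen$seqs[i]), tr$offset + 1, tr$offset + 8)
    expected <- if (tr$strand == "+") tr$word else revcomp(tr$word)
    expect_equal(window, expected)
  }
  # plant_prob 0 leaves pure background: best-hit distribution matches an
  # unplanted draw from the same generator
  bg1 <- plant_motif_sequences(pfm, 100, 60, plant_prob = 0, seed = 5)
  expect_true(all(!bg1$truth$planted))
  expect_true(all(is.na(bg1$truth$offset)))
  sc <- to_scoring_matrices(pfm)
  planted_scores <- vapply(gen$seqs, function(s) best_hit(sc, s)$score,
                           numeric(1))
  bg_scores <- vapply(bg1$seqs, function(s) best_hit(sc, s)$score, numeric(1))
  expect_gt(mean(planted_scores), mean(bg_scores) + 2)
})

test_that("SELEX simulation enriches true-motif affinity over cycles", {
  pfm <- random_pfm(8, 0.2, seed = 6)
  sc <- to_scoring_matrices(pfm)
  mean_bh <- function(reads) mean(vapply(reads, function(s)
    best_hit(sc, s)$score, numeric(1)))
  deltas <- sapply(1:3, function(sd) {
    sel <- simulate_selex(300, pfm, 3, seed = sd)
    diff(vapply(sel, mean_bh, numeric(1)))
  })
  # mean best-hit score non-decreasing with cycle, averaged over seeds
  expect_true(all(rowMeans(deltas) > -0.05))
  # rank correlation between true-motif score and cycle is positive
  sel <- simulate_selex(300, pfm, 3, seed = 11)
  pos <- do.call(rbind, lapply(1:3, function(cy)
    data.frame(seq = sel[[as.character(cy)]], cycle = cy)))
  occ <- vapply(pos$seq, function(s) sum_occupancy(sc, s), numeric(1))
  expect_gt(kendall_tau_b(occ, pos$cycle), 0.05)
  expect_error(simulate_selex(100, pfm, 3, stringency = -1), "non-negative")
})

test_that("zero stringency makes cycles exchangeable", {
  pfm <- random_pfm(8, 0.2, seed = 7)
  sc <- to_scoring_matrices(pfm)
  sel <- simulate_selex(400, pfm, 3, stringency = 0, seed = 8)
  pos <- do.call(rbind, lapply(1:3, function(cy)
    data.frame(seq = sel[[as.character(cy)]], cycle = cy)))
  occ <- vapply(pos$seq, function(s) sum_occupancy(sc, s), numeric(1))
  expect_lt(abs(kendall_tau_b(occ, pos$cycle)), 0.05)
})

test_that("genomic simulation plants sites under summits with valid variants", {
  pfm <- random_pfm(8, 0.2, seed = 9)
  sim <- simulate_genomic_experiment(pfm, n_sites = 30, n_variants = 15,
                                     seed = 10)
  # every summit sits at a planted instance center
  expect_equal(sim$peaks$summit, sim$sites$center[!sim$sites$alien])
  # positive regions contain the planted word
  pos <- extract_positive_regions(sim$peaks, sim$genome)
  seqs <- get_interval_seqs(sim$genome, pos)
  for (i in seq_along(seqs))
    expect_true(grepl(sim$sites$word[i], seqs[i], fixed = TRUE) ||
                  grepl(revcomp(sim$sites$word[i]), seqs[i], fixed = TRUE))
  # variant truth: context centered on ref, observed = true sign mostly
  v <- sim$variants
  expect_true(all(nchar(v$context) == 301))
  expect_equal(substr(v$context, 151, 151), v$ref)
  sim0 <- simulate_genomic_experiment(pfm, n_sites = 30, n_variants = 15,
                                      flip_noise = 0, seed = 12)
  expect_true(all(sim0$variants$observed_pref == sim0$variants$true_pref))
  expect_error(simulate_genomic_experiment(
    pfm, n_sites = 1000,
    chrom_lengths = c(chr1 = 10000L)), "too short")
})

test_that("PBM simulation responds to detrending and recovers top binders", {
  pfm <- random_pfm(8, 0.2, seed = 13)
  sim_sd <- simulate_pbm(pfm, n_probes = 900, grid_dims = c(30, 30),
                         n_arrays = 2, noise_sd = 0,
                         gradient_amplitude = 0.4, seed = 14)
  # SD removes the injected linear spatial gradient
  sd_out <- normalize_pbm(sim_sd$arrays[1], mode = "SD")[[1]]
  fit_raw <- lm(log10(raw_intensity) ~ row + col, data = sd_out)
  fit_det <- lm(normalized_value ~ row + col, data = sd_out)
  expect_lt(sum(abs(coef(fit_det)[-1])), 0.2 * sum(abs(coef(fit_raw)[-1])))
  # QNZS + thresholding recovers the top-occupancy decile at default noise
  sim <- simulate_pbm(pfm, seed = 15)
  arrays <- normalize_pbm(sim$arrays, mode = "QNZS")
  called <- call_pbm_positives(arrays[[1]], mode = "QNZS")
  decile <- order(-sim$truth$occupancy)[seq_len(nrow(sim$truth) %/% 10)]
  expect_gte(mean(called$positive[decile]), 0.8)
  # zero noise, no gradient, no probe effect: SD-called positives are
  # exactly the top probes by occupancy
  sim0 <- simulate_pbm(pfm, n_probes = 400, grid_dims = c(20, 20),
                       n_arrays = 2, noise_sd = 0, gradient_amplitude = 0,
                       probe_effect_sd = 0, seed = 16)
  arr0 <- normalize_pbm(sim0$arrays, mode = "SD")
  called0 <- call_pbm_positives(arr0[[1]], mode = "SD")
  # every strongly bound probe is called (the background is all ties at 0)
  expect_true(all(order(-sim0$truth$occupancy)[1:30] %in%
                    which(called0$positive)))
  # detrended values track the log signal (background occupancy is small
  # but nonzero, so the local median leaves a slight offset)
  expect_gt(cor(arr0[[1]]$normalized_value[sim0$truth$planted],
                log10(1 + 5000 * sim0$truth$occupancy[sim0$truth$planted])),
            0.99)
  expect_error(simulate_pbm(pfm, grid_dims = c(5, 5)), "11")
})

test_that("generators are deterministic under a fixed seed", {
  pfm <- random_pfm(8, 0.2, seed = 15)
  expect_identical(simulate_selex(100, pfm, 2, seed = 16),
                   simulate_selex(100, pfm, 2, seed = 16))
  expect_identical(simulate_genomic_experiment(pfm, n_sites = 10, seed = 17),
                   simulate_genomic_experiment(pfm, n_sites = 10, seed = 17))
  expect_identical(simulate_pbm(pfm, n_probes = 400, grid_dims = c(20, 20),
                                n_arrays = 4, seed = 18),
                   simulate_pbm(pfm, n_probes = 400, grid_dims = c(20, 20),
                                n_arrays = 4, seed = 18))
})
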
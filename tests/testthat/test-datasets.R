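# helpers to build a small deterministic genomic scene
toy_scene <- function(seed = 1, n_sites = 30) {
  pfm <- random_pfm(8, 0.2, seed = seed, tag = "toy")
  sim <- simulate_genomic_experiment(pfm, n_sites = n_sites, seed = seed + 1)
  list(pfm = pfm, sim = sim)
}

test_that("positive regions are 301 bp with the summit at offset 150", {
  sc <- toy_scene()
  pos <- extract_positive_regions(sc$sim$peaks, sc$sim$genome)
  expect_equal(nrow(pos), nrow(sc$sim$peaks))
  expect_true(all(pos$end - pos$start == 301))
  expect_equal(pos$start + 150, sc$sim$peaks$summit)
})

test_that("edge peaks are dropped with a warning, unknown chromosomes error", {
  genome <- c(chr1 = strrep("ACGT", 2500))
  peaks <- data.frame(chrom = "chr1", start = c(50, 4000), end = c(300, 4400),
                      summit = c(100, 4200))
  expect_warning(pos <- extract_positive_regions(peaks, genome), "dropped")
  expect_equal(nrow(pos), 1)
  expect_error(extract_positive_regions(
    data.frame(chrom = "chrZ", start = 1, end = 10, summit = 5), genome),
    "unknown chromosome")
})

test_that("shades are 300 bp, 300-600 bp away, non-overlapping, seed-stable", {
  sc <- toy_scene()
  peaks <- sc$sim$peaks
  sh <- build_shades(peaks, sc$sim$genome, seed = 7)
  expect_true(all(sh$end - sh$start == 300))
  # gap to the nearest extended peak border within [300, 600]
  ext <- motifbench:::extend_peaks(peaks, sc$sim$genome)
  for (i in seq_len(nrow(sh))) {
    same <- ext[ext$chrom == sh$chrom[i], ]
    gaps <- pmax(same$start - sh$end[i], sh$start[i] - same$end)
    expect_true(any(gaps >= 300 & gaps <= 600))
  }
  # no overlap with any extended peak and 300-bp spacer to positives
  pos <- extract_positive_regions(peaks, sc$sim$genome)
  for (i in seq_len(nrow(sh))) {
    same_pk <- ext[ext$chrom == sh$chrom[i], ]
    expect_true(all(same_pk$start >= sh$end[i] | same_pk$end <= sh$start[i]))
    same_pos <- pos[pos$chrom == sh$chrom[i], ]
    gaps <- pmax(same_pos$start - sh$end[i], sh$start[i] - same_pos$end)
    expect_true(all(gaps >= 300))
  }
  # determinism under the seed, difference across seeds
  expect_identical(sh, build_shades(peaks, sc$sim$genome, seed = 7))
  expect_false(identical(sh, build_shades(peaks, sc$sim$genome, seed = 8)))
  # 1:1 balance when space allows
  expect_equal(nrow(sh), nrow(peaks))
})

test_that("short peaks are extended symmetrically with a left bias", {
  genome <- c(chr1 = strrep("A", 10000))
  p <- data.frame(chrom = "chr1", start = 5000, end = 5101, summit = 5050)
  ext <- motifbench:::extend_peaks(p, genome)
  expect_equal(ext$end - ext$start, 300)
  # deficit 199: left gets 100, right gets 99
  expect_equal(ext$start, 5000 - 100)
  expect_equal(ext$end, 5101 + 99)
})

test_that("peak negatives honor ratio, exclusion, and GC matching", {
  sc <- toy_scene(seed = 5, n_sites = 40)
  pos <- extract_positive_regions(sc$sim$peaks, sc$sim$genome)
  neg <- sample_peak_negatives(pos, sc$sim$genome, sc$sim$peaks,
                               source = "random", ratio = 2, seed = 3)
  expect_equal(nrow(neg), 2 * nrow(pos))
  # no overlap or near-contact with target peaks / positives
  gr_n <- motifbench:::as_granges0(neg)
  gr_p <- motifbench:::as_granges0(pos)
  gr_pk <- motifbench:::as_granges0(sc$sim$peaks)
  expect_length(GenomicRanges::findOverlaps(gr_n, gr_pk), 0)
  expect_length(GenomicRanges::findOverlaps(gr_n, gr_p, maxgap = 299), 0)
  # GC distribution matches within a small per-bin tolerance
  gc_p <- gc_content(get_interval_seqs(sc$sim$genome, pos))
  gc_n <- gc_content(get_interval_seqs(sc$sim$genome, neg))
  bins <- seq(0, 1, 0.05)
  h_p <- hist(gc_p, breaks = bins, plot = FALSE)$counts / length(gc_p)
  h_n <- hist(gc_n, breaks = bins, plot = FALSE)$counts / length(gc_n)
  expect_true(all(abs(h_p - h_n) <= 0.02 + 1e-9))
})

test_that("chromosome split sends odd autosomes to train, even to test", {
  iv <- data.frame(chrom = c("chr1", "chr2", "chr21", "chr22", "chrX", "weird"),
                   start = 0, end = 10)
  expect_warning(sp <- split_by_chromosome(iv), "unparseable")
  expect_equal(sp$train$chrom, c("chr1", "chr21"))
  expect_equal(sp$test$chrom, c("chr2", "chr22"))
  expect_equal(sp$excluded$chrom, c("chrX", "weird"))
  expect_equal(nrow(sp$train) + nrow(sp$test) + nrow(sp$excluded), nrow(iv))
})

test_that("read cleaning removes within-cycle and cross-cycle duplicates", {
  cycles <- list("1" = c("AAAA", "AAAA", "BBBB"), "2" = c("BBBB", "CCCC"))
  out <- clean_reads(cycles)
  expect_equal(out[["1"]], "AAAA")
  expect_equal(out[["2"]], "CCCC")
  # idempotence and order-invariance
  expect_equal(clean_reads(out), out)
  rev_in <- lapply(cycles, rev)
  expect_equal(lapply(clean_reads(rev_in), sort), lapply(out, sort))
  # cross-TF ambiguity removal
  out2 <- clean_reads(cycles, other_tf_pools = list(c("CCCC")))
  expect_equal(out2[["2"]], character(0))
})

test_that("positive read sampling equalizes cycles under the cap", {
  set.seed(31)
  cycles <- list("1" = unique(replicate(1500, random_seq(12))),
                 "2" = unique(replicate(300, random_seq(12))))
  pos <- build_read_positives(cycles, cap = 1000, seed = 2)
  tab <- table(pos$cycle)
  n_min <- min(lengths(cycles))
  expect_equal(unname(tab[["1"]]), n_min)
  expect_equal(unname(tab[["2"]]), n_min)
  # cap binds when cycles are larger than it
  pos2 <- build_read_positives(cycles, cap = 100, seed = 2)
  expect_true(all(table(pos2$cycle) == 100))
  # determinism under seed
  expect_identical(pos, build_read_positives(cycles, cap = 1000, seed = 2))
  expect_error(build_read_positives(list(), cap = 10), "no cycles")
})

test_that("negative reads exclude positives and meet the platform ratio", {
  set.seed(32)
  pos <- data.frame(tag = paste0("p", 1:100),
                    seq = replicate(100, random_seq(20)),
                    cycle = 1L, label = 1L)
  pool <- c(pos$seq[1:10], replicate(2000, random_seq(20)))
  neg2 <- build_read_negatives(pos, pool, ratio = 2, seed = 4)
  expect_equal(nrow(neg2), 200)
  neg5 <- build_read_negatives(pos, pool, ratio = 5, seed = 4)
  expect_equal(nrow(neg5), 500)
  expect_length(intersect(neg5$seq, pos$seq), 0)
  expect_true(all(neg5$label == 0 & neg5$cycle == 0))
})

test_that("GC matching tracks the reference distribution", {
  set.seed(33)
  # reference concentrated in one bin
  ref <- replicate(50, random_seq(100, c("G", "C")))   # GC = 1
  cand <- c(replicate(100, random_seq(100, c("G", "C"))),
            replicate(100, random_seq(100, c("A", "T"))))
  idx <- gc_match_sample(cand, ref, ratio = 1)
  expect_length(idx, 50)
  expect_true(all(gc_content(cand[idx]) == 1))
  # proportional sampling over a mixed pool: chi-square distance small
  ref2 <- rbeta(400, 5, 5)
  cand2 <- runif(10000)
  idx2 <- gc_match_sample(cand2, ref2, ratio = 2, seed = 9)
  expect_length(idx2, 800)
  bins <- seq(0, 1, 0.05)
  h_r <- hist(ref2, breaks = bins, plot = FALSE)$counts / 400
  h_s <- hist(cand2[idx2], breaks = bins, plot = FALSE)$counts / 800
  chi2 <- sum((h_s - h_r)^2 / pmax(h_r, 1e-12) * (h_r > 0))
  expect_lt(chi2, 0.01)
  expect_error(gc_match_sample(character(0), ref), "empty candidate")
})

test_that("samplers are reproducible under a seed and vary across seeds", {
  cand <- runif(2000); ref <- runif(100)
  expect_identical(gc_match_sample(cand, ref, seed = 1),
                   gc_match_sample(cand, ref, seed = 1))
  expect_false(identical(gc_match_sample(cand, ref, seed = 1),
                         gc_match_sample(cand, ref, seed = 2)))
})

test_that("QNZS normalization gives identical sorted vectors and unit Z-scores", {
  set.seed(34)
  n <- 200
  ids <- sprintf("p%03d", 1:n)
  seqs <- replicate(n, random_seq(20))
  arrays <- lapply(1:5, function(k)
    data.frame(probe_id = ids, seq = seqs,
               raw_intensity = rlnorm(n, 5 + k / 10, 0.5),
               row = rep(1:20, each = 10), col = rep(1:10, 20)))
  out <- normalize_pbm(arrays, mode = "QNZS")
  z <- vapply(out, `[[`, numeric(n), "normalized_value")
  expect_equal(rowMeans(z), rep(0, n), tolerance = 1e-9)
  expect_equal(apply(z, 1, sd), rep(1, n), tolerance = 1e-9)
  expect_error(normalize_pbm(arrays[1], mode = "QNZS"), "two arrays")
})

test_that("spatial detrending flattens a constant array and needs a grid", {
  n <- 400
  arr <- data.frame(probe_id = sprintf("p%03d", 1:n),
                    seq = replicate(n, random_seq(20)),
                    raw_intensity = rep(100, n),
                    row = rep(1:20, each = 20), col = rep(1:20, 20))
  out <- normalize_pbm(list(arr), mode = "SD")[[1]]
  expect_equal(out$normalized_value, rep(0, n))
  no_grid <- arr[, c("probe_id", "seq", "raw_intensity")]
  expect_error(normalize_pbm(list(no_grid), mode = "SD"), "missing column")
})

test_that("PBM positive calling applies thresholds with a top-50 floor", {
  set.seed(35)
  n <- 2000
  mk_arr <- function(v) data.frame(probe_id = sprintf("p%04d", 1:n),
                                   seq = replicate(n, random_seq(20)),
                                   raw_intensity = 1, normalized_value = v)
  # 100 probes far above mean + 4 sd (outlier fraction kept small enough
  # that the outliers do not inflate the threshold past themselves)
  v <- c(rnorm(1900), rnorm(100, 50, 0.1))
  called <- call_pbm_positives(mk_arr(v), mode = "SD")
  expect_equal(sum(called$positive), 100)
  expect_true(all(which(called$positive) > 1900))
  # QNZS rule: Z > 4, here 12 pass so the top-50 floor applies
  v2 <- c(rnorm(n - 12), rnorm(12, 10, 0.1))
  called2 <- call_pbm_positives(mk_arr(v2), mode = "QNZS")
  expect_equal(sum(called2$positive), 50)
  expect_true(all(order(-v2)[1:50] %in% which(called2$positive)))
  # all-equal array: deterministic top-50 by probe id
  called3 <- call_pbm_positives(mk_arr(rep(1, n)), mode = "QNZS")
  expect_equal(sum(called3$positive), 50)
  expect_equal(which(called3$positive), 1:50)
  small <- data.frame(probe_id = sprintf("p%02d", 1:30),
                      seq = replicate(30, random_seq(20)),
                      raw_intensity = 1, normalized_value = rnorm(30))
  expect_error(call_pbm_positives(small, mode = "SD"), "fewer than 50")
})

test_that("PBM negatives are a disjoint GC-matched 1:10 sample", {
  set.seed(36)
  n <- 1200
  arr <- data.frame(probe_id = sprintf("p%04d", 1:n),
                    seq = replicate(n, random_seq(30)),
                    raw_intensity = 1,
                    normalized_value = c(rnorm(1140), rnorm(60, 30, 0.1)))
  called <- call_pbm_positives(arr, mode = "SD")
  lab <- suppressWarnings(sample_pbm_negatives(called, ratio = 10, seed = 6))
  expect_equal(sum(lab$label == 1, na.rm = TRUE), 60)
  expect_equal(sum(lab$label == 0, na.rm = TRUE), 600)
  expect_false(any(lab$positive & lab$label == 0, na.rm = TRUE))
})
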
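# Synthetic multi-platform data with planted motifs.
#
# The generators emulate the data-generating structure the benchmarks
# assume -- planted-motif positives over GC-controlled backgrounds, SELEX
# cycle enrichment, peak/summit structure, PBM intensity noise, and
# allelically imbalanced variants -- so the whole pipeline can be exercised
# and validated without any external dataset.

#' Default simulation configuration
#'
#' Central defaults for the synthetic study conditions: motif width 8 with
#' Dirichlet concentration 0.2 (a sharp, information-rich motif), 40-bp
#' reads (the standard random-insert length of SELEX libraries), 301-bp
#' genomic regions, background GC 0.41 (the human genome average), 3
#' selection cycles at stringency 0.3, PBM log-intensity noise sd 0.1, and a
#' 5% flip probability for observed allelic preferences.
#'
#' @param ... overrides for individual fields.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(...) {
  cfg <- list(seed = 1L, motif_width = 8L, concentration = 0.2,
              n_per_class = 300L, seq_length = 301L, gc = 0.41,
              read_length = 40L, cycles = 3L, stringency = 0.3,
              pool_size = 2000L, pbm_noise_sd = 0.1, flip_noise = 0.05)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$gc > 0, cfg$gc < 1, cfg$cycles >= 1, cfg$n_per_class >= 1)
  structure(cfg, class = "sim_config")
}

# i.i.d. background sequences at a given GC fraction
random_dna <- function(n, len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = ""),
    character(1L))
}

#' Draw a random PFM
#'
#' Rows are independent draws from a symmetric Dirichlet distribution with
#' the given concentration; small concentrations give near-consensus
#' columns (one probability close to 1), large ones give flat columns.
#'
#' @param width motif width (5..30).
#' @param concentration symmetric Dirichlet concentration (default 0.2).
#' @param seed optional RNG seed.
#' @param tag motif tag.
#' @return A [new_pfm()] object that passes [validate_pfm()].
#' @export
random_pfm <- function(width, concentration = 0.2, seed = NULL,
                       tag = "sim_motif") {
  if (width < 5L || width > 30L)
    stop("width must be in [5, 30]")
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(stats::rgamma(width * 4L, shape = concentration), ncol = 4L)
  # guard against all-zero rows at tiny concentrations
  g[rowSums(g) == 0, ] <- 1
  new_pfm(g / rowSums(g), tag = tag)
}

# sample one word from a PFM (per-position categorical draw)
sample_motif_word <- function(pfm) {
  paste(apply(pfm$probs, 1L, function(p)
    sample(c("A", "C", "G", "T"), 1L, prob = p)), collapse = "")
}

#' Generate sequences with planted motif occurrences
#'
#' Backgrounds are i.i.d. at the given GC; with probability `plant_prob` a
#' word sampled from the PFM replaces a uniformly chosen window on a
#' uniformly chosen strand. The returned truth table records exactly what
#' was planted and where.
#'
#' @param pfm a [new_pfm()] object.
#' @param n number of sequences.
#' @param length sequence length (must be at least the motif width).
#' @param gc background GC fraction (default 0.41).
#' @param plant_prob planting probability per sequence (default 1).
#' @param seed optional RNG seed.
#' @param prefix tag prefix.
#' @return A list with `seqs` (named character vector) and `truth`
#'   (data.frame `tag`, `planted`, `offset`, `strand`, `word`).
#' @export
plant_motif_sequences <- function(pfm, n, length, gc = 0.41, plant_prob = 1,
                                  seed = NULL, prefix = "seq") {
  w <- pfm_width(pfm)
  if (length < w) stop("sequence length shorter than motif width")
  if (!is.null(seed)) set.seed(seed)
  seqs <- random_dna(n, length, gc)
  planted <- stats::runif(n) < plant_prob
  offset <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  word <- rep(NA_character_, n)
  for (i in which(planted)) {
    word_i <- sample_motif_word(pfm)
    off <- sample.int(length - w + 1L, 1L) - 1L
    str <- sample(c("+", "-"), 1L)
    ins <- if (str == "+") word_i else revcomp(word_i)
    substr(seqs[i], off + 1L, off + w) <- ins
    offset[i] <- off; strand[i] <- str; word[i] <- word_i
  }
  tags <- sprintf("%s%05d", prefix, seq_len(n))
  names(seqs) <- tags
  list(seqs = seqs,
       truth = data.frame(tag = tags, planted = planted, offset = offset,
                          strand = strand, word = word,
                          stringsAsFactors = FALSE))
}

#' Simulate SELEX cycle enrichment
#'
#' Cycle 0 is a plain random library. The reads sequenced at cycle `c` are
#' a multinomial sample from a fresh library draw, weighted by
#' `sum_occupancy^(stringency * c)` under the true PFM: selection acts on
#' binding affinity cumulatively over the cycles, so the affinity of the
#' sampled reads increases monotonically with the cycle number in
#' expectation, while the reads of different cycles stay distinct (as the
#' sequenced samples of a huge molecular pool do). `stringency = 0` makes
#' all cycles exchangeable.
#'
#' @param pool_size reads per cycle.
#' @param pfm the true motif.
#' @param cycles number of selection cycles (>= 1).
#' @param stringency selection exponent (>= 0; default 0.3, a soft tilt
#'   that keeps enrichment progressive over several cycles).
#' @param read_length read length (default 40).
#' @param gc background GC (default 0.5, an unbiased random library).
#' @param candidate_factor library draw size as a multiple of `pool_size`
#'   (default 6; larger values mean stronger selection per cycle).
#' @param seed optional RNG seed.
#' @return Named list of character vectors, `"0"` (input library) through
#'   `as.character(cycles)`.
#' @export
simulate_selex <- function(pool_size, pfm, cycles, stringency = 0.3,
                           read_length = 40L, gc = 0.5,
                           candidate_factor = 6L, seed = NULL) {
  if (stringency < 0) stop("stringency must be non-negative")
  if (cycles < 1L) stop("need at least one selection cycle")
  if (!is.null(seed)) set.seed(seed)
  sc <- to_scoring_matrices(pfm)
  out <- vector("list", cycles + 1L)
  names(out) <- as.character(0:cycles)
  out[["0"]] <- random_dna(pool_size, read_length, gc)
  for (cy in seq_len(cycles)) {
    cand <- random_dna(pool_size * candidate_factor, read_length, gc)
    occ <- vapply(cand, function(s) sum_occupancy(sc, s), numeric(1L),
                  USE.NAMES = FALSE)
    wgt <- occ^(stringency * cy)
    wgt <- wgt / sum(wgt)
    idx <- sample.int(length(cand), pool_size, prob = wgt)
    out[[as.character(cy)]] <- cand[idx]
  }
  out
}

#' Simulate a toy genomic binding experiment
#'
#' Builds a small multi-chromosome genome, plants motif instances at
#' well-separated loci, and emits: the genome, a peak table with summits at
#' the planted instance centers (with randomized widths and supporting
#' peak callers), and a variant table where each variant sits inside a
#' planted site, the alternative allele changes the PWM score, and the
#' observed allelic preference equals the sign of the true score change
#' flipped with a small noise probability.
#'
#' @param pfm the true motif.
#' @param n_sites number of planted sites.
#' @param chrom_lengths named integer vector of chromosome lengths
#'   (default: `chr1`..`chr4` of 50 kb each).
#' @param gc background GC (default 0.41).
#' @param n_variants number of variants (at most `n_sites`).
#' @param flip_noise probability of flipping the observed preference away
#'   from the true score-change sign (default 0.05).
#' @param min_spacing minimal distance between planted loci (default
#'   2500 bp, enough to keep shade construction unconstrained).
#' @param alien_pfm optional second motif of a non-related TF; its
#'   instances are planted at separate loci and returned as `alien_peaks`.
#' @param n_alien_sites number of alien sites when `alien_pfm` is given
#'   (default `n_sites`).
#' @param seed optional RNG seed.
#' @return A list with `genome`, `peaks`, `variants`, `sites` (truth
#'   table of planted loci), and `alien_peaks` (`NULL` unless `alien_pfm`
#'   is given).
#' @export
simulate_genomic_experiment <- function(pfm, n_sites = 60L,
                                        chrom_lengths = NULL, gc = 0.41,
                                        n_variants = 30L, flip_noise = 0.05,
                                        min_spacing = 2500L,
                                        alien_pfm = NULL,
                                        n_alien_sites = n_sites,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(chrom_lengths))
    chrom_lengths <- stats::setNames(rep(50000L, 4L), paste0("chr", 1:4))
  w <- pfm_width(pfm)
  n_alien <- if (is.null(alien_pfm)) 0L else n_alien_sites
  n_total <- n_sites + n_alien
  if (sum(chrom_lengths) < n_total * (min_spacing + 301L))
    stop("genome too short to place ", n_total, " sites without overlap")
  genome <- vapply(names(chrom_lengths), function(ch)
    random_dna(1L, chrom_lengths[[ch]], gc), character(1L))
  # place site centers, >= min_spacing apart and clear of chromosome ends
  edge <- 1000L
  sites <- data.frame(chrom = character(), center = integer())
  attempts <- 0L
  while (nrow(sites) < n_total) {
    attempts <- attempts + 1L
    if (attempts > n_total * 200L)
      stop("cannot place sites without overlap")
    ch <- sample(names(chrom_lengths), 1L,
                 prob = chrom_lengths / sum(chrom_lengths))
    pos <- sample.int(chrom_lengths[[ch]] - 2L * edge, 1L) + edge
    same <- sites$chrom == ch
    if (any(abs(sites$center[same] - pos) < min_spacing)) next
    sites <- rbind(sites, data.frame(chrom = ch, center = pos))
  }
  is_alien <- c(rep(FALSE, n_sites), rep(TRUE, n_alien))
  # plant one motif word at each site (site center = word center)
  sites$word <- vapply(seq_len(n_total), function(i)
    sample_motif_word(if (is_alien[i]) alien_pfm else pfm), character(1L))
  word_w <- ifelse(is_alien, if (n_alien) pfm_width(alien_pfm) else w, w)
  sites$start <- sites$center - word_w %/% 2L   # 0-based word start
  for (i in seq_len(n_total)) {
    ch <- sites$chrom[i]
    substr(genome[[ch]], sites$start[i] + 1L,
           sites$start[i] + word_w[i]) <- sites$word[i]
  }
  # peaks: summit at the site center, randomized width and caller support
  mk_peaks <- function(idx) {
    widths <- sample(150:400, length(idx), replace = TRUE)
    lead <- floor(widths * stats::runif(length(idx), 0.3, 0.7))
    start <- pmax(sites$center[idx] - lead, 0L)
    end <- pmin(start + widths, chrom_lengths[sites$chrom[idx]])
    callers <- vapply(seq_along(idx), function(i)
      paste(sample(c("pics", "gem", "sissrs"),
                   sample.int(3L, 1L)), collapse = ","),
      character(1L))
    peaks_df(sites$chrom[idx], start, end, sites$center[idx],
             score = round(stats::runif(length(idx), 20, 200), 2),
             supporting_callers = callers)
  }
  peaks <- mk_peaks(which(!is_alien))
  alien_peaks <- if (n_alien) mk_peaks(which(is_alien)) else NULL
  # variants inside planted target words with a real score change
  n_variants <- min(n_variants, n_sites)
  vsites <- which(!is_alien)[sample.int(n_sites, n_variants)]
  sc <- to_scoring_matrices(pfm)
  vars <- lapply(vsites, function(i) {
    ch <- sites$chrom[i]
    for (try in 1:20) {
      off <- sample.int(w, 1L) - 1L
      pos <- sites$start[i] + off             # 0-based genomic position
      ref <- substr(genome[[ch]], pos + 1L, pos + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      context <- substr(genome[[ch]], pos - 150L + 1L, pos + 151L)
      if (nchar(context) != 301L) next
      # true preference from the best-hit score change over the windows
      # overlapping the variant (float log-odds, not the P-value machinery)
      win_ref <- substr(context, 151L - w + 1L, 151L + w - 1L)
      win_alt <- win_ref
      substr(win_alt, w, w) <- alt
      s_ref <- best_hit(sc, win_ref)$score
      s_alt <- best_hit(sc, win_alt)$score
      if (s_ref == s_alt) next
      true_pref <- if (s_ref > s_alt) "Ref" else "Alt"
      observed <- if (stats::runif(1L) < flip_noise)
        setdiff(c("Ref", "Alt"), true_pref) else true_pref
      return(data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                        observed_pref = observed, context = context,
                        true_pref = true_pref, stringsAsFactors = FALSE))
    }
    NULL
  })
  vars <- do.call(rbind, vars[!vapply(vars, is.null, logical(1L))])
  sites$alien <- is_alien
  list(genome = genome, peaks = peaks, variants = vars,
       sites = sites[, c("chrom", "center", "start", "word", "alien")],
       alien_peaks = alien_peaks)
}

#' Simulate protein-binding microarray data
#'
#' Probe sequences carry the motif with probability `plant_frac`. The
#' first `target_arrays` arrays measure the target TF: their true signal
#' is proportional to the probe's sum-occupancy. The remaining arrays are
#' the normalization pool (experiments of non-related proteins on the same
#' probe design): each binds its own random subset of the non-target
#' probes at strengths drawn from the target's signal distribution, so the
#' per-probe Z-score contrasts the target arrays against a pool in which
#' other probes light up instead. All arrays share a
#' probe-specific background effect (sequence-dependent optical bias, the
#' component the cross-array Z-score is designed to remove) and each adds
#' its own smooth spatial gradient (log-additive across the grid) plus
#' multiplicative lognormal noise.
#'
#' @param pfm the true motif.
#' @param n_probes number of probes (must fit the grid).
#' @param probe_length probe sequence length (default 36).
#' @param noise_sd sd of the lognormal noise on the log10 scale
#'   (default 0.1).
#' @param grid_dims `c(rows, cols)` of the array grid (default 40 x 40;
#'   must be at least 11 x 11).
#' @param n_arrays total number of arrays including the normalization pool
#'   (default 150; the per-probe Z-score needs a large pool to exceed
#'   threshold-level values).
#' @param target_arrays number of replicate arrays carrying the target
#'   signal (default 2; they come first in the output list).
#' @param probe_effect_sd sd of the shared per-probe background effect on
#'   the log10 scale (default 0.15).
#' @param gradient_amplitude peak-to-peak spatial gradient on the log10
#'   scale (default 0.3).
#' @param plant_frac fraction of probes carrying a planted motif word
#'   (default 0.1).
#' @param decoy_frac fraction of probes each normalization-pool array
#'   binds (default: `plant_frac`, so all arrays have comparable signal
#'   tails and quantile normalization is distribution-neutral).
#' @param gc background GC (default 0.41).
#' @param seed optional RNG seed.
#' @return A list with `arrays` (list of PBM data.frames; elements
#'   `1:target_arrays` are the target replicates) and `truth`
#'   (data.frame `probe_id`, `occupancy`, `planted`).
#' @export
simulate_pbm <- function(pfm, n_probes = 1600L, probe_length = 36L,
                         noise_sd = 0.1, grid_dims = c(40L, 40L),
                         n_arrays = 150L, target_arrays = 2L,
                         probe_effect_sd = 0.15, gradient_amplitude = 0.3,
                         plant_frac = 0.1, decoy_frac = plant_frac,
                         gc = 0.41, seed = NULL) {
  if (any(grid_dims < 11L)) stop("grid must be at least 11 x 11")
  if (n_probes > prod(grid_dims)) stop("more probes than grid positions")
  if (target_arrays > n_arrays) stop("more target arrays than arrays")
  if (!is.null(seed)) set.seed(seed)
  gen <- plant_motif_sequences(pfm, n_probes, probe_length, gc = gc,
                               plant_prob = plant_frac, prefix = "probe")
  sc <- to_scoring_matrices(pfm)
  occ <- vapply(gen$seqs, function(s) sum_occupancy(sc, s), numeric(1L),
                USE.NAMES = FALSE)
  nr <- grid_dims[1L]; nc <- grid_dims[2L]
  row <- ((seq_len(n_probes) - 1L) %/% nc) + 1L
  col <- ((seq_len(n_probes) - 1L) %% nc) + 1L
  probe_effect <- stats::rnorm(n_probes, 0, probe_effect_sd)
  planted <- gen$truth$planted
  # decoy TFs bind their own probe sets, which rarely coincide with the
  # target's: draw them from probes outside the target's high-affinity tail
  bg_pool <- setdiff(order(occ)[seq_len(floor(0.85 * n_probes))],
                     which(planted))
  arrays <- lapply(seq_len(n_arrays), function(k) {
    if (k <= target_arrays) {
      signal <- 1 + 5000 * occ
    } else {
      # a non-related protein binding its own probe set, matched in size
      # to the target's so quantile normalization is distribution-neutral
      signal <- rep(1, n_probes)
      n_decoy <- min(length(bg_pool), round(decoy_frac * n_probes))
      if (n_decoy > 0L && any(planted)) {
        sel <- bg_pool[sample.int(length(bg_pool), n_decoy)]
        signal[sel] <- 1 + 5000 * sample(occ[planted], n_decoy, replace = TRUE)
      }
    }
    dir <- sample(c(-1, 1), 2L, replace = TRUE)
    g <- gradient_amplitude *
      (dir[1L] * (row - 1) / (nr - 1) + dir[2L] * (col - 1) / (nc - 1)) / 2
    noise <- stats::rnorm(n_probes, 0, noise_sd)
    data.frame(probe_id = names(gen$seqs), seq = unname(gen$seqs),
               raw_intensity = signal * 10^(probe_effect + g + noise),
               row = row, col = col, stringsAsFactors = FALSE)
  })
  list(arrays = arrays,
       truth = data.frame(probe_id = names(gen$seqs), occupancy = occ,
                          planted = gen$truth$planted,
                          stringsAsFactors = FALSE))
}
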
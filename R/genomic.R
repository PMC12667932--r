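# Genomic benchmark construction.
#
# Coordinates are 0-based, half-open throughout ([start, end)); peaks carry
# an absolute summit coordinate with start <= summit < end. A genome is a
# named character vector of chromosome sequences.

peaks_df <- function(chrom, start, end, summit, score = 0,
                     supporting_callers = "") {
  stopifnot(all(start < end), all(start <= summit), all(summit < end))
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             summit = as.integer(summit), score = score,
             supporting_callers = supporting_callers,
             stringsAsFactors = FALSE)
}

# GRanges from 0-based half-open coordinates
as_granges0 <- function(df, start = "start", end = "end") {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df[[start]] + 1L,
                                          end = df[[end]]))
}

#' Extract fixed-width positive regions around peak summits
#'
#' One 301-bp interval per peak, centered on the summit (the summit sits at
#' offset 150 of the region). Peaks whose window would cross a chromosome
#' end are dropped with a warning.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`, `summit`
#'   (0-based half-open; `summit` absolute).
#' @param genome named character vector of chromosome sequences.
#' @param width region width (default 301).
#' @return data.frame of intervals (`chrom`, `start`, `end`,
#'   `label = "positive"`).
#' @export
extract_positive_regions <- function(peaks, genome, width = 301L) {
  unknown <- setdiff(unique(peaks$chrom), names(genome))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  half <- (width - 1L) %/% 2L
  start <- peaks$summit - half
  end <- start + width
  lens <- nchar(genome)[peaks$chrom]
  ok <- start >= 0L & end <= lens
  if (any(!ok))
    warning(sum(!ok), " peak(s) dropped: ", width,
            "-bp window crosses a chromosome end")
  data.frame(chrom = peaks$chrom[ok], start = as.integer(start[ok]),
             end = as.integer(end[ok]), label = "positive",
             stringsAsFactors = FALSE)
}

# extend short peaks symmetrically to min_len (left-biased by 1 bp for odd
# deficits), clamped into the chromosome
extend_peaks <- function(peaks, genome, min_len = 300L) {
  len <- peaks$end - peaks$start
  deficit <- pmax(min_len - len, 0L)
  left <- ceiling(deficit / 2)
  start <- peaks$start - left
  end <- peaks$end + (deficit - left)
  lens <- nchar(genome)[peaks$chrom]
  shift_r <- pmax(0L - start, 0L)
  start <- start + shift_r; end <- end + shift_r
  shift_l <- pmax(end - lens, 0L)
  start <- start - shift_l; end <- end - shift_l
  data.frame(chrom = peaks$chrom, start = as.integer(pmax(start, 0L)),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' Build shade negative regions near peaks
#'
#' For each peak (extended to at least 300 bp when shorter), places one
#' 300-bp "shade" region at a uniform-random gap of 300-600 bp from the
#' extended region border, on a uniformly chosen side. Candidate shades
#' that overlap any extended peak, come within 300 bp of any positive
#' region, or fall off the chromosome are re-drawn (up to `max_retries`
#' times) and finally dropped with a warning. Shades give negatives that
#' share the local genomic context of the positives; positives and shades
#' are balanced 1:1 by construction.
#'
#' @inheritParams extract_positive_regions
#' @param seed optional RNG seed.
#' @param max_retries redraw attempts per peak (default 100).
#' @param spacer minimal gap enforced against positive regions (default 300).
#' @return data.frame of intervals with `label = "shade"`, width 300 each.
#' @export
build_shades <- function(peaks, genome, seed = NULL, max_retries = 100L,
                         spacer = 300L) {
  if (!is.null(seed)) set.seed(seed)
  ext <- extend_peaks(peaks, genome)
  positives <- suppressWarnings(extract_positive_regions(peaks, genome))
  gr_ext <- as_granges0(ext)
  gr_pos <- as_granges0(positives)
  lens <- nchar(genome)
  out <- vector("list", nrow(peaks))
  dropped <- 0L
  for (i in seq_len(nrow(peaks))) {
    chrom <- ext$chrom[i]
    L <- lens[[chrom]]
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      side <- sample(c("left", "right"), 1L)
      gap <- sample(300:600, 1L)
      if (side == "left") {
        s_end <- ext$start[i] - gap
        s_start <- s_end - 300L
      } else {
        s_start <- ext$end[i] + gap
        s_end <- s_start + 300L
      }
      if (s_start < 0L || s_end > L) next
      cand <- GenomicRanges::GRanges(chrom,
                                     IRanges::IRanges(s_start + 1L, s_end))
      if (length(GenomicRanges::findOverlaps(cand, gr_ext)) > 0L) next
      near <- GenomicRanges::findOverlaps(cand, gr_pos,
                                          maxgap = spacer - 1L)
      if (length(near) > 0L) next
      out[[i]] <- data.frame(chrom = chrom, start = s_start, end = s_end,
                             label = "shade", stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) dropped <- dropped + 1L
  }
  if (dropped > 0L)
    warning(dropped, " shade(s) dropped after ", max_retries, " retries")
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(res))
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      stringsAsFactors = FALSE)
  res
}

#' Sample GC-matched genomic negatives
#'
#' Builds a negative interval set roughly `ratio` times the size of the
#' positive set, GC-matched to the positives via [gc_match_sample()].
#' Candidates are either 301-bp windows on the summits of "alien" peaks
#' (peaks of non-related proteins) or random genomic windows; any candidate
#' overlapping a target peak, or closer than the spacer to a positive
#' region, is excluded before sampling.
#'
#' @param positives positive intervals (from [extract_positive_regions()]).
#' @param genome named character vector of chromosome sequences.
#' @param target_peaks the target TF's (full-length) peaks, for exclusion.
#' @param source `"random"` for random genomic windows, `"aliens"` for
#'   windows on alien peak summits (requires `alien_peaks`).
#' @param alien_peaks data.frame of alien peaks (as in
#'   [extract_positive_regions()]).
#' @param ratio negatives per positive (default 2).
#' @param seed optional RNG seed.
#' @param spacer minimal gap against positive regions (default 300).
#' @param bin_width GC bin width for matching (default 0.05).
#' @param oversample candidate pool size multiplier for random windows.
#' @return data.frame of intervals with `label` set to the source.
#' @export
sample_peak_negatives <- function(positives, genome, target_peaks,
                                  source = c("random", "aliens"),
                                  alien_peaks = NULL, ratio = 2,
                                  seed = NULL, spacer = 300L,
                                  bin_width = 0.05, oversample = 6) {
  source <- match.arg(source)
  if (!is.null(seed)) set.seed(seed)
  if (source == "aliens") {
    if (is.null(alien_peaks)) stop("alien peaks required for source='aliens'")
    cand <- suppressWarnings(extract_positive_regions(alien_peaks, genome))
  } else {
    n_draw <- ceiling(oversample * ratio * nrow(positives))
    lens <- nchar(genome)
    chrom <- sample(names(genome), n_draw, replace = TRUE,
                    prob = lens / sum(lens))
    maxstart <- lens[chrom] - 301L
    ok <- maxstart >= 0L
    chrom <- chrom[ok]
    start <- floor(stats::runif(length(chrom)) * (maxstart[ok] + 1L))
    cand <- data.frame(chrom = chrom, start = as.integer(start),
                       end = as.integer(start + 301L),
                       stringsAsFactors = FALSE)
  }
  if (nrow(cand) == 0L) stop("no negative candidates available")
  gr_cand <- as_granges0(cand)
  gr_peaks <- as_granges0(target_peaks)
  gr_pos <- as_granges0(positives)
  bad <- union(
    S4Vectors::queryHits(GenomicRanges::findOverlaps(gr_cand, gr_peaks)),
    S4Vectors::queryHits(GenomicRanges::findOverlaps(gr_cand, gr_pos,
                                                     maxgap = spacer - 1L)))
  if (length(bad)) cand <- cand[-bad, , drop = FALSE]
  if (nrow(cand) == 0L) stop("all negative candidates excluded")
  cand_seq <- get_interval_seqs(genome, cand)
  pos_seq <- get_interval_seqs(genome, positives)
  idx <- gc_match_sample(cand_seq, pos_seq, ratio = ratio,
                         bin_width = bin_width)
  res <- cand[idx, , drop = FALSE]
  res$label <- if (source == "aliens") "alien" else "random"
  rownames(res) <- NULL
  res
}

#' Chromosome-holdout train/test split
#'
#' Intervals on odd-numbered autosomes go to the training split and
#' intervals on even-numbered autosomes to the test split; sex chromosomes
#' and unparseable chromosome names are excluded (with a warning for the
#' latter). The split prevents leakage of local genomic context between
#' training and testing.
#'
#' @param intervals data.frame with a `chrom` column
#'   (`chr1`..`chr22`, `chrX`, `chrY`).
#' @return list with `train`, `test`, and `excluded` data.frames.
#' @export
split_by_chromosome <- function(intervals) {
  num <- suppressWarnings(as.integer(sub("^chr", "", intervals$chrom)))
  sex <- intervals$chrom %in% c("chrX", "chrY", "X", "Y")
  unparsed <- is.na(num) & !sex
  if (any(unparsed))
    warning(sum(unparsed), " interval(s) on unparseable chromosome(s) excluded")
  train <- !is.na(num) & num %% 2L == 1L
  test <- !is.na(num) & num %% 2L == 0L
  list(train = intervals[train, , drop = FALSE],
       test = intervals[test, , drop = FALSE],
       excluded = intervals[!train & !test, , drop = FALSE])
}

#' Fetch interval sequences from a genome
#'
#' @param genome named character vector of chromosome sequences.
#' @param intervals data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return Character vector of sequences.
#' @export
get_interval_seqs <- function(genome, intervals) {
  vapply(seq_len(nrow(intervals)), function(i)
    substr(genome[[intervals$chrom[i]]], intervals$start[i] + 1L,
           intervals$end[i]),
    character(1L))
}
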
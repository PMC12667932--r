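# Readers and writers for the plain-text formats the pipeline consumes:
# narrowPeak-like peak tables, FASTA/FASTQ, labeled datasets, PBM probe
# tables, variant tables, and prediction tables.

#' Read a narrowPeak-like peak file
#'
#' Tab-separated peak calls in the macs2 narrowPeak layout (chrom, start,
#' end, name, score, strand, signalValue, pValue, qValue, summit offset)
#' with an optional extra 11th column listing the supporting peak callers
#' as a comma-separated set. The summit offset is relative to `start`; the
#' returned table carries the absolute summit. A missing caller column
#' yields an empty caller set with a warning.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `summit` (absolute), `supporting_callers` (comma-separated string).
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty peak file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L))
    stop("peak line ", which(nf < 10L)[1L], " has fewer than 10 columns")
  if (any(nf == 10L))
    warning("peak file has no supporting-caller column; using empty sets")
  parse_row <- function(i) {
    f <- fields[[i]]
    start <- as.integer(f[2L]); end <- as.integer(f[3L])
    offset <- as.integer(f[10L])
    if (is.na(start) || is.na(end) || is.na(offset))
      stop("unparseable coordinates at peak line ", i)
    if (offset < 0L || start + offset >= end)
      stop("summit offset ", offset, " outside peak at line ", i)
    data.frame(chrom = f[1L], start = start, end = end, name = f[4L],
               score = as.numeric(f[5L]), summit = start + offset,
               supporting_callers = if (length(f) >= 11L) f[11L] else "",
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_along(fields), parse_row))
}

#' Write peaks in the narrowPeak-like format
#'
#' @param peaks data.frame as returned by [read_peaks()] (columns `name`,
#'   `score` optional).
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  n <- nrow(peaks)
  name <- if (!is.null(peaks$name)) peaks$name else sprintf("peak%05d", seq_len(n))
  score <- if (!is.null(peaks$score)) peaks$score else 0
  callers <- if (!is.null(peaks$supporting_callers)) peaks$supporting_callers else ""
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.\t0\t0\t0\t%d\t%s",
                   peaks$chrom, peaks$start, peaks$end, name,
                   format(score, trim = TRUE), peaks$summit - peaks$start,
                   callers)
  writeLines(lines, path)
  invisible(path)
}

#' Read/write FASTA and FASTQ sequence files
#'
#' Thin wrappers around Biostrings returning plain named character vectors.
#'
#' @param path file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fastq
#' @export
#' @inheritParams write_fasta
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- if (!is.null(names(seqs))) names(seqs)
              else sprintf("read%06d", seq_along(seqs))
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Write and read a labeled benchmark dataset
#'
#' A labeled dataset is a data.frame with columns `tag`, `seq`, `label`
#' (1/0) and optionally `cycle`; metadata columns `tf`, `platform`,
#' `negative_kind` are carried in the manifest. On disk it is a FASTA file
#' with `tag|label|cycle` headers plus a TSV manifest; the round trip is
#' lossless.
#'
#' @param dataset labeled dataset data.frame.
#' @param fasta_path,manifest_path output paths.
#' @param tf,platform,negative_kind metadata stored in the manifest.
#' @export
write_labeled_dataset <- function(dataset, fasta_path, manifest_path,
                                  tf = "TF1", platform = "CHS",
                                  negative_kind = "random") {
  if (nrow(dataset) == 0L) stop("empty dataset")
  if (anyDuplicated(dataset$tag)) stop("duplicate tags in dataset")
  cycle <- if (!is.null(dataset$cycle)) dataset$cycle else 0L
  seqs <- stats::setNames(dataset$seq,
                          paste(dataset$tag, dataset$label, cycle, sep = "|"))
  write_fasta(seqs, fasta_path)
  manifest <- data.frame(tag = dataset$tag, tf = tf, platform = platform,
                         negative_kind = negative_kind,
                         label = dataset$label, cycle = cycle,
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta_path)
}

#' @rdname write_labeled_dataset
#' @return `read_labeled_dataset`: the dataset data.frame with manifest
#'   metadata attached as columns.
#' @export
read_labeled_dataset <- function(fasta_path, manifest_path = NULL) {
  seqs <- read_fasta(fasta_path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed labeled-dataset header; expected 'tag|label|cycle'")
  out <- data.frame(tag = vapply(parts, `[[`, character(1L), 1L),
                    seq = unname(seqs),
                    label = as.integer(vapply(parts, `[[`, character(1L), 2L)),
                    cycle = as.integer(vapply(parts, `[[`, character(1L), 3L)),
                    stringsAsFactors = FALSE)
  if (!is.null(manifest_path)) {
    man <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    out <- merge(out, man[setdiff(names(man), c("label", "cycle"))],
                 by = "tag", sort = FALSE)
  }
  out
}

#' Read/write a variant table
#'
#' Tab-separated with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#' `observed_pref` (`Ref`/`Alt`), `context` (sequence centered on the
#' variant).
#'
#' @param path file path.
#' @export
read_variants <- function(path) {
  v <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "observed_pref", "context")
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("variant table missing column(s): ",
                         paste(miss, collapse = ", "))
  center <- (nchar(v$context) + 1L) %/% 2L
  bad <- toupper(substr(v$context, center, center)) != toupper(v$ref)
  if (any(bad))
    stop("context center does not match ref at row(s) ",
         paste(utils::head(which(bad)), collapse = ", "))
  v
}

#' @rdname read_variants
#' @param variants variant data.frame.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a prediction table
#'
#' Two-column TSV of (sequence tag, score), as submitted for arbitrary
#' (non-PWM) models. Checks the predictions against a dataset's tags:
#' missing tags are an error, unknown tags are dropped.
#'
#' @param path file path.
#' @param required_tags optional character vector of tags that must all be
#'   scored.
#' @return data.frame with `tag`, `score`.
#' @export
read_predictions <- function(path, required_tags = NULL) {
  p <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(c("tag", "score") %in% names(p)))
    stop("prediction table must have 'tag' and 'score' columns")
  if (!is.null(required_tags)) {
    missing <- setdiff(required_tags, p$tag)
    if (length(missing))
      stop("predictions missing for tag(s): ",
           paste(utils::head(missing, 10L), collapse = ", "),
           if (length(missing) > 10L) sprintf(" (and %d more)",
                                              length(missing) - 10L) else "")
    p <- p[p$tag %in% required_tags, , drop = FALSE]
  }
  p
}

#' Read/write a PBM probe table
#'
#' Tab-separated with columns `probe_id`, `seq`, `raw_intensity` and
#' optionally `row`, `col`, `normalized_value`.
#'
#' @param path file path.
#' @export
read_pbm <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_pbm
#' @param array PBM data.frame.
#' @export
write_pbm <- function(array, path) {
  utils::write.table(array, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
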
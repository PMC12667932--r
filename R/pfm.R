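#' Position frequency matrices
#'
#' A `pfm` is the package's representation of a position frequency matrix:
#' a width x 4 matrix of per-position base probabilities with columns
#' `A, C, G, T`, carrying a `tag` attribute identifying the motif.
#' Rows are normalized to sum to 1 at parse time, so count matrices are
#' accepted transparently.
#'
#' @param probs numeric width x 4 matrix (probabilities or counts per row).
#' @param tag identifier string for the motif.
#' @param normalize normalize rows to sum 1 (default `TRUE`).
#' @return An object of class `pfm`.
#' @export
new_pfm <- function(probs, tag = "motif", normalize = TRUE) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L)
    stop("a PFM must have exactly 4 columns (A, C, G, T), got ", ncol(probs))
  if (!is.numeric(probs) || anyNA(probs))
    stop("PFM entries must be numeric and non-missing")
  if (any(probs < 0))
    stop("PFM entries must be non-negative")
  if (normalize) {
    rs <- rowSums(probs)
    if (any(rs <= 0)) stop("PFM row with zero total")
    probs <- probs / rs
  }
  dimnames(probs) <- list(NULL, c("A", "C", "G", "T"))
  structure(list(tag = as.character(tag), probs = probs), class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("<pfm> ", x$tag, " (width ", nrow(x$probs), ")\n", sep = "")
  print(round(x$probs, 4))
  invisible(x)
}

#' @export
#' @rdname new_pfm
#' @param x object to test or print.
is_pfm <- function(x) inherits(x, "pfm")

pfm_width <- function(pfm) nrow(pfm$probs)

#' Parse a PFM collection file
#'
#' Reads one or more position frequency matrices from the plain-text
#' interchange dialect: a header line starting with `>` carrying the matrix
#' tag, followed by one row of four whitespace-separated numbers per motif
#' position (`A C G T` order). Counts and frequencies are both accepted;
#' rows are normalized to sum to 1.
#'
#' @param path path to a PFM text file, or a character vector of lines
#'   (when `text = TRUE`).
#' @param text if `TRUE`, `path` is interpreted as file content, not a path.
#' @return A named list of [new_pfm()] objects, in file order.
#' @export
parse_pfm_collection <- function(path, text = FALSE) {
  lines <- if (text) unlist(strsplit(path, "\n", fixed = TRUE)) else readLines(path)
  lines <- sub("[ \t]+$", "", lines)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty PFM file: no records found")
  is_header <- startsWith(trimws(lines), ">")
  if (!is_header[1L]) stop("PFM file must start with a '>' header line")
  rec_id <- cumsum(is_header)
  pfms <- vector("list", max(rec_id))
  tags <- character(max(rec_id))
  for (r in seq_len(max(rec_id))) {
    idx <- which(rec_id == r)
    header <- trimws(lines[idx[1L]])
    tags[r] <- trimws(sub("^>", "", header))
    if (tags[r] == "") tags[r] <- paste0("motif", r)
    body <- idx[-1L]
    if (length(body) == 0L)
      stop("PFM record '", tags[r], "' has no matrix rows")
    rows <- lapply(body, function(i) {
      fields <- strsplit(trimws(lines[i]), "[ \t,]+")[[1L]]
      vals <- suppressWarnings(as.numeric(fields))
      if (length(vals) != 4L || anyNA(vals))
        stop("malformed PFM row at line ", line_no[i],
             ": expected 4 numbers, got '", lines[i], "'")
      vals
    })
    mat <- do.call(rbind, rows)
    if (any(mat < 0))
      stop("negative entry in PFM record '", tags[r], "'")
    pfms[[r]] <- new_pfm(mat, tag = tags[r])
  }
  names(pfms) <- make.unique(tags)
  pfms
}

#' Write a PFM collection to a file
#'
#' Inverse of [parse_pfm_collection()]; writes probabilities at full
#' precision so the round trip is lossless.
#'
#' @param pfms list of `pfm` objects (or a single `pfm`).
#' @param path output file path.
#' @export
write_pfm_collection <- function(pfms, path) {
  if (is_pfm(pfms)) pfms <- list(pfms)
  out <- unlist(lapply(pfms, function(p) {
    c(paste0(">", p$tag),
      apply(p$probs, 1L, function(row)
        paste(format(row, digits = 17, scientific = FALSE, trim = TRUE),
              collapse = " ")))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Validate a PFM for benchmarking
#'
#' A matrix is accepted when its width is between 5 and 30 positions
#' (the minimal scorable substring length accepted by the benchmark),
#' all entries are finite and non-negative, and each row sums to 1
#' within `1e-3`.
#'
#' @param pfm a [new_pfm()] object.
#' @param min_width,max_width accepted width bounds (defaults 5 and 30).
#' @return A list with elements `ok` (logical) and `reason` (character,
#'   `NA` when accepted).
#' @export
validate_pfm <- function(pfm, min_width = 5L, max_width = 30L) {
  stopifnot(is_pfm(pfm))
  verdict <- function(ok, reason = NA_character_) list(ok = ok, reason = reason)
  w <- pfm_width(pfm)
  if (anyNA(pfm$probs) || any(!is.finite(pfm$probs)))
    return(verdict(FALSE, "non-finite entry"))
  if (any(pfm$probs < 0))
    return(verdict(FALSE, "negative entry"))
  if (w < min_width || w > max_width)
    return(verdict(FALSE, sprintf("width %d outside accepted range [%d, %d]",
                                  w, min_width, max_width)))
  if (any(abs(rowSums(pfm$probs) - 1) > 1e-3))
    return(verdict(FALSE, "row does not sum to 1"))
  verdict(TRUE)
}

#' Derive the scoring matrices of a PFM
#'
#' Produces the three numeric forms used throughout scoring:
#' \describe{
#'   \item{`pfm_pseudo`}{the pseudocounted PFM, `probs + 1e-5` entrywise,
#'     not renormalized; used by sum-occupancy scanning.}
#'   \item{`pwm`}{the log-odds position weight matrix against the uniform
#'     background, `log2((probs + 1e-5) / 0.25)`; used by best-hit scanning.}
#'   \item{`ipwm`}{the integer weight matrix: each weight truncated to five
#'     decimal places and multiplied by `1e5`; the exact grid on which
#'     P-values are computed.}
#' }
#'
#' @param pfm a validated [new_pfm()] object.
#' @param pseudocount pseudocount added to each probability (default `1e-5`).
#' @return A list of class `pwm_scoring` with elements `tag`, `pfm_pseudo`,
#'   `pwm`, `ipwm`, and `width`.
#' @export
to_scoring_matrices <- function(pfm, pseudocount = 1e-5) {
  stopifnot(is_pfm(pfm))
  pseudo <- pfm$probs + pseudocount
  pwm <- log2(pseudo / 0.25)
  ipwm <- trunc5_int(pwm)
  structure(list(tag = pfm$tag, pfm_pseudo = pseudo, pwm = pwm,
                 ipwm = ipwm, width = nrow(pwm)),
            class = "pwm_scoring")
}

# truncate toward zero at 5 decimals, then scale to integers on the 1e5 grid
trunc5_int <- function(w) {
  m <- trunc(w * 1e5 + sign(w) * 1e-9)
  storage.mode(m) <- "double"  # values exceed .Machine$integer.max only never; keep double for safety
  m
}

#' @export
print.pwm_scoring <- function(x, ...) {
  cat("<pwm_scoring> ", x$tag, " (width ", x$width, ")\n", sep = "")
  invisible(x)
}

as_scoring <- function(x) {
  if (inherits(x, "pwm_scoring")) return(x)
  if (is_pfm(x)) return(to_scoring_matrices(x))
  stop("expected a 'pfm' or 'pwm_scoring' object")
}
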
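## Core containers: segregation and coverage tables.
##
## A segregation table is the primary GAM data object: a boolean matrix of
## which fixed-size genomic windows were detected in which nuclear-profile
## (NP) samples.  A coverage table holds the per-window sequenced nucleotide
## counts from which detection is called.

#' Construct a GAM segregation table
#'
#' @param windows data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), one row per genomic window, sorted by
#'   (chrom, start) with no duplicates.
#' @param detection logical matrix, windows x samples.
#' @param samples character vector of sample identifiers; defaults to the
#'   column names of `detection`.
#' @param bin_size window size in bp; inferred from the windows if omitted.
#'
#' @return An object of class `gam_segregation` with fields `windows`,
#'   `samples`, `detection` and `bin_size`.
#' @export
gam_segregation <- function(windows, detection, samples = colnames(detection),
                            bin_size = NULL) {
  windows <- as.data.frame(windows)[, c("chrom", "start", "end")]
  windows$chrom <- as.character(windows$chrom)
  detection <- as.matrix(detection)
  if (is.numeric(detection)) {
    if (!all(detection %in% c(0, 1)))
      stop("detection values must be boolean (0/1)")
    detection <- detection > 0
  }
  if (!is.logical(detection)) stop("detection must be a logical matrix")
  if (nrow(windows) != nrow(detection))
    stop("windows and detection row counts differ")
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(detection)))
  colnames(detection) <- samples
  obj <- structure(
    list(windows = windows, samples = as.character(samples),
         detection = detection,
         bin_size = bin_size %||% infer_bin_size(windows)),
    class = "gam_segregation")
  validate_windows(obj$windows)
  obj
}

#' Construct a GAM coverage table
#'
#' Same layout as [gam_segregation()] but cells hold non-negative integer
#' nucleotide counts per window per sample.
#'
#' @inheritParams gam_segregation
#' @param nucleotides numeric matrix of non-negative counts, windows x samples.
#' @return An object of class `gam_coverage`.
#' @export
gam_coverage <- function(windows, nucleotides, samples = colnames(nucleotides),
                         bin_size = NULL) {
  windows <- as.data.frame(windows)[, c("chrom", "start", "end")]
  windows$chrom <- as.character(windows$chrom)
  nucleotides <- as.matrix(nucleotides)
  if (any(!is.finite(nucleotides)) || any(nucleotides < 0))
    stop("nucleotide counts must be finite and non-negative")
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(nucleotides)))
  colnames(nucleotides) <- samples
  obj <- structure(
    list(windows = windows, samples = as.character(samples),
         nucleotides = nucleotides,
         bin_size = bin_size %||% infer_bin_size(windows)),
    class = "gam_coverage")
  validate_windows(obj$windows)
  obj
}

#' @export
print.gam_segregation <- function(x, ...) {
  cat(sprintf("GAM segregation table: %d windows x %d samples (bin size %s bp)\n",
              nrow(x$windows), length(x$samples), format(x$bin_size, big.mark = ",")))
  cat(sprintf("  chromosomes: %s\n", paste(unique(x$windows$chrom), collapse = ", ")))
  cat(sprintf("  mean per-sample detection rate: %.3f\n", mean(x$detection)))
  invisible(x)
}

#' @export
print.gam_coverage <- function(x, ...) {
  cat(sprintf("GAM coverage table: %d windows x %d samples (bin size %s bp)\n",
              nrow(x$windows), length(x$samples), format(x$bin_size, big.mark = ",")))
  invisible(x)
}

#' @export
summary.gam_segregation <- function(object, ...) {
  freq <- rowMeans(object$detection)
  res <- list(n_windows = nrow(object$windows),
              n_samples = length(object$samples),
              bin_size = object$bin_size,
              detection_frequency = summary(freq),
              per_sample_positive = summary(colSums(object$detection)))
  class(res) <- "summary.gam_segregation"
  res
}

#' @export
print.summary.gam_segregation <- function(x, ...) {
  cat(sprintf("%d windows x %d samples, bin size %d bp\n",
              x$n_windows, x$n_samples, x$bin_size))
  cat("per-window detection frequency:\n"); print(x$detection_frequency)
  cat("positive windows per sample:\n"); print(x$per_sample_positive)
  invisible(x)
}

#' Per-window detection frequency
#'
#' Fraction of NP samples in which each window is detected.
#'
#' @param seg a `gam_segregation` object.
#' @return numeric vector, one value per window.
#' @export
detection_frequency <- function(seg) {
  stopifnot(inherits(seg, "gam_segregation"))
  rowMeans(seg$detection)
}

## internal -------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

infer_bin_size <- function(windows) {
  w <- windows$end - windows$start
  as.integer(names(sort(table(w), decreasing = TRUE))[1])
}

## sortedness, no duplicates, positive width; the last window of a
## chromosome may be shorter than the bin size.
validate_windows <- function(windows) {
  if (any(windows$start >= windows$end)) stop("windows must satisfy start < end")
  key <- paste(windows$chrom, windows$start)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate window rows (first: ", d, ")")
  }
  ord <- order(windows$chrom, windows$start, method = "radix")
  if (!identical(ord, seq_len(nrow(windows))))
    stop("windows must be sorted by (chrom, start)")
  invisible(TRUE)
}

## Sort a windows/matrix pair, warning when input order had to change.
sort_windows <- function(windows, mat, what = "table") {
  ord <- order(windows$chrom, windows$start, method = "radix")
  if (!identical(ord, seq_len(nrow(windows)))) {
    warning(what, " rows were not sorted by (chrom, start); auto-sorted")
    windows <- windows[ord, , drop = FALSE]
    rownames(windows) <- NULL
    mat <- mat[ord, , drop = FALSE]
  }
  list(windows = windows, mat = mat)
}

## Row indices of one chromosome, erroring when absent.
chrom_rows <- function(windows, chrom) {
  idx <- which(windows$chrom == chrom)
  if (!length(idx))
    stop("chromosome '", chrom, "' not present; available: ",
         paste(unique(windows$chrom), collapse = ", "))
  idx
}
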
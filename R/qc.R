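## Window calling and sample QC.
##
## Each NP sample is thresholded on nucleotide coverage.  The threshold is
## chosen per sample by scanning the integer percentiles of the strictly
## positive coverage distribution and keeping the percentile whose detection
## pattern minimises the fraction of orphan windows (positive windows whose
## neighbouring windows are both negative) -- orphan windows are a noise
## proxy, so minimising them maximises the signal quality of the calls.

#' Fraction of orphan windows
#'
#' A positive window is an orphan when its adjacent windows on the same
#' chromosome are both negative.  Chromosome-edge positives with a single
#' negative neighbour also count as orphans (conservative single-neighbour
#' rule).  Returns 0 when there are no positive windows.
#'
#' @param detection logical vector of per-window detection, ordered by
#'   genomic position within each chromosome.
#' @param chrom optional chromosome label per window; windows are never
#'   compared across chromosomes.  Default: one chromosome.
#' @return proportion of positive windows that are orphans.
#' @export
orphan_fraction <- function(detection, chrom = NULL) {
  detection <- as.logical(detection)
  if (is.null(chrom)) chrom <- rep("*", length(detection))
  stopifnot(length(chrom) == length(detection))
  n_pos <- 0L; n_orph <- 0L
  for (ch in unique(chrom)) {
    d <- detection[chrom == ch]
    n <- length(d)
    if (!any(d)) next
    left <- c(FALSE, d[-n])   # missing neighbour counts as negative
    right <- c(d[-1], FALSE)
    n_pos <- n_pos + sum(d)
    n_orph <- n_orph + sum(d & !left & !right)
  }
  if (n_pos == 0L) return(0)
  n_orph / n_pos
}

#' Call positive windows for one NP sample
#'
#' Scans integer percentiles 0--99 of the strictly positive coverage values;
#' for each percentile the threshold is that quantile and windows with
#' coverage strictly greater than the threshold are positive (percentile 0
#' uses threshold 0, keeping every positive-coverage window).  The chosen
#' percentile minimises the orphan fraction, ties broken towards the lowest
#' percentile (retains more windows).
#'
#' @param coverage non-negative numeric vector of per-window nucleotide
#'   counts, genome-ordered.
#' @param chrom optional chromosome label per window (see
#'   [orphan_fraction()]).
#' @param sample_id identifier carried through to the result.
#' @return An object of class `gam_window_call`: a list with
#'   `sample_id`, `chosen_percentile`, `threshold`, `detection` (logical),
#'   `orphan_fraction` and `grid` (the full percentile scan).
#' @export
call_windows <- function(coverage, chrom = NULL, sample_id = "sample") {
  if (any(coverage < 0)) stop("coverage must be non-negative")
  pos <- coverage[coverage > 0]
  if (!length(pos)) {
    warning("all-zero coverage for ", sample_id, "; no windows called")
    res <- list(sample_id = sample_id, chosen_percentile = NA_integer_,
                threshold = NA_real_,
                detection = rep(FALSE, length(coverage)),
                orphan_fraction = 0,
                grid = data.frame(percentile = integer(), threshold = numeric(),
                                  orphan_fraction = numeric()))
    class(res) <- "gam_window_call"
    return(res)
  }
  pct <- 0:99
  thr <- unname(quantile(pos, pct / 100, type = 7))
  ## percentile 0 keeps every positive-coverage window: with a strict
  ## `> threshold` rule that requires a cut below the smallest positive value
  thr[1] <- 0
  orph <- vapply(thr, function(t)
    orphan_fraction(coverage > t, chrom), numeric(1))
  best <- which.min(orph)  # which.min takes the first (lowest percentile) tie
  res <- list(sample_id = sample_id,
              chosen_percentile = pct[best],
              threshold = thr[best],
              detection = coverage > thr[best],
              orphan_fraction = orph[best],
              grid = data.frame(percentile = pct, threshold = thr,
                                orphan_fraction = orph))
  class(res) <- "gam_window_call"
  res
}

#' @export
print.gam_window_call <- function(x, ...) {
  cat(sprintf("window call for '%s': percentile %s (threshold %s), %d positive, orphan fraction %.4f\n",
              x$sample_id, x$chosen_percentile, format(x$threshold),
              sum(x$detection), x$orphan_fraction))
  invisible(x)
}

#' Call windows for every sample of a coverage table
#'
#' Applies [call_windows()] per sample and assembles a segregation table.
#'
#' @param cov a [gam_coverage()] object.
#' @return a [gam_segregation()] object with an attribute `calls` holding the
#'   per-sample `gam_window_call` results.
#' @export
call_windows_table <- function(cov) {
  stopifnot(inherits(cov, "gam_coverage"))
  calls <- lapply(seq_along(cov$samples), function(j)
    call_windows(cov$nucleotides[, j], cov$windows$chrom, cov$samples[j]))
  det <- do.call(cbind, lapply(calls, `[[`, "detection"))
  seg <- gam_segregation(cov$windows, det, samples = cov$samples,
                         bin_size = cov$bin_size)
  attr(seg, "calls") <- calls
  seg
}

#' Jaccard index between two detection patterns
#'
#' Used as the cross-well contamination score between samples from the same
#' collection plate.  Defined as 0 when both sets are empty.
#'
#' @param a,b logical detection vectors over the same window universe.
#' @return |a intersect b| / |a union b|.
#' @export
pairwise_jaccard <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Cross-well contamination score per sample
#'
#' For each sample, the maximum Jaccard index of its detection pattern to any
#' other sample on the same collection plate.  Samples alone on their plate
#' score 0.
#'
#' @param seg a `gam_segregation` object.
#' @param plates data.frame with columns `sample` and `plate`.
#' @return named numeric vector of scores, one per sample in `seg`.
#' @export
contamination_scores <- function(seg, plates) {
  stopifnot(inherits(seg, "gam_segregation"))
  plates <- as.data.frame(plates)
  miss <- setdiff(seg$samples, plates$sample)
  if (length(miss)) stop("samples missing from plate map: ",
                         paste(miss, collapse = ", "))
  plate_of <- stats::setNames(as.character(plates$plate), plates$sample)
  scores <- stats::setNames(numeric(length(seg$samples)), seg$samples)
  for (s in seg$samples) {
    mates <- seg$samples[plate_of[seg$samples] == plate_of[s] & seg$samples != s]
    if (!length(mates)) next
    scores[s] <- max(vapply(mates, function(m)
      pairwise_jaccard(seg$detection[, s], seg$detection[, m]), numeric(1)))
  }
  scores
}

#' Assemble per-sample QC reports
#'
#' @param seg a `gam_segregation` object.
#' @param mapped_reads named numeric vector (or data.frame with columns
#'   `sample`, `mapped_reads`) of uniquely mapped read counts.
#' @param plates plate map passed to [contamination_scores()].
#' @return data.frame with columns `sample`, `orphan_fraction`,
#'   `mapped_reads`, `max_jaccard_to_platemates`, `passed`.
#' @export
sample_qc <- function(seg, mapped_reads, plates) {
  stopifnot(inherits(seg, "gam_segregation"))
  if (is.data.frame(mapped_reads))
    mapped_reads <- stats::setNames(mapped_reads$mapped_reads, mapped_reads$sample)
  orph <- vapply(seq_along(seg$samples), function(j)
    orphan_fraction(seg$detection[, j], seg$windows$chrom), numeric(1))
  jac <- contamination_scores(seg, plates)
  rep <- data.frame(sample = seg$samples,
                    orphan_fraction = orph,
                    mapped_reads = as.numeric(mapped_reads[seg$samples]),
                    max_jaccard_to_platemates = as.numeric(jac[seg$samples]))
  qc_filter(rep)
}

#' Apply the sample QC pass criteria
#'
#' A sample passes when it has an orphan fraction below 0.70, more than
#' 50,000 uniquely mapped reads and a cross-well contamination (Jaccard)
#' score below 0.4.  All three thresholds are strict.
#'
#' @param reports data.frame with columns `orphan_fraction`, `mapped_reads`,
#'   `max_jaccard_to_platemates` (plus any id columns, carried through).
#' @param max_orphan,min_reads,max_jaccard the three cut-offs.
#' @return `reports` with a logical `passed` column added.
#' @export
qc_filter <- function(reports, max_orphan = 0.70, min_reads = 50000,
                      max_jaccard = 0.4) {
  need <- c("orphan_fraction", "mapped_reads", "max_jaccard_to_platemates")
  miss <- setdiff(need, names(reports))
  if (length(miss)) stop("missing QC metrics: ", paste(miss, collapse = ", "))
  if (anyNA(reports[, need])) stop("QC metrics contain missing values")
  reports$passed <- reports$orphan_fraction < max_orphan &
    reports$mapped_reads > min_reads &
    reports$max_jaccard_to_platemates < max_jaccard
  message(sum(reports$passed), "/", nrow(reports), " samples pass QC")
  reports
}

#' Fraction of intrachromosomal window pairs sampled at least once
#'
#' Over each chromosome, considers all pairs of windows that are detected in
#' at least one sample, and counts the fraction of those pairs co-detected
#' in at least one sample.  Pairs involving never-detected windows are
#' excluded from the denominator.
#'
#' @param seg a `gam_segregation` object.
#' @return proportion in `[0, 1]`.
#' @export
pair_sampling_coverage <- function(seg) {
  stopifnot(inherits(seg, "gam_segregation"))
  if (!length(seg$samples)) stop("segregation table has no samples")
  tot <- 0; co <- 0
  for (ch in unique(seg$windows$chrom)) {
    D <- seg$detection[seg$windows$chrom == ch, , drop = FALSE]
    D <- D[rowSums(D) > 0, , drop = FALSE]
    k <- nrow(D)
    if (k < 2) next
    tot <- tot + k * (k - 1) / 2
    C <- tcrossprod(D * 1)
    co <- co + (sum(C > 0) - k) / 2   # off-diagonal co-detected pairs
  }
  if (tot == 0) return(1)
  co / tot
}
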
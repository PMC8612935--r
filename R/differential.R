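## Differential contacts between two GAM datasets and aggregate pileups.
##
## Contacts are compared on distance-normalized (Z-score) matrices:
## D = z_A - z_B on window pairs that survive three filters -- low-detection
## window removal (detection frequency below the 2nd percentile of the
## per-window detection-frequency distribution on that chromosome, removed
## jointly from both datasets), a genomic distance range (0.5-5 Mb by
## default), and an NPMI floor (> 0.15 in at least one dataset).  The top
## quantile by D is reported as A-specific, by -D as B-specific.

#' Differential contacts between two datasets on one chromosome
#'
#' @param zA,zB `gam_matrix` objects of layer `"zscore"` (same binning).
#' @param npmiA,npmiB the matching NPMI matrices, used for the contact floor.
#' @param freqA,freqB per-window detection frequencies for this chromosome
#'   (from [detection_frequency()]).
#' @param d_min,d_max genomic distance range in bp (inclusive). Defaults
#'   0.5--5 Mb.
#' @param npmi_floor minimum NPMI, required in at least one dataset.
#' @param top_quantile fraction of the filtered pairs returned in each
#'   direction (default 0.05).
#' @param low_detection_pct percentile (as a fraction) of the detection
#'   frequency distribution below which windows are removed.
#' @return An object of class `gam_differential`: list with `contacts`
#'   (data.frame: `i`, `j`, `start_i`, `start_j`, `distance`, `D`,
#'   `direction` in \{"A", "B"\}), `n_filtered_pairs`, and the parameters.
#' @export
differential_contacts <- function(zA, zB, npmiA, npmiB, freqA, freqB,
                                  d_min = 5e5, d_max = 5e6,
                                  npmi_floor = 0.15, top_quantile = 0.05,
                                  low_detection_pct = 0.02) {
  stopifnot(inherits(zA, "gam_matrix"), inherits(zB, "gam_matrix"))
  if (zA$bin_size != zB$bin_size) stop("bin size mismatch between datasets")
  n <- nrow(zA$values)
  if (nrow(zB$values) != n) stop("matrix dimension mismatch between datasets")
  stopifnot(length(freqA) == n, length(freqB) == n)

  keep <- window_detection_filter(freqA, low_detection_pct) &
    window_detection_filter(freqB, low_detection_pct)

  ut <- which(upper.tri(zA$values), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  dist_bp <- (j - i) * zA$bin_size
  nA <- npmiA$values[ut]; nB <- npmiB$values[ut]
  ok <- keep[i] & keep[j] &
    dist_bp >= d_min & dist_bp <= d_max &
    ((!is.na(nA) & nA > npmi_floor) | (!is.na(nB) & nB > npmi_floor)) &
    is.finite(zA$values[ut]) & is.finite(zB$values[ut])
  params <- list(d_min = d_min, d_max = d_max, npmi_floor = npmi_floor,
                 top_quantile = top_quantile,
                 low_detection_pct = low_detection_pct)
  empty <- data.frame(i = integer(), j = integer(), start_i = integer(),
                      start_j = integer(), distance = numeric(),
                      D = numeric(), direction = character())
  if (!any(ok)) {
    return(structure(list(contacts = empty, n_filtered_pairs = 0L,
                          chrom = zA$chrom, params = params),
                     class = "gam_differential"))
  }
  i <- i[ok]; j <- j[ok]; dist_bp <- dist_bp[ok]
  D <- zA$values[cbind(i, j)] - zB$values[cbind(i, j)]
  npairs <- length(D)
  if (max(abs(D)) == 0) {
    warning("all differential values are exactly zero; returning no contacts")
    return(structure(list(contacts = empty, n_filtered_pairs = npairs,
                          chrom = zA$chrom, params = params),
                     class = "gam_differential"))
  }
  n_top <- ceiling(top_quantile * npairs)
  ordA <- order(-D, i, j)[seq_len(n_top)]
  ordB <- order(D, i, j)[seq_len(n_top)]
  mk <- function(sel, lab) data.frame(
    i = i[sel], j = j[sel],
    start_i = zA$starts[i[sel]], start_j = zA$starts[j[sel]],
    distance = dist_bp[sel], D = D[sel], direction = lab)
  structure(list(contacts = rbind(mk(ordA, "A"), mk(ordB, "B")),
                 n_filtered_pairs = npairs, chrom = zA$chrom,
                 params = params),
            class = "gam_differential")
}

#' @export
print.gam_differential <- function(x, ...) {
  cat(sprintf("differential contacts on %s: %d filtered pairs, %d A-specific, %d B-specific\n",
              x$chrom, x$n_filtered_pairs,
              sum(x$contacts$direction == "A"),
              sum(x$contacts$direction == "B")))
  invisible(x)
}

## windows kept when detection frequency >= the low percentile of the
## detected-window frequency distribution of the chromosome
window_detection_filter <- function(freq, pct) {
  detected <- freq[freq > 0]
  if (!length(detected)) return(rep(FALSE, length(freq)))
  thr <- unname(quantile(detected, pct, type = 7))
  freq >= thr
}

#' Aggregate contact pileup
#'
#' Mean Z-score over the (2r+1) x (2r+1) patch around each contact, pooled
#' per chromosome, then averaged across chromosomes: the per-chromosome
#' pooled means are added together and divided by the number of chromosomes
#' contributing contacts.  Patches are truncated at matrix edges; masked
#' cells are excluded.
#'
#' @param z_list named list of `gam_matrix` Z-score objects, one per
#'   chromosome.
#' @param contacts data.frame with columns `chrom`, `i`, `j` (1-based bin
#'   indices into the corresponding matrix).
#' @param radius patch radius in bins (default 4).
#' @return the aggregate mean value (scalar).
#' @export
aggregate_pileup <- function(z_list, contacts, radius = 4) {
  contacts <- as.data.frame(contacts)
  chroms <- unique(contacts$chrom)
  miss <- setdiff(chroms, names(z_list))
  if (length(miss)) stop("no matrix supplied for: ", paste(miss, collapse = ", "))
  per_chrom <- vapply(chroms, function(ch) {
    v <- z_list[[ch]]$values
    n <- nrow(v)
    cc <- contacts[contacts$chrom == ch, , drop = FALSE]
    if (any(cc$i < 1 | cc$i > n | cc$j < 1 | cc$j > n))
      stop("contact outside matrix bounds on ", ch)
    cells <- numeric(0)
    for (k in seq_len(nrow(cc))) {
      ri <- max(1, cc$i[k] - radius):min(n, cc$i[k] + radius)
      rj <- max(1, cc$j[k] - radius):min(n, cc$j[k] + radius)
      cells <- c(cells, v[ri, rj])
    }
    mean(cells[is.finite(cells)])
  }, numeric(1))
  sum(per_chrom) / length(per_chrom)
}
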
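## Contact matrices: co-segregation, NPMI normalization and
## distance-stratified Z-scores.
##
## The contact strength between two windows x and y is measured by the
## pointwise mutual information of their detection across NP samples,
##   PMI  = log( p(x,y) / (p(x) p(y)) ),
## normalized to [-1, 1] by dividing by -log p(x,y):
##   NPMI = PMI / (-log p(x,y)).
## NPMI is 1 for perfect co-occurrence (p(x,y) = p(x) = p(y)), 0 under
## independence and negative for avoidance.  Entries where p(x,y) = 0 (or a
## marginal is 0, or p(x,y) = 1, where the normaliser vanishes) are
## undefined and carried as NA; NA entries are excluded from every
## downstream mean.  The logarithm base is irrelevant (NPMI is a ratio of
## logs); natural log is used.

#' Construct a contact matrix object
#'
#' @param values symmetric numeric matrix; NA marks undefined (masked)
#'   entries.
#' @param chrom chromosome name.
#' @param bin_size bin size in bp.
#' @param starts window start coordinates (bp), one per row.
#' @param layer one of `"coseg"`, `"npmi"`, `"zscore"`, `"oe"`, `"diff"`.
#' @param ... extra fields stored on the object (e.g. `marginal`,
#'   `n_samples` for co-segregation layers).
#' @return an object of class `gam_matrix`.
#' @export
gam_matrix <- function(values, chrom, bin_size, starts = NULL,
                       layer = "coseg", ...) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("contact matrix must be square")
  if (is.null(starts)) starts <- bin_size * (seq_len(nrow(values)) - 1L)
  structure(list(values = values, chrom = chrom,
                 bin_size = as.integer(bin_size),
                 starts = as.integer(starts), layer = layer, ...),
            class = "gam_matrix")
}

#' @export
print.gam_matrix <- function(x, ...) {
  fin <- mean(is.finite(x$values))
  cat(sprintf("GAM %s matrix: %s, %d bins x %d bins (bin size %s bp), %.1f%% defined\n",
              x$layer, x$chrom, nrow(x$values), ncol(x$values),
              format(x$bin_size, big.mark = ","), 100 * fin))
  invisible(x)
}

#' @export
dim.gam_matrix <- function(x) dim(x$values)

#' Co-segregation matrix for one chromosome
#'
#' Marginal detection frequencies p(x) = detections / n_samples and joint
#' frequencies p(x,y) = co-detections / n_samples.  The diagonal equals the
#' marginal.
#'
#' @param seg a [gam_segregation()] object with at least one sample.
#' @param chrom chromosome to extract (literal name match).
#' @return a `gam_matrix` with layer `"coseg"` and fields `marginal`,
#'   `n_samples`.
#' @export
cosegregation <- function(seg, chrom) {
  stopifnot(inherits(seg, "gam_segregation"))
  if (!length(seg$samples)) stop("segregation table has no samples")
  idx <- chrom_rows(seg$windows, chrom)
  D <- seg$detection[idx, , drop = FALSE] * 1
  n <- ncol(D)
  joint <- tcrossprod(D) / n
  gam_matrix(joint, chrom = chrom, bin_size = seg$bin_size,
             starts = seg$windows$start[idx], layer = "coseg",
             marginal = rowSums(D) / n, n_samples = n)
}

#' NPMI normalization of a co-segregation matrix
#'
#' NPMI = log(p(x,y) / (p(x) p(y))) / (-log p(x,y)).  Entries with
#' p(x,y) = 0, a zero marginal, or p(x,y) = 1 are masked (NA).  Defined
#' values are clamped to `[-1, 1]` against floating-point drift.
#'
#' @param coseg a `gam_matrix` of layer `"coseg"` (from [cosegregation()]).
#' @return a `gam_matrix` with layer `"npmi"`.
#' @export
npmi <- function(coseg) {
  stopifnot(inherits(coseg, "gam_matrix"), coseg$layer == "coseg")
  pxy <- coseg$values
  px <- coseg$marginal
  P <- outer(px, px)
  undef <- pxy == 0 | P == 0 | pxy == 1
  v <- suppressWarnings(log(pxy / P) / (-log(pxy)))
  v[undef] <- NA_real_
  v <- pmin(pmax(v, -1), 1)
  gam_matrix(v, chrom = coseg$chrom, bin_size = coseg$bin_size,
             starts = coseg$starts, layer = "npmi",
             marginal = px, n_samples = coseg$n_samples)
}

#' Distance-stratified Z-score normalization
#'
#' For each genomic distance (off-diagonal) the finite contact values are
#' standardised to mean 0, population sd 1.  Degenerate diagonals (fewer
#' than two finite entries or zero spread) are set to 0; masked entries stay
#' NA.  The main diagonal is set to 0.
#'
#' @param m a `gam_matrix` (typically NPMI layer).
#' @return a `gam_matrix` with layer `"zscore"` and fields `diag_mean`,
#'   `diag_sd` (the per-distance statistics used).
#' @export
distance_zscore <- function(m) {
  stopifnot(inherits(m, "gam_matrix"))
  v <- m$values
  n <- nrow(v)
  z <- matrix(NA_real_, n, n)
  dm <- rep(NA_real_, n); ds <- rep(NA_real_, n)   # index d+1 for distance d
  diag(z) <- ifelse(is.finite(diag(v)), 0, NA_real_)
  for (d in seq_len(n - 1)) {
    i <- seq_len(n - d)
    idx <- cbind(i, i + d)
    x <- v[idx]
    fin <- is.finite(x)
    if (sum(fin) >= 2) {
      mu <- mean(x[fin])
      sig <- sqrt(mean((x[fin] - mu)^2))   # population sd: normalization, not inference
    } else {
      mu <- if (any(fin)) x[fin][1] else NA_real_
      sig <- 0
    }
    dm[d + 1] <- mu; ds[d + 1] <- sig
    zx <- if (!is.na(sig) && sig > 0) (x - mu) / sig else ifelse(fin, 0, NA_real_)
    zx[!fin] <- NA_real_
    z[idx] <- zx
    z[idx[, 2:1, drop = FALSE]] <- zx
  }
  gam_matrix(z, chrom = m$chrom, bin_size = m$bin_size, starts = m$starts,
             layer = "zscore", diag_mean = dm, diag_sd = ds)
}

#' Genome-wide NPMI matrix (cis and trans)
#'
#' Joint and marginal detection frequencies over all windows of the table,
#' NPMI-normalized as in [npmi()].  Used for trans-cis ratio analysis where
#' interchromosomal entries are needed.
#'
#' @param seg a `gam_segregation` object.
#' @return list with `values` (windows x windows NPMI matrix, NA-masked),
#'   `windows` (the window table) and `marginal`.
#' @export
npmi_genomewide <- function(seg) {
  stopifnot(inherits(seg, "gam_segregation"))
  D <- seg$detection * 1
  n <- ncol(D)
  pxy <- tcrossprod(D) / n
  px <- rowSums(D) / n
  P <- outer(px, px)
  undef <- pxy == 0 | P == 0 | pxy == 1
  v <- suppressWarnings(log(pxy / P) / (-log(pxy)))
  v[undef] <- NA_real_
  v <- pmin(pmax(v, -1), 1)
  list(values = v, windows = seg$windows, marginal = px)
}
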
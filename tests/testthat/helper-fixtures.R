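## Shared fixture builders. Everything is generated in code; no binary data.

## tiny segregation table from a 0/1 matrix (rows = windows)
make_seg <- function(mat, chrom = rep("chr1", nrow(mat)), bin_size = 5e4) {
  starts <- unlist(lapply(split(seq_along(chrom), chrom)[unique(chrom)],
                          seq_along)) - 1L
  ## starts per chromosome restart at 0
  starts <- integer(length(chrom))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    starts[idx] <- (seq_along(idx) - 1L) * bin_size
  }
  gam_segregation(
    data.frame(chrom = chrom, start = starts, end = starts + bin_size),
    mat > 0,
    samples = if (is.null(colnames(mat))) paste0("S", seq_len(ncol(mat)))
              else colnames(mat),
    bin_size = bin_size)
}

## random segregation table with independent windows
random_seg <- function(n_windows, n_samples, p = 0.3,
                       chrom = rep("chr1", n_windows)) {
  make_seg(matrix(rbinom(n_windows * n_samples, 1, p), n_windows), chrom)
}

## brute-force NPMI for one window pair by explicit sample counting
npmi_pair_oracle <- function(det, i, j) {
  n <- ncol(det)
  px <- sum(det[i, ]) / n
  py <- sum(det[j, ]) / n
  pxy <- sum(det[i, ] & det[j, ]) / n
  if (pxy == 0 || px == 0 || py == 0 || pxy == 1) return(NA_real_)
  log(pxy / (px * py)) / (-log(pxy))
}

## brute-force insulation score oracle: explicit patch mean
insulation_oracle <- function(values, k) {
  n <- nrow(values)
  s <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - k < 1 || i + k > n) next
    acc <- c()
    for (r in (i - k):(i - 1)) for (cc in (i + 1):(i + k))
      acc <- c(acc, values[r, cc])
    if (any(is.finite(acc))) s[i] <- mean(acc, na.rm = TRUE)
  }
  s
}

## one-sided KS permutation p-value oracle
ks_perm_oracle <- function(ref, query, n_perm = 2000) {
  D <- ks_dplus(ref, query)
  pool <- c(ref, query)
  n1 <- length(ref)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(pool), n1)
    if (ks_dplus(pool[idx], pool[-idx]) >= D - 1e-12) cnt <- cnt + 1L
  }
  cnt / n_perm
}

## simple symmetric matrix helper
sym <- function(m) { m[lower.tri(m)] <- t(m)[lower.tri(m)]; m }
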
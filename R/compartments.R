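## A/B compartment calling.
##
## Per chromosome, the observed co-segregation matrix O(i,j) is divided by
## the expected value E(d) -- the mean contact at each genomic distance --
## to give an O/E matrix; the correlation matrix C(i,j) between its columns
## is decomposed by PCA, and among the first three components the one best
## correlated with GC content is taken as the compartment eigenvector.  The
## sign is fixed so that the GC correlation is positive: bins with positive
## values are compartment A (gene-rich, open), negative are B.  For display
## and cross-dataset correlation, A values are normalized to (0, 1] and B
## values to [-1, 0) per chromosome.

#' Observed/expected matrix
#'
#' E(d) is the mean of finite observed values over each diagonal; entries
#' are divided by the E of their distance.  Masked (NA) observed entries
#' stay masked and are excluded from E; diagonals with E = 0 are masked.
#'
#' @param m a `gam_matrix` (co-segregation layer for compartment analysis).
#' @return a `gam_matrix` with layer `"oe"`.
#' @export
observed_expected <- function(m) {
  stopifnot(inherits(m, "gam_matrix"))
  v <- m$values
  n <- nrow(v)
  oe <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    idx <- cbind(i, i + d)
    x <- v[idx]
    e <- mean(x[is.finite(x)])
    if (is.finite(e) && e > 0) {
      oe[idx] <- x / e
      oe[idx[, 2:1, drop = FALSE]] <- x / e
    }
  }
  gam_matrix(oe, chrom = m$chrom, bin_size = m$bin_size, starts = m$starts,
             layer = "oe")
}

#' Compartment eigenvector with GC orientation
#'
#' Builds the missing-aware column correlation matrix C of the O/E matrix
#' (pairwise-complete Pearson; bins with under half their entries finite are
#' dropped), runs PCA on C, and among the first three components picks the
#' one with the highest absolute Pearson correlation to GC content, flipped
#' so the correlation is positive.  Positive values are labelled A, negative
#' B; exact zeros get a missing label.  A values are normalized by the
#' chromosome maximum, B values by the absolute minimum.
#'
#' @param oe a `gam_matrix` of layer `"oe"`.
#' @param gc numeric vector of per-bin GC proportions (same binning).
#' @param min_finite_frac bins with a smaller fraction of finite O/E entries
#'   are dropped before PCA (default 0.5).
#' @return data.frame of class `gam_compartments`: `chrom`, `start`, `end`,
#'   `eigenvector` (normalized, NA for dropped bins), `label` ("A"/"B"/NA);
#'   attributes `pc_index` and `gc_correlation`.
#' @export
compartment_eigenvector <- function(oe, gc, min_finite_frac = 0.5) {
  stopifnot(inherits(oe, "gam_matrix"))
  n <- nrow(oe$values)
  stopifnot(length(gc) == n)
  out <- data.frame(chrom = oe$chrom, start = oe$starts,
                    end = oe$starts + oe$bin_size,
                    eigenvector = NA_real_, label = NA_character_)
  keep <- colMeans(is.finite(oe$values)) >= min_finite_frac
  if (sum(keep) < 10) {
    warning("fewer than 10 usable bins on ", oe$chrom, "; chromosome skipped")
    return(finish_compartments(out, NA_integer_, NA_real_))
  }
  sub <- oe$values[keep, keep, drop = FALSE]
  C <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))
  ok2 <- colMeans(is.finite(C)) >= min_finite_frac
  C <- C[ok2, ok2, drop = FALSE]
  keep_idx <- which(keep)[ok2]
  C[!is.finite(C)] <- 0
  if (nrow(C) < 10 || all(abs(C - mean(C)) < 1e-12)) {
    warning("degenerate correlation matrix on ", oe$chrom, "; chromosome skipped")
    return(finish_compartments(out, NA_integer_, NA_real_))
  }
  pc <- prcomp(C, center = TRUE, scale. = FALSE)
  ncomp <- min(3, ncol(pc$x))
  cors <- vapply(seq_len(ncomp), function(k)
    suppressWarnings(cor(pc$x[, k], gc[keep_idx])), numeric(1))
  cors[!is.finite(cors)] <- 0
  k <- which.max(abs(cors))
  ev <- pc$x[, k] * sign(cors[k])
  out$eigenvector[keep_idx] <- ev
  finish_compartments(out, k, abs(cors[k]))
}

finish_compartments <- function(out, pc_index, gc_cor) {
  ev <- out$eigenvector
  pos <- !is.na(ev) & ev > 0
  neg <- !is.na(ev) & ev < 0
  if (any(pos)) out$eigenvector[pos] <- ev[pos] / max(ev[pos])
  if (any(neg)) out$eigenvector[neg] <- ev[neg] / abs(min(ev[neg]))
  out$label[pos] <- "A"
  out$label[neg] <- "B"
  out$label[!is.na(ev) & ev == 0] <- NA_character_  # zero crossing: no side
  attr(out, "pc_index") <- pc_index
  attr(out, "gc_correlation") <- gc_cor
  class(out) <- c("gam_compartments", "data.frame")
  out
}

#' Call compartments from a segregation table
#'
#' Convenience wrapper: co-segregation, observed/expected and GC-oriented
#' eigenvector per chromosome.
#'
#' @param seg a `gam_segregation` object (typically at 250-kb bins).
#' @param gc data.frame `chrom`, `start`, `end`, `value` of per-bin GC
#'   proportions matching the segregation binning.
#' @param chroms chromosomes to process (default: all in `seg`).
#' @return a single `gam_compartments` data.frame (rows for all chromosomes).
#' @export
call_compartments <- function(seg, gc, chroms = unique(seg$windows$chrom)) {
  gc <- as.data.frame(gc)
  res <- lapply(chroms, function(ch) {
    oe <- observed_expected(cosegregation(seg, ch))
    g <- gc[gc$chrom == ch, , drop = FALSE]
    g <- g$value[match(oe$starts, g$start)]
    if (anyNA(g)) stop("GC track does not cover all bins on ", ch)
    compartment_eigenvector(oe, g)
  })
  out <- do.call(rbind, res)
  class(out) <- c("gam_compartments", "data.frame")
  out
}

#' Compartment transitions between two datasets
#'
#' Classifies each bin defined in both tracks as A->A, A->B, B->A or B->B
#' and reports genome-wide fractions over the defined bins.  Optional
#' replicate tracks enforce a consensus pre-filter: a bin is kept only when
#' the two replicates of a dataset agree on its label.
#'
#' @param trackA,trackB `gam_compartments` tracks on the same binning.
#' @param repA2,repB2 optional second replicates for consensus filtering.
#' @return list with `per_bin` (data.frame `chrom`, `start`, `class`) and
#'   `fractions` (named vector over the four classes).
#' @export
compartment_transitions <- function(trackA, trackB, repA2 = NULL, repB2 = NULL) {
  key <- function(t) paste(t$chrom, t$start)
  a <- as.data.frame(trackA); b <- as.data.frame(trackB)
  m <- match(key(a), key(b))
  lab_a <- a$label
  lab_b <- b$label[m]
  if (!is.null(repA2)) {
    r <- as.data.frame(repA2)$label[match(key(a), key(as.data.frame(repA2)))]
    lab_a[is.na(r) | is.na(lab_a) | r != lab_a] <- NA
  }
  if (!is.null(repB2)) {
    r <- as.data.frame(repB2)$label[match(key(a), key(as.data.frame(repB2)))]
    lab_b[is.na(r) | is.na(lab_b) | r != lab_b] <- NA
  }
  ok <- !is.na(lab_a) & !is.na(lab_b)
  cls <- paste0(lab_a, "->", lab_b)
  cls[!ok] <- NA
  lev <- c("A->A", "A->B", "B->A", "B->B")
  frac <- table(factor(cls[ok], levels = lev)) / max(1, sum(ok))
  list(per_bin = data.frame(chrom = a$chrom, start = a$start, class = cls),
       fractions = stats::setNames(as.numeric(frac), lev))
}
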
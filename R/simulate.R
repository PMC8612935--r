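## In-silico GAM: synthetic polymer-nucleus ensembles and slab slicing.
##
## A chromosome is modelled as a bead chain (several beads per genomic
## window) sampled as a 3D random walk with per-block step sizes.  Planted
## structure:
##  * TAD-like blocks -- beads of a block are pulled towards the block
##    centroid (compaction), so contacts are enriched within blocks and the
##    insulation score dips at block junctions;
##  * A/B compartments -- block centroids are displaced towards one of two
##    opposite anchor points (drawn along a random axis per structure), so
##    same-label blocks co-segregate preferentially, giving the long-range
##    checkerboard that compartment calling detects;
##  * melting -- decondensed blocks use a step size multiplied by a factor
##    > 1, inflating their gyration radius and washing out their contacts.
##
## GAM itself is simulated geometrically: each nuclear profile (NP) is a
## thin slab orthogonal to a uniformly random direction, its offset uniform
## over the structure's extent along that direction (slices may nearly miss
## the structure; empty NPs are allowed, as in real data); a window is
## detected when at least one of its beads falls inside the slab, and a
## sequencing sample pools 3 NPs (multiplex GAM).

#' Generate a synthetic polymer ensemble with planted structure
#'
#' @param blocks data.frame with one row per block: `n_bins` (windows),
#'   optional `step_factor` (default 1; > 1 decondenses/"melts" the block)
#'   and `compartment` ("A"/"B"; default alternating).
#' @param n_structures number of independent 3D conformations.
#' @param beads_per_window beads representing one genomic window.
#' @param step_sd base random-walk step standard deviation (sigma units).
#' @param compaction factor < 1 contracting each block towards its centroid.
#' @param comp_strength fraction of the displacement towards the compartment
#'   anchor that is applied (0 disables compartment structure).
#' @param comp_separation anchor distance from the chain centroid (sigma).
#' @param bin_size genomic window size in bp.
#' @param chrom chromosome name for the window map.
#' @param seed integer seed; the ensemble is deterministic given the seed.
#' @return An object of class `gam_ensemble`: list with `structures` (list
#'   of beads x 3 coordinate matrices), `windows`, `beads_per_window`,
#'   `bin_size` and `truth` (block ids per window, junction bins,
#'   compartment labels, melted block ids, synthetic GC track).
#' @export
simulate_ensemble <- function(blocks, n_structures = 100,
                              beads_per_window = 5, step_sd = 1,
                              compaction = 0.6, comp_strength = 0.8,
                              comp_separation = 6, bin_size = 5e4,
                              chrom = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- as.data.frame(blocks)
  nb <- nrow(blocks)
  if (is.null(blocks$step_factor)) blocks$step_factor <- 1
  if (is.null(blocks$compartment))
    blocks$compartment <- rep(c("A", "B"), length.out = nb)
  n_bins <- sum(blocks$n_bins)
  block_of_bin <- rep(seq_len(nb), blocks$n_bins)
  block_of_bead <- rep(block_of_bin, each = beads_per_window)
  sd_bead <- step_sd * blocks$step_factor[block_of_bead]
  n_beads <- n_bins * beads_per_window

  structures <- vector("list", n_structures)
  for (s in seq_len(n_structures)) {
    steps <- matrix(rnorm(3 * n_beads, sd = rep(sd_bead, 3)), ncol = 3)
    pos <- apply(steps, 2, cumsum)
    for (b in seq_len(nb)) {         # block compaction
      idx <- which(block_of_bead == b)
      cen <- colMeans(pos[idx, , drop = FALSE])
      pos[idx, ] <- (pos[idx, , drop = FALSE] -
                       rep(cen, each = length(idx))) * compaction +
        rep(cen, each = length(idx))
    }
    if (comp_strength > 0) {         # compartment anchors along a random axis
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cc <- colMeans(pos)
      for (b in seq_len(nb)) {
        idx <- which(block_of_bead == b)
        sgn <- if (blocks$compartment[b] == "A") 1 else -1
        target <- cc + sgn * comp_separation * u
        cen <- colMeans(pos[idx, , drop = FALSE])
        pos[idx, ] <- pos[idx, , drop = FALSE] +
          rep(comp_strength * (target - cen), each = length(idx))
      }
    }
    structures[[s]] <- pos
  }
  windows <- data.frame(chrom = chrom,
                        start = bin_size * (seq_len(n_bins) - 1L),
                        end = bin_size * seq_len(n_bins))
  junctions <- cumsum(blocks$n_bins)[-nb]   # last bin index of each block
  gc <- ifelse(blocks$compartment[block_of_bin] == "A", 0.45, 0.40) +
    rnorm(n_bins, 0, 0.005)
  structure(list(structures = structures, windows = windows,
                 beads_per_window = beads_per_window, bin_size = bin_size,
                 truth = list(block_of_bin = block_of_bin,
                              junctions = junctions,
                              compartment = blocks$compartment[block_of_bin],
                              melted_blocks = which(blocks$step_factor > 1),
                              gc = gc),
                 blocks = blocks),
            class = "gam_ensemble")
}

#' @export
print.gam_ensemble <- function(x, ...) {
  cat(sprintf("polymer ensemble: %d structures, %d windows x %d beads (%d blocks)\n",
              length(x$structures), nrow(x$windows), x$beads_per_window,
              nrow(x$blocks)))
  if (length(x$truth$melted_blocks))
    cat("  melted blocks:", paste(x$truth$melted_blocks, collapse = ", "), "\n")
  invisible(x)
}

#' Gyration radius of a bead range
#'
#' Root-mean-square distance of the beads from their centroid, in sigma
#' units; a compaction proxy for a genomic region.
#'
#' @param structure beads x 3 coordinate matrix.
#' @param beads optional index vector selecting a bead range (default all).
#' @return R_g (scalar).
#' @export
gyration_radius <- function(structure, beads = NULL) {
  x <- if (is.null(beads)) structure else structure[beads, , drop = FALSE]
  if (!nrow(x)) stop("empty bead range")
  cen <- colMeans(x)
  sqrt(mean(rowSums((x - rep(cen, each = nrow(x)))^2)))
}

#' Slice an ensemble into a GAM segregation table
#'
#' Each NP picks a structure uniformly at random, a uniformly random slab
#' orientation (normal on the sphere) and a slab offset uniform over the
#' structure's extent along that normal.  The slab width is
#' `thickness x extent`.  A window is positive when at least one of its
#' beads lies in the slab; a sample is the union of `nps_per_sample` NPs.
#'
#' @param ens a `gam_ensemble`.
#' @param n_samples number of sequencing samples to simulate.
#' @param thickness slab width as a fraction of the structure extent along
#'   the slicing axis (default 0.05, the ~220-nm cryosection to micron-scale
#'   nucleus ratio).  Values >= 1 detect everything (warning).
#' @param nps_per_sample nuclear profiles pooled per sample (default 3).
#' @param seed integer seed.
#' @return a [gam_segregation()] object.
#' @export
slice_sample <- function(ens, n_samples, thickness = 0.05,
                         nps_per_sample = 3, seed = NULL) {
  stopifnot(inherits(ens, "gam_ensemble"))
  if (thickness <= 0) stop("thickness must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_bins <- nrow(ens$windows)
  win_of_bead <- rep(seq_len(n_bins), each = ens$beads_per_window)
  det <- matrix(FALSE, n_bins, n_samples)
  if (thickness >= 1) {
    warning("slab thickness covers the full structure; all windows positive")
    det[] <- TRUE
  } else {
    for (s in seq_len(n_samples)) {
      hit <- rep(FALSE, n_bins)
      for (np in seq_len(nps_per_sample)) {
        X <- ens$structures[[sample.int(length(ens$structures), 1)]]
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        t <- as.vector(X %*% u)
        ext <- range(t)
        h <- thickness * (ext[2] - ext[1])
        o <- runif(1, ext[1], ext[2])
        inside <- t >= o - h / 2 & t <= o + h / 2
        if (any(inside)) hit[unique(win_of_bead[inside])] <- TRUE
      }
      det[, s] <- hit
    }
  }
  gam_segregation(ens$windows, det,
                  samples = sprintf("NP3_%04d", seq_len(n_samples)),
                  bin_size = ens$bin_size)
}

#' Ground-truth proximity matrix of an ensemble
#'
#' Mean over structures of 1 / (1 + d_ij), where d_ij is the distance
#' between the centroids of windows i and j -- a smooth, monotone proximity
#' proxy used as the reference when correlating reconstructed NPMI matrices.
#'
#' @param ens a `gam_ensemble`.
#' @return symmetric windows x windows matrix.
#' @export
truth_contact_matrix <- function(ens) {
  stopifnot(inherits(ens, "gam_ensemble"))
  n_bins <- nrow(ens$windows)
  bpw <- ens$beads_per_window
  acc <- matrix(0, n_bins, n_bins)
  for (X in ens$structures) {
    cen <- matrix(0, n_bins, 3)
    for (k in 1:3)
      cen[, k] <- colMeans(matrix(X[, k], nrow = bpw))
    d <- as.matrix(stats::dist(cen))
    acc <- acc + 1 / (1 + d)
  }
  acc / length(ens$structures)
}

#' Correlate a reconstructed NPMI matrix with the ensemble truth
#'
#' Builds the NPMI matrix from a sliced segregation table and returns its
#' Pearson correlation with a truth proximity matrix over the defined
#' off-diagonal entries.
#'
#' @param seg segregation table from [slice_sample()] (single chromosome).
#' @param truth matrix from [truth_contact_matrix()] (same binning).
#' @return Pearson correlation coefficient.
#' @export
reconstruct_and_correlate <- function(seg, truth) {
  stopifnot(inherits(seg, "gam_segregation"))
  if (length(seg$samples) < 100)
    stop("need at least 100 samples for a stable reconstruction")
  ch <- unique(seg$windows$chrom)
  stopifnot(length(ch) == 1)
  m <- npmi(cosegregation(seg, ch))
  ut <- upper.tri(truth)
  ok <- ut & is.finite(m$values) & is.finite(truth)
  x <- m$values[ok]; y <- truth[ok]
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate variance; cannot correlate")
  cor(x, y)
}

#' Default planted-block configuration
#'
#' The standard synthetic chromosome used throughout the package's tests:
#' equal blocks with alternating A/B compartments; optionally one block
#' decondensed by `melt_factor` (the planted "melting gene").
#'
#' @param n_blocks number of blocks (default 10).
#' @param bins_per_block windows per block (default 20).
#' @param melted_block index of the decondensed block, or NULL for none.
#' @param melt_factor step-size multiplier of the melted block (default 2).
#' @return data.frame usable as `blocks` in [simulate_ensemble()].
#' @export
default_blocks <- function(n_blocks = 10, bins_per_block = 20,
                           melted_block = NULL, melt_factor = 2) {
  blocks <- data.frame(n_bins = rep(bins_per_block, n_blocks),
                       step_factor = rep(1, n_blocks),
                       compartment = rep(c("A", "B"), length.out = n_blocks))
  if (!is.null(melted_block)) blocks$step_factor[melted_block] <- melt_factor
  blocks
}
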
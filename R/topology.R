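## Insulation scores and TAD boundary calling.
##
## The insulation score of bin i at square size k (in bins) is the mean
## contact value of the k x k square straddling the bin: rows [i-k, i-1]
## against columns [i+1, i+k].  Low scores mark positions across which few
## contacts occur -- topological domain (TAD) boundaries.  Boundaries are
## called from local minima of the 500-kb insulation profile, merged when
## their 3-bin intervals touch, and reported as the minimum-score bin plus
## one window on each side.

#' Multiscale insulation profile
#'
#' @param m a `gam_matrix` (typically NPMI layer).
#' @param square_sizes square sizes in bp; each must be a positive multiple
#'   of the bin size.  Default: 100 kb to 1 Mb in 100-kb steps.
#' @return An object of class `gam_insulation`: list with `scores`
#'   (bins x scales matrix, NA where the square leaves the chromosome),
#'   `square_sizes`, `chrom`, `bin_size`, `starts`.
#' @export
insulation <- function(m, square_sizes = seq(1e5, 1e6, by = 1e5)) {
  stopifnot(inherits(m, "gam_matrix"))
  v <- m$values
  n <- nrow(v)
  ks <- square_sizes / m$bin_size
  if (any(ks < 1 | ks != round(ks)))
    stop("square sizes must be positive multiples of the bin size")
  scores <- matrix(NA_real_, n, length(ks),
                   dimnames = list(NULL, as.character(square_sizes)))
  for (s in seq_along(ks)) {
    k <- as.integer(ks[s])
    if (k >= n) next   # square never fits: all missing
    for (i in (k + 1):(n - k)) {
      patch <- v[(i - k):(i - 1), (i + 1):(i + k)]
      fin <- is.finite(patch)
      if (any(fin)) scores[i, s] <- mean(patch[fin])
    }
  }
  structure(list(scores = scores, square_sizes = square_sizes,
                 chrom = m$chrom, bin_size = m$bin_size, starts = m$starts),
            class = "gam_insulation")
}

#' @export
print.gam_insulation <- function(x, ...) {
  cat(sprintf("insulation profile: %s, %d bins, square sizes %s kb\n",
              x$chrom, nrow(x$scores),
              paste(x$square_sizes / 1000, collapse = "/")))
  invisible(x)
}

#' Export one insulation scale as a bedGraph track
#'
#' @param ins a `gam_insulation` object.
#' @param path output file path.
#' @param square_size which scale to export (bp; default 500 kb).
#' @return `path`, invisibly.
#' @export
write_insulation_bedgraph <- function(ins, path, square_size = 5e5) {
  s <- insulation_scale(ins, square_size)
  track <- data.frame(chrom = ins$chrom, start = ins$starts,
                      end = ins$starts + ins$bin_size, value = s)
  write_bedgraph(track, path)
}

#' Call TAD boundaries from an insulation profile
#'
#' Local minima of the insulation score at the given square size (500 kb by
#' default), missing-aware: a bin is a candidate when its score is strictly
#' lower than the nearest finite neighbour on each side (plateaus of equal
#' minima form one candidate centred on their first bin).  Candidates whose
#' 3-bin intervals touch or overlap are merged, keeping the bin with the
#' lowest insulation.  Each boundary is reported as its minimum bin plus one
#' window each side.
#'
#' @param ins a `gam_insulation` object.
#' @param square_size scale to use (bp, default 500 kb).
#' @param min_prominence require the flanking scores to exceed the minimum
#'   by at least this much (default 0: any strict local minimum).
#' @return data.frame of class `gam_boundaries`: `chrom`, `start`, `end`
#'   (the 3-bin interval), `center_bin` (1-based), `center_start`,
#'   `insulation`.
#' @export
call_boundaries <- function(ins, square_size = 5e5, min_prominence = 0) {
  s <- insulation_scale(ins, square_size)
  n <- length(s)
  fin <- which(is.finite(s))
  cand <- integer(0)   # candidate centres (first bin of a plateau)
  if (length(fin) >= 3) {
    vals <- s[fin]
    runs <- rle(vals)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (r in seq_along(runs$values)) {
      if (r == 1 || r == length(runs$values)) next  # edges cannot be minima
      left <- runs$values[r - 1]; right <- runs$values[r + 1]
      if (runs$values[r] < left - min_prominence &&
          runs$values[r] < right - min_prominence)
        cand <- c(cand, fin[starts[r]])
    }
  }
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      center_bin = integer(), center_start = integer(),
                      insulation = numeric())
  if (!length(cand)) return(structure(empty, class = c("gam_boundaries", "data.frame")))
  ## merge candidates whose 3-bin intervals touch or overlap
  ## (centre distance <= 3 bins), transitively; keep the lowest-score bin
  grp <- cumsum(c(1, diff(cand) > 3))
  centers <- vapply(split(cand, grp), function(b) b[which.min(s[b])], numeric(1))
  centers <- as.integer(centers)
  res <- data.frame(
    chrom = ins$chrom,
    start = ins$starts[pmax(centers - 1, 1)],
    end = ins$starts[pmin(centers + 1, n)] + ins$bin_size,
    center_bin = centers,
    center_start = ins$starts[centers],
    insulation = s[centers])
  structure(res, class = c("gam_boundaries", "data.frame"))
}

#' Multiway comparison of TAD boundary sets
#'
#' Boundaries from several datasets are clustered by transitive closure of
#' the proximity rule: two boundaries belong to the same cluster when their
#' centres are separated by less than 200 kb (i.e. their 150-kb intervals
#' are separated by less than one 50-kb bin edge-to-edge).  Each cluster is
#' labelled with the subset of datasets it contains, giving UpSet-style
#' exclusive category counts.  Chromosome Y is excluded.
#'
#' @param sets named list of `gam_boundaries` data.frames.
#' @param max_center_sep centre separations strictly below this are merged
#'   (bp; default 200 kb).
#' @param exclude_chroms chromosomes dropped before comparison.
#' @return list with `clusters` (data.frame: cluster id, `chrom`,
#'   `center_start`, `datasets` comma-separated label) and `counts`
#'   (data.frame: `datasets`, `n_clusters`).
#' @export
compare_boundaries <- function(sets, max_center_sep = 2e5,
                               exclude_chroms = c("chrY", "Y")) {
  stopifnot(is.list(sets), length(sets) >= 2)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  all <- do.call(rbind, lapply(names(sets), function(nm) {
    b <- as.data.frame(sets[[nm]])
    if (!nrow(b)) return(NULL)
    data.frame(dataset = nm, chrom = b$chrom, center_start = b$center_start)
  }))
  if (is.null(all) || !nrow(all))
    return(list(clusters = data.frame(), counts = data.frame()))
  all <- all[!(all$chrom %in% exclude_chroms), , drop = FALSE]
  if (!nrow(all))
    return(list(clusters = data.frame(), counts = data.frame()))
  all <- all[order(all$chrom, all$center_start), , drop = FALSE]
  same <- c(FALSE, all$chrom[-1] == all$chrom[-nrow(all)] &
              diff(all$center_start) < max_center_sep)
  all$cluster <- cumsum(!same)
  lab <- vapply(split(all$dataset, all$cluster), function(d)
    paste(sort(unique(d)), collapse = ","), character(1))
  clusters <- data.frame(
    cluster = as.integer(names(lab)),
    chrom = vapply(split(all$chrom, all$cluster), `[`, character(1), 1),
    center_start = vapply(split(all$center_start, all$cluster), min, numeric(1)),
    datasets = unname(lab))
  counts <- as.data.frame(table(datasets = lab), stringsAsFactors = FALSE)
  names(counts)[2] <- "n_clusters"
  list(clusters = clusters, counts = counts)
}

## pull one scale out of a profile
insulation_scale <- function(ins, square_size) {
  stopifnot(inherits(ins, "gam_insulation"))
  s <- match(square_size, ins$square_sizes)
  if (is.na(s)) stop("square size ", square_size, " not in profile (",
                     paste(ins$square_sizes, collapse = ", "), ")")
  ins$scores[, s]
}
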
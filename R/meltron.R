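## Domain melting score for long genes, trans-cis contact ratio and
## length-scaled read quantification.
##
## A long gene "melts" in one cell type when its chromatin loses insulation
## across many length scales relative to a reference cell type.  The score
## pools insulation values over the gene's bins across all square sizes
## (100-1000 kb), converts them to genome-wide percentile ranks per scale
## per dataset so the two CDFs are comparable, and applies a one-sided
## Kolmogorov-Smirnov test for insulation loss in the query:
##   D = sup_x ( F_query(x) - F_ref(x) ),
##   p = exp(-2 m D^2),  m = n_ref n_query / (n_ref + n_query),
## Bonferroni-corrected by the number of genes tested, and reported as
## -log10(p).  Scores above 5 (corrected p < 1e-5) are called melting.

#' Select long genes for melting analysis
#'
#' Genes longer than `min_length` that cover at least `min_bins` whole
#' genomic bins.  With the 50-kb default binning the bin rule implies a
#' 400-kb effective minimum.
#'
#' @param genes data.frame from [read_gene_annotation()].
#' @param bin_size bin size in bp (default 50 kb).
#' @param min_length minimum gene length in bp, strict (default 300 kb).
#' @param min_bins minimum number of whole bins covered (default 8).
#' @return the qualifying subset of `genes` with an `n_bins` column.
#' @export
select_long_genes <- function(genes, bin_size = 5e4, min_length = 3e5,
                              min_bins = 8) {
  genes <- as.data.frame(genes)
  nb <- pmax(0, floor(genes$end / bin_size) - ceiling(genes$start / bin_size))
  keep <- (genes$end - genes$start) > min_length & nb >= min_bins
  out <- genes[keep, , drop = FALSE]
  out$n_bins <- nb[keep]
  out
}

#' One-sided two-sample KS statistic D+ = sup(F_query - F_ref)
#'
#' Positive when the query distribution is shifted towards smaller values
#' (stochastically smaller), i.e. insulation lost in the query.
#'
#' @param ref,query numeric vectors.
#' @return the supremum distance (scalar in `[0, 1]`).
#' @export
ks_dplus <- function(ref, query) {
  v <- sort(unique(c(ref, query)))
  max(ecdf(query)(v) - ecdf(ref)(v))
}

## p-value for D+: asymptotic closed form or permutation
ks_dplus_pvalue <- function(ref, query, method = c("asymptotic", "permutation"),
                            n_perm = 10000) {
  method <- match.arg(method)
  D <- ks_dplus(ref, query)
  n1 <- length(ref); n2 <- length(query)
  m <- n1 * n2 / (n1 + n2)
  if (method == "asymptotic") {
    p <- exp(-2 * m * D^2)
  } else {
    pool <- c(ref, query)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n1 + n2, n1)
      if (ks_dplus(pool[idx], pool[-idx]) >= D - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / n_perm
  }
  list(D = D, p = max(min(p, 1), 1e-300), m = m)
}

#' Melting score for one gene
#'
#' @param ref_values,query_values pooled insulation values for the gene
#'   (bins x scales, already normalized; see [meltron()]).
#' @param n_genes_tested Bonferroni correction factor.
#' @param method p-value method: `"asymptotic"` closed form (default) or
#'   `"permutation"`.
#' @param n_perm shuffles for the permutation method.
#' @return list with `n_ref`, `n_query`, `D`, `p_raw`, `p_bonferroni`,
#'   `melting_score`, `is_melting`; all NA when either side has fewer than
#'   8 finite values.
#' @export
melting_score <- function(ref_values, query_values, n_genes_tested = 1,
                          method = c("asymptotic", "permutation"),
                          n_perm = 10000) {
  ref_values <- ref_values[is.finite(ref_values)]
  query_values <- query_values[is.finite(query_values)]
  if (length(ref_values) < 8 || length(query_values) < 8)
    return(list(n_ref = length(ref_values), n_query = length(query_values),
                D = NA_real_, p_raw = NA_real_, p_bonferroni = NA_real_,
                melting_score = NA_real_, is_melting = NA))
  ks <- ks_dplus_pvalue(ref_values, query_values, method, n_perm)
  p_bonf <- min(1, ks$p * n_genes_tested)
  p_bonf <- max(p_bonf, 1e-300)
  score <- -log10(p_bonf)
  list(n_ref = length(ref_values), n_query = length(query_values),
       D = ks$D, p_raw = ks$p, p_bonferroni = p_bonf,
       melting_score = score, is_melting = score > 5)
}

#' Genome-wide melting analysis
#'
#' For every qualifying long gene, pools insulation values over the gene's
#' whole bins across all square sizes of the two profiles and computes the
#' melting score.  By default insulation values are first converted to
#' genome-wide percentile ranks per scale per dataset, which calibrates the
#' two datasets onto a common [0,1] scale; `normalize = FALSE` pools raw
#' values.
#'
#' @param ins_ref,ins_query `gam_insulation` objects, or named lists of them
#'   keyed by chromosome, at the same square sizes.
#' @param genes data.frame of genes (see [read_gene_annotation()]); filtered
#'   through [select_long_genes()] with the same `min_length`/`min_bins`.
#' @param min_length,min_bins gene selection parameters.
#' @param normalize use percentile-rank calibration (default TRUE).
#' @param melting_threshold score above which a gene is called melting.
#' @param method,n_perm passed to [melting_score()].
#' @return data.frame of class `gam_melting`: one row per tested gene with
#'   `gene_id`, `chrom`, `start`, `end`, `n_ref`, `n_query`, `D`, `p_raw`,
#'   `p_bonferroni`, `melting_score`, `is_melting`.
#' @export
meltron <- function(ins_ref, ins_query, genes, min_length = 3e5, min_bins = 8,
                    normalize = TRUE, melting_threshold = 5,
                    method = c("asymptotic", "permutation"), n_perm = 10000) {
  method <- match.arg(method)
  ref <- as_insulation_list(ins_ref)
  qry <- as_insulation_list(ins_query)
  check_same_chroms(names(ref), names(qry), "reference profiles", "query profiles")
  bin_size <- ref[[1]]$bin_size
  if (!identical(ref[[1]]$square_sizes, qry[[1]]$square_sizes))
    stop("reference and query profiles use different square sizes")
  if (normalize) {
    ref <- rank_normalize_profiles(ref)
    qry <- rank_normalize_profiles(qry)
  }
  long <- select_long_genes(genes, bin_size, min_length, min_bins)
  long <- long[long$chrom %in% names(ref), , drop = FALSE]
  pooled <- lapply(seq_len(nrow(long)), function(g) {
    bins <- gene_bins(long$start[g], long$end[g], ref[[long$chrom[g]]], bin_size)
    list(ref = as.vector(ref[[long$chrom[g]]]$scores[bins, , drop = FALSE]),
         qry = as.vector(qry[[long$chrom[g]]]$scores[bins, , drop = FALSE]))
  })
  testable <- vapply(pooled, function(p)
    sum(is.finite(p$ref)) >= 8 && sum(is.finite(p$qry)) >= 8, logical(1))
  n_tested <- sum(testable)
  rows <- lapply(seq_len(nrow(long)), function(g) {
    r <- melting_score(pooled[[g]]$ref, pooled[[g]]$qry,
                       n_genes_tested = max(1, n_tested),
                       method = method, n_perm = n_perm)
    r$is_melting <- if (is.na(r$melting_score)) NA else
      r$melting_score > melting_threshold
    cbind(long[g, c("chrom", "start", "end", "gene_id")],
          as.data.frame(r, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_genes_tested") <- n_tested
  class(out) <- c("gam_melting", "data.frame")
  out
}

## whole bins (fully inside the gene) expressed as matrix row indices
gene_bins <- function(start, end, ins, bin_size) {
  first_bp <- ceiling(start / bin_size) * bin_size
  last_bp <- floor(end / bin_size) * bin_size - bin_size
  if (last_bp < first_bp) return(integer(0))
  which(ins$starts >= first_bp & ins$starts <= last_bp)
}

as_insulation_list <- function(x) {
  if (inherits(x, "gam_insulation")) {
    out <- list(x); names(out) <- x$chrom
    return(out)
  }
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "gam_insulation")))
  if (is.null(names(x))) names(x) <- vapply(x, `[[`, character(1), "chrom")
  x
}

## per-scale percentile ranks across all chromosomes of a dataset
rank_normalize_profiles <- function(profiles) {
  nsc <- ncol(profiles[[1]]$scores)
  for (s in seq_len(nsc)) {
    all_vals <- unlist(lapply(profiles, function(p) p$scores[, s]))
    fin <- is.finite(all_vals)
    pr <- rep(NA_real_, length(all_vals))
    pr[fin] <- rank(all_vals[fin]) / sum(fin)
    off <- 0
    for (ch in names(profiles)) {
      nb <- nrow(profiles[[ch]]$scores)
      profiles[[ch]]$scores[, s] <- pr[off + seq_len(nb)]
      off <- off + nb
    }
  }
  profiles
}

#' Trans-cis contact ratio
#'
#' Per genomic bin, the mean interchromosomal (trans) NPMI divided by the
#' mean intrachromosomal (cis) NPMI.  Bins detected in less than 3% or more
#' than 75% of samples are removed.  When genes are supplied, each gene is
#' summarized by the median ratio over its whole bins.
#'
#' @param seg a `gam_segregation` object (typically 250-kb bins) covering at
#'   least two chromosomes.
#' @param genes optional gene annotation data.frame.
#' @param min_detection,max_detection detection-frequency bounds; bins
#'   strictly outside are removed.
#' @return list with `bins` (data.frame `chrom`, `start`, `mean_trans`,
#'   `mean_cis`, `n_trans`, `n_cis`, `ratio`) and `genes` (data.frame
#'   `gene_id`, `ratio`, NA when no surviving bins), NULL when no genes
#'   given.
#' @export
trans_cis_ratio <- function(seg, genes = NULL, min_detection = 0.03,
                            max_detection = 0.75) {
  stopifnot(inherits(seg, "gam_segregation"))
  if (length(unique(seg$windows$chrom)) < 2)
    stop("trans contacts need at least two chromosomes")
  gw <- npmi_genomewide(seg)
  freq <- gw$marginal
  keep <- freq >= min_detection & freq <= max_detection
  v <- gw$values
  chrom <- gw$windows$chrom
  nb <- nrow(v)
  res <- data.frame(chrom = chrom, start = gw$windows$start,
                    mean_trans = NA_real_, mean_cis = NA_real_,
                    n_trans = 0L, n_cis = 0L, ratio = NA_real_)
  for (i in which(keep)) {
    same <- chrom == chrom[i] & keep
    same[i] <- FALSE
    other <- chrom != chrom[i] & keep
    ci <- v[i, same]; ti <- v[i, other]
    ci <- ci[is.finite(ci)]; ti <- ti[is.finite(ti)]
    res$n_cis[i] <- length(ci); res$n_trans[i] <- length(ti)
    if (length(ci)) res$mean_cis[i] <- mean(ci)
    if (length(ti)) res$mean_trans[i] <- mean(ti)
    if (length(ci) && length(ti) && res$mean_cis[i] > 0)
      res$ratio[i] <- res$mean_trans[i] / res$mean_cis[i]
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  gene_res <- NULL
  if (!is.null(genes)) {
    genes <- as.data.frame(genes)
    gene_res <- data.frame(gene_id = genes$gene_id, ratio = NA_real_)
    for (g in seq_len(nrow(genes))) {
      first_bp <- ceiling(genes$start[g] / seg$bin_size) * seg$bin_size
      last_bp <- floor(genes$end[g] / seg$bin_size) * seg$bin_size - seg$bin_size
      sel <- res$chrom == genes$chrom[g] & res$start >= first_bp &
        res$start <= last_bp & is.finite(res$ratio)
      if (any(sel)) gene_res$ratio[g] <- median(res$ratio[sel])
    }
  }
  list(bins = res, genes = gene_res)
}

#' Length-scaled reads per million
#'
#' lsRPM = overlaps / (gene_length x 1e-6 x total_fragments x 1e-6):
#' fragment counts over a gene body scaled by gene length (Mb) and
#' sequencing depth (millions of fragments).
#'
#' @param overlaps number of fragments overlapping the gene body.
#' @param gene_length gene length in bp (> 0).
#' @param total_fragments library size (> 0).
#' @return the length-scaled reads-per-million value.
#' @export
length_scaled_rpm <- function(overlaps, gene_length, total_fragments) {
  if (any(total_fragments <= 0)) stop("total_fragments must be positive")
  if (any(gene_length <= 0)) stop("gene_length must be positive")
  if (any(overlaps < 0)) stop("overlaps must be non-negative")
  overlaps / ((gene_length * 1e-6) * (total_fragments * 1e-6))
}
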
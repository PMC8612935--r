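## Readers/writers for the external text formats: segregation/coverage TSV,
## bedGraph, gene annotation BED and dense matrix text.  Coordinates are
## 0-based half-open throughout.  gzip input is accepted transparently
## (data.table::fread).  Chromosome names are matched literally; no "chr"
## stripping is ever applied.

#' Read a GAM segregation table
#'
#' Expects a TSV with header `chrom start stop <sample...>` and cells in
#' \{0,1\}, the layout of public GAM segregation tables.  Unsorted rows are
#' auto-sorted with a warning; duplicate windows or non-boolean cells raise
#' errors.
#'
#' @param path file path (optionally gzip-compressed).
#' @return a [gam_segregation()] object.
#' @export
read_segregation_table <- function(path) {
  tab <- read_window_table(path)
  mat <- tab$mat
  bad <- which(!(mat %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(mat)) + 1
    j <- ((bad[1] - 1) %/% nrow(mat)) + 1
    stop("non-boolean cell '", mat[bad[1]], "' at window ",
         tab$windows$chrom[i], ":", tab$windows$start[i],
         ", sample '", colnames(mat)[j], "'")
  }
  gam_segregation(tab$windows, mat > 0, samples = colnames(mat))
}

#' Read a GAM coverage table
#'
#' Same dialect as [read_segregation_table()] but with non-negative integer
#' nucleotide counts in the sample columns.
#'
#' @inheritParams read_segregation_table
#' @return a [gam_coverage()] object.
#' @export
read_coverage_table <- function(path) {
  tab <- read_window_table(path)
  gam_coverage(tab$windows, tab$mat, samples = colnames(tab$mat))
}

#' Write a segregation or coverage table as TSV
#'
#' Inverse of the readers: `chrom start stop` followed by one column per
#' sample; detection written as 0/1.
#'
#' @param x a `gam_segregation` or `gam_coverage` object.
#' @param path output file path (".gz" suffix compresses).
#' @return `path`, invisibly.
#' @export
write_segregation_table <- function(x, path) {
  mat <- if (inherits(x, "gam_segregation")) x$detection * 1L else x$nucleotides
  out <- data.table::data.table(chrom = x$windows$chrom,
                                start = x$windows$start,
                                stop = x$windows$end)
  out <- cbind(out, data.table::as.data.table(mat))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write an interval track as bedGraph
#'
#' Four-column bedGraph (`chrom start end value`); records with missing
#' values are skipped.  Overlapping intervals on the same chromosome are an
#' error because genome browsers reject them.
#'
#' @param track data.frame with columns `chrom`, `start`, `end`, `value`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  track <- as.data.frame(track)[, c("chrom", "start", "end", "value")]
  ord <- order(track$chrom, track$start, method = "radix")
  track <- track[ord, , drop = FALSE]
  for (ch in unique(track$chrom)) {
    t2 <- track[track$chrom == ch, ]
    if (nrow(t2) > 1 && any(t2$start[-1] < t2$end[-nrow(t2)]))
      stop("overlapping intervals on chromosome ", ch)
  }
  keep <- is.finite(track$value)
  data.table::fwrite(track[keep, , drop = FALSE], path, sep = "\t",
                     col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Read a gene annotation (BED-like)
#'
#' At least four columns: `chrom start end gene_id`.  Strand is ignored
#' (domain melting is strand-symmetric).  Gene ids must be unique.
#'
#' @param path BED file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene_id`,
#'   `length` (bp).
#' @export
read_gene_annotation <- function(path) {
  g <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (ncol(g) < 4) stop("gene annotation needs >= 4 columns (chrom start end name)")
  g <- g[, 1:4]
  names(g) <- c("chrom", "start", "end", "gene_id")
  g$chrom <- as.character(g$chrom)
  if (any(g$end - g$start < 0)) {
    i <- which(g$end - g$start < 0)[1]
    stop("negative gene length for '", g$gene_id[i], "'")
  }
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene id: ", g$gene_id[duplicated(g$gene_id)][1])
  g$length <- g$end - g$start
  g[order(g$chrom, g$start, method = "radix"), , drop = FALSE]
}

#' Write a contact matrix as dense text
#'
#' Tab-separated dense matrix with a `# chrom=... bin_size=... layer=...`
#' header line; masked entries written as NA.  Intended for small matrices;
#' round-trips through [read_matrix_txt()].
#'
#' @param m a `gam_matrix` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_txt <- function(m, path) {
  stopifnot(inherits(m, "gam_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chrom=%s bin_size=%d layer=%s start=%d",
                     m$chrom, m$bin_size, m$layer, m$starts[1]), con)
  utils::write.table(format(m$values, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a dense text contact matrix written by [write_matrix_txt()]
#'
#' @param path file path.
#' @return a `gam_matrix` object.
#' @export
read_matrix_txt <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(sub("^[a-z_]+=", "", kv), sub("=.*", "", kv))
  vals <- as.matrix(data.table::fread(path, skip = 1, header = FALSE))
  dimnames(vals) <- NULL
  bin <- as.integer(meta[["bin_size"]])
  start0 <- as.integer(meta[["start"]])
  gam_matrix(vals, chrom = meta[["chrom"]], bin_size = bin,
             starts = start0 + bin * (seq_len(nrow(vals)) - 1L),
             layer = meta[["layer"]])
}

## shared TSV reader for segregation/coverage dialect
read_window_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  need <- c("chrom", "start", "stop")
  if (!all(need %in% names(dt)[1:3]))
    stop("expected header 'chrom\\tstart\\tstop\\t<samples...>', got: ",
         paste(utils::head(names(dt), 3), collapse = ", "))
  windows <- data.frame(chrom = as.character(dt$chrom),
                        start = as.integer(dt$start),
                        end = as.integer(dt$stop))
  mat <- as.matrix(dt[, -(1:3), drop = FALSE])
  if (!is.numeric(mat)) stop("sample columns must be numeric")
  s <- sort_windows(windows, mat)
  key <- paste(s$windows$chrom, s$windows$start)
  if (anyDuplicated(key))
    stop("duplicate window rows (first: ", key[duplicated(key)][1], ")")
  list(windows = s$windows, mat = s$mat)
}

## literal chromosome-name check between two inputs
check_same_chroms <- function(a, b, what_a = "first input", what_b = "second input") {
  ca <- unique(a); cb <- unique(b)
  if (!setequal(ca, cb))
    stop("chromosome name sets differ between ", what_a, " {",
         paste(ca, collapse = ","), "} and ", what_b, " {",
         paste(cb, collapse = ","), "}")
  invisible(TRUE)
}
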
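## TF motif feature pairs on differential contacts.
##
## Contact windows are annotated with boolean TF-motif features: a window
## carries motif f when an accessible-chromatin peak supported by at least
## 10% of single cells overlaps the window and contains a hit of f.  Each
## unordered motif pair (including homotypic pairs) is then scored on the
## two sets of differential contacts by an enrichment ratio
## (freq in A) / (freq in B) and by the information gain of the contact's
## cell-type label given pair presence.  Motif scanning itself is external;
## hits are consumed as interval tables.

#' Annotate windows with TF-motif features
#'
#' @param windows data.frame `chrom`, `start`, `end` of genomic windows.
#' @param peaks data.frame `chrom`, `start`, `end`, `support` (fraction of
#'   single cells containing the peak).
#' @param motif_hits data.frame `chrom`, `start`, `end`, `motif`.
#' @param min_support minimum cell-support fraction for a peak to count
#'   (default 0.10; the threshold is inclusive).
#' @return An object of class `gam_features`: list with `windows` and
#'   `features` (logical matrix windows x motifs).
#' @export
annotate_windows <- function(windows, peaks, motif_hits, min_support = 0.10) {
  windows <- as.data.frame(windows)
  peaks <- as.data.frame(peaks)
  motif_hits <- as.data.frame(motif_hits)
  peaks <- peaks[peaks$support >= min_support, , drop = FALSE]
  motifs <- sort(unique(motif_hits$motif))
  feat <- matrix(FALSE, nrow(windows), length(motifs),
                 dimnames = list(NULL, motifs))
  if (nrow(peaks) && nrow(motif_hits)) {
    gr_win <- GenomicRanges::GRanges(windows$chrom,
      IRanges::IRanges(windows$start + 1, windows$end))
    gr_peak <- GenomicRanges::GRanges(peaks$chrom,
      IRanges::IRanges(peaks$start + 1, peaks$end))
    gr_hit <- GenomicRanges::GRanges(motif_hits$chrom,
      IRanges::IRanges(motif_hits$start + 1, motif_hits$end))
    ph <- GenomicRanges::findOverlaps(gr_peak, gr_hit)
    wp <- GenomicRanges::findOverlaps(gr_win, gr_peak)
    ## motifs per peak -> windows per peak
    peak_motifs <- split(motif_hits$motif[S4Vectors::subjectHits(ph)],
                         S4Vectors::queryHits(ph))
    for (k in seq_along(S4Vectors::queryHits(wp))) {
      w <- S4Vectors::queryHits(wp)[k]
      p <- as.character(S4Vectors::subjectHits(wp)[k])
      mm <- unique(peak_motifs[[p]])
      if (length(mm)) feat[w, mm] <- TRUE
    }
  }
  structure(list(windows = windows, features = feat), class = "gam_features")
}

#' @export
print.gam_features <- function(x, ...) {
  cat(sprintf("window feature table: %d windows x %d motifs, %.1f%% positive\n",
              nrow(x$features), ncol(x$features), 100 * mean(x$features)))
  invisible(x)
}

#' Enumerate unordered feature pairs
#'
#' All C(F,2) heterotypic plus F homotypic pairs, lexicographically ordered.
#'
#' @param features character vector of motif names.
#' @return data.frame `f1`, `f2` with `f1 <= f2`.
#' @export
enumerate_feature_pairs <- function(features) {
  features <- sort(unique(as.character(features)))
  het <- if (length(features) > 1) t(combn(features, 2)) else
    matrix(character(0), 0, 2)
  out <- rbind(data.frame(f1 = features, f2 = features),
               data.frame(f1 = het[, 1], f2 = het[, 2]))
  out <- out[order(out$f1, out$f2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count contacts carrying each feature pair
#'
#' A contact counts for heterotypic pair (f1, f2) when one window carries f1
#' and the other f2, in either orientation; a homotypic pair (f, f)
#' requires f in both windows.
#'
#' @param contacts data.frame with columns `i`, `j`: row indices of the two
#'   windows of each contact in the feature table.
#' @param feats a `gam_features` object.
#' @return data.frame `f1`, `f2`, `count` over all pairs (zero counts
#'   included).
#' @export
count_pair_contacts <- function(contacts, feats) {
  stopifnot(inherits(feats, "gam_features"))
  contacts <- as.data.frame(contacts)
  motifs <- colnames(feats$features)
  pairs <- enumerate_feature_pairs(motifs)
  key <- paste(pairs$f1, pairs$f2, sep = "\r")
  counts <- stats::setNames(integer(nrow(pairs)), key)
  F <- feats$features
  for (k in seq_len(nrow(contacts))) {
    a <- motifs[F[contacts$i[k], ]]
    b <- motifs[F[contacts$j[k], ]]
    if (!length(a) || !length(b)) next
    pk <- unique(paste(pmin(rep(a, each = length(b)), rep(b, length(a))),
                       pmax(rep(a, each = length(b)), rep(b, length(a))),
                       sep = "\r"))
    counts[pk] <- counts[pk] + 1L
  }
  pairs$count <- unname(counts)
  pairs
}

#' Enrichment score of a feature pair between two contact sets
#'
#' (count_A / total_A) / (count_B / total_B).  When count_B is zero but
#' count_A is positive the enrichment is infinite and flagged.
#'
#' @param count_a,count_b contacts carrying the pair in each set.
#' @param total_a,total_b total contacts in each set (must be positive).
#' @return the enrichment ratio (possibly `Inf`); attribute `infinite` is
#'   TRUE when count_b is 0 and count_a > 0.
#' @export
enrichment_score <- function(count_a, total_a, count_b, total_b) {
  if (total_a <= 0 || total_b <= 0) stop("contact totals must be positive")
  if (count_b == 0 && count_a > 0) {
    return(structure(Inf, infinite = TRUE))
  }
  if (count_b == 0) return(structure(NaN, infinite = FALSE))
  structure((count_a / total_a) / (count_b / total_b), infinite = FALSE)
}

#' Information gain of the contact class given pair presence
#'
#' IG = H(class) - sum_g (|g|/n) H(class | g) over the presence/absence
#' groups, with entropies in bits.
#'
#' @param presence logical vector: pair present on each contact.
#' @param class factor/character vector of contact class labels (two
#'   classes).
#' @return information gain in bits.
#' @export
information_gain <- function(presence, class) {
  stopifnot(length(presence) == length(class))
  if (length(unique(class)) < 2) {
    warning("only one class present; information gain is 0")
    return(0)
  }
  h <- function(x) {
    p <- table(x) / length(x)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  n <- length(class)
  cond <- 0
  for (g in unique(presence)) {
    sel <- presence == g
    cond <- cond + sum(sel) / n * h(class[sel])
  }
  h(class) - cond
}

#' Score all feature pairs on two differential contact sets
#'
#' Counts each pair on the A-specific and B-specific contacts, and computes
#' the enrichment ratio in both directions and the information gain of the
#' contact direction label given pair presence.
#'
#' @param contacts_a,contacts_b data.frames with `i`, `j` window indices of
#'   the contacts specific to dataset A and B.
#' @param feats a `gam_features` object covering those windows.
#' @return data.frame `f1`, `f2`, `count_a`, `count_b`, `total_a`,
#'   `total_b`, `enrichment_a` (A over B), `enrichment_b` (B over A),
#'   `information_gain`.
#' @export
feature_pair_stats <- function(contacts_a, contacts_b, feats) {
  ca <- count_pair_contacts(contacts_a, feats)
  cb <- count_pair_contacts(contacts_b, feats)
  ta <- nrow(as.data.frame(contacts_a)); tb <- nrow(as.data.frame(contacts_b))
  stats <- ca[, c("f1", "f2")]
  stats$count_a <- ca$count; stats$count_b <- cb$count
  stats$total_a <- ta; stats$total_b <- tb
  stats$enrichment_a <- mapply(function(x, y)
    as.numeric(enrichment_score(x, ta, y, tb)), ca$count, cb$count)
  stats$enrichment_b <- mapply(function(x, y)
    as.numeric(enrichment_score(y, tb, x, ta)), ca$count, cb$count)
  cls <- rep(c("A", "B"), c(ta, tb))
  FA <- feats$features
  ia <- as.data.frame(contacts_a); ib <- as.data.frame(contacts_b)
  stats$information_gain <- vapply(seq_len(nrow(stats)), function(r) {
    f1 <- stats$f1[r]; f2 <- stats$f2[r]
    pres_a <- pair_presence(ia, FA, f1, f2)
    pres_b <- pair_presence(ib, FA, f1, f2)
    information_gain_counts(sum(pres_a), ta, sum(pres_b), tb)
  }, numeric(1))
  stats
}

pair_presence <- function(contacts, F, f1, f2) {
  if (!nrow(contacts)) return(logical(0))
  a1 <- F[contacts$i, f1]; a2 <- F[contacts$j, f2]
  b1 <- F[contacts$i, f2]; b2 <- F[contacts$j, f1]
  (a1 & a2) | (b1 & b2)
}

## IG from a 2x2 presence/class contingency (avoids re-tabulating per pair)
information_gain_counts <- function(pres_a, tot_a, pres_b, tot_b) {
  n <- tot_a + tot_b
  if (tot_a == 0 || tot_b == 0) return(0)
  h2 <- function(k, m) {
    if (m == 0) return(0)
    p <- c(k, m - k) / m
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  np <- pres_a + pres_b
  h2(tot_a, n) - np / n * h2(pres_a, np) - (n - np) / n * h2(tot_a - pres_a, n - np)
}

#' Shortlist top feature pairs
#'
#' Union of the top pairs by information gain (10 by default), by
#' A-enrichment (5) and by B-enrichment (5).  Ties are broken by the
#' lexicographic pair name, making the shortlist deterministic.
#'
#' @param stats output of [feature_pair_stats()].
#' @param n_ig,n_enr_a,n_enr_b shortlist sizes.
#' @return subset of `stats` with a `selected_by` column (comma-separated
#'   reasons).
#' @export
select_top_pairs <- function(stats, n_ig = 10, n_enr_a = 5, n_enr_b = 5) {
  nm <- paste(stats$f1, stats$f2)
  top <- function(score, k) {
    ord <- order(-score, nm)
    ord[seq_len(min(k, length(ord)))]
  }
  ig <- top(stats$information_gain, n_ig)
  ea <- top(ifelse(is.finite(stats$enrichment_a), stats$enrichment_a, Inf *
                     (stats$count_a > 0)), n_enr_a)
  eb <- top(ifelse(is.finite(stats$enrichment_b), stats$enrichment_b, Inf *
                     (stats$count_b > 0)), n_enr_b)
  sel <- sort(unique(c(ig, ea, eb)))
  out <- stats[sel, , drop = FALSE]
  out$selected_by <- vapply(sel, function(r)
    paste(c("ig", "enr_a", "enr_b")[c(r %in% ig, r %in% ea, r %in% eb)],
          collapse = ","), character(1))
  out
}

#' Motif co-occurrence network edge table
#'
#' Pairs involved in at least `min_fraction` of the total contacts become
#' weighted edges (weight = contact count) between their two motifs.
#'
#' @param pair_counts data.frame `f1`, `f2`, `count`.
#' @param total_contacts total number of contacts in the cell type.
#' @param min_fraction minimum fraction of total contacts (default 0.20;
#'   count >= min_fraction x total passes).
#' @return data.frame `from`, `to`, `weight`; zero rows when nothing passes.
#' @export
pair_network_edges <- function(pair_counts, total_contacts,
                               min_fraction = 0.20) {
  pair_counts <- as.data.frame(pair_counts)
  keep <- pair_counts$count >= min_fraction * total_contacts
  data.frame(from = pair_counts$f1[keep], to = pair_counts$f2[keep],
             weight = pair_counts$count[keep])
}
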
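test_that("orphan_fraction counts isolated positives, edges included", {
  expect_equal(orphan_fraction(c(0, 1, 0, 1, 1)), 1 / 3)
  expect_equal(orphan_fraction(rep(1, 6)), 0)
  expect_equal(orphan_fraction(c(1, 0, 1, 0, 1)), 1)
  expect_equal(orphan_fraction(rep(0, 5)), 0)
  ## chromosome boundaries split neighbourhoods: [1,1 | 1,1] on two
  ## chromosomes has no orphans, but [1,0 | 0,1] has two
  expect_equal(orphan_fraction(c(1, 1, 1, 1), c("a", "a", "b", "b")), 0)
  expect_equal(orphan_fraction(c(1, 0, 0, 1), c("a", "a", "b", "b")), 1)
})

test_that("orphan_fraction never mixes windows across chromosomes", {
  set.seed(21)
  for (rep in 1:20) {
    d <- rbinom(30, 1, 0.4)
    chrom <- rep(c("chr1", "chr2", "chr3"), each = 10)
    whole <- orphan_fraction(d, chrom)
    ## recompute chromosome by chromosome and recombine
    pos <- orph <- 0
    for (ch in unique(chrom)) {
      dd <- d[chrom == ch]
      pos <- pos + sum(dd)
      orph <- orph + orphan_fraction(dd) * sum(dd)
    }
    expect_equal(whole, if (pos == 0) 0 else orph / pos)
  }
})

test_that("call_windows picks the orphan-minimizing percentile", {
  cov <- c(0, 0, 500, 520, 480, 0, 3, 0, 510, 505)
  res <- call_windows(cov, sample_id = "toy")
  expect_equal(which(res$detection), c(3, 4, 5, 9, 10))
  expect_equal(res$orphan_fraction, 0)
  ## the full grid confirms no percentile does better
  expect_true(all(res$grid$orphan_fraction >= res$orphan_fraction))

  ## constant positive coverage on contiguous windows: everything called
  res2 <- call_windows(rep(7, 8))
  expect_true(all(res2$detection))
  expect_equal(res2$orphan_fraction, 0)

  expect_warning(res3 <- call_windows(rep(0, 5)), "all-zero")
  expect_false(any(res3$detection))
  expect_equal(res3$orphan_fraction, 0)
})

test_that("call_windows is optimal against an exhaustive threshold scan", {
  set.seed(7)
  for (rep in 1:25) {
    cov <- rpois(60, lambda = sample(c(2, 20, 200), 60, replace = TRUE)) *
      rbinom(60, 1, 0.7)
    res <- call_windows(cov)
    pos <- cov[cov > 0]
    if (!length(pos)) next
    thr <- unname(quantile(pos, 0:99 / 100, type = 7))
    thr[1] <- 0
    oracle <- min(vapply(thr, function(t) orphan_fraction(cov > t),
                         numeric(1)))
    expect_equal(res$orphan_fraction, oracle)
    ## ties broken toward the lowest percentile
    ties <- which(abs(res$grid$orphan_fraction - oracle) < 1e-15)
    expect_equal(res$chosen_percentile, res$grid$percentile[ties[1]])
  }
})

test_that("pairwise_jaccard matches set arithmetic and is symmetric", {
  a <- c(TRUE, TRUE, TRUE, FALSE)
  b <- c(FALSE, TRUE, TRUE, TRUE)
  expect_equal(pairwise_jaccard(a, b), 0.5)           # |{2,3}| / |{1,2,3,4}|
  expect_equal(pairwise_jaccard(a, a), 1)
  expect_equal(pairwise_jaccard(a, !a), 0)
  expect_equal(pairwise_jaccard(logical(4), logical(4)), 0)
  set.seed(5)
  for (rep in 1:10) {
    x <- rbinom(20, 1, 0.5) > 0; y <- rbinom(20, 1, 0.5) > 0
    expect_equal(pairwise_jaccard(x, y), pairwise_jaccard(y, x))
    expect_gte(pairwise_jaccard(x, y), 0)
    expect_lte(pairwise_jaccard(x, y), 1)
    if (any(x) && pairwise_jaccard(x, y) == 1) expect_identical(x, y)
  }
})

test_that("qc_filter applies the three strict thresholds", {
  rep1 <- data.frame(orphan_fraction = 0.69, mapped_reads = 50001,
                     max_jaccard_to_platemates = 0.39)
  expect_true(suppressMessages(qc_filter(rep1))$passed)
  rep2 <- rep1; rep2$orphan_fraction <- 0.70
  expect_false(suppressMessages(qc_filter(rep2))$passed)
  rep3 <- rep1; rep3$mapped_reads <- 50000
  expect_false(suppressMessages(qc_filter(rep3))$passed)
  rep4 <- rep1; rep4$max_jaccard_to_platemates <- 0.4
  expect_false(suppressMessages(qc_filter(rep4))$passed)

  ## batch of 10 with 3 constructed violations -> 7 pass
  batch <- data.frame(orphan_fraction = c(rep(0.3, 7), 0.9, 0.3, 0.3),
                      mapped_reads = c(rep(1e5, 8), 100, 1e5),
                      max_jaccard_to_platemates = c(rep(0.1, 9), 0.95))
  expect_equal(sum(suppressMessages(qc_filter(batch))$passed), 7)
  expect_error(suppressMessages(qc_filter(batch[, -1])), "missing QC metrics")
  batch$orphan_fraction[1] <- NA
  expect_error(suppressMessages(qc_filter(batch)), "missing values")
})

test_that("contamination score is the max Jaccard to platemates", {
  det <- cbind(s1 = c(1, 1, 0, 0), s2 = c(1, 1, 1, 0), s3 = c(0, 0, 0, 1))
  seg <- make_seg(det)
  plates <- data.frame(sample = c("s1", "s2", "s3"),
                       plate = c("P1", "P1", "P2"))
  sc <- contamination_scores(seg, plates)
  expect_equal(unname(sc["s1"]), 2 / 3)   # vs s2 only
  expect_equal(unname(sc["s3"]), 0)       # alone on P2
  expect_error(contamination_scores(seg, plates[1:2, ]), "missing from plate map")
})

test_that("pair_sampling_coverage enumerates intrachromosomal pairs", {
  ## windows {w0,w1,w2}, samples s1={w0,w1}, s2={w1,w2}: pairs (01),(12)
  ## co-detected; (02) sampled never -> 2/3
  seg <- make_seg(cbind(c(1, 1, 0), c(0, 1, 1)))
  expect_equal(pair_sampling_coverage(seg), 2 / 3)

  ## all windows positive in one sample -> 1
  expect_equal(pair_sampling_coverage(make_seg(matrix(1, 5, 1))), 1)

  ## never-detected windows are excluded from the denominator
  seg2 <- make_seg(cbind(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_equal(pair_sampling_coverage(seg2), 1)

  ## deep sampling covers nearly all pairs (simulator output)
  ens <- simulate_ensemble(default_blocks(n_blocks = 5, bins_per_block = 20),
                           n_structures = 50, seed = 42)
  seg3 <- slice_sample(ens, 500, seed = 43)
  expect_gte(pair_sampling_coverage(seg3), 0.95)
})

test_that("call_windows_table assembles a segregation table per sample", {
  set.seed(9)
  counts <- matrix(rpois(40, 50) * rbinom(40, 1, 0.8), 20)
  cov <- gam_coverage(data.frame(chrom = "chr1", start = (0:19) * 5e4,
                                 end = (1:20) * 5e4), counts)
  seg <- call_windows_table(cov)
  expect_s3_class(seg, "gam_segregation")
  calls <- attr(seg, "calls")
  expect_length(calls, 2)
  expect_identical(unname(seg$detection[, 1]), calls[[1]]$detection)
})
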
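## small annotation world: 4 windows of 50 kb on chr1
tf_windows <- data.frame(chrom = "chr1", start = (0:3) * 5e4, end = (1:4) * 5e4)

test_that("window annotation requires a supported peak containing the motif", {
  peaks <- data.frame(chrom = "chr1",
                      start = c(10e3, 60e3, 110e3),
                      end = c(11e3, 61e3, 111e3),
                      support = c(0.12, 0.09, 0.50))
  hits <- data.frame(chrom = "chr1",
                     start = c(10200, 60200, 140e3),
                     end = c(10210, 60210, 140010),
                     motif = c("M1", "M1", "M2"))
  ft <- annotate_windows(tf_windows, peaks, hits)
  ## peak 1 (12% support, hit M1) marks window 1; peak 2 fails the 10%
  ## support filter; the M2 hit lies outside any passing peak
  expect_true(ft$features[1, "M1"])
  expect_false(ft$features[2, "M1"])
  expect_false(any(ft$features[, "M2"]))

  ## a passing peak containing hits of two motifs marks the window for both
  hits2 <- rbind(hits, data.frame(chrom = "chr1", start = 10500, end = 10510,
                                  motif = "M2"))
  ft2 <- annotate_windows(tf_windows, peaks, hits2)
  expect_true(ft2$features[1, "M1"] && ft2$features[1, "M2"])
})

test_that("pair enumeration covers heterotypic plus homotypic combinations", {
  p <- enumerate_feature_pairs(paste0("M", 1:50))
  expect_equal(nrow(p), 1275)
  expect_equal(sum(p$f1 == p$f2), 50)
  expect_equal(sum(p$f1 != p$f2), 1225)
  expect_true(all(p$f1 <= p$f2))
})

test_that("pair counting needs one motif per window, either orientation", {
  feat <- matrix(FALSE, 4, 3, dimnames = list(NULL, c("M1", "M2", "M3")))
  feat[1, "M1"] <- TRUE
  feat[2, "M2"] <- TRUE
  feat[3, c("M1", "M2")] <- TRUE
  ft <- structure(list(windows = tf_windows, features = feat),
                  class = "gam_features")
  cnt <- function(cc) count_pair_contacts(cc, ft)
  lookup <- function(d, a, b) d$count[d$f1 == min(a, b) & d$f2 == max(a, b)]

  ## {M1} x {M2}: heterotypic only, no homotypic credit
  d1 <- cnt(data.frame(i = 1, j = 2))
  expect_equal(lookup(d1, "M1", "M2"), 1)
  expect_equal(lookup(d1, "M1", "M1"), 0)

  ## {M1,M2} x {M1}: homotypic (M1,M1) and heterotypic (M1,M2)
  d2 <- cnt(data.frame(i = 3, j = 1))
  expect_equal(lookup(d2, "M1", "M1"), 1)
  expect_equal(lookup(d2, "M1", "M2"), 1)
  expect_equal(lookup(d2, "M2", "M2"), 0)

  ## empty feature sets count nothing
  d3 <- cnt(data.frame(i = 4, j = 4))
  expect_equal(sum(d3$count), 0)

  ## orientation symmetry: swapping every contact leaves all counts equal
  cc <- data.frame(i = c(1, 3, 2), j = c(2, 1, 3))
  swapped <- data.frame(i = cc$j, j = cc$i)
  expect_equal(cnt(cc)$count, cnt(swapped)$count)
})

test_that("enrichment ratio and infinity flagging", {
  expect_equal(as.numeric(enrichment_score(50, 1000, 10, 500)), 2.5)
  expect_equal(as.numeric(enrichment_score(10, 100, 20, 200)), 1)
  e <- enrichment_score(5, 100, 0, 100)
  expect_true(is.infinite(e))
  expect_true(attr(e, "infinite"))
  expect_error(enrichment_score(1, 0, 1, 10), "positive")
})

test_that("information gain matches hand-computed entropies", {
  ## perfectly separating pair with balanced classes: 1 bit
  cls <- rep(c("A", "B"), each = 4)
  expect_equal(information_gain(cls == "A", cls), 1)
  ## independence: 0 bits
  expect_equal(information_gain(rep(c(TRUE, FALSE), 4), cls), 0)
  ## 8 contacts: 6 A, 2 B; pair present in 4 A, 0 B
  pres <- c(rep(TRUE, 4), rep(FALSE, 2), FALSE, FALSE)
  cls2 <- c(rep("A", 6), "B", "B")
  h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  expected <- h(c(6, 2) / 8) - 0.5 * h(c(2, 2) / 4)
  expect_equal(information_gain(pres, cls2), expected)
  expect_equal(round(expected, 4), 0.3113)
  ## bounds and degenerate cases
  expect_warning(ig <- information_gain(c(TRUE, FALSE), c("A", "A")), "one class")
  expect_equal(ig, 0)
  expect_equal(information_gain(rep(TRUE, 8), cls), 0)   # constant presence
})

test_that("feature_pair_stats ties counting, enrichment and IG together", {
  set.seed(71)
  nwin <- 30
  feat <- matrix(rbinom(nwin * 4, 1, 0.4) > 0, nwin, 4,
                 dimnames = list(NULL, paste0("M", 1:4)))
  ft <- structure(list(windows = data.frame(chrom = "chr1",
                                            start = (0:(nwin - 1)) * 5e4,
                                            end = (1:nwin) * 5e4),
                       features = feat), class = "gam_features")
  ca <- data.frame(i = sample(nwin, 20, TRUE), j = sample(nwin, 20, TRUE))
  cb <- data.frame(i = sample(nwin, 15, TRUE), j = sample(nwin, 15, TRUE))
  st <- feature_pair_stats(ca, cb, ft)
  expect_equal(nrow(st), 4 + 6)
  expect_true(all(st$count_a <= 20 & st$count_b <= 15))
  ## enrichment consistency with the scalar function
  for (r in seq_len(nrow(st))) {
    if (st$count_b[r] > 0)
      expect_equal(st$enrichment_a[r],
                   (st$count_a[r] / 20) / (st$count_b[r] / 15))
  }
  ## IG agrees with the direct definition on pooled contacts
  pres_a <- gamforge:::pair_presence(ca, feat, st$f1[1], st$f2[1])
  pres_b <- gamforge:::pair_presence(cb, feat, st$f1[1], st$f2[1])
  expect_equal(st$information_gain[1],
               information_gain(c(pres_a, pres_b),
                                rep(c("A", "B"), c(20, 15))))
  expect_true(all(st$information_gain >= 0 & st$information_gain <= 1))
})

test_that("top-pair shortlist takes the union with lexicographic ties", {
  pairs <- enumerate_feature_pairs(paste0("M", sprintf("%02d", 1:8)))
  n <- nrow(pairs)
  ## all-identical stats: shortlist filled lexicographically, <= 20 entries
  st <- data.frame(pairs, count_a = 1, count_b = 1, total_a = 10, total_b = 10,
                   enrichment_a = 1, enrichment_b = 1, information_gain = 0.5)
  sel <- select_top_pairs(st)
  expect_lte(nrow(sel), 20)
  first10 <- order(paste(st$f1, st$f2))[1:10]
  expect_true(all(first10 %in% as.integer(rownames(sel))))

  ## disjoint top sets: union has exactly 20 members
  st2 <- st
  st2$information_gain <- 0
  st2$enrichment_a <- 1
  st2$enrichment_b <- 1
  st2$information_gain[1:10] <- 0.9
  st2$enrichment_a[11:15] <- 9
  st2$enrichment_b[16:20] <- 9
  sel2 <- select_top_pairs(st2)
  expect_equal(nrow(sel2), 20)
  expect_setequal(as.integer(rownames(sel2)), 1:20)
})

test_that("network edges require 20% of total contacts", {
  counts <- data.frame(f1 = c("M1", "M1", "M2"), f2 = c("M2", "M3", "M3"),
                       count = c(19, 20, 45))
  e <- pair_network_edges(counts, total_contacts = 100)
  expect_equal(nrow(e), 2)             # 19 < 20 excluded; 20 included
  expect_equal(e$weight, c(20, 45))
  expect_equal(nrow(pair_network_edges(counts, total_contacts = 1000)), 0)
  e3 <- pair_network_edges(counts, total_contacts = 50)
  expect_equal(nrow(e3), 3)
})
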
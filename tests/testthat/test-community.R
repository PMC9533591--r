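# Filtering, rarefaction, collapse, diversity, ordination, PERMANOVA,
# clustering, paired distances.

test_that("low-abundance filter applies frequency and prevalence rules", {
  # 10,000 total reads; F1 has 1 read in 1 sample (removed on both rules);
  # F2 sits exactly at 0.01% (1 read in each of 2 samples after scaling)
  counts <- rbind(F1 = c(1, 0, 0, 0),
                  F2 = c(1, 1, 0, 0),
                  F3 = c(4999, 1998, 1500, 1500))
  colnames(counts) <- sprintf("s%d", 1:4)
  ft <- toy_feature_table(counts)
  total <- sum(counts)
  expect_equal(total, 10000)
  out <- filter_low_abundance(ft, min_global_freq = 2 / total)
  expect_setequal(rownames(out$counts), c("F2", "F3"))  # exactly at cut-off kept
  out <- filter_low_abundance(ft, min_global_freq = 1e-8, min_prevalence = 2)
  expect_false("F1" %in% rownames(out$counts))          # prevalence rule alone
  # all features above both cut-offs -> unchanged
  ft2 <- toy_feature_table(matrix(c(50, 60, 70, 80), 2, 2))
  expect_identical(filter_low_abundance(ft2)$counts, ft2$counts)
  ft0 <- toy_feature_table(matrix(0, 2, 2))
  expect_error(filter_low_abundance(ft0), "zero")
})

test_that("rarefaction subsamples without replacement to the exact depth", {
  set.seed(2)
  counts <- matrix(rpois(40, 60), 8, 5,
                   dimnames = list(sprintf("F%d", 1:8), sprintf("s%d", 1:5)))
  counts[, 5] <- c(3, 0, 1, 0, 0, 0, 1, 0)      # far below depth
  ft <- toy_feature_table(counts)
  expect_warning(rf <- rarefy(ft, depth = 300, seed = 1), "s5")
  expect_true(all(colSums(rf$counts) == 300))
  expect_false("s5" %in% colnames(rf$counts))
  expect_true(all(rf$counts <= counts[, colnames(rf$counts)]))
  # a sample already at depth is passed through unchanged
  counts2 <- matrix(c(100, 200, 150, 150), 2, 2,
                    dimnames = list(c("a", "b"), c("x", "y")))
  ft2 <- toy_feature_table(counts2)
  rf2 <- rarefy(ft2, depth = 300, seed = 1)
  expect_identical(rf2$counts, ft2$counts)
})

test_that("rarefaction preserves expected proportions (hypergeometric mean)", {
  counts <- matrix(c(120, 80, 50, 150), 2, 2,
                   dimnames = list(c("a", "b"), c("x", "y")))
  ft <- toy_feature_table(counts)
  props <- replicate(400, {
    rf <- rarefy(ft, depth = 100, seed = sample.int(1e6, 1))
    rf$counts["a", "x"] / 100
  })
  # E[p] = 120/200 = 0.6; MC sd of the mean ~ sqrt(0.6*0.4/100/400)
  expect_lt(abs(mean(props) - 0.6), 4 * sqrt(0.6 * 0.4 / 100 / 400))
})

test_that("taxonomic collapse sums lineage groups and pools unassigned", {
  counts <- rbind(A1 = c(1, 2), A2 = c(3, 4), B1 = c(5, 6), U1 = c(7, 8))
  colnames(counts) <- c("s1", "s2")
  ft <- toy_feature_table(counts,
                          genera = c("GenA", "GenA", "GenB", ""))
  g <- collapse_rank(ft, "genus")
  expect_equal(unname(g$counts["GenA", ]), c(4, 6))
  expect_equal(unname(g$counts["GenB", ]), c(5, 6))
  expect_true(any(grepl("^unassigned_", rownames(g$counts))))
  expect_equal(sum(g$counts), sum(counts))
  # 3-genus hand-summed check at family level (all same family here)
  f <- collapse_rank(ft, "phylum")
  expect_equal(unname(f$counts["Firmicutes", ]), unname(colSums(counts)))
})

test_that("alpha diversity matches closed forms", {
  counts <- matrix(rep(5, 8), 8, 1, dimnames = list(paste0("t", 1:8), "s1"))
  ft <- toy_feature_table(counts)
  a <- alpha_diversity(ft)
  expect_equal(a$observed_features, 8L)
  expect_equal(a$shannon, 3)              # log base 2
  expect_equal(a$pielou, 1)

  single <- toy_feature_table(matrix(c(40, 0), 2, 1,
                                     dimnames = list(c("t1", "t2"), "s1")))
  a <- alpha_diversity(single)
  expect_equal(a$shannon, 0)
  expect_true(is.na(a$pielou))            # undefined for one feature

  # unit star tree with 4 tips, all observed: PD = 4 (root path included)
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1):0;")
  ft4 <- toy_feature_table(matrix(1, 4, 1, dimnames = list(paste0("t", 1:4), "s1")))
  a <- alpha_diversity(ft4, star)
  expect_equal(a$faith_pd, 4)
  # partial observation drops the unobserved tip's branch
  ft3 <- toy_feature_table(matrix(c(1, 1, 1, 0), 4, 1,
                                  dimnames = list(paste0("t", 1:4), "s1")))
  expect_equal(alpha_diversity(ft3, star)$faith_pd, 3)
  # feature absent from the tree errors with ids
  ftx <- toy_feature_table(matrix(1, 2, 1, dimnames = list(c("t1", "zz"), "s1")))
  expect_error(alpha_diversity(ftx, star), "zz")
})

test_that("faith_pd agrees with picante on random trees", {
  skip_if_not_installed("picante")
  set.seed(12)
  tree <- ape::rtree(30)
  counts <- matrix(rbinom(30 * 6, 5, 0.4), 30, 6,
                   dimnames = list(tree$tip.label, sprintf("s%d", 1:6)))
  counts[counts == 0 & row(counts) == 1] <- 1   # keep samples non-empty
  ft <- toy_feature_table(counts)
  ours <- suppressWarnings(alpha_diversity(ft, tree))$faith_pd
  ref <- picante::pd(t(counts), tree, include.root = TRUE)$PD
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("Bray-Curtis matches hand-worked values and its axioms", {
  counts <- cbind(s1 = c(10, 0), s2 = c(0, 10), s3 = c(6, 4), s4 = c(4, 6),
                  s5 = c(10, 0))
  rownames(counts) <- c("a", "b")
  d <- bray_curtis(toy_feature_table(counts))
  expect_equal(d["s1", "s2"], 1)          # disjoint supports
  expect_equal(d["s3", "s4"], 0.2)
  expect_equal(d["s1", "s5"], 0)          # identical samples
  # axioms on random tables
  set.seed(30)
  for (i in 1:5) {
    counts <- random_dm_table(25, 8, 500)
    dd <- bray_curtis(toy_feature_table(counts))
    expect_equal(dd, t(dd))
    expect_true(all(diag(dd) == 0))
    expect_true(all(dd >= 0 & dd <= 1))
  }
  zero <- toy_feature_table(cbind(s1 = c(1, 1), s2 = c(0, 0)))
  expect_error(bray_curtis(zero), "zero total")
})

test_that("PCoA reproduces Euclidean geometry and orders axes", {
  set.seed(8)
  X <- matrix(rnorm(7 * 3), 7, 3)
  d <- as.matrix(dist(X))
  dimnames(d) <- list(paste0("s", 1:7), paste0("s", 1:7))
  fit <- pcoa(d, k = 3)                 # points live in R^3: rank-3 embedding
  rec <- as.matrix(dist(fit$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-8)
  expect_true(all(diff(fit$proportion_explained) <= 1e-12))

  # 3 equidistant samples: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  fit3 <- pcoa(d3, k = 2)
  pos <- fit3$eigenvalues[fit3$eigenvalues > 1e-9]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  # duplicated sample lands on coincident coordinates
  d4 <- as.matrix(dist(rbind(X[1:3, ], X[3, ])))
  dimnames(d4) <- list(paste0("s", 1:4), paste0("s", 1:4))
  fit4 <- pcoa(d4)
  expect_equal(fit4$coordinates["s3", ], fit4$coordinates["s4", ],
               tolerance = 1e-8)
  expect_error(pcoa(d3[1:2, 1:2]), "at least 3")
})

test_that("PERMANOVA pseudo-F matches vegan::adonis2", {
  set.seed(19)
  counts <- random_dm_table(40, 12, 800)
  ft <- toy_feature_table(counts)
  dm <- bray_curtis(ft)
  labels <- rep(c("A", "B", "C"), each = 4)
  ours <- permanova(dm, labels, n_permutations = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(dm) ~ g,
                        data = data.frame(g = labels), permutations = 99)
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-8)
  expect_equal(unname(ours$df["among"]), ref$Df[1])
})

test_that("PERMANOVA contracts and degenerate separations", {
  d <- matrix(1, 4, 4) - diag(4)
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_error(permanova(d, c("A", "A", "A", "B")), "single sample")
  # two tight clusters far apart: exhaustive p is the minimal achievable
  dm <- matrix(1, 6, 6); diag(dm) <- 0
  dm[1:3, 1:3] <- 0; dm[4:6, 4:6] <- 0
  dimnames(dm) <- list(paste0("s", 1:6), paste0("s", 1:6))
  r <- permanova(dm, rep(c("A", "B"), each = 3), permutations = "exhaustive")
  expect_equal(r$p_value, 2 / 20)   # both orientations of the true split
})

test_that("hierarchical clustering recovers blobs and reports composition", {
  dm <- matrix(0.9, 6, 6)
  dm[1:3, 1:3] <- 0.1; dm[4:6, 4:6] <- 0.1
  diag(dm) <- 0
  dimnames(dm) <- list(paste0("s", 1:6), paste0("s", 1:6))
  groups <- stats::setNames(rep(c("SU", "UN"), each = 3), paste0("s", 1:6))
  hc <- hierarchical_cluster(dm, k = 2, groups = groups)
  expect_equal(length(unique(hc$clusters[1:3])), 1)
  expect_equal(length(unique(hc$clusters[4:6])), 1)
  expect_false(hc$clusters[1] == hc$clusters[4])
  expect_equal(unname(hc$composition_pct[1, "SU"]), 100)

  # identical samples merge at height zero
  dm0 <- matrix(0, 3, 3)
  dimnames(dm0) <- list(paste0("s", 1:3), paste0("s", 1:3))
  hc0 <- hierarchical_cluster(dm0, k = 1)
  expect_true(all(hc0$tree$height == 0))
  expect_equal(unname(hc0$clusters), rep(1L, 3))
})

test_that("complete linkage follows the hand-traced merge order", {
  # points on a line at 0, 1, 3, 7: complete-linkage merges (a,b) at 1,
  # then (ab,c) at max(3,2)=3, then (abc,d) at max(7,6,4)=7
  x <- c(a = 0, b = 1, c = 3, d = 7)
  dm <- as.matrix(dist(x))
  hc <- hierarchical_cluster(dm, linkage = "complete", k = 2)
  expect_equal(hc$tree$height, c(1, 3, 7))
  expect_equal(length(unique(hc$clusters[c("a", "b", "c")])), 1)
  expect_false(hc$clusters[["d"]] == hc$clusters[["a"]])
})

test_that("paired pre/post distances handle identity and missing periods", {
  counts <- cbind(c1_pre = c(10, 5, 0), c1_post = c(10, 5, 0),
                  c2_pre = c(8, 0, 7), c2_post = c(0, 9, 6),
                  c3_post = c(4, 4, 4))
  rownames(counts) <- paste0("F", 1:3)
  meta <- data.frame(sample_id = colnames(counts),
                     cow_id = c("c1", "c1", "c2", "c2", "c3"),
                     period = c("prepartum", "postpartum", "prepartum",
                                "postpartum", "postpartum"),
                     group = "SU")
  ft <- suppressWarnings(feature_table(counts, meta))
  expect_warning(pp <- paired_prepost_distance(ft), "c3")
  expect_equal(nrow(pp$distances), 2)
  expect_equal(pp$distances$distance[pp$distances$cow_id == "c1"], 0)
  d2 <- (8 + 9 + 1) / (8 + 9 + 13)
  expect_equal(pp$distances$distance[pp$distances$cow_id == "c2"], d2)
})
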
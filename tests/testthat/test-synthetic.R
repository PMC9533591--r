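# Synthetic cohort generators: pH model ground truth, feature tables,
# assays, reproducibility.

test_that("flat noise-free curves give trivial ground truth", {
  p <- ph_model_params(baseline = 6.5, dip_depth = 0, noise_sd = 0,
                       diurnal_amp = 0)
  sim <- simulate_ph_trace(p, days_pre = 1, days_post = 2, seed = 1)
  expect_true(all(sim$truth$minutes_below == 0))
  expect_true(all(sim$truth$auc_below == 0))
  expect_true(all(abs(sim$trace$ph - 6.5) < 1e-12))

  p <- ph_model_params(baseline = 5.5, dip_depth = 0, noise_sd = 0,
                       diurnal_amp = 0)
  sim <- simulate_ph_trace(p, days_pre = 1, days_post = 2, seed = 1)
  expect_equal(sim$truth$minutes_below, rep(1440, 3), tolerance = 1e-8)
  expect_equal(sim$truth$auc_below, rep(720, 3), tolerance = 1e-6)
})

test_that("single-dip days match the closed-form crossing solution", {
  # baseline - depth * 2^(-t/h) < 6 until t* = h * log2(depth/(baseline-6))
  b <- 6.3; D <- 0.6; h <- 60
  t_star <- h * log2(D / (b - 6))                      # 60 min
  auc_star <- D * h / log(2) * (1 - 2^(-t_star / h)) - (b - 6) * t_star
  p <- ph_model_params(baseline = b, dip_depth = D, dip_halflife = h,
                       dip_onset = 0, noise_sd = 0, diurnal_amp = 0)
  sim <- simulate_ph_trace(p, days_pre = 1, days_post = 2, seed = 1,
                           feeding_times = "07:30")
  day1 <- sim$truth[sim$truth$day_index == 1, ]
  expect_equal(day1$minutes_below, t_star, tolerance = 0.01)
  expect_equal(day1$auc_below, auc_star, tolerance = 0.01)
})

test_that("analytic ground truth matches fine-grid integration of the curve", {
  set.seed(5)
  cases <- list(
    ph_model_params(baseline = 6.3, dip_depth = 0.8, dip_halflife = 60,
                    noise_sd = 0, diurnal_amp = 0.05),
    ph_model_params(baseline = 6.4, dip_depth = 1.2, dip_halflife = 90,
                    noise_sd = 0, diurnal_amp = 0.1, diurnal_phase = 1),
    ph_model_params(baseline = 6.25, dip_depth = 0.35, dip_halflife = 30,
                    noise_sd = 0, diurnal_amp = 0.05)
  )
  for (p in cases) {
    sim <- simulate_ph_trace(p, days_pre = 2, days_post = 3, seed = 1)
    for (d in c(-1, 1, 3)) {
      orc <- curve_oracle(p, d, days_pre = 2, days_post = 3)
      row <- sim$truth[sim$truth$day_index == d, ]
      expect_lt(abs(row$minutes_below - orc$minutes), 0.1)
      expect_lt(abs(row$auc_below - orc$auc), 0.5)
    }
  }
})

test_that("cohort construction hits each group's rule box", {
  ch <- simulate_cohort(cohort_design(seed = 3, noise_sd = 0))
  expect_equal(as.vector(table(ch$truth_labels)[c("SU", "MS", "MU", "UN")]),
               c(10L, 7L, 11L, 10L))
  # noise-free true daily metrics classify back to the construction label
  for (cw in names(ch$traces)) {
    td <- ch$truth_daily[ch$truth_daily$cow_id == cw &
                           ch$truth_daily$day_index > 0, ]
    s <- make_summary(mean(td$minutes_below), median(td$minutes_below))
    expect_equal(classify_sara(s)$label, unname(ch$truth_labels[cw]))
  }
  # an all-UN design has zero time below threshold everywhere
  un <- simulate_cohort(cohort_design(n_cows = 4L,
                                      group_sizes = c(UN = 4L),
                                      prepartum_missing = c(UN = 0L),
                                      noise_sd = 0, seed = 2))
  expect_true(all(un$truth_daily$minutes_below == 0))
})

test_that("generators are reproducible under a seed and differ across seeds", {
  d <- cohort_design(n_cows = 4L, group_sizes = c(SU = 1L, MS = 1L, MU = 1L, UN = 1L),
                     prepartum_missing = c(SU = 0L, MS = 0L, MU = 0L, UN = 0L))
  a <- simulate_cohort(d)
  b <- simulate_cohort(d)
  expect_identical(a$traces$SU01$ph, b$traces$SU01$ph)
  d2 <- d; d2$seed <- 99L
  c2 <- simulate_cohort(d2)
  expect_false(identical(a$traces$SU01$ph, c2$traces$SU01$ph))

  meta <- a$metadata
  f1 <- simulate_feature_table(meta, community_design(n_features = 120L,
                                                      n_filler_genera = 30L),
                               seed = 5)
  f2 <- simulate_feature_table(meta, community_design(n_features = 120L,
                                                      n_filler_genera = 30L),
                               seed = 5)
  expect_identical(f1$table$counts, f2$table$counts)
  f3 <- simulate_feature_table(meta, community_design(n_features = 120L,
                                                      n_filler_genera = 30L),
                               seed = 6)
  expect_false(identical(f1$table$counts, f3$table$counts))
})

test_that("per-cow streams are stable when the cohort grows", {
  d4 <- cohort_design(n_cows = 4L, group_sizes = c(SU = 1L, MS = 1L, MU = 1L, UN = 1L),
                      prepartum_missing = c(SU = 0L, MS = 0L, MU = 0L, UN = 0L))
  d5 <- cohort_design(n_cows = 5L, group_sizes = c(SU = 2L, MS = 1L, MU = 1L, UN = 1L),
                      prepartum_missing = c(SU = 0L, MS = 0L, MU = 0L, UN = 0L))
  a <- simulate_cohort(d4)
  b <- simulate_cohort(d5)
  expect_identical(a$traces$MS01$ph, b$traces$MS01$ph)
  expect_identical(a$traces$UN01$ph, b$traces$UN01$ph)
})

test_that("feature tables honour library sizes and planted multipliers", {
  meta <- data.frame(cow_id = sprintf("c%02d", 1:8),
                     group = rep(c("SU", "UN"), each = 4),
                     has_prepartum = TRUE)
  des <- community_design(n_features = 120L, n_filler_genera = 30L,
                          library_size_range = c(34000L, 34000L),
                          period_effect_sd = 0)
  sim <- simulate_feature_table(meta, des, seed = 9)
  expect_true(all(colSums(sim$table$counts) == 34000))
  expect_equal(unname(colSums(sim$table$counts)),
               unname(sim$truth$library_sizes[colnames(sim$table$counts)]))
  # row sums equal drawn library sizes exactly, and planted genera exist
  expect_true(all(c("Ruminococcus", "Streptococcus") %in%
                    sim$table$taxonomy[, "genus"]))
  # tree covers all features with non-negative lengths
  expect_setequal(sim$tree$tip.label, rownames(sim$table$counts))
  expect_true(all(sim$tree$edge.length >= 0))
  # unknown planted taxon errors
  bad <- des
  bad$planted_effects <- data.frame(genus = "NotATaxon", period = "postpartum",
                                    group = "SU", multiplier = 2)
  expect_error(simulate_feature_table(meta, bad, seed = 9), "NotATaxon")
})

test_that("planted multiplier scales the pre-renormalization expectation", {
  # with a single planted effect the expected SU:UN abundance ratio of the
  # planted genus approaches the multiplier (small planted mass -> the
  # renormalization correction is negligible)
  meta <- data.frame(cow_id = sprintf("c%02d", 1:40),
                     group = rep(c("SU", "UN"), each = 20),
                     has_prepartum = FALSE)
  des <- community_design(n_features = 120L, n_filler_genera = 30L,
                          planted_effects = data.frame(
                            genus = "Ruminococcus", period = "postpartum",
                            group = "SU", multiplier = 2),
                          library_size_range = c(40000L, 40000L))
  sim <- simulate_feature_table(meta, des, seed = 21)
  rel <- sweep(sim$table$counts, 2, colSums(sim$table$counts), "/")
  rum <- colSums(rel[sim$truth$asv_genus[rownames(rel)] == "Ruminococcus", ,
                     drop = FALSE])
  grp <- sim$table$sample_meta$group
  ratio <- mean(rum[grp == "SU"]) / mean(rum[grp == "UN"])
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("assay generator and quantification are exact inverse pairs", {
  meta <- data.frame(cow_id = sprintf("c%02d", 1:6),
                     group = rep(c("SU", "UN"), each = 3),
                     has_prepartum = TRUE)
  assays <- simulate_assays(meta, assay_design(cq_noise_sd = 0), seed = 4)
  q <- quantify_assays(assays)
  truth <- assays$truth$copies
  mi <- match(paste(q$qpcr$sample_id, q$qpcr$target),
              paste(truth$sample_id, truth$target))
  expect_equal(q$qpcr$copies_per_ml, truth$copies_per_ml[mi], tolerance = 1e-10)
  tc <- assays$truth$concentrations
  fa <- q$fatty_acids[q$fatty_acids$analyte %in% tc$analyte, ]
  mi <- match(paste(fa$sample_id, fa$analyte), paste(tc$sample_id, tc$analyte))
  expect_equal(fa$mg_per_100g, tc$mg_per_100g[mi], tolerance = 1e-10)
  # standard curves recover the designed slope/intercept
  expect_equal(q$curves$bacteria$slope, -3.32, tolerance = 1e-10)
  expect_equal(q$curves$bacteria$intercept, 38, tolerance = 1e-8)
})

test_that("zero qPCR shift gives equal group means in expectation", {
  meta <- data.frame(cow_id = sprintf("c%02d", 1:60),
                     group = rep(c("SU", "UN"), each = 30),
                     has_prepartum = FALSE)
  assays <- simulate_assays(meta, assay_design(un_shift_log10 = 0), seed = 8)
  bac <- assays$qpcr[assays$qpcr$target == "bacteria", ]
  m <- tapply(bac$cq, bac$group, mean)
  # difference within Monte-Carlo error of zero (sd 0.25/sqrt(30) per group)
  expect_lt(abs(m[["SU"]] - m[["UN"]]), 4 * 0.25 * sqrt(2 / 30))
})
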
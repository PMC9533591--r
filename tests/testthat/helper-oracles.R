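# Independent oracles and tiny fixture builders used across test files.

# Fine-grid numeric oracle for time-below and AUC-below of a sampled
# trace: evaluates the piecewise-linear interpolant on a dt-min grid and
# Riemann-sums it. Independent of the analytic crossing-split code path.
grid_oracle <- function(trace, threshold, day, dt = 0.01) {
  w <- if (day > 0) c((day - 1) * 1440, day * 1440) else c(day * 1440, (day + 1) * 1440)
  tt <- seq(w[1], w[2] - dt, by = dt) + dt / 2
  p <- approx(trace$time_min, trace$ph, xout = tt)$y
  ok <- !is.na(p)
  below <- ok & p < threshold
  list(minutes = sum(below) * dt,
       auc = sum(pmax(0, threshold - p[below])) * dt)
}

# Fine-grid oracle for the continuous noise-free synthetic curve.
curve_oracle <- function(params, day, threshold = 6, days_pre = 7, days_post = 21,
                         dt = 0.01, prepartum_depth_factor = 1) {
  feeds <- saratools:::feeding_minutes(days_pre, days_post)
  depths <- ifelse(feeds < 0, params$dip_depth * prepartum_depth_factor,
                   params$dip_depth)
  w <- if (day > 0) c((day - 1) * 1440, day * 1440) else c(day * 1440, (day + 1) * 1440)
  tt <- seq(w[1], w[2] - dt, by = dt) + dt / 2
  p <- saratools:::ph_curve_value(tt, params$baseline, params$diurnal_amp,
                                  params$diurnal_phase, feeds, depths,
                                  params$dip_halflife, params$dip_onset)
  below <- p < threshold
  list(minutes = sum(below) * dt,
       auc = sum(threshold - p[below]) * dt)
}

# Brute-force ANCOM oracle: all pairwise log-ratio Kruskal-Wallis tests
# via stats::kruskal.test, BH within each taxon's family.
ancom_oracle <- function(counts, labels, alpha = 0.05, pseudocount = 1) {
  m <- nrow(counts)
  logc <- log(counts + pseudocount)
  g <- factor(labels)
  pmat <- matrix(NA_real_, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      p <- stats::kruskal.test(logc[i, ] - logc[j, ], g)$p.value
      pmat[i, j] <- pmat[j, i] <- p
    }
  }
  W <- apply(pmat, 1, function(p) sum(p.adjust(p[!is.na(p)], "BH") < alpha))
  as.integer(W)
}

# build a small feature_table in code
toy_feature_table <- function(counts, groups = NULL, periods = NULL,
                              genera = NULL) {
  n <- ncol(counts)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("S%02d", seq_len(n))
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("F%02d", seq_len(nrow(counts)))
  if (is.null(groups)) groups <- rep("G1", n)
  if (is.null(periods)) periods <- rep("postpartum", n)
  meta <- data.frame(sample_id = colnames(counts),
                     cow_id = paste0("cow", seq_len(n)),
                     period = periods, group = groups)
  tax <- matrix("", nrow(counts), 7,
                dimnames = list(rownames(counts), saratools:::TAX_RANKS))
  tax[, "domain"] <- "Bacteria"
  tax[, "phylum"] <- "Firmicutes"
  if (!is.null(genera)) tax[, "genus"] <- genera
  feature_table(counts, meta, tax)
}

# random Dirichlet-multinomial counts table (taxa x samples)
random_dm_table <- function(m, n, depth, theta = 100, base_sd = 1) {
  p0 <- exp(stats::rnorm(m, 0, base_sd))
  p0 <- p0 / sum(p0)
  counts <- vapply(seq_len(n), function(s) {
    g <- stats::rgamma(m, shape = theta * p0)
    stats::rmultinom(1, depth, g / sum(g))[, 1]
  }, numeric(m))
  rownames(counts) <- sprintf("T%03d", seq_len(m))
  colnames(counts) <- sprintf("S%03d", seq_len(n))
  counts
}

# construct a cow_ph_summary directly from its statistics
make_summary <- function(mean_m, median_m, window = "postpartum") {
  structure(list(window = window,
                 median_minutes_below = median_m,
                 mean_minutes_below = mean_m,
                 days_over_330 = 0L, total_auc = 0,
                 mean_daily_auc = 0, n_valid_days = 21L,
                 n_days_window = 21L),
            class = "cow_ph_summary")
}
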
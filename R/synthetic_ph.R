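# Synthetic reticular pH traces with analytic ground truth.
#
# The noise-free model is
#   pH(t) = baseline + amp * sin(2*pi*t/1440 + phase) - sum_k dip_k(t)
# where each postprandial dip descends linearly to its full depth over a
# short onset ramp (intake/mixing time) and then recovers exponentially
# with a half-life:
#   dip(dt) = depth * dt/onset                  for 0 <= dt < onset
#   dip(dt) = depth * 2^(-(dt - onset)/halflife) for dt >= onset.
# The finite onset matters: an instantaneous drop produces sub-threshold
# excursions narrower than the 10-15 min bolus sampling interval, which
# no sampled trace could resolve. The sampled trace adds AR(1) noise on
# a jittered 10-15 min grid. Ground-truth daily time-below and AUC-below
# are computed on the continuous noise-free curve by bracketed
# root-finding of the threshold crossings plus adaptive quadrature, so
# they are independent of the trapezoid path used by ph_metrics.

#' Parameters of the synthetic pH curve
#'
#' @param baseline per-cow mean reticular pH (dimensionless).
#' @param dip_depth pH units removed at each postprandial event (>= 0).
#' @param dip_halflife recovery half-life, minutes.
#' @param dip_onset descent-ramp length from feeding to full dip depth,
#'   minutes (0 = instantaneous drop).
#' @param noise_sd AR(1) innovation scale, pH units (marginal sd).
#' @param ar1_rho lag-1 autocorrelation of the sampling-grid noise, in
#'   \[0, 1).
#' @param diurnal_amp amplitude of the diurnal sinusoid, pH units.
#' @param diurnal_phase phase of the sinusoid, radians.
#' @param sampling_range inter-sample interval bounds, minutes.
#' @return object of class `ph_model_params`.
#' @export
ph_model_params <- function(baseline = 6.3, dip_depth = 0.8, dip_halflife = 60,
                            dip_onset = 20, noise_sd = 0.08, ar1_rho = 0.7,
                            diurnal_amp = 0.05, diurnal_phase = 0,
                            sampling_range = c(10, 15)) {
  stopifnot(dip_depth >= 0, noise_sd >= 0, ar1_rho >= 0, ar1_rho < 1,
            dip_halflife > 0, dip_onset >= 0, length(sampling_range) == 2,
            sampling_range[1] <= sampling_range[2])
  structure(as.list(environment()), class = "ph_model_params")
}

# feeding times (minutes relative to calving) for the window
# [-days_pre, days_post] days; feeding clock times are converted through
# the calving time-of-day so day boundaries stay calving-aligned.
clock_minutes <- function(s) {
  hm <- as.numeric(strsplit(s, ":")[[1]])
  hm[1] * 60 + hm[2]
}

feeding_minutes <- function(days_pre, days_post,
                            feeding_times = c("07:30", "16:30"),
                            calving_clock = "06:00") {
  calv <- clock_minutes(calving_clock)
  offs <- vapply(feeding_times, clock_minutes, numeric(1)) - calv
  offs <- offs %% 1440
  days <- seq(-days_pre - 1L, days_post)     # one extra day so tails carry in
  sort(as.vector(outer(offs, days * 1440, `+`)))
}

# per-feed dip depths: scalar depth x per-meal factor (matched through
# the feed's clock offset) x prepartum attenuation
feed_depths <- function(feeds, depth, feeding_times, calving_clock,
                        feed_factors = 1, prepartum_factor = 1) {
  offs <- (vapply(feeding_times, clock_minutes, numeric(1)) -
             clock_minutes(calving_clock)) %% 1440
  fac <- rep_len(feed_factors, length(offs))
  idx <- match(round(feeds %% 1440, 6), round(offs, 6))
  d <- depth * fac[idx]
  d[feeds < 0] <- d[feeds < 0] * prepartum_factor
  d
}

# continuous noise-free curve; feeds/depths are parallel vectors
ph_curve_value <- function(t, baseline, amp, phase, feeds, depths, halflife,
                           onset = 0) {
  out <- baseline + amp * sin(2 * pi * t / 1440 + phase)
  for (k in seq_along(feeds)) {
    dt <- t - feeds[k]
    act <- dt >= 0
    if (!any(act)) next
    d <- dt[act]
    dip <- if (onset > 0) {
      ifelse(d < onset, d / onset, 2^(-(d - onset) / halflife))
    } else {
      2^(-d / halflife)
    }
    out[act] <- out[act] - depths[k] * dip
  }
  out
}

# Ground-truth daily metrics of the continuous curve: crossings located
# on a 0.5-min bracket grid and refined by uniroot (tol 1e-9 min); AUC by
# integrate() on each sub-threshold interval.
true_day_metrics <- function(day, threshold, baseline, amp, phase,
                             feeds, depths, halflife, onset = 0) {
  w <- day_window(day)
  f <- function(t) ph_curve_value(t, baseline, amp, phase, feeds, depths,
                                  halflife, onset)
  grid <- seq(w[1], w[2], by = 0.5)
  v <- f(grid) - threshold
  pts <- w[1]
  sgn <- sign(v)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    pts <- c(pts, stats::uniroot(function(t) f(t) - threshold,
                                 c(grid[i], grid[i + 1]),
                                 tol = 1e-9)$root)
  }
  pts <- c(pts, w[2])
  minutes <- 0; auc <- 0
  for (i in seq_len(length(pts) - 1L)) {
    mid <- (pts[i] + pts[i + 1]) / 2
    if (f(mid) < threshold) {
      minutes <- minutes + (pts[i + 1] - pts[i])
      auc <- auc + stats::integrate(function(t) threshold - f(t),
                                    pts[i], pts[i + 1],
                                    rel.tol = 1e-9, abs.tol = 1e-9,
                                    subdivisions = 500L)$value
    }
  }
  c(minutes_below = minutes, auc_below = auc)
}

#' Simulate one cow's pH trace with analytic ground truth
#'
#' Samples the noise-free curve at jittered 10-15 min intervals, adds
#' AR(1) noise, and returns both the sampled [ph_trace()] and the
#' continuous curve's exact daily time-below/AUC-below values (the
#' recovery-test ground truth).
#'
#' @param params a [ph_model_params()].
#' @param days_pre,days_post window size around the synthetic calving.
#' @param seed integer seed for this trace.
#' @param threshold pH threshold used for the truth table.
#' @param feeding_times clock times of the two daily meals.
#' @param calving_clock calving time-of-day (day boundaries align to it).
#' @param cow_id identifier for the trace.
#' @param prepartum_depth_factor multiplier applied to `dip_depth` for
#'   prepartum feedings (prepartum rations are less fermentable).
#' @param feed_depth_factors per-meal depth multipliers, recycled over
#'   `feeding_times` (e.g. `c(1, 0.25)` for a shallow evening dip).
#' @param calving_time POSIXct calving timestamp attached to the trace.
#' @return list with `trace` (a `ph_trace`) and `truth` (data.frame of
#'   per-day `minutes_below`, `auc_below` of the noise-free curve).
#' @export
simulate_ph_trace <- function(params, days_pre = 7L, days_post = 21L, seed = 1L,
                              threshold = 6, feeding_times = c("07:30", "16:30"),
                              calving_clock = "06:00", cow_id = "cow1",
                              prepartum_depth_factor = 1,
                              feed_depth_factors = 1,
                              calving_time = as.POSIXct("2019-06-15 06:00:00", tz = "UTC")) {
  if (days_pre + days_post < 1) stop("window must cover at least 1 day")
  feeds <- feeding_minutes(days_pre, days_post, feeding_times, calving_clock)
  depths <- feed_depths(feeds, params$dip_depth, feeding_times, calving_clock,
                        feed_depth_factors, prepartum_depth_factor)
  days <- setdiff(seq(-days_pre, days_post), 0)
  truth <- t(vapply(days, function(d) {
    true_day_metrics(d, threshold, params$baseline, params$diurnal_amp,
                     params$diurnal_phase, feeds, depths, params$dip_halflife,
                     params$dip_onset)
  }, numeric(2)))
  truth <- data.frame(day_index = days, truth)

  set.seed(seed)
  t0 <- -days_pre * 1440 - 30
  t1 <- days_post * 1440 + 30
  n_max <- ceiling((t1 - t0) / params$sampling_range[1]) + 2L
  steps <- stats::runif(n_max, params$sampling_range[1], params$sampling_range[2])
  times <- t0 + cumsum(c(0, steps))
  times <- times[times <= t1]
  base <- ph_curve_value(times, params$baseline, params$diurnal_amp,
                         params$diurnal_phase, feeds, depths,
                         params$dip_halflife, params$dip_onset)
  if (params$noise_sd > 0) {
    innov <- stats::rnorm(length(times), 0,
                          params$noise_sd * sqrt(1 - params$ar1_rho^2))
    noise <- stats::filter(innov, params$ar1_rho, method = "recursive")
    base <- base + as.numeric(noise)
  }
  base <- pmin(pmax(base, 3.5), 9.5)
  list(trace = ph_trace(cow_id, times, base, calving_time = calving_time),
       truth = truth)
}

#' Design of a synthetic SARA cohort
#'
#' Defaults reproduce the monitored herd: 38 multiparous cows in four
#' susceptibility groups (SU 10, MS 7, MU 11, UN 10), a 7-d prepartum and
#' 21-d postpartum window, two daily meals at 07:30 and 16:30, and 9
#' prepartum samples lost to premature calving (3 MS, 5 MU, 1 UN).
#'
#' @param n_cows total cows (>= 4).
#' @param group_sizes named integer vector over SU/MS/MU/UN summing to
#'   `n_cows`.
#' @param days_pre,days_post monitoring window, days.
#' @param feeding_times clock times of the two daily meals.
#' @param calving_clock calving time-of-day.
#' @param target_ranges per-group range of true daily minutes below
#'   threshold the generator aims for (chosen inside each rule box, with
#'   margin).
#' @param noise_sd,ar1_rho sampling-noise parameters shared by all cows.
#' @param diurnal_amp diurnal sinusoid amplitude, pH units.
#' @param prepartum_depth_factor prepartum dip attenuation.
#' @param prepartum_missing named integer vector of cows per group with
#'   no prepartum sample.
#' @param seed master seed; per-cow streams are derived by stable hashing
#'   of cow ids.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_cows = 38L,
                          group_sizes = c(SU = 10L, MS = 7L, MU = 11L, UN = 10L),
                          days_pre = 7L, days_post = 21L,
                          feeding_times = c("07:30", "16:30"),
                          calving_clock = "06:00",
                          target_ranges = list(SU = c(240, 400), MS = c(90, 150),
                                               MU = c(18, 26), UN = c(0, 0)),
                          noise_sd = 0.08, ar1_rho = 0.7, diurnal_amp = 0.05,
                          prepartum_depth_factor = 0.7,
                          prepartum_missing = c(SU = 0L, MS = 3L, MU = 5L, UN = 1L),
                          seed = 1L) {
  stopifnot(n_cows >= 4L, sum(group_sizes) == n_cows,
            all(names(group_sizes) %in% c("SU", "MS", "MU", "UN")))
  structure(as.list(environment()), class = "cohort_design")
}

# Group presets: recovery half-life and onset ramp. MU needs brief,
# steep excursions: its rule box (10-60 min/d, median <= 30) forces
# sub-threshold windows on the order of one 10-15 min sampling interval,
# which are only resolvable in a sampled trace when the curve crosses
# the threshold on steep flanks rather than grazing it at a flat nadir.
group_halflife <- c(SU = 90, MS = 60, MU = 10, UN = 60)
group_onset <- c(SU = 20, MS = 20, MU = 12, UN = 20)
# MU: only the morning meal produces a threshold-crossing dip, so its
# single daily excursion is wide enough (>= ~20 min) to be resolved
group_feed_factors <- list(SU = 1, MS = 1, MU = c(1, 0.2), UN = 1)

# solve for the dip depth whose steady-state day has `target` true
# minutes below threshold (monotone in depth; uniroot)
calibrate_depth <- function(target, baseline, amp, phase, halflife,
                            feeds, threshold = 6, onset = 20, factors = 1) {
  factors <- rep_len(factors, length(feeds))
  day_minutes <- function(depth) {
    true_day_metrics(2L, threshold, baseline, amp, phase, feeds,
                     depth * factors, halflife, onset)["minutes_below"]
  }
  lo <- baseline - threshold - amp          # below this no crossing is possible
  stopifnot(lo > 0)
  f <- function(d) day_minutes(d) - target
  stats::uniroot(f, c(lo * 1.0005, 3), tol = 1e-7)$root
}

#' Simulate a full SARA cohort of pH traces
#'
#' Each cow draws a baseline and a target daily time-below-6 from its
#' group's preset range, and the dip depth is calibrated numerically so
#' the noise-free curve's daily metrics satisfy exactly that group's
#' classification rule (UN cows get a shallow dip that never crosses the
#' threshold). Returns the sampled traces, the construction-truth labels
#' and the analytic daily metrics.
#'
#' @param design a [cohort_design()].
#' @return list with `traces` (named list of `ph_trace`), `truth_labels`
#'   (named character), `truth_daily` (data.frame cow x day metrics),
#'   `cows` (per-cow parameter table), `metadata` (cow, group, prepartum
#'   availability) and `design`.
#' @export
simulate_cohort <- function(design = cohort_design()) {
  groups <- rep(names(design$group_sizes), design$group_sizes)
  ids <- unlist(lapply(names(design$group_sizes), function(g) {
    sprintf("%s%02d", g, seq_len(design$group_sizes[[g]]))
  }))
  feeds <- feeding_minutes(design$days_pre, design$days_post,
                           design$feeding_times, design$calving_clock)
  traces <- vector("list", length(ids))
  truth_rows <- vector("list", length(ids))
  cow_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- groups[i]
    cseed <- stable_seed(ids[i], design$seed)
    set.seed(cseed)
    # MU baselines start a little higher so the attenuated evening dip
    # stays clear of the threshold
    baseline <- stats::runif(1, if (g == "MU") 6.32 else 6.25, 6.45)
    target <- stats::runif(1, design$target_ranges[[g]][1],
                           design$target_ranges[[g]][2])
    hl <- group_halflife[[g]]
    onset <- group_onset[[g]]
    ffac <- group_feed_factors[[g]]
    cal_factors <- feed_depths(feeds, 1, design$feeding_times,
                               design$calving_clock, ffac, 1)
    depth <- if (g == "UN") {
      0.5 * (baseline - 6 - design$diurnal_amp)
    } else {
      calibrate_depth(target, baseline, design$diurnal_amp, 0, hl, feeds,
                      onset = onset, factors = cal_factors)
    }
    params <- ph_model_params(baseline = baseline, dip_depth = depth,
                              dip_halflife = hl, dip_onset = onset,
                              noise_sd = design$noise_sd,
                              ar1_rho = design$ar1_rho,
                              diurnal_amp = design$diurnal_amp)
    sim <- simulate_ph_trace(params, design$days_pre, design$days_post,
                             seed = cseed + 1L, cow_id = ids[i],
                             feeding_times = design$feeding_times,
                             calving_clock = design$calving_clock,
                             prepartum_depth_factor = design$prepartum_depth_factor,
                             feed_depth_factors = ffac)
    traces[[i]] <- sim$trace
    truth_rows[[i]] <- cbind(cow_id = ids[i], sim$truth)
    cow_rows[[i]] <- data.frame(cow_id = ids[i], group = g, baseline = baseline,
                                dip_depth = depth, dip_halflife = hl,
                                target_minutes = target)
  }
  names(traces) <- ids
  # prepartum availability: drop the last `prepartum_missing[g]` cows of
  # each group (premature calvings)
  has_pre <- rep(TRUE, length(ids))
  for (g in names(design$prepartum_missing)) {
    k <- design$prepartum_missing[[g]]
    if (k > 0) {
      gi <- which(groups == g)
      has_pre[utils::tail(gi, k)] <- FALSE
    }
  }
  list(traces = traces,
       truth_labels = stats::setNames(groups, ids),
       truth_daily = do.call(rbind, truth_rows),
       cows = do.call(rbind, cow_rows),
       metadata = data.frame(cow_id = ids, group = groups,
                             has_prepartum = has_pre),
       design = design)
}
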
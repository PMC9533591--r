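# Daily pH statistics and SARA-susceptibility classification.
#
# The reticular threshold default is pH 6.0: reticular pH reads about 0.2
# units above rumen pH, so 6.0 in the reticulum corresponds to the usual
# rumen SARA threshold of ~5.8. Days are 1440-min blocks aligned to the
# calving time-of-day: postpartum day d covers [(d-1)*1440, d*1440)
# minutes after calving (d = 1..21), prepartum day -d covers
# [-d*1440, -(d-1)*1440) (d = 1..7).

day_window <- function(day_index) {
  if (day_index == 0) stop("day index 0 is undefined (days count from calving)")
  if (day_index > 0) c((day_index - 1) * 1440, day_index * 1440)
  else c(day_index * 1440, (day_index + 1) * 1440)
}

minute_to_day <- function(m) ifelse(m >= 0, floor(m / 1440) + 1, -floor(-m / 1440) - 1)

# Core per-day computation over the piecewise interpolant. Segments
# longer than max_gap contribute nothing and reduce coverage; daily
# minutes are raw (not rescaled by coverage).
day_metrics_one <- function(time_min, ph, threshold, w0, w1, max_gap,
                            interpolation) {
  keep <- time_min >= w0 - max_gap & time_min <= w1 + max_gap
  t <- time_min[keep]; p <- ph[keep]
  n <- length(t)
  if (n < 2L) {
    return(c(minutes_below = NA_real_, auc_below = NA_real_, coverage = 0))
  }
  minutes <- 0; auc <- 0; covered <- 0
  for (i in seq_len(n - 1L)) {
    t1 <- t[i]; t2 <- t[i + 1L]
    if (t2 - t1 > max_gap) next
    a <- max(t1, w0); b <- min(t2, w1)
    if (b <= a) next
    if (interpolation == "step") {
      pa <- p[i]
      covered <- covered + (b - a)
      if (pa < threshold) {
        minutes <- minutes + (b - a)
        auc <- auc + (threshold - pa) * (b - a)
      }
      next
    }
    slope <- (p[i + 1L] - p[i]) / (t2 - t1)
    pa <- p[i] + slope * (a - t1)
    pb <- p[i] + slope * (b - t1)
    covered <- covered + (b - a)
    if (pa < threshold && pb < threshold) {
      minutes <- minutes + (b - a)
      auc <- auc + ((threshold - pa) + (threshold - pb)) / 2 * (b - a)
    } else if (pa < threshold || pb < threshold) {
      tc <- a + (threshold - pa) / slope    # exact crossing of the segment
      if (pa < threshold) {
        minutes <- minutes + (tc - a)
        auc <- auc + (threshold - pa) / 2 * (tc - a)
      } else {
        minutes <- minutes + (b - tc)
        auc <- auc + (threshold - pb) / 2 * (b - tc)
      }
    }
  }
  if (covered == 0) {
    return(c(minutes_below = NA_real_, auc_below = NA_real_, coverage = 0))
  }
  c(minutes_below = minutes, auc_below = auc, coverage = covered / (w1 - w0))
}

#' Minutes per day with pH below a threshold
#'
#' Piecewise-linear interpolation between consecutive readings with
#' analytic threshold-crossing splits; inter-sample gaps longer than
#' `max_gap` minutes contribute nothing and reduce coverage. A step-wise
#' (last-observation-carried-forward) mode is available since bolus
#' studies do not always state their integration convention.
#'
#' @param trace a [ph_trace()].
#' @param threshold pH threshold (default 6.0, reticular).
#' @param day day index relative to calving (negative = prepartum; no
#'   day 0).
#' @param max_gap maximum usable inter-sample interval, minutes.
#' @param interpolation `"linear"` (default) or `"step"`.
#' @return minutes in \[0, 1440], or `NA` if the day has no coverage.
#' @export
minutes_below_threshold <- function(trace, threshold = 6, day,
                                    max_gap = 30, interpolation = c("linear", "step")) {
  interpolation <- match.arg(interpolation)
  w <- day_window(day)
  unname(day_metrics_one(trace$time_min, trace$ph, threshold, w[1], w[2],
                         max_gap, interpolation)["minutes_below"])
}

#' Daily area under the curve below a threshold
#'
#' Integral of `max(0, threshold - pH(t))` over the day (pH x min), under
#' the same interpolation and gap rules as [minutes_below_threshold()];
#' each segment uses the exact trapezoid/triangle closed form with a
#' crossing split.
#'
#' @inheritParams minutes_below_threshold
#' @return pH x min, `NA` if the day has no coverage.
#' @export
auc_below_threshold <- function(trace, threshold = 6, day,
                                max_gap = 30, interpolation = c("linear", "step")) {
  interpolation <- match.arg(interpolation)
  w <- day_window(day)
  unname(day_metrics_one(trace$time_min, trace$ph, threshold, w[1], w[2],
                         max_gap, interpolation)["auc_below"])
}

#' Compute the full daily metric table for one trace
#'
#' @inheritParams minutes_below_threshold
#' @param days integer vector of day indices; default: all days the trace
#'   spans.
#' @return data.frame with `day_index`, `minutes_below`, `auc_below`,
#'   `coverage`.
#' @export
daily_ph_metrics <- function(trace, threshold = 6, days = NULL,
                             max_gap = 30, interpolation = c("linear", "step")) {
  interpolation <- match.arg(interpolation)
  if (is.null(days)) {
    days <- setdiff(seq(minute_to_day(min(trace$time_min)),
                        minute_to_day(max(trace$time_min))), 0)
  }
  rows <- t(vapply(days, function(d) {
    w <- day_window(d)
    day_metrics_one(trace$time_min, trace$ph, threshold, w[1], w[2],
                    max_gap, interpolation)
  }, numeric(3)))
  data.frame(day_index = days,
             minutes_below = rows[, "minutes_below"],
             auc_below = rows[, "auc_below"],
             coverage = rows[, "coverage"])
}

#' Summarize a cow's daily metrics over a peripartum window
#'
#' Median and mean daily minutes below threshold, the count of days
#' exceeding 330 min/d (the usual reticular SARA-day definition), and the
#' total area under the curve. Days with coverage below `min_coverage`
#' (or missing) are excluded and counted as invalid.
#'
#' @param daily data.frame from [daily_ph_metrics()].
#' @param window `"postpartum"` (days 1..`n_days`) or `"prepartum"`
#'   (days -`n_days`..-1).
#' @param n_days window length in days (21 postpartum, 7 prepartum by
#'   convention).
#' @param min_coverage minimum daily coverage fraction to keep a day.
#' @return object of class `cow_ph_summary` (a list).
#' @export
summarize_cow <- function(daily, window = c("postpartum", "prepartum"),
                          n_days = NULL, min_coverage = 0.8) {
  window <- match.arg(window)
  if (is.null(n_days)) n_days <- if (window == "postpartum") 21L else 7L
  days <- if (window == "postpartum") seq_len(n_days) else -rev(seq_len(n_days))
  sub <- daily[daily$day_index %in% days, , drop = FALSE]
  valid <- !is.na(sub$minutes_below) & sub$coverage >= min_coverage
  if (!any(valid)) stop("no valid days in the ", window, " window")
  m <- sub$minutes_below[valid]
  structure(list(
    window = window,
    median_minutes_below = stats::median(m),
    mean_minutes_below = mean(m),
    days_over_330 = sum(m > 330),
    total_auc = sum(sub$auc_below[valid]),
    mean_daily_auc = mean(sub$auc_below[valid]),
    n_valid_days = sum(valid),
    n_days_window = n_days
  ), class = "cow_ph_summary")
}

#' @export
print.cow_ph_summary <- function(x, ...) {
  cat(sprintf("cow_ph_summary (%s): median %.1f min/d, mean %.1f min/d, %d/%d valid days\n",
              x$window, x$median_minutes_below, x$mean_minutes_below,
              x$n_valid_days, x$n_days_window))
  invisible(x)
}

# distance from (mean, median) to each rule's region, for the fallback
sara_rule_distance <- function(mean, med) {
  rect <- function(x, y, xlo, xhi, ylo, yhi) {
    dx <- max(xlo - x, 0, x - xhi)
    dy <- max(ylo - y, 0, y - yhi)
    sqrt(dx^2 + dy^2)
  }
  c(SU = min(max(180 - mean, 0), max(180 - med, 0)),
    MS = rect(mean, med, 60, 180, 0, 180),
    MU = rect(mean, med, 10, 60, 0, 30),
    UN = sqrt(med^2 + max(mean - 10, 0)^2))
}

#' Classify a cow into a SARA susceptibility group
#'
#' Four-rule classification on the postpartum summary, evaluated in the
#' order SU, UN, MU, MS:
#' \itemize{
#'   \item SU (susceptible): mean >= 180 min/d or median >= 180 min/d;
#'   \item UN (unsusceptible): median == 0 and mean < 10;
#'   \item MU (moderately unsusceptible): 10 < mean < 60 and median <= 30;
#'   \item MS (moderately susceptible): 60 < mean < 180 and median < 180.
#' }
#' A summary matching no rule (the boxes do not tile the plane, e.g.
#' median > 0 with mean < 10) is assigned the label whose region is
#' nearest in (mean, median) space and flagged unclassifiable.
#'
#' @param summary a postpartum [summarize_cow()] result.
#' @return list with `label` (`"SU"/"MS"/"MU"/"UN"`), `rule_matched`,
#'   `flag_unclassifiable`.
#' @export
classify_sara <- function(summary) {
  if (!inherits(summary, "cow_ph_summary")) stop("need a cow_ph_summary")
  if (summary$window != "postpartum") {
    stop("SARA grouping is defined on the postpartum window only")
  }
  mean_m <- summary$mean_minutes_below
  med_m <- summary$median_minutes_below
  res <- if (mean_m >= 180 || med_m >= 180) {
    list(label = "SU", rule = "mean>=180 or median>=180")
  } else if (med_m == 0 && mean_m < 10) {
    list(label = "UN", rule = "median==0 and mean<10")
  } else if (mean_m > 10 && mean_m < 60 && med_m <= 30) {
    list(label = "MU", rule = "10<mean<60 and median<=30")
  } else if (mean_m > 60 && mean_m < 180 && med_m < 180) {
    list(label = "MS", rule = "60<mean<180 and median<180")
  } else NULL
  if (is.null(res)) {
    d <- sara_rule_distance(mean_m, med_m)
    lab <- names(d)[which.min(d)]
    return(list(label = lab,
                rule_matched = sprintf("fallback: nearest rule region (%s)", lab),
                flag_unclassifiable = TRUE))
  }
  list(label = res$label, rule_matched = res$rule, flag_unclassifiable = FALSE)
}

#' Merge moderate groups for prepartum analysis
#'
#' Prepartum sample sizes are reduced by premature calvings, so the two
#' moderate groups are pooled: MS and MU become MO; SU and UN are
#' unchanged.
#'
#' @param labels character vector of postpartum labels.
#' @return character vector with MS/MU replaced by MO.
#' @export
merge_prepartum_groups <- function(labels) {
  out <- as.character(labels)
  out[out %in% c("MS", "MU")] <- "MO"
  out
}

#' Run the trace-to-group chain for a set of cows
#'
#' Convenience wrapper: daily metrics, postpartum summary and SARA label
#' per cow, as one data.frame (the `sara classify` output layout).
#'
#' @param traces named list of [ph_trace()] objects.
#' @param threshold pH threshold.
#' @param n_days postpartum window length in days.
#' @param ... passed to [daily_ph_metrics()] / [summarize_cow()].
#' @return data.frame, one row per cow: summary statistics, label, rule,
#'   flag.
#' @export
classify_cohort <- function(traces, threshold = 6, n_days = 21L, ...) {
  rows <- lapply(traces, function(tr) {
    daily <- daily_ph_metrics(tr, threshold = threshold, ...)
    s <- summarize_cow(daily, "postpartum", n_days = n_days)
    cl <- classify_sara(s)
    data.frame(cow_id = tr$cow_id,
               median_minutes_below = s$median_minutes_below,
               mean_minutes_below = s$mean_minutes_below,
               days_over_330 = s$days_over_330,
               total_auc = s$total_auc,
               n_valid_days = s$n_valid_days,
               label = cl$label,
               rule_matched = cl$rule_matched,
               flag_unclassifiable = cl$flag_unclassifiable)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
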
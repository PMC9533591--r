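# Group-comparison dispatch for scalar phenotypes, and the assay
# quantification arithmetic (GC internal-standard conversion, qPCR
# absolute quantification from external standard curves).

#' Normality-dispatched group comparison
#'
#' Shapiro-Wilk on the one-way model residuals and Levene's test across
#' groups decide the path: if both pass at `alpha_normality`, one-way
#' ANOVA with Tukey HSD letters; otherwise Kruskal-Wallis with pairwise
#' Wilcoxon rank-sum letters. Significance is declared at p < 0.05 and a
#' trend at 0.05 <= p < 0.10. Group means with per-group SEM and the
#' pooled residual SEM are reported.
#'
#' @param values numeric response, one per sample.
#' @param labels group labels (>= 2 groups, each n >= 3).
#' @param variable name recorded in the result.
#' @param alpha_normality level for the Shapiro-Wilk/Levene checks.
#' @param alpha significance level for letters.
#' @return object of class `stat_test_result`: test used, omnibus
#'   statistic and p, normality/homoscedasticity p-values, per-group
#'   means/SEM, pooled SEM, letters, and the significance call.
#' @export
dispatch_test <- function(values, labels, variable = "value",
                          alpha_normality = 0.05, alpha = 0.05) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  ok <- !is.na(values)
  values <- values[ok]; labels <- labels[ok]
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 3L)) {
    stop("group(s) with n < 3: ", paste(names(sizes)[sizes < 3], collapse = ", "))
  }
  if (stats::sd(values) == 0) stop("constant variable: ", variable)
  f <- factor(labels)
  fit <- stats::aov(values ~ f)
  sw_p <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                   error = function(e) 0)
  lev_p <- car::leveneTest(values ~ f)[1, "Pr(>F)"]
  gs <- levels(f)
  means <- tapply(values, f, mean)
  sems <- tapply(values, f, function(x) stats::sd(x) / sqrt(length(x)))
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  pooled_sem <- sqrt(mse * mean(1 / sizes[gs]))
  if (sw_p > alpha_normality && lev_p > alpha_normality) {
    test_used <- "ANOVA+Tukey"
    atab <- stats::anova(fit)
    statistic <- atab[["F value"]][1]
    p <- atab[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$f
    pm <- matrix(NA_real_, length(gs), length(gs), dimnames = list(gs, gs))
    for (r in rownames(tk)) {
      pair <- strsplit(r, "-", fixed = TRUE)[[1]]
      pm[pair[1], pair[2]] <- pm[pair[2], pair[1]] <- tk[r, "p adj"]
    }
  } else {
    test_used <- "KW+pairwise-Wilcoxon"
    kw <- stats::kruskal.test(values, f)
    statistic <- unname(kw$statistic)
    p <- kw$p.value
    pm <- matrix(NA_real_, length(gs), length(gs), dimnames = list(gs, gs))
    for (a in seq_along(gs)[-length(gs)]) {
      for (b in (a + 1):length(gs)) {
        pw <- suppressWarnings(
          stats::wilcox.test(values[labels == gs[a]], values[labels == gs[b]],
                             exact = FALSE)$p.value)
        pm[gs[a], gs[b]] <- pm[gs[b], gs[a]] <- pw
      }
    }
  }
  ord <- names(sort(means, decreasing = TRUE))
  lets <- compact_letters(ord, pm, alpha)
  call <- if (p < 0.05) "significant" else if (p < 0.10) "trend" else "ns"
  structure(list(variable = variable, test_used = test_used,
                 statistic = statistic, p_value = p,
                 shapiro_p = sw_p, levene_p = lev_p,
                 group_means = means, group_sem = sems,
                 pooled_sem = pooled_sem,
                 letters = lets[gs], pairwise_p = pm,
                 call = call),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("%s [%s]: stat = %.3f, p = %.4g (%s)\n", x$variable,
              x$test_used, x$statistic, x$p_value, x$call))
  df <- data.frame(mean = round(x$group_means, 4),
                   sem = round(x$group_sem, 4), letter = x$letters)
  print(df)
  invisible(x)
}

#' Group comparisons for a table of phenotypes
#'
#' Runs [dispatch_test()] on every numeric column of `table`, mirroring
#' the group-means / SEM / P layout of phenotype summary tables.
#'
#' @param table data.frame of per-sample phenotype values.
#' @param labels group labels, one per row of `table`.
#' @param variables columns to test (default: all numeric columns).
#' @return data.frame, one row per variable: test, statistic, p, call,
#'   pooled SEM and per-group `mean (letter)` columns.
#' @export
cohort_stat_table <- function(table, labels, variables = NULL) {
  if (is.null(variables)) {
    variables <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  rows <- lapply(variables, function(v) {
    r <- dispatch_test(table[[v]], labels, variable = v)
    out <- data.frame(variable = v, test = r$test_used,
                      statistic = r$statistic, p_value = r$p_value,
                      call = r$call, pooled_sem = r$pooled_sem)
    for (g in names(r$group_means)) {
      out[[g]] <- sprintf("%.4g%s", r$group_means[[g]],
                          ifelse(r$letters[[g]] == "", "",
                                 paste0(" (", r$letters[[g]], ")")))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quantify fatty acids from GC peak areas
#'
#' Internal-standard quantification:
#' `mass_i = (area_i / is_area) * is_mass * rf_i` (mg in the analyzed
#' aliquot), normalized to mg per 100 g dry feces. Doubling all areas
#' including the internal standard leaves results unchanged. Summary
#' groups (total odd-chain, iso-, anteiso-, total/odd/even BCFA) are
#' appended when the analyte names allow it.
#'
#' @param areas named numeric vector of analyte peak areas (one sample).
#' @param is_area internal-standard peak area (> 0).
#' @param is_mass internal-standard mass, mg.
#' @param response_factors named theoretical response factors; every
#'   analyte must be present.
#' @param sample_dry_mass dry feces analyzed, g (> 0).
#' @return named numeric vector: mg analyte per 100 g dry feces, with
#'   summary-group entries appended.
#' @export
quantify_fatty_acids <- function(areas, is_area, is_mass, response_factors,
                                 sample_dry_mass) {
  stopifnot(is_area > 0, sample_dry_mass > 0)
  missing_rf <- setdiff(names(areas), names(response_factors))
  if (length(missing_rf)) {
    stop("missing response factor for analyte(s): ",
         paste(missing_rf, collapse = ", "))
  }
  if (any(areas < 0)) stop("negative peak area")
  mass <- areas / is_area * is_mass * response_factors[names(areas)]
  conc <- mass / sample_dry_mass * 100
  nm <- names(conc)
  iso <- grepl("^iso-", nm)
  anteiso <- grepl("^anteiso-", nm)
  odd_linear <- nm %in% c("C15:0", "C17:0")
  # odd/even refers to the total carbon number of the branched chain
  carbon <- suppressWarnings(as.integer(sub("^(iso|anteiso)-C(\\d+).*", "\\2", nm)))
  odd_bcfa <- (iso | anteiso) & !is.na(carbon) & carbon %% 2 == 1
  even_bcfa <- (iso | anteiso) & !is.na(carbon) & carbon %% 2 == 0
  summaries <- c(total_odd_chain_fa = sum(conc[odd_linear]),
                 total_bcfa = sum(conc[iso | anteiso]),
                 total_iso_bcfa = sum(conc[iso]),
                 total_anteiso_bcfa = sum(conc[anteiso]),
                 total_odd_bcfa = sum(conc[odd_bcfa]),
                 total_even_bcfa = sum(conc[even_bcfa]))
  c(conc, summaries)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10 copies over the run's external
#' standards; amplification efficiency `10^(-1/slope) - 1` is derived.
#'
#' @param log10_copies log10 copies of the standards (>= 3 points).
#' @param cq measured Cq values, in (0, 45).
#' @return object of class `standard_curve`: `slope` (< 0),
#'   `intercept`, `efficiency`, `r_squared`, `range` (of log10 copies).
#' @export
fit_standard_curve <- function(log10_copies, cq) {
  stopifnot(length(log10_copies) == length(cq))
  if (length(cq) < 3L) stop("standard curve needs at least 3 points")
  if (any(cq <= 0 | cq >= 45)) stop("Cq outside (0, 45)")
  fit <- stats::lm(cq ~ log10_copies)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("standard-curve slope must be negative")
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((cq - mean(cq))^2)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = r2,
                 range = range(log10_copies)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: Cq = %.3f %+.4f * log10(copies), eff = %.1f%%, R2 = %.4f\n",
              x$intercept, x$slope, 100 * x$efficiency, x$r_squared))
  invisible(x)
}

#' Absolute quantification of gene copies from Cq
#'
#' `log10(copies) = (cq - intercept) / slope`, scaled by the dilution
#' and volume factors to gene copies per mL of sample. Cq values outside
#' the standard range are flagged with an extrapolation warning.
#'
#' @param cq measured Cq value(s).
#' @param curve a [fit_standard_curve()] result.
#' @param dilution fold-dilution of the template.
#' @param volume_factor reaction-volume to per-mL conversion factor.
#' @return numeric copies/mL (vectorized over `cq`).
#' @export
qpcr_copies <- function(cq, curve, dilution = 1, volume_factor = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  l10 <- (cq - curve$intercept) / curve$slope
  outside <- l10 < curve$range[1] | l10 > curve$range[2]
  if (any(outside)) {
    warning(sum(outside), " Cq value(s) outside the standard range; ",
            "copies extrapolated")
  }
  10^l10 * dilution * volume_factor
}

#' Quantify a simulated assay table
#'
#' Applies [fit_standard_curve()]/[qpcr_copies()] per qPCR target and
#' [quantify_fatty_acids()] per GC sample to an [simulate_assays()]
#' output, returning tidy per-sample tables (the inverse of the
#' generator in noise-free mode).
#'
#' @param assays an `assay_table` from [simulate_assays()].
#' @return list: `qpcr` (sample, target, copies/mL), `fatty_acids`
#'   (sample, analyte, mg/100 g dry feces).
#' @export
quantify_assays <- function(assays) {
  stopifnot(inherits(assays, "assay_table"))
  curves <- lapply(split(assays$standards, assays$standards$target), function(s) {
    fit_standard_curve(s$log10_copies, s$cq)
  })
  q <- assays$qpcr
  q$copies_per_ml <- NA_real_
  for (tg in names(curves)) {
    sel <- q$target == tg
    q$copies_per_ml[sel] <- suppressWarnings(
      qpcr_copies(q$cq[sel], curves[[tg]]))
  }
  fa <- do.call(rbind, lapply(split(assays$gc, assays$gc$sample_id), function(g) {
    conc <- quantify_fatty_acids(stats::setNames(g$area, g$analyte),
                                 assays$is_area, assays$is_mass,
                                 assays$response_factors,
                                 assays$sample_dry_mass)
    data.frame(sample_id = g$sample_id[1], cow_id = g$cow_id[1],
               period = g$period[1], group = g$group[1],
               analyte = names(conc), mg_per_100g = unname(conc))
  }))
  rownames(fa) <- NULL
  list(qpcr = q[, c("sample_id", "cow_id", "period", "group", "target",
                    "cq", "copies_per_ml")],
       fatty_acids = fa, curves = curves)
}
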
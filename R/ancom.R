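# ANCOM differential abundance with BH control, plus post-hoc Wilcoxon
# letters on detected taxa.
#
# ANCOM works on additive log-ratios: for every ordered taxon pair
# (i, j) the equality across groups of log(x_i + c) - log(x_j + c) is
# tested (Kruskal-Wallis by default). Each taxon's W statistic counts,
# among its m - 1 ratio tests, how many reject after Benjamini-Hochberg
# adjustment within that taxon's family; a taxon is called
# differentially abundant when W reaches a fraction of m - 1 (0.7 by
# default). A global-BH mode (one family over all m(m-1)/2 p-values) is
# provided since "BH at the 5% level" is ambiguous between the two
# readings.

#' ANCOM test for differential abundance
#'
#' @param ft a [feature_table()] collapsed to one rank (or a plain
#'   counts matrix, taxa x samples).
#' @param labels group label per sample (named by sample id, or in
#'   column order); at least 2 groups with >= 2 samples each.
#' @param alpha per-ratio significance level after BH adjustment.
#' @param w_cutoff_frac detection threshold as a fraction of `m - 1`.
#' @param pseudocount added to every count before the log (zero
#'   replacement).
#' @param test per-ratio test: `"kruskal"` (default) or `"anova"`.
#' @param bh_scope `"per_taxon"` (BH within each taxon's m - 1 tests,
#'   default) or `"global"` (one BH family over all pairs).
#' @return object of class `ancom_result`: data.frame with `taxon`, `W`,
#'   `detected`, and mean relative abundance (%) per group; attributes
#'   carry the cutoff and settings.
#' @export
ancom <- function(ft, labels, alpha = 0.05, w_cutoff_frac = 0.7,
                  pseudocount = 1, test = c("kruskal", "anova"),
                  bh_scope = c("per_taxon", "global")) {
  test <- match.arg(test)
  bh_scope <- match.arg(bh_scope)
  counts <- if (inherits(ft, "feature_table")) ft$counts else as.matrix(ft)
  m <- nrow(counts)
  if (m < 3L) stop("ANCOM needs at least 3 taxa (W is degenerate otherwise)")
  if (!is.null(names(labels)) && !is.null(colnames(counts))) {
    labels <- labels[colnames(counts)]
  }
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(counts))
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  idx <- group_indices(labels)
  logc <- log(counts + pseudocount)
  glab <- match(labels, names(idx))
  pmat <- matrix(NA_real_, m, m)
  for (i in seq_len(m - 1L)) {
    li <- logc[i, ]
    for (j in (i + 1L):m) {
      y <- li - logc[j, ]
      p <- if (test == "kruskal") {
        kw_pvalue(y, idx)
      } else {
        stats::anova(stats::lm(y ~ factor(glab)))[["Pr(>F)"]][1]
      }
      pmat[i, j] <- pmat[j, i] <- p
    }
  }
  if (bh_scope == "per_taxon") {
    adj <- t(apply(pmat, 1, function(p) {
      out <- rep(NA_real_, length(p))
      out[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], "BH")
      out
    }))
  } else {
    ut <- upper.tri(pmat)
    adj <- pmat
    adj[ut] <- stats::p.adjust(pmat[ut], "BH")
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  }
  W <- rowSums(adj < alpha, na.rm = TRUE)
  cutoff <- w_cutoff_frac * (m - 1)
  rel <- sweep(counts, 2, colSums(counts), "/") * 100
  means <- t(vapply(idx, function(g) rowMeans(rel[, g, drop = FALSE]),
                    numeric(m)))
  res <- data.frame(taxon = rownames(counts), W = as.integer(W),
                    detected = W >= cutoff, row.names = NULL)
  for (g in rownames(means)) res[[paste0("mean_pct_", g)]] <- means[g, ]
  structure(res, class = c("ancom_result", "data.frame"),
            cutoff = cutoff, alpha = alpha, test = test,
            bh_scope = bh_scope, pseudocount = pseudocount,
            p_adjusted = adj)
}

#' Post-hoc pairwise Wilcoxon letters for detected taxa
#'
#' For each supplied taxon passing the mean-relative-abundance filter,
#' all group pairs are compared with two-sided Wilcoxon rank-sum tests
#' on relative abundances, and a compact letter display is assembled
#' from the pairwise significance graph (deterministic; groups ordered
#' by descending mean).
#'
#' @param ft counts ([feature_table()] or matrix) at the tested rank.
#' @param labels group label per sample.
#' @param taxa taxa to test (typically the ANCOM-detected set).
#' @param min_rel_abund minimum overall mean relative abundance
#'   (fraction; 1e-4 = 0.01%); taxa below it are excluded with a
#'   warning.
#' @param alpha significance level for the letters.
#' @param p_adjust_method adjustment across the pairwise family of one
#'   taxon (`"none"` by default, matching pairwise rank-sum reporting).
#' @return data.frame: one row per taxon x group with mean (%), letter,
#'   plus an attribute `pairwise` holding the p-value matrices.
#' @export
posthoc_wilcoxon <- function(ft, labels, taxa, min_rel_abund = 1e-4,
                             alpha = 0.05, p_adjust_method = "none") {
  counts <- if (inherits(ft, "feature_table")) ft$counts else as.matrix(ft)
  if (!is.null(names(labels)) && !is.null(colnames(counts))) {
    labels <- labels[colnames(counts)]
  }
  labels <- as.character(labels)
  rel <- sweep(counts, 2, colSums(counts), "/")
  overall <- rowMeans(rel)
  taxa <- as.character(taxa)
  low <- taxa[overall[taxa] < min_rel_abund]
  if (length(low)) {
    warning("taxa below the ", min_rel_abund * 100,
            "% relative-abundance filter excluded: ",
            paste(low, collapse = ", "))
  }
  taxa <- setdiff(taxa, low)
  gs <- sort(unique(labels))
  pair_list <- list()
  rows <- list()
  for (tx in taxa) {
    y <- rel[tx, ]
    pm <- matrix(NA_real_, length(gs), length(gs), dimnames = list(gs, gs))
    for (a in seq_along(gs)[-length(gs)]) {
      for (b in (a + 1):length(gs)) {
        p <- suppressWarnings(
          stats::wilcox.test(y[labels == gs[a]], y[labels == gs[b]],
                             exact = FALSE)$p.value)
        pm[gs[a], gs[b]] <- pm[gs[b], gs[a]] <- p
      }
    }
    if (p_adjust_method != "none") {
      ut <- upper.tri(pm)
      pm[ut] <- stats::p.adjust(pm[ut], p_adjust_method)
      pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
    }
    means <- vapply(gs, function(g) mean(y[labels == g]) * 100, numeric(1))
    ord <- names(sort(means, decreasing = TRUE))
    lets <- compact_letters(ord, pm, alpha)
    rows[[tx]] <- data.frame(taxon = tx, group = gs,
                             mean_pct = unname(means[gs]),
                             letter = unname(lets[gs]))
    pair_list[[tx]] <- pm
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, pairwise = pair_list, alpha = alpha)
}
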
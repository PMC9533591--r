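# Feature-table processing and community ecology: filtering,
# rarefaction, taxonomic collapse, alpha diversity, Bray-Curtis, PCoA,
# PERMANOVA, hierarchical clustering and within-cow pre/post similarity.

#' Remove low-abundance features
#'
#' Drops features whose global relative frequency (total count over the
#' grand total) is strictly below `min_global_freq` or that occur in
#' fewer than `min_prevalence` samples. The defaults match the usual
#' amplicon filter (frequency < 0.01% or present in < 2 samples). The
#' sample set is unchanged.
#'
#' @param ft a [feature_table()].
#' @param min_global_freq minimum global relative frequency (strict `<`
#'   removal, so a feature at exactly the cut-off is retained).
#' @param min_prevalence minimum number of samples with a non-zero
#'   count.
#' @return filtered [feature_table()].
#' @export
filter_low_abundance <- function(ft, min_global_freq = 1e-4, min_prevalence = 2L) {
  total <- sum(ft$counts)
  if (total == 0) stop("feature table grand total is zero")
  freq <- rowSums(ft$counts) / total
  prev <- rowSums(ft$counts > 0)
  keep <- !(freq < min_global_freq | prev < min_prevalence)
  out <- ft
  out$counts <- ft$counts[keep, , drop = FALSE]
  out$taxonomy <- ft$taxonomy[keep, , drop = FALSE]
  out
}

#' Rarefy samples to an even depth
#'
#' Each retained sample is subsampled without replacement to exactly
#' `depth` reads; samples with fewer reads than `depth` are dropped with
#' a warning. The default depth is the rarefaction cut-off used for the
#' fecal ASV tables this package emulates (33,787 reads).
#'
#' @param ft a [feature_table()].
#' @param depth target reads per sample.
#' @param seed integer seed (subsampling is reproducible under it).
#' @return rarefied [feature_table()]; every column sums to `depth`.
#' @export
rarefy <- function(ft, depth = 33787L, seed = 1L) {
  stopifnot(depth >= 1)
  totals <- colSums(ft$counts)
  drop <- totals < depth
  if (all(drop)) stop("no sample reaches the rarefaction depth")
  if (any(drop)) {
    warning("dropped ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(colnames(ft$counts)[drop], collapse = ", "))
  }
  keep <- which(!drop)
  set.seed(seed)
  m <- nrow(ft$counts)
  new_counts <- vapply(keep, function(j) {
    x <- ft$counts[, j]
    if (sum(x) == depth) return(x)
    reads <- rep.int(seq_len(m), x)
    tabulate(reads[sample.int(length(reads), depth)], m)
  }, numeric(m))
  dimnames(new_counts) <- list(rownames(ft$counts), colnames(ft$counts)[keep])
  out <- ft
  out$counts <- new_counts
  out$sample_meta <- ft$sample_meta[keep, , drop = FALSE]
  rownames(out$sample_meta) <- NULL
  out
}

#' Collapse a feature table to a taxonomic rank
#'
#' Counts are summed over features sharing the lineage prefix through
#' `rank`; features with an empty value at that rank are pooled into
#' `unassigned_<parent>` where parent is the deepest filled higher rank.
#' The grand total is invariant.
#'
#' @param ft a [feature_table()].
#' @param rank one of `"phylum"`, `"family"`, `"genus"` (any of the 7
#'   ranks is accepted).
#' @return collapsed [feature_table()]; row names are the rank labels,
#'   taxonomy keeps the ranks down to `rank`.
#' @export
collapse_rank <- function(ft, rank = c("genus", "family", "phylum",
                                       "domain", "class", "order", "species")) {
  rank <- match.arg(rank)
  ri <- match(rank, TAX_RANKS)
  lab <- ft$taxonomy[, rank]
  empty <- lab == ""
  if (any(empty)) {
    parent <- apply(ft$taxonomy[empty, seq_len(ri - 1), drop = FALSE], 1,
                    function(r) {
                      filled <- which(r != "")
                      if (length(filled)) r[max(filled)] else "root"
                    })
    lab[empty] <- paste0("unassigned_", parent)
  }
  # group by the full lineage prefix so homonym genera in different
  # families stay separate
  key <- apply(cbind(ft$taxonomy[, seq_len(ri), drop = FALSE]), 1,
               paste, collapse = "|")
  key[empty] <- paste0("zz|", lab[empty])
  uk <- unique(key)
  counts <- rowsum(ft$counts, group = key, reorder = FALSE)
  newlab <- lab[match(rownames(counts), key)]
  # disambiguate duplicated display labels by their lineage key
  dup <- duplicated(newlab) | duplicated(newlab, fromLast = TRUE)
  newlab[dup] <- make.unique(newlab, sep = "#")[dup]
  tax <- matrix("", nrow(counts), 7, dimnames = list(newlab, TAX_RANKS))
  src <- match(rownames(counts), key)
  tax[, seq_len(ri)] <- ft$taxonomy[src, seq_len(ri)]
  rownames(counts) <- newlab
  out <- ft
  out$counts <- counts
  out$taxonomy <- tax
  out
}

#' Per-sample alpha diversity
#'
#' Observed features, Shannon entropy in bits (log base 2, the QIIME
#' convention), Pielou evenness `H / log2(observed)` (reported missing
#' for single-feature samples) and, when a tree is supplied, Faith's
#' phylogenetic diversity (sum of branch lengths on the union of
#' root-to-tip paths of the observed features, root path included).
#'
#' @param ft a [feature_table()] (rarefied; a warning is issued if
#'   sample totals are unequal).
#' @param tree optional rooted `ape::phylo` covering every feature.
#' @return data.frame: `sample_id`, `observed_features`, `shannon`,
#'   `pielou`, and `faith_pd` when a tree is given.
#' @export
alpha_diversity <- function(ft, tree = NULL) {
  totals <- colSums(ft$counts)
  if (length(unique(totals)) > 1L) {
    warning("sample totals are unequal; rarefy before comparing alpha diversity")
  }
  obs <- colSums(ft$counts > 0)
  shannon <- apply(ft$counts, 2, function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log2(p))
  })
  pielou <- ifelse(obs > 1, shannon / log2(obs), NA_real_)
  out <- data.frame(sample_id = colnames(ft$counts),
                    observed_features = as.integer(obs),
                    shannon = shannon, pielou = pielou,
                    row.names = NULL)
  if (!is.null(tree)) {
    out$faith_pd <- faith_pd(ft$counts, tree)
  }
  out
}

# Faith's PD for every sample at once: an edge contributes its length to
# a sample iff its subtended clade contains at least one observed tip;
# the path to the root is therefore included.
faith_pd <- function(counts, tree) {
  missing <- setdiff(rownames(counts), tree$tip.label)
  if (length(missing)) {
    stop("feature(s) absent from tree: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # presence matrix: node x sample, filled tips-first then postorder OR;
  # tree tips not in the table (e.g. filtered features) count as absent
  pres <- matrix(FALSE, nnode, ncol(counts))
  hit <- match(tree$tip.label, rownames(counts))
  pres[which(!is.na(hit)), ] <- counts[hit[!is.na(hit)], , drop = FALSE] > 0
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    par <- eo$edge[k, 1]; child <- eo$edge[k, 2]
    pres[par, ] <- pres[par, ] | pres[child, ]
  }
  pd <- numeric(ncol(counts))
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    pd <- pd + tree$edge.length[k] * pres[child, ]
  }
  pd
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(u, v) = sum |u_i - v_i| / sum (u_i + v_i)` on counts, computed on
#' the rarefied table (at equal depths this equals the
#' proportion-based form).
#'
#' @param ft a [feature_table()] with at least 2 samples.
#' @return symmetric matrix with zero diagonal, entries in \[0, 1],
#'   dimnames = sample ids.
#' @export
bray_curtis <- function(ft) {
  if (ncol(ft$counts) < 2L) stop("need at least 2 samples")
  totals <- colSums(ft$counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total: ",
         paste(colnames(ft$counts)[totals == 0], collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(t(ft$counts), method = "bray"))
  diag(d) <- 0
  d
}

#' Principal-coordinate analysis (classical MDS)
#'
#' Classical scaling of the double-centred `-1/2 d^2` matrix. Negative
#' eigenvalues (Bray-Curtis is non-Euclidean) are dropped from the
#' variance-explained denominator, with a message.
#'
#' @param dm symmetric dissimilarity matrix (n >= 3).
#' @param k number of axes to retain.
#' @return list: `coordinates` (n x k), `eigenvalues`,
#'   `proportion_explained` (non-increasing over retained axes).
#' @export
pcoa <- function(dm, k = 2L) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("PCoA needs at least 3 samples")
  k <- min(k, n - 1L)
  fit <- stats::cmdscale(stats::as.dist(dm), k = k, eig = TRUE)
  eig <- fit$eig
  neg <- sum(eig < 0)
  if (neg > 0) {
    message("PCoA: dropped ", neg,
            " negative eigenvalue(s) from the variance-explained denominator")
  }
  pos <- eig[eig > 1e-12]
  prop <- eig[seq_len(k)] / sum(pos)
  coords <- fit$points
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = prop)
}

# pseudo-F for a given grouping over a squared-distance matrix
permanova_F <- function(d2, idx, n, a) {
  sst <- sum(d2) / (2 * n)              # d2 is the full symmetric matrix
  ssw <- 0
  for (g in idx) {
    ssw <- ssw + sum(d2[g, g]) / (2 * length(g))
  }
  ssa <- sst - ssw
  (ssa / (a - 1)) / (ssw / (n - a))
}

#' PERMANOVA on a dissimilarity matrix
#'
#' One-factor permutational multivariate ANOVA (Anderson's pseudo-F from
#' among/within sums of squared dissimilarities), with label permutation
#' only. `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`; with
#' `permutations = "exhaustive"` every distinct label arrangement is
#' enumerated (feasible for small n) and p is the exact proportion.
#'
#' @param dm symmetric dissimilarity matrix with sample-id dimnames.
#' @param labels group labels (named, or in `dm` order); at least 2
#'   groups with at least 2 samples each.
#' @param n_permutations number of random permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param permutations `"random"` or `"exhaustive"`.
#' @return list of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `seed`, `ss_among`, `ss_within`, `df`.
#' @export
permanova <- function(dm, labels, n_permutations = 999L, seed = 1L,
                      permutations = c("random", "exhaustive")) {
  permutations <- match.arg(permutations)
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (!is.null(names(labels)) && !is.null(rownames(dm))) {
    labels <- labels[rownames(dm)]
  }
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) {
    stop("group(s) with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  a <- length(sizes)
  d2 <- dm^2
  idx <- group_indices(labels)
  f_obs <- permanova_F(d2, idx, n, a)
  sst <- sum(d2) / (2 * n)
  ssw <- sum(vapply(idx, function(g) sum(d2[g, g]) / (2 * length(g)), 0))
  if (permutations == "exhaustive") {
    perms <- all_label_arrangements(labels)
    f_all <- vapply(perms, function(lb) {
      permanova_F(d2, group_indices(lb), n, a)
    }, numeric(1))
    p <- mean(f_all >= f_obs - 1e-12)
    n_used <- length(perms)
  } else {
    set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_permutations)) {
      lb <- labels[sample.int(n)]
      if (permanova_F(d2, group_indices(lb), n, a) >= f_obs - 1e-12) ge <- ge + 1L
    }
    p <- (1 + ge) / (1 + n_permutations)
    n_used <- n_permutations
  }
  structure(list(pseudo_F = f_obs, p_value = p, n_permutations = n_used,
                 seed = seed, ss_among = sst - ssw, ss_within = ssw,
                 df = c(among = a - 1L, within = n - a)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f (df %d, %d), p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$p_value, x$n_permutations))
  invisible(x)
}

# enumerate all distinct arrangements of a label multiset (small n only)
all_label_arrangements <- function(labels) {
  n <- length(labels)
  if (n > 10L) stop("exhaustive enumeration limited to n <= 10")
  perms <- list(integer(0))
  for (i in seq_len(n)) {
    perms <- unlist(lapply(perms, function(p) {
      rest <- setdiff(seq_len(n), p)
      lapply(rest, function(r) c(p, r))
    }), recursive = FALSE)
  }
  arr <- unique(lapply(perms, function(p) labels[p]))
  arr
}

#' Pairwise PERMANOVA between all group pairs
#'
#' Runs [permanova()] on every pair of groups (the study-style pairwise
#' mode, complementing the omnibus test).
#'
#' @inheritParams permanova
#' @return data.frame: `group1`, `group2`, `pseudo_F`, `p_value`.
#' @export
pairwise_permanova <- function(dm, labels, n_permutations = 999L, seed = 1L) {
  dm <- as.matrix(dm)
  if (!is.null(names(labels)) && !is.null(rownames(dm))) labels <- labels[rownames(dm)]
  labels <- as.character(labels)
  gs <- sort(unique(labels))
  pairs <- utils::combn(gs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    sel <- labels %in% c(g1, g2)
    r <- permanova(dm[sel, sel], labels[sel], n_permutations,
                   seed = seed + k)
    data.frame(group1 = g1, group2 = g2, pseudo_F = r$pseudo_F,
               p_value = r$p_value)
  })
  do.call(rbind, rows)
}

#' Agglomerative hierarchical clustering of samples
#'
#' Clusters the dissimilarity matrix ([stats::hclust]) and cuts the tree
#' at `k` clusters. When group labels are supplied, the cluster x group
#' contingency and its composition percentages are reported (the
#' prepartum-clustering readout).
#'
#' @param dm symmetric dissimilarity matrix.
#' @param linkage `"complete"` (default), `"average"` or `"ward.D2"`.
#' @param k number of clusters to cut.
#' @param groups optional named group labels for the contingency table.
#' @return list: `clusters` (named integer), `tree` (hclust), and when
#'   groups are given `contingency` plus `composition_pct` (percent of
#'   each cluster made up by each group) and `group_capture_pct`
#'   (percent of each group captured by each cluster).
#' @export
hierarchical_cluster <- function(dm, linkage = c("complete", "average", "ward.D2"),
                                 k = 2L, groups = NULL) {
  linkage <- match.arg(linkage)
  dm <- as.matrix(dm)
  ord <- order(rownames(dm))          # lexicographic id order: deterministic ties
  dm <- dm[ord, ord]
  hc <- stats::hclust(stats::as.dist(dm), method = linkage)
  cl <- stats::cutree(hc, k = k)
  out <- list(clusters = cl, tree = hc)
  if (!is.null(groups)) {
    g <- groups[names(cl)]
    tab <- table(cluster = cl, group = g)
    out$contingency <- tab
    out$composition_pct <- round(100 * prop.table(tab, 1), 1)
    out$group_capture_pct <- round(100 * prop.table(tab, 2), 1)
  }
  out
}

#' Within-cow prepartum-to-postpartum Bray-Curtis distance
#'
#' For each cow with exactly one prepartum and one postpartum sample,
#' the Bray-Curtis distance between the two; cows missing a period are
#' excluded with a warning. When at least two groups have >= 3 cows the
#' distances are compared across groups via [dispatch_test()].
#'
#' @param ft a rarefied [feature_table()] with both periods.
#' @param merge_moderate merge MS/MU into MO before comparing (the
#'   prepartum grouping convention).
#' @return list: `distances` (data.frame cow, group, distance) and
#'   `comparison` (a [dispatch_test()] result, or `NULL` if group sizes
#'   do not allow it).
#' @export
paired_prepost_distance <- function(ft, merge_moderate = TRUE) {
  meta <- ft$sample_meta
  cows <- unique(meta$cow_id)
  rows <- list()
  skipped <- character(0)
  for (cw in cows) {
    pre <- meta$sample_id[meta$cow_id == cw & meta$period == "prepartum"]
    post <- meta$sample_id[meta$cow_id == cw & meta$period == "postpartum"]
    if (length(pre) != 1L || length(post) != 1L) {
      skipped <- c(skipped, cw)
      next
    }
    u <- ft$counts[, pre]; v <- ft$counts[, post]
    d <- sum(abs(u - v)) / sum(u + v)
    rows[[cw]] <- data.frame(cow_id = cw,
                             group = meta$group[meta$cow_id == cw][1],
                             distance = d)
  }
  if (length(skipped)) {
    warning("excluded cow(s) without both periods: ",
            paste(skipped, collapse = ", "))
  }
  dist_df <- do.call(rbind, rows)
  rownames(dist_df) <- NULL
  if (merge_moderate) dist_df$group <- merge_prepartum_groups(dist_df$group)
  comparison <- NULL
  sizes <- table(dist_df$group)
  if (sum(sizes >= 3) >= 2) {
    keep <- dist_df$group %in% names(sizes)[sizes >= 3]
    comparison <- try(dispatch_test(dist_df$distance[keep],
                                    dist_df$group[keep],
                                    variable = "prepost_bray_curtis"),
                      silent = TRUE)
    if (inherits(comparison, "try-error")) comparison <- NULL
  }
  list(distances = dist_df, comparison = comparison)
}
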
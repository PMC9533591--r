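# Internal helpers shared across modules.

#' Derive a stable per-id random seed from a master seed
#'
#' Polynomial string hash of `id` folded with `master`, reduced modulo a
#' prime below 2^31 so the result is a valid [set.seed()] value. Used so
#' each simulated cow/sample gets its own reproducible stream: adding a
#' cow never perturbs the draws of the others.
#'
#' @param id character scalar (e.g. a cow id).
#' @param master integer master seed.
#' @return integer seed in \[0, 2147483628].
#' @keywords internal
stable_seed <- function(id, master = 0L) {
  p <- 2147483629
  h <- 0
  for (x in utf8ToInt(as.character(id))) h <- (h * 131 + x) %% p
  as.integer((h + (as.numeric(master) %% p) * 7919) %% p)
}

# Kruskal-Wallis p-value without the formula/htest overhead; `idx` is a
# list of integer index vectors (one per group), precomputed by callers
# that run many tests on the same grouping.
kw_pvalue <- function(x, idx) {
  n <- length(x)
  r <- rank(x)
  ss <- vapply(idx, function(i) sum(r[i])^2 / length(i), numeric(1))
  H <- 12 / (n * (n + 1)) * sum(ss) - 3 * (n + 1)
  tab <- tabulate(match(x, unique(x)))
  tie <- 1 - sum(tab^3 - tab) / (n^3 - n)
  if (tie <= 0) return(NA_real_)
  stats::pchisq(H / tie, df = length(idx) - 1, lower.tail = FALSE)
}

group_indices <- function(labels) {
  labels <- as.character(labels)
  split(seq_along(labels), labels)
}

#' Compact letter display from a pairwise significance matrix
#'
#' Groups sharing at least one letter are not significantly different at
#' `alpha`. Letters are derived from the maximal cliques of the
#' "not-significantly-different" graph (enumerated exhaustively; the
#' number of groups is small), ordered by the first member in `groups`
#' order, so the display is a deterministic function of the p-value
#' matrix and the supplied group order.
#'
#' @param groups character vector of group names (display order).
#' @param p_matrix symmetric matrix of pairwise p-values with
#'   dimnames = groups; the diagonal is ignored.
#' @param alpha significance level separating letters.
#' @return named character vector of letter strings, one per group.
#' @export
compact_letters <- function(groups, p_matrix, alpha = 0.05) {
  k <- length(groups)
  if (k == 1L) return(stats::setNames("a", groups))
  if (k > 16L) stop("compact_letters: too many groups")
  adj <- matrix(TRUE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- p_matrix[groups[i], groups[j]]
      adj[i, j] <- adj[j, i] <- is.na(p) || p >= alpha
    }
  }
  # enumerate maximal cliques by bitmask
  masks <- seq_len(2^k - 1)
  is_clique <- function(m) {
    mem <- which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0)
    all(adj[mem, mem])
  }
  cl <- Filter(is_clique, masks)
  maximal <- Filter(function(m) {
    !any(vapply(cl, function(o) o != m && bitwAnd(o, m) == m, logical(1)))
  }, cl)
  members <- lapply(maximal, function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  ord <- order(vapply(members, min, numeric(1)),
               -vapply(members, length, numeric(1)))
  members <- members[ord]
  lets <- rep("", k)
  for (ci in seq_along(members)) {
    lets[members[[ci]]] <- paste0(lets[members[[ci]]], letters[ci])
  }
  stats::setNames(lets, groups)
}

# read a delimited table, auto-detecting tab vs comma from the header line
read_table_auto <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
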
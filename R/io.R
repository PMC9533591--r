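# Domain containers and on-disk readers/writers.
#
# All downstream modules consume only the in-memory objects built here:
# `ph_trace` (one cow's reticular pH series, time in minutes relative to
# calving), `feature_table` (ASV counts + sample metadata + taxonomy) and
# rooted `phylo` trees from ape.

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Construct a reticular pH trace for one cow
#'
#' Time is stored in minutes relative to calving (negative = prepartum),
#' so all window arithmetic ("first 21 d postpartum", "last 7 d prior to
#' calving") is independent of clock conventions.
#'
#' @param cow_id cow identifier.
#' @param time_min numeric, strictly increasing sampling times in minutes
#'   relative to calving.
#' @param ph numeric pH readings, same length as `time_min`, in
#'   \[3.5, 9.5].
#' @param calving_time optional POSIXct calving timestamp (metadata only).
#' @return object of class `ph_trace`.
#' @export
ph_trace <- function(cow_id, time_min, ph, calving_time = NULL) {
  if (length(time_min) != length(ph)) stop("time_min and ph lengths differ")
  if (length(ph) < 2L) stop("a ph_trace needs at least 2 samples")
  if (anyNA(time_min) || anyNA(ph)) stop("NA in pH trace for cow ", cow_id)
  if (any(diff(time_min) <= 0)) stop("timestamps not strictly increasing for cow ", cow_id)
  if (any(ph < 3.5 | ph > 9.5)) stop("pH outside [3.5, 9.5] for cow ", cow_id)
  structure(list(cow_id = as.character(cow_id),
                 time_min = as.numeric(time_min),
                 ph = as.numeric(ph),
                 calving_time = calving_time),
            class = "ph_trace")
}

#' @export
print.ph_trace <- function(x, ...) {
  cat(sprintf("ph_trace: cow %s, %d samples, %.1f d span, pH %.2f-%.2f\n",
              x$cow_id, length(x$ph), diff(range(x$time_min)) / 1440,
              min(x$ph), max(x$ph)))
  invisible(x)
}

#' Read per-cow pH bolus traces from CSV
#'
#' The trace file has columns `cow_id,timestamp,ph` (ISO-8601 timestamps,
#' irregular 10-15 min sampling); the calving table maps `cow_id` to
#' `calving_time`. Rows are sorted by time per cow and duplicate
#' timestamps are collapsed to their mean pH. Times are converted to
#' minutes relative to each cow's calving.
#'
#' @param path CSV of pH readings.
#' @param calving_path CSV/TSV with columns `cow_id`, `calving_time`.
#' @param tz timezone used to parse timestamps (farm-local).
#' @return named list of [ph_trace()] objects.
#' @export
read_ph_traces <- function(path, calving_path, tz = "UTC") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("cow_id", "timestamp", "ph")
  if (!all(need %in% names(raw))) {
    stop("pH trace file must have columns: ", paste(need, collapse = ", "))
  }
  ph <- suppressWarnings(as.numeric(raw$ph))
  bad <- which(is.na(ph) & !is.na(raw$ph))
  if (length(bad)) {
    stop(sprintf("unparseable pH value '%s' at line %d of %s",
                 raw$ph[bad[1]], bad[1] + 1L, path))
  }
  ts <- as.POSIXct(raw$timestamp, tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (anyNA(ts)) {
    stop(sprintf("unparseable timestamp '%s' at line %d of %s",
                 raw$timestamp[which(is.na(ts))[1]], which(is.na(ts))[1] + 1L, path))
  }
  calv <- read_table_auto(calving_path)
  if (!all(c("cow_id", "calving_time") %in% names(calv))) {
    stop("calving table must have columns cow_id, calving_time")
  }
  calv_ts <- as.POSIXct(calv$calving_time, tz = tz,
                        tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                       "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  names(calv_ts) <- as.character(calv$cow_id)
  cows <- sort(unique(raw$cow_id))
  missing <- setdiff(cows, names(calv_ts))
  if (length(missing)) {
    stop("cow(s) missing from calving table: ", paste(missing, collapse = ", "))
  }
  out <- lapply(cows, function(cw) {
    sel <- raw$cow_id == cw
    tmin <- as.numeric(difftime(ts[sel], calv_ts[[cw]], units = "mins"))
    agg <- tapply(ph[sel], tmin, mean)          # collapse duplicate timestamps
    tt <- as.numeric(names(agg))
    o <- order(tt)
    ph_trace(cw, tt[o], as.numeric(agg)[o], calving_time = calv_ts[[cw]])
  })
  stats::setNames(out, cows)
}

#' Write a collection of pH traces to CSV (round-trip of [read_ph_traces()])
#'
#' @param traces named list of `ph_trace` objects with `calving_time` set.
#' @param path output CSV for readings.
#' @param calving_path output table for calving times.
#' @export
write_ph_traces <- function(traces, path, calving_path) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(cow_id = tr$cow_id,
               timestamp = format(tr$calving_time + tr$time_min * 60,
                                  "%Y-%m-%dT%H:%M:%S"),
               ph = sprintf("%.6f", tr$ph))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  calv <- data.frame(cow_id = vapply(traces, `[[`, "", "cow_id"),
                     calving_time = vapply(traces, function(tr) {
                       format(tr$calving_time, "%Y-%m-%dT%H:%M:%S")
                     }, ""))
  utils::write.table(calv, calving_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a sample x feature count table with metadata and taxonomy
#'
#' Counts are stored features-as-rows, samples-as-columns (the QIIME
#' export orientation). `sample_meta` must cover every sample column;
#' `taxonomy` is a feature x 7-rank character matrix (ranks may be empty).
#'
#' @param counts non-negative integer matrix, features x samples, with
#'   unique dimnames.
#' @param sample_meta data.frame with columns `sample_id`, `cow_id`,
#'   `period` (`"prepartum"`/`"postpartum"`), `group`.
#' @param taxonomy feature x rank character matrix (7 ranks); features
#'   absent get empty lineages (with a warning).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(counts, sample_meta, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double"
  sm <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "cow_id", "period", "group")
  if (!all(need %in% names(sm))) {
    stop("sample_meta must have columns: ", paste(need, collapse = ", "))
  }
  absent <- setdiff(colnames(counts), sm$sample_id)
  if (length(absent)) {
    stop("sample(s) in counts absent from metadata: ", paste(absent, collapse = ", "))
  }
  if (!all(sm$period %in% c("prepartum", "postpartum"))) {
    stop("period must be 'prepartum' or 'postpartum'")
  }
  sm <- sm[match(colnames(counts), sm$sample_id), , drop = FALSE]
  rownames(sm) <- NULL
  feats <- rownames(counts)
  tax <- matrix("", nrow = length(feats), ncol = 7,
                dimnames = list(feats, TAX_RANKS))
  if (!is.null(taxonomy)) {
    taxonomy <- as.matrix(taxonomy)
    known <- intersect(rownames(taxonomy), feats)
    tax[known, ] <- taxonomy[known, seq_len(7), drop = FALSE]
    lost <- setdiff(feats, rownames(taxonomy))
    if (length(lost)) {
      warning(length(lost), " feature(s) missing taxonomy; assigned empty lineage")
    }
  } else {
    warning("no taxonomy supplied; all lineages empty")
  }
  structure(list(counts = counts, sample_meta = sm, taxonomy = tax),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples (total %s reads)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

# split "d__Bacteria; p__Firmicutes; ..." into 7 ranks, stripping rank
# prefixes; missing trailing ranks are empty strings.
split_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";\\s*")
  t(vapply(parts, function(p) {
    p <- sub("^[a-z]__", "", p)
    p <- p[!is.na(p)]
    out <- character(7)
    out[seq_len(min(7, length(p)))] <- p[seq_len(min(7, length(p)))]
    out
  }, character(7)))
}

join_lineage <- function(tax) {
  pref <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
  apply(tax, 1, function(r) {
    last <- max(c(0, which(r != "")))
    if (last == 0) return("")
    paste0(pref[seq_len(last)], r[seq_len(last)], collapse = "; ")
  })
}

#' Read a feature table from QIIME-style TSV exports
#'
#' The counts TSV has features as rows and samples as columns; a
#' `#OTU ID` corner cell is accepted. The taxonomy TSV maps feature id to
#' a `"; "`-separated lineage string (`d__...; p__...` prefixes are
#' stripped); the metadata TSV has `sample_id`, `cow_id`, `period`,
#' `group` columns. A `.biom` (JSON) counts file is also accepted when
#' the biomformat package is available.
#'
#' @param counts_path counts TSV (or JSON BIOM).
#' @param taxonomy_path taxonomy TSV (feature id, lineage).
#' @param meta_path sample metadata TSV.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(counts_path, taxonomy_path, meta_path) {
  if (grepl("\\.biom$", counts_path)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM requires the biomformat package")
    }
    counts <- as.matrix(biomformat::biom_data(biomformat::read_biom(counts_path)))
  } else {
    raw <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                             comment.char = "", check.names = FALSE,
                             stringsAsFactors = FALSE)
    idcol <- names(raw)[1]
    counts <- as.matrix(raw[, -1, drop = FALSE])
    rownames(counts) <- as.character(raw[[idcol]])
  }
  if (any(counts < 0)) stop("negative count in ", counts_path)
  taxr <- utils::read.table(taxonomy_path, header = TRUE, sep = "\t",
                            comment.char = "", check.names = FALSE,
                            stringsAsFactors = FALSE, quote = "")
  tax <- split_lineage(taxr[[2]])
  rownames(tax) <- as.character(taxr[[1]])
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  ft <- feature_table(counts, meta, tax)
  # canonical internal order, independent of file row order
  ft$counts <- ft$counts[order(rownames(ft$counts)), , drop = FALSE]
  ft$taxonomy <- ft$taxonomy[rownames(ft$counts), , drop = FALSE]
  ft
}

#' Write a feature table as QIIME-style TSVs (round-trip of
#' [read_feature_table()])
#'
#' @param ft a [feature_table()].
#' @param counts_path,taxonomy_path,meta_path output paths.
#' @export
write_feature_table <- function(ft, counts_path, taxonomy_path, meta_path) {
  df <- data.frame(`#OTU ID` = rownames(ft$counts), ft$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(`Feature ID` = rownames(ft$taxonomy),
                                Taxon = join_lineage(ft$taxonomy),
                                check.names = FALSE),
                     taxonomy_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(ft$sample_meta, meta_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(counts_path)
}

#' Read a rooted phylogeny in newick format
#'
#' Branch lengths are required (they feed Faith's PD) and must be finite
#' and non-negative; tip labels must be unique.
#'
#' @param path newick file.
#' @return an `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths (required)")
  if (any(!is.finite(tree$edge.length))) stop("non-finite branch length")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

#' Write result tables plus a machine-readable run log
#'
#' Each element of `tables` (data.frames) is written as
#' `<out_dir>/<name>.tsv` with its column order preserved; a
#' `run_log.json` records the seed, configuration and software versions.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed used for the run (recorded).
#' @param config optional list of configuration values (recorded).
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, seed = NA_integer_, config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }, character(1))
  log <- list(seed = seed, config = config,
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("saratools")),
              written = as.list(unname(paths)),
              time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, file.path(out_dir, "run_log.json")))
}

#' Read a pipeline configuration file
#'
#' A single YAML file holding thresholds, windows, seeds, rarefaction
#' depth and filter settings; values omitted from the file fall back to
#' the package defaults (and command-line flags override both).
#'
#' @param path YAML config, or `NULL` for pure defaults.
#' @return named list of settings.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    ph_threshold = 6.0,
    max_gap_min = 30,
    min_coverage = 0.8,
    postpartum_days = 21L,
    prepartum_days = 7L,
    rarefaction_depth = 33787L,
    min_global_freq = 1e-4,
    min_prevalence = 2L,
    n_permutations = 999L,
    ancom_alpha = 0.05,
    ancom_w_cutoff = 0.7,
    seed = 1L
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}
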
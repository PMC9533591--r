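# Synthetic fecal 16S community and assay tables with planted effects.
#
# Per sample the composition is a Dirichlet draw around a base
# composition, with group x period multipliers applied to the ASVs of
# planted genera before renormalization, and counts drawn multinomially
# at the sample's library size. Planted genera carry the names reported
# for SARA-associated fecal taxa so end-to-end direction-recovery tests
# read naturally.

PLANTED_GENERA <- data.frame(
  genus = c("Ruminococcus", "Streptococcus", "Prevotellaceae_UCG-001",
            "Lachnospiraceae_UCG-001", "Anaerosporobacter",
            "Candidatus_Stoquefichus", "Clostridia_UCG-014"),
  family = c("Ruminococcaceae", "Streptococcaceae", "Prevotellaceae",
             "Lachnospiraceae", "Lachnospiraceae",
             "Erysipelatoclostridiaceae", "Clostridia_UCG-014"),
  phylum = c("Firmicutes", "Firmicutes", "Bacteroidota", "Firmicutes",
             "Firmicutes", "Firmicutes", "Firmicutes"),
  base_prop = c(0.018, 0.0002, 0.003, 0.002, 0.0004, 0.002, 0.014),
  n_asv = c(12L, 1L, 5L, 4L, 2L, 4L, 10L),
  stringsAsFactors = FALSE
)

# one postpartum sample per cow plus a prepartum sample where available
cohort_sample_frame <- function(cohort_meta) {
  post <- data.frame(cow_id = cohort_meta$cow_id, group = cohort_meta$group,
                     period = "postpartum", stringsAsFactors = FALSE)
  pre_sel <- which(cohort_meta$has_prepartum)
  samples <- if (length(pre_sel)) {
    rbind(post, data.frame(cow_id = cohort_meta$cow_id[pre_sel],
                           group = cohort_meta$group[pre_sel],
                           period = "prepartum", stringsAsFactors = FALSE))
  } else post
  samples$sample_id <- paste0(samples$cow_id, "_",
                              ifelse(samples$period == "prepartum", "pre", "post"))
  samples
}

#' Default planted group/period effects
#'
#' Log-fold multipliers encoding the reported direction of each
#' SARA-associated genus: postpartum, Ruminococcus / Streptococcus /
#' Prevotellaceae_UCG-001 / Anaerosporobacter / Candidatus_Stoquefichus
#' higher in SU than UN and Clostridia_UCG-014 higher in MS; prepartum,
#' Lachnospiraceae_UCG-001 higher in UN and Ruminococcus lowest in UN.
#' Magnitudes are 1.5-2.5x, the scale of the reported contrasts.
#'
#' @return data.frame with columns `genus`, `period`, `group`,
#'   `multiplier`.
#' @export
default_planted_effects <- function() {
  rbind(
    data.frame(genus = "Ruminococcus", period = "postpartum",
               group = c("SU", "MS", "MU"), multiplier = 1.5),
    data.frame(genus = "Streptococcus", period = "postpartum",
               group = "SU", multiplier = 2.5),
    data.frame(genus = "Prevotellaceae_UCG-001", period = "postpartum",
               group = "SU", multiplier = 1.8),
    data.frame(genus = "Anaerosporobacter", period = "postpartum",
               group = c("SU", "MS", "MU"), multiplier = 2.5),
    data.frame(genus = "Candidatus_Stoquefichus", period = "postpartum",
               group = c("SU", "UN"), multiplier = 1.8),
    data.frame(genus = "Clostridia_UCG-014", period = "postpartum",
               group = "MS", multiplier = 2.0),
    data.frame(genus = "Lachnospiraceae_UCG-001", period = "prepartum",
               group = "UN", multiplier = 1.85),
    data.frame(genus = "Ruminococcus", period = "prepartum",
               group = c("SU", "MS", "MU"), multiplier = 1.5)
  )
}

#' Design of the synthetic ASV community
#'
#' @param n_features number of ASVs (default 1000, yielding ~900
#'   observed ASVs per sample at rarefaction-scale depths).
#' @param n_filler_genera filler genera beside the planted ones.
#' @param theta Dirichlet concentration mass (inter-sample variability;
#'   larger = more reproducible compositions).
#' @param genus_sd,asv_sd lognormal spread of genus masses and of ASV
#'   shares within a genus; together they set the evenness of the base
#'   composition (defaults give ~900 observed ASVs and Pielou ~0.9 at
#'   rarefaction-scale depths).
#' @param period_effect_sd lognormal scale of a fixed feature-wise
#'   prepartum shift applied to `period_effect_frac` of the features
#'   (emulating the diet-driven prepartum/postpartum community shift);
#'   0 disables it.
#' @param period_effect_frac fraction of features carrying the period
#'   shift.
#' @param planted_effects data.frame as [default_planted_effects()];
#'   multipliers must be positive and genera must exist in the generated
#'   taxonomy.
#' @param library_size_range min/max reads per sample.
#' @param dropout_frac fraction of samples drawn below the rarefaction
#'   depth (to exercise sample dropping).
#' @param rarefaction_depth depth the dropout fraction is defined
#'   against.
#' @return object of class `community_design`.
#' @export
community_design <- function(n_features = 1000L, n_filler_genera = 140L,
                             theta = 3000, genus_sd = 1.3, asv_sd = 1.0,
                             planted_effects = default_planted_effects(),
                             library_size_range = c(34000L, 45000L),
                             dropout_frac = 0, rarefaction_depth = 33787L,
                             period_effect_sd = 0.8, period_effect_frac = 0.5) {
  stopifnot(all(planted_effects$multiplier > 0), n_features >= 50L,
            library_size_range[1] <= library_size_range[2],
            dropout_frac >= 0, dropout_frac < 1)
  structure(as.list(environment()), class = "community_design")
}

# build the ASV-level taxonomy and base proportions for a design
build_community <- function(design) {
  unknown <- setdiff(unique(design$planted_effects$genus), PLANTED_GENERA$genus)
  if (length(unknown)) {
    stop("planted taxon not in taxonomy: ", paste(unknown, collapse = ", "))
  }
  g <- PLANTED_GENERA
  n_planted_asv <- sum(g$n_asv)
  n_filler_asv <- design$n_features - n_planted_asv
  stopifnot(n_filler_asv >= design$n_filler_genera)
  # filler genera: lognormal weights over the non-planted mass
  fill_w <- exp(stats::rnorm(design$n_filler_genera, 0, design$genus_sd))
  fill_w <- fill_w / sum(fill_w) * (1 - sum(g$base_prop))
  fill_phyla <- sample(c("Firmicutes", "Bacteroidota", "Spirochaetota",
                         "Proteobacteria", "Actinobacteriota", "Patescibacteria",
                         "Verrucomicrobiota"),
                       design$n_filler_genera, replace = TRUE,
                       prob = c(0.62, 0.24, 0.04, 0.03, 0.03, 0.02, 0.02))
  # allocate filler ASVs proportionally to genus weight (>= 1 each)
  extra <- n_filler_asv - design$n_filler_genera
  add <- if (extra > 0) {
    tabulate(sample.int(design$n_filler_genera, extra, replace = TRUE,
                        prob = fill_w), design$n_filler_genera)
  } else integer(design$n_filler_genera)
  fill_nasv <- 1L + add
  genus_tab <- rbind(
    data.frame(genus = g$genus, family = g$family, phylum = g$phylum,
               weight = g$base_prop, n_asv = g$n_asv, planted = TRUE),
    data.frame(genus = sprintf("Genus_%03d", seq_len(design$n_filler_genera)),
               family = sprintf("Family_%03d", seq_len(design$n_filler_genera)),
               phylum = fill_phyla, weight = fill_w, n_asv = fill_nasv,
               planted = FALSE)
  )
  asv_genus <- rep(genus_tab$genus, genus_tab$n_asv)
  ids <- sprintf("ASV_%04d", seq_along(asv_genus))
  # split each genus' mass over its ASVs with lognormal shares
  p0 <- numeric(length(ids))
  for (gi in seq_len(nrow(genus_tab))) {
    sel <- which(asv_genus == genus_tab$genus[gi])
    sh <- exp(stats::rnorm(length(sel), 0, design$asv_sd))
    p0[sel] <- genus_tab$weight[gi] * sh / sum(sh)
  }
  p0 <- p0 / sum(p0)
  # fixed feature-wise prepartum multiplier (diet-driven period shift)
  period_mult <- rep(1, length(ids))
  if (design$period_effect_sd > 0 && design$period_effect_frac > 0) {
    hit <- sample(length(ids), round(design$period_effect_frac * length(ids)))
    period_mult[hit] <- exp(stats::rnorm(length(hit), 0, design$period_effect_sd))
  }
  tax <- matrix("", length(ids), 7, dimnames = list(ids, TAX_RANKS))
  gi <- match(asv_genus, genus_tab$genus)
  tax[, "domain"] <- "Bacteria"
  tax[, "phylum"] <- genus_tab$phylum[gi]
  tax[, "class"] <- paste0("Class_", genus_tab$phylum[gi])
  tax[, "order"] <- paste0("Order_", genus_tab$family[gi])
  tax[, "family"] <- genus_tab$family[gi]
  tax[, "genus"] <- asv_genus
  list(ids = ids, p0 = p0, tax = tax, asv_genus = asv_genus,
       period_mult = period_mult)
}

#' Simulate pre/postpartum ASV tables with planted group effects
#'
#' One prepartum (where available) and one postpartum sample per cow.
#' Per sample the base composition is perturbed by the planted
#' group x period multipliers, renormalized, drawn from a Dirichlet with
#' mass `theta`, and counted multinomially at the sample's library size.
#' A random bifurcating tree with exponential branch lengths is emitted
#' over the ASVs.
#'
#' @param cohort_meta data.frame with `cow_id`, `group` and
#'   `has_prepartum` (as produced by [simulate_cohort()]`$metadata`).
#' @param design a [community_design()].
#' @param seed master seed (per-sample streams derived by stable
#'   hashing).
#' @return list with `table` (a [feature_table()]), `tree`
#'   (`ape::phylo`), and `truth` (planted effects, ASV-to-genus map,
#'   drawn library sizes).
#' @export
simulate_feature_table <- function(cohort_meta, design = community_design(),
                                   seed = 1L) {
  set.seed(stable_seed("community-base", seed))
  com <- build_community(design)
  samples <- cohort_sample_frame(cohort_meta)
  pe <- design$planted_effects
  counts <- matrix(0, nrow = length(com$ids), ncol = nrow(samples),
                   dimnames = list(com$ids, samples$sample_id))
  libsizes <- integer(nrow(samples))
  n_drop <- round(design$dropout_frac * nrow(samples))
  drop_idx <- if (n_drop > 0) {
    sample.int(nrow(samples), n_drop)
  } else integer(0)
  for (s in seq_len(nrow(samples))) {
    set.seed(stable_seed(samples$sample_id[s], seed))
    mult <- if (samples$period[s] == "prepartum") com$period_mult else
      rep(1, length(com$ids))
    hits <- pe[pe$period == samples$period[s] & pe$group == samples$group[s], ,
               drop = FALSE]
    for (r in seq_len(nrow(hits))) {
      mult[com$asv_genus == hits$genus[r]] <-
        mult[com$asv_genus == hits$genus[r]] * hits$multiplier[r]
    }
    alpha <- design$theta * (com$p0 * mult) / sum(com$p0 * mult)
    gam <- stats::rgamma(length(alpha), shape = alpha)
    if (sum(gam) == 0) gam[which.max(alpha)] <- 1
    comp <- gam / sum(gam)
    L <- if (s %in% drop_idx) {
      lo <- round(design$rarefaction_depth * 0.5)
      lo + sample.int(design$rarefaction_depth - lo, 1L) - 1L
    } else {
      design$library_size_range[1] +
        sample.int(diff(design$library_size_range) + 1L, 1L) - 1L
    }
    libsizes[s] <- L
    counts[, s] <- stats::rmultinom(1, L, comp)
  }
  set.seed(stable_seed("community-tree", seed))
  # branch lengths scaled so whole-community PD lands on the tens scale
  # typical of rarefied fecal ASV tables
  tree <- ape::rtree(length(com$ids), br = function(n) stats::rexp(n, rate = 33))
  tree$tip.label <- sample(com$ids)
  meta <- samples[, c("sample_id", "cow_id", "period", "group")]
  ft <- feature_table(counts, meta, com$tax)
  list(table = ft, tree = tree,
       truth = list(planted_effects = pe,
                    asv_genus = stats::setNames(com$asv_genus, com$ids),
                    base_composition = stats::setNames(com$p0, com$ids),
                    library_sizes = stats::setNames(libsizes, samples$sample_id)))
}

#' Design of the synthetic assay tables
#'
#' @param qpcr_log10_mean,qpcr_log10_sd per-target lognormal parameters
#'   of gene copies/mL (bacteria 16S, methanogen mcrA, protozoa 18S,
#'   fungal 5.8S).
#' @param un_shift_log10 postpartum UN-vs-rest shift (log10 copies) for
#'   bacteria and methanogens; protozoa/fungi are unshifted.
#' @param curve_slope,curve_intercept standard-curve parameters
#'   (Cq = intercept + slope * log10 copies); slope -3.32 is 100%
#'   amplification efficiency.
#' @param cq_noise_sd Cq measurement noise (0 = noise-free, exactly
#'   invertible).
#' @param obcfa_mean named vector of true OBCFA concentrations, mg/100 g
#'   dry feces.
#' @param obcfa_cv lognormal coefficient of variation of concentrations.
#' @param is_mass internal-standard mass, mg.
#' @param is_area internal-standard peak area (arbitrary units).
#' @param response_factors named theoretical response factors per
#'   analyte.
#' @param sample_dry_mass dry feces analyzed, g.
#' @param fecal_ph_mean,fecal_ph_sd,dm_mean,dm_sd,dmi_mean,dmi_sd scalar
#'   phenotype distributions (no group effect: none was observed).
#' @return object of class `assay_design`.
#' @export
assay_design <- function(qpcr_log10_mean = c(bacteria = 11.0, methanogens = 9.0,
                                             protozoa = 5.5, fungi = 5.0),
                         qpcr_log10_sd = 0.25,
                         un_shift_log10 = 0.4,
                         curve_slope = -3.32, curve_intercept = 38,
                         cq_noise_sd = 0,
                         obcfa_mean = c(`anteiso-C15:0` = 42, `anteiso-C17:0` = 22,
                                        `iso-C14:0` = 9.4, `iso-C15:0` = 17.5,
                                        `iso-C16:0` = 14.3, `iso-C17:0` = 30,
                                        `C15:0` = 58, `C17:0` = 56),
                         obcfa_cv = 0.15,
                         is_mass = 10, is_area = 1e6,
                         response_factors = NULL,
                         sample_dry_mass = 1.5,
                         fecal_ph_mean = 6.45, fecal_ph_sd = 0.15,
                         dm_mean = 140, dm_sd = 15,
                         dmi_mean = 20, dmi_sd = 1.5) {
  if (is.null(response_factors)) {
    response_factors <- stats::setNames(rep(1, length(obcfa_mean)),
                                        names(obcfa_mean))
  }
  stopifnot(curve_slope < 0, is_area > 0, is_mass > 0, sample_dry_mass > 0)
  structure(as.list(environment()), class = "assay_design")
}

#' Simulate qPCR, GC and scalar phenotype assay tables
#'
#' qPCR copies/mL are lognormal per target with a configurable UN shift
#' for bacteria/methanogens postpartum; Cq values are back-computed
#' through the standard curve, so [qpcr_copies()] inverts the generator
#' exactly in noise-free mode. GC peak areas are generated from true
#' OBCFA concentrations through the internal-standard relation, so
#' [quantify_fatty_acids()] also inverts exactly.
#'
#' @param cohort_meta data.frame with `cow_id`, `group`,
#'   `has_prepartum`.
#' @param design an [assay_design()].
#' @param seed master seed.
#' @return list of class `assay_table`: `qpcr` (per sample/target Cq),
#'   `standards` (per-target standard-curve points), `gc` (peak areas),
#'   `phenotypes` (fecal pH, DM, DMI), and `truth` (true copies and
#'   concentrations).
#' @export
simulate_assays <- function(cohort_meta, design = assay_design(), seed = 1L) {
  samples <- cohort_sample_frame(cohort_meta)
  targets <- names(design$qpcr_log10_mean)
  qpcr <- list(); truth_copies <- list(); gc <- list(); pheno <- list()
  truth_conc <- list()
  for (s in seq_len(nrow(samples))) {
    set.seed(stable_seed(paste0("assay-", samples$sample_id[s]), seed))
    shift <- ifelse(targets %in% c("bacteria", "methanogens") &
                      samples$group[s] == "UN" &
                      samples$period[s] == "postpartum",
                    design$un_shift_log10, 0)
    l10 <- stats::rnorm(length(targets),
                        design$qpcr_log10_mean + shift, design$qpcr_log10_sd)
    cq <- design$curve_intercept + design$curve_slope * l10 +
      stats::rnorm(length(targets), 0, design$cq_noise_sd)
    qpcr[[s]] <- data.frame(sample_id = samples$sample_id[s],
                            cow_id = samples$cow_id[s],
                            period = samples$period[s],
                            group = samples$group[s],
                            target = targets, cq = cq)
    truth_copies[[s]] <- data.frame(sample_id = samples$sample_id[s],
                                    target = targets, copies_per_ml = 10^l10)
    conc <- design$obcfa_mean *
      exp(stats::rnorm(length(design$obcfa_mean), 0, design$obcfa_cv) -
            design$obcfa_cv^2 / 2)
    mass <- conc * design$sample_dry_mass / 100   # mg in the analyzed aliquot
    area <- mass / (design$is_mass * design$response_factors[names(conc)]) *
      design$is_area
    gc[[s]] <- data.frame(sample_id = samples$sample_id[s],
                          cow_id = samples$cow_id[s],
                          period = samples$period[s],
                          group = samples$group[s],
                          analyte = names(conc), area = unname(area))
    truth_conc[[s]] <- data.frame(sample_id = samples$sample_id[s],
                                  analyte = names(conc),
                                  mg_per_100g = unname(conc))
    pheno[[s]] <- data.frame(sample_id = samples$sample_id[s],
                             cow_id = samples$cow_id[s],
                             period = samples$period[s],
                             group = samples$group[s],
                             fecal_ph = stats::rnorm(1, design$fecal_ph_mean,
                                                     design$fecal_ph_sd),
                             dm_g_per_kg = stats::rnorm(1, design$dm_mean,
                                                        design$dm_sd),
                             dmi_kg_per_d = stats::rnorm(1, design$dmi_mean,
                                                         design$dmi_sd))
  }
  set.seed(stable_seed("assay-standards", seed))
  standards <- do.call(rbind, lapply(targets, function(tg) {
    l10 <- 3:8
    data.frame(target = tg, log10_copies = l10,
               cq = design$curve_intercept + design$curve_slope * l10)
  }))
  structure(list(qpcr = do.call(rbind, qpcr),
                 standards = standards,
                 gc = do.call(rbind, gc),
                 phenotypes = do.call(rbind, pheno),
                 is_area = design$is_area, is_mass = design$is_mass,
                 response_factors = design$response_factors,
                 sample_dry_mass = design$sample_dry_mass,
                 truth = list(copies = do.call(rbind, truth_copies),
                              concentrations = do.call(rbind, truth_conc)),
                 design = design),
            class = "assay_table")
}
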
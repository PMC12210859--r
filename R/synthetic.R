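#' Configuration for the synthetic cohort generator
#'
#' Describes a five-group esophageal cohort with bacterial (16S) and fungal
#' (ITS) feature tables, taxonomy, clinical covariates and planted ground
#' truth. The `"ci"` profile (default) is a scaled-down cohort — 200
#' bacterial and 60 fungal taxa, ten samples per group — sized for routine
#' testing; `"full"` matches the study-scale cohort (2314 bacterial and 573
#' fungal ASVs; group sizes 13/10/10/12/12).
#'
#' The count model: each taxon has a log-normal baseline abundance; planted
#' differential taxa add a group-specific log fold change; per sample, a
#' latent Gaussian perturbation with group-specific standard deviation
#' (`dispersion_by_group`) and block-correlated components
#' (`correlation_blocks`) is added; sequencing depth is drawn proportional
#' to the sample's total latent biomass (times log-normal noise), and counts
#' are multinomial at that depth. Coupling depth to biomass makes the
#' fitted Type-I Taylor exponent rise with the dispersion parameter, which
#' is how the generator controls spatial heterogeneity per group.
#'
#' @param profile `"ci"` or `"full"`.
#' @param seed master integer seed; every stochastic choice derives from it.
#' @param group_sizes named integer vector over [stage_groups()].
#' @param n_taxa named vector `c(bacteria =, fungi =)`.
#' @param library_size list with `mean_depth` (per kingdom, named) and
#'   `sdlog` noise.
#' @param base_composition list with `meanlog`, `sdlog` of taxon baselines.
#' @param differential_taxa `data.frame` with columns `taxon` (index within
#'   kingdom), `kingdom`, `groups` (comma-separated labels), `log2fc`.
#' @param dispersion_by_group named numeric vector of latent noise SD per
#'   group; defaults make the early-lesion group the most heterogeneous and
#'   the carcinoma group the least coupled, mirroring the stage pattern the
#'   package is designed to analyse.
#' @param correlation_blocks list of blocks, each
#'   `list(kingdom =, taxa = indices, r = latent correlation, groups =
#'   labels)`; blocks are active only in their groups.
#' @param oral_flag_probability probability a bacterial taxon is flagged as
#'   an oral-cavity resident.
#' @param clinical_tables list: `categorical` — covariate -> named yes-count
#'   vector per group; `age` — `data.frame(group, mean, sd)`.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(profile = c("ci", "full"), seed = 1,
                             group_sizes = NULL, n_taxa = NULL,
                             library_size = NULL, base_composition = NULL,
                             differential_taxa = NULL,
                             dispersion_by_group = NULL,
                             correlation_blocks = NULL,
                             oral_flag_probability = 0.3,
                             clinical_tables = NULL) {
  profile <- match.arg(profile)
  groups <- stage_groups()
  if (is.null(group_sizes))
    group_sizes <- if (profile == "full")
      stats::setNames(c(13L, 10L, 10L, 12L, 12L), groups)
    else stats::setNames(rep(10L, 5), groups)
  if (is.null(n_taxa))
    n_taxa <- if (profile == "full") c(bacteria = 2314L, fungi = 573L)
    else c(bacteria = 200L, fungi = 60L)
  if (is.null(library_size))
    library_size <- list(mean_depth = c(bacteria = 30000, fungi = 40000),
                         sdlog = 0.3)
  if (is.null(base_composition))
    base_composition <- list(meanlog = 0, sdlog = 2)
  if (is.null(dispersion_by_group))
    dispersion_by_group <- stats::setNames(c(0.6, 0.7, 1.3, 0.7, 0.5), groups)
  if (is.null(differential_taxa))
    differential_taxa <- data.frame(
      taxon = c(1L, 2L, 3L, 1L, 2L),
      kingdom = c("bacteria", "bacteria", "bacteria", "fungi", "fungi"),
      groups = c("ESCC", "ESCC,ESCCA", "ESIN", "ESIN", "ESCC"),
      log2fc = c(2, 2, 2, 3, 2),
      stringsAsFactors = FALSE)
  if (is.null(correlation_blocks))
    correlation_blocks <- list(
      list(kingdom = "bacteria", taxa = 11:16, r = 0.8,
           groups = c("HC", "ESINA", "ESIN", "ESCCA", "ESCC")),
      list(kingdom = "bacteria", taxa = 21:24, r = 0.7,
           groups = c("HC", "ESINA", "ESIN")),
      list(kingdom = "fungi", taxa = 11:13, r = 0.8,
           groups = c("HC", "ESINA", "ESIN")))
  if (is.null(clinical_tables)) {
    # reference cohort margins (13/10/12); rescaled to the configured group
    # sizes so any profile keeps the same yes-proportions
    ref_n <- c(HC = 13, ESIN = 10, ESCC = 12)
    rescale <- function(yes) {
      n <- cfg_sizes <- group_sizes[names(yes)]
      pmin(round(yes * n / ref_n[names(yes)]), n)
    }
    clinical_tables <- list(
      categorical = lapply(list(
        male = c(HC = 9, ESIN = 9, ESCC = 11),
        current_alcohol = c(HC = 4, ESIN = 7, ESCC = 11),
        family_history_cancer = c(HC = 0, ESIN = 3, ESCC = 0),
        hot_food_preference = c(HC = 0, ESIN = 5, ESCC = 3),
        low_income = c(HC = 5, ESIN = 6, ESCC = 11),
        current_smoking = c(HC = 5, ESIN = 6, ESCC = 10)), rescale),
      age = data.frame(group = c("HC", "ESIN", "ESCC"),
                       mean = c(64.3, 63.5, 66.8),
                       sd = c(11.0, 9.80, 5.94),
                       stringsAsFactors = FALSE))
  }
  cfg <- list(profile = profile, seed = seed, group_sizes = group_sizes,
              n_taxa = n_taxa, library_size = library_size,
              base_composition = base_composition,
              differential_taxa = differential_taxa,
              dispersion_by_group = dispersion_by_group,
              correlation_blocks = correlation_blocks,
              oral_flag_probability = oral_flag_probability,
              clinical_tables = clinical_tables)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (any(cfg$group_sizes < 2)) stopf("group sizes must be >= 2")
  if (any(!is.finite(cfg$differential_taxa$log2fc))) stopf("fold changes must be finite")
  for (b in cfg$correlation_blocks) {
    k <- length(b$taxa)
    if (abs(b$r) >= 1) stopf("|latent correlation| must be < 1")
    if (b$r < -1 / (k - 1))
      stopf("block correlation %g with %d taxa is not positive semi-definite", b$r, k)
    if (max(b$taxa) > cfg$n_taxa[[b$kingdom]])
      stopf("block taxon index exceeds n_taxa for %s", b$kingdom)
  }
  for (cv in names(cfg$clinical_tables$categorical)) {
    yes <- cfg$clinical_tables$categorical[[cv]]
    n <- cfg$group_sizes[names(yes)]
    if (any(yes > n)) stopf("clinical yes-counts exceed group size for '%s'", cv)
  }
  invisible(cfg)
}

#' Generate the synthetic cohort
#'
#' Emits bacterial and fungal count tables, taxonomy, sample metadata with
#' clinical covariates, and the planted ground truth. Deterministic under a
#' fixed config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `bacteria`, `fungi` (feature tables), `taxonomy`,
#'   `metadata`, `truth` (class `planted_truth`).
#' @export
generate_tables <- function(cfg) {
  validate_synthetic_config(cfg)
  groups <- names(cfg$group_sizes)
  sample_group <- rep(groups, cfg$group_sizes)
  sids <- sprintf("S%02d_%s", seq_along(sample_group), sample_group)
  out <- list()
  truth_corr <- list()
  for (kg in c("bacteria", "fungi")) {
    gen <- simulate_kingdom(cfg, kg, sids, sample_group)
    out[[kg]] <- gen$table
    truth_corr[[kg]] <- gen$latent_correlation
  }
  taxonomy <- synth_taxonomy(cfg)
  metadata <- generate_clinical(cfg, sids = sids, sample_group = sample_group)
  truth <- structure(list(
    differential_taxa = annotate_differential(cfg),
    latent_correlation = truth_corr,
    dispersion_by_group = cfg$dispersion_by_group,
    correlation_blocks = cfg$correlation_blocks,
    clinical_tables = cfg$clinical_tables), class = "planted_truth")
  list(bacteria = out$bacteria, fungi = out$fungi, taxonomy = taxonomy,
       metadata = metadata, truth = truth)
}

annotate_differential <- function(cfg) {
  df <- cfg$differential_taxa
  df$taxon_id <- ifelse(df$kingdom == "bacteria",
                        sprintf("B%04d", df$taxon), sprintf("F%04d", df$taxon))
  df$direction <- ifelse(df$log2fc >= 0, "up", "down")
  df
}

kingdom_offset <- function(kg) if (kg == "bacteria") 1000L else 2000L

simulate_kingdom <- function(cfg, kg, sids, sample_group) {
  D <- cfg$n_taxa[[kg]]
  n <- length(sids)
  ids <- sprintf("%s%04d", if (kg == "bacteria") "B" else "F", seq_len(D))
  set.seed(derive_seed(cfg$seed, kingdom_offset(kg)))
  base <- stats::rnorm(D, cfg$base_composition$meanlog, cfg$base_composition$sdlog)
  # planted taxa (differential and correlation-block members) are pinned to
  # an upper-quartile baseline: ground truth that drowns below the detection
  # floor cannot anchor recovery checks
  planted <- unique(c(
    cfg$differential_taxa$taxon[cfg$differential_taxa$kingdom == kg],
    unlist(lapply(Filter(function(b) b$kingdom == kg, cfg$correlation_blocks),
                  `[[`, "taxa"))))
  base[planted] <- cfg$base_composition$meanlog +
    1.2 * cfg$base_composition$sdlog
  # group effects from planted differential taxa
  eff <- matrix(0, D, length(cfg$group_sizes),
                dimnames = list(ids, names(cfg$group_sizes)))
  dt <- cfg$differential_taxa[cfg$differential_taxa$kingdom == kg, , drop = FALSE]
  for (i in seq_len(nrow(dt))) {
    gs <- trimws(strsplit(dt$groups[i], ",")[[1]])
    eff[dt$taxon[i], gs] <- dt$log2fc[i] * log(2)
  }
  blocks <- Filter(function(b) b$kingdom == kg, cfg$correlation_blocks)
  # latent correlation truth (per group it may differ; store the union-of-
  # groups block structure as matrices per group)
  latent_corr <- lapply(names(cfg$group_sizes), function(g) {
    C <- diag(D)
    for (b in blocks) if (g %in% b$groups)
      C[b$taxa, b$taxa] <- (1 - b$r) * diag(length(b$taxa)) + b$r
    dimnames(C) <- list(ids, ids)
    C
  })
  names(latent_corr) <- names(cfg$group_sizes)
  mean_depth <- cfg$library_size$mean_depth[[kg]]
  counts <- matrix(0L, D, n, dimnames = list(ids, sids))
  # reference biomass so depths center on mean_depth
  for (s in seq_len(n)) {
    g <- sample_group[s]
    sig <- cfg$dispersion_by_group[[g]]
    z <- stats::rnorm(D)
    for (b in blocks) if (g %in% b$groups) {
      k <- length(b$taxa)
      C <- (1 - b$r) * diag(k) + b$r
      z[b$taxa] <- t(chol(C)) %*% stats::rnorm(k)
    }
    # bound the perturbation tails: a single unbounded draw on a dominant
    # taxon would hand one sample the whole fit's leverage
    z <- pmin(pmax(z, -2.5), 2.5)
    lam <- exp(base + eff[, g] + sig * z)
    biomass <- sum(lam)
    ref <- sum(exp(base + eff[, g] + sig^2 / 2))
    depth <- round(mean_depth * biomass / ref *
                     exp(stats::rnorm(1, 0, cfg$library_size$sdlog)))
    depth <- max(500, min(depth, 10 * mean_depth))
    counts[, s] <- stats::rmultinom(1, depth, lam / biomass)[, 1]
  }
  list(table = feature_table(counts), latent_correlation = latent_corr)
}

synth_taxonomy <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 3000L))
  bac_phyla <- c("Proteobacteria", "Firmicutes", "Fusobacteriota",
                 "Bacteroidota", "Actinobacteriota")
  bac_genera <- c("Vibrio", "Pseudoalteromonas", "Streptococcus",
                  "Lactobacillus", "Fusobacterium", "Capnocytophaga",
                  "Haemophilus", "Rothia", "Porphyromonas", "Acinetobacter")
  fun_phyla <- c("Ascomycota", "Basidiomycota")
  fun_genera <- c("Aspergillus", "Candida", "Alternaria", "Monascus",
                  "Coniochaeta", "Neosetophoma")
  mk <- function(kg, D) {
    ids <- sprintf("%s%04d", if (kg == "bacteria") "B" else "F", seq_len(D))
    phyla <- sample(if (kg == "bacteria") bac_phyla else fun_phyla, D, TRUE)
    genera <- sample(if (kg == "bacteria") bac_genera else fun_genera, D, TRUE)
    # leave some species ranks empty to exercise unclassified pooling
    species <- ifelse(stats::runif(D) < 0.85, paste0(tolower(genera), "_sp", seq_len(D)), "")
    lineage <- sprintf("k__%s;p__%s;c__;o__;f__;g__%s;s__%s",
                       if (kg == "bacteria") "Bacteria" else "Fungi",
                       phyla, genera, species)
    oral <- if (kg == "bacteria")
      stats::runif(D) < cfg$oral_flag_probability else rep(FALSE, D)
    data.frame(taxon_id = ids, kingdom = kg, lineage = lineage, oral = oral,
               stringsAsFactors = FALSE)
  }
  rbind(mk("bacteria", cfg$n_taxa[["bacteria"]]),
        mk("fungi", cfg$n_taxa[["fungi"]]))
}

#' Generate clinical metadata with exact contingency margins
#'
#' Emits one metadata row per sample: group, age (normal draw from the
#' configured per-group mean/sd) and categorical covariates hitting the
#' configured per-group yes-counts exactly — which samples within a group
#' carry the "yes" is randomised by the seed, the margins are not. Groups
#' without a configured column for a covariate get `NA`. Adjacent-tissue
#' groups inherit the configuration of their lesion group when not
#' configured themselves.
#'
#' @param cfg a [synthetic_config()].
#' @param sids,sample_group optional precomputed sample ids and group
#'   labels (used internally by [generate_tables()]).
#' @return metadata `data.frame` (`sample_id`, `group`, covariates).
#' @export
generate_clinical <- function(cfg, sids = NULL, sample_group = NULL) {
  validate_synthetic_config(cfg)
  if (is.null(sids)) {
    sample_group <- rep(names(cfg$group_sizes), cfg$group_sizes)
    sids <- sprintf("S%02d_%s", seq_along(sample_group), sample_group)
  }
  set.seed(derive_seed(cfg$seed, 4000L))
  lesion_of <- c(HC = "HC", ESINA = "ESIN", ESIN = "ESIN",
                 ESCCA = "ESCC", ESCC = "ESCC")
  meta <- data.frame(sample_id = sids, group = sample_group,
                     stringsAsFactors = FALSE)
  age_cfg <- cfg$clinical_tables$age
  meta$age <- NA_real_
  for (g in unique(sample_group)) {
    src <- lesion_of[[g]] %||% g
    row <- age_cfg[age_cfg$group == src, ]
    if (nrow(row))
      meta$age[meta$group == g] <- round(stats::rnorm(sum(meta$group == g),
                                                      row$mean, row$sd), 1)
  }
  for (cv in names(cfg$clinical_tables$categorical)) {
    yes <- cfg$clinical_tables$categorical[[cv]]
    meta[[cv]] <- NA
    for (g in unique(sample_group)) {
      src <- if (g %in% names(yes)) g else lesion_of[[g]]
      if (!src %in% names(yes)) next
      idx <- which(meta$group == g)
      k <- if (g %in% names(yes)) yes[[g]]
      else round(yes[[src]] * length(idx) / cfg$group_sizes[[src]])
      k <- min(k, length(idx))
      flags <- rep(FALSE, length(idx))
      flags[sample(length(idx), k)] <- TRUE
      meta[[cv]][idx] <- flags
    }
  }
  meta$group <- factor(meta$group, levels = names(cfg$group_sizes))
  meta
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth> %d differential taxa; %d correlation blocks; dispersion: %s\n",
              nrow(x$differential_taxa), length(x$correlation_blocks),
              paste(sprintf("%s=%.2g", names(x$dispersion_by_group),
                            x$dispersion_by_group), collapse = ", ")))
  invisible(x)
}

#' Write the synthetic cohort to a directory
#'
#' Emits the same TSV formats the readers consume: per-kingdom feature
#' tables, taxonomy and metadata.
#'
#' @param tables output of [generate_tables()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(tables$bacteria, file.path(dir, "bacteria_counts.tsv"))
  write_feature_table(tables$fungi, file.path(dir, "fungi_counts.tsv"))
  write_taxonomy(tables$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_metadata(tables$metadata, file.path(dir, "metadata.tsv"))
  invisible(dir)
}
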
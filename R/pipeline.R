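#' Pipeline configuration
#'
#' One configuration object drives the full analysis: simulate (or load) ->
#' filter -> diversity -> heterogeneity -> shared species -> biomarker
#' screen -> networks -> clinical statistics. All stochastic stages derive
#' their seeds from the single `seed`.
#'
#' @param synthetic a [synthetic_config()], or `NULL` to read tables from
#'   `input_dir` (expects the file layout of [write_synthetic()]).
#' @param input_dir directory of input TSVs when `synthetic` is `NULL`.
#' @param output_dir where stage artifacts are written.
#' @param seed master integer seed.
#' @param depth_thresholds named vector, minimum sample depth per kingdom.
#' @param feature_min_reads,feature_min_samples feature filter thresholds.
#' @param n_perm permutations for the permutation-based stages.
#' @param lda_threshold effect-size pass threshold (log10 scale).
#' @param r_min,q_max network edge filters.
#' @param sparcc_iterations,sparcc_permutations SparCC effort knobs.
#' @param network_groups groups for which co-occurrence networks are built.
#' @param covariates clinical covariates to tabulate (default: all present).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            input_dir = NULL,
                            output_dir = tempfile("esomicro_run_"),
                            seed = 1,
                            depth_thresholds = c(bacteria = 14000, fungi = 19500),
                            feature_min_reads = 10, feature_min_samples = 2,
                            n_perm = 999, lda_threshold = 3.0,
                            r_min = 0.4, q_max = 0.05,
                            sparcc_iterations = 20, sparcc_permutations = 200,
                            network_groups = c("HC", "ESIN", "ESCC"),
                            covariates = NULL) {
  if (is.null(synthetic) && is.null(input_dir))
    stopf("either a synthetic config or an input directory is required")
  stopifnot(feature_min_reads > 0, feature_min_samples > 0, n_perm >= 1,
            lda_threshold > 0, r_min > 0, q_max > 0)
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 output_dir = output_dir, seed = seed,
                 depth_thresholds = depth_thresholds,
                 feature_min_reads = feature_min_reads,
                 feature_min_samples = feature_min_samples,
                 n_perm = n_perm, lda_threshold = lda_threshold,
                 r_min = r_min, q_max = q_max,
                 sparcc_iterations = sparcc_iterations,
                 sparcc_permutations = sparcc_permutations,
                 network_groups = network_groups,
                 covariates = covariates),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writes per-stage TSV/JSON
#' artifacts under `cfg$output_dir`, and a `manifest.json` echoing the
#' configuration, seeds and stage outputs. Re-running with the same config
#' and seed reproduces every stochastic output exactly. A stage failure
#' aborts with an error naming the stage.
#'
#' @param cfg a [pipeline_config()].
#' @param force overwrite a non-empty output directory.
#' @return invisible list of in-memory stage results (also on disk).
#' @export
run_pipeline <- function(cfg, force = FALSE) {
  out <- cfg$output_dir
  if (dir.exists(out) && length(list.files(out)) && !force)
    stopf("output directory '%s' is non-empty; use force = TRUE", out)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out, "pipeline.log")
  logmsg <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    cat(line, "\n", file = log_file, append = TRUE, sep = "")
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  manifest <- list(package = "esomicro",
                   version = as.character(utils::packageVersion("esomicro")),
                   seed = cfg$seed, stages = list(),
                   parameters = cfg[setdiff(names(cfg), c("synthetic", "covariates"))])
  results <- list()

  # ---- inputs -------------------------------------------------------------
  dat <- stage("input", {
    if (!is.null(cfg$synthetic)) {
      logmsg("simulating synthetic cohort (profile %s, seed %d)",
             cfg$synthetic$profile, cfg$synthetic$seed)
      generate_tables(cfg$synthetic)
    } else {
      logmsg("reading tables from %s", cfg$input_dir)
      list(bacteria = read_feature_table(file.path(cfg$input_dir, "bacteria_counts.tsv")),
           fungi = read_feature_table(file.path(cfg$input_dir, "fungi_counts.tsv")),
           taxonomy = read_taxonomy(file.path(cfg$input_dir, "taxonomy.tsv")),
           metadata = read_metadata(file.path(cfg$input_dir, "metadata.tsv")),
           truth = NULL)
    }
  })
  manifest$stages$input <- c("bacteria_counts.tsv", "fungi_counts.tsv",
                             "taxonomy.tsv", "metadata.tsv")
  write_synthetic(dat, out)

  # ---- filtering ----------------------------------------------------------
  filtered <- stage("filter", {
    lapply(c(bacteria = "bacteria", fungi = "fungi"), function(kg) {
      t0 <- dat[[kg]]
      thr <- cfg$depth_thresholds[[kg]]
      t1 <- filter_samples_by_depth(t0, thr)
      logmsg("%s: depth >= %s keeps %d/%d samples", kg,
             format(thr, big.mark = ","), ncol(t1$counts), ncol(t0$counts))
      t2 <- filter_features(t1, cfg$feature_min_reads, cfg$feature_min_samples)
      logmsg("%s: feature filter (>= %d reads, >= %d samples) keeps %d/%d taxa",
             kg, cfg$feature_min_reads, cfg$feature_min_samples,
             nrow(t2$counts), nrow(t1$counts))
      t2
    })
  })
  for (kg in names(filtered))
    write_feature_table(filtered[[kg]], file.path(out, paste0(kg, "_filtered.tsv")))
  manifest$stages$filter <- paste0(names(filtered), "_filtered.tsv")
  results$filtered <- filtered
  meta <- dat$metadata

  # ---- composition / oral fraction ---------------------------------------
  results$oral <- stage("composition", {
    of <- oral_fraction(filtered$bacteria, dat$taxonomy,
                        groups = group_vector(meta))
    utils::write.table(
      data.frame(sample_id = names(of), oral_fraction = as.numeric(of)),
      file.path(out, "oral_fraction.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    of
  })
  manifest$stages$composition <- "oral_fraction.tsv"

  # ---- diversity ----------------------------------------------------------
  results$diversity <- stage("diversity", {
    lapply(filtered, function(t) {
      prof <- hill_profile(t)
      d <- bray_curtis(hellinger(t))
      g <- group_vector(meta, sample_ids(t))
      omnibus <- permanova(d, g, cfg$n_perm, derive_seed(cfg$seed, 61L))
      pw <- pairwise_beta(d, g, "permanova_R2", n_perm = cfg$n_perm,
                          seed = derive_seed(cfg$seed, 62L))
      list(profile = prof, dist = d, permanova = omnibus, pairwise = pw,
           pcoa = pcoa(d, 2))
    })
  })
  for (kg in names(results$diversity)) {
    dv <- results$diversity[[kg]]
    utils::write.table(dv$profile, file.path(out, paste0(kg, "_hill.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dv$pairwise, file.path(out, paste0(kg, "_beta_pairwise.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest$stages$diversity <- as.vector(outer(names(filtered),
                                               c("_hill.tsv", "_beta_pairwise.tsv"), paste0))

  # ---- heterogeneity -------------------------------------------------------
  results$tple <- stage("tple", {
    lapply(filtered, function(t) {
      fits <- tple_by_group(t, meta)
      tab <- do.call(rbind, lapply(fits, function(f)
        data.frame(group = f$group, b = f$b, ln_a = f$ln_a, R = f$R,
                   p = f$p, n = f$n)))
      tab
    })
  })
  for (kg in names(results$tple))
    utils::write.table(results$tple[[kg]], file.path(out, paste0(kg, "_tple.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$tple <- paste0(names(filtered), "_tple.tsv")

  # ---- shared species ------------------------------------------------------
  results$shared <- stage("shared", {
    lapply(filtered, function(t) {
      g <- group_vector(meta, sample_ids(t))
      prs <- t(utils::combn(intersect(stage_groups(), unique(g)), 2))
      do.call(rbind, lapply(seq_len(nrow(prs)), function(i) {
        a <- names(g)[g == prs[i, 1]]; b <- names(g)[g == prs[i, 2]]
        r <- a2_null(t, a, b, n_perm = min(cfg$n_perm, 299),
                     seed = derive_seed(cfg$seed, 70L + i))
        data.frame(group_a = prs[i, 1], group_b = prs[i, 2],
                   observed = r$observed, null_mean = r$null_mean,
                   null_sd = r$null_sd, p = r$p)
      }))
    })
  })
  for (kg in names(results$shared))
    utils::write.table(results$shared[[kg]], file.path(out, paste0(kg, "_shared.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$shared <- paste0(names(filtered), "_shared.tsv")

  # ---- biomarker screen ----------------------------------------------------
  results$lefse <- stage("lefse", {
    lapply(filtered, function(t) {
      rel <- to_relative(t)
      lda_effect_size(rel, group_vector(meta, sample_ids(t)),
                      lda_threshold = cfg$lda_threshold,
                      seed = derive_seed(cfg$seed, 81L))
    })
  })
  for (kg in names(results$lefse))
    utils::write.table(results$lefse[[kg]], file.path(out, paste0(kg, "_effect_size.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$lefse <- paste0(names(filtered), "_effect_size.tsv")

  # ---- networks ------------------------------------------------------------
  results$networks <- stage("network", {
    g_all <- group_vector(meta)
    nets <- list()
    for (grp in cfg$network_groups) {
      ids_b <- intersect(sample_ids(filtered$bacteria), names(g_all)[g_all == grp])
      ids_f <- intersect(sample_ids(filtered$fungi), names(g_all)[g_all == grp])
      ids <- intersect(ids_b, ids_f)
      if (length(ids) < 4) {
        logmsg("network stage for %s skipped: only %d samples", grp, length(ids))
        next
      }
      comb <- feature_table(rbind(filtered$bacteria$counts[, ids, drop = FALSE],
                                  filtered$fungi$counts[, ids, drop = FALSE]))
      # keep the most prevalent taxa so the basis system stays well-posed
      keep <- order(rowSums(comb$counts > 0), rowSums(comb$counts),
                    decreasing = TRUE)[seq_len(min(40, nrow(comb$counts)))]
      comb <- feature_table(comb$counts[sort(keep), , drop = FALSE])
      fit <- sparcc(comb, n_iterations = cfg$sparcc_iterations,
                    seed = derive_seed(cfg$seed, 90L + match(grp, cfg$network_groups)))
      fit <- edge_significance(comb, fit, n_perm = cfg$sparcc_permutations,
                               seed = derive_seed(cfg$seed, 95L + match(grp, cfg$network_groups)))
      net <- suppressWarnings(build_network(fit, cfg$r_min, cfg$q_max))
      net <- backbone(mcode_cores(net))
      write_network(net, file.path(out, paste0("network_", grp, ".tsv")))
      logmsg("network %s: %d nodes, %d edges", grp, nrow(net$nodes), nrow(net$edges))
      nets[[grp]] <- net
    }
    nets
  })
  manifest$stages$network <- paste0("network_", names(results$networks), ".tsv")

  if (all(c("HC", "ESIN", "ESCC") %in% names(results$networks))) {
    results$functional_group <- stage("functional_group", {
      fg <- functional_group(results$networks$HC, results$networks$ESIN,
                             results$networks$ESCC)
      writeLines(fg$species, file.path(out, "functional_group.txt"))
      fg
    })
    manifest$stages$functional_group <- "functional_group.txt"
  } else {
    logmsg("functional-group stage skipped: missing one of HC/ESIN/ESCC networks")
  }

  # ---- clinical ------------------------------------------------------------
  results$clinical <- stage("clinstats", {
    covs <- cfg$covariates %||% setdiff(names(meta), c("sample_id", "group"))
    covs <- covs[vapply(covs, function(cv) !anyNA(meta[[cv]]) ||
                          any(!is.na(meta[[cv]])), logical(1))]
    sub <- meta[stats::complete.cases(meta[covs]), , drop = FALSE]
    summary_table(sub, covs)
  })
  utils::write.table(results$clinical, file.path(out, "clinical_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$clinstats <- "clinical_table.tsv"

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logmsg("pipeline complete: %d stages written to %s",
         length(manifest$stages), out)
  invisible(results)
}
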
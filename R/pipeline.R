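# End-to-end orchestration: simulate -> preprocess -> DE -> network ->
# scenario -> popgen -> enrichment from a single config, with deterministic
# per-stage seeding and a written manifest.

#' Default pipeline configuration
#'
#' A nested list mirroring the module specifications; every block can be
#' overridden and the whole structure round-trips through YAML. Stage
#' toggles live under `stages`.
#'
#' @param seed global seed; per-stage seeds are derived deterministically
#'   from it (see the manifest).
#' @return Configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, preprocess = TRUE, de = TRUE,
                  network = TRUE, scenario = TRUE, popgen = TRUE,
                  enrich = TRUE),
    design = list(n_replicates = c(H = 7, O = 6, HH = 7, HO = 7,
                                   OO = 5, OH = 6)),
    effects = list(constitutive_host = 0.08, ch_plastic = 0.005,
                   co_plastic = 0, reciprocal_plastic = 0, stress = 0.02,
                   lfc_location = 0.5, lfc_scale = 0.75,
                   inversion_enrichment_odds = 3.0),
    modules = list(n_modules = 4, size_min = 40, size_max = 60,
                   drivers = c("host_race", "stress", "ch_plastic", "none"),
                   factor_noise_sd = 1.2),
    genome = list(n_linkage_groups = 6, lg_length_bp = 5e7,
                  inversion_lg = 3, inversion_start = 1e7,
                  inversion_end = 3e7, n_genes = 4000),
    popsim = list(window_size_bp = 50000, sites_per_window = 100,
                  n1 = 20, n2 = 20, f_background = 0.02,
                  f_inversion = 0.30),
    filter = list(min_count = 5, min_samples = 6),
    de = list(s_threshold = 0.001, min_replicates_for_replace = 8,
              contrasts = list(c("H", "O"), c("HH", "OO"),
                               c("HH", "HO"), c("OO", "OH"))),
    network = list(scale_free_target = 0.8, min_module_size = 30,
                   merge_correlation = 0.70, kme_threshold = 0.5),
    scenario = list(r_threshold = 0.5, p_threshold = 0.01),
    popgen = list(min_coverage = 0.2),
    enrich = list(flank = 2000))
}

.cfg_specs <- function(config) {
  list(
    design = design_spec(config$design$n_replicates),
    effects = do.call(effect_class_spec, config$effects),
    modules = module_plant_spec(
      n_modules = config$modules$n_modules,
      size_range = c(config$modules$size_min, config$modules$size_max),
      drivers = config$modules$drivers,
      factor_noise_sd = config$modules$factor_noise_sd),
    genome = genome_spec(
      n_linkage_groups = config$genome$n_linkage_groups,
      lg_length_bp = config$genome$lg_length_bp,
      inversion = c(config$genome$inversion_lg,
                    config$genome$inversion_start,
                    config$genome$inversion_end),
      n_genes = config$genome$n_genes),
    popsim = do.call(popsim_spec, config$popsim),
    network = network_params(
      scale_free_target = config$network$scale_free_target,
      min_module_size = config$network$min_module_size,
      merge_correlation = config$network$merge_correlation,
      kme_threshold = config$network$kme_threshold))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every enabled stage, writes all stage outputs as TSVs plus a
#' manifest (`manifest.tsv`: file, md5, seed, package version) into
#' `outdir`, and returns the in-memory results. Reruns with the same config
#' reproduce every deterministic output bit-exactly. Enrichment against
#' outlier windows is skipped (with explicit status) when the popgen stage
#' is disabled.
#'
#' @param config configuration list from [default_config()] (or a YAML file
#'   path).
#' @param outdir output directory (created).
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  specs <- .cfg_specs(config)
  seed <- config$seed
  res <- list(config = config)
  on <- function(st) isTRUE(config$stages[[st]])

  if (on("simulate")) {
    genes <- simulate_genome(specs$genome, stage_seed(seed, "genome"))
    sim <- simulate_counts(specs$design, specs$effects, specs$modules,
                           genes, stage_seed(seed, "counts"))
    freqs <- simulate_allele_freqs(specs$popsim, specs$genome,
                                   stage_seed(seed, "sites"))
    write_fixtures(outdir, counts = sim$counts, samples = sim$samples,
                   genes = genes, truth = sim$truth, sites = freqs$sites,
                   coverage = freqs$coverage, config = config)
    res$genes <- genes; res$sim <- sim; res$freqs <- freqs
  } else stop("the pipeline starts from simulated data; enable 'simulate'")

  if (on("preprocess")) {
    filt <- filter_genes(sim$counts, config$filter$min_count,
                         config$filter$min_samples)
    sf <- size_factors(filt)
    norm <- moderated_log(filt, sf)
    pca <- pca_top_variable(norm, n_top = min(5000, nrow(norm)))
    utils::write.table(pca$scores, file.path(outdir, "pca_scores.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    res$filtered <- filt; res$sf <- sf; res$norm <- norm; res$pca <- pca
    res$sample_tree <- sample_clustering(norm)
  }

  if (on("de")) {
    cond <- factor(sim$samples$treatment, levels = TREATMENTS)
    disp <- estimate_dispersions(res$filtered, res$sf, cond)
    fit <- fit_nb_glm(res$filtered, res$sf, disp, cond)
    fit <- cooks_outliers(fit, config$de$min_replicates_for_replace)
    res$fit <- fit
    res$de <- lapply(config$de$contrasts, function(ct)
      de_contrast(fit, unlist(ct), config$de$s_threshold))
    names(res$de) <- vapply(config$de$contrasts,
                            function(ct) paste(unlist(ct), collapse = "_vs_"),
                            character(1))
    for (nm in names(res$de))
      utils::write.table(res$de[[nm]],
                         file.path(outdir, paste0("de_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (on("network")) {
    ms <- coexpression_modules(res$norm, specs$network)
    res$modules <- ms
    utils::write.table(
      data.frame(gene = names(ms$assignment),
                 module = module_label(ms$assignment), kme = ms$kme),
      file.path(outdir, "modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(ms$eigengenes, file.path(outdir, "eigengenes.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }

  if (on("scenario") && on("network")) {
    dv <- build_design_vectors(sim$samples)
    sc <- correlate_modules(res$modules$eigengenes, dv,
                            config$scenario$r_threshold,
                            config$scenario$p_threshold)
    res$scenario <- sc
    res$module_labels <- classify_modules(sc)
    utils::write.table(sc, file.path(outdir, "scenario_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (on("popgen")) {
    ws <- window_stats(freqs$sites, contig_lengths(genes),
                       config$popsim$window_size_bp,
                       coverage = freqs$coverage,
                       min_coverage = config$popgen$min_coverage)
    res$windows <- ws
    utils::write.table(ws, file.path(outdir, "window_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    comp <- ws[which(ws$composite), c("chrom", "start", "end")]
    utils::write.table(comp, file.path(outdir, "outliers.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }

  if (on("enrich")) {
    expressed <- rownames(res$filtered)
    gsub <- genes[genes$gene_id %in% expressed, , drop = FALSE]
    inv_genes <- gsub$gene_id[gsub$inside_inversion]
    de_set <- res$de[["H_vs_O"]]
    de_genes <- de_set$gene[de_set$svalue < config$de$s_threshold]
    tests <- list(
      de_in_inversion = hypergeom_enrichment(de_genes, inv_genes, expressed))
    if (on("popgen")) {
      map <- intersect_genes_windows(gsub, res$windows,
                                     config$enrich$flank)
      out_genes <- intersect(outlier_genes(map, res$windows), expressed)
      tests$de_in_outlier_windows <-
        hypergeom_enrichment(de_genes, out_genes, expressed)
      res$gene_window_map <- map
    } else {
      tests$de_in_outlier_windows <- NULL
      res$enrich_status <- "popgen disabled; outlier-window test skipped"
    }
    enr <- do.call(rbind, tests)
    enr$test <- rownames(enr)
    enr$padj <- bh_adjust(enr$p)
    res$enrichment <- enr
    utils::write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  files <- setdiff(list.files(outdir), "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = as.character(tools::md5sum(file.path(outdir, files))),
    seed = seed,
    version = as.character(utils::packageVersion("hostshift")),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res$manifest <- manifest
  res$outdir <- outdir
  invisible(res)
}

#' Summary report of a pipeline run
#'
#' Collates DE counts per contrast, the module table with scenario labels,
#' outlier-window counts and the enrichment table into one summary list,
#' and writes `report.tsv` blocks if `outdir` is given. Missing stages are
#' reported as explicit gaps rather than dropped rows.
#'
#' @param res result list from [run_pipeline()].
#' @param outdir optional directory for `report.tsv`.
#' @return List of summary tables.
#' @export
pipeline_report <- function(res, outdir = NULL) {
  de_tab <- if (!is.null(res$de)) {
    do.call(rbind, lapply(names(res$de), function(nm) {
      r <- res$de[[nm]]
      data.frame(contrast = nm, up = sum(r$call == 1),
                 down = sum(r$call == -1), stringsAsFactors = FALSE)
    }))
  } else data.frame(contrast = "(de stage not run)", up = NA, down = NA)
  mod_tab <- if (!is.null(res$modules)) {
    sizes <- table(module_label(res$modules$assignment))
    lab <- res$module_labels$labels %||% list()
    data.frame(module = names(sizes), n_genes = as.integer(sizes),
               labels = vapply(names(sizes), function(m)
                 paste(lab[[m]] %||% character(0), collapse = ";"),
                 character(1)),
               stringsAsFactors = FALSE)
  } else data.frame(module = "(network stage not run)", n_genes = NA,
                    labels = NA)
  win_tab <- if (!is.null(res$windows)) {
    data.frame(windows = nrow(res$windows),
               composite_outliers = sum(res$windows$composite, na.rm = TRUE))
  } else data.frame(windows = NA, composite_outliers = NA)
  rep <- list(de = de_tab, modules = mod_tab, windows = win_tab,
              enrichment = res$enrichment %||%
                data.frame(note = "(enrichment stage not run)"))
  if (!is.null(outdir)) {
    f <- file.path(outdir, "report.tsv")
    con <- file(f, "w")
    for (nm in names(rep)) {
      writeLines(paste0("# ", nm), con)
      utils::write.table(rep[[nm]], con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      writeLines("", con)
    }
    close(con)
  }
  rep
}
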
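pipelineStages <- c("simulate", "score", "tfactivity", "vko",
                    "survival", "spatial")

#' Validate a pipeline run configuration
#'
#' A config is a named list (or YAML file) with global keys `seed` and
#' `outdir` plus one block per stage; unknown keys are rejected. All
#' randomness flows from the single global seed via named substreams, so a
#' rerun with an identical config reproduces identical outputs.
#'
#' @param config a named list or path to a YAML file.
#' @return The validated config list with defaults filled in.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("seed", "outdir", pipelineStages)
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 1L)
  if (is.null(config$outdir)) stop("config must set 'outdir'")
  stageKnown <- list(
    simulate = c("enabled", "n_genes", "n_cells", "rho_planted",
                 "library_size_mean", "nb_dispersion", "matrix_dir"),
    score = c("enabled", "method", "gmt", "n_bins", "n_ctrl", "tau"),
    tfactivity = c("enabled", "regulons_gmt", "min_overlap"),
    vko = c("enabled", "regulator", "rho_min", "p_max", "min_cells"),
    survival = c("enabled", "n_subjects", "effect_scale", "censoring_rate",
                 "model_csv", "cohort_csv"),
    spatial = c("enabled", "n_spots_side", "gradient_high", "gradient_low",
                "k"))
  for (st in pipelineStages) {
    block <- config[[st]] %||% list()
    bad <- setdiff(names(block), stageKnown[[st]])
    if (length(bad))
      stop("unknown key(s) in '", st, "' block: ", paste(bad, collapse = ", "))
    block$enabled <- isTRUE(block$enabled %||% TRUE)
    config[[st]] <- block
  }
  # referenced input paths must exist before any stage runs
  for (pth in c(config$score$gmt, config$tfactivity$regulons_gmt,
                config$survival$model_csv, config$survival$cohort_csv,
                config$simulate$matrix_dir)) {
    if (!is.null(pth) && !file.exists(pth))
      stop("configured input does not exist: ", pth)
  }
  config
}

#' Run the ferroptosis pipeline from one configuration
#'
#' Executes the enabled stages in dependency order — simulate (or load) a
#' single-cell matrix, score the five ferroptosis axes, score TF regulon
#' activity and rank by resistance correlation, run the virtual knockout,
#' run the survival stratification on a simulated (or supplied) cohort, and
#' score/cluster/test a spatial grid — writing per-stage CSV/JSON outputs
#' and a manifest of parameters, seeds and output checksums.
#'
#' @param config a named list or YAML path (see [validateRunConfig()]).
#' @param outdir optional override of the configured output directory.
#' @return The manifest list, invisibly; written to `manifest.json`.
#' @export
runPipeline <- function(config, outdir = NULL) {
  config <- validateRunConfig(config)
  if (!is.null(outdir)) config$outdir <- outdir
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  outputs <- character(0)
  note <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      seed = substreamSeed(config$seed, stage),
      params = params, outputs = files)
    outputs <<- c(outputs, files)
  }
  runStage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      manifest$partial <- TRUE
      writeManifest(manifest, outdir)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  se <- NULL; scores <- NULL; tfres <- NULL
  sets <- if (!is.null(config$score$gmt))
    readGMT(config$score$gmt) else ferroptosisGeneSets()

  if (config$simulate$enabled) runStage("simulate", function() {
    blk <- config$simulate
    if (!is.null(blk$matrix_dir)) {
      se <<- readExpression(blk$matrix_dir)
    } else {
      cfg <- simConfig(
        nGenes = blk$n_genes %||% 300, nCells = blk$n_cells %||% 2000,
        rhoPlanted = blk$rho_planted %||% 0.5,
        librarySizeMean = blk$library_size_mean %||% 2500,
        nbDispersion = blk$nb_dispersion %||% 10,
        seed = substreamSeed(config$seed, "simulate"))
      sim <- simulateSingleCell(cfg)
      se <<- sim$se
      writeExpression(se, file.path(outdir, "sc"), truth = sim$truth)
    }
    note("simulate", config$simulate, file.path(outdir, "sc", "matrix.mtx"))
  })
  if (is.null(se)) stop("downstream stages need the simulate stage")
  se <- normalizeLogNorm(se)

  if (config$score$enabled) runStage("score", function() {
    blk <- config$score
    scores <<- scoreCollection(
      se, sets, method = blk$method %||% "module",
      nBins = blk$n_bins %||% 25, nCtrl = blk$n_ctrl %||% 50,
      tau = blk$tau %||% 0.25,
      seed = substreamSeed(config$seed, "score"))
    f <- file.path(outdir, "scores.csv")
    writeScores(scores, f)
    note("score", blk, f)
  })

  if (config$tfactivity$enabled) runStage("tfactivity", function() {
    blk <- config$tfactivity
    regulons <- if (!is.null(blk$regulons_gmt))
      readGMT(blk$regulons_gmt) else tfRegulons()
    tfres <<- scoreTFActivity(se, regulons,
                              minOverlap = blk$min_overlap %||% 5)
    ferro <- scoreMatrix(scores)[, "ferroptosis_all"]
    ranked <- correlateWithResistance(tfres, ferro)
    f <- file.path(outdir, "tf_activity.csv")
    writeScores(tfres$activity, f)
    f2 <- file.path(outdir, "tf_resistance_ranking.csv")
    write.csv(ranked, f2, row.names = FALSE)
    note("tfactivity", blk, c(f, f2))
  })

  if (config$vko$enabled) runStage("vko", function() {
    blk <- config$vko
    ko <- virtualKO(se, regulator = blk$regulator %||% "NFE2L2",
                    sets = sets,
                    rhoMin = blk$rho_min %||% 0.1,
                    pMax = blk$p_max %||% 0.05,
                    minCells = blk$min_cells %||% 5)
    fw <- file.path(outdir, "vko_weights.csv")
    write.csv(data.frame(gene = names(ko$weights@rho),
                         rho = ko$weights@rho, p = ko$weights@p,
                         p_adj = ko$weights@pAdj, mask = ko$weights@mask),
              fw, row.names = FALSE)
    fd <- file.path(outdir, "vko_deltas.csv")
    ad <- koAxisDelta(ko$result)
    write.csv(cbind(data.frame(observation_id = names(koDelta(ko$result)),
                               delta_overall = koDelta(ko$result),
                               responder = responderLabels(ko$result)),
                    as.data.frame(ad)),
              fd, row.names = FALSE)
    fc <- file.path(outdir, "vko_celltype.csv")
    write.csv(ko$cellTypeTable, fc, row.names = FALSE)
    fm <- file.path(outdir, "vko_markers.csv")
    write.csv(ko$markers, fm, row.names = FALSE)
    note("vko", blk, c(fw, fd, fc, fm))
  })

  if (config$survival$enabled) runStage("survival", function() {
    blk <- config$survival
    model <- if (!is.null(blk$model_csv))
      readSignatureModel(blk$model_csv) else prognosticSignature()
    cohort <- if (!is.null(blk$cohort_csv)) readSurvivalCohort(blk$cohort_csv)
    else simulateSurvivalCohort(
      n = blk$n_subjects %||% 400, signature = model,
      effectScale = blk$effect_scale %||% 1,
      censoringRate = blk$censoring_rate %||% 0.3,
      seed = substreamSeed(config$seed, "survival"))$cohort
    strat <- survivalStratification(cohort, model)
    fg <- file.path(outdir, "survival_groups.csv")
    write.csv(strat$cohort[, c("subject_id", "time", "event",
                               "risk_score", "risk_group")],
              fg, row.names = FALSE)
    fk <- file.path(outdir, "survival_km.csv")
    km <- rbind(cbind(group = "high", as.data.frame(strat$km$high)),
                cbind(group = "low", as.data.frame(strat$km$low)))
    write.csv(km, fk, row.names = FALSE)
    ft <- file.path(outdir, "survival_tests.json")
    jsonlite::write_json(
      list(logrank_chisq = strat$logrank$statistic,
           logrank_p = strat$logrank$p_value,
           cindex = strat$cindex,
           missing_genes = strat$missing_genes),
      ft, auto_unbox = TRUE, digits = NA)
    note("survival", blk, c(fg, fk, ft))
  })

  if (config$spatial$enabled) runStage("spatial", function() {
    blk <- config$spatial
    sim <- simulateSpatial(
      nSpotsSide = blk$n_spots_side %||% 8,
      gradientHigh = blk$gradient_high %||% 4,
      gradientLow = blk$gradient_low %||% 2,
      seed = substreamSeed(config$seed, "spatial"))
    sp <- normalizeLogNorm(sim$sp)
    st <- spotScores(sp, sets,
                     seed = substreamSeed(config$seed, "spatial_score"))
    sp <- buildKnnGraph(sp, k = blk$k %||% 6)
    sp <- clusterGraph(sp, seed = substreamSeed(config$seed, "spatial_clust"))
    ferro <- scoreMatrix(st)[, "ferroptosis_all"]
    kw <- clusterScoreTest(ferro,
                           SummarizedExperiment::colData(sp)$cluster)
    fs <- file.path(outdir, "spatial_scores.csv")
    writeScores(st, fs)
    fc <- file.path(outdir, "spatial_clusters.csv")
    cd <- SummarizedExperiment::colData(sp)
    write.csv(data.frame(spot_id = rownames(cd), x = cd$x, y = cd$y,
                         region = cd$region, cluster = cd$cluster),
              fc, row.names = FALSE)
    ft <- file.path(outdir, "spatial_test.json")
    jsonlite::write_json(
      list(kw_statistic = kw$statistic, kw_p = kw$p_value,
           medians = as.list(kw$medians)),
      ft, auto_unbox = TRUE, digits = NA)
    note("spatial", blk, c(fs, fc, ft))
  })

  missing <- outputs[!file.exists(outputs)]
  if (length(missing)) {
    manifest$partial <- TRUE
    stop("declared outputs missing: ", paste(missing, collapse = ", "))
  }
  manifest$checksums <- as.list(tools::md5sum(outputs))
  writeManifest(manifest, outdir)
  invisible(manifest)
}

writeManifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Path to the bundled demo pipeline configuration
#'
#' A small end-to-end configuration over the bundled synthetic fixtures.
#'
#' @return File path of `demo_run.yaml`.
#' @export
demoConfig <- function() {
  system.file("extdata", "demo_run.yaml", package = "ferroscope")
}
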
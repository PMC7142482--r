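#' Pipeline configuration and orchestration
#'
#' A single YAML configuration drives the full chain simulate -> preprocess
#' -> quantify -> statistics -> flux. Each stage writes CSV/TSV artifacts
#' plus a JSON provenance sidecar (`<file>.prov.json`) recording the package
#' version, the canonical config hash, the seed and the stage parameters —
#' enough to re-run the stage exactly. With a fixed seed the data artifacts
#' are byte-identical across runs. Stages whose inputs are supplied
#' externally (a directory of measured spectra, or a ready concentration
#' table) are skipped.
#'
#' @name pipeline
NULL

pipelineSchema <- function() {
  list(
    seed = NULL, outputDir = NULL,
    inputs = list(spectraDir = NULL, metadataCsv = NULL,
                  concentrationsCsv = NULL),
    simulate = list(nMetabolites = NULL, gridPoints = NULL, groups = NULL,
                    replicates = NULL, baseConcentration = NULL,
                    effects = NULL, biologicalCV = NULL, noiseSd = NULL,
                    shiftJitterSd = NULL, baselineAmp = NULL),
    preprocess = list(normalization = NULL, referenceWindow = NULL,
                      alignment = NULL, maxShift = NULL,
                      excludeWater = NULL, waterWindow = NULL),
    quantify = list(plsComponents = NULL),
    stats = list(labels = NULL, anovaThreshold = NULL, pcaComponents = NULL,
                 corrDiff = list(groupA = NULL, groupB = NULL),
                 ora = list(gmt = NULL)),
    flux = list(network = NULL, contexts = NULL, cutoff = NULL,
                objectiveFraction = NULL)
  )
}

collectUnknownKeys <- function(cfg, schema, prefix = "") {
  bad <- character(0)
  for (k in names(cfg)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    if (!k %in% names(schema)) bad <- c(bad, full)
    else if (is.list(schema[[k]]) && length(schema[[k]]) && is.list(cfg[[k]]))
      bad <- c(bad, collectUnknownKeys(cfg[[k]], schema[[k]], full))
  }
  bad
}

#' Validate a pipeline configuration file
#'
#' Reads the YAML config, applies defaults and collects *all* problems
#' (unknown keys, out-of-range values, missing input files) into a single
#' error, so a broken config is diagnosed in one pass.
#'
#' @param path YAML configuration file.
#' @return A `RunConfig` (classed list) on success; otherwise an error
#'   listing every problem found.
#' @export
validateConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  # resolve file references relative to the config's own directory
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) return(p)
    cand <- file.path(base, p)
    if (file.exists(cand)) cand else p
  }
  for (k in c("spectraDir", "metadataCsv", "concentrationsCsv"))
    cfg$inputs[[k]] <- resolve(cfg$inputs[[k]])
  cfg$stats$ora$gmt <- resolve(cfg$stats$ora$gmt)
  if (!is.null(cfg$flux$network) &&
      !cfg$flux$network %in% c("chain", "branched", "mini_tca",
                               "glutathione"))
    cfg$flux$network <- resolve(cfg$flux$network)
  errs <- character(0)
  errs <- c(errs, vapply(collectUnknownKeys(cfg, pipelineSchema()),
                         function(k) paste0("unknown key: ", k),
                         character(1)))
  num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (is.null(cfg$seed) || !num(cfg$seed))
    errs <- c(errs, "seed: required integer")
  sim <- cfg$simulate
  if (!is.null(sim)) {
    if (!is.null(sim$noiseSd) && (!num(sim$noiseSd) || sim$noiseSd < 0))
      errs <- c(errs, "simulate.noiseSd: must be a number >= 0")
    if (!is.null(sim$shiftJitterSd) &&
        (!num(sim$shiftJitterSd) || sim$shiftJitterSd < 0))
      errs <- c(errs, "simulate.shiftJitterSd: must be a number >= 0")
    if (!is.null(sim$baselineAmp) &&
        (!num(sim$baselineAmp) || sim$baselineAmp < 0))
      errs <- c(errs, "simulate.baselineAmp: must be a number >= 0")
    if (!is.null(sim$replicates) && (!num(sim$replicates) ||
                                     sim$replicates < 1))
      errs <- c(errs, "simulate.replicates: must be >= 1")
    if (!is.null(sim$nMetabolites) &&
        (!num(sim$nMetabolites) || sim$nMetabolites < 1 ||
         sim$nMetabolites > 20))
      errs <- c(errs, "simulate.nMetabolites: must be 1..20")
  }
  fx <- cfg$flux
  if (!is.null(fx)) {
    if (!is.null(fx$network) &&
        !fx$network %in% c("chain", "branched", "mini_tca", "glutathione") &&
        !file.exists(fx$network))
      errs <- c(errs, paste0("flux.network: not a toy network kind or ",
                             "existing model file: ", fx$network))
    if (!is.null(fx$objectiveFraction) &&
        (!num(fx$objectiveFraction) || fx$objectiveFraction <= 0 ||
         fx$objectiveFraction > 1))
      errs <- c(errs, "flux.objectiveFraction: must be in (0, 1]")
  }
  inp <- cfg$inputs
  if (!is.null(inp)) {
    for (k in c("spectraDir", "metadataCsv", "concentrationsCsv"))
      if (!is.null(inp[[k]]) && !file.exists(inp[[k]]))
        errs <- c(errs, sprintf("inputs.%s: file not found: %s", k,
                                inp[[k]]))
  }
  if (!is.null(cfg$stats$ora$gmt) && !file.exists(cfg$stats$ora$gmt))
    errs <- c(errs, paste0("stats.ora.gmt: file not found: ",
                           cfg$stats$ora$gmt))
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(cfg, class = "RunConfig", sourcePath = path)
}

# canonical hash of a config: keys sorted recursively, stable serialization
configHash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x)) && any(nzchar(names(x))))
        x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  attributes(cfg) <- attributes(cfg)["names"]
  txt <- jsonlite::toJSON(canon(unclass(cfg)), auto_unbox = TRUE,
                          digits = NA)
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(as.character(txt), tf)
  unname(tools::md5sum(tf))
}

writeProvenance <- function(artifact, stage, params, cfg, seed) {
  prov <- list(
    tool = "nmrflux",
    version = as.character(utils::packageVersion("nmrflux")),
    configHash = configHash(cfg),
    seed = seed,
    stage = stage,
    parameters = params,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, paste0(artifact, ".prov.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# default per-group effect layout used when the config gives none
defaultGroups <- function() {
  data.frame(cellLine = c("LN18", "A172", "U118", "NHA"),
             sourceType = "cell")
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate -> preprocess -> quantify -> statistics -> flux in
#' order, writing every artifact under the output directory together with
#' its provenance sidecar. A failing stage halts the run with the stage
#' named. Stages are skipped when the config supplies their outputs as
#' external inputs.
#'
#' @param config a `RunConfig` from [validateConfig()], or a path to one.
#' @param outDir output directory; overrides `config$outputDir`.
#' @param verbose log stage progress to stderr.
#' @return Invisibly, a named list of written artifact paths.
#' @export
runPipeline <- function(config, outDir = NULL, verbose = TRUE) {
  if (is.character(config)) config <- validateConfig(config)
  cfg <- config
  seed <- as.integer(cfg$seed)
  out <- outDir %||% cfg$outputDir %||% "nmrflux_out"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[nmrflux] ", sprintf(...))
  artifacts <- list()
  stage <- "simulate"
  res <- tryCatch({
    sim <- cfg$simulate %||% list()
    nMet <- sim$nMetabolites %||% 12L
    grid <- defaultGrid(sim$gridPoints %||% 4096L)
    defs <- defaultMetabolites(nMet)
    lib <- makeSpectralLibrary(defs, grid)
    skipSpectra <- !is.null(cfg$inputs$concentrationsCsv) &&
      is.null(cfg$inputs$spectraDir)

    if (skipSpectra) {
      say("simulate: skipped (external concentrations supplied)")
      spectra <- list()
    } else if (!is.null(cfg$inputs$spectraDir)) {
      say("simulate: skipped (external spectra supplied)")
      md <- read.csv(cfg$inputs$metadataCsv)
      spectra <- lapply(seq_len(nrow(md)), function(i)
        readSpectrumTSV(file.path(cfg$inputs$spectraDir,
                                  paste0(md$sampleId[i], ".tsv")),
                        sampleId = md$sampleId[i],
                        cellLine = md$cellLine[i],
                        sourceType = md$sourceType[i],
                        replicate = md$replicate[i]))
      truth <- NULL
    } else {
      groups <- if (is.null(sim$groups)) defaultGroups()
                else do.call(rbind, lapply(sim$groups, as.data.frame))
      baseLevel <- sim$baseConcentration %||% 1.0
      base <- setNames(rep(baseLevel, nMet),
                       vapply(defs, `[[`, character(1), "name"))
      effects <- lapply(sim$effects %||% list(), function(e)
        unlist(e))
      design <- cohortDesign(
        groups = groups, replicatesPerGroup = sim$replicates %||% 3L,
        baseConcentrations = base, effects = effects,
        biologicalCV = sim$biologicalCV %||% 0.1,
        noiseSd = sim$noiseSd %||% 0,
        shiftJitterSd = sim$shiftJitterSd %||% 0,
        baselineAmp = sim$baselineAmp %||% 0, seed = seed)
      cohort <- makeCohort(design, defs, grid)
      spectra <- cohort$spectra
      truth <- cohort$truth
      specDir <- file.path(out, "spectra")
      dir.create(specDir, showWarnings = FALSE)
      for (s in spectra)
        writeSpectrumTSV(s, file.path(specDir, paste0(s@sampleId, ".tsv")))
      mdPath <- file.path(out, "metadata.csv")
      md <- data.frame(
        sampleId = vapply(spectra, slot, character(1), "sampleId"),
        cellLine = vapply(spectra, slot, character(1), "cellLine"),
        sourceType = vapply(spectra, slot, character(1), "sourceType"),
        replicate = vapply(spectra, slot, integer(1), "replicate"))
      write.csv(md, mdPath, row.names = FALSE, quote = FALSE)
      gtPath <- file.path(out, "ground_truth.csv")
      writeConcentrationTable(truth, gtPath)
      writeProvenance(gtPath, "simulate", sim, cfg, seed)
      writeProvenance(mdPath, "simulate", sim, cfg, seed)
      artifacts$groundTruth <- gtPath
      artifacts$metadata <- mdPath
      say("simulate: %d spectra on %d grid points", length(spectra),
          length(grid))
    }

    stage <- "preprocess"
    pp <- cfg$preprocess %||% list()
    norm <- pp$normalization %||% "none"
    if (!skipSpectra) {
    spectra <- lapply(spectra, function(s) {
      s <- phaseCorrect(s)
      switch(norm,
        none = s,
        reference = normalizeReferencePeak(
          s, pp$referenceWindow %||% c(-0.05, 0.05)),
        total = normalizeTotalArea(s),
        stop("unknown normalization mode: ", norm))
    })
    alignMode <- pp$alignment %||% "none"
    if (alignMode == "fft") {
      ref <- spectra[[1]]
      spectra <- lapply(spectra, function(s)
        alignFFT(s, ref, pp$maxShift %||% 50L)$spectrum)
    } else if (alignMode == "icoshift") {
      rng <- range(ppm(spectra[[1]]))
      spectra <- alignIcoshift(spectra, list(rng),
                               maxShift = pp$maxShift %||% 50L)
    }
    say("preprocess: normalization=%s alignment=%s", norm, alignMode)
    }

    stage <- "quantify"
    if (!is.null(cfg$inputs$concentrationsCsv)) {
      say("quantify: skipped (external concentrations supplied)")
      ct <- readConcentrationTable(cfg$inputs$concentrationsCsv,
                                   cfg$inputs$metadataCsv)
    } else {
      ct <- quantifyCohort(lib, spectra,
                           plsComponents = cfg$quantify$plsComponents %||%
                             min(10L, nMet))
      ctPath <- file.path(out, "concentrations.csv")
      writeConcentrationTable(ct, ctPath)
      writeProvenance(ctPath, "quantify", cfg$quantify %||% list(), cfg,
                      seed)
      artifacts$concentrations <- ctPath
      say("quantify: %d samples x %d metabolites", nrow(concentrations(ct)),
          ncol(concentrations(ct)))
    }

    stage <- "statistics"
    st <- cfg$stats %||% list()
    labels <- st$labels %||% "cellLine"
    rk <- anovaRank(ct, labels, threshold = st$anovaThreshold %||% 5)
    rkPath <- file.path(out, "anova_ranking.csv")
    write.csv(rk, rkPath, row.names = FALSE, quote = FALSE)
    writeProvenance(rkPath, "statistics", st, cfg, seed)
    artifacts$ranking <- rkPath

    pcs <- runPCA(ct, st$pcaComponents %||% 2L)
    scPath <- file.path(out, "pca_scores.csv")
    write.csv(data.frame(sampleId = rownames(pcs$scores), pcs$scores),
              scPath, row.names = FALSE, quote = FALSE)
    ldPath <- file.path(out, "pca_loadings.csv")
    write.csv(data.frame(metabolite = rownames(pcs$loadings),
                         pcs$loadings),
              ldPath, row.names = FALSE, quote = FALSE)
    writeProvenance(scPath, "statistics", st, cfg, seed)
    writeProvenance(ldPath, "statistics", st, cfg, seed)
    artifacts$pcaScores <- scPath
    artifacts$pcaLoadings <- ldPath

    if (!is.null(st$corrDiff)) {
      cd <- st$corrDiff
      pick <- function(sel) {
        m <- concentrations(ct)
        cdta <- as.data.frame(SummarizedExperiment::colData(ct))
        keep <- rep(TRUE, nrow(m))
        for (k in names(sel)) keep <- keep & cdta[[k]] %in% sel[[k]]
        m[keep, , drop = FALSE]
      }
      dr <- correlationDifference(pick(cd$groupA), pick(cd$groupB))
      drPath <- file.path(out, "correlation_difference.csv")
      write.csv(data.frame(metabolite = rownames(dr), dr,
                           check.names = FALSE),
                drPath, row.names = FALSE, quote = FALSE)
      writeProvenance(drPath, "statistics", st, cfg, seed)
      artifacts$correlationDifference <- drPath
    }

    if (!is.null(st$ora$gmt)) {
      pathways <- readGMT(st$ora$gmt)
      universe <- colnames(concentrations(ct))
      selected <- rk$metabolite[rk$selected]
      ora <- oraHypergeometric(selected, pathways, universe)
      oraPath <- file.path(out, "ora.csv")
      write.csv(ora, oraPath, row.names = FALSE, quote = FALSE)
      writeProvenance(oraPath, "statistics", st, cfg, seed)
      artifacts$ora <- oraPath
    }
    say("statistics: %d/%d metabolites selected (threshold %g)",
        sum(rk$selected), nrow(rk), st$anovaThreshold %||% 5)

    stage <- "flux"
    fx <- cfg$flux %||% list()
    if (!is.null(fx$network)) {
      model <- if (fx$network %in% c("chain", "branched", "mini_tca",
                                     "glutathione"))
        makeToyNetwork(fx$network)
      else readModel(fx$network)
      base <- fba(model)
      fbaPath <- file.path(out, "flux_fba.csv")
      writeFluxCSV(base, fbaPath)
      writeProvenance(fbaPath, "flux", fx, cfg, seed)
      artifacts$fba <- fbaPath
      contexts <- fx$contexts %||% list()
      for (ctx in names(contexts)) {
        prof <- makeExpressionProfile(model,
                                      unlist(contexts[[ctx]]))
        rxnExpr <- reactionExpression(model, prof)
        sol <- gimme(model, rxnExpr, cutoff = fx$cutoff %||% 50,
                     objectiveFraction = fx$objectiveFraction %||% 0.9)
        fp <- file.path(out, sprintf("flux_gimme_%s.csv", ctx))
        writeFluxCSV(sol, fp, rxnExpr = rxnExpr,
                     cutoff = fx$cutoff %||% 50)
        writeProvenance(fp, "flux", c(fx["cutoff"], fx["objectiveFraction"],
                                      context = ctx), cfg, seed)
        artifacts[[paste0("gimme_", ctx)]] <- fp
        sub <- contextSubnetwork(model, sol)
        sp <- file.path(out, sprintf("subnetwork_%s.json", ctx))
        writeModel(sub$model, sp, format = "json")
        writeProvenance(sp, "flux", list(context = ctx,
                                         deadEnds = sub$deadEnds),
                        cfg, seed)
        artifacts[[paste0("subnetwork_", ctx)]] <- sp
        say("flux[%s]: objective %.4g, inconsistency %.4g, %d active reactions",
            ctx, objectiveValue(sol), inconsistencyScore(sol),
            length(reactionIds(sub$model)))
      }
    }
    artifacts
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
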
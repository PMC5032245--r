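.stageOrder <- c("simulate", "entropy", "scan", "classify", "zscore",
                 "regions", "eqtm", "enrich", "replicate")
.stageDeps <- list(classify = "scan", zscore = "classify",
                   regions = "classify", eqtm = "classify",
                   enrich = "classify", replicate = "classify")

#' Run the aVMP pipeline end to end
#'
#' Chains the pipeline stages over either files on disk or a simulated
#' cohort, writing one tab-delimited output per stage plus the effective
#' configuration and a log of every threshold applied into `outDir`.
#' Stage dependencies are resolved automatically (e.g. `"zscore"` pulls
#' in `"scan"` and `"classify"`); a scan-only request writes no eQTM
#' output.  Runs with identical configuration and seed produce identical
#' output files.
#'
#' @param config a [vmpConfig()].
#' @param stages character vector of stages among `"simulate"`,
#'   `"entropy"`, `"scan"`, `"classify"`, `"zscore"`, `"regions"`,
#'   `"eqtm"`, `"enrich"`, `"replicate"`, or `"all"`.
#' @param outDir output directory (created).
#' @param paths named list of input files for file-based runs: `beta`,
#'   `cpgAnnot`, `covariates`, and per stage `expr` + `geneAnnot`
#'   (eqtm), `tracks` (enrich), `validationBeta` + `validationCovariates`
#'   (replicate).  Ignored when `"simulate"` is requested.
#' @param design a [simulationDesign()] (required with `"simulate"`).
#' @param verbose logical; echo log lines.
#' @return invisibly, a list of in-memory stage results.
#' @export
runPipeline <- function(config = vmpConfig(), stages = "all",
                        outDir, paths = list(), design = NULL,
                        verbose = TRUE) {
  stopifnot(inherits(config, "VmpConfig"))
  if (identical(stages, "all")) stages <- .stageOrder[-1]
  bad <- setdiff(stages, .stageOrder)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  repeat {
    need <- unique(unlist(.stageDeps[stages]))
    if (all(need %in% stages)) break
    stages <- union(stages, need)
  }
  stages <- .stageOrder[.stageOrder %in% stages]

  simulate <- "simulate" %in% stages || !is.null(design)
  if ("simulate" %in% stages && is.null(design))
    stop("stage 'simulate' requires a simulation design")
  if (!simulate) {
    req <- c("beta", "covariates")
    if ("eqtm" %in% stages) req <- c(req, "expr", "geneAnnot")
    if ("enrich" %in% stages) req <- c(req, "tracks")
    if ("replicate" %in% stages)
      req <- c(req, "validationBeta", "validationCovariates")
    miss <- setdiff(req, names(paths))
    if (length(miss))
      stop("missing required path(s): ", paste(miss, collapse = ", "))
  }

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "pipeline.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)
  note <- function(...) {
    line <- paste0(...)
    writeLines(line, logCon)
    if (verbose) message(line)
  }
  writeVmpConfig(config, file.path(outDir, "config.txt"))
  note("stages: ", paste(stages, collapse = ", "))
  note("thresholds: alphaBonferroni=", config$alphaBonferroni,
       " effectThresholdPerDecade=", config$effectThresholdPerDecade,
       " fdrQ=", config$fdrQ, " cisWindow=", config$cisWindow,
       " transMinDistance=", config$transMinDistance,
       " transHubFraction=", config$transHubFraction)
  set.seed(config$rngSeed)
  results <- list()

  runStage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- inputs ---------------------------------------------------------
  bset <- NULL; eset <- NULL; truth <- NULL; valBset <- NULL
  if (simulate) {
    runStage("simulate", function() {
      cohort <- simulateCohort(design)
      bset <<- cohort$beta; truth <<- cohort$truth
      if ("eqtm" %in% stages) {
        se <- simulateExpression(cohort, design)
        eset <<- se$expr; truth <<- se$truth
      }
      if ("replicate" %in% stages) {
        d2 <- design; d2$rngSeed <- design$rngSeed + 1L
        valBset <<- simulateCohort(d2)$beta
      }
      writeMatrixTsv(betaValues(bset),
                     file.path(outDir, "simulated_beta.tsv"), "cpg_id")
      writeTableTsv(truth$cpgs, file.path(outDir, "truth_cpgs.tsv"))
      if (nrow(truth$cis))
        writeTableTsv(truth$cis, file.path(outDir, "truth_cis.tsv"))
      if (nrow(truth$trans))
        writeTableTsv(truth$trans, file.path(outDir, "truth_trans.tsv"))
      note("simulated ", nrow(bset), " CpGs x ", ncol(bset), " samples")
    })
  } else {
    bset <- runStage("input", function() {
      b <- readBetaMatrix(paths$beta, paths$cpgAnnot)
      cov <- readCovariateTable(paths$covariates, config)
      if (!is.null(paths$expr))
        eset <<- readExpressionMatrix(paths$expr, paths$geneAnnot)
      al <- alignSamples(b, cov, eset, config)
      eset <<- al$expr
      note("aligned samples; dropped: ",
           paste(names(al$dropped), al$dropped, collapse = ", ",
                 sep = "="))
      al$beta
    })
  }

  # --- stages ---------------------------------------------------------
  if ("entropy" %in% stages) {
    results$entropy <- runStage("entropy", function() {
      s <- shannonEntropy(bset, config = config)
      writeTableTsv(data.frame(sample_id = names(s), entropy = s),
                    file.path(outDir, "entropy.tsv"))
      s
    })
  }
  scanTab <- NULL
  if ("scan" %in% stages) {
    scanTab <- runStage("scan", function() {
      tab <- scanVariability(bset, config)
      note("scanned ", attr(tab, "nScanned"), " CpGs; dropped fraction ",
           "covariate: ", attr(tab, "droppedFraction"))
      writeTableTsv(tab, file.path(outDir, "scan.tsv"))
      tab
    })
  }
  if ("classify" %in% stages) {
    scanTab <- runStage("classify",
                        function() classifyAvmps(scanTab, config))
    writeTableTsv(scanTab, file.path(outDir, "scan.tsv"))
    note(sum(scanTab$is_avmp_candidate), " aVMP candidate(s); classes: ",
         paste(names(table(scanTab$class_label)),
               table(scanTab$class_label), collapse = ", ", sep = "="))
  }
  results$scan <- scanTab
  avmps <- if (!is.null(scanTab))
    scanTab$cpg_id[scanTab$is_avmp_candidate &
                     scanTab$direction == "increase"]
  if ("zscore" %in% stages && length(avmps)) {
    results$zscores <- runStage("zscore", function() {
      z <- zscoreVsYoung(bset, avmps, config$youngAgeMax)
      writeMatrixTsv(z, file.path(outDir, "zscores.tsv"), "cpg_id")
      z
    })
  }
  if ("regions" %in% stages && length(avmps)) {
    results$avmrs <- runStage("regions", function() {
      rd <- as.data.frame(rowData(bset))
      pos <- data.frame(cpg_id = rownames(bset), rd,
                        stringsAsFactors = FALSE)
      genes <- if (!is.null(eset)) geneRanges(eset)
      av <- callAvmrs(pos[pos$cpg_id %in% avmps, ], genes, config)
      writeTableTsv(av$regions, file.path(outDir, "avmrs.tsv"))
      writeTableTsv(av$members, file.path(outDir, "avmr_members.tsv"))
      writeAvmrBed(av, file.path(outDir, "avmrs.bed"))
      av
    })
  }
  if ("eqtm" %in% stages && length(avmps)) {
    results$cis <- runStage("eqtm", function() {
      hits <- cisMap(bset, eset, avmps, config)
      writeTableTsv(hits, file.path(outDir, "cis_pairs.tsv"))
      hits
    })
    results$trans <- runStage("eqtm", function() {
      tr <- transMap(bset, eset, avmps, config)
      writeTableTsv(tr$pairs, file.path(outDir, "trans_pairs.tsv"))
      writeTableTsv(tr$hits, file.path(outDir, "trans_hits.tsv"))
      writeTableTsv(tr$clusters,
                    file.path(outDir, "trans_clusters.tsv"))
      note("trans hub threshold: ", tr$hubThreshold)
      tr
    })
  }
  if ("enrich" %in% stages && length(avmps)) {
    results$enrichment <- runStage("enrich", function() {
      tracks <- if (simulate) .syntheticTracks(bset, config)
        else readAnnotationTracks(paths$tracks)
      bg <- cpgRanges(bset[scanTab$cpg_id, ])
      st <- bg[bg$cpg_id %in% avmps]
      en <- enrichCpgs(st, bg, tracks, nPermutations = 0,
                       seed = config$rngSeed)
      writeTableTsv(en, file.path(outDir, "enrichment.tsv"))
      en
    })
  }
  if ("replicate" %in% stages && length(avmps)) {
    results$replication <- runStage("replicate", function() {
      if (!simulate) {
        vb <- readBetaMatrix(paths$validationBeta, paths$cpgAnnot)
        vc <- readCovariateTable(paths$validationCovariates, config)
        valBset <<- alignSamples(vb, vc, config = config)$beta
      }
      rep <- replicateScan(scanTab, valBset, config)
      writeTableTsv(rep$table, file.path(outDir, "replication.tsv"))
      note(sprintf(
        "replication: %.3f replicated, %.3f concordant, r=%.3f",
        rep$summary$replicatedFraction, rep$summary$concordance,
        rep$summary$effectCorrelation))
      rep
    })
  }
  invisible(results)
}

# A minimal two-label synthetic segmentation (alternating 1 Mb bins) so
# that simulated runs exercise the enrichment stage without real tracks.
.syntheticTracks <- function(bset, config) {
  gr <- cpgRanges(bset)
  chroms <- sort(unique(as.character(seqnames(gr))))
  starts <- seq(1, 5e7, by = 1e6)
  bins <- GRanges(rep(chroms, each = length(starts)),
                  IRanges(rep(starts, length(chroms)), width = 1e6))
  odd <- rep_len(c(TRUE, FALSE), length(bins))
  list(binA = bins[odd], binB = bins[!odd])
}
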
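#' Pipeline configuration
#'
#' Collects every tunable threshold of the aVMP pipeline in one validated
#' object.  All defaults follow the whole-blood analysis the package
#' implements: Bonferroni alpha 0.05 on the variance test, a minimum
#' variability increase of 0.05 beta units of standard deviation per decade,
#' a young reference below 30 years, a 500 kb cis window, a 5 Mb minimum
#' trans distance, a 5\% trans hub filter and FDR 0.05 elsewhere.
#'
#' @param alphaBonferroni family-wise alpha for the Bonferroni-corrected
#'   variance test (and the mean-model aDMP call).
#' @param effectThresholdPerDecade minimum absolute change of the fitted
#'   residual standard deviation per 10 years of age, in beta units.
#' @param effectRelative logical; if `TRUE` the effect threshold is read as
#'   a fraction of the fitted SD at the mean age instead of an absolute
#'   change in beta units.
#' @param youngAgeMax upper age bound (exclusive, years) of the young
#'   reference used for baselines and Z-scores.
#' @param cisWindow maximum CpG-to-gene distance (bp) for cis pairs.
#' @param transMinDistance minimum same-chromosome distance (bp) for trans
#'   pairs; cross-chromosome pairs always qualify.
#' @param transHubFraction trans genes associated with at most
#'   `floor(transHubFraction * nAvmps)` aVMPs are discarded.
#' @param fdrQ Benjamini-Hochberg q threshold.
#' @param avmrMaxGap maximum gap (bp) between consecutive aVMPs merged into
#'   one region.
#' @param avmrMinCpgs minimum number of member CpGs for a region call.
#' @param lowBaseline,highBaseline young-baseline methylation bounds below
#'   (above) which a candidate is eligible for the gain (loss) class.
#' @param meanSlopeFloor minimum |mean slope| per decade separating gain and
#'   loss from the constant class.
#' @param minSamples minimum number of samples with complete covariates
#'   required by the scan.
#' @param minYoung minimum size of the young reference; below it the
#'   youngest decile of samples is used instead (with a warning).
#' @param maxMissingFraction a CpG enters an analysis only if missing in at
#'   most this fraction of samples.
#' @param ageRangePlausible two-element declared plausible age range used
#'   when reading covariate tables.
#' @param bpMethod variance-test statistic: `"wald"` tests the age
#'   coefficient of the squared-residual regression (covariate-adjusted);
#'   `"lm"` is the classical n-R-squared Lagrange-multiplier variant.
#' @param distanceMode `"body"` measures CpG-gene distance to the nearest
#'   gene-body boundary, `"tss"` to the transcription start site.
#' @param codingOnlyTrans logical; restrict trans tests to genes flagged as
#'   protein-coding (when the annotation carries a `coding` column).
#' @param sexLevels length-2 character vector mapping textual sex codes to
#'   0 and 1, in that order.
#' @param trackPriority optional character vector fixing the tie order of
#'   annotation labels in modal CpG annotation.
#' @param rngSeed integer seed for any stochastic step (permutations).
#' @return a `VmpConfig` list object.
#' @examples
#' cfg <- vmpConfig(fdrQ = 0.01)
#' cfg$fdrQ
#' @export
vmpConfig <- function(alphaBonferroni = 0.05,
                      effectThresholdPerDecade = 0.05,
                      effectRelative = FALSE,
                      youngAgeMax = 30,
                      cisWindow = 5e5,
                      transMinDistance = 5e6,
                      transHubFraction = 0.05,
                      fdrQ = 0.05,
                      avmrMaxGap = 1000,
                      avmrMinCpgs = 3,
                      lowBaseline = 0.3,
                      highBaseline = 0.7,
                      meanSlopeFloor = 0.01,
                      minSamples = 50,
                      minYoung = 20,
                      maxMissingFraction = 0.05,
                      ageRangePlausible = c(15, 110),
                      bpMethod = c("wald", "lm"),
                      distanceMode = c("body", "tss"),
                      codingOnlyTrans = FALSE,
                      sexLevels = c("F", "M"),
                      trackPriority = NULL,
                      rngSeed = 1L) {
  cfg <- list(alphaBonferroni = alphaBonferroni,
              effectThresholdPerDecade = effectThresholdPerDecade,
              effectRelative = isTRUE(effectRelative),
              youngAgeMax = youngAgeMax,
              cisWindow = cisWindow,
              transMinDistance = transMinDistance,
              transHubFraction = transHubFraction,
              fdrQ = fdrQ,
              avmrMaxGap = avmrMaxGap,
              avmrMinCpgs = avmrMinCpgs,
              lowBaseline = lowBaseline,
              highBaseline = highBaseline,
              meanSlopeFloor = meanSlopeFloor,
              minSamples = minSamples,
              minYoung = minYoung,
              maxMissingFraction = maxMissingFraction,
              ageRangePlausible = ageRangePlausible,
              bpMethod = match.arg(bpMethod),
              distanceMode = match.arg(distanceMode),
              codingOnlyTrans = isTRUE(codingOnlyTrans),
              sexLevels = sexLevels,
              trackPriority = trackPriority,
              rngSeed = as.integer(rngSeed))
  pos <- c("alphaBonferroni", "effectThresholdPerDecade", "youngAgeMax",
           "cisWindow", "transMinDistance", "fdrQ", "avmrMaxGap",
           "avmrMinCpgs", "minSamples", "minYoung")
  for (p in pos)
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1 || cfg[[p]] <= 0)
      stop("config field '", p, "' must be a positive scalar")
  frac <- c("transHubFraction", "fdrQ", "alphaBonferroni",
            "maxMissingFraction")
  for (p in frac)
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1)
      stop("config field '", p, "' must lie in (0, 1)")
  if (cfg$lowBaseline >= cfg$highBaseline)
    stop("lowBaseline must be below highBaseline")
  if (length(cfg$ageRangePlausible) != 2 ||
      diff(cfg$ageRangePlausible) <= 0)
    stop("ageRangePlausible must be an increasing length-2 vector")
  class(cfg) <- "VmpConfig"
  cfg
}

#' @export
print.VmpConfig <- function(x, ...) {
  cat("VmpConfig\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v)) v <- "<default>"
    cat(sprintf("  %-26s %s\n", nm, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

#' Read / write a flat key-value configuration file
#'
#' The file format is one `key = value` pair per line, `#` comments
#' allowed.  Vector values are comma-separated.  Unknown keys are an error;
#' missing keys keep their defaults.
#'
#' @param path file path.
#' @param config a `VmpConfig` (for writing).
#' @return `readVmpConfig` returns a `VmpConfig`.
#' @export
readVmpConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- vmpConfig()
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!(key %in% names(defaults))) stop("unknown config key: ", key)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!any(is.na(num))) parts <- num
    else if (all(parts %in% c("TRUE", "FALSE"))) parts <- as.logical(parts)
    args[[key]] <- parts
  }
  do.call(vmpConfig, args)
}

#' @rdname readVmpConfig
#' @export
writeVmpConfig <- function(config, path) {
  stopifnot(inherits(config, "VmpConfig"))
  lines <- vapply(names(config), function(nm) {
    v <- config[[nm]]
    if (is.null(v)) return(NA_character_)
    sprintf("%s = %s", nm, paste(v, collapse = ","))
  }, character(1))
  writeLines(lines[!is.na(lines)], path)
  invisible(path)
}
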
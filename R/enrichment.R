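#' Test CpG membership in an interval track
#'
#' A CpG at 1-based point position `pos` lies inside a 0-based half-open
#' interval `[start0, end0)` exactly when `pos - 1` is in that interval.
#' Tracks read by [readAnnotationTracks()] already carry the matching
#' 1-based inclusive `GRanges` convention, so membership reduces to a
#' point overlap.
#'
#' @param cpgs a [GenomicRanges::GRanges] of width-1 CpG positions with a
#'   `cpg_id` column (e.g. from [cpgRanges()]).
#' @param track a [GenomicRanges::GRanges] of intervals.
#' @return named logical vector of membership flags.
#' @export
cpgInTrack <- function(cpgs, track) {
  hits <- suppressWarnings(findOverlaps(cpgs, track))
  flags <- logical(length(cpgs))
  flags[S4Vectors::queryHits(hits)] <- TRUE
  setNames(flags, cpgs$cpg_id)
}

#' Modal annotation label per CpG
#'
#' Given several segmentations (e.g. chromatin-state calls in different
#' blood cell types), each CpG receives the most frequent label across
#' segmentations; ties are broken by a fixed priority order
#' (`config$trackPriority`, defaulting to the alphabetical label order).
#' CpGs overlapping no interval in a segmentation contribute no vote.
#'
#' @param cpgs width-1 [GenomicRanges::GRanges] with `cpg_id`.
#' @param segmentations list of [GenomicRanges::GRanges], each with a
#'   `name` column of labels (one element per cell type), or a single
#'   such GRanges.
#' @param config a [vmpConfig()].
#' @return named character vector of labels (`NA` where no vote).
#' @export
annotateCpgs <- function(cpgs, segmentations, config = vmpConfig()) {
  if (is(segmentations, "GRanges"))
    segmentations <- list(segmentations)
  votes <- matrix(NA_character_, length(cpgs), length(segmentations))
  for (k in seq_along(segmentations)) {
    seg <- segmentations[[k]]
    hits <- findOverlaps(cpgs, seg)
    lab <- rep(NA_character_, length(cpgs))
    lab[S4Vectors::queryHits(hits)] <-
      seg$name[S4Vectors::subjectHits(hits)]
    votes[, k] <- lab
  }
  labels <- sort(unique(as.vector(votes[!is.na(votes)])))
  priority <- config$trackPriority
  if (is.null(priority)) priority <- labels
  out <- apply(votes, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_character_)
    tab <- table(v)
    top <- names(tab)[tab == max(tab)]
    top[order(match(top, priority))][1]
  })
  setNames(out, cpgs$cpg_id)
}

#' Odds-ratio enrichment of a CpG set in interval tracks
#'
#' For each track a 2x2 table is formed: `a` CpGs of the set inside the
#' track, `b` outside, and `c`/`d` the same counts over the background
#' (all scanned CpGs, which contains the set).  The odds ratio is
#' `(a*d)/(b*c)` (Haldane-Anscombe +0.5 applied to all cells when any
#' cell is 0) and is also reported on the log2 scale; significance is the
#' two-sided Fisher exact test on the table, optionally complemented by a
#' permutation p drawing `|set|` CpGs uniformly from the background and
#' counting overlaps at least as large as observed (one-sided, with the
#' +1 correction, so never below `1/(nPermutations + 1)`).
#'
#' @param setCpgs width-1 [GenomicRanges::GRanges] of the CpG set (with
#'   `cpg_id`), a subset of `backgroundCpgs`.
#' @param backgroundCpgs width-1 GRanges of all scanned CpGs.
#' @param tracks named list of interval [GenomicRanges::GRanges].
#' @param nPermutations permutation count (0 disables).
#' @param seed integer seed for the permutations.
#' @return `data.frame`: `track`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `log2_odds_ratio`, `fisher_p`, `perm_p`, `n_permutations`.
#' @export
enrichCpgs <- function(setCpgs, backgroundCpgs, tracks,
                       nPermutations = 0, seed = 1L) {
  if (!all(setCpgs$cpg_id %in% backgroundCpgs$cpg_id))
    stop("CpG set must be contained in the background")
  rows <- lapply(names(tracks), function(nm) {
    inBg <- cpgInTrack(backgroundCpgs, tracks[[nm]])
    inSet <- inBg[match(setCpgs$cpg_id, backgroundCpgs$cpg_id)]
    a <- sum(inSet); b <- length(inSet) - a
    cc <- sum(inBg); d <- length(inBg) - cc
    orRaw <- c(a, b, cc, d)
    if (any(orRaw == 0)) orRaw <- orRaw + 0.5
    orv <- (orRaw[1] * orRaw[4]) / (orRaw[2] * orRaw[3])
    fp <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    pp <- NA_real_
    if (nPermutations > 0) {
      set.seed(seed)
      nSet <- length(inSet)
      exceed <- sum(vapply(seq_len(nPermutations), function(i)
        sum(sample(inBg, nSet)) >= a, logical(1)))
      pp <- (exceed + 1) / (nPermutations + 1)
    }
    data.frame(track = nm, a = a, b = b, c = cc, d = d,
               odds_ratio = orv, log2_odds_ratio = log2(orv),
               fisher_p = fp, perm_p = pp,
               n_permutations = nPermutations,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicate a variability scan in an independent cohort
#'
#' Re-runs [scanVariability()] on a validation cohort restricted to the
#' discovery aVMPs, applies Benjamini-Hochberg FDR across that set, and
#' calls a CpG replicated when its validation FDR is at most `fdrQ` and
#' the direction of the variability change matches the discovery.
#'
#' @param discovery scan output ([scanVariability()] rows) restricted to,
#'   or at least containing, the discovery aVMPs.
#' @param validationBset a [BetaSet-class] of the validation cohort with
#'   covariates attached.
#' @param config a [vmpConfig()].
#' @return list with `table` (per-CpG discovery and validation effects,
#'   `validation_p`, `validation_p_fdr`, `replicated`) and `summary`
#'   (`replicatedFraction`, `concordance`, `concordanceP`,
#'   `effectCorrelation`).
#' @export
replicateScan <- function(discovery, validationBset,
                          config = vmpConfig()) {
  disc <- discovery[discovery$is_avmp_candidate, , drop = FALSE]
  if (nrow(disc) == 0) disc <- discovery
  shared <- intersect(disc$cpg_id, rownames(validationBset))
  if (length(shared) == 0)
    stop("validation cohort shares no CpGs with the discovery set")
  disc <- disc[match(shared, disc$cpg_id), ]
  sub <- validationBset[shared, ]
  val <- scanVariability(sub, config)
  val <- val[match(shared, val$cpg_id), ]
  pFdr <- p.adjust(val$bp_p, method = "BH")
  signMatch <- sign(val$sd_change_per_decade) ==
    sign(disc$sd_change_per_decade)
  tab <- data.frame(
    cpg_id = shared,
    discovery_effect = disc$sd_change_per_decade,
    validation_effect = val$sd_change_per_decade,
    validation_p = val$bp_p,
    validation_p_fdr = pFdr,
    replicated = !is.na(pFdr) & pFdr <= config$fdrQ & signMatch,
    stringsAsFactors = FALSE)
  conc <- directionConcordance(
    setNames(tab$discovery_effect, tab$cpg_id),
    setNames(tab$validation_effect, tab$cpg_id))
  list(table = tab,
       summary = list(
         replicatedFraction = mean(tab$replicated),
         concordance = conc$concordance,
         concordanceP = conc$p,
         effectCorrelation = stats::cor(tab$discovery_effect,
                                        tab$validation_effect)))
}

#' Percentage bookkeeping helper
#'
#' Formats a count as a percentage of a total at the reporting precision
#' used throughout the package's summaries (one decimal).
#'
#' @param count,total non-negative counts.
#' @param digits decimal places.
#' @return numeric percentage rounded to `digits`.
#' @examples
#' pctShare(6343, 6366)  # 99.6
#' @export
pctShare <- function(count, total, digits = 1) {
  stopifnot(total > 0, count >= 0)
  round(100 * count / total, digits)
}
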
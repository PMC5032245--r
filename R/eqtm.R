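# Residualize the rows of a feature x sample matrix on a sample-level
# design (Frisch-Waugh step shared by the cis and trans eQTM tests).
.residOnDesign <- function(M, Z) {
  M - (M %*% Z) %*% chol2inv(chol(crossprod(Z))) %*% t(Z)
}

# Signed CpG-to-gene distance: 0 inside the gene body, positive when the
# gene starts downstream of the CpG, negative when it ends upstream.
# NA for different chromosomes.  "tss" mode measures to the strand-aware
# transcription start site instead.
.cpgGeneDistance <- function(chrom, pos, geneDf, mode = "body") {
  d <- rep(NA_real_, nrow(geneDf))
  same <- !is.na(geneDf$chrom) & geneDf$chrom == chrom
  if (mode == "tss") {
    tss <- ifelse(geneDf$strand == "-", geneDf$end, geneDf$start)
    d[same] <- tss[same] - pos
  } else {
    d[same] <- ifelse(geneDf$start[same] > pos,
                      geneDf$start[same] - pos,
                      ifelse(geneDf$end[same] < pos,
                             -(pos - geneDf$end[same]), 0))
  }
  d
}

.eqtmSetup <- function(bset, eset, avmps, config) {
  samples <- intersect(colnames(bset), colnames(eset))
  if (length(samples) == 0) stop("no shared samples")
  bsub <- bset[, samples]
  rd <- as.data.frame(rowData(bset))
  pos <- rd[match(avmps, rownames(bset)), c("chrom", "pos")]
  keep <- !is.na(pos$pos)
  if (!all(keep))
    message(sum(!keep), " aVMP(s) without coordinates excluded")
  avmps <- avmps[keep]; pos <- pos[keep, ]
  meth <- betaValues(bsub)[avmps, , drop = FALSE]
  ok <- rowSums(is.na(meth)) == 0
  if (!all(ok)) {
    message(sum(!ok), " aVMP(s) with missing values excluded")
    avmps <- avmps[ok]; pos <- pos[ok, ]
    meth <- meth[ok, , drop = FALSE]
  }
  if (length(avmps) == 0) stop("no usable aVMPs")
  geneDf <- as.data.frame(rowData(eset))
  geneDf$gene_id <- rownames(eset)
  expr <- exprValues(eset)[, samples, drop = FALSE]
  # adjust for sex and blood cell composition (not age: the age signal in
  # methylation is the object of study)
  Z <- .designMatrix(bsub, c("sex", "fractions"))
  list(samples = samples, avmps = avmps, pos = pos, meth = meth,
       geneDf = geneDf, expr = expr,
       methR = .residOnDesign(meth, Z),
       exprR = .residOnDesign(expr, Z),
       df = length(samples) - ncol(Z) - 1)
}

.pairTests <- function(methR, exprR, df) {
  sm2 <- rowSums(methR^2)
  se2 <- rowSums(exprR^2)
  num <- exprR %*% t(methR)                     # genes x cpgs
  denom <- sqrt(outer(se2, sm2))
  r <- num / denom
  r[denom == 0] <- NA
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  list(beta = sweep(num, 2, sm2, "/"), t = tt,
       p = 2 * pt(-abs(tt), df))
}

#' Trans hub filter threshold
#'
#' A trans gene is retained only when associated with more than
#' `floor(fraction * nAvmps)` aVMPs; genes at or below the threshold are
#' discarded as non-hubs.  With 6366 aVMPs and the default 5\% fraction
#' the threshold is 318.
#'
#' @param nAvmps number of aVMPs entering the trans analysis.
#' @param fraction hub fraction in (0, 1).
#' @return integer threshold.
#' @examples
#' hubThreshold(6366, 0.05)  # 318
#' @export
hubThreshold <- function(nAvmps, fraction = 0.05) {
  stopifnot(nAvmps >= 1, fraction > 0, fraction < 1)
  as.integer(floor(fraction * nAvmps))
}

#' Map aVMP methylation to gene expression in cis
#'
#' For each aVMP, every gene whose nearest body boundary (or TSS,
#' depending on `config$distanceMode`) lies within `cisWindow` is tested
#' by OLS of expression on methylation adjusted for sex and cell
#' fractions.  P-values are Bonferroni-corrected within the aVMP for the
#' number of genes tested; the single most significant gene (ties broken
#' by smaller distance, then gene id) is retained when its corrected p is
#' at most `alphaBonferroni`; Benjamini-Hochberg FDR is then applied
#' across the retained aVMP-gene pairs and pairs with `p_fdr <= fdrQ` are
#' reported.
#'
#' @param bset a [BetaSet-class] with covariates attached.
#' @param eset an [ExprSet-class] with gene coordinates; samples must
#'   overlap `bset`'s.
#' @param avmps character vector of aVMP identifiers.
#' @param config a [vmpConfig()].
#' @return `data.frame` of cis hits: `cpg_id`, `gene_id`, `mode`,
#'   `beta_coefficient`, `p_raw`, `p_within_cpg`, `p_fdr`, `distance_bp`.
#'   Attribute `nNoCandidate` counts aVMPs with no positioned gene in
#'   their window.
#' @export
cisMap <- function(bset, eset, avmps, config = vmpConfig()) {
  s <- .eqtmSetup(bset, eset, avmps, config)
  rows <- list(); noCand <- 0L
  sm2 <- rowSums(s$methR^2)
  for (i in seq_along(s$avmps)) {
    if (sm2[i] == 0) next  # degenerate regressor
    d <- .cpgGeneDistance(s$pos$chrom[i], s$pos$pos[i], s$geneDf,
                          config$distanceMode)
    cand <- which(!is.na(d) & abs(d) <= config$cisWindow)
    if (!length(cand)) { noCand <- noCand + 1L; next }
    num <- s$exprR[cand, , drop = FALSE] %*% s$methR[i, ]
    se2 <- rowSums(s$exprR[cand, , drop = FALSE]^2)
    r <- as.vector(num) / sqrt(se2 * sm2[i])
    r[se2 == 0] <- NA
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt(s$df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    pRaw <- 2 * pt(-abs(tt), s$df)
    pWithin <- pmin(1, pRaw * length(cand))
    okp <- which(!is.na(pWithin))
    if (!length(okp)) next
    best <- okp[order(pWithin[okp], abs(d[cand[okp]]),
                      s$geneDf$gene_id[cand[okp]])][1]
    if (pWithin[best] > config$alphaBonferroni) next
    rows[[length(rows) + 1L]] <- data.frame(
      cpg_id = s$avmps[i], gene_id = s$geneDf$gene_id[cand[best]],
      mode = "cis", beta_coefficient = as.vector(num)[best] / sm2[i],
      p_raw = pRaw[best], p_within_cpg = pWithin[best],
      p_fdr = NA_real_, distance_bp = d[cand[best]],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cpg_id = character(), gene_id = character(),
               mode = character(), beta_coefficient = numeric(),
               p_raw = numeric(), p_within_cpg = numeric(),
               p_fdr = numeric(), distance_bp = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(out)) {
    out$p_fdr <- p.adjust(out$p_within_cpg, method = "BH")
    out <- out[out$p_fdr <= config$fdrQ, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "nNoCandidate") <- noCand
  out
}

#' Map aVMP methylation to gene expression in trans
#'
#' Tests every aVMP-gene pair lying on different chromosomes or more than
#' `transMinDistance` apart, with the same covariate-adjusted regression
#' as [cisMap()].  Benjamini-Hochberg FDR is applied across all tested
#' pairs; genes associated with at most [hubThreshold()] retained aVMPs
#' are discarded; the expression of the surviving hub genes is clustered
#' (average-linkage on 1 - Pearson correlation, cut into 2 groups) and
#' each group is labelled `"up"` or `"down"` by the sign of its mean
#' methylation-expression coefficient.
#'
#' @inheritParams cisMap
#' @return list with `pairs` (all FDR-significant pairs), `hits` (pairs
#'   involving surviving hub genes), `clusters` (`gene_id`, `cluster`,
#'   `n_linked_avmps`), `hubThreshold` and `nTests`.
#' @export
transMap <- function(bset, eset, avmps, config = vmpConfig()) {
  s <- .eqtmSetup(bset, eset, avmps, config)
  geneDf <- s$geneDf
  exprR <- s$exprR
  if (config$codingOnlyTrans && "coding" %in% colnames(geneDf)) {
    keep <- !is.na(geneDf$coding) & geneDf$coding
    geneDf <- geneDf[keep, ]; exprR <- exprR[keep, , drop = FALSE]
  }
  dist <- vapply(seq_along(s$avmps), function(i)
    .cpgGeneDistance(s$pos$chrom[i], s$pos$pos[i], geneDf,
                     config$distanceMode), numeric(nrow(geneDf)))
  if (is.null(dim(dist))) dist <- matrix(dist, nrow = nrow(geneDf))
  qualifies <- is.na(dist) | abs(dist) > config$transMinDistance
  pt <- .pairTests(s$methR, exprR, s$df)
  p <- pt$p
  p[!qualifies] <- NA
  nTests <- sum(!is.na(p))
  pAdj <- matrix(NA_real_, nrow(p), ncol(p))
  pAdj[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
  sig <- which(!is.na(pAdj) & pAdj <= config$fdrQ, arr.ind = TRUE)
  pairs <- data.frame(
    cpg_id = s$avmps[sig[, 2]], gene_id = geneDf$gene_id[sig[, 1]],
    mode = rep("trans", nrow(sig)), beta_coefficient = pt$beta[sig],
    p_raw = p[sig], p_within_cpg = rep(NA_real_, nrow(sig)),
    p_fdr = pAdj[sig], distance_bp = dist[sig],
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$p_fdr, pairs$cpg_id, pairs$gene_id), ]
  rownames(pairs) <- NULL

  thr <- hubThreshold(length(s$avmps), config$transHubFraction)
  counts <- table(pairs$gene_id)
  hubGenes <- names(counts)[counts > thr]
  hits <- pairs[pairs$gene_id %in% hubGenes, , drop = FALSE]

  clusters <- data.frame(gene_id = character(), cluster = character(),
                         n_linked_avmps = integer(),
                         stringsAsFactors = FALSE)
  if (length(hubGenes) < 2) {
    if (length(hubGenes) > 0 || nrow(pairs) > 0)
      warning("fewer than 2 hub genes; trans-gene clusters undefined")
  } else {
    e <- exprValues(eset)[hubGenes, s$samples, drop = FALSE]
    cc <- stats::cor(t(e))
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    grp <- stats::cutree(hc, k = 2)
    coefMean <- vapply(hubGenes, function(g)
      mean(hits$beta_coefficient[hits$gene_id == g]), numeric(1))
    gm <- vapply(1:2, function(k) mean(coefMean[grp == k]), numeric(1))
    lab <- if (sign(gm[1]) != sign(gm[2]))
      ifelse(gm > 0, "up", "down")
    else c("up", "down")[order(-gm)]
    clusters <- data.frame(
      gene_id = hubGenes, cluster = lab[grp],
      n_linked_avmps = as.integer(counts[hubGenes]),
      stringsAsFactors = FALSE)
    rownames(clusters) <- NULL
  }
  list(pairs = pairs, hits = hits, clusters = clusters,
       hubThreshold = thr, nTests = nTests)
}

#' Sign concordance of two effect vectors
#'
#' Fraction of shared CpGs whose effects agree in sign, with a two-sided
#' exact binomial p-value against chance (0.5) -- the statistic used to
#' compare variability or mean-trend directions across tissues or
#' cohorts.
#'
#' @param slopesA,slopesB named numeric vectors of signed effects.
#' @return list with `concordance`, `p`, `n` (shared CpGs).
#' @export
directionConcordance <- function(slopesA, slopesB) {
  shared <- intersect(names(slopesA), names(slopesB))
  if (length(shared) == 0) stop("no shared CpG keys")
  agree <- sign(slopesA[shared]) == sign(slopesB[shared])
  list(concordance = mean(agree),
       p = binom.test(sum(agree), length(shared), 0.5,
                      alternative = "two.sided")$p.value,
       n = length(shared))
}
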
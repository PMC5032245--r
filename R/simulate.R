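#' Describe a synthetic methylation cohort
#'
#' Defines the statistical structure of a simulated cohort on the beta
#' scale: ages drawn uniformly over `ageRange`; CpGs split into five
#' classes (`null`, `admp`, `gain`, `loss`, `constant`); an age-linear
#' mean trend of `meanSlopePerDecade` beta units per decade for aDMP,
#' gain (+) and loss (-) CpGs; an age-linear residual standard deviation
#' `sdBase + sdSlopePerDecade * (age - min age)/10` for the three aVMP
#' classes; blood-like cell fractions from a symmetric Dirichlet with an
#' optional linear age trend on one component; and optional per-CpG
#' loadings of otherwise-null CpGs on that trending fraction (the
#' cell-composition confounder the scan must adjust away).  Values are
#' truncated to \[0.001, 0.999\].
#'
#' Baselines follow the three archetypes: gain CpGs start hypomethylated
#' (uniform in \[0.05, 0.25\]), loss CpGs hypermethylated (\[0.75, 0.95\]),
#' constant CpGs intermediate (\[0.35, 0.65\]) with zero mean slope.
#'
#' @param nSamples number of samples.
#' @param ageRange length-2 years; ages are uniform over it.
#' @param nCpgs number of CpGs.
#' @param classMix named fractions over
#'   `c("null", "admp", "gain", "loss", "constant")`; must sum to 1.
#' @param meanSlopePerDecade beta units per decade for the mean trend.
#' @param sdBase baseline residual SD (beta units), > 0.
#' @param sdSlopePerDecade SD change per decade for aVMP classes.
#' @param nGenes number of genes for [simulateExpression()].
#' @param cisLinkFraction fraction of non-null aVMP-class CpGs given a
#'   dedicated cis-linked gene.
#' @param cisEffect,cisDecoys effect size of planted cis links and number
#'   of unlinked decoy genes placed inside each linked CpG's cis window.
#' @param transHub list `nHubGenes`, `nAvmpsPerHub`, `effectSize` (sign
#'   may alternate across hubs via a vector).  Hub-linked CpGs share a
#'   per-sample latent drift factor whose SD grows linearly with age
#'   (`sdSlopePerDecade` per decade) on top of independent `sdBase`
#'   noise, so they are mutually correlated -- the property that makes a
#'   hub gene detectable against each of its hundreds of partner CpGs.
#' @param confounder list `ageTrend` (fraction units per decade added to
#'   the first cell fraction), `loading` (beta units per unit fraction)
#'   and `nLoaded` (number of null CpGs given that loading).
#' @param divergentSubset optional fraction in (0, 1): only this random
#'   subset of samples receives the age-dependent extra SD, emulating a
#'   divergent-subpopulation mixture instead of smooth heteroscedasticity.
#' @param clusteredPlacement optional list `nClusters`, `span` placing all
#'   aVMP-class CpGs in tight clusters on one chromosome (for
#'   region-calling tests).
#' @param exprNoiseSd residual SD of simulated expression.
#' @param cisWindow,transMinDistance genomic distance settings used when
#'   placing linked genes (match [vmpConfig()] defaults).
#' @param rngSeed integer seed.
#' @return a `SimulationDesign` list.
#' @export
simulationDesign <- function(nSamples = 500,
                             ageRange = c(18, 88),
                             nCpgs = 1000,
                             classMix = c(null = 0.90, admp = 0.04,
                                          gain = 0.02, loss = 0.02,
                                          constant = 0.02),
                             meanSlopePerDecade = 0.02,
                             sdBase = 0.04,
                             sdSlopePerDecade = 0.05,
                             nGenes = 100,
                             cisLinkFraction = 0,
                             cisEffect = 1,
                             cisDecoys = 5,
                             transHub = list(nHubGenes = 0,
                                             nAvmpsPerHub = 0,
                                             effectSize = 1),
                             confounder = list(ageTrend = 0, loading = 0,
                                               nLoaded = 0),
                             divergentSubset = NULL,
                             clusteredPlacement = NULL,
                             exprNoiseSd = 0.5,
                             cisWindow = 5e5,
                             transMinDistance = 5e6,
                             rngSeed = 1L) {
  design <- as.list(environment())
  cls <- c("null", "admp", "gain", "loss", "constant")
  if (!all(names(classMix) %in% cls))
    stop("classMix names must be among: ", paste(cls, collapse = ", "))
  if (abs(sum(classMix) - 1) > 1e-8)
    stop("class fractions must sum to 1")
  if (sdBase <= 0) stop("sdBase must be > 0")
  span <- diff(range(ageRange)) / 10
  if (sdBase + min(0, sdSlopePerDecade) * span <= 0)
    stop("sdSlopePerDecade yields non-positive SD within the age range")
  class(design) <- "SimulationDesign"
  design
}

# 5 synthetic chromosomes of 50 Mb; plenty for cis/trans distance logic
.simChromLen <- 5e7
.simChroms <- paste0("chr", 1:5)

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), n, k, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a methylation cohort with planted ground truth
#'
#' Draws a cohort under a [simulationDesign()]: for sample with age a and
#' CpG j the latent value is
#' `mu_j(a) + lambda_j * (f1(a) - mean f1) + eps`,
#' `eps ~ N(0, sigma_j(a)^2)`, truncated to \[0.001, 0.999\].
#'
#' @param design a [simulationDesign()].
#' @return list with `beta` (a [BetaSet-class] with covariates attached
#'   and uniform random positions on 5 x 50 Mb synthetic chromosomes) and
#'   `truth`, a list of data.frames: `cpgs` (`cpg_id`, `class`,
#'   `baseline`, `mean_slope`, `sd_slope`, `cell_loading`), with `cis` and
#'   `trans` link tables filled by [simulateExpression()].
#' @export
simulateCohort <- function(design) {
  stopifnot(inherits(design, "SimulationDesign"))
  set.seed(design$rngSeed)
  n <- design$nSamples
  m <- design$nCpgs
  age <- runif(n, design$ageRange[1], design$ageRange[2])
  sex <- rbinom(n, 1, 0.5)
  sampleIds <- sprintf("s%04d", seq_len(n))

  fracNames <- c("neutro", "lympho", "mono", "eos", "baso")
  f <- .rdirichlet(n, rep(10, 5))
  f[, 1] <- pmax(f[, 1] + design$confounder$ageTrend *
                   (age - design$ageRange[1]) / 10, 0)
  f <- f / rowSums(f)
  colnames(f) <- fracNames

  # class assignment with exact counts
  mix <- design$classMix[design$classMix > 0]
  counts <- diff(c(0, round(cumsum(mix) * m)))
  classes <- rep(names(mix), counts)
  stopifnot(length(classes) == m)

  baseline <- numeric(m)
  baseline[classes == "null"] <- runif(sum(classes == "null"), 0.05, 0.95)
  baseline[classes == "admp"] <- runif(sum(classes == "admp"), 0.25, 0.75)
  baseline[classes == "gain"] <- runif(sum(classes == "gain"), 0.05, 0.25)
  baseline[classes == "loss"] <- runif(sum(classes == "loss"), 0.75, 0.95)
  baseline[classes == "constant"] <-
    runif(sum(classes == "constant"), 0.35, 0.65)

  meanSlope <- numeric(m)
  meanSlope[classes == "gain"] <- design$meanSlopePerDecade
  meanSlope[classes == "loss"] <- -design$meanSlopePerDecade
  # aDMPs drift toward intermediate methylation, keeping the whole
  # trajectory inside the beta bounds (a drift into a bound would induce
  # variance changes and contaminate the pure-mean class)
  admp <- classes == "admp"
  meanSlope[admp] <- design$meanSlopePerDecade *
    ifelse(baseline[admp] > 0.5, -1, 1)
  sdSlope <- ifelse(classes %in% c("gain", "loss", "constant"),
                    design$sdSlopePerDecade, 0)

  loading <- numeric(m)
  nl <- design$confounder$nLoaded
  if (nl > 0) {
    nullIdx <- which(classes == "null")
    if (nl > length(nullIdx))
      stop("confounder$nLoaded exceeds the number of null CpGs")
    loading[nullIdx[seq_len(nl)]] <- design$confounder$loading
  }

  # genomic placement: uniform by default, tight clusters on request
  chrom <- sample(.simChroms, m, replace = TRUE)
  pos <- sample.int(.simChromLen, m, replace = FALSE)
  if (!is.null(design$clusteredPlacement)) {
    cp <- design$clusteredPlacement
    avmp <- which(classes %in% c("gain", "loss", "constant"))
    centers <- sort(sample.int(.simChromLen - cp$span,
                               cp$nClusters)) + seq_len(cp$nClusters) * 1e6
    assign <- sort(rep_len(seq_len(cp$nClusters), length(avmp)))
    chrom[avmp] <- "chr1"
    pos[avmp] <- centers[assign] +
      unlist(lapply(table(assign), function(k)
        sort(sample.int(cp$span, k))))
  }

  # hub membership: disjoint groups of aVMP-class CpGs sharing a latent
  # per-sample drift factor (heteroscedastic in age).  Each hub gene's
  # anchor position is fixed first and members are drawn from CpGs in
  # trans of it (other chromosomes or beyond the minimum distance plus a
  # margin for the gene body).
  hub <- integer(m)
  th <- design$transHub
  hubAnchor <- NULL
  if (th$nHubGenes > 0) {
    avmpIdx <- which(classes %in% c("gain", "loss", "constant"))
    if (th$nHubGenes * th$nAvmpsPerHub > length(avmpIdx))
      stop("requested trans links exceed available aVMP-class CpGs")
    hubAnchor <- data.frame(
      hub = seq_len(th$nHubGenes),
      chrom = .simChroms[(seq_len(th$nHubGenes) - 1L) %% 5L + 1L],
      start = sample.int(.simChromLen - 2e5, th$nHubGenes))
    for (h in seq_len(th$nHubGenes)) {
      far <- avmpIdx[hub[avmpIdx] == 0 &
                       (chrom[avmpIdx] != hubAnchor$chrom[h] |
                          abs(pos[avmpIdx] - hubAnchor$start[h]) >
                            design$transMinDistance + 2e5)]
      if (length(far) < th$nAvmpsPerHub)
        stop("requested trans links exceed available distal CpGs")
      hub[sample(far, th$nAvmpsPerHub)] <- h
    }
  }

  decades <- (age - design$ageRange[1]) / 10
  mu <- outer(meanSlope, decades) + baseline
  sigma <- outer(sdSlope, decades) + design$sdBase
  if (!is.null(design$divergentSubset)) {
    q <- design$divergentSubset
    stopifnot(q > 0, q < 1)
    div <- runif(n) < q
    sigma[, !div] <- design$sdBase
  }
  hubFactor <- NULL
  if (th$nHubGenes > 0) {
    hubFactor <- vapply(seq_len(th$nHubGenes), function(h)
      rnorm(n, 0, design$sdSlopePerDecade * decades), numeric(n))
    sigma[hub > 0, ] <- design$sdBase
  }
  eps <- matrix(rnorm(m * n), m, n) * sigma
  if (!is.null(hubFactor))
    eps[hub > 0, ] <- eps[hub > 0, , drop = FALSE] +
      t(hubFactor)[hub[hub > 0], , drop = FALSE]
  conf <- outer(loading, f[, 1] - mean(f[, 1]))
  beta <- pmin(pmax(mu + conf + eps, 0.001), 0.999)
  cpgIds <- sprintf("cg%06d", seq_len(m))
  dimnames(beta) <- list(cpgIds, sampleIds)
  annot <- data.frame(cpg_id = cpgIds, chrom = chrom, pos = pos,
                      stringsAsFactors = FALSE)
  cov <- data.frame(sample_id = sampleIds, age = age, sex = sex,
                    batch = "sim", f, stringsAsFactors = FALSE)
  bset <- BetaSet(beta, annot = annot, covariates = cov,
                  cellFractionNames = fracNames, fractionsComplete = TRUE)
  truth <- list(
    cpgs = data.frame(cpg_id = cpgIds, class = classes,
                      baseline = baseline, mean_slope = meanSlope,
                      sd_slope = sdSlope, cell_loading = loading,
                      hub = hub, stringsAsFactors = FALSE),
    cis = data.frame(cpg_id = character(), gene_id = character(),
                     effect = numeric(), stringsAsFactors = FALSE),
    trans = data.frame(cpg_id = character(), gene_id = character(),
                       effect = numeric(), stringsAsFactors = FALSE),
    hubAnchor = hubAnchor)
  list(beta = bset, truth = truth)
}

#' Simulate expression linked to a methylation cohort
#'
#' Gene expression is `baseline + sum(effect * methylation of linked
#' CpGs) + N(0, exprNoiseSd^2)`.  Cis-linked genes are placed within the
#' cis window of their CpG on the same synthetic chromosome; trans hub
#' genes are placed so that every linked CpG is over `transMinDistance`
#' away or on another chromosome.  Decoy genes are placed uniformly.
#'
#' @param cohort output of [simulateCohort()].
#' @param design the same [simulationDesign()].
#' @return list with `expr` (an [ExprSet-class]) and `truth` (the cohort
#'   truth with `cis` and `trans` link tables filled).
#' @export
simulateExpression <- function(cohort, design) {
  stopifnot(inherits(design, "SimulationDesign"))
  set.seed(design$rngSeed + 1L)
  bset <- cohort$beta
  truth <- cohort$truth
  b <- betaValues(bset)
  n <- ncol(b)
  annot <- as.data.frame(rowData(bset))
  annot$cpg_id <- rownames(bset)
  avmpIds <- truth$cpgs$cpg_id[truth$cpgs$class %in%
                                 c("gain", "loss", "constant")]

  geneIds <- sprintf("gene%04d", seq_len(design$nGenes))
  gchrom <- sample(.simChroms, design$nGenes, replace = TRUE)
  glen <- sample(5e3:1e5, design$nGenes, replace = TRUE)
  gstart <- vapply(glen, function(l)
    sample.int(.simChromLen - l, 1), integer(1))
  gstrand <- sample(c("+", "-"), design$nGenes, replace = TRUE)
  expr <- matrix(rnorm(design$nGenes * n, mean = 5, sd = design$exprNoiseSd),
                 design$nGenes, n,
                 dimnames = list(geneIds, colnames(b)))

  geneUsed <- rep(FALSE, design$nGenes)
  cis <- truth$cis
  nCis <- round(design$cisLinkFraction * length(avmpIds))
  if (nCis > 0) {
    if (nCis * (1 + design$cisDecoys) > design$nGenes)
      stop("requested cis links (plus decoys) exceed available genes")
    linked <- sample(avmpIds, nCis)
    for (k in seq_len(nCis)) {
      cg <- linked[k]
      i <- match(cg, rownames(b))
      slots <- which(!geneUsed)[seq_len(1 + design$cisDecoys)]
      for (g in slots) {
        gchrom[g] <- annot$chrom[i]
        off <- sample(seq(-design$cisWindow + glen[g] + 1000,
                          design$cisWindow - glen[g] - 1000,
                          by = 1000), 1)
        s <- min(max(annot$pos[i] + off - glen[g] %/% 2, 1),
                 .simChromLen - glen[g])
        # clamping near a chromosome edge must not push the gene out of
        # the cis window
        if (min(abs(c(s, s + glen[g]) - annot$pos[i])) > design$cisWindow)
          s <- annot$pos[i]
        gstart[g] <- s
        geneUsed[g] <- TRUE
      }
      expr[slots[1], ] <- expr[slots[1], ] + design$cisEffect * b[i, ]
      cis <- rbind(cis, data.frame(cpg_id = cg,
                                   gene_id = geneIds[slots[1]],
                                   effect = design$cisEffect,
                                   stringsAsFactors = FALSE))
    }
  }

  trans <- truth$trans
  th <- design$transHub
  if (th$nHubGenes > 0) {
    effects <- rep_len(th$effectSize, th$nHubGenes)
    for (h in seq_len(th$nHubGenes)) {
      g <- which(!geneUsed)[1]
      geneUsed[g] <- TRUE
      linked <- truth$cpgs$cpg_id[truth$cpgs$hub == h]
      # the cohort fixed each hub's anchor and drew its members in
      # trans of it; the gene body stays within the reserved margin
      gchrom[g] <- truth$hubAnchor$chrom[h]
      gstart[g] <- truth$hubAnchor$start[h]
      glen[g] <- min(glen[g], 1e5)
      contrib <- colMeans(b[linked, , drop = FALSE])
      expr[g, ] <- expr[g, ] + effects[h] * (contrib - mean(contrib))
      trans <- rbind(trans, data.frame(cpg_id = linked,
                                       gene_id = geneIds[g],
                                       effect = effects[h],
                                       stringsAsFactors = FALSE))
    }
  }

  geneAnnot <- data.frame(gene_id = geneIds, chrom = gchrom,
                          start = gstart, end = gstart + glen,
                          strand = gstrand, coding = TRUE,
                          stringsAsFactors = FALSE)
  truth$cis <- cis
  truth$trans <- trans
  list(expr = ExprSet(expr, geneAnnot = geneAnnot), truth = truth)
}
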
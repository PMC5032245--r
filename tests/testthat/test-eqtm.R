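# Shared mid-sized cohort with planted cis and trans structure.
eqtmFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- simulationDesign(
        nSamples = 400, nCpgs = 120,
        classMix = c(null = 1 / 6, constant = 5 / 6),
        sdBase = 0.04, sdSlopePerDecade = 0.08,
        nGenes = 60, cisLinkFraction = 0.03, cisEffect = 1,
        cisDecoys = 5, exprNoiseSd = 0.3,
        transHub = list(nHubGenes = 1, nAvmpsPerHub = 60,
                        effectSize = 1),
        rngSeed = 37)
      co <- simulateCohort(d)
      se <- simulateExpression(co, d)
      cfg <- vmpConfig(minYoung = 2)
      tab <- scanVariability(co$beta, cfg)
      avmps <- tab$cpg_id[tab$bp_p_bonferroni <= 0.05 &
                            tab$direction == "increase"]
      cache <<- list(beta = co$beta, expr = se$expr, truth = se$truth,
                     cfg = cfg, avmps = avmps)
    }
    cache
  }
})

test_that("hub threshold reproduces the 5% bookkeeping", {
  expect_identical(hubThreshold(6366, 0.05), 318L)
  expect_identical(hubThreshold(100, 0.05), 5L)
  expect_identical(hubThreshold(6366, 0.05),
                   as.integer(floor(0.05 * 6366)))
  expect_error(hubThreshold(0, 0.05))
})

test_that("per-pair association p matches an lm oracle", {
  fx <- eqtmFixture()
  hits <- cisMap(fx$beta, fx$expr, fx$avmps, fx$cfg)
  expect_gt(nrow(hits), 0)
  cd <- as.data.frame(SummarizedExperiment::colData(fx$beta))
  for (k in seq_len(min(3, nrow(hits)))) {
    y <- exprValues(fx$expr)[hits$gene_id[k], ]
    x <- betaValues(fx$beta)[hits$cpg_id[k], ]
    fit <- summary(lm(y ~ x + cd$sex + cd$neutro + cd$mono + cd$eos +
                        cd$baso))
    expect_equal(hits$p_raw[k], fit$coefficients["x", 4],
                 tolerance = 1e-8)
    expect_equal(hits$beta_coefficient[k],
                 fit$coefficients["x", 1], tolerance = 1e-8)
  }
})

test_that("a planted cis pair is recovered through the hierarchy", {
  fx <- eqtmFixture()
  hits <- cisMap(fx$beta, fx$expr, fx$avmps, fx$cfg)
  planted <- fx$truth$cis
  found <- merge(hits, planted, by = c("cpg_id", "gene_id"))
  expect_gte(nrow(found), 1)
  expect_true(all(found$p_fdr <= 0.05))
  # at most one gene retained per aVMP
  expect_false(anyDuplicated(hits$cpg_id) > 0)
  # cis distance constraint honoured exhaustively
  expect_true(all(abs(hits$distance_bp) <= fx$cfg$cisWindow))
})

test_that("trans mapping recovers the planted hub and labels it up", {
  fx <- eqtmFixture()
  tr <- transMap(fx$beta, fx$expr, fx$avmps, fx$cfg)
  hubGene <- unique(fx$truth$trans$gene_id)
  expect_true(hubGene %in% tr$hits$gene_id)
  # every retained pair honours the trans distance constraint
  rd <- as.data.frame(SummarizedExperiment::rowData(fx$beta))
  gd <- as.data.frame(SummarizedExperiment::rowData(fx$expr))
  for (k in seq_len(nrow(tr$pairs))) {
    i <- match(tr$pairs$cpg_id[k], rownames(fx$beta))
    g <- match(tr$pairs$gene_id[k], rownames(fx$expr))
    if (rd$chrom[i] == gd$chrom[g])
      expect_gt(abs(tr$pairs$distance_bp[k]),
                fx$cfg$transMinDistance)
  }
  expect_true(all(is.na(tr$pairs$distance_bp) |
                    abs(tr$pairs$distance_bp) >
                      fx$cfg$transMinDistance))
})

test_that("opposite-sign hubs split into up and down clusters", {
  d <- simulationDesign(
    nSamples = 400, nCpgs = 140, classMix = c(constant = 1),
    sdBase = 0.04, sdSlopePerDecade = 0.08, nGenes = 30,
    exprNoiseSd = 0.3,
    transHub = list(nHubGenes = 2, nAvmpsPerHub = 60,
                    effectSize = c(1, -1)),
    rngSeed = 41)
  co <- simulateCohort(d)
  se <- simulateExpression(co, d)
  cfg <- vmpConfig(minYoung = 2)
  tab <- scanVariability(co$beta, cfg)
  avmps <- tab$cpg_id[tab$bp_p_bonferroni <= 0.05 &
                        tab$direction == "increase"]
  tr <- transMap(co$beta, se$expr, avmps, cfg)
  expect_setequal(tr$clusters$cluster, c("up", "down"))
  up <- tr$clusters$gene_id[tr$clusters$cluster == "up"]
  posHub <- unique(se$truth$trans$gene_id[se$truth$trans$effect > 0])
  expect_true(posHub %in% up)
})

test_that("null expression yields no trans hubs", {
  d <- simulationDesign(
    nSamples = 300, nCpgs = 100, classMix = c(constant = 1),
    sdBase = 0.04, sdSlopePerDecade = 0.08, nGenes = 40,
    rngSeed = 43)
  co <- simulateCohort(d)
  se <- simulateExpression(co, d)
  cfg <- vmpConfig(minYoung = 2)
  tab <- scanVariability(co$beta, cfg)
  avmps <- tab$cpg_id[tab$bp_p_bonferroni <= 0.05 &
                        tab$direction == "increase"]
  tr <- suppressWarnings(transMap(co$beta, se$expr, avmps, cfg))
  expect_equal(nrow(tr$hits), 0)
  expect_equal(nrow(tr$clusters), 0)
})

test_that("retained pairs are invariant to gene order", {
  fx <- eqtmFixture()
  perm <- sample(nrow(fx$expr))
  eshuf <- fx$expr[perm, ]
  tr1 <- transMap(fx$beta, fx$expr, fx$avmps, fx$cfg)
  tr2 <- transMap(fx$beta, eshuf, fx$avmps, fx$cfg)
  key <- function(p) sort(paste(p$cpg_id, p$gene_id))
  expect_identical(key(tr1$pairs), key(tr2$pairs))
})

test_that("BH selection matches the brute-force step-up rule", {
  set.seed(6)
  for (k in 1:10) {
    m <- sample(5:100, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- sample(c(0.05, 0.1, 0.2), 1)
    mine <- which(p.adjust(p, "BH") <= q)
    expect_identical(mine, bhOracle(p, q))
  }
})

test_that("direction concordance matches the exact binomial oracle", {
  a <- c(rep(1, 15), rep(-1, 5))
  names(a) <- sprintf("cg%02d", 1:20)
  b <- setNames(rep(1, 20), names(a))
  dc <- directionConcordance(a, b)
  expect_equal(dc$concordance, 0.75)
  pOracle <- sum(dbinom(c(0:5, 15:20), 20, 0.5))
  expect_equal(dc$p, pOracle, tolerance = 1e-12)
  expect_equal(directionConcordance(a, a)$concordance, 1)
  expect_equal(directionConcordance(a, -a)$concordance, 0)
  expect_error(directionConcordance(a, setNames(1, "zz")), "shared")
})
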
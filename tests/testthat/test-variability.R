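test_that("residualization matches the closed-form hat-matrix oracle", {
  bs <- toyBetaSet(nSamples = 6, nCpgs = 4, seed = 7)
  r <- residualize(bs)
  X <- cbind(1, sampleAges(bs), sampleSex(bs),
             cellFractions(bs)[, "fracB"])
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  for (i in 1:4) {
    y <- betaValues(bs)[i, ]
    expect_equal(unname(r[i, ]), unname(drop((diag(6) - H) %*% y)),
                 tolerance = 1e-10)
  }
})

test_that("exact fits leave zero residuals", {
  bs <- toyBetaSet(nSamples = 10, nCpgs = 2, seed = 1)
  b <- betaValues(bs)
  b[1, ] <- 0.5                                     # constant CpG
  b[2, ] <- 0.2 + 0.005 * sampleAges(bs)            # linear in age
  bs2 <- BetaSet(b, covariates = data.frame(
    sample_id = colnames(b), age = sampleAges(bs), sex = sampleSex(bs)))
  r <- residualize(bs2, terms = "age")
  expect_equal(max(abs(r)), 0, tolerance = 1e-12)
})

test_that("rank-deficient designs fail naming the collinear column", {
  b <- matrix(runif(20, 0.2, 0.8), 2, 10,
              dimnames = list(c("cgA", "cgB"), paste0("s", 1:10)))
  cov <- data.frame(sample_id = colnames(b), age = 1:10 * 5 + 15,
                    sex = rep(0, 10))  # sex constant == intercept
  bs <- BetaSet(b, covariates = cov)
  expect_error(residualize(bs, terms = c("age", "sex")), "sex")
})

test_that("Shannon entropy identities hold", {
  n <- 5
  mk <- function(vals) {
    b <- matrix(vals, length(vals) / n, n,
                dimnames = list(sprintf("cg%d",
                                        seq_len(length(vals) / n)),
                                sprintf("s%d", seq_len(n))))
    BetaSet(b)
  }
  s1 <- shannonEntropy(mk(rep(0.5, 2 * n)), adjust = FALSE)
  expect_equal(unname(s1), rep(1, n), tolerance = 1e-12)
  s0 <- shannonEntropy(mk(rep(1e-6, 2 * n)), adjust = FALSE)
  expect_lt(max(s0), 0.001)
  # two CpGs at (0.5, eps): the 0.5 term contributes log(1/2), the eps
  # term ~0, so S = 1/2
  s2 <- shannonEntropy(mk(rep(c(0.5, 1e-6), n)), adjust = FALSE)
  expect_equal(unname(s2), rep(0.5, n), tolerance = 1e-3)
})

test_that("entropy stays in [0, 1] and equals 1 only at 0.5", {
  set.seed(8)
  for (k in 1:5) {
    b <- matrix(runif(200), 20, 10,
                dimnames = list(sprintf("cg%d", 1:20),
                                sprintf("s%d", 1:10)))
    s <- shannonEntropy(BetaSet(b), adjust = FALSE)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(s < 1))
  }
})

test_that("scan stages reproduce an explicit normal-equations oracle", {
  bs <- toyBetaSet(nSamples = 8, nCpgs = 3, seed = 3)
  cfg <- toyConfig()
  tab <- scanVariability(bs, cfg)
  X <- cbind(intercept = 1, age = unname(sampleAges(bs)),
             sex = unname(sampleSex(bs)),
             fracB = unname(cellFractions(bs)[, "fracB"]))
  for (i in 1:3) {
    y <- betaValues(bs)[i, ]
    o1 <- olsOracle(y, X, "age")
    expect_equal(tab$mean_slope_per_decade[i], 10 * o1$coef["age"],
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(tab$mean_p[i], o1$p, tolerance = 1e-8)
    o2 <- olsOracle(o1$resid^2, X, "age")
    expect_equal(tab$bp_stat[i], o2$t, tolerance = 1e-8)
    expect_equal(tab$bp_p[i], o2$p, tolerance = 1e-8)
    expect_equal(tab$bp_p_bonferroni[i], min(1, o2$p * 3),
                 tolerance = 1e-8)
    # effect size from the fitted variance line at the mean-age decade
    abar <- mean(sampleAges(bs))
    vat <- function(a) max(o2$coef["intercept"] + o2$coef["age"] * a +
                             o2$coef["sex"] * mean(X[, "sex"]) +
                             o2$coef["fracB"] * mean(X[, "fracB"]), 0)
    expect_equal(tab$sd_change_per_decade[i],
                 sqrt(vat(abar + 5)) - sqrt(vat(abar - 5)),
                 tolerance = 1e-8)
  }
})

test_that("the scan separates mean drift from variance change", {
  # pure-aDMP CpGs: strong mean slope, constant variance
  d <- simulationDesign(nSamples = 600, nCpgs = 300,
                        classMix = c(admp = 1),
                        meanSlopePerDecade = 0.05, rngSeed = 17)
  co <- simulateCohort(d)
  tab <- scanVariability(co$beta, vmpConfig(minYoung = 2))
  expect_gt(mean(tab$is_admp), 0.9)
  ks <- suppressWarnings(ks.test(tab$bp_p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted variance slopes are detected and recovered", {
  d <- simulationDesign(nSamples = 1000, nCpgs = 150,
                        classMix = c(constant = 1), sdBase = 0.04,
                        sdSlopePerDecade = 0.05, rngSeed = 19)
  co <- simulateCohort(d)
  tab <- scanVariability(co$beta, vmpConfig(minYoung = 2))
  expect_gt(mean(tab$bp_p_bonferroni <= 0.05), 0.95)
  expect_true(all(tab$direction[tab$bp_p_bonferroni <= 0.05] ==
                    "increase"))
  # beta-scale truncation attenuates the estimate below the planted
  # 0.05/decade; recovery is asserted at the +-0.02 tolerance
  expect_equal(median(tab$sd_change_per_decade), 0.05, tolerance = 0.4)
  expect_lt(abs(median(tab$sd_change_per_decade) - 0.05), 0.02)
})

test_that("increasing planted SD slope never decreases the test signal", {
  meds <- vapply(c(0.01, 0.03, 0.05, 0.08), function(s) {
    d <- simulationDesign(nSamples = 500, nCpgs = 60,
                          classMix = c(constant = 1), sdBase = 0.04,
                          sdSlopePerDecade = s, rngSeed = 23)
    co <- simulateCohort(d)
    tab <- scanVariability(co$beta, vmpConfig(minYoung = 2))
    median(abs(tab$bp_stat))
  }, numeric(1))
  expect_true(all(diff(meds) > -0.3))  # monotone up to noise
  expect_gt(meds[4], meds[1])
})

test_that("classification follows the archetype rules", {
  rec <- data.frame(
    cpg_id = c("a", "b", "c", "d", "e"),
    baseline_young_mean = c(0.10, 0.85, 0.50, 0.50, 0.10),
    mean_slope_per_decade = c(0.03, -0.03, 0.002, 0.04, 0.03),
    direction = c(rep("increase", 4), "decrease"),
    is_avmp_candidate = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    class_label = "none", stringsAsFactors = FALSE)
  out <- classifyAvmps(rec, vmpConfig())
  expect_equal(out$class_label,
               c("gain", "loss", "constant", "constant", "none"))
})

test_that("Z-scores match the displayed formula and its identities", {
  young <- c(0.1, 0.2, 0.2, 0.3, 0.2)
  b <- matrix(c(young, 0.2, 0.4), 1, 7,
              dimnames = list("cgA", sprintf("s%d", 1:7)))
  cov <- data.frame(sample_id = colnames(b),
                    age = c(rep(25, 5), 50, 70), sex = 0)
  bs <- BetaSet(b, covariates = cov)
  z <- zscoreVsYoung(bs, "cgA", youngAgeMax = 30)
  expect_equal(z["cgA", "s6"], 0)                   # at the young mean
  expect_equal(z["cgA", "s7"], 0.2 / sd(young))     # hand formula
  expect_equal(z["cgA", "s7"], 2.8284, tolerance = 1e-4)
  # young reference standardization: mean 0, SD 1 (n-1 denominator)
  expect_equal(mean(z[1, 1:5]), 0, tolerance = 1e-10)
  expect_equal(sd(z[1, 1:5]), 1, tolerance = 1e-10)
})

test_that("Z-score young standardization holds on arbitrary input", {
  bs <- toyBetaSet(nSamples = 30, nCpgs = 10, seed = 77,
                   ages = c(rep(22, 10), seq(35, 85, length.out = 20)))
  z <- zscoreVsYoung(bs, rownames(bs), youngAgeMax = 30)
  young <- sampleAges(bs) < 30
  expect_lt(max(abs(rowMeans(z[, young]))), 1e-10)
  expect_lt(max(abs(apply(z[, young], 1, sd) - 1)), 1e-10)
})

test_that("refined-fraction rescan is idempotent and guards its inputs", {
  d <- simulationDesign(nSamples = 400, nCpgs = 80,
                        classMix = c(null = 0.5, constant = 0.5),
                        sdSlopePerDecade = 0.08, rngSeed = 29)
  co <- simulateCohort(d)
  cfg <- vmpConfig(minYoung = 2)
  tab <- scanVariability(co$beta, cfg)
  prior <- tab$cpg_id[tab$bp_p_bonferroni <= 0.05 &
                        tab$direction == "increase"]
  expect_gt(length(prior), 20)
  cd <- as.data.frame(SummarizedExperiment::colData(co$beta))
  cov <- data.frame(sample_id = colnames(co$beta), cd)
  res <- refinedFractionRescan(co$beta, cov, prior, cfg)
  expect_equal(res$reidentifiedFraction, 1)
  expect_error(refinedFractionRescan(co$beta, cov, character(0), cfg),
               "empty")
})

test_that("refined fractions of pure noise keep strong aVMPs", {
  d <- simulationDesign(nSamples = 800, nCpgs = 100,
                        classMix = c(constant = 1),
                        sdSlopePerDecade = 0.08, rngSeed = 31)
  co <- simulateCohort(d)
  cfg <- vmpConfig(minYoung = 2)
  tab <- scanVariability(co$beta, cfg)
  prior <- tab$cpg_id[tab$bp_p_bonferroni <= 0.05 &
                        tab$direction == "increase"]
  set.seed(1)
  cd <- as.data.frame(SummarizedExperiment::colData(co$beta))
  noise <- matrix(runif(5 * nrow(cd), 0, 0.4), nrow(cd), 5)
  noise <- noise / rowSums(noise)
  colnames(noise) <- paste0("ref", 1:5)
  cov <- data.frame(sample_id = colnames(co$beta),
                    age = cd$age, sex = cd$sex, noise)
  res <- refinedFractionRescan(co$beta, cov, prior, cfg)
  expect_gte(res$reidentifiedFraction, 0.9)
})
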
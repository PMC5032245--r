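#' @importFrom stats pt pchisq p.adjust quantile rnorm runif rbinom
#'   setNames binom.test fisher.test
NULL

# Build the sample-level design matrix: intercept + requested terms.
# Compositional cell fractions are collinear with the intercept, so the
# fraction with the largest mean is dropped; its name travels as an
# attribute and is logged by callers.
.designMatrix <- function(bset, terms = c("age", "sex", "fractions")) {
  X <- matrix(1, ncol(bset), 1,
              dimnames = list(colnames(bset), "intercept"))
  if ("age" %in% terms) X <- cbind(X, age = sampleAges(bset))
  if ("sex" %in% terms) X <- cbind(X, sex = sampleSex(bset))
  dropped <- NULL
  if ("fractions" %in% terms) {
    f <- cellFractions(bset)
    if (ncol(f) > 0) {
      dropped <- colnames(f)[which.max(colMeans(f))]
      X <- cbind(X, f[, setdiff(colnames(f), dropped), drop = FALSE])
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient design matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  attr(X, "droppedFraction") <- dropped
  X
}

# Row-wise ordinary least squares of Y (features x samples) on X
# (samples x p).  Rows without missing values share one closed-form
# solve; rows with NAs are refit on their complete cases.
.rowOls <- function(Y, X) {
  m <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  coef <- matrix(NA_real_, m, p, dimnames = list(rownames(Y),
                                                 colnames(X)))
  se <- coef
  resid <- matrix(NA_real_, m, n, dimnames = dimnames(Y))
  df <- rep(NA_real_, m)
  sigma2 <- rep(NA_real_, m)
  complete <- rowSums(is.na(Y)) == 0
  if (any(complete)) {
    XtXinv <- chol2inv(chol(crossprod(X)))
    Yc <- Y[complete, , drop = FALSE]
    B <- Yc %*% X %*% XtXinv
    R <- Yc - tcrossprod(B, X)
    s2 <- rowSums(R^2) / (n - p)
    coef[complete, ] <- B
    resid[complete, ] <- R
    sigma2[complete] <- s2
    se[complete, ] <- sqrt(outer(s2, diag(XtXinv)))
    df[complete] <- n - p
  }
  for (i in which(!complete)) {
    ok <- !is.na(Y[i, ])
    if (sum(ok) <= p) next
    Xi <- X[ok, , drop = FALSE]
    XtXinv <- tryCatch(chol2inv(chol(crossprod(Xi))),
                       error = function(e) NULL)
    if (is.null(XtXinv)) next
    b <- XtXinv %*% crossprod(Xi, Y[i, ok])
    r <- Y[i, ok] - as.vector(Xi %*% b)
    dfi <- sum(ok) - p
    coef[i, ] <- b
    resid[i, ok] <- r
    df[i] <- dfi
    sigma2[i] <- sum(r^2) / dfi
    se[i, ] <- sqrt(sigma2[i] * diag(XtXinv))
  }
  list(coef = coef, se = se, resid = resid, df = df, sigma2 = sigma2)
}

.usableCpgs <- function(b, maxMissingFraction) {
  rowMeans(is.na(b)) <= maxMissingFraction
}

#' Regress covariates out of a beta matrix
#'
#' Per CpG, ordinary-least-squares residuals of methylation on an
#' intercept plus the requested covariate terms.  Missing values are
#' omitted pairwise per CpG and stay missing in the output.
#'
#' @param bset a [BetaSet-class] with covariates attached.
#' @param terms subset of `c("age", "sex", "fractions")`.
#' @return residual matrix with the input's dimnames.
#' @export
residualize <- function(bset, terms = c("age", "sex", "fractions")) {
  X <- .designMatrix(bset, terms)
  .rowOls(betaValues(bset), X)$resid
}

#' Per-sample methylome Shannon entropy
#'
#' Methylation is first residualized on age, sex and cell fractions, then
#' re-centered by adding back each CpG's grand mean so values stay on the
#' beta scale, and clipped to `[eps, 1 - eps]`.  For sample j over the N
#' usable CpGs,
#' \deqn{S_j = \sum_i [ b_{ij} \log b_{ij} + (1-b_{ij}) \log(1-b_{ij}) ] /
#'   (N \log 1/2),}
#' so entropy is 1 when every value is 0.5 and approaches 0 for a fully
#' ordered (all 0/1) methylome.  The natural log is used; the
#' normalization makes the base irrelevant.
#'
#' @param bset a [BetaSet-class] with covariates attached.
#' @param adjust logical; residualize on age, sex and cell fractions first.
#' @param eps clipping bound keeping logs finite.
#' @param config a [vmpConfig()] (missingness rule).
#' @return named numeric vector of per-sample entropies in \[0, 1\].
#' @export
shannonEntropy <- function(bset, adjust = TRUE, eps = 1e-6,
                           config = vmpConfig()) {
  b <- betaValues(bset)
  b <- b[.usableCpgs(b, config$maxMissingFraction), , drop = FALSE]
  if (nrow(b) == 0) stop("no usable CpGs for entropy")
  if (adjust) {
    r <- .rowOls(b, .designMatrix(bset))$resid
    b <- r + rowMeans(b, na.rm = TRUE)
  }
  b <- pmin(pmax(b, eps), 1 - eps)
  term <- b * log(b) + (1 - b) * log1p(-b)
  nUsed <- colSums(!is.na(term))
  if (any(nUsed == 0)) stop("sample(s) without usable CpGs")
  setNames(colSums(term, na.rm = TRUE) / (nUsed * log(0.5)),
           colnames(b))
}

#' Scan CpGs for age-related increases in methylation variability
#'
#' The two-stage heteroscedasticity scan.  Stage 1 regresses each CpG's
#' beta values on age, sex and cell fractions; the age coefficient (x 10)
#' is the mean change per decade and a Bonferroni-significant age term
#' flags the CpG as an aDMP.  Stage 2 regresses the squared stage-1
#' residuals on the same covariates and tests the age coefficient
#' (Breusch-Pagan-type heteroscedasticity test; the default Wald form
#' tests age only, leaving sex and cell composition as adjustments).
#'
#' The variability effect size converts the fitted linear variance
#' function v(a) into a change of standard deviation across the decade
#' centered at the mean age:
#' `sd_change_per_decade = sqrt(max(v(mean age + 5), 0)) -
#'  sqrt(max(v(mean age - 5), 0))`,
#' with other covariates held at their means.  A CpG is an aVMP candidate
#' when its Bonferroni-corrected stage-2 p-value is at most
#' `alphaBonferroni` and `|sd_change_per_decade|` reaches
#' `effectThresholdPerDecade` (0.05 beta units, i.e. 5\% per 10 years, by
#' default).
#'
#' @param bset a [BetaSet-class] with covariates attached.
#' @param config a [vmpConfig()].
#' @param terms covariate terms; `"age"` is mandatory.
#' @return `data.frame` with one row per scanned CpG: `cpg_id`, `n_used`,
#'   `mean_slope_per_decade`, `mean_p`, `is_admp`, `baseline_young_mean`,
#'   `bp_stat`, `bp_p`, `bp_p_bonferroni`, `sd_change_per_decade`,
#'   `direction`, `is_avmp_candidate`, `class_label` (filled by
#'   [classifyAvmps()]).  Attributes: `nScanned` (the Bonferroni
#'   denominator), `droppedFraction`, `skipped` (zero-variance CpGs).
#' @export
scanVariability <- function(bset, config = vmpConfig(),
                            terms = c("age", "sex", "fractions")) {
  if (!("age" %in% terms)) stop("'age' must be part of the scan design")
  age <- sampleAges(bset)
  if (ncol(bset) < config$minSamples)
    stop("scan requires at least ", config$minSamples,
         " samples with complete covariates")
  b <- betaValues(bset)
  usable <- .usableCpgs(b, config$maxMissingFraction)
  b <- b[usable, , drop = FALSE]
  if (nrow(b) == 0) stop("no usable CpGs")
  X <- .designMatrix(bset, terms)
  s1 <- .rowOls(b, X)

  skipped <- is.na(s1$sigma2) | s1$sigma2 <= 0
  if (any(skipped))
    message(sum(skipped), " CpG(s) skipped (zero residual variance)")
  b <- b[!skipped, , drop = FALSE]
  s1 <- lapply(s1, function(x)
    if (is.matrix(x)) x[!skipped, , drop = FALSE] else x[!skipped])
  mScan <- nrow(b)

  tMean <- s1$coef[, "age"] / s1$se[, "age"]
  meanP <- 2 * pt(-abs(tMean), s1$df)
  s2 <- .rowOls(s1$resid^2, X)

  if (config$bpMethod == "wald") {
    bpStat <- s2$coef[, "age"] / s2$se[, "age"]
    bpP <- 2 * pt(-abs(bpStat), s2$df)
  } else {
    # classical LM statistic n * R-squared of the auxiliary regression
    e2 <- s1$resid^2
    tss <- rowSums((e2 - rowMeans(e2, na.rm = TRUE))^2, na.rm = TRUE)
    rss <- rowSums(s2$resid^2, na.rm = TRUE)
    nUsed <- rowSums(!is.na(e2))
    bpStat <- nUsed * (1 - rss / tss)
    bpP <- pchisq(bpStat, df = ncol(X) - 1, lower.tail = FALSE)
  }
  bpBonf <- pmin(1, bpP * mScan)

  # fitted variance at the decade around the mean age, other covariates
  # at their means
  others <- setdiff(colnames(X), c("intercept", "age"))
  offset <- s2$coef[, "intercept"] +
    if (length(others))
      as.vector(s2$coef[, others, drop = FALSE] %*% colMeans(X)[others])
    else 0
  vAt <- function(a) pmax(offset + s2$coef[, "age"] * a, 0)
  aBar <- mean(age)
  sdChange <- sqrt(vAt(aBar + 5)) - sqrt(vAt(aBar - 5))
  zeroVar <- vAt(min(age)) == 0 & vAt(max(age)) == 0
  direction <- ifelse(sdChange > 0, "increase",
                      ifelse(sdChange < 0, "decrease",
                             ifelse(s2$coef[, "age"] > 0,
                                    "increase", "decrease")))
  effect <- if (config$effectRelative) {
    atMean <- sqrt(vAt(aBar))
    ifelse(atMean > 0, abs(sdChange) / atMean, 0)
  } else abs(sdChange)
  candidate <- !is.na(bpBonf) & bpBonf <= config$alphaBonferroni &
    effect >= config$effectThresholdPerDecade & !zeroVar

  young <- age < config$youngAgeMax
  if (sum(young) < config$minYoung) {
    warning("fewer than ", config$minYoung, " young samples; ",
            "using the youngest decile as baseline reference")
    young <- age <= quantile(age, 0.1)
  }
  baseline <- rowMeans(b[, young, drop = FALSE], na.rm = TRUE)

  out <- data.frame(
    cpg_id = rownames(b),
    n_used = rowSums(!is.na(b)),
    mean_slope_per_decade = 10 * s1$coef[, "age"],
    mean_p = meanP,
    is_admp = !is.na(meanP) & pmin(1, meanP * mScan) <=
      config$alphaBonferroni,
    baseline_young_mean = baseline,
    bp_stat = bpStat,
    bp_p = bpP,
    bp_p_bonferroni = bpBonf,
    sd_change_per_decade = sdChange,
    direction = direction,
    is_avmp_candidate = candidate,
    class_label = "none",
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "nScanned") <- mScan
  attr(out, "droppedFraction") <- attr(X, "droppedFraction")
  attr(out, "skipped") <- sum(skipped)
  out
}

#' Classify aVMP candidates into gain, loss and constant subtypes
#'
#' Deterministic rules over the scan output, applied to candidates whose
#' variability increases with age (decrease-direction candidates keep the
#' label `"none"` and are excluded from downstream stages): gain when the
#' young baseline is hypomethylated (`< lowBaseline`) and the mean slope
#' exceeds `+meanSlopeFloor`; loss when hypermethylated (`> highBaseline`)
#' with slope below `-meanSlopeFloor`; constant when the mean slope is
#' within `meanSlopeFloor` of zero.  Any remaining candidate is assigned
#' the class whose baseline-interval midpoint (0.15 / 0.50 / 0.85) is
#' nearest to its young baseline.
#'
#' @param records scan output of [scanVariability()].
#' @param config a [vmpConfig()].
#' @return `records` with `class_label` in
#'   `c("gain", "loss", "constant", "none")`.
#' @export
classifyAvmps <- function(records, config = vmpConfig()) {
  lo <- config$lowBaseline; hi <- config$highBaseline
  fl <- config$meanSlopeFloor
  lab <- records$class_label
  idx <- which(records$is_avmp_candidate & records$direction == "increase")
  for (i in idx) {
    b <- records$baseline_young_mean[i]
    s <- records$mean_slope_per_decade[i]
    lab[i] <- if (b < lo && s > fl) "gain"
      else if (b > hi && s < -fl) "loss"
      else if (abs(s) <= fl) "constant"
      else {
        mids <- c(gain = lo / 2, constant = (lo + hi) / 2,
                  loss = (1 + hi) / 2)
        names(which.min(abs(mids - b)))
      }
  }
  records$class_label <- lab
  records
}

#' Z-scores against a young reference
#'
#' For aVMP i and sample j,
#' \deqn{Z_{ij} = (M_{ij} - \bar{M}_{y,i}) / \sigma_{y,i},}
#' where the mean and standard deviation (denominator n - 1) are taken
#' over the young reference samples (age below `youngAgeMax`).
#'
#' @param bset a [BetaSet-class] with covariates attached.
#' @param avmps character vector of CpG identifiers to score.
#' @param youngAgeMax age bound (exclusive) of the reference.
#' @return matrix of Z-scores (aVMPs x samples).  CpGs with zero young
#'   standard deviation get `NA` rows (with a message).
#' @export
zscoreVsYoung <- function(bset, avmps, youngAgeMax = 30) {
  b <- betaValues(bset)
  miss <- setdiff(avmps, rownames(b))
  if (length(miss))
    stop("unknown CpG(s): ", paste(utils::head(miss, 5), collapse = ", "))
  b <- b[avmps, , drop = FALSE]
  young <- sampleAges(bset) < youngAgeMax
  ny <- rowSums(!is.na(b[, young, drop = FALSE]))
  if (any(ny < 2))
    stop("need >= 2 young samples with non-missing values per CpG")
  my <- rowMeans(b[, young, drop = FALSE], na.rm = TRUE)
  sy <- sqrt(rowSums((b[, young, drop = FALSE] - my)^2,
                     na.rm = TRUE) / (ny - 1))
  z <- (b - my) / sy
  if (any(sy == 0)) {
    message(sum(sy == 0),
            " CpG(s) with zero young-reference SD set to NA")
    z[sy == 0, ] <- NA_real_
  }
  z
}

#' Re-scan prior aVMPs with refined cell-fraction covariates
#'
#' Sensitivity analysis: the variance scan is repeated on a covariate set
#' carrying more finely resolved cell-type fractions, restricted to a
#' previously identified aVMP set, and re-identification is judged by
#' Benjamini-Hochberg FDR across that restricted set (increase direction
#' required).
#'
#' @param bset a [BetaSet-class] (beta values of the cohort).
#' @param refinedCovariates covariate `data.frame` (with `sample_id`)
#'   holding the refined fraction columns.
#' @param priorAvmps character vector of previously identified aVMPs.
#' @param config a [vmpConfig()].
#' @return list with `table` (scan rows plus `p_fdr` and `reidentified`)
#'   and `reidentifiedFraction`.
#' @export
refinedFractionRescan <- function(bset, refinedCovariates, priorAvmps,
                                  config = vmpConfig()) {
  if (length(priorAvmps) == 0) stop("empty prior aVMP set")
  miss <- setdiff(priorAvmps, rownames(bset))
  if (length(miss))
    stop("prior aVMP(s) absent from beta matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  b <- betaValues(bset)[priorAvmps, , drop = FALSE]
  annotDf <- as.data.frame(rowData(bset))[priorAvmps, , drop = FALSE]
  annot <- if ("pos" %in% colnames(annotDf))
    data.frame(cpg_id = priorAvmps, annotDf, stringsAsFactors = FALSE)
  sub <- BetaSet(b, annot = annot, covariates = refinedCovariates)
  tab <- scanVariability(sub, config)
  tab$p_fdr <- p.adjust(tab$bp_p, method = "BH")
  tab$reidentified <- tab$p_fdr <= config$fdrQ &
    tab$direction == "increase"
  list(table = tab,
       reidentifiedFraction = mean(tab$reidentified))
}
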
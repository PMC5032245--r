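# Shared fixtures built in code.

# A tiny BetaSet with hand-set covariates; beta values deterministic
# given the seed.
toyBetaSet <- function(nSamples = 8, nCpgs = 3, seed = 42,
                       ages = NULL, withFractions = TRUE) {
  set.seed(seed)
  if (is.null(ages)) ages <- seq(20, 80, length.out = nSamples)
  sex <- rep_len(c(0, 1), nSamples)
  b <- matrix(runif(nCpgs * nSamples, 0.2, 0.8), nCpgs, nSamples,
              dimnames = list(sprintf("cg%03d", seq_len(nCpgs)),
                              sprintf("s%02d", seq_len(nSamples))))
  cov <- data.frame(sample_id = colnames(b), age = ages, sex = sex)
  if (withFractions) {
    f1 <- runif(nSamples, 0.5, 0.7)
    cov$fracA <- f1
    cov$fracB <- 1 - f1
  }
  annot <- data.frame(cpg_id = rownames(b), chrom = "chr1",
                      pos = seq_len(nCpgs) * 1000L)
  BetaSet(b, annot = annot, covariates = cov)
}

# Config with small-sample floors relaxed so toy fixtures scan quietly.
toyConfig <- function(...) {
  vmpConfig(minSamples = 4, minYoung = 1, ...)
}

# Independent normal-equations OLS oracle: coefficients, residuals and
# the two-sided t-test p-value for one coefficient.
olsOracle <- function(y, X, coefName) {
  XtX <- t(X) %*% X
  XtXinv <- solve(XtX)
  b <- XtXinv %*% t(X) %*% y
  r <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(r^2) / df
  se <- sqrt(s2 * diag(XtXinv))
  tt <- unname(b[coefName, 1] / se[coefName])
  list(coef = drop(b), resid = drop(r), t = tt,
       p = 2 * pt(-abs(tt), df))
}

# Exact two-sided Fisher p by hypergeometric point-probability summation
# over all tables with the observed margins.
fisherOracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Brute-force Benjamini-Hochberg step-up: returns the rejection set
# indices at level q.
bhOracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[o[i]] <= q * i / m) k <- i
  if (k == 0) integer(0) else sort(o[seq_len(k)])
}
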
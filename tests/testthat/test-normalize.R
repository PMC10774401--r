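test_that("background subtraction matches hand arithmetic for each method", {
  x <- normFixture(endo = c(10, 3), hk = c(20, 20), pos1 = c(50, 50),
                   pos2 = c(50, 50), neg1 = c(2, 2), neg2 = c(4, 4))
  # add a third negative so negatives are {2,4,8} per lane
  m <- rbind(SummarizedExperiment::assay(x), NEG_03 = c(8, 8))
  x3 <- NanoCountSet(m, probeClass = c(probeClass(x), NEG_03 = "Negative"))

  bgm <- subtractBackground(x3, method = "mean")
  expect_equal(unname(normFactors(bgm)$background), rep(14 / 3, 2))
  out <- SummarizedExperiment::assay(bgm)
  expect_equal(out["GeneA", 1], 10 - 14 / 3)   # 5.333...
  expect_equal(out["GeneA", 2], 1)             # 3 - 4.667 floored at 1
  expect_match(tail(stageLog(bgm), 1), "background:mean")

  bgx <- subtractBackground(x3, method = "max")
  expect_equal(unname(normFactors(bgx)$background), rep(8, 2))

  bgs <- subtractBackground(x3, method = "mean2sd")
  expect_equal(unname(normFactors(bgs)$background),
               rep(14 / 3 + 2 * sd(c(2, 4, 8)), 2))

  # all-zero negatives: zero background, so probes at/above the floor are
  # untouched (the zero-count negatives themselves rise to the floor)
  x0 <- normFixture(endo = c(10, 3), hk = c(20, 20), pos1 = c(50, 50),
                    pos2 = c(50, 50), neg1 = c(0, 0), neg2 = c(0, 0))
  bg0 <- subtractBackground(x0)
  expect_equal(unname(normFactors(bg0)$background), c(0, 0))
  expect_equal(SummarizedExperiment::assay(bg0)[1:4, ],
               SummarizedExperiment::assay(x0)[1:4, ])

  # no Negative probes -> configuration error
  m2 <- matrix(1:4, 2, 2, dimnames = list(c("A", "P"), c("L1", "L2")))
  noneg <- NanoCountSet(m2, probeClass = c("Endogenous", "Positive"))
  expect_error(subtractBackground(noneg), "Negative")
})

test_that("geometric-mean lane scaling equalizes the reference geomeans", {
  # two lanes with Positive geomeans 100 and 400 -> factors 2.0 and 0.5
  x <- normFixture(endo = c(10, 10), hk = c(30, 60), pos1 = c(50, 200),
                   pos2 = c(200, 800), neg1 = c(0, 0), neg2 = c(0, 0))
  x <- subtractBackground(x)
  pn <- positiveControlNormalize(x)
  expect_equal(unname(normFactors(pn)$posFactor), c(2, 0.5))
  m <- SummarizedExperiment::assay(pn)
  geo <- function(v) exp(mean(log(v)))
  expect_equal(geo(m[c("POS_A", "POS_B"), 1]), geo(m[c("POS_A", "POS_B"), 2]))

  # content normalization: housekeeping geomeans 50 and 200 -> 2.0 and 0.5
  y <- normFixture(endo = c(10, 10), hk = c(50, 200), pos1 = c(100, 100),
                   pos2 = c(100, 100), neg1 = c(0, 0), neg2 = c(0, 0))
  y <- positiveControlNormalize(subtractBackground(y))
  cn <- contentNormalize(y)
  expect_equal(unname(normFactors(cn)$contentFactor), c(2, 0.5))
  # factors have geometric mean 1 (spec invariant, 1e-9 relative)
  expect_equal(exp(mean(log(normFactors(cn)$contentFactor))), 1,
               tolerance = 1e-9)

  # identical lanes -> unit factors; single lane -> unit factor
  z <- normFixture(endo = c(7, 7), hk = c(9, 9), pos1 = c(40, 40),
                   pos2 = c(90, 90), neg1 = c(0, 0), neg2 = c(0, 0))
  z <- positiveControlNormalize(subtractBackground(z))
  expect_equal(unname(normFactors(z)$posFactor), c(1, 1))
  one <- normFixture(endo = 7, hk = 9, pos1 = 40, pos2 = 90, neg1 = 0,
                     neg2 = 0)
  one <- positiveControlNormalize(subtractBackground(one))
  expect_equal(unname(normFactors(one)$posFactor), 1)

  # global content reference on a 1-endogenous-gene panel scales by that gene
  g <- normFixture(endo = c(10, 40), hk = c(5, 5), pos1 = c(40, 40),
                   pos2 = c(90, 90), neg1 = c(0, 0), neg2 = c(0, 0))
  g <- positiveControlNormalize(subtractBackground(g))
  gc <- contentNormalize(g, reference = "global")
  expect_equal(SummarizedExperiment::assay(gc)["GeneA", 1],
               SummarizedExperiment::assay(gc)["GeneA", 2])
})

test_that("log2 transform and its exp2 inverse round trip", {
  x <- normFixture(endo = c(1, 7), hk = c(2, 2), pos1 = c(4, 4),
                   pos2 = c(8, 8), neg1 = c(1, 2), neg2 = c(2, 4))
  lt <- log2Transform(x, pseudocount = 1)
  expect_equal(SummarizedExperiment::assay(lt)["GeneA", 2], 3)  # log2(7+1)
  lt0 <- log2Transform(x, pseudocount = 0)
  expect_equal(SummarizedExperiment::assay(lt0)["GeneA", 1], 0) # log2(1)
  back <- 2^SummarizedExperiment::assay(lt0)
  expect_equal(back, SummarizedExperiment::assay(x), tolerance = 1e-12)
})

test_that("quantile normalization matches its definition, ties included", {
  # two lanes [1,3] and [2,4] -> both become [1.5, 3.5]
  m <- matrix(c(1, 3, 2, 4), 2, 2,
              dimnames = list(c("A", "B"), c("L1", "L2")))
  x <- NanoCountSet(m, probeClass = c("Endogenous", "Endogenous"),
                    stageLog = c("raw", "log2"))
  qn <- quantileNormalize(x)
  expect_equal(unname(SummarizedExperiment::assay(qn)),
               matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))

  # identical lanes and single lanes are unchanged
  mi <- matrix(c(5, 1, 5, 1), 2, 2, dimnames = list(c("A", "B"), c("L1", "L2")))
  xi <- NanoCountSet(mi, probeClass = rep("Endogenous", 2),
                     stageLog = c("raw", "log2"))
  expect_equal(SummarizedExperiment::assay(quantileNormalize(xi)), mi * 1.0)
  x1 <- NanoCountSet(mi[, 1, drop = FALSE], probeClass = rep("Endogenous", 2),
                     stageLog = c("raw", "log2"))
  expect_equal(SummarizedExperiment::assay(quantileNormalize(x1)),
               mi[, 1, drop = FALSE] * 1.0)

  # tied values receive the mean of the reference values they span
  mt <- matrix(c(1, 1, 4, 2, 3, 9), 3, 2,
               dimnames = list(c("A", "B", "C"), c("L1", "L2")))
  xt <- NanoCountSet(mt, probeClass = rep("Endogenous", 3),
                     stageLog = c("raw", "log2"))
  qt <- SummarizedExperiment::assay(quantileNormalize(xt))
  ref <- unname(rowMeans(apply(mt, 2, sort)))    # c(1.5, 2, 6.5)
  expect_equal(unname(qt[, 1]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
  expect_equal(unname(qt[, 2]), ref)

  # agrees with limma on tie-free data
  skip_if_not_installed("limma")
  set.seed(1)
  mr <- matrix(rnorm(200), 50, 4,
               dimnames = list(sprintf("G%02d", 1:50), sprintf("L%d", 1:4)))
  mr <- abs(mr) + 1
  xr <- NanoCountSet(mr, probeClass = rep("Endogenous", 50),
                     stageLog = c("raw", "log2"))
  expect_equal(unname(SummarizedExperiment::assay(quantileNormalize(xr))),
               unname(limma::normalizeQuantiles(mr)), tolerance = 1e-12)
})

test_that("stage log gates ordering and forbids double application", {
  sim <- simulateExperiment(simConfig(nEndogenous = 30L, seed = 4))
  x <- sim$counts
  expect_error(positiveControlNormalize(x), "background")
  expect_error(quantileNormalize(x), "log2")
  x <- subtractBackground(x)
  expect_error(subtractBackground(x), "already been applied")
  x <- positiveControlNormalize(x)
  expect_error(positiveControlNormalize(x), "already been applied")
  x <- contentNormalize(x)
  expect_error(contentNormalize(x, reference = "global"),
               "already been applied")
  x <- log2Transform(x)
  x <- quantileNormalize(x)
  expect_error(quantileNormalize(x, scope = "joint"), "already been applied")
})

test_that("the full chain is equivariant under lane relabeling", {
  sim <- simulateExperiment(simConfig(nEndogenous = 60L, seed = 8))
  x <- sim$counts
  set.seed(1); perm <- sample(ncol(x))
  a <- normalizeCounts(x)
  b <- normalizeCounts(x[, perm])
  expect_equal(SummarizedExperiment::assay(a)[, colnames(b)],
               SummarizedExperiment::assay(b), tolerance = 1e-12)
})
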
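test_that("pooled t-test matches the textbook formula and stats::t.test", {
  r <- geneTTest(1:5, 2:6, variant = "pooled")
  expect_equal(r$t, -1)
  expect_equal(r$df, 8)
  expect_equal(r$p, 2 * pt(-1, 8))
  # identical groups -> t = 0, p = 1
  r0 <- geneTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)
  # antisymmetry in t, invariance of p under group swap
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5, 1)
    a <- geneTTest(x, y); b <- geneTTest(y, x)
    expect_equal(a$t, -b$t); expect_equal(a$p, b$p)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(a$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(a$p, ref$p.value, tolerance = 1e-12)
    refw <- t.test(x, y)
    w <- geneTTest(x, y, variant = "welch")
    expect_equal(w$t, unname(refw$statistic), tolerance = 1e-12)
    expect_equal(w$p, refw$p.value, tolerance = 1e-12)
    expect_equal(w$df, unname(refw$parameter), tolerance = 1e-12)
  }
  # degenerate contracts
  d <- geneTTest(c(2, 2, 2), c(5, 5, 5))
  expect_true(d$degenerate); expect_equal(d$p, 0)
})

test_that("t-test p-values agree with the permutation null", {
  # the 5v5 permutation null is coarse (252 splits), so pointwise agreement
  # fluctuates; the t p-value must track the exact permutation p to within
  # 0.02 on average over random vectors
  splits <- combn(10, 5)
  exactPermP <- function(x, y) {
    pool <- c(x, y)
    obs <- abs(geneTTest(x, y)$t)
    ts <- apply(splits, 2, function(idx)
      abs(geneTTest(pool[idx], pool[-idx])$t))
    mean(ts >= obs - 1e-12)
  }
  set.seed(42)
  diffs <- replicate(30, {
    x <- rnorm(5); y <- rnorm(5, 0.8)
    abs(geneTTest(x, y)$p - exactPermP(x, y))
  })
  expect_lt(mean(diffs), 0.02)

  # a 10,000-draw Monte Carlo permutation agrees with the exact enumeration
  set.seed(43)
  x <- rnorm(5); y <- rnorm(5, 0.8)
  pool <- c(x, y); obs <- abs(geneTTest(x, y)$t)
  mc <- replicate(10000, {
    idx <- sample(10, 5)
    abs(geneTTest(pool[idx], pool[-idx])$t)
  })
  expect_lt(abs(mean(mc >= obs - 1e-12) - exactPermP(x, y)), 0.02)
})

test_that("runComparison computes log2FC on Endogenous genes only", {
  sim <- simulateExperiment(simConfig(nEndogenous = 80L, nDegDarkOnly = 5L,
                                      seed = 31))
  norm <- normalizeCounts(sim$counts)
  tab <- runComparison(norm, region = "HYP", phase = "dark")
  expect_equal(nrow(tab), 80L)
  expect_true(all(grepl("^GENE_", tab$gene)))
  # log2fc equals mean(tumor) - mean(vehicle) on the log2 matrix
  cd <- SummarizedExperiment::colData(norm)
  m <- SummarizedExperiment::assay(norm)
  tum <- cd$region == "HYP" & cd$phase == "dark" & cd$condition == "tumor"
  veh <- cd$region == "HYP" & cd$phase == "dark" & cd$condition == "vehicle"
  g <- tab$gene[1]
  expect_equal(tab$log2fc[1], mean(m[g, tum]) - mean(m[g, veh]))
  md <- S4Vectors::metadata(tab)
  expect_equal(md$nTumor, 5L); expect_equal(md$nVehicle, 5L)
  # missing condition -> error
  onlyTum <- norm[, cd$condition == "tumor"]
  expect_error(runComparison(onlyTum, "HYP", "dark"), "replicates")
  # raw data refused
  expect_error(runComparison(sim$counts, "HYP", "dark"), "log2")
})

test_that("p filter uses a strict cutoff and no correction", {
  tab <- statTable(log2fc = c(1, -1, 2), p = c(0.05, 0.049, 0.2))
  tab <- filterP(tab, alpha = 0.05)
  expect_equal(tab$flag_p, c(FALSE, TRUE, FALSE))
  expect_equal(tab$direction, c("none", "down", "none"))
  expect_error(filterP(tab, alpha = 0), "alpha")
  expect_error(filterP(tab, alpha = 1), "alpha")
  # uniform p-values -> flagged fraction ~ alpha
  set.seed(7)
  big <- statTable(log2fc = rnorm(20000), p = runif(20000))
  big <- filterP(big, 0.05)
  expect_lt(abs(mean(big$flag_p) - 0.05), 0.01)
})

test_that("fold-change SD filter matches the hand-computed outlier example", {
  # 98 zeros plus {+10, -10}: mu = 0, sigma = sqrt(200/99), cutoff ~ 2.8427
  fc <- c(rep(0, 98), 10, -10)
  tab <- filterFcSd(statTable(log2fc = fc), k = 2)
  md <- S4Vectors::metadata(tab)
  expect_equal(md$fc_mean, 0)
  expect_equal(md$fc_sd, sqrt(200 / 99))
  expect_equal(which(tab$flag_fc), c(99L, 100L))
  expect_equal(tab$direction[99:100], c("up", "down"))
  # all-equal log2fc: zero SD flags nothing, with a warning
  expect_warning(z <- filterFcSd(statTable(log2fc = rep(1.3, 10))), "zero SD")
  expect_false(any(z$flag_fc))
})

test_that("combined filter is the conjunction and counts are monotone in cutoffs", {
  set.seed(11)
  tab <- statTable(log2fc = rnorm(500), p = runif(500))
  tab <- filterCombined(filterFcSd(filterP(tab, 0.05), k = 2))
  expect_equal(tab$flag_both, tab$flag_p & tab$flag_fc)
  expect_lte(sum(tab$flag_both), min(sum(tab$flag_p), sum(tab$flag_fc)))
  # monotone in alpha, antitone in k
  n_p <- sapply(c(0.01, 0.05, 0.2), function(a) sum(filterP(tab, a)$flag_p))
  expect_true(all(diff(n_p) >= 0))
  n_fc <- sapply(c(1, 2, 3), function(k) sum(filterFcSd(tab, k)$flag_fc))
  expect_true(all(diff(n_fc) <= 0))
  # direction always matches the log2fc sign for flagged genes
  fl <- tab$flag_p | tab$flag_fc | tab$flag_both
  expect_true(all(tab$direction[fl & tab$log2fc > 0] == "up"))
  expect_true(all(tab$direction[fl & tab$log2fc < 0] == "down"))
})

test_that("planted +2 log2 effects are recovered within [1.5, 2.5]", {
  # recovery of the estimator on geometric-mean-normalized log2 data; the
  # quantile stage is assessed separately below (it shrinks extreme FCs)
  hits <- 0L; total <- 0L
  shrink_full <- c(); fc_gm <- c()
  for (s in 1:20) {
    sim <- simulateExperiment(simConfig(nDegDarkOnly = 5L, dispersion = 0.05,
                                        seed = 400 + s))
    norm <- normalizeCounts(sim$counts, quantile = FALSE)
    tab <- runComparison(norm, "HYP", "dark")
    fc <- c(tab[sim$truth$degSets$dark_up, "log2fc"],
            -tab[sim$truth$degSets$dark_down, "log2fc"])
    hits <- hits + sum(fc >= 1.5 & fc <= 2.5)
    total <- total + length(fc)
    fc_gm <- c(fc_gm, fc)
    nq <- quantileNormalize(norm)
    tq <- runComparison(nq, "HYP", "dark")
    shrink_full <- c(shrink_full,
                     c(tq[sim$truth$degSets$dark_up, "log2fc"],
                       -tq[sim$truth$degSets$dark_down, "log2fc"]))
  }
  expect_gte(hits / total, 0.9)
  # quantile normalization compresses tail fold changes toward the center
  expect_lt(mean(shrink_full), mean(fc_gm))
  expect_gt(mean(shrink_full), 1.5)
})
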
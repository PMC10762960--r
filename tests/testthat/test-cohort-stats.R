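test_that("AUC equals exhaustive pair counting, including ties", {
  set.seed(77)
  for (i in 1:100) {
    n1 <- sample(3:25, 1); n0 <- sample(3:25, 1)
    # integer scores force plenty of ties
    s <- c(sample(0:8, n1, replace = TRUE) + rnorm(n1, 1, 1.5),
           sample(0:8, n0, replace = TRUE))
    s <- round(s)
    y <- rep(c(1, 0), c(n1, n0))
    expect_equal(auc(rocAuc(s, y)), oracleAucPairs(s, y), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  s <- rnorm(60); y <- rbinom(60, 1, 0.5)
  y[1:2] <- c(0, 1)
  a <- auc(rocAuc(s, y))
  expect_equal(auc(rocAuc(exp(s), y)), a)
  expect_equal(auc(rocAuc(qlogis(plogis(s)) * 3 + 10, y)), a)
  expect_equal(auc(rocAuc(rank(s), y)), a)
})

test_that("ROC extremes behave: perfect separation and pure noise", {
  y <- rep(c(1, 0), c(30, 30))
  expect_equal(auc(rocAuc(c(rnorm(30, 10), rnorm(30, -10)), y)), 1.0)
  set.seed(5)
  a <- mean(replicate(50, auc(rocAuc(rnorm(200), rbinom(200, 1, 0.5)))))
  expect_lt(abs(a - 0.5), 0.02)
  r <- rocAuc(rnorm(60), y)
  pts <- rocPoints(r)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$sensitivity[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$sensitivity[nrow(pts)], 1)
  expect_error(rocAuc(rnorm(10), rep(1, 10)), "both classes")
})

test_that("DeLong CI contains the AUC and the SE matches a bootstrap", {
  set.seed(11)
  y <- rep(c(1, 0), c(30, 20))
  s <- c(rnorm(30, 1), rnorm(20))
  r <- rocAuc(s, y)
  expect_true(aucCI(r)[1] <= auc(r) && auc(r) <= aucCI(r)[2])
  delong_se <- (aucCI(r)[2] - aucCI(r)[1]) / (2 * 1.96)
  boot_se <- oracleBootAucSE(s, y, n_boot = 10000)
  expect_lt(abs(delong_se - boot_se) / boot_se, 0.15)
})

test_that("DeLong paired test: exact tie gives P = 1, shifted scores do not", {
  set.seed(12)
  y <- rep(c(1, 0), c(40, 40))
  s <- c(rnorm(40, 1.2), rnorm(40))
  tie <- delongTest(s, s, y)
  expect_equal(tie$p, 1)
  expect_equal(tie$delta, 0)
  other <- delongTest(s, rnorm(80), y)
  expect_lt(other$p, 0.05)
  expect_error(delongTest(s, rep(1, 80), y), "degenerate")
})

test_that("logistic fit recovers known coefficients with valid Wald CIs", {
  set.seed(13)
  # symmetric balanced data: intercept near 0
  x <- rnorm(4000)
  ysym <- rbinom(4000, 1, plogis(1.5 * x))
  fsym <- fitLogisticScores(x, rnorm(4000), ysym)
  expect_lt(abs(fsym$coefficients[["(Intercept)"]]), 0.15)
  # coverage of the generating coefficients over replicate fits
  truth <- c(0.8, -0.5)
  hits <- replicate(300, {
    M <- rnorm(159, 0, 1.5); R <- rnorm(159, 0, 1.5)
    yy <- rbinom(159, 1, plogis(0.2 + truth[1] * M + truth[2] * R))
    if (length(unique(yy)) < 2) return(NA)
    f <- suppressWarnings(fitLogisticScores(M, R, yy))
    f$ci["M", "lower"] <= truth[1] & truth[1] <= f$ci["M", "upper"]
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.92)
  expect_error(fitLogisticScores(1:5, 1:5, rep(1, 5)), "both classes")
})

test_that("group-label logistic fit on a calibrated cohort is of the
           reported order", {
  sc <- scoreCohort(simulateCcfdnaCohort(cohortSpec(seed = 99)))
  fit <- suppressWarnings(fitLogisticScores(sc$M, sc$R, sc$group == "CRC"))
  expect_gt(fit$coefficients[["M"]], 0.25)
  expect_lt(fit$coefficients[["M"]], 2.5)
  expect_lt(fit$p[["M"]], 0.001)
})

test_that("stratified CV is deterministic, separable data reach AUC 1", {
  set.seed(14)
  y <- rep(c(1, 0), c(40, 40))
  M <- ifelse(y == 1, 5, -5) + rnorm(80, 0, 0.1)
  R <- rnorm(80)
  cv <- stratifiedKfoldCv(M, R, y, k = 5, seed = 42)
  expect_equal(auc(cv), 1.0)
  cv2 <- stratifiedKfoldCv(M, R, y, k = 5, seed = 42)
  expect_identical(attr(cv, "folds"), attr(cv2, "folds"))
  expect_identical(auc(cv), auc(cv2))
  # folds are stratified: every fold holds both classes proportionally
  f <- attr(cv, "folds")
  expect_true(all(table(f, y) == 8))
  # permuted labels: chance-level CV AUC at large n (small-sample CV on
  # pure noise is slightly pessimistic, so n matters here)
  set.seed(15)
  yp <- sample(rep(c(1, 0), 200))
  Mp <- rnorm(400); Rp <- rnorm(400)
  aucs <- replicate(10, auc(stratifiedKfoldCv(Mp, Rp, yp, 5,
                                              seed = sample.int(1e6, 1))))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  expect_error(stratifiedKfoldCv(rnorm(8), rnorm(8), rep(c(0, 1), 4), k = 5),
               "at least k")
})

test_that("Dunn test agrees with a permutation null and handles ties", {
  set.seed(16)
  # identical groups: adjusted P near 1
  v <- rep(c(1, 2, 3, 4, 5), 8)
  g <- rep(c("ctl", "g1"), each = 20)
  d <- dunnTest(v, g, "ctl")
  expect_gt(d$p_adj, 0.9)
  # strongly shifted group is detected
  v2 <- c(rnorm(50), rnorm(50, 3))
  g2 <- rep(c("ctl", "g1"), each = 50)
  expect_lt(dunnTest(v2, g2, "ctl")$p_adj, 0.001)
  # z-based P close to the merged-rank permutation null (3 groups, shifts)
  v3 <- c(rnorm(12), rnorm(12, 0.8), rnorm(12, 0.4))
  g3 <- rep(c("ctl", "gA", "gB"), each = 12)
  d3 <- dunnTest(v3, g3, "ctl")
  for (gg in c("gA", "gB")) {
    pperm <- oraclePermRankP(v3, g3, "ctl", gg, n_perm = 10000)
    expect_lt(abs(d3$p[d3$group == gg] - pperm), 0.04)
  }
  expect_error(dunnTest(v3, g3, "missing"), "control")
})

test_that("Wilcoxon rank-sum matches exhaustive enumeration for small n", {
  w <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(w$U), 0)
  expect_equal(w$p, 0.1)
  expect_true(w$exact)
  set.seed(17)
  for (i in 1:8) {
    nx <- sample(3:5, 1); ny <- sample(3:5, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    expect_equal(wilcoxonRankSum(x, y)$p, oracleWilcoxonExact(x, y),
                 tolerance = 1e-10)
  }
  # large shifted samples: decisive
  expect_lt(wilcoxonRankSum(rnorm(200), rnorm(200, 2))$p, 1e-10)
  expect_error(wilcoxonRankSum(numeric(0), 1:3), "non-empty")
})

test_that("region association: exact line, independence, band coverage", {
  x <- seq(0.05, 0.9, length.out = 20)
  ra <- regionAssociation(x, x)
  expect_equal(ra$slope, 1)
  expect_equal(ra$pearson, 1)
  set.seed(18)
  ra2 <- regionAssociation(runif(2000), runif(2000))
  expect_lt(abs(ra2$pearson), 0.08)
  expect_error(regionAssociation(rep(0.3, 5), runif(5)), "zero variance")
  # pointwise 95% band covers the true regression value
  hits <- replicate(200, {
    xx <- runif(30)
    yy <- 0.2 + 0.8 * xx + rnorm(30, 0, 0.1)
    b <- regionAssociation(xx, yy, band_at = 0.5)
    b$band$lower <= 0.2 + 0.8 * 0.5 && 0.2 + 0.8 * 0.5 <= b$band$upper
  })
  expect_gte(mean(hits), 0.9)
})
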
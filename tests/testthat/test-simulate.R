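test_that("molecule pools follow their per-CpG probabilities", {
  l <- defaultLocusPanel()[1]
  ncpg <- length(cpgPositions(l)[[1]])
  expect_true(all(moleculeStates(generateMoleculePool(l, 1, 100, seed = 1))))
  expect_false(any(moleculeStates(generateMoleculePool(l, 0, 100, seed = 1))))
  pool <- generateMoleculePool(l, 0.3, 10000, seed = 2)
  se3 <- 3 * sqrt(0.3 * 0.7 / 10000)
  expect_true(all(abs(colMeans(moleculeStates(pool)) - 0.3) < se3))
  expect_error(generateMoleculePool(l, rep(0.5, ncpg + 1), 10),
               "one probability per CpG")
  # reproducible under fixed seed
  expect_identical(moleculeStates(generateMoleculePool(l, 0.4, 50, seed = 9)),
                   moleculeStates(generateMoleculePool(l, 0.4, 50, seed = 9)))
})

test_that("ccfDNA cohorts have exact group sizes and are seed-deterministic", {
  spec <- cohortSpec(seed = 1)
  se <- simulateCcfdnaCohort(spec)
  expect_equal(ncol(se), 159)
  expect_equal(sum(se$group == "CRC"), 97)
  expect_equal(sum(se$group %in% c("NN", "AP")), 62)
  expect_equal(unname(table(se$stage)[c("I", "II", "III", "IV")]),
               c(23, 26, 27, 21), ignore_attr = TRUE)
  se2 <- simulateCcfdnaCohort(spec)
  expect_identical(assay(se, "meth1"), assay(se2, "meth1"))
  expect_identical(se$conc_ng_ml, se2$conc_ng_ml)
})

test_that("perfect replicate correlation duplicates the ratios exactly", {
  spec <- cohortSpec(replicate_correlation = 1, seed = 4)
  se <- simulateCcfdnaCohort(spec)
  expect_equal(assay(se, "meth1"), assay(se, "meth2"))
})

test_that("duplicate-run correlation is monotone in the copula parameter", {
  cors <- vapply(c(0.2, 0.5, 0.9), function(r) {
    spec <- cohortSpec(replicate_correlation = r, seed = 10)
    se <- simulateCcfdnaCohort(spec)
    crc <- se$group == "CRC"
    cor(as.vector(assay(se, "meth1")[, crc]),
        as.vector(assay(se, "meth2")[, crc]))
  }, numeric(1))
  expect_false(is.unsorted(cors))
  expect_gt(cors[3], 0.5)
})

test_that("generator grand means converge to the calibration targets", {
  s <- cohortCalibrationSummary(n_cohorts = 60, spec = cohortSpec(),
                                seed = 123)
  expect_lt(abs(s$mean_conc_crc - 15.2), 3 * s$se_conc_crc + 0.05)
  expect_lt(abs(s$mean_R_crc - 15.8), 3 * s$se_R_crc + 0.02)
})

test_that("recovery calibration reproduces mean and SD after clamping", {
  for (tg in list(c(15.8, sdFromCI(0.3, 97)), c(14.1, sdFromCI(0.4, 62)))) {
    cal <- calibrateRecoveryModel(tg[1], tg[2])
    expect_lt(abs(cal$mean - tg[1]), 1e-4)
    expect_lt(abs(cal$sd_achieved - tg[2]), 1e-3)
  }
})

test_that("tissue generator hits degenerate and calibrated positivity", {
  se1 <- simulateTissueCohort(c(I = 30), positivity = 1, seed = 1)
  sc1 <- scoreCohort(se1, context = "tissue")
  expect_true(all(sc1$meth_score_1 == 6))
  se0 <- simulateTissueCohort(c(I = 30), positivity = 0, seed = 1)
  expect_true(all(scoreCohort(se0, context = "tissue")$meth_score_1 == 0))
  # calibrated one-factor model reproduces both printed tail frequencies
  cal <- calibrateTissueModel(0.961, 0.948)
  expect_lt(abs(cal$ge1 - 0.961), 1e-4)
  expect_lt(abs(cal$ge2 - 0.948), 1e-4)
  se <- simulateTissueCohort(c(I = 3000), seed = 2)
  m <- scoreCohort(se, context = "tissue")$meth_score_1
  expect_lt(abs(mean(m >= 1) - 0.961), 3 * sqrt(0.961 * 0.039 / 3000))
  expect_lt(abs(mean(m >= 2) - 0.948), 3 * sqrt(0.948 * 0.052 / 3000))
  # positive loci always meet the tissue threshold
  r <- assay(se, "meth1")
  expect_true(all(r[r >= 0.05] >= 0.05))
})

test_that("trajectories honor coupling, CEA mode and determinism", {
  # zero coupling, zero noise: flat Fc, no detection
  sp0 <- trajectorySpec(fc_gain = 0,
                        noise = list(fc = 0, cea = 0, burden = 0), seed = 5)
  t0 <- simulateTrajectory(sp0)
  expect_equal(var(draws(t0)$fc), 0)
  expect_true(is.na(detectRise(draws(t0)$day, draws(t0)$fc)))
  # nonsecretor CEA stays below the normal limit
  tn <- simulateTrajectory(trajectorySpec(cea_mode = "nonsecretor", seed = 6))
  expect_lt(max(draws(tn)$cea), 5)
  # at least one PD event
  tr <- simulateTrajectory(trajectorySpec(seed = 7))
  expect_gte(sum(events(tr)$type == "radiological_PD"), 1)
  # with zero lead and zero noise Fc is exactly proportional to burden
  tp <- simulateTrajectory(trajectorySpec(
    fc_lead_days = 0, noise = list(fc = 0, cea = 0, burden = 0), seed = 8))
  d <- draws(tp)
  expect_equal(d$fc, 0.25 * d$burden)
  # determinism
  tr2 <- simulateTrajectory(trajectorySpec(seed = 7))
  expect_identical(draws(tr), draws(tr2))
  expect_error(trajectorySpec(n_draws = 1), "n_draws")
})
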
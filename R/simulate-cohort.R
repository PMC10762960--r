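#' Construct a HiSAExperiment from assay matrices
#'
#' @param meth1,meth2 6 x n methylation-ratio matrices (rows = panel loci).
#' @param rec1,rec2 6 x n recovery-signal matrices.
#' @param colData `DataFrame`/data.frame with `group`, `stage`, `conc_ng_ml`.
#' @param panel the [LocusPanel-class] the rows refer to (kept in metadata).
#' @return a [HiSAExperiment-class].
#' @export
HiSAExperiment <- function(meth1, meth2, rec1, rec2, colData,
                           panel = defaultLocusPanel()) {
  se <- SummarizedExperiment(
    assays = list(meth1 = meth1, meth2 = meth2, rec1 = rec1, rec2 = rec2),
    colData = colData)
  rownames(se) <- locusNames(panel)
  out <- new("HiSAExperiment", se)
  metadata(out)$panel <- panel
  out
}

#' Specification of a synthetic ccfDNA cohort
#'
#' Defaults encode the blood-cohort conditions the assay was characterized
#' under: 97 CRC patients (23/26/27/21 at UICC stages I-IV) and 62 controls
#' (46 no-neoplasia NN, 16 adenomatous-polyp AP); mean ccfDNA concentration
#' 15.2 ng/ml in CRC vs 9.5 ng/ml in controls and mean two-time recovery
#' score 15.8 vs 14.1, with group SDs back-derived from the 95\% CIs of
#' those means via [sdFromCI()]. Concentrations are log-normal (with a mild
#' stage gradient averaging to the group mean, stage IV highest); recovery
#' scores follow the rounded/clamped latent-normal model calibrated by
#' [calibrateRecoveryModel()]; per-locus methylation ratios are
#' zero-inflated Beta draws coupled within a sample (shared shedding
#' factor) and between duplicate runs (Gaussian copula at
#' `replicate_correlation`). Per-locus ccfDNA positivity is not printed
#' anywhere, so the group positivity defaults were calibrated once,
#' indirectly, so that the two-time methylation score separates the groups
#' at an AUC near the reported 0.85.
#'
#' @param n_crc_by_stage named counts of CRC patients per UICC stage.
#' @param n_nn,n_ap control-group sizes (no neoplasia / adenomatous polyp).
#' @param conc_params per-group `mean`/`sd` of ccfDNA concentration (ng/ml)
#'   plus `stage_rel`, relative stage multipliers on the CRC mean
#'   (internally normalized so the stage-weighted mean stays at the group
#'   mean).
#' @param recovery_params per-group `mean`/`sd` of the two-time recovery
#'   score plus `rep_sd`, the per-replicate latent noise SD.
#' @param methylation_params per-group per-locus positivity probability
#'   (`positivity`, scalar or length-6), Beta `ratio_shape`/`ratio_scale`
#'   for positive ratios, and `cross_locus`, the loading coupling loci
#'   within a sample.
#' @param replicate_correlation Gaussian-copula correlation between the
#'   duplicate Hi-SA runs, in \[0,1\].
#' @param seed default RNG seed used by [simulateCcfdnaCohort()].
#' @return a validated `CohortSpec` (list) with calibrated latent recovery
#'   parameters attached.
#' @export
cohortSpec <- function(
    n_crc_by_stage = c(I = 23, II = 26, III = 27, IV = 21),
    n_nn = 46, n_ap = 16,
    conc_params = list(
      crc = list(mean = 15.2, sd = sdFromCI(1.7, 97)),
      control = list(mean = 9.5, sd = sdFromCI(0.8, 62)),
      stage_rel = c(I = 0.79, II = 0.89, III = 1.02, IV = 1.34)),
    recovery_params = list(
      crc = list(mean = 15.8, sd = sdFromCI(0.3, 97)),
      control = list(mean = 14.1, sd = sdFromCI(0.4, 62)),
      rep_sd = 0.8),
    methylation_params = list(
      crc = list(positivity = 0.38),
      control = list(positivity = 0.05),
      ratio_shape = c(1.5, 6), ratio_scale = 0.25,
      cross_locus = 0.8),
    replicate_correlation = 0.7,
    seed = NULL) {
  n_crc_by_stage <- unlist(n_crc_by_stage)  # tolerate YAML-style lists
  if (is.null(names(n_crc_by_stage)))       # unnamed counts: stages in order
    names(n_crc_by_stage) <- c("I", "II", "III", "IV")[seq_along(n_crc_by_stage)]
  stopifnot(all(n_crc_by_stage >= 0), n_nn >= 0, n_ap >= 0,
            replicate_correlation >= 0, replicate_correlation <= 1)
  for (g in c("crc", "control")) {
    p <- methylation_params[[g]]$positivity
    stopifnot(all(p >= 0), all(p <= 1))
  }
  spec <- list(
    n_crc_by_stage = n_crc_by_stage, n_nn = n_nn, n_ap = n_ap,
    conc_params = conc_params, recovery_params = recovery_params,
    methylation_params = methylation_params,
    replicate_correlation = replicate_correlation, seed = seed)
  # normalize the stage gradient so the weighted CRC mean is exact
  sr <- conc_params$stage_rel[names(n_crc_by_stage)]
  wmean <- sum(sr * n_crc_by_stage) / sum(n_crc_by_stage)
  spec$conc_params$stage_rel <- sr / wmean
  # latent recovery calibration (deterministic; done once per spec)
  spec$recovery_calib <- list(
    crc = calibrateRecoveryModel(recovery_params$crc$mean,
                                 recovery_params$crc$sd,
                                 recovery_params$rep_sd),
    control = calibrateRecoveryModel(recovery_params$control$mean,
                                     recovery_params$control$sd,
                                     recovery_params$rep_sd))
  class(spec) <- "CohortSpec"
  spec
}

# split an integer replicate recovery score (0-18) into 6 grades 0-3
.gradesFromScore <- function(score) {
  base <- score %/% 6L
  rem <- score %% 6L
  g <- rep(base, 6L)
  if (rem > 0) g[sample.int(6L, rem)] <- base + 1L
  g
}

# recovery signal drawn uniformly within the band of its grade
.signalFromGrade <- function(grade, cutpoints = c(250, 500, 1000)) {
  lo <- c(50, cutpoints)[grade + 1L]
  hi <- c(cutpoints, 2 * cutpoints[3])[grade + 1L]
  runif(length(grade), lo, hi)
}

# zero-inflated Beta methylation ratios via Gaussian copula
# z: latent N(0,1) draws; pi: positivity probability (recycled)
.ratioFromLatent <- function(z, pi, shape, scale) {
  pi <- rep_len(pi, length(z))
  q <- pnorm(z)
  pos <- pi > 0 & q >= 1 - pi
  out <- numeric(length(z))
  if (any(pos)) {
    u <- (q[pos] - (1 - pi[pos])) / pi[pos]
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    out[pos] <- qbeta(u, shape[1], shape[2]) * scale
  }
  out
}

#' Simulate a ccfDNA Hi-SA cohort
#'
#' Draws a full blood cohort under a [cohortSpec()]: group labels and
#' stages, ccfDNA concentrations, duplicate per-locus methylation ratios
#' and recovery signals, packaged as a [HiSAExperiment-class]. Identical
#' spec and seed give an identical cohort.
#'
#' @param spec a [cohortSpec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @param panel the [LocusPanel-class] providing locus names.
#' @return a [HiSAExperiment-class] with `group` (NN/AP/CRC), `stage` and
#'   `conc_ng_ml` in `colData`.
#' @export
simulateCcfdnaCohort <- function(spec = cohortSpec(), seed = spec$seed,
                                 panel = defaultLocusPanel()) {
  if (!is.null(seed)) set.seed(seed)
  stages <- rep(names(spec$n_crc_by_stage), spec$n_crc_by_stage)
  group <- c(rep("NN", spec$n_nn), rep("AP", spec$n_ap),
             rep("CRC", length(stages)))
  stage <- c(rep(NA_character_, spec$n_nn + spec$n_ap), stages)
  n <- length(group)
  isCRC <- group == "CRC"

  # concentrations: log-normal, stage gradient within CRC
  conc <- numeric(n)
  cp <- spec$conc_params
  if (any(!isCRC)) {
    lp <- lognormalParams(cp$control$mean, cp$control$sd)
    conc[!isCRC] <- rlnorm(sum(!isCRC), lp$meanlog, lp$sdlog)
  }
  if (any(isCRC)) {
    rel <- cp$stage_rel[stage[isCRC]]
    m <- cp$crc$mean * rel
    s <- cp$crc$sd * rel  # constant coefficient of variation across stages
    sdlog2 <- log(1 + (s / m)^2)
    conc[isCRC] <- rlnorm(sum(isCRC), log(m) - sdlog2 / 2, sqrt(sdlog2))
  }

  # recovery: latent level + replicate noise, rounded and clamped to 0-18
  calib <- spec$recovery_calib
  mu <- ifelse(isCRC, calib$crc$mu, calib$control$mu)
  sdl <- ifelse(isCRC, calib$crc$sd, calib$control$sd)
  lat <- rnorm(n, mu, sdl)
  repScore <- function() {
    as.integer(pmin(18L, pmax(0L,
      round(lat + rnorm(n, 0, spec$recovery_params$rep_sd)))))
  }
  s1 <- repScore(); s2 <- repScore()
  rec1 <- vapply(s1, function(s) .signalFromGrade(.gradesFromScore(s)),
                 numeric(6))
  rec2 <- vapply(s2, function(s) .signalFromGrade(.gradesFromScore(s)),
                 numeric(6))

  # methylation: sample shedding factor -> locus latents -> replicate pair
  mp <- spec$methylation_params
  a <- mp$cross_locus
  rho <- spec$replicate_correlation
  u <- rnorm(n)
  meth1 <- matrix(0, 6, n); meth2 <- matrix(0, 6, n)
  piMat <- matrix(0, 6, n)
  piMat[, isCRC] <- rep_len(mp$crc$positivity, 6)
  piMat[, !isCRC] <- rep_len(mp$control$positivity, 6)
  v <- matrix(rnorm(6 * n), 6, n)
  w <- sweep(sqrt(1 - a^2) * v, 2, a * u, `+`)
  for (r in 1:2) {
    eps <- matrix(rnorm(6 * n), 6, n)
    z <- sqrt(rho) * w + sqrt(1 - rho) * eps
    ratio <- .ratioFromLatent(as.vector(z), as.vector(piMat),
                              mp$ratio_shape, mp$ratio_scale)
    if (r == 1) meth1 <- matrix(ratio, 6, n) else meth2 <- matrix(ratio, 6, n)
  }

  cd <- DataFrame(group = group, stage = stage, conc_ng_ml = conc,
                  row.names = sprintf("S%03d", seq_len(n)))
  colnames(meth1) <- colnames(meth2) <- rownames(cd)
  colnames(rec1) <- colnames(rec2) <- rownames(cd)
  HiSAExperiment(meth1, meth2, rec1, rec2, cd, panel = panel)
}

#' Simulate a tissue COBRA cohort
#'
#' Tissue specimens are measured once by fluorescent COBRA; for container
#' compatibility the single run is stored in both replicate slots. When
#' `positivity` is `NULL` the per-stage marginal positivity and
#' within-sample factor loading are calibrated with [calibrateTissueModel()]
#' to the printed frequencies of tumors with >=1 (96.1/98.5/99.3/96.6\%)
#' and >=2 (94.8/93.2/97.3/89.2\%) methylation-positive regions at stages
#' I-IV. An explicit `positivity` (per-stage vector or stages x loci
#' matrix) is used as independent per-locus Bernoulli probabilities
#' instead, so empirical per-locus frequencies converge to the inputs.
#'
#' Positive loci draw ratios of at least the 0.05 tissue threshold;
#' negative loci draw small sub-threshold ratios.
#'
#' @param n_by_stage named counts of specimens per UICC stage.
#' @param positivity optional explicit positivity probabilities.
#' @param targets_ge1,targets_ge2 per-stage calibration targets used when
#'   `positivity` is `NULL`.
#' @param seed RNG seed.
#' @param panel the [LocusPanel-class].
#' @return a [HiSAExperiment-class] with `group = "CRC"` throughout.
#' @export
simulateTissueCohort <- function(
    n_by_stage = c(I = 232, II = 241, III = 261, IV = 215),
    positivity = NULL,
    targets_ge1 = c(I = 0.961, II = 0.985, III = 0.993, IV = 0.966),
    targets_ge2 = c(I = 0.948, II = 0.932, III = 0.973, IV = 0.892),
    seed = NULL, panel = defaultLocusPanel()) {
  if (!is.null(seed)) set.seed(seed)
  stages <- names(n_by_stage)
  n <- sum(n_by_stage)
  stage <- rep(stages, n_by_stage)
  pos <- matrix(FALSE, 6, n)
  if (is.null(positivity)) {
    for (s in stages) {
      idx <- which(stage == s)
      cal <- calibrateTissueModel(targets_ge1[[s]], targets_ge2[[s]])
      t <- qnorm(1 - cal$q)
      Z <- rnorm(length(idx))
      e <- matrix(rnorm(6 * length(idx)), 6)
      lat <- sweep(sqrt(1 - cal$r) * e, 2, sqrt(cal$r) * Z, `+`)
      pos[, idx] <- lat > t
    }
  } else {
    # scalar / length-6 vector (all stages alike) or stages x 6 matrix
    for (s in stages) {
      idx <- which(stage == s)
      p <- if (is.matrix(positivity)) positivity[s, ] else positivity
      pos[, idx] <- matrix(runif(6 * length(idx)), 6) < rep_len(p, 6)
    }
  }
  ratio <- matrix(0, 6, n)
  npos <- sum(pos)
  ratio[pos] <- 0.05 + 0.95 * rbeta(npos, 1.3, 2.5)
  ratio[!pos] <- 0.05 * rbeta(sum(!pos), 1, 12)
  rec <- matrix(1200, 6, n)
  cd <- DataFrame(group = rep("CRC", n), stage = stage,
                  conc_ng_ml = rep(NA_real_, n),
                  row.names = sprintf("T%04d", seq_len(n)))
  colnames(ratio) <- colnames(rec) <- rownames(cd)
  HiSAExperiment(ratio, ratio, rec, rec, cd, panel = panel)
}
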
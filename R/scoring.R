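#' Scoring configuration
#'
#' Collects every tunable of the scoring system. Positivity uses closed
#' thresholds ("at X or more"): 0.05 for tissue COBRA and 0.01 for ccfDNA
#' Hi-SA. The combination score is `Fc = beta1 * M + beta2 * R` with both
#' coefficients fixed at 1 by default (the logistic estimates behind that
#' choice were 0.95 and 0.99, indistinguishable from 1). Recovery signals
#' are graded 0-3 per locus by ordered cutpoints, so a 6-locus replicate
#' recovery score spans 0-18. The two-time rules default to `sum` for the
#' methylation score (either replicate can contribute a detection, M in
#' 0-12) and `mean` for the recovery score (R in 0-18).
#'
#' @param tissue_threshold closed methylation-ratio threshold for tissue.
#' @param ccfdna_threshold closed methylation-ratio threshold for ccfDNA.
#' @param beta1,beta2 combination-score coefficients.
#' @param recovery_cutpoints strictly increasing signal cutpoints mapping a
#'   recovery signal to grades 0,1,2,3.
#' @param two_time_methylation `"sum"` or `"mean"`.
#' @param two_time_recovery `"mean"` or `"sum"`.
#' @return a `ScoringConfig` (validated list).
#' @export
scoringConfig <- function(tissue_threshold = 0.05, ccfdna_threshold = 0.01,
                          beta1 = 1.0, beta2 = 1.0,
                          recovery_cutpoints = c(250, 500, 1000),
                          two_time_methylation = c("sum", "mean"),
                          two_time_recovery = c("mean", "sum")) {
  stopifnot(tissue_threshold > 0, tissue_threshold < 1,
            ccfdna_threshold > 0, ccfdna_threshold < 1)
  if (is.unsorted(recovery_cutpoints, strictly = TRUE))
    stop("recovery_cutpoints must be strictly increasing")
  cfg <- list(tissue_threshold = tissue_threshold,
              ccfdna_threshold = ccfdna_threshold,
              beta1 = beta1, beta2 = beta2,
              recovery_cutpoints = recovery_cutpoints,
              two_time_methylation = match.arg(two_time_methylation),
              two_time_recovery = match.arg(two_time_recovery))
  class(cfg) <- "ScoringConfig"
  cfg
}

#' Methylation positivity call
#'
#' Positive when the methylation ratio meets or exceeds the context
#' threshold (closed bound). An undefined ratio (no recovery) yields `NA`:
#' the region is non-evaluable, not negative.
#'
#' @param ratio methylation ratio(s) in \[0,1\], `NA` = no recovery.
#' @param context `"tissue"` (threshold 0.05) or `"ccfdna"` (0.01).
#' @param cfg a [scoringConfig()].
#' @return logical vector (`NA` = non-evaluable).
#' @export
callPositivity <- function(ratio, context = c("ccfdna", "tissue"),
                           cfg = scoringConfig()) {
  context <- match.arg(context)
  thr <- if (context == "tissue") cfg$tissue_threshold else cfg$ccfdna_threshold
  ifelse(is.na(ratio), NA, ratio >= thr)
}

#' Promoter methylation-spread classification
#'
#' A gene is extensively methylated when both promoter regions are
#' positive, partially methylated when exactly one is, and unmethylated
#' when neither is. A non-evaluable region makes the spread call
#' non-evaluable (`NA`).
#'
#' @param region1,region2 logical positivity calls (possibly `NA`).
#' @return factor with levels `unmethylated`, `partial`, `extensive`.
#' @export
classifySpread <- function(region1, region2) {
  n <- max(length(region1), length(region2))
  region1 <- rep_len(region1, n); region2 <- rep_len(region2, n)
  out <- ifelse(is.na(region1) | is.na(region2), NA_character_,
         ifelse(region1 & region2, "extensive",
         ifelse(region1 | region2, "partial", "unmethylated")))
  factor(out, levels = c("unmethylated", "partial", "extensive"))
}

#' Per-replicate methylation score
#'
#' Counts methylation-positive regions among the six panel regions (0-6).
#' Non-evaluable regions are excluded from the count rather than imputed;
#' the result carries `n_evaluable` so completeness is visible.
#'
#' @param calls logical vector of region positivity calls (length 6 for the
#'   full panel; `NA` = non-evaluable).
#' @return list with `score`, `n_evaluable`, `complete`.
#' @export
methylationScore <- function(calls) {
  list(score = sum(calls, na.rm = TRUE),
       n_evaluable = sum(!is.na(calls)),
       complete = !anyNA(calls))
}

#' Recovery grade and per-replicate recovery score
#'
#' `recoveryGrade()` maps a recovery signal to a grade in 0-3 via the
#' ordered cutpoints; `recoveryScore()` sums the grades over the six loci
#' (0-18), a marker of how much amplifiable, non-apoptotically fragmented
#' DNA was recovered.
#'
#' @param signal non-negative recovery signal(s).
#' @param signals length-6 vector of per-locus signals.
#' @param cfg a [scoringConfig()].
#' @return integer grade(s) / integer score.
#' @export
recoveryGrade <- function(signal, cfg = scoringConfig()) {
  stopifnot(all(signal >= 0, na.rm = TRUE))
  grade <- findInterval(signal, cfg$recovery_cutpoints)
  grade[is.na(signal)] <- NA_integer_
  as.integer(grade)
}

#' @rdname recoveryGrade
#' @export
recoveryScore <- function(signals, cfg = scoringConfig()) {
  sum(recoveryGrade(signals, cfg), na.rm = TRUE)
}

#' Two-time (duplicate-run) scores
#'
#' Combines the two Hi-SA replicates of one blood sample into the two-time
#' methylation score M (default: sum of the per-replicate scores, 0-12) and
#' the two-time recovery score R (default: mean of the per-replicate
#' scores, 0-18). With a single replicate the function degrades to that
#' replicate's values and flags the result.
#'
#' @param meth1,meth2 per-replicate methylation scores (0-6); `meth2` may be
#'   `NA` for single-replicate (degraded) mode.
#' @param rec1,rec2 per-replicate recovery scores (0-18).
#' @param cfg a [scoringConfig()].
#' @return list with `M`, `R`, `complete`.
#' @export
twoTimeScores <- function(meth1, meth2, rec1, rec2, cfg = scoringConfig()) {
  degraded <- is.na(meth2) | is.na(rec2)
  if (any(degraded))
    warning("single-replicate input: two-time scores degrade to the available replicate")
  comb <- function(a, b, rule) {
    out <- switch(rule, sum = a + b, mean = (a + b) / 2)
    ifelse(is.na(b), a, out)
  }
  list(M = comb(meth1, meth2, cfg$two_time_methylation),
       R = comb(rec1, rec2, cfg$two_time_recovery),
       complete = !degraded)
}

#' Combination score Fc
#'
#' `Fc = beta1 * M + beta2 * R`, linear in both two-time scores.
#'
#' @param M two-time methylation score.
#' @param R two-time recovery score.
#' @param cfg a [scoringConfig()].
#' @return numeric Fc.
#' @export
combinationScore <- function(M, R, cfg = scoringConfig()) {
  stopifnot(all(is.finite(M)), all(is.finite(R)))
  cfg$beta1 * M + cfg$beta2 * R
}

#' Score every sample of a Hi-SA cohort
#'
#' Applies the full scoring chain to a [HiSAExperiment-class]: per-replicate
#' positivity calls and methylation scores, per-replicate recovery scores,
#' two-time M and R, combination score Fc, and per-gene spread calls (a
#' region counts positive for the spread call when positive in either
#' replicate).
#'
#' @param se a [HiSAExperiment-class].
#' @param cfg a [scoringConfig()].
#' @param context `"ccfdna"` or `"tissue"` positivity threshold.
#' @return data.frame, one row per sample: `sample_id`, `group`, `stage`,
#'   `conc_ng_ml`, `meth_score_1`, `meth_score_2`, `M`, `rec_score_1`,
#'   `rec_score_2`, `R`, `Fc`, `n_evaluable_1`, `n_evaluable_2`, `complete`,
#'   and one spread column per gene.
#' @export
scoreCohort <- function(se, cfg = scoringConfig(),
                        context = c("ccfdna", "tissue")) {
  context <- match.arg(context)
  stopifnot(methods::is(se, "HiSAExperiment"))
  m1 <- assay(se, "meth1"); m2 <- assay(se, "meth2")
  r1 <- assay(se, "rec1"); r2 <- assay(se, "rec2")
  call1 <- callPositivity(m1, context, cfg)
  call2 <- callPositivity(m2, context, cfg)
  dim(call1) <- dim(m1); dim(call2) <- dim(m2)
  ms1 <- colSums(call1, na.rm = TRUE)
  ms2 <- colSums(call2, na.rm = TRUE)
  ne1 <- colSums(!is.na(call1)); ne2 <- colSums(!is.na(call2))
  g1 <- matrix(recoveryGrade(r1, cfg), nrow = nrow(r1))
  g2 <- matrix(recoveryGrade(r2, cfg), nrow = nrow(r2))
  rs1 <- colSums(g1, na.rm = TRUE); rs2 <- colSums(g2, na.rm = TRUE)
  tt <- twoTimeScores(ms1, ms2, rs1, rs2, cfg)
  fc <- combinationScore(tt$M, tt$R, cfg)
  cd <- colData(se)
  out <- data.frame(
    sample_id = colnames(se), group = as.character(cd$group),
    stage = as.character(cd$stage), conc_ng_ml = cd$conc_ng_ml,
    meth_score_1 = ms1, meth_score_2 = ms2, M = tt$M,
    rec_score_1 = rs1, rec_score_2 = rs2, R = tt$R, Fc = fc,
    n_evaluable_1 = ne1, n_evaluable_2 = ne2,
    complete = ne1 == nrow(se) & ne2 == nrow(se),
    row.names = NULL)
  genes <- unique(sub("_R[12]$", "", rownames(se)))
  either <- (!is.na(call1) & call1) | (!is.na(call2) & call2)
  either[is.na(call1) & is.na(call2)] <- NA
  for (g in genes) {
    i1 <- match(paste0(g, "_R1"), rownames(se))
    i2 <- match(paste0(g, "_R2"), rownames(se))
    out[[paste0("spread_", g)]] <-
      as.character(classifySpread(either[i1, ], either[i2, ]))
  }
  out
}
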
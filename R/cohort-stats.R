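#' Logistic fit of case status on the two-time scores
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of
#' case/control status on the two-time methylation score M and two-time
#' recovery score R. Wald 95\% CIs are `estimate +/- 1.96 * SE`. Separable
#' or non-converged fits are flagged and reported with a warning rather
#' than suppressed.
#'
#' @param M,R per-sample two-time scores.
#' @param labels case/control labels: logical, 0/1, or factor with the case
#'   level last.
#' @return object of class `LogisticFit`: list with `coefficients`, `se`,
#'   `ci` (matrix), `p`, `logLik`, `converged`, `n`.
#' @export
fitLogisticScores <- function(M, R, labels) {
  y <- .asBinary(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (anyNA(M) || anyNA(R)) stop("missing features are not allowed")
  df <- data.frame(y = y, M = M, R = R)
  fit <- glm(y ~ M + R, data = df, family = binomial(),
             control = list(epsilon = 1e-8, maxit = 100))
  sm <- summary(fit)
  est <- sm$coefficients[, "Estimate"]
  se <- sm$coefficients[, "Std. Error"]
  sep <- !fit$converged || any(abs(est[-1]) > 15)
  if (sep)
    warning("possible separation / non-convergence: coefficients reported with caution")
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  structure(list(coefficients = est, se = se, ci = ci,
                 p = sm$coefficients[, "Pr(>|z|)"],
                 logLik = as.numeric(logLik(fit)),
                 converged = fit$converged && !sep, n = length(y),
                 glm = fit),
            class = "LogisticFit")
}

#' @export
print.LogisticFit <- function(x, ...) {
  cat("Logistic fit (n =", x$n, if (!x$converged) "; NOT converged", ")\n")
  tab <- cbind(estimate = x$coefficients, se = x$se, x$ci, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

.asBinary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) return(as.integer(labels == levels(labels)[nlevels(labels)]))
  if (is.character(labels)) {
    lv <- sort(unique(labels))
    if (length(lv) > 2) stop("labels must be binary")
    return(as.integer(labels == lv[length(lv)]))
  }
  as.integer(labels != 0)
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' The AUC equals the Mann-Whitney statistic `U / (n_cases * n_controls)`
#' with ties counted one half; the curve enumerates all distinct score
#' thresholds. Computation is delegated to \pkg{pROC}; the 95\% CI is
#' DeLong by default, bootstrap optionally.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels case/control labels (see [fitLogisticScores()]).
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_n bootstrap replicates when `ci_method = "bootstrap"`.
#' @return an [RocResult-class].
#' @export
rocAuc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                   boot_n = 2000) {
  ci_method <- match.arg(ci_method)
  y <- .asBinary(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  r <- pROC::roc(response = y, predictor = scores, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  ci <- if (ci_method == "delong") {
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)])
  } else {
    as.numeric(pROC::ci.auc(r, method = "bootstrap",
                            boot.n = boot_n, progress = "none"))[c(1, 3)]
  }
  co <- pROC::coords(r, x = "all", ret = c("threshold", "sensitivity",
                                           "specificity"),
                     transpose = FALSE)
  pts <- data.frame(threshold = co$threshold,
                    sensitivity = co$sensitivity,
                    fpr = 1 - co$specificity)
  pts <- pts[order(pts$fpr, pts$sensitivity), , drop = FALSE]
  rownames(pts) <- NULL
  new("RocResult", points = pts, auc = as.numeric(pROC::auc(r)),
      ci = pmin(pmax(ci, 0), 1),
      nCases = sum(y == 1L), nControls = sum(y == 0L))
}

#' DeLong comparison of two paired ROC curves
#'
#' DeLong variance/covariance-based test for the AUC difference of two
#' scores measured on the same subjects, with DeLong 95\% CIs for both
#' AUCs. Identical score vectors are an exact tie (difference and its
#' variance are both zero): P = 1.
#'
#' @param scoresA,scoresB paired score vectors.
#' @param labels case/control labels.
#' @return list with `aucA`, `aucB`, `ciA`, `ciB`, `delta`, `p`.
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  y <- .asBinary(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (sd(scoresA) == 0 || sd(scoresB) == 0)
    stop("degenerate (constant) scores")
  ra <- rocAuc(scoresA, labels)
  rb <- rocAuc(scoresB, labels)
  if (isTRUE(all.equal(scoresA, scoresB)))
    return(list(aucA = auc(ra), aucB = auc(rb), ciA = aucCI(ra),
                ciB = aucCI(rb), delta = 0, p = 1))
  pa <- pROC::roc(y, scoresA, quiet = TRUE, direction = "<",
                  levels = c(0, 1))
  pb <- pROC::roc(y, scoresB, quiet = TRUE, direction = "<",
                  levels = c(0, 1))
  tst <- pROC::roc.test(pa, pb, method = "delong", paired = TRUE)
  list(aucA = auc(ra), aucB = auc(rb), ciA = aucCI(ra), ciB = aucCI(rb),
       delta = auc(ra) - auc(rb), p = as.numeric(tst$p.value))
}

#' Stratified k-fold cross-validated ROC
#'
#' Folds are stratified by class label; within each fold assignment the
#' logistic model [fitLogisticScores()] is trained on the other k-1 folds
#' and scores the held-out fold; the pooled out-of-fold linear predictors
#' form a single ROC curve. Fixed seed gives identical folds and AUC.
#'
#' @param M,R per-sample two-time scores.
#' @param labels case/control labels.
#' @param k number of folds (each class must have at least `k` members).
#' @param seed RNG seed for the fold assignment.
#' @return an [RocResult-class] of the pooled out-of-fold predictions, with
#'   the fold assignment attached as attribute `folds`.
#' @export
stratifiedKfoldCv <- function(M, R, labels, k = 5L, seed = NULL) {
  y <- .asBinary(labels)
  if (k < 2L) stop("k must be >= 2")
  if (min(table(y)) < k) stop("each class needs at least k members")
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  oof <- numeric(length(y))
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- glm(y ~ M + R,
               data = data.frame(y = y, M = M, R = R)[!test, ],
               family = binomial(),
               control = list(epsilon = 1e-8, maxit = 100))
    oof[test] <- predict(fit, newdata = data.frame(M = M, R = R)[test, ],
                         type = "link")
  }
  out <- rocAuc(oof, y)
  attr(out, "folds") <- folds
  attr(out, "oof") <- oof
  out
}

#' Dunn's test versus a control group
#'
#' Rank-based multiple comparison on the merged sample: mid-ranks are
#' computed over all groups jointly, and each group is compared with the
#' control group by the Dunn z statistic
#' `z = (meanRank_ctrl - meanRank_g) / sqrt((N(N+1)/12 - T) (1/n_c + 1/n_g))`
#' with the tie correction `T = sum(t^3 - t) / (12 (N - 1))`. Two-sided
#' p-values are Bonferroni-adjusted over the control comparisons.
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @param control label of the control group.
#' @return data.frame with one row per non-control group: `group`, `n`,
#'   `mean_rank`, `z`, `p`, `p_adj`.
#' @export
dunnTest <- function(values, groups, control) {
  groups <- as.character(groups)
  if (!control %in% groups) stop("control group not present")
  tab <- table(groups)
  if (any(tab == 0)) stop("empty group")
  N <- length(values)
  rk <- rank(values)  # mid-ranks
  ties <- table(values)
  tieC <- sum(ties^3 - ties) / (12 * (N - 1))
  meanRank <- tapply(rk, groups, mean)
  others <- setdiff(names(tab), control)
  z <- p <- numeric(length(others))
  for (i in seq_along(others)) {
    g <- others[i]
    se <- sqrt((N * (N + 1) / 12 - tieC) *
                 (1 / tab[[control]] + 1 / tab[[g]]))
    z[i] <- (meanRank[[g]] - meanRank[[control]]) / se
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  data.frame(group = others, n = as.integer(tab[others]),
             mean_rank = as.numeric(meanRank[others]), z = z, p = p,
             p_adj = pmin(1, p * length(others)), row.names = NULL)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon test: exact p-value when the combined
#' sample size is at most 20 and there are no ties, normal approximation
#' with tie correction otherwise (delegated to [stats::wilcox.test()]).
#'
#' @param x,y the two samples.
#' @return list with `U` (Mann-Whitney statistic for `x`), `p`, `exact`.
#' @export
wilcoxonRankSum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- (length(x) + length(y)) <= 20 &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Association between region-1 and region-2 methylation ratios
#'
#' Least-squares regression of region-2 on region-1 ratios with a pointwise
#' 95\% confidence band, plus Pearson and Spearman correlations.
#'
#' @param region1,region2 paired methylation ratios (n >= 3).
#' @param band_at x values at which to evaluate the confidence band
#'   (default: the observed region-1 ratios).
#' @return list with `slope`, `intercept`, `pearson`, `spearman`, and
#'   `band` (data.frame `x`, `fit`, `lower`, `upper`).
#' @export
regionAssociation <- function(region1, region2, band_at = NULL) {
  ok <- stats::complete.cases(region1, region2)
  x <- region1[ok]; y <- region2[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0) stop("zero variance in region-1 ratios")
  fit <- lm(y ~ x)
  if (is.null(band_at)) band_at <- sort(unique(x))
  pr <- predict(fit, newdata = data.frame(x = band_at),
                interval = "confidence", level = 0.95)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       pearson = cor(x, y), spearman = cor(x, y, method = "spearman"),
       band = data.frame(x = band_at, fit = pr[, "fit"],
                         lower = pr[, "lwr"], upper = pr[, "upr"]))
}
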
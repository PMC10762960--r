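#' Back-derive a group SD from a 95\% confidence interval of the mean
#'
#' Cohort summaries are typically printed as `mean [95% CI]`; the group
#' standard deviation is recovered as `half-width / 1.96 * sqrt(n)`.
#'
#' @param half_width half-width of the 95\% CI of the mean.
#' @param n group size.
#' @return the implied group SD.
#' @export
sdFromCI <- function(half_width, n) half_width / 1.96 * sqrt(n)

#' Log-normal parameters matching a target mean and SD
#'
#' @param mean,sd target arithmetic mean and SD (both > 0).
#' @return list with `meanlog`, `sdlog`.
#' @export
lognormalParams <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# Moments of the observed two-time recovery score R = (s1+s2)/2 under the
# latent model  s_r = clamp(round(l + e_r), 0, max)  with l ~ N(mu, sd_lat),
# e_r ~ N(0, rep_sd) iid. Deterministic quadrature over l.
.recoveryMoments <- function(mu, sd_lat, rep_sd, max_score = 18L,
                             n_grid = 801L) {
  k <- 0:max_score
  upper <- c(k[-length(k)] + 0.5, Inf)
  lower <- c(-Inf, k[-1] - 0.5)
  l <- seq(mu - 8 * sd_lat, mu + 8 * sd_lat, length.out = n_grid)
  w <- dnorm(l, mu, sd_lat); w <- w / sum(w)
  # P(s = k | l): (max_score+1) x n_grid
  Pu <- pnorm(outer(upper, l, function(u, ll) (u - ll) / rep_sd))
  Pl <- pnorm(outer(lower, l, function(u, ll) (u - ll) / rep_sd))
  Pk <- Pu - Pl
  m1 <- colSums(k * Pk)         # E[s | l]
  m2 <- colSums(k^2 * Pk)       # E[s^2 | l]
  vc <- m2 - m1^2               # Var(s | l)
  ER <- sum(w * m1)
  VarR <- sum(w * (m1 - ER)^2) + sum(w * vc) / 2
  list(mean = ER, sd = sqrt(VarR))
}

#' Calibrate the latent recovery-score model to a printed group summary
#'
#' The generator draws a per-sample latent recovery level `l ~ N(mu, sd)`
#' and two replicate scores `round(l + noise)` clamped to the 0-18 grade
#' range. Rounding and the 18-point ceiling shift the observed moments, so
#' the latent parameters are solved numerically (deterministic quadrature
#' plus Nelder-Mead) such that the post-clamping mean and SD of the
#' two-replicate mean match the targets exactly.
#'
#' @param target_mean,target_sd target mean and SD of the two-time recovery
#'   score across subjects (SD typically from [sdFromCI()]).
#' @param rep_sd SD of the per-replicate assay noise on the latent scale.
#' @param max_score top of the grade range (6 loci x grade 3 = 18).
#' @return list with latent `mu`, `sd`, the `rep_sd` used, and the achieved
#'   `mean`/`sd`.
#' @export
calibrateRecoveryModel <- function(target_mean, target_sd, rep_sd = 0.8,
                                   max_score = 18L) {
  obj <- function(p) {
    m <- .recoveryMoments(p[1], exp(p[2]), rep_sd, max_score)
    (m$mean - target_mean)^2 + (m$sd - target_sd)^2
  }
  # latent SD must at least absorb replicate noise + rounding variance
  start <- c(target_mean,
             log(sqrt(max(target_sd^2 - rep_sd^2 / 2 - 1 / 24, 0.05))))
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  got <- .recoveryMoments(fit$par[1], exp(fit$par[2]), rep_sd, max_score)
  list(mu = fit$par[1], sd = exp(fit$par[2]), rep_sd = rep_sd,
       mean = got$mean, sd_achieved = got$sd)
}

# P(score >= 1) and P(score >= 2) over n_loci exchangeable loci under a
# one-factor Gaussian copula with marginal positivity q and loading^2 = r.
.tissueTailProbs <- function(q, r, n_loci = 6L, n_grid = 801L) {
  t <- qnorm(1 - q)
  z <- seq(-8, 8, length.out = n_grid)
  w <- dnorm(z); w <- w / sum(w)
  pz <- if (r >= 1) as.numeric(z > t / max(sqrt(r), 1e-12))
        else pnorm((sqrt(r) * z - t) / sqrt(1 - r))
  P0 <- sum(w * (1 - pz)^n_loci)
  P1 <- sum(w * n_loci * pz * (1 - pz)^(n_loci - 1))
  c(ge1 = 1 - P0, ge2 = 1 - P0 - P1)
}

#' Calibrate per-stage tissue positivity to printed score frequencies
#'
#' Tissue cohorts report the fraction of tumors with at least one and at
#' least two methylation-positive regions per stage. Under independent loci
#' those two numbers are incompatible (the observed `>=2` fractions are far
#' too close to the `>=1` fractions), so loci share a per-sample factor: a
#' one-factor Gaussian copula with marginal positivity `q` and factor
#' loading squared `r` is solved per stage so both tail frequencies match.
#'
#' @param p_ge1,p_ge2 target frequencies of methylation score >= 1 and >= 2.
#' @param n_loci number of panel regions.
#' @return list with `q`, `r`, and the achieved tail probabilities.
#' @export
calibrateTissueModel <- function(p_ge1, p_ge2, n_loci = 6L) {
  stopifnot(p_ge2 <= p_ge1, p_ge1 < 1, p_ge2 > 0)
  obj <- function(p) {
    got <- .tissueTailProbs(plogis(p[1]), plogis(p[2]), n_loci)
    (got["ge1"] - p_ge1)^2 + (got["ge2"] - p_ge2)^2
  }
  fit <- optim(c(qlogis(0.7), qlogis(0.6)), obj, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-13))
  q <- plogis(fit$par[1]); r <- plogis(fit$par[2])
  got <- .tissueTailProbs(q, r, n_loci)
  list(q = q, r = r, ge1 = unname(got["ge1"]), ge2 = unname(got["ge2"]))
}
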
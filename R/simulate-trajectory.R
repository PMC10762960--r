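#' Specification of a synthetic mCRC treatment trajectory
#'
#' The latent imaging tumor burden shrinks exponentially during the
#' response phase of each treatment line and then regrows exponentially;
#' radiological progressive disease (PD) is declared on the day the burden
#' exceeds its within-line nadir by `pd_factor` (default 1.2, emulating a
#' 20\% regrowth call), at which point the next line, if any, begins. The
#' combination score tracks the latent burden advanced by `fc_lead_days`
#' (methylated-template shedding responds to tumor dynamics before imaging
#' can see them), so the Fc series rises approximately that many days ahead
#' of radiological PD. Serum CEA tracks the burden with no lead in
#' `"secretor"` mode and stays flat below the normal limit in
#' `"nonsecretor"` mode (some tumors never secrete CEA). Blood draws are
#' taken every `draw_interval_days`; all channels carry multiplicative
#' log-normal measurement noise.
#'
#' @param n_draws number of blood draws (>= 2).
#' @param draw_interval_days days between draws.
#' @param baseline_burden latent burden at day 0 (mm, sum of maximum
#'   equators of metastatic lesions).
#' @param lines list of per-treatment-line parameters, each with
#'   `response_days`, `shrink_rate` and `regrow_rate` (per-day exponential
#'   rates).
#' @param pd_factor burden/nadir ratio that triggers radiological PD.
#' @param fc_gain gain linking latent burden to Fc (0 decouples them).
#' @param fc_base additive Fc baseline (default 0: Fc is modeled as the
#'   tumor-coupled excess over the patient's own baseline).
#' @param fc_lead_days programmed lead of the Fc signal ahead of imaging.
#' @param cea_mode `"secretor"` or `"nonsecretor"`.
#' @param cea_base baseline CEA (ng/ml) for secretors.
#' @param cea_normal_limit upper normal limit for CEA.
#' @param noise per-channel log-scale noise SDs (`fc`, `cea`, `burden`).
#' @param seed default RNG seed used by [simulateTrajectory()].
#' @return a validated `TrajectorySpec` (list).
#' @export
trajectorySpec <- function(
    n_draws = 16L, draw_interval_days = 7L, baseline_burden = 60,
    lines = list(list(response_days = 70, shrink_rate = 0.012,
                      regrow_rate = 0.045)),
    pd_factor = 1.2, fc_gain = 0.25, fc_base = 0, fc_lead_days = 35,
    cea_mode = c("secretor", "nonsecretor"), cea_base = 8,
    cea_normal_limit = 5,
    noise = list(fc = 0.03, cea = 0.10, burden = 0.02),
    seed = NULL) {
  stopifnot(n_draws >= 2L, draw_interval_days >= 1, fc_lead_days >= 0,
            pd_factor > 1, baseline_burden > 0, length(lines) >= 1)
  spec <- list(n_draws = as.integer(n_draws),
               draw_interval_days = as.integer(draw_interval_days),
               baseline_burden = baseline_burden, lines = lines,
               pd_factor = pd_factor, fc_gain = fc_gain, fc_base = fc_base,
               fc_lead_days = fc_lead_days, cea_mode = match.arg(cea_mode),
               cea_base = cea_base, cea_normal_limit = cea_normal_limit,
               noise = noise, seed = seed)
  class(spec) <- "TrajectorySpec"
  spec
}

# latent daily burden plus PD / line-start days out to `horizon` days
.latentBurden <- function(spec, horizon) {
  day <- 0:horizon
  burden <- numeric(horizon + 1)
  pd_days <- integer(0)
  line_starts <- integer(0)
  line_of_day <- integer(horizon + 1)
  b <- spec$baseline_burden
  t0 <- 0
  li <- 1
  while (t0 <= horizon) {
    ln <- spec$lines[[min(li, length(spec$lines))]]
    line_starts <- c(line_starts, t0)
    nadir_day <- t0 + ln$response_days
    nadir <- b * exp(-ln$shrink_rate * ln$response_days)
    pd_day <- nadir_day + log(spec$pd_factor) / ln$regrow_rate
    seg_end <- if (li < length(spec$lines)) ceiling(pd_day) else horizon
    seg_end <- min(seg_end, horizon)
    tt <- t0:seg_end
    bb <- ifelse(tt <= nadir_day,
                 b * exp(-ln$shrink_rate * (tt - t0)),
                 nadir * exp(ln$regrow_rate * (tt - nadir_day)))
    burden[tt + 1] <- bb
    line_of_day[tt + 1] <- li
    if (pd_day <= horizon) pd_days <- c(pd_days, round(pd_day))
    if (li >= length(spec$lines) || ceiling(pd_day) >= horizon) break
    b <- burden[seg_end + 1]
    t0 <- seg_end + 1
    li <- li + 1
  }
  list(day = day, burden = burden, pd_days = pd_days,
       line_starts = line_starts[-1], line_of_day = line_of_day)
}

#' Simulate a monitoring trajectory
#'
#' @param spec a [trajectorySpec()].
#' @param patient_id identifier stamped on the trajectory.
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return a [Trajectory-class]; radiological PD days and treatment-line
#'   starts (as `regimen_change`) are recorded in `events`.
#' @export
simulateTrajectory <- function(spec = trajectorySpec(), patient_id = "P1",
                               seed = spec$seed) {
  if (!is.null(seed)) set.seed(seed)
  last_day <- (spec$n_draws - 1L) * spec$draw_interval_days
  horizon <- last_day + ceiling(spec$fc_lead_days)
  lat <- .latentBurden(spec, horizon)
  dday <- seq(0L, last_day, by = spec$draw_interval_days)
  mnoise <- function(sd, k) exp(rnorm(k, 0, sd))
  k <- length(dday)
  fc <- (spec$fc_base + spec$fc_gain *
           lat$burden[dday + ceiling(spec$fc_lead_days) + 1]) *
        mnoise(spec$noise$fc, k)
  burden_obs <- lat$burden[dday + 1] * mnoise(spec$noise$burden, k)
  cea <- if (spec$cea_mode == "secretor") {
    spec$cea_base * (lat$burden[dday + 1] / spec$baseline_burden) *
      mnoise(spec$noise$cea, k)
  } else {
    pmin(spec$cea_normal_limit * 0.98,
         0.4 * spec$cea_normal_limit * mnoise(spec$noise$cea, k))
  }
  drawsDf <- data.frame(day = as.integer(dday), fc = fc, cea = cea,
                        burden = burden_obs,
                        line = lat$line_of_day[dday + 1])
  ev <- data.frame(day = integer(0), type = character(0))
  if (length(lat$pd_days))
    ev <- rbind(ev, data.frame(day = lat$pd_days, type = "radiological_PD"))
  if (length(lat$line_starts))
    ev <- rbind(ev, data.frame(day = lat$line_starts,
                               type = "regimen_change"))
  ev <- ev[order(ev$day), , drop = FALSE]
  rownames(ev) <- NULL
  new("Trajectory", patientId = patient_id, draws = drawsDf, events = ev)
}
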
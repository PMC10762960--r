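#' Approximation curve: tricube local-linear smoothing on the day axis
#'
#' Locally weighted linear regression with tricube weights over a window of
#' `span_days` days, evaluated on a daily grid inside the observed range
#' (no extrapolation beyond the first and last draw). Local linear fits
#' reproduce straight lines exactly and are linear in the value scale.
#' Windows that contain fewer than two distinct days are widened to the
#' nearest two observations so the local fit is always defined.
#'
#' @param day,value observation days and values (>= 3 points).
#' @param span_days half-width of the tricube window, in days.
#' @param grid_days evaluation days (default: every day from first to last
#'   observation).
#' @return data.frame with columns `day`, `value` (the fitted curve).
#' @export
smoothCurve <- function(day, value, span_days = 60, grid_days = NULL) {
  stopifnot(length(day) == length(value), span_days > 0)
  keep <- !is.na(day) & !is.na(value)
  day <- day[keep]; value <- value[keep]
  if (length(day) < 3) stop("smoothing needs at least 3 points")
  o <- order(day); day <- day[o]; value <- value[o]
  if (is.null(grid_days)) grid_days <- seq(min(day), max(day), by = 1)
  if (any(grid_days < min(day) | grid_days > max(day)))
    stop("grid_days must lie within the observed day range (no extrapolation)")
  fit <- vapply(grid_days, function(t) {
    h <- span_days
    d <- abs(day - t)
    if (sum(d < h) < 2) h <- sort(d)[2] * (1 + 1e-8)  # widen to 2 nearest
    w <- (1 - pmin(d / h, 1)^3)^3
    w[d >= h] <- 0
    x <- day - t
    sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
    sy <- sum(w * value); sxy <- sum(w * x * value)
    det <- sw * sxx - sx^2
    if (det <= .Machine$double.eps * sw * max(sxx, 1)) return(sy / sw)
    (sxx * sy - sx * sxy) / det  # local intercept = fitted value at t
  }, numeric(1))
  data.frame(day = grid_days, value = fit)
}

#' Detect a sustained rise of the combination score
#'
#' Nadir-relative rule: within each treatment line (the running nadir
#' resets at each line start, a new regimen implying a new baseline), a
#' rise is detected at the first time the series exceeds its running nadir
#' by a relative `threshold` (default +30\%) and stays above that level for
#' at least `confirm` consecutive draws. With `interpolate = TRUE` the
#' reported day is the linear interpolation of the crossing between the
#' last sub-threshold and first supra-threshold draw, otherwise the first
#' supra-threshold draw day.
#'
#' @param day,value the Fc draw series (raw or smoothed).
#' @param line optional treatment-line index per draw; `NULL` = one line.
#' @param threshold relative rise above the running nadir.
#' @param confirm number of consecutive supra-threshold draws required.
#' @param interpolate report the interpolated crossing day.
#' @return detection day (numeric) or `NA` if no sustained rise occurs.
#' @export
detectRise <- function(day, value, line = NULL, threshold = 0.30,
                       confirm = 2L, interpolate = TRUE) {
  stopifnot(length(day) == length(value), threshold >= 0, confirm >= 1)
  if (is.null(line)) line <- rep(1L, length(day))
  for (ln in unique(line)) {
    idx <- which(line == ln)
    d <- day[idx]; v <- value[idx]
    nadir <- cummin(v)
    above <- v >= (1 + threshold) * nadir & nadir > 0
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    hit <- which(runs$values & runs$lengths >= confirm)
    if (!length(hit)) next
    i <- starts[hit[1]]
    if (interpolate && i > 1L) {
      lev <- (1 + threshold) * nadir[i - 1L]
      if (v[i - 1L] < lev && v[i] > v[i - 1L]) {
        frac <- (lev - v[i - 1L]) / (v[i] - v[i - 1L])
        return(d[i - 1L] + frac * (d[i] - d[i - 1L]))
      }
    }
    return(as.numeric(d[i]))
  }
  NA_real_
}

#' Lead time of the combination-score rise before progressive disease
#'
#' Applies [detectRise()] to a trajectory's Fc series and measures the time
#' from detection to the first PD event at or after detection. Radiological
#' and clinical PD are treated identically for the arithmetic; the event
#' type is carried through. If detection happens only after every PD event
#' the result is flagged (`after_pd = TRUE`) and the (non-positive) lead
#' relative to the last PD is reported separately.
#'
#' @param trajectory a [Trajectory-class] with at least one PD event.
#' @param threshold,confirm,interpolate rise-rule parameters, see
#'   [detectRise()].
#' @param smooth_first smooth the Fc series with [smoothCurve()] before
#'   detection (default `FALSE`: detection runs on the raw draws).
#' @param span_days smoothing span when `smooth_first = TRUE`.
#' @return list with `detected`, `detection_day`, `pd_day`, `pd_type`,
#'   `lead_days`, `after_pd`, and `rule` (the parameters used).
#' @export
leadTime <- function(trajectory, threshold = 0.30, confirm = 2L,
                     interpolate = TRUE, smooth_first = FALSE,
                     span_days = 60) {
  stopifnot(methods::is(trajectory, "Trajectory"))
  ev <- events(trajectory)
  pd <- ev[ev$type %in% c("radiological_PD", "clinical_PD"), , drop = FALSE]
  if (!nrow(pd)) stop("trajectory has no PD event")
  pd <- pd[order(pd$day), , drop = FALSE]
  d <- draws(trajectory)
  rule <- list(threshold = threshold, confirm = confirm,
               interpolate = interpolate, smooth_first = smooth_first,
               span_days = if (smooth_first) span_days else NA)
  if (smooth_first) {
    sc <- smoothCurve(d$day, d$fc, span_days = span_days,
                      grid_days = d$day)
    det <- detectRise(sc$day, sc$value, line = d$line,
                      threshold = threshold, confirm = confirm,
                      interpolate = interpolate)
  } else {
    det <- detectRise(d$day, d$fc, line = d$line, threshold = threshold,
                      confirm = confirm, interpolate = interpolate)
  }
  if (is.na(det))
    return(list(detected = FALSE, detection_day = NA_real_,
                pd_day = NA_real_, pd_type = NA_character_,
                lead_days = NA_real_, after_pd = FALSE, rule = rule))
  nxt <- which(pd$day >= det)
  if (length(nxt)) {
    i <- nxt[1]
    list(detected = TRUE, detection_day = det, pd_day = pd$day[i],
         pd_type = pd$type[i], lead_days = pd$day[i] - det,
         after_pd = FALSE, rule = rule)
  } else {
    i <- nrow(pd)
    list(detected = TRUE, detection_day = det, pd_day = pd$day[i],
         pd_type = pd$type[i], lead_days = pd$day[i] - det,
         after_pd = TRUE, rule = rule)
  }
}

#' Trend concordance of two approximation curves
#'
#' Spearman correlation of the day-to-day first differences of two curves
#' on their common daily grid: +1 for identical trends, -1 for opposite
#' trends, near 0 for unrelated ones.
#'
#' @param curveA,curveB data.frames with columns `day`, `value` (e.g. from
#'   [smoothCurve()]).
#' @return concordance in \[-1, 1\].
#' @export
trendConcordance <- function(curveA, curveB) {
  common <- intersect(curveA$day, curveB$day)
  if (length(common) < 3)
    stop("curves need at least 3 common grid days (2 first differences)")
  common <- sort(common)
  a <- curveA$value[match(common, curveA$day)]
  b <- curveB$value[match(common, curveB$day)]
  da <- diff(a); db <- diff(b)
  if (sd(da) == 0 || sd(db) == 0) {
    # a flat curve has no trend; concordance with anything is 0
    return(0)
  }
  cor(da, db, method = "spearman")
}
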
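#' Nodule diameter at an arbitrary time
#'
#' Evaluates the piecewise-linear diameter trajectory implied by a sparse
#' observation series at time `t`: exact at observation times, linear
#' interpolation between them, and linear extrapolation through the last two
#' observations beyond the series. With a single observation the value is
#' carried forward unchanged. The result is clamped at 0 mm.
#'
#' @param series Data frame with columns `t` (days, strictly increasing) and
#'   `diameter` (mm) — one patient's observation series.
#' @param t Time(s) in days from the baseline screen; vectorized.
#' @return Diameter(s) in mm.
#' @examples
#' s <- data.frame(t = c(0, 365), diameter = c(4, 6))
#' diameter_at(s, c(365, 730))  # 6 at the knot, 8 extrapolated
#' @export
diameter_at <- function(series, t) {
  check_series(series)
  tt <- series$t
  dd <- series$diameter
  if (length(tt) == 1) return(rep(max(0, dd), length(t)))
  slope_last <- (dd[length(dd)] - dd[length(dd) - 1]) /
    (tt[length(tt)] - tt[length(tt) - 1])
  slope_first <- (dd[2] - dd[1]) / (tt[2] - tt[1])
  out <- vapply(t, function(ti) {
    if (ti <= tt[1]) return(dd[1] + slope_first * (ti - tt[1]))
    if (ti >= tt[length(tt)])
      return(dd[length(dd)] + slope_last * (ti - tt[length(tt)]))
    i <- findInterval(ti, tt)
    dd[i] + (dd[i + 1] - dd[i]) * (ti - tt[i]) / (tt[i + 1] - tt[i])
  }, numeric(1))
  pmax(out, 0)
}

#' Nodule appearance at an arbitrary time
#'
#' Last-observation-carried-forward lookup of the categorical nodule state:
#' returns the attenuation class and margin spiculation of the latest
#' observation at or before `t`.
#'
#' @inheritParams diameter_at
#' @param t A single time in days; must not precede the first observation.
#' @return A list with `attenuation` and `spiculated`.
#' @export
appearance_at <- function(series, t) {
  check_series(series, need_classes = TRUE)
  if (t < series$t[1])
    stop("t precedes the first observation; appearance is undefined",
         call. = FALSE)
  i <- findInterval(t, series$t)
  list(attenuation = series$attenuation[i], spiculated = series$spiculated[i])
}

#' Diameter rate of change between consecutive observations
#'
#' The growth rate between observations `i - 1` and `i`:
#' `(diameter_i - diameter_{i-1}) / (t_i - t_{i-1})` in mm/day. Defined only
#' from the second observation onward.
#'
#' @inheritParams diameter_at
#' @param i Observation index, `>= 2`.
#' @return Rate of change in mm/day (negative for a shrinking nodule).
#' @examples
#' nodule_delta(data.frame(t = c(0, 365), diameter = c(4, 6)), 2)
#' @export
nodule_delta <- function(series, i) {
  check_series(series)
  if (i < 2 || i > nrow(series))
    stop("delta requires an observation index between 2 and the series length",
         call. = FALSE)
  dt <- series$t[i] - series$t[i - 1]
  if (dt <= 0) stop("coincident observation times", call. = FALSE)
  (series$diameter[i] - series$diameter[i - 1]) / dt
}

#' Interpolated nodule state at a decision time
#'
#' Convenience wrapper combining [diameter_at()] and [appearance_at()], plus
#' the rate of change of the interpolated diameter since a previous decision
#' time when one is supplied.
#'
#' @inheritParams appearance_at
#' @param t_prev Optional earlier decision time; when given, `delta` is the
#'   interpolated diameter change between `t_prev` and `t` in mm/day.
#' @return A list with `t`, `diameter`, `attenuation`, `spiculated`, and
#'   `delta` (`NA` when `t_prev` is missing).
#' @export
interpolated_state <- function(series, t, t_prev = NULL) {
  app <- appearance_at(series, t)
  d <- diameter_at(series, t)
  delta <- NA_real_
  if (!is.null(t_prev)) {
    if (t_prev >= t) stop("t_prev must precede t", call. = FALSE)
    delta <- (d - diameter_at(series, t_prev)) / (t - t_prev)
  }
  list(t = t, diameter = d, attenuation = app$attenuation,
       spiculated = app$spiculated, delta = delta)
}

check_series <- function(series, need_classes = FALSE) {
  if (is.null(series) || nrow(series) == 0)
    stop("empty observation series", call. = FALSE)
  if (is.unsorted(series$t, strictly = TRUE))
    stop("observation times must be strictly increasing", call. = FALSE)
  if (need_classes && (is.null(series$attenuation) || is.null(series$spiculated)))
    stop("series lacks attenuation/spiculation columns", call. = FALSE)
  invisible(series)
}
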
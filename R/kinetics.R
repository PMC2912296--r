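# Analysis of compaction and soluble-ligand depletion time series:
# piecewise rate estimation around a breakpoint and compaction-shape
# metrics.

#' Early- and late-phase ligand depletion rates
#'
#' Splits a soluble-fibronectin time series at a breakpoint (72 h unless
#' stated otherwise) and estimates the depletion rate in each window by
#' ordinary least squares of concentration on time, sign-flipped so that a
#' falling series has a positive rate.
#'
#' @param t_hr Measurement times in hours (increasing).
#' @param Fn Soluble-Fn concentrations (ug/ml), same length as `t_hr`.
#' @param breakpoint_hr Phase boundary in hours; points at the breakpoint
#'   belong to both windows.
#' @return List with elements `early` and `late`, each a list with `phase`,
#'   `window` (hours), and `rate` (ug/ml/hr).
#' @export
depletion_rates <- function(t_hr, Fn, breakpoint_hr = 72) {
  if (is.data.frame(t_hr)) {
    df <- t_hr
    if (!is.null(df$t_day)) { Fn <- df$Fn_ug_ml; t_hr <- df$t_day * 24 }
    else stop("schema error: expected columns t_day, Fn_ug_ml")
  }
  if (length(t_hr) != length(Fn)) stop("window too sparse: unequal lengths")
  if (any(!is.finite(t_hr)) || any(!is.finite(Fn))) stop("non-finite input")
  fit_window <- function(idx, phase) {
    if (sum(idx) < 2) stop("window too sparse: need >= 2 points per window")
    tt <- t_hr[idx]
    if (stats::var(tt) == 0) stop("window too sparse: coincident times")
    slope <- unname(stats::coef(stats::lm(Fn[idx] ~ tt))[2])
    list(phase = phase,
         window = c(t_start = min(tt), t_end = max(tt)),
         rate = -slope)
  }
  list(early = fit_window(t_hr <= breakpoint_hr, "early"),
       late = fit_window(t_hr >= breakpoint_hr, "late"))
}

#' Shape metrics of a compaction time course
#'
#' Flags whether the series is monotone non-increasing (up to a relative
#' jitter tolerance), locates the day of minimum area, and measures the
#' rebound (decompaction) from that minimum to the end of the series.
#'
#' @param t_day Measurement days (increasing), or a `"compaction_series"`
#'   data frame (then `area` is taken from its `area_rel` column).
#' @param area Relative projected areas, same length as `t_day`.
#' @param tol Relative tolerance on increases, as a fraction of the initial
#'   area (default 1%, the scale of hand-traced perimeter noise).
#' @return List with `is_monotone`, `t_min` (day of minimum area), and
#'   `rebound` (`area(end) - area(t_min)`; 0 when monotone).
#' @export
compaction_metrics <- function(t_day, area, tol = 0.01) {
  if (is.data.frame(t_day)) {
    area <- t_day$area_rel
    t_day <- t_day$t_day
  }
  if (length(t_day) < 3) stop("series too short: need >= 3 points")
  if (length(area) != length(t_day)) stop("series too short: unequal lengths")
  slack <- tol * area[1L]
  is_monotone <- all(diff(area) <= slack)
  i_min <- which.min(area)
  rebound <- if (is_monotone) 0 else max(0, area[length(area)] - area[i_min])
  list(is_monotone = is_monotone, t_min = t_day[i_min], rebound = rebound)
}
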
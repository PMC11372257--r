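#' Net influx rate Ki
#'
#' `Ki = K1 * k3 / (k2 + k3)` for the two-tissue models; undefined for the
#' one-tissue model.
#'
#' @param params a [kinetic_params()].
#' @return Ki in mL/min/mL.
#' @export
compute_ki <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$model == "1T4P")
    stop("Ki is undefined for the one-tissue model")
  if (params$k2 + params$k3 <= 0) stop("Ki requires k2 + k3 > 0")
  params$K1 * params$k3 / (params$k2 + params$k3)
}

#' Total volume of distribution VT
#'
#' `VT = K1/k2` for the one-tissue model and `K1/k2 * (1 + k3/k4)` for the
#' reversible two-tissue model.  The irreversible 2T5P model (`k4 = 0`) has
#' no finite VT.
#'
#' @param params a [kinetic_params()].
#' @export
compute_vt <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$k2 <= 0) stop("VT requires k2 > 0")
  if (params$model == "1T4P") return(params$K1 / params$k2)
  if (params$k4 <= 0)
    stop("VT is undefined for the irreversible model (k4 = 0)")
  params$K1 / params$k2 * (1 + params$k3 / params$k4)
}

#' Blood-volume-corrected volume of distribution
#'
#' `VT(vb) = vb + (1 - vb) * VT`: the exact equilibrium limit of the
#' measured-region-to-blood ratio under the measurement equation
#' `C_m = vb * C_wb + (1 - vb) * C_t`.  This is the value the extrapolated
#' SUVR curve converges to for a reversible model.
#'
#' @param params a [kinetic_params()].
#' @export
compute_vt_vb <- function(params) {
  vt <- compute_vt(params)
  params$vb + (1 - params$vb) * vt
}

# Per-frame blood values over a schedule: the measured frame values when the
# schedule is the input's own sampling grid (no shift applied), otherwise
# frame averages of the continuous evaluator.
.frame_avg_input <- function(input, schedule, n_sub = 20) {
  own <- input$t_d == 0 && schedule$n == input$schedule$n &&
    isTRUE(all.equal(schedule$start, input$schedule$start)) &&
    isTRUE(all.equal(schedule$end, input$schedule$end))
  if (own) return(input$y)
  vapply(seq_len(schedule$n), function(i) {
    tt <- seq(schedule$start[i], schedule$end[i], length.out = n_sub)
    vals <- predict(input, tt)
    mean((vals[-1] + vals[-n_sub]) / 2)
  }, numeric(1))
}

#' Tissue-to-blood SUV ratio per frame
#'
#' Elementwise ratio of the regional TAC to the frame-averaged whole-blood
#' input.  Frames with a nonpositive blood value are excluded with a
#' warning.
#'
#' @param tac_obs a [tac()].
#' @param input an [input_function()] (extrapolated if the schedule extends
#'   beyond the measured blood curve).
#' @return Data frame with `mid` (min), `suvr`.
#' @export
suvr_curve <- function(tac_obs, input) {
  stopifnot(inherits(tac_obs, "tac"), inherits(input, "input_function"))
  sch <- tac_obs$schedule
  blood <- .frame_avg_input(input, sch)
  ok <- blood > 0
  if (!all(ok))
    warning(sprintf("%d frame(s) with nonpositive blood value excluded",
                    sum(!ok)))
  data.frame(mid = sch$mid[ok], suvr = tac_obs$values[ok] / blood[ok])
}

#' Windowed SUVR scalar
#'
#' Ratio of the duration-weighted mean tissue activity to the
#' duration-weighted mean blood activity over the frames whose midpoints lie
#' in `window` (default 60-90 min).
#'
#' @inheritParams suvr_curve
#' @param window `(t0, t1)` in minutes.
#' @export
suvr_window <- function(tac_obs, input, window = c(60, 90)) {
  sch <- tac_obs$schedule
  sel <- sch$mid >= window[1] & sch$mid <= window[2]
  if (!any(sel)) stop("no frame midpoints inside the SUVR window")
  blood <- .frame_avg_input(input, sch)
  num <- sum(tac_obs$values[sel] * sch$dur[sel]) / sum(sch$dur[sel])
  den <- sum(blood[sel] * sch$dur[sel]) / sum(sch$dur[sel])
  if (den <= 0) stop("blood activity nonpositive over the SUVR window")
  num / den
}

#' Windowed SUV scalar
#'
#' Duration-weighted mean of the TAC over the frames whose midpoints lie in
#' `window`; the static-uptake measure SUVR and kinetic macroparameters are
#' compared against.
#'
#' @param tac_obs a [tac()].
#' @param window `(t0, t1)` in minutes.
#' @export
suv_window <- function(tac_obs, window = c(60, 90)) {
  sch <- tac_obs$schedule
  sel <- sch$mid >= window[1] & sch$mid <= window[2]
  if (!any(sel)) stop("no frame midpoints inside the SUV window")
  sum(tac_obs$values[sel] * sch$dur[sel]) / sum(sch$dur[sel])
}

# zero-anchored cumulative trapezoid on (0, x1, ...), values (0, y1, ...)
.cumtrapz0 <- function(x, y) {
  xx <- c(0, x)
  yy <- c(0, y)
  cumsum(c(0, diff(xx) * (yy[-1] + yy[-length(yy)]) / 2))[-1]
}

#' Logan graphical analysis
#'
#' Ordinary least-squares line through the transformed points
#' `int_0^t C_T / C_T(t)` versus `int_0^t C_P / C_T(t)` for frames with
#' midpoint at or after `t_star`; the slope estimates the distribution
#' volume of a reversible tracer (the blood-volume-corrected VT when the
#' measured TAC includes the vascular signal).  Cumulative integrals use a
#' zero-anchored trapezoid on frame midpoints.
#'
#' @inheritParams suvr_curve
#' @param t_star linearity onset time (min), default 30.
#' @return List with `K_Logan` (slope), `intercept`, `n_points`, `t_star`.
#' @export
logan <- function(tac_obs, input, t_star = 30) {
  stopifnot(inherits(tac_obs, "tac"), inherits(input, "input_function"))
  sch <- tac_obs$schedule
  ct <- tac_obs$values
  cp <- predict(input, sch$mid)
  int_ct <- .cumtrapz0(sch$mid, ct)
  int_cp <- .cumtrapz0(sch$mid, cp)
  sel <- sch$mid >= t_star - 1e-9 & ct > 0
  if (sum(sel) < 3)
    stop("Logan analysis needs at least 3 usable frames after t_star")
  x <- int_cp[sel] / ct[sel]
  y <- int_ct[sel] / ct[sel]
  fit <- lm(y ~ x)
  list(K_Logan = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n_points = sum(sel), t_star = t_star)
}
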
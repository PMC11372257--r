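#' Whole-blood input function
#'
#' Wraps a measured blood-pool TAC into a continuous-time evaluator.  Within
#' the measured window the curve is linear between frame midpoints, rising
#' linearly from zero at injection (t = 0) to the first midpoint.  Beyond the
#' last midpoint evaluation requires a fitted biexponential tail (see
#' [fit_biexp_tail()]), which enables extrapolation to equilibrium times.
#'
#' @param blood a [tac()] of a blood-pool region, or a numeric vector of
#'   per-frame values with `schedule` supplied.
#' @param schedule [frame_schedule()] (ignored when `blood` is a `tac`).
#' @param unit concentration unit.
#' @return An object of class `input_function`.
#' @seealso [predict.input_function()], [shift_input()], [fit_biexp_tail()],
#'   [extrapolate_input()]
#' @export
input_function <- function(blood, schedule = NULL, unit = "SUV") {
  if (inherits(blood, "tac")) {
    schedule <- blood$schedule
    unit <- blood$unit
    values <- blood$values
  } else {
    stopifnot(inherits(schedule, "frame_schedule"))
    values <- as.numeric(blood)
    if (length(values) != schedule$n) stop("values/schedule length mismatch")
  }
  structure(list(t = schedule$mid, y = values, t_d = 0, tail = NULL,
                 unit = unit, schedule = schedule),
            class = "input_function")
}

#' Evaluate an input function at arbitrary times
#'
#' @param object an [input_function()].
#' @param t times in minutes (t >= 0).
#' @param ... unused.
#' @return Concentrations at `t`.  Values are 0 for `t` at or before the
#'   (delay-shifted) injection, interpolated within the measured window, and
#'   follow the biexponential tail beyond it; an error is raised beyond the
#'   measured range when no tail has been fitted.
#' @export
predict.input_function <- function(object, t, ...) {
  t <- as.numeric(t)
  if (any(t < 0)) stop("input function is undefined for t < 0")
  u <- t - object$t_d                      # time on the unshifted curve
  last <- object$t[length(object$t)]
  out <- numeric(length(t))
  inside <- u > 0 & u <= last
  if (any(inside))
    out[inside] <- approx(c(0, object$t), c(0, object$y), xout = u[inside],
                          rule = 1)$y
  beyond <- u > last
  if (any(beyond)) {
    if (!is.null(object$tail)) {
      tl <- object$tail
      ub <- u[beyond]
      out[beyond] <- tl$A1 * exp(-tl$lam1 * ub) + tl$A2 * exp(-tl$lam2 * ub)
    } else {
      # no tail: continue the final linear segment, but only through the
      # last measured frame (plus a 1-min delay margin) -- the final frame's
      # average is measured even though its midpoint precedes the frame end
      margin <- object$schedule$end[object$schedule$n] + 1
      if (any(u[beyond] > margin + 1e-9))
        stop(sprintf(
          "cannot evaluate input at %.4g min: beyond measured range (%.4g min) and no biexponential tail fitted",
          max(t[beyond]), margin))
      nt <- length(object$t)
      slope <- (object$y[nt] - object$y[nt - 1]) /
        (object$t[nt] - object$t[nt - 1])
      out[beyond] <- pmax(object$y[nt] + slope * (u[beyond] - last), 0)
    }
  }
  out
}

#' Apply a time delay to an input function
#'
#' Returns an input whose evaluation satisfies
#' `predict(shifted, t) == predict(original, t - t_d)`, clamped to zero for
#' `t - t_d < 0`.  Delays accumulate across repeated shifts.
#'
#' @param input an [input_function()].
#' @param t_d delay in minutes; must satisfy `|t_d| <= bound`.
#' @param bound allowed delay magnitude (min).
#' @export
shift_input <- function(input, t_d, bound = 1) {
  stopifnot(inherits(input, "input_function"), .is_number(t_d))
  if (abs(t_d) > bound + 1e-12)
    stop(sprintf("|t_d| = %.3g min exceeds the configured bound (%g min)",
                 abs(t_d), bound))
  input$t_d <- input$t_d + t_d
  input
}

#' Biologic half-life of an exponential clearance component
#'
#' @param lam decay rate in 1/min.
#' @return `log(2)/lam` in minutes.
#' @export
half_life <- function(lam) {
  stopifnot(all(lam > 0))
  log(2) / lam
}

#' Fit a biexponential tail to the late part of a blood curve
#'
#' Nonlinear least squares of `A1*exp(-lam1*t) + A2*exp(-lam2*t)` on the
#' frame midpoints whose midpoint falls inside `window` (default 14-90 min),
#' with nonnegativity bounds and a deterministic multistart over log-spaced
#' rate pairs (biexponential objectives are multimodal).  Components are
#' returned ordered fast/slow (`lam1 > lam2`).
#'
#' @param input an [input_function()].
#' @param window `(t0, t1)` fit window in minutes.
#' @return The input with a fitted `tail` (class `biexp_tail`: amplitudes,
#'   rates, half-lives `log(2)/lam`, window, RSS).
#' @export
fit_biexp_tail <- function(input, window = c(14, 90)) {
  stopifnot(inherits(input, "input_function"))
  sel <- input$t >= window[1] - 1e-9 & input$t <= window[2] + 1e-9
  if (sum(sel) < 4)
    stop("need at least 4 frame midpoints inside the tail-fit window")
  tt <- input$t[sel]
  yy <- input$y[sel]
  lower <- c(0, 1e-6, 0, 1e-7)
  upper <- c(Inf, 10, Inf, 10)
  resid_fn <- function(p) p[1] * exp(-p[2] * tt) + p[3] * exp(-p[4] * tt) - yy
  # starts: log-spaced fast rates, slow rate a fixed factor below, amplitudes
  # from a clamped linear solve at those rates
  fast <- 10^seq(-2, 0.5, length.out = 6)
  best <- NULL
  for (lf in fast) {
    ls <- lf / 25
    X <- cbind(exp(-lf * tt), exp(-ls * tt))
    ab <- tryCatch(pmax(qr.solve(crossprod(X), crossprod(X, yy)), 1e-8),
                   error = function(e) c(mean(yy), mean(yy)) / 2)
    start <- c(ab[1], lf, ab[2], ls)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 400, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    stop("biexponential tail fit failed from every start")
  p <- best$par
  if (p[2] < p[4]) p <- p[c(3, 4, 1, 2)]  # order fast/slow
  tail <- structure(list(
    A1 = p[1], lam1 = p[2], A2 = p[3], lam2 = p[4],
    half_lives = c(fast = log(2) / p[2], slow = log(2) / p[4]),
    window = window, rss = best$rss), class = "biexp_tail")
  input$tail <- tail
  input
}

#' @export
print.biexp_tail <- function(x, ...) {
  cat(sprintf(
    "Biexponential tail (window %g-%g min):\n  A1=%.4g, lam1=%.4g /min (t1/2 %.3g min)\n  A2=%.4g, lam2=%.4g /min (t1/2 %.3g min)\n  RSS %.3g\n",
    x$window[1], x$window[2], x$A1, x$lam1, x$half_lives["fast"],
    x$A2, x$lam2, x$half_lives["slow"], x$rss))
  invisible(x)
}

#' Extend an input function beyond the scan with its fitted tail
#'
#' Marks the input as valid for evaluation up to `horizon` minutes (default
#' 600 min = 10 h, the equilibrium horizon).  Measured values are untouched
#' on the measured support; the biexponential tail takes over beyond the
#' last frame midpoint.
#'
#' @param input an [input_function()] with a fitted tail.
#' @param horizon extrapolation horizon in minutes.
#' @export
extrapolate_input <- function(input, horizon = 600) {
  stopifnot(inherits(input, "input_function"))
  last <- input$t[length(input$t)]
  if (horizon < last) {
    warning(sprintf(
      "horizon (%g min) is before the scan end (%.4g min); nothing to do",
      horizon, last))
    return(input)
  }
  if (is.null(input$tail))
    stop("fit the biexponential tail before extrapolating")
  input$horizon <- horizon
  input
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("Input function: %d frames to %.4g min, delay %+.3g min, %s\n",
              length(x$t), x$t[length(x$t)], x$t_d,
              if (is.null(x$tail)) "no tail" else
                sprintf("biexp tail (t1/2 %.3g/%.3g min)",
                        x$tail$half_lives["fast"], x$tail$half_lives["slow"])))
  invisible(x)
}
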
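.MODEL_KINDS <- c("1T4P", "2T5P", "2T6P")

#' Kinetic microparameters of a compartment model
#'
#' The measured regional signal is modeled as
#' `C_m(t) = v_b * C_wb(t - t_d) + (1 - v_b) * C_t(t)`, where `C_wb` is the
#' whole-blood input and `C_t` the tissue response.  For the one-tissue model
#' `dC_t/dt = K1 * C_wb(t - t_d) - k2 * C_t`; for the serial two-tissue model
#' `dC1/dt = K1 * C_wb(t - t_d) - (k2 + k3) * C1 + k4 * C2`,
#' `dC2/dt = k3 * C1 - k4 * C2`, with `C_t = C1 + C2`.  `2T5P` is the
#' irreversible special case `k4 = 0`; `1T4P` fixes `k3 = k4 = 0`.
#'
#' @param model `"1T4P"`, `"2T5P"` or `"2T6P"` (the digit counts fitted
#'   parameters including the time delay).
#' @param vb fractional blood volume in `[0, 1]`.
#' @param K1 delivery rate constant (mL/min/mL).
#' @param k2,k3,k4 rate constants (1/min), nonnegative.
#' @param td time delay between the sampled blood pool and tracer arrival at
#'   the region (min).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(model = c("2T6P", "1T4P", "2T5P"), vb, K1, k2,
                           k3 = 0, k4 = 0, td = 0) {
  model <- match.arg(model)
  vb <- unname(vb); K1 <- unname(K1); k2 <- unname(k2)
  k3 <- unname(k3); k4 <- unname(k4); td <- unname(td)
  p <- c(vb = vb, K1 = K1, k2 = k2, k3 = k3, k4 = k4, td = td)
  if (any(!is.finite(p))) stop("non-finite kinetic parameter")
  if (vb < 0 || vb > 1) stop("vb must lie in [0, 1]")
  if (any(p[c("K1", "k2", "k3", "k4")] < 0))
    stop("rate constants must be nonnegative")
  if (model == "1T4P" && (k3 != 0 || k4 != 0))
    stop("1T4P requires k3 = k4 = 0")
  if (model == "2T5P" && k4 != 0) stop("2T5P requires k4 = 0")
  structure(list(model = model, vb = vb, K1 = K1, k2 = k2, k3 = k3, k4 = k4,
                 td = td), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "%s: vb=%.4g K1=%.4g k2=%.4g k3=%.4g k4=%.4g td=%.4g\n",
    x$model, x$vb, x$K1, x$k2, x$k3, x$k4, x$td))
  invisible(x)
}

# Decompose the tissue impulse response into exponential modes
# h(t) = sum_m B[m] * exp(-theta[m] * t).  A numerically coincident
# eigenvalue pair (possible only when k3 = 0 and k2 = k4) is evaluated as
# the analytic confluent limit via a symmetric epsilon-split of the repeated
# eigenvalue; the O(eps^2 t^2) error is below double precision for scan
# times.
.kinetic_modes <- function(params) {
  with(params, {
    if (model == "1T4P") return(list(theta = k2, B = K1))
    s <- k2 + k3 + k4
    disc <- s * s - 4 * k2 * k4
    sq <- sqrt(max(disc, 0))
    th1 <- (s + sq) / 2
    th2 <- (s - sq) / 2
    gap_tol <- 1e-7 * max(th1, 1e-3)
    if (th1 - th2 < gap_tol) {
      th <- s / 2
      eps <- gap_tol / 2
      th1 <- th + eps
      th2 <- max(th - eps, 0)
    }
    a <- k3 + k4
    d <- th1 - th2
    list(theta = c(th1, th2), B = K1 * c((th1 - a) / d, (a - th2) / d))
  })
}

#' Forward-simulate a compartment model to a framed TAC
#'
#' Computes the measured model curve by exact exponential convolution of the
#' tissue impulse response against the piecewise-linear input, then averages
#' over each frame (PET frames integrate activity, which matters for the 2-s
#' early frames).  This is the forward model used by fitting, sensitivity and
#' simulation; [ode_oracle()] provides an independent numeric check.
#'
#' @param params a [kinetic_params()].
#' @param input an [input_function()] covering the schedule (after the delay
#'   shift); fit/extrapolate a tail first if the schedule extends beyond the
#'   measured blood curve.
#' @param schedule a [frame_schedule()].
#' @return A [tac()] of frame-averaged model values, region label `"model"`.
#' @export
model_tac <- function(params, input, schedule) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(input, "input_function"),
            inherits(schedule, "frame_schedule"))
  tac("model", schedule, .forward_values(params, input, schedule),
      unit = input$unit)
}

# lean forward evaluation (numeric vector only); the optimizer's hot path
.forward_values <- function(params, input, schedule) {
  modes <- .kinetic_modes(params)
  tl <- input$tail
  .forward_cpp(schedule$start, schedule$end,
               c(0, input$t), c(0, input$y),
               input$t_d + params$td, !is.null(tl),
               if (is.null(tl)) 0 else tl$A1,
               if (is.null(tl)) 1 else tl$lam1,
               if (is.null(tl)) 0 else tl$A2,
               if (is.null(tl)) 1 else tl$lam2,
               input$schedule$end[input$schedule$n] + 1,
               modes$theta, modes$B, params$vb)
}

# unvalidated parameter container for optimizer internals (the bounds make
# the values valid by construction)
.params_raw <- function(model, p) {
  structure(list(model = model, vb = p[["vb"]], K1 = p[["K1"]],
                 k2 = p[["k2"]],
                 k3 = if ("k3" %in% names(p)) p[["k3"]] else 0,
                 k4 = if ("k4" %in% names(p)) p[["k4"]] else 0,
                 td = if ("td" %in% names(p)) p[["td"]] else 0),
            class = "kinetic_params")
}

#' Independent ODE oracle for the forward model
#'
#' Integrates the compartment ODEs directly with adaptive stiff integration
#' (`deSolve::lsoda`) at tight tolerances, accumulating exact frame integrals
#' through auxiliary quadrature states.  Used only for verification of
#' [model_tac()]; it shares nothing with the analytic convolution except the
#' input evaluator the contract is defined on.
#'
#' @inheritParams model_tac
#' @return A [tac()] of frame-averaged model values.
#' @export
ode_oracle <- function(params, input, schedule) {
  stopifnot(inherits(params, "kinetic_params"))
  shifted <- shift_input(input, params$td, bound = Inf)
  times <- sort(unique(c(0, schedule$start, schedule$end)))
  deriv <- function(t, y, parms) {
    u <- predict(shifted, t)
    with(params, {
      if (model == "1T4P") {
        d1 <- K1 * u - k2 * y[1]
        d2 <- 0
      } else {
        d1 <- K1 * u - (k2 + k3) * y[1] + k4 * y[2]
        d2 <- k3 * y[1] - k4 * y[2]
      }
      list(c(d1, d2, y[1] + if (model == "1T4P") 0 else y[2], u))
    })
  }
  sol <- deSolve::lsoda(c(C1 = 0, C2 = 0, intCt = 0, intU = 0), times, deriv,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0) stop("ODE integration failed")
  i0 <- match(schedule$start, times)
  i1 <- match(schedule$end, times)
  tis <- (sol[i1, "intCt"] - sol[i0, "intCt"]) / schedule$dur
  blood <- (sol[i1, "intU"] - sol[i0, "intU"]) / schedule$dur
  vals <- params$vb * blood + (1 - params$vb) * tis
  tac("model", schedule, unname(vals), unit = input$unit)
}
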
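#' @export
print.kinetic_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("Kinetic fit (%s)%s\n", x$model,
              if (x$fixed_delay) ", fixed delay" else ""))
  cat(sprintf("  vb=%.4g  K1=%.4g  k2=%.4g  k3=%.4g  k4=%.4g  td=%.4g min\n",
              p$vb, p$K1, p$k2, p$k3, p$k4, p$td))
  cat(sprintf("  RSS %.4g on %d frames, AICc %.3f%s\n", x$rss, x$n, x$aicc,
              if (!x$converged) " (not converged)" else ""))
  if (any(x$at_boundary))
    cat("  at bound:", paste(names(which(x$at_boundary)), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  p <- object$params
  out <- c(vb = p$vb, K1 = p$K1, k2 = p$k2, k3 = p$k3, k4 = p$k4, td = p$td)
  nm <- .free_params(object$model)
  if (object$fixed_delay) nm <- setdiff(nm, "td")
  out[nm]
}

#' @export
predict.kinetic_fit <- function(object, schedule = NULL, ...) {
  if (is.null(schedule)) schedule <- object$tac$schedule
  model_tac(object$params, object$input, schedule)$values
}

#' @export
residuals.kinetic_fit <- function(object, ...) {
  object$tac$values - predict(object)
}

#' Summary of a kinetic fit, including macroparameters
#'
#' @param object a [fit_kinetic()] result.
#' @param ... unused.
#' @return A list of class `summary.kinetic_fit` with the coefficient table,
#'   fit diagnostics and the derived macroparameters (`Ki`, `VT`, `VT_vb`)
#'   where the model defines them.
#' @export
summary.kinetic_fit <- function(object, ...) {
  p <- object$params
  macro <- list(
    Ki = if (p$model != "1T4P" && p$k2 + p$k3 > 0) compute_ki(p) else NA_real_,
    VT = tryCatch(compute_vt(p), error = function(e) NA_real_),
    VT_vb = tryCatch(compute_vt_vb(p), error = function(e) NA_real_))
  structure(list(fit = object, macro = macro), class = "summary.kinetic_fit")
}

#' @export
print.summary.kinetic_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  Ki=%.4g mL/min/mL  VT=%.4g  VT(vb)=%.4g\n",
              x$macro$Ki, x$macro$VT, x$macro$VT_vb))
  invisible(x)
}

#' Simulate noisy replicate TACs from a fitted model
#'
#' Parametric bootstrap: adds framed PET noise (see [noise_sigma()]) to the
#' model-predicted curve at the fitted parameters.  This is the replicate
#' generator behind the practical-identifiability Monte Carlo.
#'
#' @param object a [fit_kinetic()] result.
#' @param nsim number of replicate TACs.
#' @param seed RNG seed.
#' @param noise_scale noise scale passed to [noise_sigma()].
#' @param ... unused.
#' @return List of [tac()] objects.
#' @export
simulate.kinetic_fit <- function(object, nsim = 1, seed = 1,
                                 noise_scale = default_config()$noise_scale,
                                 ...) {
  mu <- predict(object)
  schedule <- object$tac$schedule
  sig <- noise_sigma(mu, schedule, noise_scale)
  eps <- .with_seed(seed,
                    matrix(rnorm(nsim * length(mu)), nsim) *
                      rep(sig, each = nsim))
  lapply(seq_len(nsim), function(i)
    tac(sprintf("sim%03d", i), schedule, mu + eps[i, ],
        unit = object$tac$unit))
}

#' Plot a kinetic fit
#'
#' Observed TAC, fitted model curve and (optionally) the scaled blood input,
#' on base graphics.
#'
#' @param x a [fit_kinetic()] result.
#' @param log_time plot time on a log axis (shows the bolus).
#' @param ... passed to [plot()].
#' @export
plot.kinetic_fit <- function(x, log_time = FALSE, ...) {
  sch <- x$tac$schedule
  fitv <- predict(x)
  plot(sch$mid, x$tac$values, pch = 16, cex = 0.6,
       log = if (log_time) "x" else "",
       xlab = "time (min)", ylab = sprintf("activity (%s)", x$tac$unit),
       main = sprintf("%s fit, AICc %.1f", x$model, x$aicc), ...)
  graphics::lines(sch$mid, fitv, col = "red3", lwd = 2)
  graphics::legend("topright", c("observed", "fitted"), bty = "n",
                   pch = c(16, NA), lty = c(NA, 1), col = c("black", "red3"))
  invisible(x)
}
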
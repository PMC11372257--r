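#' Corrected Akaike information criterion
#'
#' Small-sample corrected AIC under the Gaussian least-squares likelihood,
#' `n*log(rss/n) + 2k + 2k(k+1)/(n-k-1)`.  The noise-variance parameter is
#' absorbed in the `n*log(rss/n)` term, so `k` counts the fitted kinetic
#' parameters (including the time delay); the convention is applied
#' uniformly, making differences between nested models consistent.
#'
#' @param rss residual sum of squares (> 0).
#' @param n number of fitted data points.
#' @param k number of fitted parameters; requires `n > k + 1`.
#' @export
aicc <- function(rss, n, k) {
  stopifnot(.is_number(rss), .is_number(n), .is_number(k))
  if (rss <= 0) stop("AICc requires rss > 0")
  if (n <= k + 1) stop("AICc correction undefined for n <= k + 1")
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# default physiologic parameter bounds for fitting
.fit_bounds <- function(model, delay_bound = 1) {
  nm <- .free_params(model)
  lower <- c(vb = 0, K1 = 0, k2 = 0, k3 = 0, k4 = 0, td = -delay_bound)
  upper <- c(vb = 1, K1 = 5, k2 = 5, k3 = 5, k4 = 5, td = delay_bound)
  list(lower = lower[nm], upper = upper[nm])
}

.free_params <- function(model) {
  switch(model,
         "1T4P" = c("vb", "K1", "k2", "td"),
         "2T5P" = c("vb", "K1", "k2", "k3", "td"),
         "2T6P" = c("vb", "K1", "k2", "k3", "k4", "td"))
}

.vec_to_params <- function(model, p, td_fixed = NULL) {
  full <- c(vb = 0, K1 = 0, k2 = 0, k3 = 0, k4 = 0, td = 0)
  full[names(p)] <- p
  if (!is.null(td_fixed)) full["td"] <- td_fixed
  kinetic_params(model, vb = full["vb"], K1 = full["K1"], k2 = full["k2"],
                 k3 = full["k3"], k4 = full["k4"], td = full["td"])
}

#' Fit a compartment model to a time-activity curve
#'
#' Bound-constrained weighted nonlinear least squares (Levenberg-Marquardt
#' via \pkg{minpack.lm}) minimizing `sum_i w_i (C_obs_i - C_model_i)^2`, with
#' the time delay `t_d` fitted jointly as a continuous parameter unless
#' fixed.  The objective is multimodal for the two-tissue models, so the
#' optimizer is restarted from `n_starts` quasi-random points (Latin
#' hypercube within the bounds, fixed seed, so fits are deterministic).
#'
#' @param tac_obs observed [tac()].
#' @param input [input_function()] sharing the schedule's time support.
#' @param model model kind: `"1T4P"`, `"2T5P"` or `"2T6P"`.
#' @param weights `"uniform"` (default) or `"framevar"`
#'   (`w_i = dur_i / max(C_obs_i, eps)`, the inverse of the framed count
#'   noise variance model), or a numeric vector.
#' @param fix_delay `NULL` to fit `t_d`, or a number to fix it.
#' @param start optional [kinetic_params()] (or named vector) used as the
#'   first start; defaults to a generic physiologic guess.
#' @param n_starts number of multistart points (including `start`).
#' @param seed RNG seed for the start ladder.
#' @param delay_bound bound on `|t_d|` in minutes.
#' @return Object of class `kinetic_fit`: estimated `params`, `rss`, `n`,
#'   `k`, `aicc`, `converged`, `n_restarts`, `fixed_delay`, `at_boundary`
#'   flags, and the data needed by the methods ([predict.kinetic_fit()],
#'   [residuals.kinetic_fit()], [simulate.kinetic_fit()], ...).
#' @export
fit_kinetic <- function(tac_obs, input, model = c("2T6P", "1T4P", "2T5P"),
                        weights = "uniform", fix_delay = NULL, start = NULL,
                        n_starts = 10, seed = 1, delay_bound = 1) {
  model <- match.arg(model)
  stopifnot(inherits(tac_obs, "tac"), inherits(input, "input_function"))
  schedule <- tac_obs$schedule
  obs <- tac_obs$values
  n <- length(obs)
  w <- .fit_weights(weights, obs, schedule)
  sw <- sqrt(w)

  nm <- .free_params(model)
  if (!is.null(fix_delay)) nm <- setdiff(nm, "td")
  bounds <- .fit_bounds(model, delay_bound)
  lower <- bounds$lower[nm]
  upper <- bounds$upper[nm]

  resid_fn <- function(p) {
    names(p) <- nm
    pr <- .params_raw(model, p)
    if (!is.null(fix_delay)) pr$td <- fix_delay
    sw * (obs - .forward_values(pr, input, schedule))
  }

  td0 <- if (is.null(fix_delay) && is.null(start))
    .initial_delay(obs, input, schedule, delay_bound) else 0
  starts <- .fit_starts(model, nm, start, n_starts, seed, lower, upper,
                        td0 = td0)
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, info = fit$info)
  }
  if (is.null(best))
    stop("kinetic fit failed from every start (model ", model, ")")

  p <- setNames(best$par, nm)
  k <- length(nm) + 0L  # td already excluded when fixed
  at_bound <- abs(p - lower) < 1e-6 * pmax(1, abs(upper - lower)) |
    abs(p - upper) < 1e-6 * pmax(1, abs(upper - lower))
  params <- .vec_to_params(model, p, td_fixed = fix_delay)
  structure(list(
    params = params, rss = best$rss, n = n, k = k,
    aicc = aicc(max(best$rss, 1e-300), n, k),
    converged = best$info %in% 1:4, n_restarts = n_ok,
    fixed_delay = !is.null(fix_delay), weights = w,
    at_boundary = at_bound, tac = tac_obs, input = input,
    model = model), class = "kinetic_fit")
}

.fit_weights <- function(weights, obs, schedule) {
  if (is.numeric(weights)) {
    stopifnot(length(weights) == length(obs), all(weights >= 0))
    return(weights)
  }
  switch(match.arg(weights, c("uniform", "framevar")),
         uniform = rep(1, length(obs)),
         framevar = schedule$dur / pmax(obs, 0.01 * max(abs(obs))))
}

.fit_starts <- function(model, nm, start, n_starts, seed, lower, upper,
                        td0 = 0) {
  guess <- c(vb = 0.05, K1 = 0.3, k2 = 0.2, k3 = 0.05, k4 = 0.02, td = td0)
  if (!is.null(start)) {
    sv <- if (inherits(start, "kinetic_params"))
      unlist(start[c("vb", "K1", "k2", "k3", "k4", "td")]) else start
    guess[names(sv)] <- sv
  }
  first <- pmin(pmax(guess[nm], lower), upper)
  starts <- matrix(first, nrow = 1, dimnames = list(NULL, nm))
  if (n_starts <= 1) return(starts)
  # structured starts spanning exchange-rate magnitudes: the 2T objective's
  # local minima mostly differ in the (k3, k4) trapping regime
  if (all(c("k3", "k4") %in% nm)) {
    for (kk in list(c(0.02, 0.01), c(0.1, 0.03), c(0.3, 0.1))) {
      alt <- first
      alt["k3"] <- kk[1]
      alt["k4"] <- kk[2]
      starts <- rbind(starts, alt)
    }
  } else if ("k3" %in% nm) {
    for (kk in c(0.02, 0.2)) {
      alt <- first
      alt["k3"] <- kk
      starts <- rbind(starts, alt)
    }
  }
  starts <- starts[seq_len(min(nrow(starts), n_starts)), , drop = FALSE]
  n_rand <- n_starts - nrow(starts)
  if (n_rand > 0) {
    # quasi-random ladder; rate-like axes squared so small rates (the
    # physiologically common regime) are well covered; vb stays linear and
    # td is drawn near its first-start value (delay basins are narrow)
    lhs_u <- .with_seed(seed, lhs::randomLHS(n_rand, length(nm)))
    colnames(lhs_u) <- nm
    sq <- intersect(c("K1", "k2", "k3", "k4"), nm)
    lhs_u[, sq] <- lhs_u[, sq]^2
    span <- upper - lower
    ladder <- sweep(sweep(lhs_u, 2, span, "*"), 2, lower, "+")
    if ("td" %in% nm)
      ladder[, "td"] <- pmin(pmax(first["td"] + 0.2 * (lhs_u[, "td"] - 0.5),
                                  lower["td"]), upper["td"])
    starts <- rbind(starts, ladder)
  }
  rownames(starts) <- NULL
  starts
}

#' Select the best model by AICc
#'
#' Returns the fit with strictly lowest AICc; ties within `1e-9` go to the
#' model with fewer parameters.  Per-model AICc differences are attached as
#' attribute `"delta_aicc"`.
#'
#' @param fits list of [fit_kinetic()] results of distinct model kinds on
#'   one TAC.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, logical(1),
                                          "kinetic_fit")))
  kinds <- vapply(fits, function(f) f$model, character(1))
  if (anyDuplicated(kinds)) stop("fits must be of distinct model kinds")
  a <- vapply(fits, function(f) f$aicc, numeric(1))
  kp <- vapply(fits, function(f) f$k, numeric(1))
  o <- order(a, kp)  # ties (within float equality) -> fewer parameters
  near <- which(a - a[o[1]] < 1e-9)
  pick <- near[which.min(kp[near])]
  chosen <- fits[[pick]]
  attr(chosen, "delta_aicc") <- setNames(a - a[pick], kinds)
  chosen
}

#' Fit all candidate models and select by AICc
#'
#' Models are fitted in order of increasing complexity and each model is
#' warm-started from the previous (nested) solution in addition to the
#' multistart ladder, which guarantees the RSS nesting
#' `RSS(2T6P) <= RSS(2T5P) <= RSS(1T4P)`.
#'
#' @inheritParams fit_kinetic
#' @param models model kinds to fit (any subset of 1T4P/2T5P/2T6P).
#' @param ... passed to [fit_kinetic()] (`weights`, `n_starts`, `seed`, ...).
#' @return The selected [fit_kinetic()] (attribute `"delta_aicc"` records
#'   the comparison); all fits are attached as attribute `"fits"`.
#' @export
fit_all_models <- function(tac_obs, input, models = .MODEL_KINDS, ...) {
  ord <- intersect(.MODEL_KINDS, models)
  if (length(ord) < 1) stop("no valid model kinds")
  fits <- list()
  prev <- NULL
  for (m in ord) {
    fits[[m]] <- fit_kinetic(tac_obs, input, m, start = prev, ...)
    prev <- fits[[m]]$params
  }
  if (length(fits) == 1) return(fits[[1]])
  chosen <- select_model(fits)
  attr(chosen, "fits") <- fits
  chosen
}

# Data-driven initial delay: align the observed early activity peak (the
# vascular bolus passing through the region) with the input peak.
.initial_delay <- function(obs, input, schedule, bound) {
  early <- schedule$mid < 5
  if (sum(early) < 2) return(0)
  t_obs <- schedule$mid[early][which.max(obs[early])]
  grid <- seq(0, min(5, max(schedule$end)), by = 0.01)
  vals <- tryCatch(predict(input, grid), error = function(e) NULL)
  if (is.null(vals)) return(0)
  t_inp <- grid[which.max(vals)]
  min(max(t_obs - t_inp, -bound), bound)
}
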
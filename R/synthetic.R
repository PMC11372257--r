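#' Framed PET noise standard deviation
#'
#' The standard count-statistics model for decay-corrected framed PET:
#' `sigma_i = s * sqrt(Cbar_i * exp(lambda * t_i) / dur_i)` with
#' `lambda = log(2) / 109.77` per minute (the physical decay constant of
#' 18F), `Cbar_i` the frame mean activity, `t_i` the frame midpoint and
#' `dur_i` the frame duration.  Short early frames and late (more decayed)
#' frames are noisier.
#'
#' @param values per-frame mean activity.
#' @param schedule [frame_schedule()].
#' @param noise_scale overall scale `s` (unit-bearing; the package default
#'   is calibrated so the tumor-like reference region has a VT SD of about
#'   5\% over a 90-min scan).
#' @export
noise_sigma <- function(values, schedule, noise_scale) {
  stopifnot(length(values) == schedule$n, noise_scale >= 0)
  lam <- log(2) / 109.77
  # scatter/randoms floor: even frames with no tracer carry background
  # variance; 1% of the curve maximum keeps pre-arrival frames finite
  floor_val <- max(0.01 * max(values, 0), 1e-9)
  noise_scale * sqrt(pmax(values, floor_val) * exp(lam * schedule$mid) /
                       schedule$dur)
}

#' Input-function shape: gamma-variate bolus plus biexponential washout
#'
#' Continuous arterial model `u(t) = 0` before the arrival time `t0`, then
#' `A * (tau/tp)^alpha * exp(alpha (1 - tau/tp))` (peak-normalized
#' gamma-variate bolus) plus
#' `(1 - exp(-tau/ramp)) * (B1 exp(-mu1 tau) + B2 exp(-mu2 tau))`
#' with `tau = t - t0`.  Defaults give an aorta-like curve: a single sharp
#' peak within the first minute, an intermediate clearance phase that has
#' largely washed out by the Logan linearity onset, and a slow terminal
#' phase whose clearance is much slower than the tissue eigenvalues, so
#' late-time tissue-to-blood ratios approach the blood-volume-corrected VT
#' (the quasi-equilibrium regime the analysis assumes).
#'
#' @param t0 arrival time (min).
#' @param A bolus peak amplitude (SUV).
#' @param alpha gamma shape.
#' @param tp bolus time-to-peak after arrival (min).
#' @param B1,mu1 fast washout amplitude (SUV) and rate (1/min).
#' @param B2,mu2 slow washout amplitude (SUV) and rate (1/min).
#' @param ramp washout onset time constant (min).
#' @return A function of time (min) returning concentration, with the
#'   parameter list attached as attribute `"shape"`.
#' @export
input_shape <- function(t0 = 0.25, A = 55, alpha = 2, tp = 0.15,
                        B1 = 1.8, mu1 = 0.08, B2 = 0.75, mu2 = 0.001,
                        ramp = 0.4) {
  pars <- list(t0 = t0, A = A, alpha = alpha, tp = tp, B1 = B1, mu1 = mu1,
               B2 = B2, mu2 = mu2, ramp = ramp)
  if (any(unlist(pars) < 0)) stop("input shape parameters must be nonnegative")
  f <- function(t) {
    tau <- t - t0
    out <- numeric(length(t))
    pos <- tau > 0
    tp_ <- tau[pos]
    out[pos] <- A * (tp_ / tp)^alpha * exp(alpha * (1 - tp_ / tp)) +
      (1 - exp(-tp_ / ramp)) * (B1 * exp(-mu1 * tp_) + B2 * exp(-mu2 * tp_))
    out
  }
  attr(f, "shape") <- pars
  f
}

#' Right-ventricle variant of the default input shape
#'
#' Slightly earlier arrival and higher, narrower peak than the aorta (the RV
#' blood pool sees the bolus before systemic dispersion).
#' @export
rv_input_shape <- function() {
  input_shape(t0 = 0.15, A = 70, tp = 0.12, B1 = 1.9, mu1 = 0.085,
              B2 = 0.75, mu2 = 0.001)
}

#' Generate a noiseless blood input sampled to frame averages
#'
#' @param shape a continuous shape function from [input_shape()].
#' @param schedule [frame_schedule()].
#' @return An [input_function()] whose per-frame values are the exact frame
#'   averages of the continuous shape.
#' @export
generate_input <- function(shape = input_shape(), schedule = default_schedule()) {
  stopifnot(is.function(shape), inherits(schedule, "frame_schedule"))
  vals <- vapply(seq_len(schedule$n), function(i)
    integrate(shape, schedule$start[i], schedule$end[i],
              rel.tol = 1e-10, subdivisions = 500L)$value / schedule$dur[i],
    numeric(1))
  if (any(vals < 0)) stop("input shape produced negative activity")
  input_function(vals, schedule)
}

#' Ground-truth kinetic presets for synthetic regions
#'
#' Synthetic parameter sets spanning the regimes seen in total-body
#' T-cell-tracer studies: high-uptake reversible organs, low-uptake tissue,
#' high blood-volume myocardium (the right ventricle is one-tissue), lungs
#' driven by the right-ventricle input.  All values are synthetic, chosen to
#' exercise both 1T- and 2T-favored code paths; they are not measurements.
#'
#' @return Named list; each element has `params` ([kinetic_params()]),
#'   `input` (`"aorta"` or `"right_ventricle"`) and `aggregation`.
#' @export
region_presets <- function() {
  p <- function(model, vb, K1, k2, k3 = 0, k4 = 0, td = 0.1,
                input = "aorta", aggregation = "mean", noise_mult = 1)
    list(params = kinetic_params(model, vb, K1, k2, k3, k4, td),
         input = input, aggregation = aggregation, noise_mult = noise_mult)
  # noise_mult reflects VOI size: large segmented organs average many voxels
  # and see proportionally less noise than a small spheric VOI (= 1)
  list(
    spleen          = p("2T6P", 0.15, 0.80, 0.50, 0.120, 0.040,
                        noise_mult = 0.7),
    liver           = p("2T6P", 0.20, 1.00, 0.60, 0.150, 0.050,
                        noise_mult = 0.5),
    kidneys         = p("2T6P", 0.15, 0.90, 0.50, 0.200, 0.050,
                        noise_mult = 0.6),
    lungs           = p("2T6P", 0.12, 0.15, 0.40, 0.050, 0.030,
                        input = "right_ventricle", noise_mult = 0.5),
    myocardium_lv   = p("2T6P", 0.35, 0.70, 0.60, 0.080, 0.040,
                        noise_mult = 0.7),
    myocardium_rv   = p("1T4P", 0.50, 0.50, 0.45, noise_mult = 0.8),
    thyroid         = p("2T6P", 0.10, 0.50, 0.45, 0.100, 0.050,
                        noise_mult = 0.9),
    bone_marrow     = p("2T6P", 0.06, 0.30, 0.25, 0.100, 0.035,
                        noise_mult = 0.8),
    muscle          = p("2T6P", 0.03, 0.08, 0.18, 0.040, 0.035,
                        noise_mult = 0.35),
    skin_underarm   = p("2T6P", 0.04, 0.12, 0.20, 0.060, 0.030,
                        noise_mult = 0.9),
    cerebrum        = p("2T6P", 0.04, 0.03, 0.25, 0.020, 0.035,
                        noise_mult = 0.15),
    choroid_plexus  = p("2T6P", 0.25, 0.60, 0.50, 0.100, 0.030,
                        noise_mult = 0.8),
    salivary_glands = p("2T6P", 0.08, 0.40, 0.35, 0.090, 0.040,
                        noise_mult = 0.8),
    pancreas        = p("2T6P", 0.10, 0.60, 0.40, 0.150, 0.040,
                        noise_mult = 0.8),
    pituitary       = p("2T6P", 0.20, 0.50, 0.40, 0.120, 0.050,
                        noise_mult = 0.9)
  )
}

#' Tumor-like reference parameters
#'
#' The reversible two-tissue parameter set used as the reference region for
#' identifiability and calibration: `vb = 0.05`, `K1 = 0.4`, `k2 = 0.3`,
#' `k3 = 0.06`, `k4 = 0.03` (VT = 4), delay 0.1 min.
#' @export
tumor_preset <- function() {
  kinetic_params("2T6P", vb = 0.05, K1 = 0.4, k2 = 0.3, k3 = 0.06,
                 k4 = 0.03, td = 0.1)
}

# 7 tumor subregions spanning low- to high-uptake kinetics
.tumor_subregions <- function() {
  base <- tumor_preset()
  k1_mul <- c(0.5, 0.7, 0.85, 1.0, 1.15, 1.3, 1.5)
  k3_mul <- c(0.6, 1.4, 0.8, 1.0, 1.2, 0.7, 1.3)
  out <- list()
  for (i in 1:7) {
    pr <- base
    pr$K1 <- base$K1 * k1_mul[i]
    pr$k3 <- base$k3 * k3_mul[i]
    out[[sprintf("tumor_sub%d", i)]] <-
      list(params = pr, input = "right_ventricle", aggregation = "mean")
  }
  out
}

# mediastinal (2 enlarged + 2 nonenlarged) and axillary/pelvic lymph nodes,
# SUV_peak aggregation because of their small size
.node_presets <- function(n_mediastinal = 4, n_axillary = 3, n_pelvic = 3) {
  node <- function(vb, K1, k2, k3, k4)
    list(params = kinetic_params("2T6P", vb, K1, k2, k3, k4, td = 0.12),
         input = "aorta", aggregation = "peak")
  out <- list()
  n_enl <- min(2L, n_mediastinal)
  for (i in seq_len(n_mediastinal)) {
    enlarged <- i <= n_enl
    out[[sprintf("ln_mediastinal_%d%s", i, if (enlarged) "_enl" else "")]] <-
      if (enlarged) node(0.08, 0.55, 0.40, 0.16, 0.030)
      else node(0.06, 0.35, 0.35, 0.09, 0.035)
  }
  for (i in seq_len(n_axillary))
    out[[sprintf("ln_axillary_%d", i)]] <- node(0.05, 0.40, 0.38, 0.11, 0.033)
  for (i in seq_len(n_pelvic))
    out[[sprintf("ln_pelvic_%d", i)]] <- node(0.05, 0.45, 0.40, 0.12, 0.032)
  out
}

#' Generate one noisy regional TAC from its ground-truth kinetics
#'
#' Forward model plus one framed-noise draw; reproducible given `seed`.
#'
#' @param spec list with `params` ([kinetic_params()]) and optionally
#'   `aggregation`, as produced by [region_presets()].
#' @param input [input_function()].
#' @param schedule [frame_schedule()].
#' @param noise_scale see [noise_sigma()]; 0 gives the exact forward model.
#' @param seed RNG seed.
#' @param region region label.
#' @export
generate_region_tac <- function(spec, input, schedule, noise_scale, seed = 1,
                                region = "region") {
  mu <- model_tac(spec$params, input, schedule)$values
  sig <- noise_sigma(mu, schedule, noise_scale)
  eps <- .with_seed(seed, rnorm(schedule$n) * sig)
  tac(region, schedule, mu + eps, unit = input$unit,
      aggregation = if (is.null(spec$aggregation)) "mean" else spec$aggregation)
}

#' Cohort specification for the synthetic study
#'
#' Mirrors the study structure this package emulates: healthy subjects with
#' the full organ set, plus one patient scanned pre and post therapy whose
#' tumor subregions receive a multiplicative treatment effect on `k3`
#' (increase) and `k4` (decrease), so true VT increases in every subregion.
#' Enlarged and nonenlarged mediastinal nodes receive opposite-signed VT
#' shifts (decrease vs increase); axillary/pelvic nodes receive a `k3`
#' increase.
#'
#' @param n_healthy number of healthy subjects.
#' @param patient include the pre/post-therapy patient.
#' @param n_tumor tumor subregion count.
#' @param n_mediastinal mediastinal node count (first 2 enlarged).
#' @param n_axillary,n_pelvic axillary/pelvic node counts.
#' @param delta_k3 post-therapy tumor `k3` multiplier is `1 + delta_k3`.
#' @param delta_k4 post-therapy tumor `k4` multiplier is `1 - delta_k4`
#'   (`0 < delta_k4 < 1`).
#' @param delta_ln mediastinal-node effect size.
#' @param jitter_cv between-subject lognormal coefficient of variation of
#'   the kinetic parameters.
#' @param noise_scale measurement noise (see [noise_sigma()]).
#' @param organs organ subset (names of [region_presets()]).
#' @param seed RNG seed; cohort generation is a pure function of
#'   (spec, schedule, seed).
#' @export
cohort_spec <- function(n_healthy = 4, patient = TRUE, n_tumor = 7,
                        n_mediastinal = 4, n_axillary = 3, n_pelvic = 3,
                        delta_k3 = 0.5, delta_k4 = 0.3, delta_ln = 0.4,
                        jitter_cv = 0.15,
                        noise_scale = default_config()$noise_scale,
                        organs = names(region_presets()), seed = 42) {
  stopifnot(n_healthy >= 1 || patient, n_tumor >= 1, n_mediastinal >= 1,
            delta_k3 >= 0, delta_k4 >= 0, delta_k4 < 1, jitter_cv >= 0,
            noise_scale >= 0)
  structure(list(n_healthy = n_healthy, patient = patient, n_tumor = n_tumor,
                 n_mediastinal = n_mediastinal, n_axillary = n_axillary,
                 n_pelvic = n_pelvic, delta_k3 = delta_k3,
                 delta_k4 = delta_k4, delta_ln = delta_ln,
                 jitter_cv = jitter_cv, noise_scale = noise_scale,
                 organs = organs, seed = seed), class = "cohort_spec")
}

# lognormal jitter preserving the mean on the log scale
.jitter_params <- function(params, cv) {
  if (cv <= 0) return(params)
  sdlog <- sqrt(log(1 + cv^2))
  for (nm in c("K1", "k2", "k3", "k4"))
    if (params[[nm]] > 0)
      params[[nm]] <- params[[nm]] * exp(rnorm(1, -sdlog^2 / 2, sdlog))
  params$vb <- min(max(params$vb * exp(rnorm(1, -sdlog^2 / 2, sdlog)),
                       0.005), 0.9)
  params$td <- runif(1, 0.02, 0.3)
  params
}

#' Generate a synthetic cohort of dynamic scans with known ground truth
#'
#' @param cohort a [cohort_spec()].
#' @param schedule [frame_schedule()].
#' @return List of class `synthetic_cohort` with `scans` (list of
#'   [scan_record()]: healthy subjects, then patient `pre` and `post`) and
#'   `truth` (data frame of every region's true kinetic parameters and VT).
#' @export
generate_cohort <- function(cohort, schedule = default_schedule()) {
  stopifnot(inherits(cohort, "cohort_spec"))
  presets <- region_presets()[cohort$organs]
  aorta_if <- generate_input(input_shape(), schedule)
  rv_if <- generate_input(rv_input_shape(), schedule)
  truth <- list()
  scans <- list()
  seed0 <- cohort$seed

  build_scan <- function(subject, scan_id, specs, subj_seed) {
    tacs <- list()
    # measured blood curves share the region noise model
    for (b in .BLOOD_REGIONS) {
      blood_if <- if (b == "aorta") aorta_if else rv_if
      sig <- noise_sigma(blood_if$y, schedule, 0.5 * cohort$noise_scale)
      eps <- .with_seed(subj_seed * 1000L + match(b, .BLOOD_REGIONS),
                        rnorm(schedule$n) * sig)
      tacs[[b]] <- tac(b, schedule, blood_if$y + eps)
    }
    for (i in seq_along(specs)) {
      nm <- names(specs)[i]
      sp <- specs[[i]]
      input <- if (sp$input == "right_ventricle") rv_if else aorta_if
      mult <- if (is.null(sp$noise_mult)) 1 else sp$noise_mult
      tacs[[nm]] <- generate_region_tac(
        sp, input, schedule, cohort$noise_scale * mult,
        seed = subj_seed * 1000L + 10L + i, region = nm)
      truth[[length(truth) + 1L]] <<- data.frame(
        subject = subject, scan = scan_id, region = nm,
        model = sp$params$model, vb = sp$params$vb, K1 = sp$params$K1,
        k2 = sp$params$k2, k3 = sp$params$k3, k4 = sp$params$k4,
        td = sp$params$td, input = sp$input,
        VT = tryCatch(compute_vt(sp$params), error = function(e) NA_real_),
        VT_vb = tryCatch(compute_vt_vb(sp$params),
                         error = function(e) NA_real_))
    }
    scan_record(subject, scan_id, tacs)
  }

  for (s in seq_len(cohort$n_healthy)) {
    specs <- .with_seed(seed0 + s, lapply(presets, function(pr) {
      pr$params <- .jitter_params(pr$params, cohort$jitter_cv)
      pr
    }))
    scans[[sprintf("healthy%d", s)]] <-
      build_scan(sprintf("healthy%d", s), "scan1", specs, seed0 + s)
  }

  if (cohort$patient) {
    tum <- .tumor_subregions()[seq_len(min(cohort$n_tumor, 7))]
    nodes <- .node_presets(cohort$n_mediastinal, cohort$n_axillary,
                           cohort$n_pelvic)
    pat_pre <- c(presets, tum, nodes)
    pat_post <- pat_pre
    for (nm in names(tum)) {
      pp <- pat_post[[nm]]$params
      pp$k3 <- pp$k3 * (1 + cohort$delta_k3)
      pp$k4 <- pp$k4 * (1 - cohort$delta_k4)
      pat_post[[nm]]$params <- pp
    }
    for (nm in grep("^ln_mediastinal", names(nodes), value = TRUE)) {
      pp <- pat_post[[nm]]$params
      if (grepl("_enl$", nm)) {          # enlarged: VT decreases
        pp$k3 <- pp$k3 * (1 - cohort$delta_ln)
        pp$k4 <- pp$k4 * (1 + cohort$delta_ln)
      } else {                           # nonenlarged: VT increases
        pp$k3 <- pp$k3 * (1 + cohort$delta_ln)
        pp$k4 <- pp$k4 * (1 - min(cohort$delta_ln, 0.9))
      }
      pat_post[[nm]]$params <- pp
    }
    for (nm in grep("^ln_(axillary|pelvic)", names(nodes), value = TRUE)) {
      pp <- pat_post[[nm]]$params
      pp$k3 <- pp$k3 * (1 + 0.3)
      pat_post[[nm]]$params <- pp
    }
    scans[["patient_pre"]] <- build_scan("patient", "pre", pat_pre,
                                         seed0 + 101L)
    scans[["patient_post"]] <- build_scan("patient", "post", pat_post,
                                          seed0 + 102L)
  }

  structure(list(scans = scans, truth = do.call(rbind, truth),
                 spec = cohort),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d scan(s), %d region truths\n",
              length(x$scans), nrow(x$truth)))
  invisible(x)
}
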
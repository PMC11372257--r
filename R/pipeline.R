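#' @name pipeline
#' @title Pipeline stages: simulate, fit, identifiability, statistics
#'
#' @description
#' File-level drivers wrapping the package's analysis functions, mirroring
#' the stages of a dynamic-PET kinetic study.  Each stage writes tidy CSV
#' tables plus a JSON run manifest (config, seed, input file digests,
#' outputs) so any run is reproducible from its manifest.  The thin
#' command-line wrapper in `exec/tbkin` exposes these as subcommands.
NULL

.write_manifest <- function(outdir, stage, cfg, inputs, outputs) {
  digest <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(stage = stage, config = cfg, input_md5 = digest,
                   outputs = outputs,
                   package_version = as.character(utils::packageVersion("tbkin")))
  path <- file.path(outdir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.log_msg <- function(...) message(sprintf(...))

#' @rdname pipeline
#' @param config configuration list from [load_config()].
#' @param outdir output directory (created if missing).
#' @param cohort optional [cohort_spec()]; defaults to the study-structure
#'   defaults with the config's seed and noise scale.
#' @param schedule [frame_schedule()].
#' @return `run_simulate()`: invisibly, the list of written TAC table paths
#'   (plus `truth.csv`).
#' @export
run_simulate <- function(config = load_config(), outdir = ".",
                         cohort = NULL, schedule = default_schedule()) {
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
    .log_msg("created output directory %s", outdir)
  }
  if (is.null(cohort))
    cohort <- cohort_spec(noise_scale = config$noise_scale,
                          seed = config$seed)
  coh <- generate_cohort(cohort, schedule)
  paths <- character()
  for (nm in names(coh$scans)) {
    p <- file.path(outdir, sprintf("tac_%s.csv", nm))
    write_tac_table(coh$scans[[nm]], p)
    paths <- c(paths, p)
  }
  truth_path <- file.path(outdir, "truth.csv")
  write.csv(coh$truth, truth_path, row.names = FALSE)
  paths <- c(paths, truth_path)
  .write_manifest(outdir, "simulate", config, character(),
                  as.list(basename(paths)))
  .log_msg("simulate: wrote %d scan table(s) + truth.csv to %s",
           length(paths) - 1L, outdir)
  invisible(paths)
}

# fit one scan: per-region three-model fit, AICc selection, macroparameters
.fit_scan <- function(scan, config) {
  sch <- scan$schedule
  make_input <- function(region) {
    inp <- input_function(scan$tacs[[region]])
    inp <- fit_biexp_tail(inp, config$biexp_window)
    extrapolate_input(inp, config$horizon)
  }
  inputs <- list(aorta = make_input("aorta"),
                 right_ventricle = make_input("right_ventricle"))
  regions <- setdiff(names(scan$tacs), .BLOOD_REGIONS)
  fit_rows <- list()
  macro_rows <- list()
  for (rg in regions) {
    # lungs and lung-tumor subregions are supplied by the pulmonary
    # circulation: use the right-ventricle blood pool
    input_name <- if (grepl("^(lungs|tumor_)", rg)) "right_ventricle"
                  else "aorta"
    input <- inputs[[input_name]]
    tac_r <- scan$tacs[[rg]]
    sel <- tryCatch(
      fit_all_models(tac_r, input, seed = config$seed,
                     n_starts = config$n_starts,
                     delay_bound = config$delay_bound),
      error = function(e) NULL)
    if (is.null(sel)) {
      .log_msg("region %s: model fitting failed, skipped", rg)
      next
    }
    fits <- attr(sel, "fits")
    for (m in names(fits)) {
      f <- fits[[m]]
      p <- f$params
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        subject = scan$subject, scan = scan$scan, region = rg, model = m,
        vb = p$vb, K1 = p$K1, k2 = p$k2, k3 = p$k3, k4 = p$k4, td = p$td,
        rss = f$rss, aicc = f$aicc, converged = f$converged,
        selected = identical(m, sel$model), input = input_name)
    }
    psel <- sel$params
    lg <- tryCatch(logan(tac_r, input, config$t_star),
                   error = function(e) list(K_Logan = NA_real_,
                                            intercept = NA_real_))
    macro_rows[[length(macro_rows) + 1L]] <- data.frame(
      subject = scan$subject, scan = scan$scan, region = rg,
      model = sel$model,
      vb = psel$vb, K1 = psel$K1, k2 = psel$k2, k3 = psel$k3, k4 = psel$k4,
      td = psel$td,
      Ki_2T6P = if (!is.null(fits[["2T6P"]]))
        tryCatch(compute_ki(fits[["2T6P"]]$params),
                 error = function(e) NA_real_) else NA_real_,
      Ki_2T5P = if (!is.null(fits[["2T5P"]]))
        tryCatch(compute_ki(fits[["2T5P"]]$params),
                 error = function(e) NA_real_) else NA_real_,
      VT = tryCatch(compute_vt(psel), error = function(e) NA_real_),
      VT_vb = tryCatch(compute_vt_vb(psel), error = function(e) NA_real_),
      SUV = suv_window(tac_r, config$suvr_window),
      SUVR = suvr_window(tac_r, input, config$suvr_window),
      K_Logan = lg$K_Logan, intercept = lg$intercept,
      t_star = config$t_star)
  }
  list(fits = do.call(rbind, fit_rows), macro = do.call(rbind, macro_rows))
}

#' @rdname pipeline
#' @param scan_paths TAC table files from [run_simulate()] (or any files in
#'   the same format).
#' @return `run_fit()`: invisibly, paths of `fits.csv` and `macro.csv`.
#' @export
run_fit <- function(scan_paths, config = load_config(), outdir = ".") {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  all_fits <- list()
  all_macro <- list()
  for (p in scan_paths) {
    scan <- read_tac_table(p)
    .log_msg("fitting %s/%s (%d regions)", scan$subject, scan$scan,
             length(scan$tacs) - 2L)
    res <- .fit_scan(scan, config)
    all_fits[[p]] <- res$fits
    all_macro[[p]] <- res$macro
  }
  fits_path <- file.path(outdir, "fits.csv")
  macro_path <- file.path(outdir, "macro.csv")
  write.csv(do.call(rbind, all_fits), fits_path, row.names = FALSE)
  write.csv(do.call(rbind, all_macro), macro_path, row.names = FALSE)
  .write_manifest(outdir, "fit", config, scan_paths,
                  list("fits.csv", "macro.csv"))
  invisible(c(fits_path, macro_path))
}

#' @rdname pipeline
#' @param regions named list of region specs (as from [region_presets()]);
#'   defaults to the tumor preset plus the organ presets.
#' @param truncate_min optional scan truncation for a 60- vs 90-min
#'   comparison table.
#' @return `run_identifiability()`: invisibly, the written CSV paths.
#' @export
run_identifiability <- function(config = load_config(), outdir = ".",
                                regions = NULL,
                                schedule = default_schedule(),
                                truncate_min = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (is.null(regions)) {
    regions <- region_presets()
    regions$tumor <- list(params = tumor_preset(),
                          input = "right_ventricle")
  }
  aorta_if <- generate_input(input_shape(), schedule)
  rv_if <- generate_input(rv_input_shape(), schedule)
  rows <- list()
  for (nm in names(regions)) {
    sp <- regions[[nm]]
    input <- if (identical(sp$input, "right_ventricle")) rv_if else aorta_if
    mult <- if (is.null(sp$noise_mult)) 1 else sp$noise_mult
    rep_fit <- monte_carlo_identifiability(
      sp$params, input, schedule, config$noise_scale * mult,
      n_reps = config$n_reps, seed = config$seed)
    tbl <- rep_fit$table
    tbl$region <- nm
    tbl$variant <- "fitted_delay"
    rows[[length(rows) + 1L]] <- tbl
    if (!is.null(truncate_min)) {
      cmp <- monte_carlo_identifiability(
        sp$params, input, schedule, config$noise_scale * mult,
        n_reps = config$n_reps, seed = config$seed,
        truncate_min = truncate_min)
      tbl <- cmp$table
      tbl$region <- nm
      tbl$variant <- sprintf("truncated_%g", truncate_min)
      rows[[length(rows) + 1L]] <- tbl
    }
  }
  out <- do.call(rbind, rows)
  path <- file.path(outdir, "identifiability.csv")
  write.csv(out, path, row.names = FALSE)
  .write_manifest(outdir, "identifiability", config, character(),
                  list("identifiability.csv"))
  invisible(path)
}

#' @rdname pipeline
#' @param macro_path path to a `macro.csv` from [run_fit()].
#' @param pre_scan,post_scan scan labels of the paired comparison.
#' @return `run_stats()`: invisibly, paths of `surrogacy.csv` and
#'   `paired_tests.csv`.
#' @export
run_stats <- function(macro_path, config = load_config(), outdir = ".",
                      pre_scan = "pre", post_scan = "post") {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  macro <- read.csv(macro_path)
  sur_rows <- list()
  healthy <- macro[!macro$scan %in% c(pre_scan, post_scan), ]
  if (nrow(healthy) >= 3) {
    res <- surrogacy_analysis(healthy)
    sur_rows <- lapply(res, function(r)
      data.frame(pair = r$label, rho = r$rho, p = r$p, n = r$n,
                 method = r$method))
  }
  paired_rows <- list()
  pre <- macro[macro$scan == pre_scan, ]
  post <- macro[macro$scan == post_scan, ]
  tumor_regions <- grep("^tumor_", intersect(pre$region, post$region),
                        value = TRUE)
  if (length(tumor_regions) >= 2 && nrow(pre) && nrow(post)) {
    for (what in c("SUVR", "K_Logan", "VT", "k3", "k4")) {
      tst <- tryCatch(paired_region_test(pre, post, what, tumor_regions),
                      error = function(e) NULL)
      if (!is.null(tst))
        paired_rows[[what]] <- data.frame(
          quantity = what, n = tst$n, statistic = tst$statistic, p = tst$p)
    }
  }
  sur_path <- file.path(outdir, "surrogacy.csv")
  paired_path <- file.path(outdir, "paired_tests.csv")
  write.csv(do.call(rbind, sur_rows), sur_path, row.names = FALSE)
  write.csv(do.call(rbind, paired_rows), paired_path, row.names = FALSE)
  .write_manifest(outdir, "stats", config, macro_path,
                  list("surrogacy.csv", "paired_tests.csv"))
  invisible(c(sur_path, paired_path))
}
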
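# Shared fixtures, built once per test run.

sch90 <- default_schedule()
aif90 <- generate_input(input_shape(), sch90)
rvf90 <- generate_input(rv_input_shape(), sch90)
aif90_ext <- extrapolate_input(fit_biexp_tail(aif90), 600)
rvf90_ext <- extrapolate_input(fit_biexp_tail(rvf90), 600)

# 90-min schedule extended with 5-min frames out to 600 min (equilibrium)
sch600 <- frame_schedule(c(sch90$start, seq(90, 595, 5)),
                         c(sch90$end, seq(95, 600, 5)), unit = "min")

# small contiguous toy schedule: 3 x 60 s
sch_toy <- frame_schedule(c(0, 60, 120), c(60, 120, 180))

make_toy_scan <- function(values_by_region = NULL) {
  if (is.null(values_by_region))
    values_by_region <- list(aorta = c(5, 3, 2), right_ventricle = c(6, 3, 2),
                             liver = c(1, 2, 3), spleen = c(2, 2, 2))
  tacs <- lapply(names(values_by_region), function(r)
    tac(r, sch_toy, values_by_region[[r]]))
  names(tacs) <- names(values_by_region)
  scan_record("s1", "scan1", tacs)
}

# region presets including the tumor-like reference, as used throughout
all_presets <- local({
  p <- region_presets()
  p$tumor <- list(params = tumor_preset(), input = "right_ventricle",
                  aggregation = "mean", noise_mult = 1)
  p
})

preset_input <- function(sp, extended = FALSE) {
  if (identical(sp$input, "right_ventricle")) {
    if (extended) rvf90_ext else rvf90
  } else {
    if (extended) aif90_ext else aif90
  }
}
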
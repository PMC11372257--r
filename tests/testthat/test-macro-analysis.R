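test_that("Ki follows K1*k3/(k2+k3)", {
  expect_equal(compute_ki(kinetic_params("2T6P", 0.05, 0.6, 0.3, 0.1, 0.02)),
               0.15)
  expect_equal(compute_ki(kinetic_params("2T5P", 0.05, 0.6, 0.3, 0)), 0)
  expect_error(compute_ki(kinetic_params("1T4P", 0.05, 0.6, 0.3)),
               "one-tissue")
})

test_that("Ki equals the asymptotic Patlak slope for irreversible kinetics", {
  p <- kinetic_params("2T5P", 0, 0.4, 0.25, 0.08)
  ki <- compute_ki(p)
  mt <- model_tac(p, aif90_ext, sch90)
  cp <- predict(aif90_ext, sch90$mid)
  int_cp <- tbkin:::.cumtrapz0(sch90$mid, cp)
  sel <- sch90$mid >= 40
  # Patlak: C(t)/Cp(t) vs int Cp / Cp(t); late slope -> Ki
  slope <- coef(lm(I(mt$values[sel] / cp[sel]) ~
                     I(int_cp[sel] / cp[sel])))[2]
  expect_equal(unname(slope), ki, tolerance = 0.02)
})

test_that("VT follows the model formulas and rejects undefined cases", {
  expect_equal(compute_vt(kinetic_params("2T6P", 0.05, 0.5, 0.25, 0.1,
                                         0.05)), 6)
  expect_equal(compute_vt(kinetic_params("1T4P", 0.05, 0.4, 0.2)), 2)
  expect_equal(compute_vt(kinetic_params("2T6P", 0.05, 0.4, 0.2, 0,
                                         0.05)), 2)  # k3 = 0 continuity
  expect_error(compute_vt(kinetic_params("2T5P", 0.05, 0.4, 0.2, 0.1)),
               "irreversible")
  expect_error(compute_vt(kinetic_params("1T4P", 0.05, 0.4, 0)), "k2 > 0")
})

test_that("VT(vb) is the exact mixture vb + (1-vb)*VT", {
  p <- kinetic_params("2T6P", 0.1, 0.5, 0.25, 0.1, 0.05)  # VT = 6
  expect_equal(compute_vt_vb(p), 0.1 + 0.9 * 6)
  expect_equal(compute_vt_vb(kinetic_params("2T6P", 0, 0.5, 0.25, 0.1,
                                            0.05)), 6)
  expect_equal(compute_vt_vb(kinetic_params("2T6P", 1, 0.5, 0.25, 0.1,
                                            0.05)), 1)  # blood vs itself
})

test_that("SUVR of the blood curve against itself is 1", {
  blood_tac <- tac("aorta", sch90, aif90$y)
  sc <- suppressWarnings(suvr_curve(blood_tac, aif90))
  expect_true(all(abs(sc$suvr - 1) < 1e-9))
  expect_equal(suvr_window(blood_tac, aif90, c(60, 90)), 1, tolerance = 1e-9)
})

test_that("windowed SUVR reduces to the single-frame ratio", {
  p <- tumor_preset()
  mt <- model_tac(p, rvf90, sch90)
  # window holding exactly one frame midpoint (87.5 min)
  one <- suvr_window(mt, rvf90, c(86, 89))
  sc <- suppressWarnings(suvr_curve(mt, rvf90))
  expect_equal(one, sc$suvr[sc$mid == 87.5], tolerance = 1e-12)
  expect_error(suvr_window(mt, rvf90, c(91, 95)), "no frame midpoints")
})

test_that("extrapolated SUVR approaches the blood-volume-corrected VT", {
  for (nm in c("tumor", "spleen", "thyroid")) {
    sp <- all_presets[[nm]]
    inp <- preset_input(sp, extended = TRUE)
    vtvb <- compute_vt_vb(sp$params)
    mt <- model_tac(sp$params, inp, sch600)
    sc <- suppressWarnings(suvr_curve(mt, inp))
    s600 <- sc$suvr[nrow(sc)]
    expect_equal(s600, vtvb, tolerance = 0.05, label = nm)
  }
})

test_that("SUVR converges: closer to VT(vb) at 10 h than at 90 min", {
  for (nm in names(all_presets)) {
    sp <- all_presets[[nm]]
    inp <- preset_input(sp, extended = TRUE)
    vtvb <- compute_vt_vb(sp$params)
    sc <- suppressWarnings(suvr_curve(model_tac(sp$params, inp, sch600),
                                      inp))
    s90 <- sc$suvr[which.min(abs(sc$mid - 87.5))]
    s600 <- sc$suvr[nrow(sc)]
    expect_lt(abs(s600 - vtvb), abs(s90 - vtvb), label = nm)
  }
})

test_that("Logan identity: a region identical to blood has slope 1", {
  blood_tac <- tac("b", sch90, predict(aif90, sch90$mid))
  lg <- logan(blood_tac, aif90, 30)
  expect_equal(lg$K_Logan, 1, tolerance = 1e-9)
  expect_equal(lg$intercept, 0, tolerance = 1e-9)
})

test_that("Logan slope estimates the distribution volume", {
  # one-tissue, no blood volume: slope ~ K1/k2
  p1 <- kinetic_params("1T4P", 0, 0.3, 0.1)
  lg1 <- logan(model_tac(p1, aif90_ext, sch90), aif90_ext, 30)
  expect_equal(lg1$K_Logan, 3, tolerance = 0.02 * 3)
  # reversible two-tissue with blood volume: slope ~ VT(vb)
  p2 <- kinetic_params("2T6P", 0.05, 0.4, 0.3, 0.06, 0.03)
  lg2 <- logan(model_tac(p2, rvf90_ext, sch90), rvf90_ext, 30)
  expect_equal(lg2$K_Logan, compute_vt_vb(p2),
               tolerance = 0.03 * compute_vt_vb(p2))
  expect_error(logan(model_tac(p2, rvf90_ext, sch90), rvf90_ext, 88),
               "at least 3")
})

test_that("Logan slope is invariant to joint rescaling of both curves", {
  p <- tumor_preset()
  mt <- model_tac(p, rvf90_ext, sch90)
  lg <- logan(mt, rvf90_ext, 30)
  mt2 <- tac("t", sch90, mt$values * 0.037)
  inp2 <- rvf90_ext
  inp2$y <- inp2$y * 0.037
  inp2$tail$A1 <- inp2$tail$A1 * 0.037
  inp2$tail$A2 <- inp2$tail$A2 * 0.037
  lg2 <- logan(mt2, inp2, 30)
  expect_equal(lg2$K_Logan, lg$K_Logan, tolerance = 1e-9)
})

test_that("Logan slope converges monotonely in t* on slow kinetics", {
  for (nm in c("tumor", "bone_marrow", "choroid_plexus")) {
    sp <- all_presets[[nm]]
    inp <- preset_input(sp, extended = TRUE)
    mt <- model_tac(sp$params, inp, sch90)
    s <- vapply(c(20, 30, 45), function(ts) logan(mt, inp, ts)$K_Logan,
                numeric(1))
    expect_true(all(diff(s) > 0), label = nm)
    expect_lt(s[3], compute_vt_vb(sp$params) * 1.01)
  }
})
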
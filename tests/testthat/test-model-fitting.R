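test_that("AICc matches its closed form and limits", {
  expect_equal(aicc(1, 20, 5), 20 * log(1 / 20) + 10 + 60 / 14,
               tolerance = 1e-12)
  expect_equal(aicc(1, 20, 5), -45.629, tolerance = 1e-3)
  # halving the RSS at fixed k lowers AICc by n*log(2)
  expect_equal(aicc(2, 30, 4) - aicc(1, 30, 4), 30 * log(2),
               tolerance = 1e-12)
  # large-n limit converges to the uncorrected AIC
  n <- 1e7
  expect_equal(aicc(n, n, 5) - (n * log(1) + 10), 0, tolerance = 1e-4)
  expect_error(aicc(1, 6, 5), "n <= k")
  expect_error(aicc(0, 20, 5), "rss > 0")
})

test_that("noiseless parameter recovery is better than 1% for every model", {
  cases <- list(
    list(model = "1T4P", p = kinetic_params("1T4P", 0.08, 0.5, 0.25,
                                            td = 0.15)),
    list(model = "2T5P", p = kinetic_params("2T5P", 0.06, 0.45, 0.3, 0.08,
                                            td = 0.05)),
    list(model = "2T6P", p = kinetic_params("2T6P", 0.05, 0.4, 0.3, 0.05,
                                            0.02, td = 0.1)))
  for (cs in cases) {
    truth <- unlist(cs$p[tbkin:::.free_params(cs$model)])
    obs <- model_tac(cs$p, aif90, sch90)
    fit <- fit_kinetic(obs, aif90, cs$model, seed = 1)
    est <- coef(fit)[names(truth)]
    expect_lt(max(abs(est - truth) / abs(truth)), 0.01, label = cs$model)
    expect_true(fit$converged)
  }
})

test_that("fitted k counts all estimated parameters including the delay", {
  obs <- model_tac(tumor_preset(), rvf90, sch90)
  f6 <- fit_kinetic(obs, rvf90, "2T6P", seed = 1, n_starts = 2)
  expect_equal(f6$k, 6L)
  f6f <- fit_kinetic(obs, rvf90, "2T6P", seed = 1, n_starts = 2,
                     fix_delay = 0.1)
  expect_equal(f6f$k, 5L)
  expect_true(f6f$fixed_delay)
  expect_false("td" %in% names(coef(f6f)))
})

test_that("nested models never fit worse (2T6P <= 2T5P <= 1T4P in RSS)", {
  p <- tumor_preset()
  mu <- model_tac(p, rvf90, sch90)$values
  set.seed(3)
  for (i in 1:3) {
    obs <- tac("t", sch90, mu + rnorm(sch90$n, 0, 0.05 * mean(mu)))
    sel <- fit_all_models(obs, rvf90, seed = i, n_starts = 4)
    fits <- attr(sel, "fits")
    expect_lte(fits[["2T6P"]]$rss, fits[["2T5P"]]$rss + 1e-10)
    expect_lte(fits[["2T5P"]]$rss, fits[["1T4P"]]$rss + 1e-10)
  }
})

test_that("the time delay is recovered jointly with the kinetics", {
  p <- tumor_preset()  # td = 0.1 min
  shifted <- shift_input(rvf90, 0.1)  # extra 6-s delay before generation
  obs <- model_tac(p, shifted, sch90)
  fit <- fit_kinetic(obs, rvf90, "2T6P", seed = 1)
  # total delay = 0.1 (truth) + 0.1 (shift); tolerance: half the finest frame
  # tolerance: half the finest (2-s) frame duration
  expect_equal(unname(coef(fit)["td"]), 0.2, tolerance = 1 / 60)
  expect_lt(max(abs(coef(fit)[c("vb", "K1", "k2", "k3", "k4")] -
                      c(p$vb, p$K1, p$k2, p$k3, p$k4)) /
                  c(p$vb, p$K1, p$k2, p$k3, p$k4)), 0.01)
})

test_that("model selection picks the lowest AICc, ties to fewer parameters", {
  fake <- function(model, aicc_val, k)
    structure(list(model = model, aicc = aicc_val, k = k),
              class = "kinetic_fit")
  sel <- select_model(list(fake("1T4P", -40, 4), fake("2T5P", -45, 5),
                           fake("2T6P", -42, 6)))
  expect_equal(sel$model, "2T5P")
  expect_equal(unname(attr(sel, "delta_aicc")["1T4P"]), 5)
  sel2 <- select_model(list(fake("2T6P", -45, 6), fake("1T4P", -45, 4)))
  expect_equal(sel2$model, "1T4P")
  expect_error(select_model(list(fake("1T4P", 1, 4))), "2")
  expect_error(select_model(list(fake("1T4P", 1, 4), fake("1T4P", 2, 4))),
               "distinct")
})

test_that("AICc selection identifies the generating model", {
  # 1T data at moderate noise: 1T4P selected in the majority of replicates
  p1 <- kinetic_params("1T4P", 0.1, 0.5, 0.3, td = 0.1)
  mu1 <- model_tac(p1, aif90, sch90)$values
  sig <- noise_sigma(mu1, sch90, 0.05)
  picks <- character(12)
  set.seed(21)
  for (i in seq_along(picks)) {
    obs <- tac("t", sch90, mu1 + rnorm(sch90$n) * sig)
    picks[i] <- fit_all_models(obs, aif90, seed = 1, n_starts = 3,
                               weights = 1 / sig^2)$model
  }
  expect_gt(mean(picks == "1T4P"), 0.5)

  # well-separated 2T6P at low noise: 2T6P selected
  p2 <- kinetic_params("2T6P", 0.05, 0.6, 0.4, 0.15, 0.05, td = 0.1)
  mu2 <- model_tac(p2, aif90, sch90)$values
  sig2 <- noise_sigma(mu2, sch90, 0.01)
  set.seed(22)
  obs2 <- tac("t", sch90, mu2 + rnorm(sch90$n) * sig2)
  expect_equal(fit_all_models(obs2, aif90, seed = 1, n_starts = 3,
                              weights = 1 / sig2^2)$model, "2T6P")
})

test_that("fits are invariant to unit rescaling up to amplitude parameters", {
  p <- tumor_preset()
  obs <- model_tac(p, rvf90, sch90)
  f1 <- fit_kinetic(obs, rvf90, "2T6P", seed = 1, n_starts = 3)
  obs_k <- tac("t", sch90, obs$values * 37)  # SUV -> kBq/mL-like rescale
  inp_k <- rvf90
  inp_k$y <- inp_k$y * 37
  f2 <- fit_kinetic(obs_k, inp_k, "2T6P", seed = 1, n_starts = 3)
  for (nm in c("vb", "K1", "k2", "k3", "k4", "td"))
    expect_equal(unname(coef(f2)[nm]), unname(coef(f1)[nm]),
                 tolerance = 1e-5, label = nm)
})

test_that("fits are deterministic given the seed", {
  p <- tumor_preset()
  mu <- model_tac(p, rvf90, sch90)$values
  set.seed(9)
  obs <- tac("t", sch90, mu + rnorm(sch90$n, 0, 0.03))
  f1 <- fit_kinetic(obs, rvf90, "2T6P", seed = 4)
  f2 <- fit_kinetic(obs, rvf90, "2T6P", seed = 4)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rss, f2$rss)
})
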
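test_that("Spearman rho hits its exact extremes", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(spearman(x, exp(x))$rho, 1)
  expect_equal(spearman(x, -x^3)$rho, -1)
  expect_error(spearman(c(1, 1, 1), 1:3), "constant")
})

test_that("small-sample Spearman p equals the exhaustive permutation null", {
  set.seed(14)
  x <- rnorm(6)
  y <- rnorm(6)
  res <- spearman(x, y)
  # independent oracle: loop over all 720 permutations explicitly
  perms <- tbkin:::.permutations(6)
  rx <- rank(x)
  ry <- rank(y)
  rho_all <- apply(perms, 1, function(ix) cor(rx, ry[ix]))
  p_oracle <- mean(abs(rho_all) >= abs(res$rho) - 1e-12)
  expect_equal(res$p, p_oracle)
  # and agrees with the base-R exact test on tie-free data
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(res$rho, unname(ct$estimate))
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
})

test_that("Spearman handles ties by midranks and stays monotone-invariant", {
  x <- c(1, 2, 2, 3, 5, 5, 7)
  y <- c(2, 1, 4, 4, 6, 8, 9)
  r1 <- spearman(x, y)
  expect_equal(r1$rho, cor(rank(x), rank(y)))
  r2 <- spearman(exp(x), y)       # strictly monotone transform of x
  r3 <- spearman(x, qlogis((rank(y) - 0.4) / 10))
  expect_equal(r2$rho, r1$rho)
  expect_equal(r2$p, r1$p)
  expect_equal(r3$rho, r1$rho)
  # large-n branch matches the t-approximation of base R
  set.seed(2)
  xx <- rnorm(30)
  yy <- xx + rnorm(30)
  rl <- spearman(xx, yy)
  ct <- cor.test(xx, yy, method = "spearman", exact = FALSE)
  expect_equal(rl$rho, unname(ct$estimate))
  expect_equal(rl$p, ct$p.value, tolerance = 1e-9)
})

test_that("the exact signed-rank test reproduces the printed p-values", {
  # 7 concordant pairs -> 2/128, printed as 0.016
  all_up <- wilcoxon_exact(c(0.5, 1.2, 0.3, 2.2, 0.9, 1.1, 0.4))
  expect_identical(all_up$p, 2 / 128)
  expect_equal(round(all_up$p, 3), 0.016)
  expect_equal(all_up$statistic, 0)
  # smaller rank sum of 2 with n = 7 -> 6/128, printed as 0.047
  one_down <- wilcoxon_exact(c(-2, 3, 4, 5, 6, 7, 1))
  expect_equal(one_down$statistic, 2)
  expect_identical(one_down$p, 6 / 128)
  expect_equal(round(one_down$p, 3), 0.047)
  # n = 5, all one sign -> 2/32
  expect_identical(wilcoxon_exact(c(-1, -2, -3, -4, -5))$p, 0.0625)
  expect_error(wilcoxon_exact(c(0, 0)), "zero")
})

test_that("signed-rank enumeration matches independent oracles up to n = 12", {
  set.seed(31)
  for (n in c(5, 8, 12)) {
    d <- round(rnorm(n, 0.3, 1), 3)
    d <- d[d != 0]
    res <- wilcoxon_exact(d)
    # brute force over all 2^n sign assignments
    r <- rank(abs(d))
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    w_all <- signs %*% r
    tot <- sum(r)
    w <- min(res$W_plus, tot - res$W_plus)
    p_brute <- (sum(w_all <= w + 1e-9) + sum(w_all >= tot - w - 1e-9)) /
      nrow(signs)
    expect_equal(res$p, min(1, p_brute), label = paste("n =", n))
    # and the base-R exact distribution on tie-free data
    if (!anyDuplicated(abs(d))) {
      wt <- wilcox.test(d, exact = TRUE)
      expect_equal(res$p, wt$p.value, label = paste("wilcox.test n =", n))
    }
  }
})

test_that("tied absolute differences are enumerated with midranks", {
  d <- c(1, -1, 2, 2, -3, 3, 4)  # heavy ties
  res <- wilcoxon_exact(d)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 7)))
  w_all <- signs %*% r
  tot <- sum(r)
  w <- min(res$W_plus, tot - res$W_plus)
  p_brute <- (sum(w_all <= w + 1e-9) + sum(w_all >= tot - w - 1e-9)) / 128
  expect_equal(res$p, min(1, p_brute))
  expect_lte(res$statistic, 7 * 8 / 2)
  expect_gt(res$p, 0)
})

test_that("surrogacy analysis computes the fixed seven-pair set", {
  # macro table from noiseless forward models of five presets
  rows <- lapply(c("spleen", "thyroid", "lungs", "muscle", "tumor"),
                 function(nm) {
    sp <- all_presets[[nm]]
    inp <- preset_input(sp, extended = TRUE)
    mt <- model_tac(sp$params, inp, sch90)
    p2 <- sp$params
    data.frame(
      region = nm,
      SUV = suv_window(mt, c(60, 90)),
      SUVR = suvr_window(mt, inp, c(60, 90)),
      K_Logan = logan(mt, inp, 30)$K_Logan,
      VT = compute_vt(p2),
      VT_vb = compute_vt_vb(p2),
      Ki_2T6P = if (p2$model == "1T4P") NA_real_ else compute_ki(p2),
      Ki_2T5P = if (p2$model == "1T4P") NA_real_ else compute_ki(p2))
  })
  macro <- do.call(rbind, rows)
  res <- surrogacy_analysis(macro)
  expect_length(res, 7)
  labels <- vapply(res, function(r) r$label, character(1))
  expect_true("SUVR vs VT_vb" %in% labels)
  # noiseless, Logan ~ VT_vb and VT_vb spread out: perfect rank agreement
  kl <- res[[which(labels == "K_Logan vs VT_vb")]]
  expect_equal(kl$rho, 1)
  expect_error(surrogacy_analysis(macro[, setdiff(names(macro), "SUVR")]),
               "SUVR")
  expect_error(surrogacy_analysis(macro[1:2, ]), "3 regions")
})

test_that("paired region tests match labels and report exact p-values", {
  pre <- data.frame(region = c("a", "b", "c", "d", "e"),
                    VT = c(1, 2, 3, 4, 5))
  post <- data.frame(region = rev(pre$region), VT = rev(pre$VT) + 1)
  res <- paired_region_test(pre, post, "VT")
  expect_identical(res$p, 2 / 32)
  expect_error(paired_region_test(pre, post[1:3, ], "VT"), "unmatched")
})
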
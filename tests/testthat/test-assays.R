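# binding models and fits, release titrations, growth kinetics,
# fluorescence normalization

test_that("hill model hits its anchor points and stays bounded monotone", {
  expect_equal(hill_model(494, 494, 2), 0.5)
  expect_equal(hill_model(0, 494, 2), 0)
  # 1.6 uM protein against K_D = 494 nM at n = 1
  expect_equal(hill_model(1600, 494, 1), 1600 / (494 + 1600), tolerance = 1e-12)
  p <- seq(0, 5000, by = 50)
  f <- hill_model(p, 494, 1.7)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f < 1))
})

test_that("the exact 1:1 isotherm behaves in the deep-titration regime", {
  expect_equal(isotherm_model(500, 0, 10300), 0)
  # 500 nM protein, K_D 10.3 uM: half-bound near L = K_D
  f_half <- isotherm_model(0.5, 10.3, 10.3)   # uM units
  expect_lt(abs(f_half - 0.5), 0.02 * 0.5 + 0.02)
  L <- seq(0, 100, by = 0.5)
  f <- isotherm_model(0.5, L, 10.3)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f <= 1))
  # reduces to the simple isotherm as protein -> 0
  expect_equal(isotherm_model(1e-6, 10.3, 10.3), 10.3 / (10.3 + 10.3),
               tolerance = 1e-5)
})

test_that("noiseless binding fits recover the generating parameters", {
  x <- c(25, 50, 100, 200, 300, 450, 600, 800, 1000, 1200, 1400, 1600)
  hd <- generate_curve(curve_spec("hill", list(K_D = 494, n = 2),
                                  x_values = x, noise_cv = 0))
  fit <- fit_binding(hd, "hill")
  expect_lt(abs(fit$K_D - 494) / 494, 0.001)
  expect_lt(abs(fit$hill_n - 2) / 2, 0.001)
  expect_true(fit$converged)

  Lx <- 100 / 2^(15:0)
  idat <- generate_curve(curve_spec("isotherm_1to1",
                                    list(K_D = 10.3, protein_total = 0.5),
                                    x_values = Lx, noise_cv = 0))
  ifit <- fit_binding(idat, "isotherm_1to1")
  expect_lt(abs(ifit$K_D - 10.3) / 10.3, 0.001)

  flat <- list(x = x, y = rep(0.4, length(x)))
  expect_error(fit_binding(flat, "hill"), "degenerate data")
})

test_that("noisy fits agree with the grid-search oracle within one cell", {
  x <- c(25, 50, 100, 200, 300, 450, 600, 800, 1000, 1200, 1400, 1600)
  cd <- generate_curve(curve_spec("hill", list(K_D = 494, n = 1),
                                  x_values = x, noise_cv = 0.05, seed = 42))
  fit <- fit_binding(cd, "hill")
  expect_lt(abs(fit$K_D - 494) / 494, 0.15)
  gr <- oracle_grid_binding(cd$x, cd$y, "hill")
  expect_lt(abs(log(fit$K_D) - log(gr$K)), gr$log_step + 1e-9)

  Lx <- 100 / 2^(15:0)
  idat <- generate_curve(curve_spec("isotherm_1to1",
                                    list(K_D = 32.9, protein_total = 0.5),
                                    x_values = Lx, noise_cv = 0.05, seed = 42))
  ifit <- fit_binding(idat, "isotherm_1to1")
  expect_lt(abs(ifit$K_D - 32.9) / 32.9, 0.15)
  gri <- oracle_grid_binding(idat$x, idat$y, "isotherm_1to1",
                             protein_total = 0.5)
  expect_lt(abs(log(ifit$K_D) - log(gri$K)), gri$log_step + 1e-9)
})

test_that("fold ratios reproduce the printed affinity comparisons", {
  emsa <- fold_ratio(1945, 494, "nM")
  expect_equal(emsa$ratio, 1945 / 494, tolerance = 1e-12)
  expect_equal(emsa$fold, 4)
  mst <- fold_ratio(32.9, 10.3, "uM")
  expect_equal(round(mst$ratio, 2), 3.19)
  expect_equal(mst$fold, 3)
  expect_equal(fold_ratio(7, 7)$ratio, 1)
  # reciprocal ratios multiply to one exactly
  expect_equal(fold_ratio(1945, 494)$ratio * fold_ratio(494, 1945)$ratio, 1)
  expect_error(fold_ratio(1, 1, "nM", "uM"), "unit mismatch")
})

test_that("release titrations call the first fully released concentration", {
  # twofold series; curve crosses the 5% threshold between 0.8 and 1.6 mM
  x <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4)
  y <- c(0.95, 0.90, 0.75, 0.45, 0.12, 0.03, 0.01, 0.005)
  call <- release_titration(list(x = x, y = y))
  expect_true(call$released)
  expect_equal(call$concentration, 1.6)

  none <- release_titration(list(x = x, y = rep(0.9, 8)))
  expect_false(none$released)
  expect_true(is.na(none$concentration))

  all_released <- release_titration(list(x = x, y = y), threshold = 1.0)
  expect_equal(all_released$concentration, x[1])

  expect_warning(release_titration(list(x = x, y = rev(y))), "increasing")
})

test_that("growth fits recover doubling time exactly on pure exponentials", {
  t <- seq(0, 8, by = 0.5)
  pure <- list(x = t, y = 0.03 * 2^(t / 1.62))
  fit <- fit_growth(pure)
  expect_equal(round(fit$doubling_time, 3), 1.62)
  expect_equal(fit$doubling_time, log(2) / fit$growth_rate)
  expect_false(fit$degenerate)

  const <- list(x = t, y = rep(0.05, length(t)))
  dfit <- fit_growth(const)
  expect_true(dfit$degenerate)
  expect_true(is.na(dfit$doubling_time))

  expect_error(fit_growth(list(x = t, y = rep(-1, length(t)))),
               "non-positive OD")
})

test_that("lag estimates land within an hour of the generator truth", {
  # the threshold lag definition has a known upward bias of about one
  # doubling time (OD must double before it can cross 2x), so a fast grower
  # exposes the lag cleanly
  gs <- curve_spec("growth_lag_exp",
                   list(od0 = 0.03, lag_h = 6, doubling_h = 0.5,
                        plateau = 1.2),
                   x_values = seq(0, 16, by = 0.25), noise_cv = 0.02,
                   seed = 13)
  gd <- generate_curve(gs)
  fit <- fit_growth(gd)
  expect_lt(abs(fit$lag_time - 6), 1)
  expect_lt(abs(fit$doubling_time - 0.5) / 0.5, 0.15)
  # tangent-intercept agrees on clean data
  clean <- generate_curve(curve_spec("growth_lag_exp",
                                     list(od0 = 0.03, lag_h = 6,
                                          doubling_h = 0.8, plateau = 1.2),
                                     x_values = seq(0, 16, by = 0.25),
                                     noise_cv = 0))
  tfit <- fit_growth(clean, lag_method = "tangent")
  expect_lt(abs(tfit$lag_time - 6), 1)
})

test_that("fluorescence normalization divides and subtracts correctly", {
  expect_equal(normalize_fluorescence(1000, 0.5), 2000)
  expect_equal(normalize_fluorescence(0, 0.5), 0)
  expect_equal(normalize_fluorescence(c(1200, 900), c(0.4, 0.3),
                                      background = c(200, 150)),
               c(2500, 2500))
  expect_error(normalize_fluorescence(100, 0), "OD must be > 0")
})

test_that("median K_D recovery stays under 10% across seeded replicates", {
  x <- c(25, 50, 100, 200, 300, 450, 600, 800, 1000, 1200, 1400, 1600)
  errs <- vapply(1:40, function(s) {
    cd <- generate_curve(curve_spec("hill", list(K_D = 494, n = 1),
                                    x_values = x, noise_cv = 0.05, seed = s))
    abs(fit_binding(cd, "hill")$K_D - 494) / 494
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})
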
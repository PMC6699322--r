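b12 <- default_bvalues()

test_that("biexponential signal model evaluates correctly", {
  expect_equal(biexp_signal(0.76, 9.38, 0.215, 0), 1)
  expect_equal(biexp_signal(1.0, 20, 0, 1000), exp(-1))
  # cyst parameters at b = 1000, against independent scalar arithmetic
  expected <- (1 - 0.411) * exp(-1000 * 1.59e-3) + 0.411 * exp(-1000 * 4.62e-3)
  expect_equal(biexp_signal(1.59, 4.62, 0.411, 1000), expected)
  expect_error(biexp_signal(1, 10, 0.2, -5), ">= 0")
})

test_that("two-point ADC matches log arithmetic and validates input", {
  expect_equal(adc_two_point(1, exp(-1), 0, 1000), 1.0)
  expect_equal(adc_two_point(50, 50, 0, 800), 0)
  expect_equal(adc_two_point(1, 0.124, 0, 1000), log(1 / 0.124) / 1000 / 1e-3)
  expect_error(adc_two_point(1, 1, 500, 500), "differ")
  expect_error(adc_two_point(-1, 1, 0, 1000), "positive")
})

test_that("log-linear ADC fit is exact on monoexponential input", {
  s <- 90 * exp(-b12 * 1.23e-3)
  expect_equal(fit_adc(s, b12), 1.23, tolerance = 1e-9)
  expect_equal(fit_adc(rep(7, 12), b12), 0)
  # perfusion inflates ADC above D on biexponential input
  cyst <- biexp_signal(1.59, 4.62, 0.411, b12)
  expect_gt(fit_adc(cyst, b12), 1.59)
  expect_error(fit_adc(c(1, 0, 1), c(0, 10, 20)), "b = 10")
})

test_that("slope summarizes normalized decay against b/1000", {
  expect_equal(fit_slope(rep(3, 12), b12), 0)
  lin <- 1 - 0.5 * (b12 / 1000)
  expect_equal(fit_slope(lin, b12), -0.5, tolerance = 1e-12)
  # independent least-squares oracle on the central-tumor curve
  s <- biexp_signal(0.76, 9.38, 0.215, b12)
  oracle <- unname(coef(lm(I(s / s[1]) ~ I(b12 / 1000)))[2])
  expect_equal(fit_slope(s, b12), oracle, tolerance = 1e-10)
})

test_that("biexponential fit recovers noiseless parameters within 1%", {
  for (i in seq_len(nrow(table2_params()))) {
    p <- table2_params()[i, ]
    f <- fit_ivim(55 * biexp_signal(p$d, p$dstar, p$pf, b12), b12)
    expect_lt(abs(f$d / p$d - 1), 0.01)
    expect_lt(abs(f$dstar / p$dstar - 1), 0.01)
    expect_lt(abs(f$pf / p$pf - 1), 0.01)
    expect_true(f$converged)
  }
})

test_that("degenerate and invalid fit inputs behave as specified", {
  s <- exp(-b12 * 1.1e-3)  # PF = 0
  expect_lte(fit_ivim(s, b12)$pf, 0.01)
  expect_error(fit_ivim(replace(s, 3, 0), b12), "Nonpositive")
  expect_error(fit_ivim(s, b12, b_split = 999), "Fewer than 2")
  expect_error(fit_ivim(s[-1], b12[-1]), "b = 0")
})

test_that("fit invariants hold: D <= ADC, two-point equality, refinement, scale", {
  set.seed(1)
  for (k in 1:20) {
    d <- runif(1, 0.3, 2); ds <- runif(1, 3, 30); pf <- runif(1, 0.05, 0.5)
    s <- biexp_signal(d, ds, pf, b12)
    f <- fit_ivim(s, b12)
    expect_lte(f$d, f$adc + 1e-9)
    # refinement never worsens the objective, including under noise
    sn <- s * exp(rnorm(12, 0, 0.02))
    expect_lte(fit_ivim(sn, b12, method = "full")$resid_norm,
               fit_ivim(sn, b12, method = "segmented")$resid_norm + 1e-12)
    # scale invariance
    f2 <- fit_ivim(100 * sn, b12)
    f1 <- fit_ivim(sn, b12)
    expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-6)
  }
  expect_equal(fit_adc(c(1, 0.5), c(0, 600)), adc_two_point(1, 0.5, 0, 600))
})

test_that("tidy and glance expose the fit in broom layout", {
  f <- fit_ivim(biexp_signal(0.93, 9.02, 0.253, b12), b12)
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("adc", "slope", "d", "dstar", "pf"))
  g <- glance(f)
  expect_named(g, c("resid_norm", "converged", "method"))
})

test_that("parameter maps flag pixels instead of zeroing and honor the mask", {
  ph <- generate_phantom(single_tissue_spec(1.14, 5.98, 0.311, 100,
                                            rows = 12, cols = 12, slices = 1))
  body <- ph$labels$data != 0
  one <- array(FALSE, dim(body)); one[6, 6, 1] <- TRUE
  pm <- compute_param_maps(ph$cube, one)
  expect_equal(sum(pm$valid), 1L)
  expect_true(is.na(pm$d[1, 1, 1]))
  expect_error(compute_param_maps(ph$cube, array(FALSE, dim(body))), "Empty")
  # a zero-signal pixel inside the mask is flagged, not fitted
  cube2 <- ph$cube
  cube2$data[6, 7, 1, 4] <- 0
  two <- one; two[6, 7, 1] <- TRUE
  pm2 <- compute_param_maps(cube2, two, presmooth = 0)
  expect_false(pm2$valid[6, 7, 1])
  expect_true(pm2$valid[6, 6, 1])
})

test_that("noiseless single-tissue maps recover ground truth at every pixel", {
  ph <- generate_phantom(single_tissue_spec(0.93, 9.02, 0.253, 110,
                                            rows = 24, cols = 24, slices = 1))
  body <- ph$labels$data != 0
  pm <- compute_param_maps(ph$cube, body)  # default presmooth is mask-aware
  expect_true(all(pm$valid[body]))
  expect_lt(max(abs(pm$d[body] / 0.93 - 1)), 0.01)
  expect_lt(max(abs(pm$dstar[body] / 9.02 - 1)), 0.01)
  expect_lt(max(abs(pm$pf[body] / 0.253 - 1)), 0.01)
})

test_that("masked smoothing reproduces constant fields and respects the mask", {
  arr <- array(5, c(10, 10, 1, 2))
  arr[1, 1, 1, ] <- 1000  # out-of-mask value must not bleed in
  cube <- ivim_cube(arr, c(0, 500))
  mask <- array(TRUE, c(10, 10, 1)); mask[1, 1, 1] <- FALSE
  sm <- smooth_cube(cube, mask, 0.8)
  expect_equal(sm$data[, , , 1][mask], rep(5, sum(mask)))
  expect_equal(sm$data[1, 1, 1, 1], 1000)  # untouched outside the mask
})
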
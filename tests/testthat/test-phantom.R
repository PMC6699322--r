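test_that("identical spec and seed reproduce the cube bit for bit", {
  sp <- reference_phantom_spec(sigma = 2, seed = 9L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$cube$data, b$cube$data)
  expect_identical(a$labels$data, b$labels$data)
})

test_that("noiseless in-body signal equals direct biexponential evaluation", {
  ph <- generate_phantom(reference_phantom_spec())
  tt <- table2_params()
  lab <- tidy(ph$labels)
  for (tis in tt$tissue) {
    px <- which(lab$tissue == tis)[1]
    at <- lab[px, ]
    sig <- ph$cube$data[at$row, at$col, at$slice, ]
    row <- tt[tt$tissue == tis, ]
    expect_equal(sig,
                 row$s0 * biexp_signal(row$d, row$dstar, row$pf,
                                       ph$cube$bvalues),
                 tolerance = 1e-12)
  }
  # air is zero before noise
  expect_true(all(ph$cube$data[1, 1, , ] == 0))
})

test_that("noiseless signal is strictly decreasing in b for body pixels", {
  ph <- generate_phantom(reference_phantom_spec())
  body <- which(ph$labels$data != 0)
  X <- matrix(ph$cube$data, ncol = length(ph$cube$bvalues))[body, ]
  expect_true(all(X[, -1] < X[, -ncol(X)]))
})

test_that("ground-truth maps agree with the tissue table at every label", {
  ph <- generate_phantom(reference_phantom_spec())
  df <- dplyr::inner_join(
    dplyr::filter(tidy(ph$labels), .data$tissue != "background"),
    tidy(ph$truth), by = c("row", "col", "slice"))
  tt <- table2_params()
  by_tis <- dplyr::distinct(df, .data$tissue, .data$d, .data$dstar, .data$pf)
  expect_equal(nrow(by_tis), 4L)  # one parameter triple per tissue
  m <- dplyr::inner_join(by_tis, tt, by = "tissue",
                         suffix = c("_map", "_tab"))
  expect_equal(m$d_map, m$d_tab)
  expect_equal(m$dstar_map, m$dstar_tab)
  expect_equal(m$pf_map, m$pf_tab)
})

test_that("partially overlapping lesions of different tissues are rejected", {
  expect_error(
    phantom_spec(lesions = list(
      phantom_lesion("cyst", c(30, 30), c(6, 6), 1:3),
      phantom_lesion("tumor_central", c(34, 34), c(6, 6), 1:3))) |>
      generate_phantom(),
    "partially overlap")
  # strict nesting (the concentric tumor) is allowed
  expect_silent(generate_phantom(reference_phantom_spec()))
})

test_that("noiseless cyst phantom round-trips through the biexponential fit", {
  sp <- single_tissue_spec(1.59, 4.62, 0.411, 130, rows = 16, cols = 16,
                           slices = 1)
  ph <- generate_phantom(sp)
  lab <- tidy(ph$labels)
  px <- lab[lab$tissue == "normal", ][5, ]
  f <- fit_ivim(ph$cube$data[px$row, px$col, px$slice, ], ph$cube$bvalues)
  expect_lt(abs(f$d / 1.59 - 1), 0.01)
  expect_lt(abs(f$dstar / 4.62 - 1), 0.01)
  expect_lt(abs(f$pf / 0.411 - 1), 0.01)
})

test_that("rician noise: zero sigma is identity, outputs are nonnegative", {
  ph <- generate_phantom(reference_phantom_spec())
  expect_identical(add_rician_noise(ph$cube, 0)$data, ph$cube$data)
  noisy <- add_rician_noise(ph$cube, 5, seed = 3)
  expect_true(all(noisy$data >= 0))
  expect_error(add_rician_noise(ph$cube, -1), ">=")
})

test_that("rician sample mean matches the closed-form mean", {
  n <- 1e5
  cube <- ivim_cube(array(100, c(n, 1, 1, 1)), 0)
  noisy <- add_rician_noise(cube, 2, seed = 7)
  draws <- as.vector(noisy$data)
  se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - rician_mean(100, 2)), 3 * se)
})

test_that("bias field multiplies the slice pattern and rejects bad terms", {
  sp <- phantom_spec(rows = 16, cols = 16, slices = 1,
                     bias = list(coef = c(u = 0.2, vv = -0.1)))
  ph <- generate_phantom(sp)
  flat <- generate_phantom(phantom_spec(rows = 16, cols = 16, slices = 1))
  ratio <- ph$cube$data[, , 1, 1] / flat$cube$data[, , 1, 1]
  ratio <- ratio[is.finite(ratio)]
  expect_gt(max(ratio), 1.05)  # spatially varying multiplier
  expect_lt(min(ratio), 0.95)
  expect_error(
    generate_phantom(phantom_spec(rows = 8, cols = 8, slices = 1,
                                  bias = list(coef = c(q = 1)))),
    "Unknown bias term")
})
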
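test_that("threshold derivation takes midpoints of adjacent class means", {
  tab <- dplyr::rename(default_tissue_table(), class = tissue)
  thr <- derive_thresholds(tab)
  expect_equal(thr$d_tumor, (0.93 + 1.14) / 2)   # 1.035
  expect_equal(thr$d_cyst, (1.14 + 1.59) / 2)    # 1.365
  expect_equal(thr$pf_cyst, (0.311 + 0.411) / 2) # 0.361
  expect_equal(thr$d_central, (0.76 + 0.93) / 2) # 0.845
  # defaults encode exactly these cuts
  def <- decision_thresholds()
  expect_equal(unclass(thr)[names(unclass(def))], unclass(def))
  # equal adjacent means have no separating cut
  bad <- tab; bad$d[bad$class == "normal"] <- 0.93
  expect_error(derive_thresholds(bad), "Equal class means")
  # every cut lies strictly between the two means it separates
  set.seed(26)
  for (i in 1:10) {
    t2 <- tab
    t2$d <- sort(runif(4, 0.3, 2.5))[c(1, 2, 4, 3)]
    t2$pf <- runif(4, 0.05, 0.55)
    if (t2$pf[3] == t2$pf[4]) next
    th <- try(derive_thresholds(t2), silent = TRUE)
    if (inherits(th, "try-error")) next
    expect_gt(th$d_tumor, min(t2$d[2], t2$d[4]))
    expect_lt(th$d_tumor, max(t2$d[2], t2$d[4]))
  }
})

test_that("the decision tree classifies the class prototype vectors", {
  tab <- table2_params()
  got <- classify_pixel(tab$d, tab$pf, decision_thresholds())
  expect_identical(got, c("tumor", "tumor", "cyst", "normal"))
  expect_identical(classify_pixel(NA_real_, 0.3), "other")
})

test_that("prototype self-consistency holds for thresholds derived from any means", {
  set.seed(27)
  for (i in 1:25) {
    d <- sort(runif(4, 0.2, 2.8))          # central < peripheral < normal < cyst
    pf <- c(runif(2, 0.1, 0.3), 0, 0)
    pf[3] <- runif(1, 0.05, 0.4)           # normal
    pf[4] <- pf[3] + runif(1, 0.05, 0.15)  # cyst above normal
    tab <- tibble::tibble(
      class = c("tumor_central", "tumor_peripheral", "normal", "cyst"),
      d = d, pf = pf)
    thr <- derive_thresholds(tab)
    got <- classify_pixel(tab$d, tab$pf, thr)
    expect_identical(got, c("tumor", "tumor", "normal", "cyst"))
    zones <- split_central_peripheral(tab$d[1:2], thr)
    expect_identical(zones, c("tumor_central", "tumor_peripheral"))
  }
})

test_that("central/peripheral split follows the cut and median conventions", {
  thr <- decision_thresholds()
  expect_identical(split_central_peripheral(c(0.7, 0.845, 0.9), thr),
                   c("tumor_central", "tumor_central", "tumor_peripheral"))
  same <- split_central_peripheral(rep(0.845, 5), thr)
  expect_true(all(same == "tumor_central"))  # ties go to central
  med <- split_central_peripheral(c(0.7, 0.8, 0.9), thr, mode = "median")
  expect_identical(med, c("tumor_central", "tumor_peripheral",
                          "tumor_peripheral"))
  expect_error(split_central_peripheral(numeric(0)), "Empty")
  expect_error(split_central_peripheral(0.8, mode = "median"), ">= 2")
})

test_that("noiseless concentric tumor splits at 99%+ accuracy", {
  ph <- ref_noiseless()
  body <- ph$labels$data != 0
  pm <- ref_noiseless_maps()
  truth <- tidy(ph$labels)$tissue
  tum <- truth %in% c("tumor_central", "tumor_peripheral")
  got <- split_central_peripheral(pm$d[array(tum, dim(body))],
                                  decision_thresholds())
  expect_gte(mean(got == truth[tum]), 0.99)
})

test_that("histogram statistics follow the Fisher conventions", {
  hs <- histogram_stats(c(1, 2, 3))
  expect_equal(hs$skewness, 0)
  expect_equal(hs$mean, 2)
  expect_equal(hs$median, 2)
  one <- histogram_stats(5)
  expect_true(is.na(one$skewness) && is.na(one$kurtosis))
  expect_equal(one$n, 1L)
  set.seed(28)
  x <- rnorm(5000)
  expect_lt(abs(histogram_stats(x)$kurtosis), 0.2)  # excess kurtosis ~ 0
  expect_error(histogram_stats(NA_real_), "finite")
})

test_that("case averaging appends the arithmetic mean row", {
  df <- example_case_slices()
  avg <- case_average(df)
  expect_identical(avg$slice[nrow(avg)], "average")
  expect_equal(avg$adc[nrow(avg)], mean(df$adc))
  one <- case_average(df[3, ])
  expect_equal(one$adc[2], df$adc[3])  # single slice: average equals it
})

test_that("summarize_case aggregates per slice and class with an average row", {
  ph <- ref_noiseless()
  pm <- ref_noiseless_maps()
  sm <- summarize_case(ph$labels, pm)
  expect_true(all(c("slice", "class", "n_pixels", "adc", "slope", "d",
                    "dstar", "pf") %in% names(sm)))
  for (cl in unique(sm$class)) {
    per <- sm[sm$class == cl & sm$slice != "average", ]
    avg <- sm[sm$class == cl & sm$slice == "average", ]
    expect_equal(avg$d, mean(per$d))
    expect_equal(avg$n_pixels, sum(per$n_pixels))
  }
  # noiseless per-class means equal the generating table
  tt <- table2_params()
  m <- dplyr::inner_join(sm[sm$slice == "average", ], tt,
                         by = c(class = "tissue"), suffix = c("_fit", "_gen"))
  expect_lt(max(abs(m$d_fit / m$d_gen - 1)), 0.001)
  expect_lt(max(abs(m$pf_fit / m$pf_gen - 1)), 0.001)
})

test_that("classify_map gates zone labels to the lesion mask", {
  ph <- ref_noiseless()
  body <- ph$labels$data != 0
  pm <- ref_noiseless_maps()
  lesion <- ph$labels$data %in% c(3L, 4L)  # true tumor support
  lm_ <- classify_map(pm, body_mask = body, lesion_mask = lesion)
  lab <- lm_$data
  zones <- lab == 3L | lab == 4L
  expect_true(all(lesion[zones]))          # zones only inside the mask
  # central and peripheral partition the in-mask tumor pixels
  expect_identical(sort(unique(lab[lesion])), c(3L, 4L))
  # without a mask every tree-tumor pixel is split
  lm2 <- classify_map(pm, body_mask = body)
  expect_false(any(lm2$data == 5L))
})
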
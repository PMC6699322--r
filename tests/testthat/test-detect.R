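test_that("OSP projector has the projector identities", {
  expect_equal(osp_projector(matrix(c(1, 0), 2, 1)), diag(c(0, 1)))
  set.seed(4)
  U <- matrix(rnorm(10), 5, 2)
  P <- osp_projector(U)
  expect_equal(P, t(P), tolerance = 1e-10)
  expect_equal(P %*% P, P, tolerance = 1e-10)
  expect_lt(max(abs(P %*% U)), 1e-10)
  # QR-based oracle: projector onto the orthogonal complement
  Q <- qr.Q(qr(U), complete = TRUE)[, 3:5]
  expect_equal(P, Q %*% t(Q), tolerance = 1e-10)
  expect_error(osp_projector(cbind(U[, 1], 2 * U[, 1])), "rank")
})

test_that("spectral angle mapper is exact on canonical pairs", {
  expect_equal(sam(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(sam(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(sam(c(1, 0), c(1, 1)), pi / 4)
  expect_error(sam(c(0, 0), c(1, 1)), "zero vector")
  set.seed(5)
  s <- rnorm(6); t <- rnorm(6)
  expect_equal(sam(3.7 * s, t), sam(s, t))   # scale invariance
  expect_equal(sam(s, t), sam(t, s))         # symmetry
})

test_that("ATGP takes the brightest pixel first and separates orthogonal blocks", {
  arr <- array(0.01, c(2, 2, 1, 2))
  arr[1, 1, 1, ] <- c(9, 0)   # unique largest norm
  arr[2, 2, 1, ] <- c(0, 5)
  ts <- atgp(arr, n_targets = 2)
  expect_equal(ts$positions$pixel[1], 1L)
  expect_equal(sort(ts$positions$pixel[1:2]), c(1L, 4L))
  expect_error(atgp(array(0, c(2, 2, 1, 2)), 1), "All-zero")
  expect_error(atgp(arr, n_targets = 50), "targets")
})

test_that("ATGP matches the exhaustive argmax oracle on random small cubes", {
  set.seed(6)
  for (i in 1:100) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1); nb <- sample(2:3, 1)
    arr <- array(runif(nr * nc * nb, 0.1, 2), c(nr, nc, 1, nb))
    k <- sample(1:min(3, nb), 1)
    got <- atgp(arr, n_targets = k)$positions$pixel
    want <- atgp_oracle(matrix(arr, ncol = nb), k)
    expect_identical(got, want[seq_along(got)])
  }
})

test_that("ATGP epsilon stopping ends the sequence early", {
  set.seed(7)
  arr <- array(runif(5 * 5 * 3, 0.5, 1), c(5, 5, 1, 3))
  full <- atgp(arr, n_targets = 4)
  stopped <- atgp(arr, n_targets = 4, epsilon = pi)  # any angle <= pi stops
  expect_lt(nrow(stopped$positions), nrow(full$positions))
  expect_equal(stopped$stopped, "epsilon")
})

test_that("training-sample selection respects the angle radius", {
  arr <- array(0, c(4, 1, 1, 2))
  arr[1:2, 1, 1, 1] <- c(2, 4)        # cluster along e1
  arr[3:4, 1, 1, 2] <- c(3, 5)        # cluster along e2
  ts <- atgp(arr, n_targets = 2)
  tr <- select_training_samples(arr, ts, angle_threshold = 0.2)
  sets <- split(tr$samples$pixel, tr$samples$target)
  expect_setequal(sets[[1]], c(3L, 4L))  # brightest target is the e2 cluster
  expect_setequal(sets[[2]], c(1L, 2L))
  expect_false(tr$overlap)
  # threshold 0 keeps only spectrally identical pixels; pi keeps all nonzero
  tr0 <- select_training_samples(arr, ts, angle_threshold = 0)
  expect_setequal(split(tr0$samples$pixel, tr0$samples$target)[[1]],
                  c(3L, 4L))
  trpi <- select_training_samples(arr, ts, angle_threshold = pi)
  expect_setequal(unique(trpi$samples$pixel), 1:4)
})

test_that("correlation matrix equals its definition", {
  r <- c(1, 2, 3)
  expect_equal(correlation_matrix(array(r, c(1, 1, 1, 3))), r %*% t(r))
  two <- array(c(1, 0, 0, 1), c(2, 1, 1, 2))
  expect_equal(correlation_matrix(two), diag(2) / 2)
  set.seed(8)
  arr <- array(rnorm(10 * 4), c(10, 1, 1, 4))
  X <- matrix(arr, ncol = 4)
  loop <- Reduce(`+`, lapply(1:10, function(i) X[i, ] %*% t(X[i, ]))) / 10
  expect_equal(correlation_matrix(arr), loop, tolerance = 1e-12)
})

test_that("CEM satisfies its constraint and matches the Lagrange oracle", {
  set.seed(9)
  arr <- array(runif(4 * 4 * 1 * 3, 0.2, 2), c(4, 4, 1, 3))
  d <- as.vector(arr[2, 3, 1, ])
  dm <- cem(arr, d, ridge = 0)
  expect_equal(dm$data[2, 3, 1], 1, tolerance = 1e-9)
  # 3-pixel, 2-band instance: w from an independent constrained minimization
  X <- matrix(c(1, 0.2, 0.5, 1.1, 0.1, 0.9), 3, 2, byrow = TRUE)
  d2 <- X[1, ]
  R <- crossprod(X) / 3
  w_oracle <- solve(R, d2) / drop(t(d2) %*% solve(R, d2))
  got <- cem(array(X, c(3, 1, 1, 2)), d2, ridge = 0)
  expect_equal(as.vector(got$data), as.vector(X %*% w_oracle),
               tolerance = 1e-10)
  # orthogonal background: ~0 off target, 1 on target
  Xo <- rbind(c(0, 0, 2), c(0, 0, 1.4), c(1, 0, 0))
  dmo <- cem(array(Xo, c(3, 1, 1, 3)), c(1, 0, 0), ridge = 1e-10)
  expect_equal(dmo$data[3, 1, 1], 1, tolerance = 1e-6)
  expect_lt(max(abs(dmo$data[1:2, 1, 1])), 1e-4)
})

test_that("CEM is invariant to joint rescaling of cube and signature", {
  set.seed(10)
  arr <- array(runif(5 * 5 * 1 * 3, 0.1, 1), c(5, 5, 1, 3))
  d <- as.vector(arr[1, 1, 1, ])
  a <- cem(arr, d)
  b <- cem(arr * 7, d * 7)
  expect_equal(a$data, b$data, tolerance = 1e-8)
})

test_that("RBF kernel matches its formula", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 3), 1)
  x <- c(0, 0); y <- c(2, 0)
  expect_equal(rbf_kernel(x, y, sqrt(2)), exp(-1))
  set.seed(11)
  a <- rnorm(7); b <- rnorm(7)
  d2 <- sum((a - b)^2)
  expect_equal(rbf_kernel(a, b, 1.3), exp(-d2 / (2 * 1.3^2)),
               tolerance = 1e-12)
  expect_error(rbf_kernel(a, b, 0), "> 0")
})

test_that("KCEM with the linear kernel reproduces CEM everywhere", {
  set.seed(12)
  arr <- array(runif(6 * 5 * 1 * 4, 0.3, 2), c(6, 5, 1, 4))
  cube <- ivim_cube(arr, c(0, 100, 500, 1000))
  d <- as.vector(arr[4, 2, 1, ])
  ridge <- 1e-8
  k <- kcem(cube, d, kernel = "linear", ridge = ridge)
  c_ <- cem(cube, d, ridge = ridge)
  expect_lt(max(abs(k$data - c_$data)), 1e-6)
})

test_that("KCEM response at the desired signature is one for any kernel", {
  set.seed(13)
  arr <- array(runif(4 * 4 * 1 * 3, 0.2, 1.5), c(4, 4, 1, 3))
  d <- as.vector(arr[2, 2, 1, ])
  for (kern in c("linear", "rbf")) {
    km <- kcem(arr, d, kernel = kern, sigma = 1)
    expect_equal(km$data[2, 2, 1], 1, tolerance = 1e-6)
  }
})

test_that("wide-bandwidth RBF ranking approaches the centered linear ranking", {
  # as sigma grows the RBF feature map limits to constant + centered linear,
  # so the ranking converges to CEM on mean-centered data
  set.seed(14)
  arr <- array(runif(6 * 6 * 1 * 4, 0.5, 2), c(6, 6, 1, 4))
  d <- as.vector(arr[3, 3, 1, ])
  X <- matrix(arr, ncol = 4)
  mu <- colMeans(X)
  centered <- array(sweep(X, 2, mu), dim(arr))
  lin <- kcem(centered, d - mu, kernel = "linear", ridge = 1e-8)
  rbf <- kcem(arr, d, kernel = "rbf", sigma = 1e4, ridge = 1e-12)
  expect_gt(cor(as.vector(rbf$data), as.vector(lin$data),
                method = "spearman"), 0.99)
})
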
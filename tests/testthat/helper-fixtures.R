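# Shared fixtures and independent oracles used across test files.

# tiny random cube-like array builder
random_cube <- function(rows, cols, slices, bands, min = 0.1, max = 2) {
  arr <- array(runif(rows * cols * slices * bands, min, max),
               c(rows, cols, slices, bands))
  ivim_cube(arr, c(0, sort(sample(1:1000, bands - 1L))))
}

table2_params <- function() {
  tibble::tibble(
    tissue = c("tumor_central", "tumor_peripheral", "cyst", "normal"),
    d = c(0.76, 0.93, 1.59, 1.14),
    dstar = c(9.38, 9.02, 4.62, 5.98),
    pf = c(0.215, 0.253, 0.411, 0.311),
    s0 = c(110, 110, 130, 100))
}

# single-tissue phantom spec: an all-"normal" body carrying the given
# parameters (the label is irrelevant for recovery checks)
single_tissue_spec <- function(d, dstar, pf, s0, rows = 64L, cols = 64L,
                               slices = 3L, sigma = 0, seed = 5L) {
  phantom_spec(rows = rows, cols = cols, slices = slices,
               tissues = tibble::tibble(tissue = "normal", d = d,
                                        dstar = dstar, pf = pf, s0 = s0),
               sigma = sigma, seed = seed)
}

# session-level cache for expensive shared fixtures
.fixture_cache <- new.env(parent = emptyenv())

ref_noiseless <- function() {
  if (is.null(.fixture_cache$ph))
    .fixture_cache$ph <- generate_phantom(reference_phantom_spec())
  .fixture_cache$ph
}

# exact (unsmoothed) parameter maps of the noiseless reference phantom
ref_noiseless_maps <- function() {
  if (is.null(.fixture_cache$pm)) {
    ph <- ref_noiseless()
    .fixture_cache$pm <- compute_param_maps(ph$cube, ph$labels$data != 0,
                                            presmooth = 0)
  }
  .fixture_cache$pm
}

# ---- independent oracles ----------------------------------------------------

# exhaustive per-iteration ATGP: argmax of ||P r||^2 evaluated pixel by pixel
atgp_oracle <- function(X, n_targets) {
  picks <- integer(0)
  for (k in seq_len(n_targets)) {
    scores <- vapply(seq_len(nrow(X)), function(i) {
      r <- X[i, ]
      if (length(picks) == 0) return(sum(r^2))
      U <- t(X[picks, , drop = FALSE])
      P <- diag(ncol(X)) - U %*% solve(crossprod(U), t(U))
      drop(t(r) %*% P %*% r)
    }, numeric(1))
    scores[picks] <- -Inf
    picks <- c(picks, which.max(scores))
  }
  picks
}

# brute-force co-occurrence local-entropy threshold (independent of the
# package's prefix-sum implementation)
local_entropy_oracle <- function(img, G) {
  M <- matrix(0, G, G)
  nr <- nrow(img); nc <- ncol(img)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (r < nr) {
      M[img[r, c] + 1, img[r + 1, c] + 1] <- M[img[r, c] + 1, img[r + 1, c] + 1] + 1
      M[img[r + 1, c] + 1, img[r, c] + 1] <- M[img[r + 1, c] + 1, img[r, c] + 1] + 1
    }
    if (c < nc) {
      M[img[r, c] + 1, img[r, c + 1] + 1] <- M[img[r, c] + 1, img[r, c + 1] + 1] + 1
      M[img[r, c + 1] + 1, img[r, c] + 1] <- M[img[r, c + 1] + 1, img[r, c] + 1] + 1
    }
  }
  ent <- function(q) {
    s <- sum(q)
    if (s == 0) return(NA_real_)
    p <- q[q > 0] / s
    -sum(p * log(p))
  }
  best <- -Inf; thr <- NA_integer_
  for (t in 0:(G - 2)) {
    hBB <- ent(M[1:(t + 1), 1:(t + 1)])
    hFF <- ent(M[(t + 2):G, (t + 2):G, drop = FALSE])
    if (is.na(hBB) || is.na(hFF)) next
    if (hBB + hFF > best) { best <- hBB + hFF; thr <- t }
  }
  thr
}

# brute-force Otsu: maximize between-class variance directly
otsu_oracle <- function(img, G) {
  v <- as.vector(img)
  best <- -Inf; thr <- NA_integer_
  for (t in 0:(G - 2)) {
    b <- v[v <= t]; f <- v[v > t]
    if (!length(b) || !length(f)) next
    w0 <- length(b) / length(v)
    crit <- w0 * (1 - w0) * (mean(b) - mean(f))^2
    if (crit > best + 1e-12) { best <- crit; thr <- t }
  }
  thr
}

# closed-form mean of a Rician(nu, sigma) using scaled Bessel functions
rician_mean <- function(nu, sigma) {
  a <- nu^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) *
    ((1 + a) * besselI(a / 2, 0, expon.scaled = TRUE) +
       a * besselI(a / 2, 1, expon.scaled = TRUE))
}
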
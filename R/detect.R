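# Unsupervised hyperspectral target detection on the expanded cube:
# automatic target generation (ATGP) by successive orthogonal subspace
# projection, spectral angle mapping (SAM) to harvest training samples, and
# constrained energy minimization (CEM) with its kernelized form (KCEM).

#' Orthogonal subspace projector
#'
#' `P = I - U (U^T U)^-1 U^T`, the projector onto the orthogonal complement
#' of the column space of `U`. Symmetric, idempotent, and annihilates every
#' column of `U`.
#'
#' @param U numeric matrix with full column rank.
#' @return The `nrow(U) x nrow(U)` projection matrix.
#' @export
osp_projector <- function(U) {
  U <- as.matrix(U)
  if (qr(U)$rank < ncol(U))
    stop_ivim("`U` is rank deficient; target signatures must be linearly ",
              "independent.")
  diag(nrow(U)) - U %*% solve(crossprod(U), t(U))
}

#' Spectral angle between two signatures
#'
#' `SAM(s, t) = arccos(s.t / (|s| |t|))` in radians; 0 for identical
#' directions, pi/2 for orthogonal ones. Scale-invariant and symmetric.
#'
#' @param s,t nonzero numeric vectors of equal length.
#' @return Angle in radians in `[0, pi]`.
#' @examples
#' sam(c(1, 0), c(1, 1))  # pi / 4
#' @export
sam <- function(s, t) {
  ns <- sqrt(sum(s^2)); nt <- sqrt(sum(t^2))
  if (ns == 0 || nt == 0) stop_ivim("SAM is undefined for a zero vector.")
  acos(clamp(sum(s * t) / (ns * nt), c(-1, 1)))
}

# angles of every row of X (N x M) to a single signature t; zero rows -> NA
sam_to_rows <- function(X, t) {
  nt <- sqrt(sum(t^2))
  nr <- sqrt(rowSums(X^2))
  ang <- acos(clamp(as.vector(X %*% t) / (nr * nt), c(-1, 1)))
  ang[nr == 0] <- NA_real_
  ang
}

#' Automatic target generation process
#'
#' Picks the maximum-norm (brightest) pixel as the first target, then
#' repeatedly projects all pixels onto the orthogonal complement of the
#' targets found so far and takes the pixel with the largest residual
#' norm. Stops after `n_targets` targets, or earlier when
#' `measure(t_[k-1], t_k) <= epsilon` (with `measure = sam` by default), or
#' when the residual image is numerically zero (all spectra are spanned by
#' the targets already found).
#'
#' @param cube a `band_cube`, `ivim_cube` or 3-/4-D array.
#' @param n_targets maximum number of targets (default 5).
#' @param epsilon optional stopping threshold on `measure` between
#'   consecutive targets; `NULL` disables the rule.
#' @param measure two-argument discrimination measure used with `epsilon`.
#' @return A `target_set`: list with `signatures` (targets x bands matrix),
#'   `positions` (tibble `target`, `pixel`, `row`, `col`, `slice`) and the
#'   stopping metadata.
#' @export
atgp <- function(cube, n_targets = 5L, epsilon = NULL, measure = sam) {
  X <- as_pixel_matrix(cube)
  d3 <- cube_spatial_dim(cube)
  N <- nrow(X)
  if (n_targets < 1L) stop_ivim("`n_targets` must be >= 1.")
  if (n_targets > N) stop_ivim("Requested ", n_targets, " targets from ",
                               N, " pixels.")
  norms2 <- rowSums(X^2)
  if (max(norms2) == 0) stop_ivim("All-zero cube: no targets exist.")
  picks <- integer(0L)
  stopped <- "n_targets"
  tol <- max(norms2) * 1e-12
  repeat {
    if (length(picks) == 0L) {
      res2 <- norms2
    } else {
      P <- osp_projector(t(X[picks, , drop = FALSE]))
      res2 <- rowSums((X %*% P) * X)   # ||P r||^2 (P idempotent, symmetric)
      res2[picks] <- -Inf              # already-taken locations
    }
    if (max(res2) <= tol) { stopped <- "residual_zero"; break }
    cand <- which.max(res2)
    if (!is.null(epsilon) && length(picks) >= 1L) {
      m <- measure(X[picks[length(picks)], ], X[cand, ])
      if (m <= epsilon) { stopped <- "epsilon"; break }
    }
    picks <- c(picks, cand)
    if (length(picks) >= n_targets) break
  }
  if (length(picks) == 0L)
    stop_ivim("ATGP found no nonzero target.")
  sp <- spatial_index(d3)[picks, ]
  structure(list(
    signatures = X[picks, , drop = FALSE],
    positions = tibble(target = seq_along(picks), pixel = picks,
                       row = sp$row, col = sp$col, slice = sp$slice),
    stopped = stopped, n_requested = n_targets, epsilon = epsilon
  ), class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("<target_set> ", nrow(x$signatures), " targets (stop: ", x$stopped,
      ")\n", sep = "")
  invisible(x)
}

#' Select training samples around each target by spectral angle
#'
#' For every ATGP target, collects the pixels whose spectral angle to the
#' target is at most `angle_threshold` and averages them into a desired
#' signature for the matched filter. Sets may overlap across targets (the
#' result flags this); a target with no neighbors keeps itself as a
#' singleton set, with a warning.
#'
#' @param cube the cube the targets came from.
#' @param targets a `target_set`.
#' @param angle_threshold SAM radius in radians (> 0).
#' @return A list with `samples` (tibble `target`, `pixel`, `angle`),
#'   `signatures` (targets x bands matrix of mean signatures) and
#'   `overlap` (logical).
#' @export
select_training_samples <- function(cube, targets, angle_threshold = 0.1) {
  stopifnot(inherits(targets, "target_set"))
  check_number(angle_threshold, "angle_threshold", min = 0)
  X <- as_pixel_matrix(cube)
  nt <- nrow(targets$signatures)
  rows <- vector("list", nt)
  sig <- matrix(0, nt, ncol(X))
  for (j in seq_len(nt)) {
    ang <- sam_to_rows(X, targets$signatures[j, ])
    sel <- which(!is.na(ang) & ang <= angle_threshold)
    if (!length(sel)) {
      warn(paste0("Target ", j, " has no SAM neighbors at threshold ",
                  signif(angle_threshold, 3), "; using the target alone."))
      sel <- targets$positions$pixel[j]
      ang[sel] <- 0
    }
    rows[[j]] <- tibble(target = j, pixel = sel, angle = ang[sel])
    sig[j, ] <- colMeans(X[sel, , drop = FALSE])
  }
  samples <- dplyr::bind_rows(rows)
  list(samples = samples, signatures = sig,
       overlap = anyDuplicated(samples$pixel) > 0L)
}

#' Sample autocorrelation matrix of a cube
#'
#' `R = (1/N) sum_i r_i r_i^T` over all pixel spectra; symmetric positive
#' semidefinite.
#'
#' @param cube a cube-like object.
#' @return The `M x M` correlation matrix.
#' @export
correlation_matrix <- function(cube) {
  X <- as_pixel_matrix(cube)
  crossprod(X) / nrow(X)
}

default_ridge <- function(R) 1e-6 * sum(diag(R)) / nrow(R)

#' Constrained energy minimization detector
#'
#' The CEM filter `w = R^-1 d / (d^T R^-1 d)` minimizes the average filter
#' output energy over the image subject to unit response to the desired
#' signature `d`; the detection map is `w^T r` per pixel. A ridge
#' `R + ridge I` regularizes ill-conditioned correlation matrices; the
#' default `ridge = NULL` uses `1e-6 trace(R)/M` (scale-free), and
#' `ridge = 0` requests the unregularized solve.
#'
#' @param cube a cube-like object.
#' @param d desired signature, length = number of bands.
#' @param ridge nonnegative ridge, or `NULL` for the scale-free default.
#' @return A `detection_map`: list with `data` (3-D array) and metadata.
#' @export
cem <- function(cube, d, ridge = NULL) {
  X <- as_pixel_matrix(cube)
  d <- as.numeric(d)
  if (length(d) != ncol(X))
    stop_ivim("`d` has length ", length(d), " but the cube has ", ncol(X),
              " bands.")
  if (all(d == 0)) stop_ivim("`d` must be nonzero.")
  R <- crossprod(X) / nrow(X)
  if (is.null(ridge)) ridge <- default_ridge(R)
  check_number(ridge, "ridge", min = 0)
  Rr <- R + diag(ridge, nrow(R))
  Rinv_d <- tryCatch(solve(Rr, d), error = function(e)
    stop_ivim("Correlation matrix is singular; pass a positive `ridge` ",
              "(e.g. ridge = NULL for the scale-free default)."))
  w <- Rinv_d / sum(d * Rinv_d)
  new_detection_map(array(as.vector(X %*% w), cube_spatial_dim(cube)),
                    detector = "cem", ridge = ridge)
}

#' Gaussian radial basis function kernel
#'
#' `k(x, y) = exp(-|x - y|^2 / (2 sigma^2))`, in `(0, 1]`.
#'
#' @param x,y numeric vectors of equal length.
#' @param sigma bandwidth (> 0).
#' @return Scalar kernel value.
#' @export
rbf_kernel <- function(x, y, sigma) {
  check_number(sigma, "sigma", min = 0, strict_min = TRUE)
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

# Gram/cross-kernel matrices. A: n x M, B: m x M -> n x m kernel matrix.
kernel_matrix <- function(A, B, kernel, sigma = NULL) {
  if (kernel == "linear") return(A %*% t(B))
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

# Median pairwise distance of a seeded pixel subsample ("median heuristic").
# Distances that are zero up to rounding (duplicate spectra, e.g. noiseless
# synthetic data) are excluded so the bandwidth reflects real structure.
median_heuristic_sigma <- function(X, n = 500L, seed = NULL) {
  idx <- if (nrow(X) <= n) seq_len(nrow(X)) else
    with_seed(seed, sample.int(nrow(X), n))
  ds <- as.vector(stats::dist(X[idx, , drop = FALSE]))
  ds <- ds[is.finite(ds)]
  if (!length(ds)) return(1)
  ds <- ds[ds > 1e-8 * max(ds)]
  if (!length(ds)) return(1)
  median(ds)
}

#' Kernel constrained energy minimization detector
#'
#' Kernelized CEM: the CEM quadratic form is evaluated in the feature space
#' of a positive-definite kernel via the kernel trick, with the feature-space
#' correlation operator estimated from a background sample of pixels. For a
#' background `{x_1..x_n}` with Gram matrix `K`, a ridge `rho > 0`, and
#' kernel columns `k_d = k(x_i, d)`, `k_r = k(x_i, r)`, the response is
#' \deqn{\delta(r) = \frac{k(d, r) - k_d^T (K + n\rho I)^{-1} k_r}
#'                        {k(d, d) - k_d^T (K + n\rho I)^{-1} k_d}}
#' (the Woodbury form of the regularized feature-space quadratic form),
#' normalized so the response at `d` is exactly 1. With the linear kernel
#' and the full image as background this reproduces [cem()] with the same
#' ridge exactly.
#'
#' @param cube a cube-like object.
#' @param d desired signature.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param sigma RBF bandwidth; `NULL` uses the median pairwise distance of a
#'   seeded 500-pixel subsample.
#' @param ridge feature-space ridge (> 0); `NULL` picks a scale-free
#'   default (the [cem()] rule for the linear kernel, `1e-6` for RBF whose
#'   Gram entries are already order 1).
#' @param background_size background pixels used for the Gram matrix; all
#'   pixels when the image has at most this many, otherwise a seeded uniform
#'   subsample.
#' @param seed seed for the subsampling (and sigma heuristic).
#' @return A `detection_map`.
#' @export
kcem <- function(cube, d, kernel = c("rbf", "linear"), sigma = NULL,
                 ridge = NULL, background_size = 2000L, seed = 1L) {
  kernel <- match.arg(kernel)
  X <- as_pixel_matrix(cube)
  d <- as.numeric(d)
  if (length(d) != ncol(X))
    stop_ivim("`d` has length ", length(d), " but the cube has ", ncol(X),
              " bands.")
  if (all(d == 0)) stop_ivim("`d` must be nonzero.")
  if (kernel == "rbf" && is.null(sigma))
    sigma <- median_heuristic_sigma(X, seed = seed)
  if (!is.null(sigma)) check_number(sigma, "sigma", min = 0,
                                    strict_min = TRUE)
  ctx <- kcem_background(X, kernel, sigma, ridge, background_size, seed)
  vals <- kcem_response(ctx, d, X)[, 1L]
  new_detection_map(array(vals, cube_spatial_dim(cube)),
                    detector = paste0("kcem-", kernel), ridge = ctx$ridge,
                    sigma = sigma)
}

# Precompute the background Gram factorization so several desired
# signatures can share it (one chol, many solves).
kcem_background <- function(X, kernel, sigma, ridge, background_size, seed) {
  n_all <- nrow(X)
  idx <- if (n_all <= background_size) seq_len(n_all) else
    with_seed(seed, sample.int(n_all, background_size))
  B <- X[idx, , drop = FALSE]
  n <- nrow(B)
  K <- kernel_matrix(B, B, kernel, sigma)
  if (is.null(ridge)) {
    # linear: mirror cem()'s 1e-6 tr(R)/M (tr(R) = tr(K)/n); rbf: Gram
    # entries are already O(1), so an absolute 1e-6 is scale-free.
    ridge <- if (kernel == "linear")
      1e-6 * sum(diag(K)) / (n * ncol(B)) else 1e-6
  }
  check_number(ridge, "ridge", min = 0, strict_min = TRUE)
  G <- K + diag(n * ridge, n)
  ch <- tryCatch(chol(G), error = function(e)
    stop_ivim("Regularized Gram matrix is not positive definite; ",
              "increase `ridge`."))
  list(B = B, chol = ch, kernel = kernel, sigma = sigma, ridge = ridge,
       n = n)
}

# Responses of one or several desired signatures over the pixels of X,
# sharing the background factorization and the chunked cross-kernel matrix
# across signatures. D: n_t x M matrix (or vector); returns N x n_t.
kcem_response <- function(ctx, D, X) {
  if (is.null(dim(D))) D <- rbind(D)
  Kd <- kernel_matrix(ctx$B, D, ctx$kernel, ctx$sigma)      # n x n_t
  A <- backsolve(ctx$chol, forwardsolve(t(ctx$chol), Kd))   # n x n_t
  kdd <- diag(kernel_matrix(D, D, ctx$kernel, ctx$sigma))
  den <- kdd - colSums(Kd * A)
  if (any(den <= 0))
    stop_ivim("Degenerate KCEM normalization; increase `ridge`.")
  N <- nrow(X)
  out <- matrix(0, N, nrow(D))
  step <- 20000L
  for (s in seq(1L, N, by = step)) {
    e <- min(s + step - 1L, N)
    Xc <- X[s:e, , drop = FALSE]
    Kr <- kernel_matrix(ctx$B, Xc, ctx$kernel, ctx$sigma)   # n x chunk
    Kdr <- kernel_matrix(D, Xc, ctx$kernel, ctx$sigma)      # n_t x chunk
    out[s:e, ] <- t((Kdr - t(A) %*% Kr) / den)
  }
  out
}

new_detection_map <- function(data, detector, ...) {
  structure(list(data = data, detector = detector, meta = list(...)),
            class = "detection_map")
}

#' @export
print.detection_map <- function(x, ...) {
  cat("<detection_map:", x$detector, "> ",
      paste(dim(x$data), collapse = " x "), ", range [",
      signif(min(x$data), 3), ", ", signif(max(x$data), 3), "]\n", sep = "")
  invisible(x)
}

#' Tidy a detection map
#' @param x a `detection_map`.
#' @param ... unused.
#' @return Tibble with `row`, `col`, `slice`, `response`.
#' @export
tidy.detection_map <- function(x, ...) {
  spatial_index(dim(x$data)) |>
    dplyr::mutate(response = as.vector(x$data)) |>
    dplyr::select(-"pixel")
}
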
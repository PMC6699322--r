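# Convert real-valued detection maps into binary lesion masks. Two global
# thresholders operate on a quantized gray-level image: the co-occurrence
# local-entropy criterion and Otsu's between-class variance baseline.
# Foreground is "strictly above the threshold" (lesions are high response),
# and argmax ties break toward the smaller threshold (more inclusive mask).

#' Quantize a real-valued map to integer gray levels
#'
#' Linear min-max mapping onto `{0, ..., G-1}` (order preserving). The
#' source range is kept so levels can be mapped back to response values.
#'
#' @param map a `detection_map` or numeric array/matrix; must not be
#'   constant.
#' @param G number of gray levels (>= 2; default 256).
#' @return A `quantized_image`: list with integer `data`, `G`, `range`.
#' @export
quantize <- function(map, G = 256L) {
  arr <- if (inherits(map, "detection_map")) map$data else map
  if (!is.numeric(arr)) stop_ivim("`map` must be numeric.")
  if (G < 2L) stop_ivim("`G` must be >= 2.")
  rng <- range(arr)
  if (!all(is.finite(rng))) stop_ivim("`map` contains non-finite values.")
  if (rng[1L] == rng[2L])
    stop_ivim("Constant map: degenerate histogram, nothing to threshold.")
  q <- as.integer(round((arr - rng[1L]) / (rng[2L] - rng[1L]) * (G - 1L)))
  structure(list(data = array(q, dim(arr) %||% length(arr)), G = as.integer(G),
                 range = rng),
            class = "quantized_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_quantized <- function(img) {
  if (!inherits(img, "quantized_image"))
    stop_ivim("Expected a `quantized_image` (see quantize()).")
  if (length(unique(as.vector(img$data))) < 2L)
    stop_ivim("Constant image: nothing to threshold.")
  invisible(img)
}

# Symmetric gray-level co-occurrence matrix over horizontal and vertical
# 4-neighbor adjacencies, counted in both directions. 3-D images contribute
# in-plane adjacencies from every slice.
cooccurrence_matrix <- function(img) {
  G <- img$G
  arr <- img$data
  if (is.null(dim(arr))) dim(arr) <- c(length(arr), 1L)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop_ivim("Thresholding expects a 2-D slice or 3-D map, got a ",
              length(dim(arr)), "-D array.")
  M <- matrix(0, G, G)
  tab <- function(a, b) {
    t2 <- table(factor(a, levels = 0:(G - 1L)),
                factor(b, levels = 0:(G - 1L)))
    matrix(as.numeric(t2), G, G)
  }
  for (s in seq_len(dim(arr)[3L])) {
    m <- arr[, , s]
    nr <- nrow(m); nc <- ncol(m)
    if (nr > 1L) {
      a <- m[-nr, , drop = FALSE]; b <- m[-1L, , drop = FALSE]
      M <- M + tab(a, b)
    }
    if (nc > 1L) {
      a <- m[, -nc, drop = FALSE]; b <- m[, -1L, drop = FALSE]
      M <- M + tab(a, b)
    }
  }
  M <- M + t(M)  # both directions
  M
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Local-entropy threshold from the co-occurrence matrix
#'
#' Builds the symmetric gray-level co-occurrence matrix over 4-neighbor
#' adjacencies, and for each candidate threshold `t` partitions it into
#' quadrants. The local entropy criterion is the sum of the Shannon
#' entropies of the background-background quadrant (levels `<= t` on both
#' axes) and the foreground-foreground quadrant (levels `> t` on both axes),
#' each renormalized to a probability distribution. The threshold maximizing
#' the criterion is returned (smallest level on ties), with the mask
#' `img > t`.
#'
#' @param img a `quantized_image`.
#' @return List with `threshold` (gray level), `mask` (logical array),
#'   `criterion` (per-candidate values, `NA` where a quadrant is empty).
#' @export
local_entropy_threshold <- function(img) {
  check_quantized(img)
  M <- cooccurrence_matrix(img)
  if (sum(M > 0) < 2L)
    stop_ivim("Degenerate co-occurrence matrix (single occupied cell).")
  G <- img$G
  # cumulative quadrant sums of m and m*log(m) via 2-D prefix sums
  Mlog <- M * ifelse(M > 0, log(M), 0)
  ps <- apply(apply(M, 2L, cumsum), 1L, cumsum)     # ps[j, i] = sum M[1..i, 1..j]
  pl <- apply(apply(Mlog, 2L, cumsum), 1L, cumsum)
  tot_s <- ps[G, G]; tot_l <- pl[G, G]
  crit <- rep(NA_real_, G - 1L)
  for (t in seq_len(G - 1L)) {        # threshold level t-1 (0-based)
    sBB <- ps[t, t]; lBB <- pl[t, t]
    sFF <- tot_s - ps[G, t] - ps[t, G] + ps[t, t]
    lFF <- tot_l - pl[G, t] - pl[t, G] + pl[t, t]
    if (sBB > 0 && sFF > 0)
      crit[t] <- (log(sBB) - lBB / sBB) + (log(sFF) - lFF / sFF)
  }
  if (all(is.na(crit)))
    stop_ivim("No admissible threshold: a co-occurrence quadrant is always ",
              "empty.")
  thr <- which.max(crit) - 1L         # which.max takes the first (smallest) max
  list(threshold = thr, mask = img$data > thr, criterion = crit)
}

#' Otsu threshold (between-class variance)
#'
#' Exhaustively maximizes `w0 w1 (mu0 - mu1)^2` over all candidate
#' thresholds of the gray-level histogram; smallest level on ties; mask is
#' `img > t`.
#'
#' @param img a `quantized_image`.
#' @return List with `threshold`, `mask`, `criterion`.
#' @export
otsu_threshold <- function(img) {
  check_quantized(img)
  G <- img$G
  h <- tabulate(as.vector(img$data) + 1L, nbins = G)
  p <- h / sum(h)
  lev <- 0:(G - 1L)
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[G]
  crit <- rep(NA_real_, G - 1L)
  for (t in seq_len(G - 1L)) {
    if (w0[t] > 0 && w0[t] < 1) {
      m0 <- mu[t] / w0[t]
      m1 <- (mu_t - mu[t]) / (1 - w0[t])
      crit[t] <- w0[t] * (1 - w0[t]) * (m0 - m1)^2
    }
  }
  if (all(is.na(crit))) stop_ivim("Constant image: nothing to threshold.")
  thr <- which.max(crit) - 1L
  list(threshold = thr, mask = img$data > thr, criterion = crit)
}

#' Threshold a detection map into a binary lesion mask
#'
#' Convenience wrapper: quantize to `G` levels and apply the selected
#' thresholder. A `manual` threshold (on the quantized scale) overrides the
#' automatic criterion.
#'
#' @param map a `detection_map` or numeric array.
#' @param method `"local_entropy"` (default) or `"otsu"`.
#' @param G quantization levels.
#' @param manual optional integer gray level to threshold at instead.
#' @return List with `mask`, `threshold` (gray level), `threshold_value`
#'   (back on the map's scale), `method`.
#' @export
threshold_map <- function(map, method = c("local_entropy", "otsu"),
                          G = 256L, manual = NULL) {
  method <- match.arg(method)
  img <- quantize(map, G)
  if (!is.null(manual)) {
    thr <- as.integer(manual)
    res <- list(threshold = thr, mask = img$data > thr)
    method <- "manual"
  } else {
    res <- switch(method,
                  local_entropy = local_entropy_threshold(img),
                  otsu = otsu_threshold(img))
  }
  tv <- img$range[1L] +
    res$threshold / (img$G - 1L) * (img$range[2L] - img$range[1L])
  list(mask = res$mask, threshold = res$threshold, threshold_value = tv,
       method = method)
}
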
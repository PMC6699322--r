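# Automatic breast-region extraction from a single slice. The sequence is:
# high-pass boundary enhancement, Sobel gradient (contour diagnostic),
# optional midline (sternum) exclusion, Otsu binarization, morphological
# opening with a 2x2 structuring element, largest connected component, and
# a Sobel contour of the final mask. The 2x2 opening and the 8-connected
# labeling are implemented here because the structuring element is
# even-sized (off-center) and needs shift-consistent handling.

laplacian_sharpen <- function(img) {
  k <- matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3L, 3L)
  EBImage::filter2(img, k, boundary = "replicate")
}

sobel_magnitude <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L, byrow = TRUE)
  gx <- EBImage::filter2(img, kx, boundary = "replicate")
  gy <- EBImage::filter2(img, t(kx), boundary = "replicate")
  sqrt(gx^2 + gy^2)
}

# binary erosion/dilation with a 2x2 structuring element anchored at its
# top-left pixel, so that opening keeps the mask inside the original
shift_pad <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

erode22 <- function(m) {
  m & shift_pad(m, 1L, 0L, FALSE) & shift_pad(m, 0L, 1L, FALSE) &
    shift_pad(m, 1L, 1L, FALSE)
}

dilate22 <- function(m) {
  m | shift_pad(m, -1L, 0L, FALSE) | shift_pad(m, 0L, -1L, FALSE) |
    shift_pad(m, -1L, -1L, FALSE)
}

open22 <- function(m) dilate22(erode22(m))

# 8-connected component labeling (iterative scan-and-propagate; images here
# are a few thousand pixels, so simplicity wins over speed)
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      r <- (i - 1L) %% nr + 1L
      c_ <- (i - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c_ + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        j <- (cc - 1L) * nr + rr
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

largest_component8 <- function(mask) {
  lab <- label_components8(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

#' Extract the breast region from a slice
#'
#' Runs the automatic extraction sequence: Laplacian high-pass sharpening to
#' enhance the tissue-air boundary, Sobel gradient (returned as a
#' diagnostic), optional exclusion of a vertical midline strip (a stand-in
#' for hit-or-miss sternum removal on bilateral acquisitions; off by
#' default), Otsu binarization of the sharpened image, morphological opening
#' with a 2 x 2 structuring element to detach thin bridges, retention of the
#' largest 8-connected component, and a Sobel contour of the final mask.
#'
#' The mask is invariant to adding a constant offset to the input: every
#' step after the (offset-preserving) sharpening is contrast-based.
#'
#' @param img numeric matrix, one image slice (non-constant).
#' @param midline_exclude `NULL` (default) or the half-width in pixels of a
#'   vertical strip centered on the image midline to suppress before
#'   binarization.
#' @param G gray levels used for the Otsu step.
#' @return List with `mask` (logical matrix, single 8-connected component),
#'   `contour` (logical matrix), `gradient` (Sobel magnitude of the input),
#'   `threshold` (Otsu gray level).
#' @export
extract_breast_region <- function(img, midline_exclude = NULL, G = 256L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop_ivim("`img` must be a numeric matrix (one slice).")
  if (max(img) == min(img))
    stop_ivim("Constant slice: no breast region found.")
  enhanced <- laplacian_sharpen(img)
  gradient <- sobel_magnitude(img)
  work <- enhanced
  if (!is.null(midline_exclude)) {
    mid <- (ncol(work) + 1) / 2
    cols <- which(abs(seq_len(ncol(work)) - mid) <= midline_exclude)
    work[, cols] <- min(work)
  }
  ot <- otsu_threshold(quantize(work, G))
  binary <- matrix(ot$mask, nrow(img), ncol(img))
  opened <- open22(binary)
  if (!any(opened)) stop_ivim("No breast region found after opening.")
  mask <- largest_component8(opened)
  contour <- sobel_magnitude(mask * 1) > 0 & mask
  list(mask = mask, contour = contour, gradient = gradient,
       threshold = ot$threshold)
}

#' Integer-shift alignment of a cube across b-values
#'
#' Aligns every b-volume to the first one by the integer in-plane shift (up
#' to `max_shift` pixels per axis) maximizing normalized cross-correlation,
#' a deliberately simple rigid registration for respiration-type drift.
#'
#' @param cube an `ivim_cube`.
#' @param max_shift maximum shift searched per axis (pixels).
#' @return List with the aligned `cube` and a tibble `shifts`
#'   (`b`, `dr`, `dc`).
#' @export
align_cube <- function(cube, max_shift = 5L) {
  stopifnot(inherits(cube, "ivim_cube"))
  arr <- cube$data
  d <- dim(arr)
  ref <- arr[, , , 1L, drop = FALSE]
  shifts <- tibble(b = cube$bvalues, dr = 0L, dc = 0L)
  ncc <- function(a, b) {
    a <- a - mean(a); b <- b - mean(b)
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) 0 else sum(a * b) / den
  }
  shift_vol <- function(v, dr, dc) {
    out <- array(0, dim(v))
    for (s in seq_len(dim(v)[3L]))
      out[, , s] <- shift_pad(v[, , s], -dr, -dc, 0)
    out
  }
  for (k in seq_len(d[4L])[-1L]) {
    vol <- arr[, , , k]
    if (length(dim(vol)) == 2L) dim(vol) <- c(d[1:2], 1L)
    best <- c(0L, 0L); best_v <- -Inf
    for (dr in -max_shift:max_shift) for (dc in -max_shift:max_shift) {
      v <- ncc(as.vector(shift_vol(vol, dr, dc)), as.vector(ref))
      if (v > best_v) { best_v <- v; best <- c(dr, dc) }
    }
    shifts$dr[k] <- best[1L]; shifts$dc[k] <- best[2L]
    arr[, , , k] <- shift_vol(vol, best[1L], best[2L])
  }
  list(cube = ivim_cube(arr, cube$bvalues), shifts = shifts)
}
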
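#' Reference tissue parameter table
#'
#' Mean biexponential IVIM parameters for the four breast tissue classes the
#' package models: central tumor, peripheral tumor, cyst and normal
#' fibroglandular tissue. Diffusivities are in 1e-3 mm^2/s, the perfusion
#' fraction is dimensionless, and `s0` is the unit-free baseline (b = 0)
#' signal used by the phantom (air is 0; lesions are brighter than normal
#' tissue, mimicking T2 shine-through on DWI).
#'
#' @return A tibble with columns `tissue`, `d`, `dstar`, `pf`, `s0`.
#' @examples
#' default_tissue_table()
#' @export
default_tissue_table <- function() {
  tibble(
    tissue = c("tumor_central", "tumor_peripheral", "cyst", "normal"),
    d      = c(0.76, 0.93, 1.59, 1.14),
    dstar  = c(9.38, 9.02, 4.62, 5.98),
    pf     = c(0.215, 0.253, 0.411, 0.311),
    s0     = c(110, 110, 130, 100)
  )
}

# Integer coding shared by phantoms and classification output.
tissue_levels <- function() {
  c(background = 0L, normal = 1L, cyst = 2L, tumor_central = 3L,
    tumor_peripheral = 4L, other = 5L)
}

#' Describe an elliptical lesion for the phantom
#'
#' @param tissue tissue name; must appear in the phantom's tissue table.
#' @param center `(row, col)` ellipse center in pixels (pixel centers are at
#'   integer coordinates, 1-based in R).
#' @param axes `(row, col)` semi-axes in pixels.
#' @param slices slice indices the lesion spans.
#' @return A `phantom_lesion` list.
#' @export
phantom_lesion <- function(tissue, center, axes, slices) {
  stopifnot(is.character(tissue), length(tissue) == 1L,
            length(center) == 2L, length(axes) == 2L)
  if (any(axes <= 0)) stop_ivim("Lesion semi-axes must be positive.")
  structure(list(tissue = tissue, center = as.numeric(center),
                 axes = as.numeric(axes), slices = as.integer(slices)),
            class = "phantom_lesion")
}

#' Specify a digital IVIM phantom
#'
#' The phantom is an elliptical "body" of normal tissue in an air background,
#' containing elliptical lesions. Each pixel's noiseless signal across b
#' follows the biexponential IVIM decay of its tissue class; optional Rician
#' noise and a multiplicative polynomial bias field emulate magnitude-MRI
#' artifacts.
#'
#' @param rows,cols,slices grid shape.
#' @param bvalues b-value schedule (s/mm^2), strictly increasing from 0.
#' @param body list with `center` `(row, col)` and `axes` `(row, col)`
#'   semi-axes of the body ellipse (same on every slice).
#' @param lesions list of [phantom_lesion()] objects. Lesions of different
#'   tissues may be strictly nested (the inner one wins, which is how the
#'   default tumor gets its central core inside the peripheral rim) but any
#'   partial overlap is an error.
#' @param tissues tissue table as in [default_tissue_table()]; must contain
#'   `normal` plus every lesion tissue.
#' @param sigma Rician noise level in the same unit as `s0` (0 = noiseless).
#' @param bias optional per-slice bias field: list with `coef`, named numeric
#'   coefficients of a low-order 2-D polynomial in normalized coordinates
#'   u, v in [-1, 1] (names among `"u"`, `"v"`, `"uu"`, `"uv"`, `"vv"`);
#'   the multiplier is `1 + sum(coef * term)`. `NULL` disables it.
#' @param seed integer seed making the phantom a pure function of the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(rows = 64L, cols = 64L, slices = 3L,
                         bvalues = default_bvalues(),
                         body = list(center = c((rows + 1) / 2, (cols + 1) / 2),
                                     axes = c(rows * 0.42, cols * 0.45)),
                         lesions = list(),
                         tissues = default_tissue_table(),
                         sigma = 0, bias = NULL, seed = 1L) {
  validate_bvalues(bvalues, require_zero = TRUE, min_len = 2L)
  check_number(sigma, "sigma", min = 0)
  stopifnot(rows >= 4L, cols >= 4L, slices >= 1L)
  if (!all(c("tissue", "d", "dstar", "pf", "s0") %in% names(tissues)))
    stop_ivim("`tissues` must have columns tissue, d, dstar, pf, s0.")
  if (!"normal" %in% tissues$tissue)
    stop_ivim("`tissues` must contain a 'normal' row for the body.")
  validate_tissue_params(tissues)
  for (les in lesions) {
    if (!inherits(les, "phantom_lesion"))
      stop_ivim("Every lesion must be built with phantom_lesion().")
    if (!les$tissue %in% tissues$tissue)
      stop_ivim("Lesion tissue '", les$tissue, "' missing from tissue table.")
    if (any(les$slices < 1L) || any(les$slices > slices))
      stop_ivim("Lesion '", les$tissue, "' spans slices outside the grid.")
    inside <- ellipse_mask(rows, cols, les$center, les$axes) &
      !ellipse_mask(rows, cols, body$center, body$axes)
    if (any(inside))
      stop_ivim("Lesion '", les$tissue, "' lies partly outside the body ",
                "ellipse.")
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 slices = as.integer(slices), bvalues = as.numeric(bvalues),
                 body = body, lesions = lesions, tissues = tissues,
                 sigma = sigma, bias = bias, seed = seed),
            class = "phantom_spec")
}

validate_tissue_params <- function(tissues) {
  with(tissues, {
    if (any(d <= 0)) stop_ivim("Tissue D must be > 0.")
    if (any(pf < 0 | pf > 1)) stop_ivim("Tissue PF must lie in [0, 1].")
    if (any(s0 <= 0)) stop_ivim("Tissue S0 must be > 0.")
    if (any(dstar < d))
      warn(paste("Tissue table has D* < D for:",
                 paste(tissue[dstar < d], collapse = ", ")))
  })
  invisible(tissues)
}

#' The seeded reference phantom used in examples and tests
#'
#' A 64 x 64 x 3 body of normal tissue containing a two-zone tumor (central
#' core nested in a peripheral rim) and a cyst, at the default tissue
#' parameters.
#'
#' @param sigma Rician noise level (default 0 = noiseless; `2` corresponds
#'   to SNR 50 at the normal-tissue baseline of 100).
#' @param seed integer seed.
#' @param bias optional bias field passed through to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
reference_phantom_spec <- function(sigma = 0, seed = 1L, bias = NULL) {
  phantom_spec(
    rows = 64L, cols = 64L, slices = 3L,
    lesions = list(
      phantom_lesion("tumor_peripheral", center = c(24, 26), axes = c(9, 8),
                     slices = 1:3),
      phantom_lesion("tumor_central", center = c(24, 26), axes = c(4.5, 4),
                     slices = 1:3),
      phantom_lesion("cyst", center = c(44, 40), axes = c(6, 7), slices = 1:3)
    ),
    sigma = sigma, bias = bias, seed = seed
  )
}

# Pixel-center rasterization of an ellipse; a pixel belongs iff its center
# lies inside.
ellipse_mask <- function(rows, cols, center, axes) {
  r <- matrix(seq_len(rows), rows, cols)
  c_ <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  ((r - center[1L]) / axes[1L])^2 + ((c_ - center[2L]) / axes[2L])^2 <= 1
}

#' Generate a synthetic IVIM cube with known ground truth
#'
#' Rasterizes the phantom geometry, evaluates the biexponential decay of
#' each pixel's tissue at every b-value, applies the optional bias field and
#' Rician noise, and returns the cube together with the label map and
#' ground-truth parameter maps. Identical spec (including seed) reproduces
#' the cube bit for bit.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{cube}{`ivim_cube`, the (possibly noisy) signal stack.}
#'     \item{labels}{`tissue_labels` ground-truth label map.}
#'     \item{truth}{`param_maps` holding per-pixel generating D, D*, PF plus
#'       the ADC and slope implied by the noiseless decay sampled on the
#'       phantom's b schedule.}
#'     \item{spec}{the input spec.}
#'   }
#' @examples
#' ph <- generate_phantom(reference_phantom_spec())
#' table(tidy(ph$labels)$tissue)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d3 <- c(spec$rows, spec$cols, spec$slices)
  lab2 <- lapply(seq_len(spec$slices), function(s) {
    m <- matrix("background", spec$rows, spec$cols)
    m[ellipse_mask(spec$rows, spec$cols, spec$body$center,
                   spec$body$axes)] <- "normal"
    m
  })
  les_masks <- lapply(spec$lesions, function(l)
    ellipse_mask(spec$rows, spec$cols, l$center, l$axes))
  check_lesion_overlaps(spec$lesions, les_masks)
  # paint larger lesions first so a strictly nested lesion overrides its host
  if (length(spec$lesions)) {
    ord <- order(vapply(les_masks, sum, numeric(1L)), decreasing = TRUE)
    for (i in ord) {
      l <- spec$lesions[[i]]
      for (s in l$slices) lab2[[s]][les_masks[[i]]] <- l$tissue
    }
  }
  labels <- array(unlist(lab2), dim = d3)

  tt <- spec$tissues
  lookup <- function(colname, default = NA_real_) {
    v <- setNames(tt[[colname]], tt$tissue)
    out <- unname(v[labels])
    out[labels == "background"] <- default
    array(out, d3)
  }
  d_map <- lookup("d"); dstar_map <- lookup("dstar")
  pf_map <- lookup("pf"); s0_map <- lookup("s0", default = 0)

  nb <- length(spec$bvalues)
  arr <- array(0, c(d3, nb))
  body <- labels != "background"
  for (k in seq_len(nb)) {
    rel <- array(1, d3)
    rel[body] <- biexp_signal(d_map[body], dstar_map[body], pf_map[body],
                              spec$bvalues[k])
    arr[, , , k] <- s0_map * rel
  }
  if (!is.null(spec$bias)) arr <- apply_bias_field(arr, spec$bias)
  cube <- ivim_cube(arr, spec$bvalues)
  if (spec$sigma > 0)
    cube <- add_rician_noise(cube, spec$sigma, seed = spec$seed)

  # ADC and slope implied by the (noiseless, unbiased) decay on this schedule
  rel_tt <- vapply(seq_len(nrow(tt)),
                   function(i) biexp_signal(tt$d[i], tt$dstar[i], tt$pf[i],
                                            spec$bvalues),
                   numeric(nb))
  adc_tt <- apply(rel_tt, 2L, function(s) fit_adc(s, spec$bvalues))
  slope_tt <- apply(rel_tt, 2L, function(s) fit_slope(s, spec$bvalues))
  lookup_vec <- function(vals) {
    v <- setNames(vals, tt$tissue)
    out <- unname(v[labels]); out[labels == "background"] <- NA_real_
    array(out, d3)
  }
  truth <- new_param_maps(adc = lookup_vec(adc_tt), slope = lookup_vec(slope_tt),
                          d = d_map, dstar = dstar_map, pf = pf_map,
                          valid = body)
  list(cube = cube,
       labels = new_tissue_labels(labels),
       truth = truth,
       spec = spec)
}

check_lesion_overlaps <- function(lesions, masks) {
  n <- length(lesions)
  if (n < 2L) return(invisible())
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    li <- lesions[[i]]; lj <- lesions[[j]]
    if (li$tissue == lj$tissue) next
    if (!length(intersect(li$slices, lj$slices))) next
    both <- masks[[i]] & masks[[j]]
    if (!any(both)) next
    nested <- all(masks[[i]][masks[[j]]]) || all(masks[[j]][masks[[i]]])
    if (!nested)
      stop_ivim("Lesions '", li$tissue, "' and '", lj$tissue,
                "' partially overlap; only strict nesting is allowed.")
  }
  invisible()
}

apply_bias_field <- function(arr, bias) {
  d <- dim(arr)
  u <- matrix(seq(-1, 1, length.out = d[1L]), d[1L], d[2L])
  v <- matrix(seq(-1, 1, length.out = d[2L]), d[1L], d[2L], byrow = TRUE)
  terms <- list(u = u, v = v, uu = u * u, uv = u * v, vv = v * v)
  mult <- matrix(1, d[1L], d[2L])
  for (nm in names(bias$coef)) {
    if (!nm %in% names(terms))
      stop_ivim("Unknown bias term '", nm, "'.")
    mult <- mult + bias$coef[[nm]] * terms[[nm]]
  }
  if (any(mult <= 0)) stop_ivim("Bias field multiplier must stay positive.")
  arr * as.vector(mult)  # recycled over slices and b-volumes
}

#' Add Rician noise to a cube
#'
#' Magnitude MRI reconstructs `sqrt((S + n1)^2 + n2^2)` with `n1`, `n2`
#' independent zero-mean Gaussians of standard deviation `sigma`; the output
#' is therefore nonnegative and positively biased at low SNR. Noise is drawn
#' independently for every pixel of every b-value volume.
#'
#' @param cube an `ivim_cube`.
#' @param sigma noise standard deviation (>= 0); 0 returns the input.
#' @param seed integer seed; the caller's RNG state is preserved.
#' @return A noisy `ivim_cube`.
#' @export
add_rician_noise <- function(cube, sigma, seed = NULL) {
  stopifnot(inherits(cube, "ivim_cube"))
  check_number(sigma, "sigma", min = 0)
  if (sigma == 0) return(cube)
  arr <- cube$data
  noisy <- with_seed(seed, {
    n1 <- array(rnorm(length(arr), sd = sigma), dim(arr))
    n2 <- array(rnorm(length(arr), sd = sigma), dim(arr))
    sqrt((arr + n1)^2 + n2^2)
  })
  ivim_cube(noisy, cube$bvalues)
}
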
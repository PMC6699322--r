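#' Multi-b-value IVIM image cube
#'
#' An `ivim_cube` holds one case's diffusion-weighted stack as a 4-D array
#' `rows x cols x slices x b` together with its b-value schedule in s/mm^2.
#' The schedule must be strictly increasing and, for normalized fitting,
#' start at b = 0. A 3-D array is promoted to a single-slice cube.
#'
#' @param data numeric array, `rows x cols x slices x length(bvalues)`
#'   (or `rows x cols x length(bvalues)` for a single slice).
#' @param bvalues strictly increasing numeric vector of b-values (s/mm^2).
#' @return An object of class `ivim_cube` with elements `data` and `bvalues`.
#' @examples
#' arr <- array(runif(4 * 4 * 1 * 3, 50, 100), c(4, 4, 1, 3))
#' cube <- ivim_cube(arr, c(0, 500, 1000))
#' dim(cube$data)
#' @export
ivim_cube <- function(data, bvalues) {
  if (!is.numeric(data)) stop_ivim("`data` must be a numeric array.")
  if (length(dim(data)) == 3L)
    dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3L])
  if (length(dim(data)) != 4L)
    stop_ivim("`data` must be a 4-D array (rows x cols x slices x b).")
  bvalues <- as.numeric(bvalues)
  validate_bvalues(bvalues, require_zero = FALSE)
  if (dim(data)[4L] != length(bvalues))
    stop_ivim("Cube has ", dim(data)[4L], " volumes but ", length(bvalues),
              " b-values.")
  structure(list(data = data, bvalues = bvalues), class = "ivim_cube")
}

validate_bvalues <- function(b, require_zero = TRUE, min_len = 1L) {
  if (!is.numeric(b) || length(b) < min_len || anyNA(b))
    stop_ivim("b-value schedule must be numeric with >= ", min_len,
              " finite values.")
  if (any(b < 0)) stop_ivim("b-values must be >= 0.")
  if (anyDuplicated(b)) stop_ivim("Duplicate b-values in schedule.")
  if (is.unsorted(b, strictly = TRUE))
    stop_ivim("b-values must be strictly increasing.")
  if (require_zero && b[1L] != 0)
    stop_ivim("b-value schedule must start at b = 0 for normalized fits.")
  invisible(b)
}

#' The 12-b-value acquisition schedule used throughout the package
#'
#' Breast IVIM protocols sample the decay curve densely at low b (where
#' perfusion dominates) and sparsely at high b. The default schedule is
#' b = 0, 15, 30, 45, 60, 100, 250, 400, 550, 700, 850, 1000 s/mm^2.
#'
#' @return Numeric vector of 12 b-values (s/mm^2).
#' @export
default_bvalues <- function() {
  c(0, 15, 30, 45, 60, 100, 250, 400, 550, 700, 850, 1000)
}

#' @export
print.ivim_cube <- function(x, ...) {
  d <- dim(x$data)
  cat("<ivim_cube> ", d[1L], " x ", d[2L], " x ", d[3L], " spatial, ",
      d[4L], " b-values (", min(x$bvalues), "-", max(x$bvalues),
      " s/mm^2)\n", sep = "")
  invisible(x)
}

# N x M pixel matrix view of a cube-like object (ivim_cube, band_cube or a
# bare 3-/4-D array); rows are pixels in column-major spatial order.
as_pixel_matrix <- function(x) {
  arr <- cube_array(x)
  d <- dim(arr)
  matrix(arr, nrow = prod(d[1:3]), ncol = d[4L])
}

cube_array <- function(x) {
  arr <- if (inherits(x, c("ivim_cube", "band_cube"))) x$data else x
  if (!is.numeric(arr)) stop_ivim("Expected a numeric cube.")
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr)[1:2], 1L, dim(arr)[3L])
  if (length(dim(arr)) != 4L) stop_ivim("Expected a 3-D or 4-D array.")
  arr
}

cube_spatial_dim <- function(x) dim(cube_array(x))[1:3]

#' Tidy a cube into a long pixel table
#'
#' @param x an `ivim_cube`.
#' @param ... unused.
#' @return A tibble with one row per pixel per b-value: `row`, `col`,
#'   `slice`, `b`, `signal`.
#' @export
tidy.ivim_cube <- function(x, ...) {
  d <- dim(x$data)
  sp <- spatial_index(d[1:3])
  tidyr::crossing(sp, b = x$bvalues) |>
    dplyr::arrange(.data$pixel, .data$b) |>
    dplyr::mutate(signal = as.vector(aperm(x$data, c(4L, 1L, 2L, 3L)))) |>
    dplyr::select(-"pixel")
}

#' Read / write an IVIM cube as NIfTI plus a b-value sidecar
#'
#' The cube is stored as 4-D NIfTI with the 4th axis indexing b, and the
#' schedule as JSON (`{"bvalues": [...]}`). If the sidecar schedule is
#' unsorted the volumes are permuted consistently so the in-memory cube is
#' always ordered by increasing b.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param bvals_path JSON sidecar path; defaults to `path` with the NIfTI
#'   extension replaced by `_bvals.json`.
#' @return `read_ivim_cube()` returns an `ivim_cube`; `write_ivim_cube()`
#'   returns `path` invisibly.
#' @export
read_ivim_cube <- function(path, bvals_path = NULL) {
  if (is.null(bvals_path)) bvals_path <- sidecar_path(path)
  if (!file.exists(path)) stop_ivim("Cube file not found: ", path)
  if (!file.exists(bvals_path)) stop_ivim("b-value sidecar not found: ",
                                          bvals_path)
  arr <- as.array(RNifti::readNifti(path))
  b <- as.numeric(jsonlite::fromJSON(bvals_path)$bvalues)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr)[1:2], 1L, dim(arr)[3L])
  if (dim(arr)[4L] != length(b))
    stop_ivim("File has ", dim(arr)[4L], " volumes but the sidecar lists ",
              length(b), " b-values.")
  ord <- order(b)
  ivim_cube(arr[, , , ord, drop = FALSE], b[ord])
}

#' @rdname read_ivim_cube
#' @param cube an `ivim_cube`.
#' @export
write_ivim_cube <- function(cube, path, bvals_path = NULL) {
  stopifnot(inherits(cube, "ivim_cube"))
  if (is.null(bvals_path)) bvals_path <- sidecar_path(path)
  RNifti::writeNifti(RNifti::asNifti(cube$data), path)
  jsonlite::write_json(list(bvalues = cube$bvalues), bvals_path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), "_bvals.json")
}

# Write a named list of 3-D maps as one NIfTI per map.
write_map_set <- function(maps, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(maps), function(nm) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]] * 1), p)
    p
  }, character(1L))
  invisible(paths)
}
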
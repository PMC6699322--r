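# Band expansion process (BEP): nonlinearly grow an L-band cube into
# correlated band images so that a 12-band IVIM stack can be treated as a
# hyperspectral cube. Only products of the original bands (second- and
# optionally third-order correlation terms) plus optional sqrt/log stretches
# are generated; band order is fixed by the manifest contract below.

# Enumerate the band manifest for an L-band input. Order contract:
#   original 1..L;
#   auto l^2 (l ascending);
#   cross k*l (k < l, lexicographic);
#   [order 3] cube l^3; cross2 k^2*l (ordered pairs k != l, lexicographic);
#              cross3 k*l*m (k < l < m, lexicographic);
#   sqrt bands; log bands.
band_manifest <- function(L, order = 2L, include_sqrt = FALSE,
                          include_log = FALSE) {
  stopifnot(L >= 1L, order %in% 1:3)
  rows <- list(tibble(type = "original", k = seq_len(L), l = NA_integer_,
                      m = NA_integer_))
  if (order >= 2L) {
    rows <- c(rows, list(tibble(type = "auto", k = seq_len(L),
                                l = NA_integer_, m = NA_integer_)))
    if (L >= 2L) {
      cc <- utils::combn(L, 2L)
      rows <- c(rows, list(tibble(type = "cross", k = cc[1L, ], l = cc[2L, ],
                                  m = NA_integer_)))
    }
  }
  if (order >= 3L) {
    rows <- c(rows, list(tibble(type = "cube", k = seq_len(L),
                                l = NA_integer_, m = NA_integer_)))
    if (L >= 2L) {
      pr <- expand.grid(l = seq_len(L), k = seq_len(L))[, 2:1]
      pr <- pr[pr$k != pr$l, , drop = FALSE]
      pr <- pr[order(pr$k, pr$l), , drop = FALSE]
      rows <- c(rows, list(tibble(type = "cross2", k = pr$k, l = pr$l,
                                  m = NA_integer_)))
    }
    if (L >= 3L) {
      cc3 <- utils::combn(L, 3L)
      rows <- c(rows, list(tibble(type = "cross3", k = cc3[1L, ],
                                  l = cc3[2L, ], m = cc3[3L, ])))
    }
  }
  if (include_sqrt)
    rows <- c(rows, list(tibble(type = "sqrt", k = seq_len(L),
                                l = NA_integer_, m = NA_integer_)))
  if (include_log)
    rows <- c(rows, list(tibble(type = "log", k = seq_len(L),
                                l = NA_integer_, m = NA_integer_)))
  man <- dplyr::bind_rows(rows)
  man$band <- seq_len(nrow(man))
  man$tag <- with(man, ifelse(type %in% c("cross", "cross2"),
                              paste0(type, "(", k, ",", l, ")"),
                       ifelse(type == "cross3",
                              paste0("cross3(", k, ",", l, ",", m, ")"),
                              paste0(type, "(", k, ")"))))
  man[, c("band", "type", "k", "l", "m", "tag")]
}

#' Number of bands the expansion process produces
#'
#' Closed-form count of the manifest [expand_bands()] emits:
#' `L` originals; order 2 adds `L` auto plus `choose(L, 2)` cross bands;
#' order 3 further adds `L` cubes, `L (L - 1)` ordered two-band products
#' `k^2 l` and `choose(L, 3)` three-band products; each enabled stretch adds
#' `L` more. A 12-band cube at order 2 expands to 90 bands.
#'
#' @param L number of original bands (>= 1).
#' @param order highest correlation order, 1, 2 or 3.
#' @param include_sqrt,include_log whether the nonlinear stretches are added.
#' @return Integer band count.
#' @examples
#' band_count(12, 2)  # 90
#' @export
band_count <- function(L, order = 2L, include_sqrt = FALSE,
                       include_log = FALSE) {
  stopifnot(L >= 1L, order %in% 1:3)
  n <- L
  if (order >= 2L) n <- n + L + choose(L, 2L)
  if (order >= 3L) n <- n + L + L * (L - 1L) + choose(L, 3L)
  as.integer(n + (include_sqrt + include_log) * L)
}

#' Expand a cube into correlated band images
#'
#' Generates the second- (and optionally third-) order correlated bands of
#' the input cube -- elementwise squares and cross-products of band images --
#' plus optional square-root and log stretches, in the deterministic order
#' described under [band_count()]. When `normalize = TRUE`, each correlated
#' band is divided by the product of its source bands' standard deviations
#' (counting multiplicity), the conventional variance rescaling; stretches
#' are never rescaled.
#'
#' @param cube an `ivim_cube`, `band_cube`, or 3-/4-D numeric array.
#' @param order highest correlation order (1, 2 or 3).
#' @param include_sqrt add `sqrt(B_l)` bands (requires nonnegative data).
#' @param include_log add log-stretched bands. With `log_offset = TRUE`
#'   (default) these are `log1p(B_l)`, defined for nonnegative data; with
#'   `log_offset = FALSE` they are `log(B_l)` and nonpositive pixels are an
#'   error.
#' @param normalize divide correlated bands by source-band SD products.
#' @param log_offset see `include_log`.
#' @return A `band_cube`: list with `data` (4-D array, spatial x M) and
#'   `manifest` (tibble `band`, `type`, `k`, `l`, `m`, `tag`).
#' @examples
#' ph <- generate_phantom(reference_phantom_spec())
#' bc <- expand_bands(ph$cube)
#' nrow(bc$manifest)  # 90
#' @export
expand_bands <- function(cube, order = 2L, include_sqrt = FALSE,
                         include_log = FALSE, normalize = FALSE,
                         log_offset = TRUE) {
  arr <- cube_array(cube)
  d3 <- dim(arr)[1:3]
  L <- dim(arr)[4L]
  man <- band_manifest(L, order, include_sqrt, include_log)
  X <- matrix(arr, ncol = L)            # N x L pixel view of the originals
  if (include_sqrt && any(X < 0))
    stop_ivim("sqrt stretch requires nonnegative band values.")
  if (include_log && !log_offset && any(X <= 0))
    stop_ivim("log stretch with log_offset = FALSE requires strictly ",
              "positive band values.")
  sds <- apply(X, 2L, sd)
  out <- matrix(0, nrow(X), nrow(man))
  for (i in seq_len(nrow(man))) {
    r <- man[i, ]
    v <- switch(r$type,
      original = X[, r$k],
      auto     = X[, r$k]^2,
      cross    = X[, r$k] * X[, r$l],
      cube     = X[, r$k]^3,
      cross2   = X[, r$k]^2 * X[, r$l],
      cross3   = X[, r$k] * X[, r$l] * X[, r$m],
      sqrt     = sqrt(X[, r$k]),
      log      = if (log_offset) log1p(X[, r$k]) else log(X[, r$k]))
    if (normalize) {
      nrm <- switch(r$type,
        auto   = sds[r$k]^2,
        cross  = sds[r$k] * sds[r$l],
        cube   = sds[r$k]^3,
        cross2 = sds[r$k]^2 * sds[r$l],
        cross3 = sds[r$k] * sds[r$l] * sds[r$m],
        1)
      if (nrm > 0) v <- v / nrm
    }
    out[, i] <- v
  }
  structure(list(data = array(out, c(d3, nrow(man))), manifest = man,
                 normalized = normalize),
            class = "band_cube")
}

#' @export
print.band_cube <- function(x, ...) {
  d <- dim(x$data)
  cat("<band_cube> ", d[1L], " x ", d[2L], " x ", d[3L], " spatial, ",
      d[4L], " bands (", paste(unique(x$manifest$type), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
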
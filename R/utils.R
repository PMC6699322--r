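# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library calls never disturb user code.
# seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

stop_ivim <- function(...) rlang::abort(paste0(...), class = "ivimhsi_error")

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ivim("`", name, "` must be a single finite number.")
  if (strict_min && x <= min)
    stop_ivim("`", name, "` must be > ", min, " (got ", x, ").")
  if (!strict_min && x < min)
    stop_ivim("`", name, "` must be >= ", min, " (got ", x, ").")
  if (x > max) stop_ivim("`", name, "` must be <= ", max, " (got ", x, ").")
  invisible(x)
}

# Row/col/slice index tibble for a 3-D spatial grid, pixel i in column-major
# order (rows fastest). The inverse of this ordering is used everywhere a
# pixel matrix is reshaped back into a cube.
spatial_index <- function(dim3) {
  idx <- arrayInd(seq_len(prod(dim3)), .dim = dim3)
  tibble(pixel = seq_len(nrow(idx)),
         row = idx[, 1L], col = idx[, 2L], slice = idx[, 3L])
}
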
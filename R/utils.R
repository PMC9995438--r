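# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library functions stay pure in their seed argument.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Voxel-center coordinates (mm) along each axis, origin at the volume center.
axis_coords_mm <- function(grid_shape, spacing) {
  lapply(1:3, function(i) {
    n <- grid_shape[i]
    (seq_len(n) - (n + 1) / 2) * spacing[i]
  })
}

# Full 3D coordinate arrays (mm), origin at the volume center.
coord_arrays_mm <- function(grid_shape, spacing) {
  ax <- axis_coords_mm(grid_shape, spacing)
  d <- grid_shape
  list(
    x = array(rep(ax[[1]], times = d[2] * d[3]), dim = d),
    y = array(rep(rep(ax[[2]], each = d[1]), times = d[3]), dim = d),
    z = array(rep(ax[[3]], each = d[1] * d[2]), dim = d)
  )
}

# n x 3 integer voxel coordinates -> linear indices (column-major).
coords_to_index <- function(coords, dim) {
  coords[, 1] + (coords[, 2] - 1L) * dim[1] + (coords[, 3] - 1L) * dim[1] * dim[2]
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok) stop(sprintf("`%s` must be %s", name,
                        if (strict) "strictly positive" else "non-negative"),
                call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
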
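#' @keywords internal
"_PACKAGE"

## Seed plumbing: one master seed fans out to named substreams so that the
## stages (events, noise, gaze, permutations) are independently reproducible.

# Deterministic 31-bit hash of a label string, mixed with the master seed.
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(master) * 2654435 + h) %% 2147483647)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# linear index <-> (i,j,k) helpers, 0-based grid indices internally
grid_to_linear <- function(ijk, dim) {
  ijk <- matrix(as.integer(ijk), ncol = 3L)
  1L + ijk[, 1L] + dim[1L] * (ijk[, 2L] + dim[2L] * ijk[, 3L])
}

linear_to_grid <- function(lin, dim) {
  lin0 <- as.integer(lin) - 1L
  i <- lin0 %% dim[1L]
  j <- (lin0 %/% dim[1L]) %% dim[2L]
  k <- lin0 %/% (dim[1L] * dim[2L])
  cbind(i = i, j = j, k = k)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}
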
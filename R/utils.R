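#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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

# Deterministic child seed for subject/replicate i, kept inside 32-bit range.
child_seed <- function(seed, i) {
  (as.integer(seed) %% 100000L) * 10000L + as.integer(i) %% 10000L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

# linear index (1-based) <-> (i,j,k) helpers for 3D arrays
ijk_to_lin <- function(ijk, dims) {
  (ijk[, 3L] - 1L) * dims[1L] * dims[2L] + (ijk[, 2L] - 1L) * dims[1L] + ijk[, 1L]
}

lin_to_ijk <- function(lin, dims) {
  lin0 <- lin - 1L
  k <- lin0 %/% (dims[1L] * dims[2L])
  rem <- lin0 %% (dims[1L] * dims[2L])
  cbind(i = rem %% dims[1L] + 1L, j = rem %/% dims[1L] + 1L, k = k + 1L)
}
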
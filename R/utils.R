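# Small internal vector helpers shared across the geometry code.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Orthonormal basis (e1, e2) spanning the plane normal to unit vector `ax`.
plane_basis <- function(ax) {
  ref <- if (abs(ax[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(ref - sum(ref * ax) * ax)
  e2 <- cross3(ax, e1)
  list(e1 = e1, e2 = e2)
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

# Evaluate `expr` with the global RNG seeded by `seed`, restoring the previous
# RNG state afterwards so generators do not perturb user simulations.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
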
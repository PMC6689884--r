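# Internal helpers shared across modules.

# Raise a classed condition so callers can distinguish error families
# (vgnp_parse_error, vgnp_packing_error, ...) without string matching.
vgnp_abort <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "vgnp_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
# Keeps package randomness (anchor placement, fold assignment, fixture
# noise) out of the user's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-item child seed from a base seed; stays below 2^31 - 1.
derive_seed <- function(base, index) {
  as.integer((as.numeric(base) * 48271 + as.numeric(index) * 104729) %%
               2147483647)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x)) {
    vgnp_abort(sprintf("`%s` must be a single finite number", name),
               "vgnp_domain_error")
  }
  if (positive && x <= 0) {
    vgnp_abort(sprintf("`%s` must be > 0 (got %g)", name, x),
               "vgnp_domain_error")
  }
  invisible(x)
}

# Rotation matrix taking unit vector `a` onto unit vector `b` (Rodrigues).
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {
    # antiparallel: rotate pi about any axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(a[2] * ref[3] - a[3] * ref[2],
            a[3] * ref[1] - a[1] * ref[3],
            a[1] * ref[2] - a[2] * ref[1])
    ax <- ax / sqrt(sum(ax^2))
    return(rotation_about(ax, pi))
  }
  K <- matrix(c(0, v[3], -v[2],
                -v[3], 0, v[1],
                v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + cth)
}

# Rotation matrix about unit axis `u` by angle `theta`.
rotation_about <- function(u, theta) {
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
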
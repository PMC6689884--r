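# Molecular lipophilicity potential (MLP) on the SAS, and the logG/R
# nanohydrophobicity statistic.
#
# Each SAS point x receives mlp(x) = sum_i f_i * w(||x - atom_i||) over
# atoms within the kernel cutoff, where f_i are the atomic logP
# contributions.  Positive mlp is hydrophobic ("green"), negative is
# hydrophilic ("red").  The particle-level statistic is
#   logG/R = log10( sum_x max(mlp, 0) / sum_x max(-mlp, 0) ).

#' Distance-weighting kernel for the lipophilicity potential
#'
#' Two classic MLP weighting traditions are available: the exponential
#' (Fauchere-type) kernel `w(d) = exp(-d / lambda)` and the hyperbolic
#' Audry kernel `w(d) = 1 / (1 + d)`.  Both satisfy `w(0) = 1` and are
#' monotone non-increasing; weights beyond `cutoff` are treated as zero.
#'
#' @param name `"exponential"` or `"audry"`.
#' @param lambda Decay length in Angstrom (exponential kernel only).
#' @param cutoff Distance beyond which atoms are ignored, Angstrom.
#' @return A `weighting_kernel` object.
#' @export
#' @examples
#' k <- weighting_kernel()
#' kernel_weight(k, c(0, 1.5))   # 1, exp(-1)
weighting_kernel <- function(name = c("exponential", "audry"),
                             lambda = 1.5, cutoff = 10) {
  name <- match.arg(name)
  stopifnot_scalar(lambda, "lambda", positive = TRUE)
  stopifnot_scalar(cutoff, "cutoff", positive = TRUE)
  structure(list(name = name, lambda = lambda, cutoff = cutoff),
            class = "weighting_kernel")
}

#' @rdname weighting_kernel
#' @param kernel A `weighting_kernel`.
#' @param d Numeric vector of distances, Angstrom.
#' @export
kernel_weight <- function(kernel, d) {
  w <- switch(kernel$name,
              exponential = exp(-d / kernel$lambda),
              audry = 1 / (1 + d))
  w[d >= kernel$cutoff] <- 0
  w
}

#' Lipophilicity potential at arbitrary points
#'
#' Direct summation of distance-weighted atomic contributions.  The
#' implicit core sphere carries `f = 0` and never contributes.
#'
#' @param points Numeric vector of length 3, or an n x 3 matrix.
#' @param vgnp A `vgnp` particle whose atoms carry contributions `f`.
#' @param kernel A [weighting_kernel()].
#' @return Numeric vector of mlp values, one per point.
#' @export
mlp_at_point <- function(points, vgnp, kernel = weighting_kernel()) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  stopifnot(ncol(points) == 3, inherits(vgnp, "vgnp"),
            inherits(kernel, "weighting_kernel"))
  a <- vgnp$atoms
  a <- a[a$f != 0, , drop = FALSE]
  vals <- numeric(nrow(points))
  if (nrow(a) == 0) return(vals)
  px <- points[, 1]; py <- points[, 2]; pz <- points[, 3]
  # cheap rejection: atoms farther than cutoff from the point cloud's box
  # cannot contribute
  cut <- kernel$cutoff
  inbox <- a$x > min(px) - cut & a$x < max(px) + cut &
    a$y > min(py) - cut & a$y < max(py) + cut &
    a$z > min(pz) - cut & a$z < max(pz) + cut
  a <- a[inbox, , drop = FALSE]
  for (k in seq_len(nrow(a))) {
    d <- sqrt((px - a$x[k])^2 + (py - a$y[k])^2 + (pz - a$z[k])^2)
    vals <- vals + a$f[k] * kernel_weight(kernel, d)
  }
  vals
}

#' Score a SAS with the lipophilicity potential
#'
#' Computes the per-point mlp and the hydrophobic / hydrophilic intensity
#' sums `I_G = sum(max(mlp, 0))` and `I_R = sum(max(-mlp, 0))`.
#'
#' @param sas A `sas_points` set (nonempty).
#' @param vgnp The particle the surface belongs to.
#' @param kernel A [weighting_kernel()].
#' @return A `scored_surface`: list with `points`, `mlp`, `i_g`, `i_r`.
#' @export
score_surface <- function(sas, vgnp, kernel = weighting_kernel()) {
  stopifnot(inherits(sas, "sas_points"))
  if (sas$n == 0) {
    vgnp_abort("empty SAS point set", "vgnp_domain_error")
  }
  mlp <- mlp_at_point(sas$points, vgnp, kernel)
  structure(list(points = sas$points, mlp = mlp,
                 i_g = sum(pmax(mlp, 0)), i_r = sum(pmax(-mlp, 0)),
                 kernel = kernel, grid = sas$grid),
            class = "scored_surface")
}

#' The logG/R nanohydrophobicity statistic
#'
#' `logG/R = log10(I_G / I_R)`, the base-10 log ratio of summed hydrophobic
#' to hydrophilic surface intensity.  A surface whose points are all of one
#' sign is degenerate: by default this is an error carrying both sums; with
#' `clamp = TRUE` the zero sum is replaced by `1e-6 * (I_G + I_R)` and a
#' warning is emitted.
#'
#' @param surface A `scored_surface`.
#' @param clamp Substitute a small epsilon for a zero intensity sum instead
#'   of failing.
#' @return The logG/R value.
#' @export
log_g_over_r <- function(surface, clamp = FALSE) {
  stopifnot(inherits(surface, "scored_surface"))
  i_g <- surface$i_g; i_r <- surface$i_r
  if (i_g == 0 && i_r == 0) {
    vgnp_abort("surface has zero total intensity (all mlp = 0)",
               "vgnp_degenerate_surface", i_g = i_g, i_r = i_r)
  }
  if (i_g == 0 || i_r == 0) {
    if (!clamp) {
      vgnp_abort(sprintf(
        "degenerate surface: I_G = %g, I_R = %g; one channel is empty (use clamp to substitute an epsilon)",
        i_g, i_r), "vgnp_degenerate_surface", i_g = i_g, i_r = i_r)
    }
    eps <- 1e-6 * (i_g + i_r)
    warning(sprintf(
      "degenerate surface (I_G = %g, I_R = %g): clamping the zero sum to %g",
      i_g, i_r, eps), call. = FALSE)
    if (i_g == 0) i_g <- eps else i_r <- eps
  }
  # difference of logs, not log of the quotient: makes the channel-swap
  # antisymmetry (f -> -f  ==>  logG/R -> -logG/R) exact in floating point
  log10(i_g) - log10(i_r)
}

#' @export
print.scored_surface <- function(x, ...) {
  cat(sprintf("<scored_surface> %d points, I_G = %.4g, I_R = %.4g\n",
              length(x$mlp), x$i_g, x$i_r))
  lgr <- tryCatch(log_g_over_r(x), vgnp_degenerate_surface = function(e) NA)
  cat(sprintf("  logG/R = %s (%s kernel, lambda %g, cutoff %g A)\n",
              ifelse(is.na(lgr), "<degenerate>", sprintf("%.4f", lgr)),
              x$kernel$name, x$kernel$lambda, x$kernel$cutoff))
  invisible(x)
}
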
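# Grid-based solvent-accessible (Connolly) surface.
#
# Every occluding body (ligand atom, shell atom, or the implicit core
# sphere) has a centre c_i and radius R_i.  With probe radius p and grid
# unit h, a grid node g is a SAS point iff
#   (a) ||g - c_i|| >= R_i + p  for ALL bodies  (the probe overlaps nothing)
#   (b) ||g - c_j|| <= R_j + p + h for SOME body (the probe is within one
#       grid unit of touching the particle)
# Distances are Euclidean.  The grid is anchored at the lower bound of the
# padded bounding box so a fixed particle always yields the same nodes.

#' Build the surface grid for a particle
#'
#' The axis-aligned box covers every body inflated by its radius, padded by
#' `probe_radius + 2 h`; nodes sit at `origin + integer multiples of h`.
#'
#' @param vgnp A `vgnp` particle.
#' @param h Grid spacing (grid unit), Angstrom.
#' @param probe_radius Solvent probe radius, Angstrom; 1.4 for water.
#' @return A `vgnp_grid`: list with `h`, `probe_radius`, `origin`, `dims`.
#' @export
build_grid <- function(vgnp, h = 0.8, probe_radius = 1.4) {
  stopifnot_scalar(h, "h", positive = TRUE)
  stopifnot_scalar(probe_radius, "probe_radius", positive = TRUE)
  b <- particle_bodies(vgnp)
  if (nrow(b) == 0) {
    vgnp_abort("particle has no occluding body (no core, no atoms)",
               "vgnp_domain_error")
  }
  pad <- probe_radius + 2 * h
  lo <- c(min(b$x - b$R), min(b$y - b$R), min(b$z - b$R)) - pad
  hi <- c(max(b$x + b$R), max(b$y + b$R), max(b$z + b$R)) + pad
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  structure(list(h = h, probe_radius = probe_radius, origin = lo,
                 dims = dims),
            class = "vgnp_grid")
}

# All occluding bodies of a particle as a data.frame(x, y, z, R, f).
particle_bodies <- function(vgnp) {
  stopifnot(inherits(vgnp, "vgnp"))
  a <- vgnp$atoms
  b <- data.frame(x = a$x, y = a$y, z = a$z, R = a$vdw, f = a$f)
  core <- vgnp$core
  if (!is.null(core) && core$representation == "implicit_sphere") {
    b <- rbind(b, data.frame(x = 0, y = 0, z = 0,
                             R = core$occlusion_radius, f = 0))
  }
  b
}

#' Identify the SAS points of a particle
#'
#' Evaluates the SAS predicate over the grid.  The default implementation
#' visits, per body, only the nodes inside the body's contact band (a cell
#' restriction); its output is identical to the exhaustive
#' [sas_points_bruteforce()] evaluation, which serves as the reference.
#'
#' @param vgnp A `vgnp` particle with at least one occluding body.
#' @param grid A `vgnp_grid`, or `NULL` to build one from `h` and
#'   `probe_radius`.
#' @inheritParams build_grid
#' @return A `sas_points` object: list with `points` (n x 3 matrix of node
#'   coordinates, Angstrom), `idx` (sorted linear node indices), `grid`.
#' @export
identify_sas_points <- function(vgnp, grid = NULL, h = 0.8,
                                probe_radius = 1.4) {
  if (is.null(grid)) grid <- build_grid(vgnp, h = h,
                                        probe_radius = probe_radius)
  b <- particle_bodies(vgnp)
  if (nrow(b) == 0) {
    vgnp_abort("particle has no occluding body", "vgnp_domain_error")
  }
  h <- grid$h; p <- grid$probe_radius
  o <- grid$origin; dims <- grid$dims
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  near <- logical(nx * ny * nz)
  overlap <- logical(nx * ny * nz)

  for (k in seq_len(nrow(b))) {
    Rph <- b$R[k] + p + h
    c_k <- c(b$x[k], b$y[k], b$z[k])
    # candidate node range per axis, one node of slack against FP rounding
    lo_i <- pmax(ceiling((c_k - Rph - o) / h) - 1, 0)
    hi_i <- pmin(floor((c_k + Rph - o) / h) + 1, dims - 1L)
    if (any(lo_i > hi_i)) next
    ix <- lo_i[1]:hi_i[1]; iy <- lo_i[2]:hi_i[2]; iz <- lo_i[3]:hi_i[3]
    dx2 <- (o[1] + ix * h - c_k[1])^2
    dy2 <- (o[2] + iy * h - c_k[2])^2
    dz2 <- (o[3] + iz * h - c_k[3])^2
    d2 <- as.vector(outer(outer(dx2, dy2, `+`), dz2, `+`))
    idx <- as.vector(outer(outer(ix, nx * iy, `+`), nx * ny * iz, `+`)) + 1
    near[idx[d2 <= Rph^2]] <- TRUE
    overlap[idx[d2 < (b$R[k] + p)^2]] <- TRUE
  }

  keep <- which(near & !overlap)
  iz <- (keep - 1) %/% (nx * ny)
  iy <- ((keep - 1) %/% nx) %% ny
  ix <- (keep - 1) %% nx
  pts <- cbind(x = o[1] + ix * h, y = o[2] + iy * h, z = o[3] + iz * h)
  structure(list(points = pts, idx = keep, grid = grid, n = length(keep)),
            class = "sas_points")
}

#' Brute-force SAS reference
#'
#' Evaluates the SAS predicate at every grid node against every body, with
#' no spatial restriction.  Reference implementation for correctness
#' checks; use only on small particles.
#'
#' @inheritParams identify_sas_points
#' @return A `sas_points` object.
#' @export
sas_points_bruteforce <- function(vgnp, grid = NULL, h = 0.8,
                                  probe_radius = 1.4) {
  if (is.null(grid)) grid <- build_grid(vgnp, h = h,
                                        probe_radius = probe_radius)
  b <- particle_bodies(vgnp)
  if (nrow(b) == 0) {
    vgnp_abort("particle has no occluding body", "vgnp_domain_error")
  }
  h <- grid$h; p <- grid$probe_radius
  o <- grid$origin; dims <- grid$dims
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  gx <- o[1] + (seq_len(nx) - 1) * h
  gy <- o[2] + (seq_len(ny) - 1) * h
  gz <- o[3] + (seq_len(nz) - 1) * h
  X <- rep(gx, times = ny * nz)
  Y <- rep(rep(gy, each = nx), times = nz)
  Z <- rep(gz, each = nx * ny)
  near <- logical(length(X))
  overlap <- logical(length(X))
  for (k in seq_len(nrow(b))) {
    d2 <- (X - b$x[k])^2 + (Y - b$y[k])^2 + (Z - b$z[k])^2
    near <- near | (d2 <= (b$R[k] + p + h)^2)
    overlap <- overlap | (d2 < (b$R[k] + p)^2)
  }
  keep <- which(near & !overlap)
  pts <- cbind(x = X[keep], y = Y[keep], z = Z[keep])
  structure(list(points = pts, idx = keep, grid = grid, n = length(keep)),
            class = "sas_points")
}

#' @export
print.sas_points <- function(x, ...) {
  cat(sprintf(
    "<sas_points> %d grid points (h = %g A, probe = %g A, dims %s)\n",
    x$n, x$grid$h, x$grid$probe_radius, paste(x$grid$dims, collapse = "x")))
  invisible(x)
}
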
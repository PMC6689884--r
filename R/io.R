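# File export/import: library CSVs, scores CSV, PDB/XYZ particle dumps,
# SAS and scored-surface exports.  Every CSV carries a '#'-prefixed
# provenance header (package version, full configuration, seeds) so a run
# can be regenerated from its outputs alone.

provenance_lines <- function(config = NULL, extra = list()) {
  # no timestamp: outputs must be byte-identical across reruns with the
  # same parameters and seeds
  lines <- sprintf("# vgnp %s", as.character(utils::packageVersion("vgnp")))
  if (!is.null(config)) {
    lines <- c(lines, sprintf("# config %s",
                              jsonlite::toJSON(unclass(config),
                                               auto_unbox = TRUE,
                                               digits = NA)))
  }
  for (nm in names(extra)) {
    lines <- c(lines, sprintf("# %s %s", nm,
                              jsonlite::toJSON(extra[[nm]],
                                               auto_unbox = TRUE,
                                               digits = NA)))
  }
  lines
}

write_csv_with_header <- function(df, path, header) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write the per-particle scores table
#'
#' @param run A `vgnp_run` from [run_pipeline()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(run, path) {
  stopifnot(inherits(run, "vgnp_run"))
  write_csv_with_header(run$scores, path,
                        provenance_lines(run$config,
                                         list(model = unclass(run$model))))
}

#' Write / read a particle library as CSV
#'
#' `particles.csv` holds `particle_id`, `core_diameter_nm` and optional
#' `elogp`; `ligands.csv` is long format with one row per (particle,
#' ligand): `particle_id`, `ligand_id`, `smiles`, and `count` or
#' `density_per_nm2`.  Round-trips a `fixture_library` bit-exactly up to
#' the timestamp header.
#'
#' @param lib A `fixture_library`.
#' @param dir Output directory (created if missing).
#' @return The directory (write) or a `fixture_library` (read), invisibly.
#' @export
write_fixture_library <- function(lib, dir) {
  stopifnot(inherits(lib, "fixture_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_lines(NULL, list(params = lib$params, seed = lib$seed))
  write_csv_with_header(lib$particles, file.path(dir, "particles.csv"), hdr)
  write_csv_with_header(lib$ligands, file.path(dir, "ligands.csv"), hdr)
  invisible(dir)
}

#' @rdname write_fixture_library
#' @param particles_csv,ligands_csv CSV paths as written by
#'   [write_fixture_library()] (or hand-made to the same schema).
#' @export
read_particle_library <- function(particles_csv, ligands_csv) {
  particles <- utils::read.csv(particles_csv, comment.char = "#",
                               stringsAsFactors = FALSE)
  ligands <- utils::read.csv(ligands_csv, comment.char = "#",
                             stringsAsFactors = FALSE)
  new_fixture_library(particles, ligands, params = list(), seed = NA_integer_)
}

#' Export an assembled particle
#'
#' `write_particle_pdb()` writes HETATM records with the element field set
#' (via bio3d); `write_particle_xyz()` writes plain XYZ.
#'
#' @param particle A `vgnp`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_particle_pdb <- function(particle, path) {
  stopifnot(inherits(particle, "vgnp"))
  a <- particle$atoms
  if (nrow(a) == 0) vgnp_abort("particle has no atoms to write",
                               "vgnp_domain_error")
  n <- nrow(a)
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("HETATM", n),
                   resno = rep(1L, n), resid = rep("LIG", n),
                   eleno = seq_len(n), elety = a$element,
                   elesy = a$element, chain = rep("A", n),
                   o = rep(1, n), b = a$f)
  invisible(path)
}

#' @rdname write_particle_pdb
#' @export
write_particle_xyz <- function(particle, path) {
  stopifnot(inherits(particle, "vgnp"))
  a <- particle$atoms
  lines <- c(as.character(nrow(a)),
             sprintf("vgnp particle, seed %s", particle$seed),
             sprintf("%-2s %12.6f %12.6f %12.6f", a$element, a$x, a$y, a$z))
  writeLines(lines, path)
  invisible(path)
}

#' Export surface points
#'
#' `write_sas_csv()` writes the raw SAS nodes; `write_scored_csv()` adds
#' the mlp value, the G/R channel, and a per-particle min-max normalized
#' `|mlp|` intensity in `[0, 1]` (visualization only — the raw sums enter
#' logG/R).  `write_surface_pdb()` writes pseudo-atoms with mlp in the
#' B-factor column for viewer coloring.
#'
#' @param sas A `sas_points` set.
#' @param surface A `scored_surface`.
#' @param path Output path.
#' @param config Optional [vgnp_config()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_sas_csv <- function(sas, path, config = NULL) {
  stopifnot(inherits(sas, "sas_points"))
  df <- as.data.frame(sas$points)
  names(df) <- c("x", "y", "z")
  write_csv_with_header(df, path, provenance_lines(config, list(
    grid = list(h = sas$grid$h, probe_radius = sas$grid$probe_radius,
                origin = sas$grid$origin, dims = sas$grid$dims))))
}

#' @rdname write_sas_csv
#' @export
write_scored_csv <- function(surface, path, config = NULL) {
  stopifnot(inherits(surface, "scored_surface"))
  amp <- abs(surface$mlp)
  rng <- range(amp)
  intensity <- if (diff(rng) > 0) (amp - rng[1]) / diff(rng)
               else rep(0, length(amp))
  df <- data.frame(x = surface$points[, 1], y = surface$points[, 2],
                   z = surface$points[, 3], mlp = surface$mlp,
                   channel = ifelse(surface$mlp >= 0, "G", "R"),
                   intensity_normalized = intensity)
  write_csv_with_header(df, path, provenance_lines(config, list(
    kernel = unclass(surface$kernel),
    sums = list(i_g = surface$i_g, i_r = surface$i_r))))
}

#' @rdname write_sas_csv
#' @export
write_surface_pdb <- function(surface, path) {
  stopifnot(inherits(surface, "scored_surface"))
  n <- nrow(surface$points)
  xyz <- as.vector(t(surface$points))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("HETATM", n),
                   resno = rep(1L, n), resid = rep("SAS", n),
                   eleno = seq_len(n), elety = rep("X", n),
                   elesy = rep("X", n), chain = rep("S", n),
                   o = rep(1, n), b = surface$mlp)
  invisible(path)
}
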
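# Synthetic particle libraries.
#
# Two archetype thiol ligands with strongly opposite contribution sums
# stand in for a real composition table: a short thiol-PEG-ol
# (hydrophilic, Crippen logP about -0.06) and dodecanethiol (hydrophobic,
# Crippen logP about +4.8).  Varying their ratio spans the
# nanohydrophobicity range the method is designed to resolve.

#' Archetype fixture ligands
#'
#' @return Data frame with `ligand_id`, `smiles`, `role`.
#' @export
vgnp_archetypes <- function() {
  data.frame(
    ligand_id = c("EG2-thiol", "C12-thiol"),
    smiles = c("SCCOCCOCCO", "SCCCCCCCCCCCC"),
    role = c("hydrophilic", "hydrophobic"))
}

new_fixture_library <- function(particles, ligands, params, seed) {
  structure(list(particles = particles, ligands = ligands, params = params,
                 seed = as.integer(seed)),
            class = "fixture_library")
}

#' Two-ligand ratio series
#'
#' A family of particles sharing one hydrophilic and one hydrophobic
#' archetype ligand, with the hydrophobic fraction `phi` evenly spaced in
#' `[0, 1]` — the in-silico ratio series that sweeps nanohydrophobicity
#' from low to high.  Structure generation is deterministic in the
#' parameters; `seed` is recorded for the downstream placement stage.
#'
#' @param n_steps Number of particles (>= 2); 8 by default.
#' @param core_diameter Shared core diameter, nm.
#' @param total_ligands Total ligand copies per particle; the default 38
#'   corresponds to about 3 thiols per nm^2 on a 2 nm core.
#' @param seed Base placement seed recorded in the library.
#' @return A `fixture_library` (lists `particles`, `ligands`, `params`).
#' @export
#' @examples
#' lib <- generate_ratio_series()
#' lib$particles$phi
generate_ratio_series <- function(n_steps = 8L, core_diameter = 2,
                                  total_ligands = 38L, seed = 1L) {
  if (!is_scalar_number(n_steps) || n_steps < 2) {
    vgnp_abort("`n_steps` must be >= 2", "vgnp_domain_error")
  }
  arch <- vgnp_archetypes()
  phi <- seq(0, 1, length.out = n_steps)
  n_phob <- round(phi * total_ligands)
  ids <- sprintf("ratio_%02d", seq_len(n_steps))
  particles <- data.frame(particle_id = ids, core_diameter_nm = core_diameter,
                          phi = phi, elogp = NA_real_)
  ligands <- rbind(
    data.frame(particle_id = ids, ligand_id = arch$ligand_id[1],
               smiles = arch$smiles[1], count = total_ligands - n_phob),
    data.frame(particle_id = ids, ligand_id = arch$ligand_id[2],
               smiles = arch$smiles[2], count = n_phob))
  ligands <- ligands[order(ligands$particle_id, ligands$ligand_id), ]
  rownames(ligands) <- NULL
  new_fixture_library(particles, ligands,
                      params = list(n_steps = n_steps,
                                    core_diameter = core_diameter,
                                    total_ligands = total_ligands),
                      seed = seed)
}

#' Seed-averaged logG/R of a ratio series
#'
#' Runs the pipeline over several placement seeds and averages logG/R per
#' particle, damping the grid- and placement-level noise of a single
#' realisation.  Pure-hydrophobic endpoints have an empty hydrophilic
#' channel, so the ratio is clamped there (see [log_g_over_r()]).
#'
#' @param lib A ratio-series `fixture_library`.
#' @param config A [vgnp_config()]; clamping is forced on.
#' @param n_seeds Number of placement seeds to average over.
#' @param verbose Passed to [run_pipeline()].
#' @return Data frame with `particle_id`, `phi`, `log_g_over_r` (mean over
#'   seeds), `nanologp` (published calibration applied to the mean).
#' @export
ratio_series_logg <- function(lib, config = vgnp_config(), n_seeds = 5L,
                              verbose = FALSE) {
  stopifnot(inherits(lib, "fixture_library"))
  config$clamp <- TRUE
  acc <- matrix(NA_real_, nrow(lib$particles), n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- config
    cfg$placement_seed <- derive_seed(lib$seed, s)
    run <- suppressWarnings(
      run_pipeline(lib$particles, lib$ligands, config = cfg, fit = FALSE,
                   verbose = verbose))
    acc[, s] <- run$scores$log_g_over_r
  }
  mean_lgr <- rowMeans(acc)
  data.frame(particle_id = lib$particles$particle_id,
             phi = lib$particles$phi, log_g_over_r = mean_lgr,
             nanologp = predict_nanologp(mean_lgr))
}

#' Synthetic calibration library
#'
#' Emulates a modeling set of two-ligand particles whose synthetic
#' experimental logP is generated from their own computed logG/R:
#' `elogp = slope * logG/R + intercept + N(0, noise_sd^2)`.  With
#' `slope`/`intercept` `NULL`, the affine map is auto-derived so the
#' noiseless elogP spans exactly `[-3, 3]`, the hydrophobicity range a
#' well-designed modeling library covers.  The hydrophobic fraction runs
#' over `[0, 0.9]` (both surface channels stay populated) and core
#' diameters cycle through `core_diameters`.
#'
#' Structure and placement are controlled by `structure_seed`; the elogP
#' noise alone is controlled by `seed`, so distinct `seed` values give
#' distinct noise on identical structures.
#'
#' @param n Number of particles (>= 2).
#' @param slope,intercept Calibration truth used to generate elogP, or
#'   `NULL` to auto-scale onto `[-3, 3]`.
#' @param noise_sd Gaussian noise SD on elogP; default 0.8, a realistic
#'   shake-flask measurement scatter.
#' @param seed Noise seed.
#' @param structure_seed Placement seed base (structure realisation).
#' @param core_diameters Diameters (nm) cycled over the particles.
#' @param density Thiol grafting density, ligands per nm^2.
#' @param config A [vgnp_config()]; clamping is forced on.
#' @param verbose Passed to [run_pipeline()].
#' @return A `fixture_library`; `particles` carries `elogp` and the
#'   computed `log_g_over_r`, `params` records the realised
#'   slope/intercept truth.
#' @export
generate_calibration_library <- function(n = 41L, slope = NULL,
                                         intercept = NULL, noise_sd = 0.8,
                                         seed = 1L, structure_seed = 1L,
                                         core_diameters = c(2, 2.5, 3),
                                         density = 3,
                                         config = vgnp_config(),
                                         verbose = FALSE) {
  if (!is_scalar_number(n) || n < 2) {
    vgnp_abort("`n` must be >= 2", "vgnp_domain_error")
  }
  if (noise_sd < 0) vgnp_abort("`noise_sd` must be >= 0",
                               "vgnp_domain_error")
  arch <- vgnp_archetypes()
  phi <- seq(0, 0.9, length.out = n)
  diam <- rep_len(core_diameters, n)
  total <- vapply(diam, function(d) {
    as.integer(round(density * 4 * pi * (d / 2)^2))
  }, integer(1))
  n_phob <- as.integer(round(phi * total))
  ids <- sprintf("cal_%02d", seq_len(n))
  particles <- data.frame(particle_id = ids, core_diameter_nm = diam,
                          phi = phi, elogp = NA_real_)
  ligands <- rbind(
    data.frame(particle_id = ids, ligand_id = arch$ligand_id[1],
               smiles = arch$smiles[1], count = total - n_phob),
    data.frame(particle_id = ids, ligand_id = arch$ligand_id[2],
               smiles = arch$smiles[2], count = n_phob))
  ligands <- ligands[order(ligands$particle_id, ligands$ligand_id), ]
  rownames(ligands) <- NULL

  cfg <- config
  cfg$clamp <- TRUE
  cfg$placement_seed <- as.integer(structure_seed)
  run <- suppressWarnings(
    run_pipeline(particles, ligands, config = cfg, fit = FALSE,
                 verbose = verbose))
  x <- run$scores$log_g_over_r
  if (any(!is.finite(x))) {
    vgnp_abort("calibration-library generation failed for some particles",
               "vgnp_pipeline_error")
  }
  if (is.null(slope) || is.null(intercept)) {
    span <- range(x)
    slope <- 6 / diff(span)
    intercept <- -3 - slope * span[1]
  }
  noise <- with_seed(seed, stats::rnorm(n, 0, noise_sd))
  particles$log_g_over_r <- x
  particles$elogp <- slope * x + intercept + noise

  new_fixture_library(particles, ligands,
                      params = list(n = n, slope = slope,
                                    intercept = intercept,
                                    noise_sd = noise_sd,
                                    structure_seed = structure_seed,
                                    core_diameters = core_diameters,
                                    density = density),
                      seed = seed)
}

#' @export
print.fixture_library <- function(x, ...) {
  cat(sprintf("<fixture_library> %d particles, %d composition rows\n",
              nrow(x$particles), nrow(x$ligands)))
  utils::str(x$params, no.list = TRUE)
  invisible(x)
}
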
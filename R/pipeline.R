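# End-to-end orchestration: composition table -> particles -> SAS ->
# lipophilicity surface -> logG/R -> nanologP (-> calibration fit / CV).

#' Score one particle composition
#'
#' Builds the particle, identifies its SAS, scores the surface and returns
#' the particle-level summary.  The workhorse behind [run_pipeline()].
#'
#' @param specs List of [ligand_spec()] for this particle.
#' @param core_diameter Core diameter, nm.
#' @param config A [vgnp_config()].
#' @param seed Placement seed for this particle.
#' @return List with `n_atoms`, `n_sas`, `i_g`, `i_r`, `log_g_over_r`,
#'   `baseline_logp`, and the `vgnp`/`scored_surface` objects.
#' @export
score_particle <- function(specs, core_diameter, config = vgnp_config(),
                           seed = NULL) {
  particle <- build_vgnp(specs, core_diameter, config = config, seed = seed)
  sas <- identify_sas_points(particle, h = config$h,
                             probe_radius = config$probe_radius)
  surface <- score_surface(sas, particle, config_kernel(config))
  lgr <- log_g_over_r(surface, clamp = config$clamp)
  mols <- parse_ligands(specs, embed_seed = config$embed_seed,
                        table = config$contribution_table)
  counts <- particle$composition$count
  baseline <- if (sum(counts) > 0) {
    ligand_baseline_logp(vapply(mols, ligand_logp, numeric(1)), counts)
  } else NA_real_
  list(n_atoms = nrow(particle$atoms), n_sas = sas$n,
       i_g = surface$i_g, i_r = surface$i_r, log_g_over_r = lgr,
       baseline_logp = baseline, particle = particle, surface = surface)
}

specs_for_particle <- function(ligand_rows) {
  lapply(seq_len(nrow(ligand_rows)), function(i) {
    row <- ligand_rows[i, ]
    has_count <- "count" %in% names(row) && is.finite(row$count)
    has_dens <- "density_per_nm2" %in% names(row) &&
      is.finite(row$density_per_nm2)
    if (has_count && row$count == 0) return(NULL)
    ligand_spec(row$ligand_id, row$smiles,
                count = if (has_count) row$count else NULL,
                density = if (!has_count && has_dens)
                  row$density_per_nm2 else NULL)
  })
}

#' Run the full nanohydrophobicity pipeline
#'
#' For every particle in the library: build, extract the SAS, score, and
#' compute logG/R and the ligand-averaged baseline logP.  If experimental
#' logP values are present (and `fit` is not `FALSE`) the calibration line
#' is fitted on them and used for nanologP; otherwise the supplied (or
#' published default) model is applied.  Per-particle failures are recorded
#' and the run continues over the remaining particles.
#'
#' @param particles A `fixture_library`, or a data frame with columns
#'   `particle_id`, `core_diameter_nm` and optionally `elogp`.
#' @param ligands Long-format data frame with columns `particle_id`,
#'   `ligand_id`, `smiles` and `count` (or `density_per_nm2`); ignored when
#'   `particles` is a `fixture_library`.
#' @param config A [vgnp_config()].
#' @param model Calibration applied when not fitting; the published default
#'   if `NULL`.
#' @param fit `TRUE`/`FALSE`, or `NULL` to fit exactly when >= 2 particles
#'   carry `elogp`.
#' @param cv_folds If non-`NULL`, also run k-fold cross-validation with
#'   this many folds (requires fitting).
#' @param cv_seed Fold-assignment seed.
#' @param output_dir If non-`NULL`, write `scores.csv` and `model.json`
#'   here, each with a provenance header.
#' @param verbose Log per-particle progress with [message()].
#' @return A `vgnp_run`: list with `scores` (data frame), `model`, `cv`,
#'   `errors`, `config`.
#' @export
run_pipeline <- function(particles, ligands = NULL, config = vgnp_config(),
                         model = NULL, fit = NULL, cv_folds = NULL,
                         cv_seed = 1L, output_dir = NULL, verbose = FALSE) {
  if (inherits(particles, "fixture_library")) {
    ligands <- particles$ligands
    particles <- particles$particles
  }
  stopifnot(is.data.frame(particles), is.data.frame(ligands),
            all(c("particle_id", "core_diameter_nm") %in% names(particles)),
            all(c("particle_id", "ligand_id", "smiles") %in% names(ligands)))

  n <- nrow(particles)
  scores <- data.frame(particle_id = particles$particle_id,
                       core_diameter_nm = particles$core_diameter_nm,
                       n_atoms = NA_integer_, n_sas = NA_integer_,
                       i_g = NA_real_, i_r = NA_real_,
                       log_g_over_r = NA_real_, baseline_logp = NA_real_,
                       nanologp = NA_real_,
                       elogp = if ("elogp" %in% names(particles))
                         particles$elogp else NA_real_,
                       seed = NA_integer_)
  errors <- list()
  for (i in seq_len(n)) {
    pid <- particles$particle_id[i]
    seed_i <- derive_seed(config$placement_seed, i)
    scores$seed[i] <- seed_i
    rows <- ligands[ligands$particle_id == pid, , drop = FALSE]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      specs <- Filter(Negate(is.null), specs_for_particle(rows))
      score_particle(specs, particles$core_diameter_nm[i], config = config,
                     seed = seed_i)
    }, vgnp_error = function(e) e)
    if (inherits(res, "condition")) {
      errors[[pid]] <- conditionMessage(res)
      if (verbose) message(sprintf("[vgnp] %s: FAILED (%s)", pid,
                                   conditionMessage(res)))
      next
    }
    scores$n_atoms[i] <- res$n_atoms
    scores$n_sas[i] <- res$n_sas
    scores$i_g[i] <- res$i_g
    scores$i_r[i] <- res$i_r
    scores$log_g_over_r[i] <- res$log_g_over_r
    scores$baseline_logp[i] <- res$baseline_logp
    if (verbose) {
      message(sprintf(
        "[vgnp] %s: n_atoms=%d n_sas=%d I_G=%.4g I_R=%.4g logG/R=%.4f seed=%d (%.1fs)",
        pid, res$n_atoms, res$n_sas, res$i_g, res$i_r, res$log_g_over_r,
        seed_i, proc.time()[["elapsed"]] - t0))
    }
  }
  if (length(errors) == n && n > 0) {
    vgnp_abort(sprintf("all %d particles failed; first error: %s", n,
                       errors[[1]]), "vgnp_pipeline_error", errors = errors)
  }

  usable <- sum(is.finite(scores$log_g_over_r) & is.finite(scores$elogp))
  do_fit <- if (is.null(fit)) usable >= 2 else isTRUE(fit)
  cv <- NULL
  if (do_fit) {
    model <- fit_calibration(scores)
    if (!is.null(cv_folds)) cv <- kfold_cv(scores, k = cv_folds,
                                           seed = cv_seed)
  } else if (is.null(model)) {
    model <- default_calibration()
  }
  scores$nanologp <- predict_nanologp(scores$log_g_over_r, model)

  run <- structure(list(scores = scores, model = model, cv = cv,
                        errors = errors, config = config),
                   class = "vgnp_run")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_scores_csv(run, file.path(output_dir, "scores.csv"))
    write_calibration(model, file.path(output_dir, "model.json"))
  }
  if (length(errors) > 0) {
    warning(sprintf("%d of %d particles failed: %s", length(errors), n,
                    paste(names(errors), collapse = ", ")), call. = FALSE)
  }
  run
}

#' @export
print.vgnp_run <- function(x, ...) {
  cat(sprintf("<vgnp_run> %d particles (%d failed)\n", nrow(x$scores),
              length(x$errors)))
  print(x$model)
  if (!is.null(x$cv)) {
    cat(sprintf("  %d-fold CV: R^2 = %.3f, MAE = %.3f, RMSE = %.3f\n",
                x$cv$k, x$cv$metrics$r_squared, x$cv$metrics$mae,
                x$cv$metrics$rmse))
  }
  cat(sprintf("  logG/R range: [%.3f, %.3f]\n",
              min(x$scores$log_g_over_r, na.rm = TRUE),
              max(x$scores$log_g_over_r, na.rm = TRUE)))
  invisible(x)
}
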
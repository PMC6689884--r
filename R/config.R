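#' Run configuration
#'
#' Collects every tunable of the pipeline in one validated list.  Defaults:
#' grid unit 0.8 A, water probe 1.4 A, exponential MLP kernel with decay
#' length 1.5 A and 10 A cutoff, implicit-sphere core, 2.0 A minimum anchor
#' separation, 2.4 A S-Au bond offset, Wildman-Crippen contribution table,
#' hard error on degenerate (single-channel) surfaces.
#'
#' @param h Grid spacing, Angstrom.
#' @param probe_radius Solvent probe radius, Angstrom.
#' @param kernel MLP kernel name: `"exponential"` or `"audry"`.
#' @param lambda Kernel decay length, Angstrom.
#' @param cutoff Kernel cutoff distance, Angstrom.
#' @param core_representation `"implicit_sphere"` or `"atomistic_shell"`.
#' @param min_separation Minimum anchor separation (arc), Angstrom.
#' @param bond_offset Attachment-atom offset from the core surface, Angstrom.
#' @param embed_seed Ligand 3D-embedding seed.
#' @param placement_seed Base seed for ligand placement.
#' @param contribution_table Atomic contribution table id.
#' @param clamp Substitute an epsilon for a zero intensity channel in
#'   logG/R instead of failing.
#' @param max_attempts Anchor rejection-sampling budget.
#' @return A validated `vgnp_config` list.
#' @export
vgnp_config <- function(h = 0.8, probe_radius = 1.4,
                        kernel = c("exponential", "audry"), lambda = 1.5,
                        cutoff = 10,
                        core_representation = c("implicit_sphere",
                                                "atomistic_shell"),
                        min_separation = 2.0, bond_offset = 2.4,
                        embed_seed = 42L, placement_seed = 1L,
                        contribution_table = "wildman_crippen",
                        clamp = FALSE, max_attempts = 2000L) {
  cfg <- list(h = h, probe_radius = probe_radius,
              kernel = match.arg(kernel), lambda = lambda, cutoff = cutoff,
              core_representation = match.arg(core_representation),
              min_separation = min_separation, bond_offset = bond_offset,
              embed_seed = as.integer(embed_seed),
              placement_seed = as.integer(placement_seed),
              contribution_table = contribution_table,
              clamp = isTRUE(clamp), max_attempts = as.integer(max_attempts))
  for (nm in c("h", "probe_radius", "lambda", "cutoff", "min_separation",
               "bond_offset")) {
    stopifnot_scalar(cfg[[nm]], nm, positive = nm != "min_separation")
  }
  if (cfg$min_separation < 0) {
    vgnp_abort("`min_separation` must be >= 0", "vgnp_domain_error")
  }
  structure(cfg, class = "vgnp_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys in the file override the package defaults; anything passed through
#' `...` overrides the file (the precedence CLI flags use).
#'
#' @param path YAML file of `key: value` pairs named as in [vgnp_config()].
#' @param ... Overrides applied after the file.
#' @return A validated `vgnp_config`.
#' @export
read_config <- function(path, ...) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    vgnp_abort("reading YAML configs requires the 'yaml' package",
               "vgnp_domain_error")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(vgnp_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    vgnp_abort(sprintf("unknown config key(s): %s",
                       paste(unknown, collapse = ", ")),
               "vgnp_domain_error")
  }
  over <- list(...)
  vals[names(over)] <- over
  do.call(vgnp_config, vals)
}

config_kernel <- function(config) {
  weighting_kernel(config$kernel, lambda = config$lambda,
                   cutoff = config$cutoff)
}

#' @export
print.vgnp_config <- function(x, ...) {
  cat("<vgnp_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, x[[nm]]))
  invisible(x)
}
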
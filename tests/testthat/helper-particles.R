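# Shared fixtures: hand-built ligands and particles that exercise the
# geometry without touching the chemistry bridge, plus cached parses of
# the archetype ligands for tests that do need real chemistry.

# A rigid synthetic ligand: attachment atom at the origin, the rest laid
# out deterministically along +x with a slight twist so the molecule has a
# well-defined principal axis.
fake_ligand <- function(id = "fake", n = 5, f = rep(0.2, n), vdw = 1.7) {
  stopifnot(length(f) == n)
  t <- seq_len(n) - 1
  atoms <- data.frame(
    element = c("S", rep("C", n - 1)),
    x = 1.5 * t, y = 0.3 * sin(t), z = 0.3 * cos(t) - 0.3,
    aromatic = FALSE, formal_charge = 0L, f = f, vdw = vdw)
  bonds <- if (n > 1) {
    data.frame(i = seq_len(n - 1), j = seq_len(n - 1) + 1L,
               order = 1, aromatic = FALSE)
  } else {
    data.frame(i = integer(0), j = integer(0), order = numeric(0),
               aromatic = logical(0))
  }
  structure(list(ligand_id = id, atoms = atoms, bonds = bonds,
                 attachment_index = 1L, attachment_matches = 1L,
                 mol_logp = sum(f), embed_seed = 0L,
                 contribution_table = "wildman_crippen",
                 source = list(ligand_id = id, structure = "<synthetic>",
                               attachment_rule = default_attachment_rule())),
            class = "ligand_molecule")
}

# Random free-floating particle: n atoms in a box, mixed-sign contributions.
random_particle <- function(n, seed = 1, extent = 6, with_core = FALSE) {
  atoms <- vgnp:::with_seed(seed, data.frame(
    element = "C",
    x = runif(n, -extent, extent),
    y = runif(n, -extent, extent),
    z = runif(n, -extent, extent),
    vdw = runif(n, 1.2, 2.0),
    f = rnorm(n, 0, 0.3)))
  core <- if (with_core) build_core(2) else NULL
  if (with_core) {
    # push atoms outside the core so they are not all buried
    r <- sqrt(atoms$x^2 + atoms$y^2 + atoms$z^2)
    scale <- (core$occlusion_radius + 1 + r) / pmax(r, 1e-6)
    atoms$x <- atoms$x * scale
    atoms$y <- atoms$y * scale
    atoms$z <- atoms$z * scale
  }
  vgnp_from_atoms(atoms, core = core)
}

single_atom_particle <- function(r = 1.7, f = 1, at = c(0, 0, 0)) {
  vgnp_from_atoms(data.frame(element = "C", x = at[1], y = at[2], z = at[3],
                             vdw = r, f = f))
}

# Minimal sas_points wrapper for scoring arbitrary point sets.
fake_sas <- function(points) {
  structure(list(points = points, idx = seq_len(nrow(points)),
                 grid = structure(list(h = 1, probe_radius = 1.4,
                                       origin = c(0, 0, 0),
                                       dims = c(1L, 1L, 1L)),
                                  class = "vgnp_grid"),
                 n = nrow(points)),
            class = "sas_points")
}

# Archetype ligand parses are cached per session by the bridge; these
# wrappers keep test files terse.
archetype_mol <- local({
  cache <- new.env(parent = emptyenv())
  function(role = c("hydrophilic", "hydrophobic"), seed = 42L) {
    role <- match.arg(role)
    key <- paste(role, seed)
    if (is.null(cache[[key]])) {
      arch <- vgnp_archetypes()
      row <- arch[arch$role == role, ]
      cache[[key]] <- parse_ligand(
        ligand_spec(row$ligand_id, row$smiles, count = 1),
        embed_seed = seed)
    }
    cache[[key]]
  }
})

# V2000 molfile without coordinates; the parser must embed it.
ethanethiol_molblock <- function() {
  paste(c("ethanethiol", "  vgnp", "",
          "  3  2  0  0  0  0  0  0  0  0999 V2000",
          "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
          "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
          "    0.0000    0.0000    0.0000 S   0  0  0  0  0  0  0  0  0  0  0  0",
          "  1  2  1  0", "  2  3  1  0", "M  END"),
        collapse = "\n")
}
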
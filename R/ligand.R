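#' Bondi-type van der Waals radii
#'
#' Default van der Waals radii (in Angstrom) for the elements supported by
#' the particle builder.  Gold is assigned 1.66 A and a zero lipophilicity
#' contribution: the core contributes occlusion, not lipophilicity.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
#' @examples
#' vgnp_vdw_radii()[c("C", "S", "Au")]
vgnp_vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
    S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, Au = 1.66)
}

#' Default attachment rule: thiol / thiolate sulfur
#'
#' SMARTS pattern matching a thiol sulfur (`[SX2H1]`) or a terminal sulfur
#' (`[SX1]`), the anchoring chemistry of thiol-on-gold ligation.
#'
#' @return A SMARTS string.
#' @export
default_attachment_rule <- function() "[SX2H1,SX1]"

#' Describe a surface ligand
#'
#' A ligand specification pairs a structure (SMILES string or path to a
#' MOL/SDF file) with either an absolute copy number on the particle or a
#' grafting density in ligands per nm^2 of core surface.  Exactly one of
#' `count`/`density` must be given.
#'
#' @param ligand_id Character label for the ligand.
#' @param structure SMILES string, or path to a `.mol`/`.sdf` V2000 file.
#' @param attachment_rule SMARTS pattern selecting the core-attachment atom;
#'   defaults to thiol/thiolate sulfur ([default_attachment_rule()]).
#' @param count Positive integer number of copies on the particle.
#' @param density Positive grafting density, ligands per nm^2.
#' @return A `ligand_spec` object.
#' @export
#' @examples
#' ligand_spec("C12-thiol", "SCCCCCCCCCCCC", count = 20)
ligand_spec <- function(ligand_id, structure, attachment_rule = NULL,
                        count = NULL, density = NULL) {
  if (!is.character(ligand_id) || length(ligand_id) != 1L) {
    vgnp_abort("`ligand_id` must be a single string", "vgnp_domain_error")
  }
  if (!is.character(structure) || length(structure) != 1L ||
      !nzchar(structure)) {
    vgnp_abort(sprintf("ligand '%s': `structure` must be a non-empty string",
                       ligand_id), "vgnp_domain_error")
  }
  if (is.null(count) == is.null(density)) {
    vgnp_abort(sprintf(
      "ligand '%s': exactly one of `count`/`density` must be set",
      ligand_id), "vgnp_domain_error")
  }
  if (!is.null(count)) {
    stopifnot_scalar(count, "count")
    if (count < 0 || count != round(count)) {
      vgnp_abort(sprintf("ligand '%s': `count` must be a non-negative integer",
                         ligand_id), "vgnp_domain_error")
    }
  }
  if (!is.null(density)) stopifnot_scalar(density, "density", positive = TRUE)
  structure(list(ligand_id = ligand_id, structure = structure,
                 attachment_rule = attachment_rule %||%
                   default_attachment_rule(),
                 count = count, density = density),
            class = "ligand_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_ligand_spec <- function(x) {
  if (inherits(x, "ligand_spec")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(ligand_spec(x, x, count = 1L))
  }
  vgnp_abort("expected a ligand_spec or a SMILES string", "vgnp_domain_error")
}

structure_format <- function(structure) {
  if (grepl("\\.(sdf|mol)$", structure, ignore.case = TRUE)) "molfile"
  else "smiles"
}

bridge_request <- function(spec, embed_seed) {
  fmt <- structure_format(spec$structure)
  text <- spec$structure
  if (fmt == "molfile") {
    if (!file.exists(spec$structure)) {
      vgnp_abort(sprintf("ligand '%s': file '%s' not found",
                         spec$ligand_id, spec$structure),
                 "vgnp_parse_error", ligand_id = spec$ligand_id)
    }
    text <- paste(readLines(spec$structure, warn = FALSE), collapse = "\n")
  }
  list(ligand_id = spec$ligand_id, structure = text, format = fmt,
       seed = as.integer(embed_seed),
       attachment_smarts = spec$attachment_rule)
}

#' Parse and embed surface ligands
#'
#' Parses each ligand structure, adds explicit hydrogens, generates one 3D
#' conformer with a seeded distance-geometry embedding (ETKDGv3), assigns
#' Wildman-Crippen per-atom lipophilicity contributions `f_i` and van der
#' Waals radii, and locates the core-attachment atom under the spec's
#' attachment rule.  Embedding is deterministic for a fixed
#' `(structure, embed_seed)` pair.
#'
#' @param specs A list of [ligand_spec()] objects (or SMILES strings).
#' @param embed_seed Integer seed for the 3D embedding.
#' @param radii Named vector of van der Waals radii in Angstrom, by element
#'   symbol; defaults to [vgnp_vdw_radii()].
#' @param table Contribution-table identifier; only `"wildman_crippen"` is
#'   shipped.
#' @return A list of `ligand_molecule` objects (see [parse_ligand()]).
#' @seealso [parse_ligand()] for the single-ligand variant.
#' @export
parse_ligands <- function(specs, embed_seed = 42L, radii = vgnp_vdw_radii(),
                          table = "wildman_crippen") {
  specs <- lapply(specs, as_ligand_spec)
  requests <- lapply(specs, bridge_request, embed_seed = embed_seed)
  results <- run_ligand_bridge(requests)
  mapply(function(spec, res) {
    build_ligand_molecule(spec, res, radii = radii, table = table)
  }, specs, results, SIMPLIFY = FALSE)
}

#' @rdname parse_ligands
#' @param spec A single [ligand_spec()] (or SMILES string).
#' @export
#' @examples
#' \dontrun{
#' mol <- parse_ligand(ligand_spec("meSH", "CS", count = 1))
#' mol$attachment_index          # the sulfur atom
#' sum(mol$atoms$f)              # whole-molecule Crippen logP
#' }
parse_ligand <- function(spec, embed_seed = 42L, radii = vgnp_vdw_radii(),
                         table = "wildman_crippen") {
  parse_ligands(list(spec), embed_seed = embed_seed, radii = radii,
                table = table)[[1]]
}

build_ligand_molecule <- function(spec, res, radii, table) {
  if (!is.null(res$error)) {
    cls <- switch(res$error, parse = "vgnp_parse_error",
                  embed = "vgnp_embed_error", "vgnp_parse_error")
    vgnp_abort(sprintf("ligand '%s': %s", spec$ligand_id,
                       res$detail %||% res$error),
               cls, ligand_id = spec$ligand_id)
  }
  atoms <- data.frame(element = unlist(res$atoms$element),
                      x = unlist(res$atoms$x),
                      y = unlist(res$atoms$y),
                      z = unlist(res$atoms$z),
                      aromatic = unlist(res$atoms$aromatic),
                      formal_charge = unlist(res$atoms$formal_charge),
                      f = unlist(res$atoms$crippen_logp),
                      stringsAsFactors = FALSE)
  bonds <- if (length(res$bonds$i) > 0) {
    data.frame(i = unlist(res$bonds$i), j = unlist(res$bonds$j),
               order = unlist(res$bonds$order),
               aromatic = unlist(res$bonds$aromatic))
  } else {
    data.frame(i = integer(0), j = integer(0), order = numeric(0),
               aromatic = logical(0))
  }
  mol <- structure(
    list(ligand_id = spec$ligand_id, atoms = atoms, bonds = bonds,
         attachment_index = NA_integer_,
         attachment_matches = as.integer(unlist(res$attachment_matches)),
         mol_logp = res$mol_logp, embed_seed = res$seed,
         contribution_table = NA_character_, source = spec),
    class = "ligand_molecule")
  mol <- assign_lipophilicity(mol, table = table, radii = radii)
  matches <- mol$attachment_matches
  if (length(matches) > 1) {
    warning(sprintf(
      "ligand '%s': attachment rule matched %d atoms; using atom %d (first in canonical order)",
      spec$ligand_id, length(matches), matches[1]), call. = FALSE)
  }
  if (length(matches) >= 1) mol$attachment_index <- matches[1]
  mol
}

#' Assign atomic lipophilicity contributions and radii
#'
#' Attaches the chosen atom-contribution logP scheme's per-atom values
#' `f_i` and the van der Waals radii to a parsed ligand.  Contributions are
#' topology-only: re-embedding the same structure leaves `f_i` unchanged.
#' Gold atoms always carry `f = 0`.  The sum of `f_i` over the molecule
#' equals the scheme's whole-molecule logP.
#'
#' @param mol A `ligand_molecule`.
#' @param table Contribution-table identifier (`"wildman_crippen"`).
#' @param radii Named vdW radius vector by element symbol.
#' @return The ligand with validated `f` and `vdw` columns.
#' @export
assign_lipophilicity <- function(mol, table = "wildman_crippen",
                                 radii = vgnp_vdw_radii()) {
  if (!identical(table, "wildman_crippen")) {
    vgnp_abort(sprintf("unknown contribution table '%s'", table),
               "vgnp_typing_error")
  }
  atoms <- mol$atoms
  supported <- names(radii)
  bad <- setdiff(unique(atoms$element), supported)
  if (length(bad) > 0) {
    vgnp_abort(sprintf(
      "ligand '%s': element(s) not covered by the contribution/radius tables: %s",
      mol$ligand_id, paste(bad, collapse = ", ")),
      "vgnp_typing_error", elements = bad)
  }
  atoms$vdw <- unname(radii[atoms$element])
  atoms$f[atoms$element == "Au"] <- 0
  if (!all(is.finite(atoms$f))) {
    vgnp_abort(sprintf("ligand '%s': non-finite contribution values",
                       mol$ligand_id), "vgnp_typing_error")
  }
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    vgnp_abort(sprintf("ligand '%s': non-finite coordinates",
                       mol$ligand_id), "vgnp_embed_error")
  }
  mol$atoms <- atoms
  mol$contribution_table <- table
  mol
}

#' Locate the core-attachment atom
#'
#' Matches a substructure pattern against the ligand and returns the index
#' of the first matching atom under the canonical atom ordering (input
#' heavy-atom order with explicit hydrogens appended).  More than one match
#' emits a warning and returns the first; no match is an error.
#'
#' @param mol A `ligand_molecule`.
#' @param rule SMARTS pattern; defaults to the rule the ligand was parsed
#'   with.
#' @return Integer atom index (1-based).
#' @export
find_attachment_atom <- function(mol, rule = NULL) {
  if (is.null(rule) || identical(rule, mol$source$attachment_rule)) {
    matches <- mol$attachment_matches
  } else {
    spec <- mol$source
    spec$attachment_rule <- rule
    res <- run_ligand_bridge(list(bridge_request(spec, mol$embed_seed)))[[1]]
    if (!is.null(res$error)) {
      vgnp_abort(sprintf("ligand '%s': %s", mol$ligand_id,
                         res$detail %||% res$error),
                 "vgnp_attachment_error", ligand_id = mol$ligand_id)
    }
    matches <- as.integer(unlist(res$attachment_matches))
  }
  if (length(matches) == 0) {
    vgnp_abort(sprintf(
      "ligand '%s': attachment rule matched no atom", mol$ligand_id),
      "vgnp_attachment_error", ligand_id = mol$ligand_id)
  }
  if (length(matches) > 1) {
    warning(sprintf(
      "ligand '%s': attachment rule matched %d atoms; using atom %d",
      mol$ligand_id, length(matches), matches[1]), call. = FALSE)
  }
  matches[1]
}

#' Whole-molecule atom-contribution logP of a ligand
#'
#' @param mol A `ligand_molecule`.
#' @return Sum of the per-atom contributions.
#' @export
ligand_logp <- function(mol) sum(mol$atoms$f)

#' @export
print.ligand_molecule <- function(x, ...) {
  cat(sprintf("<ligand_molecule '%s'>\n", x$ligand_id))
  cat(sprintf("  %d atoms (%s), embed seed %d\n", nrow(x$atoms),
              paste(names(sort(table(x$atoms$element), decreasing = TRUE)),
                    collapse = ""), x$embed_seed))
  cat(sprintf("  contribution table: %s, sum f_i = %.4f\n",
              x$contribution_table, sum(x$atoms$f)))
  cat(sprintf("  attachment atom: %s\n",
              ifelse(is.na(x$attachment_index), "<none>",
                     sprintf("%d (%s)", x$attachment_index,
                             x$atoms$element[x$attachment_index]))))
  invisible(x)
}
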
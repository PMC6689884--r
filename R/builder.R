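#' Construct the gold core
#'
#' The core is modelled as a single occluding sphere centred at the origin
#' with radius equal to half the stated diameter (`occlusion_radius`, in
#' Angstrom).  The default implicit representation is scale-free: because
#' gold carries no lipophilicity contribution, only the occlusion geometry
#' enters the surface score.  An atomistic shell (gold atoms on a spherical
#' Fibonacci lattice at the occlusion radius) is available for
#' visualization and export.
#'
#' @param diameter Core diameter in nm (> 0).
#' @param representation `"implicit_sphere"` (default) or
#'   `"atomistic_shell"`.
#' @param lattice_spacing Target Au-Au spacing of the atomistic shell in
#'   Angstrom (bulk-gold nearest-neighbour distance by default).
#' @return A `vgnp_core` object with fields `diameter` (nm),
#'   `occlusion_radius` (A), `representation` and, for atomistic shells,
#'   a `shell` data frame of gold atoms.
#' @export
#' @examples
#' build_core(2)$occlusion_radius   # 10 Angstrom
build_core <- function(diameter,
                       representation = c("implicit_sphere",
                                          "atomistic_shell"),
                       lattice_spacing = 2.884) {
  stopifnot_scalar(diameter, "diameter", positive = TRUE)
  representation <- match.arg(representation)
  r <- diameter * 10 / 2
  core <- structure(list(diameter = diameter, occlusion_radius = r,
                         representation = representation, shell = NULL),
                    class = "vgnp_core")
  if (representation == "atomistic_shell") {
    n <- max(1L, round(4 * pi * r^2 / lattice_spacing^2))
    pts <- fibonacci_sphere(n) * r
    core$shell <- data.frame(element = "Au", x = pts[, 1], y = pts[, 2],
                             z = pts[, 3],
                             vdw = unname(vgnp_vdw_radii()["Au"]), f = 0)
  }
  core
}

# Near-uniform deterministic point set on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Convert grafting density to a copy number
#'
#' `count = round(density * 4 pi r_nm^2)` with `r_nm` the core radius in nm.
#'
#' @param density Ligands per nm^2 (> 0).
#' @param core A `vgnp_core`.
#' @return Integer count; a zero result is allowed and warned about.
#' @export
#' @examples
#' density_to_count(1, build_core(2))   # round(4*pi) = 13
density_to_count <- function(density, core) {
  stopifnot_scalar(density, "density", positive = TRUE)
  stopifnot(inherits(core, "vgnp_core"))
  r_nm <- core$diameter / 2
  n <- as.integer(round(density * 4 * pi * r_nm^2))
  if (n == 0) {
    warning(sprintf(
      "density %g /nm^2 on a %g nm core rounds to 0 ligands", density,
      core$diameter), call. = FALSE)
  }
  n
}

#' Graft ligands onto the core
#'
#' Anchor points are drawn uniformly on the core sphere (normalized 3D
#' Gaussian draws) with rejection of candidates closer than
#' `min_separation` (arc length at the core surface) to an accepted anchor.
#' Ligand identities are assigned to anchors in seeded random order, so
#' mixed-ligand particles are interleaved rather than patched.  Each copy
#' is rigid-body placed with its attachment atom at
#' `anchor + bond_offset` along the outward normal, the attachment-to-
#' centroid axis aligned radially outward, and a seeded random roll about
#' that axis.  No clash relaxation is performed; overlapping atoms between
#' different ligand copies are counted and warned about (the surface step
#' handles buried atoms naturally).
#'
#' @param core A `vgnp_core`.
#' @param ligands List of `list(mol = <ligand_molecule>, count = <int>)`.
#' @param seed Integer seed governing anchors, identity order and rolls.
#' @param min_separation Minimum anchor separation, Angstrom of arc.
#' @param bond_offset S-Au bond offset along the outward normal, Angstrom.
#' @param max_attempts Rejection-sampling budget per anchor.
#' @return A `vgnp` object: the assembled particle.
#' @export
place_ligands <- function(core, ligands, seed = 1L, min_separation = 2.0,
                          bond_offset = 2.4, max_attempts = 2000L) {
  stopifnot(inherits(core, "vgnp_core"))
  counts <- vapply(ligands, function(l) as.integer(l$count), integer(1))
  if (any(counts < 0)) {
    vgnp_abort("ligand counts must be non-negative", "vgnp_domain_error")
  }
  mols <- lapply(ligands, function(l) l$mol)
  ids <- vapply(mols, function(m) m$ligand_id, character(1))
  if (anyDuplicated(ids)) {
    vgnp_abort("duplicated ligand_id in composition", "vgnp_domain_error")
  }
  for (m in mols) {
    if (is.na(m$attachment_index)) {
      vgnp_abort(sprintf(
        "ligand '%s' has no attachment atom; cannot graft", m$ligand_id),
        "vgnp_attachment_error", ligand_id = m$ligand_id)
    }
  }
  n_total <- sum(counts)
  R <- core$occlusion_radius

  placed <- with_seed(seed, {
    anchors <- sample_anchors(n_total, R, min_separation, max_attempts)
    assignment <- if (n_total > 0) {
      sample(rep.int(seq_along(ids), counts))
    } else integer(0)
    rolls <- stats::runif(n_total, 0, 2 * pi)
    list(anchors = anchors, assignment = assignment, rolls = rolls)
  })

  atom_blocks <- vector("list", n_total)
  rec_ligand <- character(n_total)
  copy_counter <- integer(length(ids))
  copy_index <- integer(n_total)
  for (k in seq_len(n_total)) {
    li <- placed$assignment[k]
    mol <- mols[[li]]
    u <- placed$anchors[k, ] / R
    xyz <- pose_ligand(mol, u, R, bond_offset, placed$rolls[k])
    blk <- mol$atoms[, c("element", "vdw", "f")]
    blk$x <- xyz[, 1]; blk$y <- xyz[, 2]; blk$z <- xyz[, 3]
    blk$ligand_id <- mol$ligand_id
    copy_counter[li] <- copy_counter[li] + 1L
    blk$copy <- copy_counter[li]
    atom_blocks[[k]] <- blk[, c("element", "x", "y", "z", "vdw", "f",
                                "ligand_id", "copy")]
    rec_ligand[k] <- mol$ligand_id
    copy_index[k] <- copy_counter[li]
  }

  atoms <- if (n_total > 0) do.call(rbind, atom_blocks) else
    data.frame(element = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), vdw = numeric(0), f = numeric(0),
               ligand_id = character(0), copy = integer(0))
  if (!is.null(core$shell)) {
    shell <- core$shell
    shell$ligand_id <- NA_character_
    shell$copy <- NA_integer_
    atoms <- rbind(atoms, shell[, names(atoms)])
  }
  rownames(atoms) <- NULL

  records <- data.frame(ligand_id = rec_ligand, copy = copy_index,
                        anchor_x = placed$anchors[, 1],
                        anchor_y = placed$anchors[, 2],
                        anchor_z = placed$anchors[, 3])

  particle <- structure(
    list(core = core, atoms = atoms, ligand_records = records,
         composition = data.frame(ligand_id = ids, count = counts),
         seed = as.integer(seed), min_separation = min_separation,
         bond_offset = bond_offset),
    class = "vgnp")

  n_clash <- count_interligand_overlaps(particle)
  if (n_clash > 0) {
    warning(sprintf(
      "%d inter-ligand atom pair(s) overlap (d < (r_i+r_j)/2); no relaxation is applied",
      n_clash), call. = FALSE)
  }
  particle
}

sample_anchors <- function(n, R, min_separation, max_attempts) {
  anchors <- matrix(NA_real_, n, 3)
  if (n == 0) return(anchors)
  min_cos <- cos(min_separation / R)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      v <- stats::rnorm(3)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) next
      u <- v / nv
      if (k == 1) { ok <- TRUE } else {
        prev <- anchors[seq_len(k - 1), , drop = FALSE] / R
        # arc distance >= min_separation  <=>  cos(angle) <= cos(min/R)
        ok <- all(prev %*% u <= min_cos + 1e-12)
      }
      if (ok) { anchors[k, ] <- u * R; break }
    }
    if (!ok) {
      vgnp_abort(sprintf(
        "anchor packing failed: placed %d of %d ligands at min separation %.2f A (attempt budget %d)",
        k - 1L, n, min_separation, max_attempts),
        "vgnp_packing_error", achieved = k - 1L, requested = n)
    }
  }
  anchors
}

pose_ligand <- function(mol, u, R, bond_offset, roll) {
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  att <- xyz[mol$attachment_index, ]
  centred <- sweep(xyz, 2, att)
  centroid <- colMeans(centred)
  ncen <- sqrt(sum(centroid^2))
  rot <- if (ncen > 1e-8) {
    rotation_about(u, roll) %*% rotation_between(centroid / ncen, u)
  } else {
    rotation_about(u, roll)
  }
  out <- centred %*% t(rot)
  sweep(out, 2, u * (R + bond_offset), `+`)
}

# Count atom pairs from *different* ligand copies closer than half the sum
# of their vdW radii (a severe clash).  Cell-list based, O(n).
count_interligand_overlaps <- function(particle) {
  atoms <- particle$atoms
  atoms <- atoms[!is.na(atoms$ligand_id), , drop = FALSE]
  n <- nrow(atoms)
  if (n < 2) return(0L)
  tag <- paste(atoms$ligand_id, atoms$copy)
  cell <- 2 * max(atoms$vdw)
  key <- floor(cbind(atoms$x, atoms$y, atoms$z) / cell)
  keystr <- paste(key[, 1], key[, 2], key[, 3])
  buckets <- split(seq_len(n), keystr)
  keymap <- do.call(rbind, lapply(strsplit(names(buckets), " "), as.numeric))
  total <- 0L
  for (b in seq_along(buckets)) {
    i0 <- buckets[[b]]
    kb <- keymap[b, ]
    neigh <- which(abs(keymap[, 1] - kb[1]) <= 1 &
                     abs(keymap[, 2] - kb[2]) <= 1 &
                     abs(keymap[, 3] - kb[3]) <= 1)
    cand <- unlist(buckets[neigh], use.names = FALSE)
    for (i in i0) {
      j <- cand[cand > i]
      j <- j[tag[j] != tag[i]]
      if (length(j) == 0) next
      d2 <- (atoms$x[j] - atoms$x[i])^2 + (atoms$y[j] - atoms$y[i])^2 +
        (atoms$z[j] - atoms$z[i])^2
      lim <- ((atoms$vdw[j] + atoms$vdw[i]) / 2)^2
      total <- total + sum(d2 < lim)
    }
  }
  total
}

#' Assemble a particle directly from an atom table
#'
#' Low-level constructor used when the atoms are already known (tests,
#' imported structures).  `atoms` needs columns `x`, `y`, `z`, `vdw`, `f`;
#' `element` defaults to `"C"`.
#'
#' @param atoms Data frame of atoms.
#' @param core Optional `vgnp_core` providing the occluding sphere.
#' @return A `vgnp` object.
#' @export
vgnp_from_atoms <- function(atoms, core = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("x", "y", "z", "vdw", "f") %in% names(atoms)))
  n <- nrow(atoms)
  if (is.null(atoms$element)) atoms$element <- rep("C", n)
  if (is.null(atoms$ligand_id)) atoms$ligand_id <- rep(NA_character_, n)
  if (is.null(atoms$copy)) atoms$copy <- rep(NA_integer_, n)
  structure(list(core = core,
                 atoms = atoms[, c("element", "x", "y", "z", "vdw", "f",
                                   "ligand_id", "copy")],
                 ligand_records = data.frame(),
                 composition = data.frame(), seed = NA_integer_,
                 min_separation = NA_real_, bond_offset = NA_real_),
            class = "vgnp")
}

#' Build a virtual nanoparticle from ligand specs
#'
#' High-level wrapper: parses the ligand specs, resolves densities into
#' counts for the given core, and grafts the ligands.
#'
#' @param specs List of [ligand_spec()] objects.
#' @param core_diameter Core diameter in nm.
#' @param config A [vgnp_config()] list (grid values are ignored here).
#' @param seed Placement seed; defaults to `config$placement_seed`.
#' @return A `vgnp` object.
#' @export
#' @examples
#' \dontrun{
#' p <- build_vgnp(list(ligand_spec("C12", "SCCCCCCCCCCCC", count = 10)),
#'                 core_diameter = 2)
#' }
build_vgnp <- function(specs, core_diameter, config = vgnp_config(),
                       seed = NULL) {
  core <- build_core(core_diameter,
                     representation = config$core_representation)
  mols <- parse_ligands(specs, embed_seed = config$embed_seed,
                        table = config$contribution_table)
  ligands <- mapply(function(spec, mol) {
    cnt <- if (!is.null(spec$count)) spec$count
           else density_to_count(spec$density, core)
    list(mol = mol, count = cnt)
  }, lapply(specs, as_ligand_spec), mols, SIMPLIFY = FALSE)
  place_ligands(core, ligands, seed = seed %||% config$placement_seed,
                min_separation = config$min_separation,
                bond_offset = config$bond_offset,
                max_attempts = config$max_attempts)
}

#' @export
print.vgnp <- function(x, ...) {
  cat("<vgnp>\n")
  if (!is.null(x$core)) {
    cat(sprintf("  core: %g nm %s (occlusion radius %.1f A)\n",
                x$core$diameter, x$core$representation,
                x$core$occlusion_radius))
  }
  comp <- if (nrow(x$composition) > 0) {
    paste(sprintf("%s x%d", x$composition$ligand_id, x$composition$count),
          collapse = ", ")
  } else "none"
  cat(sprintf("  ligands: %s\n", comp))
  cat(sprintf("  atoms: %d, placement seed: %s\n", nrow(x$atoms),
              ifelse(is.na(x$seed), "<none>", x$seed)))
  invisible(x)
}
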
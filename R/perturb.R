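# Self-supervision data engine: measure chi angles, re-pose side chains at
# sampled rotamers by rigid rotation about the chi axes, and record per-atom
# displacements between the original and perturbed conformations.

#' Backbone phi/psi dihedrals
#' @param structure A `ProteinStructure`.
#' @return data.frame with `phi` and `psi` in degrees (NA at termini).
#' @export
backbone_dihedrals <- function(structure) {
  res <- structure$residues
  n <- length(res)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1) {
      phi[i] <- dihedral(res_coord(res[[i - 1]], "C"), res_coord(res[[i]], "N"),
                         res_coord(res[[i]], "CA"), res_coord(res[[i]], "C"))
    }
    if (i < n) {
      psi[i] <- dihedral(res_coord(res[[i]], "N"), res_coord(res[[i]], "CA"),
                         res_coord(res[[i]], "C"), res_coord(res[[i + 1]], "N"))
    }
  }
  data.frame(phi = phi, psi = psi)
}

#' Measure side-chain chi angles
#'
#' @param structure A `ProteinStructure`.
#' @param residue_index 0-based residue index.
#' @return Numeric vector of chi angles in degrees, (-180, 180]; empty for
#'   GLY/ALA.
#' @export
measure_chi_angles <- function(structure, residue_index) {
  res <- get_residue(structure, residue_index)
  topo <- residue_topology(res$type3)
  vapply(topo$chi, function(q) {
    miss <- setdiff(q, res$atom_names)
    if (length(miss)) stop("missing atom ", miss[1], " for chi in residue ", residue_index)
    dihedral(res_coord(res, q[1]), res_coord(res, q[2]),
             res_coord(res, q[3]), res_coord(res, q[4]))
  }, numeric(1))
}

#' Re-pose a side chain at given chi angles
#'
#' Rotates, for each chi k in order, the atoms distal to the chi axis so the
#' measured chi equals the target; backbone, CB, and all other residues are
#' untouched, and intra-side-chain bond geometry is preserved exactly.
#'
#' @param structure A `ProteinStructure`.
#' @param residue_index 0-based residue index.
#' @param chi Target chi vector (degrees), length equal to the residue's chi
#'   count.
#' @return New `ProteinStructure`.
#' @export
apply_side_chain_torsions <- function(structure, residue_index, chi) {
  pos <- which(vapply(structure$residues, `[[`, 0L, "index") == residue_index)
  if (length(pos) != 1) stop("no residue with index ", residue_index)
  res <- structure$residues[[pos]]
  topo <- residue_topology(res$type3)
  if (length(chi) != length(topo$chi)) {
    stop("chi length ", length(chi), " does not match ", res$type3,
         " chi count ", length(topo$chi))
  }
  xyz <- res$xyz
  for (k in seq_along(chi)) {
    q <- topo$chi[[k]]
    cur <- dihedral(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
    delta <- wrap_angle(chi[k] - cur)
    mv <- intersect(topo$moving_sets[[k]], rownames(xyz))
    if (length(mv) == 0) next
    # rotate_about_axis is right-handed about q2->q3; the measured dihedral
    # decreases by that rotation, so apply the negated delta
    xyz[mv, ] <- rotate_about_axis(xyz[mv, , drop = FALSE],
                                   xyz[q[2], ], xyz[q[3], ], -delta)
  }
  res$xyz <- xyz
  structure$residues[[pos]] <- res
  structure
}

#' Perturb one residue to a sampled rotamer
#'
#' GLY and ALA have no chi angles: the structure is returned unchanged with
#' an all-zero displacement record. Otherwise a rotamer is sampled from the
#' library, applied, and the per-atom Euclidean displacement between the
#' original and perturbed positions recorded (zero for backbone and CB).
#'
#' @param structure A `ProteinStructure`.
#' @param residue_index 0-based residue index.
#' @param library A rotamer library.
#' @return List with `structure` (perturbed) and `record` (fields
#'   `residue_index`, `chi_original`, `chi_sampled`, `displacement`: named
#'   per-atom distances in Angstrom).
#' @export
perturb_residue <- function(structure, residue_index, library = default_rotamer_library()) {
  res <- get_residue(structure, residue_index)
  zero_rec <- function() {
    list(residue_index = residue_index, chi_original = numeric(0),
         chi_sampled = numeric(0),
         displacement = stats::setNames(numeric(length(res$atom_names)),
                                        res$atom_names))
  }
  if (n_chi(res$type3) == 0) {
    return(list(structure = structure, record = zero_rec()))
  }
  chi0 <- measure_chi_angles(structure, residue_index)
  bb <- backbone_dihedrals(structure)
  pos <- which(vapply(structure$residues, `[[`, 0L, "index") == residue_index)
  chi1 <- sample_rotamer(library, res$type3, bb$phi[pos], bb$psi[pos])
  pert <- apply_side_chain_torsions(structure, residue_index, chi1)
  new_xyz <- get_residue(pert, residue_index)$xyz
  disp <- sqrt(rowSums((new_xyz - res$xyz)^2))
  rec <- list(residue_index = residue_index, chi_original = chi0,
              chi_sampled = chi1,
              displacement = stats::setNames(as.numeric(disp), res$atom_names))
  list(structure = pert, record = rec)
}

#' Residues eligible for perturbation
#' @param structure A `ProteinStructure`.
#' @param exclude_proline Drop prolines (ring closure is not modelled).
#' @return Integer vector of 0-based residue indices with >= 1 chi angle.
#' @export
perturbable_residues <- function(structure, exclude_proline = TRUE) {
  keep <- vapply(structure$residues, function(r) {
    n_chi(r$type3) > 0 && !(exclude_proline && r$type3 == "PRO")
  }, logical(1))
  vapply(structure$residues[keep], `[[`, 0L, "index")
}

#' Build a self-supervision perturbation dataset
#'
#' For each structure, draws `per_structure` residues uniformly at random
#' (with replacement) among chi-bearing residues and perturbs each
#' independently from the original structure.
#'
#' @param structures List of `ProteinStructure` objects.
#' @param per_structure Perturbations per structure.
#' @param library A rotamer library.
#' @param exclude_proline Drop prolines from the draw.
#' @return List of samples, each with `structure_id`, `structure`
#'   (perturbed), and `record`.
#' @export
make_perturbation_dataset <- function(structures, per_structure = 2000L,
                                      library = default_rotamer_library(),
                                      exclude_proline = TRUE) {
  if (per_structure < 1) stop("per_structure must be >= 1")
  out <- list()
  for (s in structures) {
    cand <- perturbable_residues(s, exclude_proline)
    if (length(cand) == 0) {
      warning("structure ", s$id, " has no perturbable residue; skipped")
      next
    }
    picks <- cand[sample.int(length(cand), per_structure, replace = TRUE)]
    for (ri in picks) {
      p <- perturb_residue(s, ri, library)
      out[[length(out) + 1L]] <- list(structure_id = s$id,
                                      structure = p$structure,
                                      record = p$record)
    }
  }
  out
}

#' Perturbation sample budget
#'
#' Planner for the size of a self-supervision dataset: total samples
#' produced by `make_perturbation_dataset` over `n_structures` structures
#' at `per_structure` draws each.
#'
#' @param n_structures Number of structures.
#' @param per_structure Perturbations per structure.
#' @return Total sample count.
#' @export
n_perturbation_samples <- function(n_structures, per_structure = 2000) {
  stopifnot(n_structures >= 0, per_structure >= 1)
  as.numeric(n_structures) * as.numeric(per_structure)
}
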
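# ddG feature construction: mutant side-chain placement, atom-set
# definitions over the wild-type and mutant graphs, max/mean pooling of the
# layer-3/4 representations, block differences, concatenation, and
# training-set standardization.

# Improper torsion (C, N, CA, CB) fixing the L-configuration of CB.
CB_IMPROPER <- 122.0
CB_BOND <- 1.532
CB_ANGLE <- 110.5  # N-CA-CB

# Build side-chain coordinates for a residue type given backbone N/CA/C and
# a chi vector; returns a named coordinate matrix (CB first).
place_side_chain <- function(N, CA, C, type3, chi) {
  topo <- residue_topology(type3)
  if (length(chi) != length(topo$chi)) {
    stop("chi length mismatch for ", type3)
  }
  if (type3 == "GLY") return(matrix(numeric(0), 0, 3))
  pos <- list(N = N, CA = CA, C = C)
  pos$CB <- place_atom(C, N, CA, CB_BOND, CB_ANGLE, CB_IMPROPER)
  for (row in topo$zmat) {
    tors <- if (!is.na(row$chi)) wrap_angle(chi[row$chi] + row$off) else row$off
    pos[[row$name]] <- place_atom(pos[[row$a]], pos[[row$b]], pos[[row$c]],
                                  row$bond, row$angle, tors)
  }
  side <- setdiff(topo$atoms, BACKBONE_ATOMS)
  out <- do.call(rbind, pos[side])
  rownames(out) <- side
  out
}

#' Build a mutant structure by template side-chain placement
#'
#' Replaces the side chain at `position` with the mutant type's idealized
#' template geometry posed at the library's highest-probability rotamer;
#' the backbone and every other residue are unchanged.
#'
#' @param structure Wild-type `ProteinStructure`.
#' @param position 0-based residue index of the mutation.
#' @param wt_aa,mut_aa One-letter codes; `wt_aa` must match the structure.
#' @param library A rotamer library.
#' @return Mutant `ProteinStructure`.
#' @export
build_mutant_structure <- function(structure, position, wt_aa, mut_aa,
                                   library = default_rotamer_library()) {
  if (wt_aa == mut_aa) stop("wt and mutant residues are identical (", wt_aa, ")")
  pos <- which(vapply(structure$residues, `[[`, 0L, "index") == position)
  if (length(pos) != 1) stop("no residue with index ", position)
  res <- structure$residues[[pos]]
  if (aa_one(res$type3) != toupper(wt_aa)) {
    stop("wild-type mismatch at position ", position, ": structure has ",
         aa_one(res$type3), ", record says ", wt_aa)
  }
  mut3 <- aa_three(mut_aa)
  bb <- backbone_dihedrals(structure)
  chi <- top_rotamer(library, mut3, bb$phi[pos], bb$psi[pos])
  side <- place_side_chain(res_coord(res, "N"), res_coord(res, "CA"),
                           res_coord(res, "C"), mut3, chi)
  topo <- residue_topology(mut3)
  xyz <- rbind(res$xyz[BACKBONE_ATOMS, , drop = FALSE], side)
  new_res <- new_residue(mut3, res$index, topo$atoms,
                         xyz[topo$atoms, , drop = FALSE], res$resno)
  structure$residues[[pos]] <- new_res
  structure$id <- paste0(structure$id, "_", toupper(wt_aa), position, toupper(mut_aa))
  structure
}

#' Atom sets for feature pooling
#'
#' Partitions each graph's nodes into the mutated residue's atoms and the
#' remaining environment atoms.
#'
#' @param wt_graph,mut_graph `ProteinGraph`s centered on the mutated residue.
#' @param position 0-based residue index of the mutation.
#' @return List with `A_mo`, `A_no` (wild-type graph node indices) and
#'   `A_mm`, `A_nm` (mutant graph node indices).
#' @export
define_atom_sets <- function(wt_graph, mut_graph, position) {
  if (wt_graph$center_residue != position || mut_graph$center_residue != position) {
    stop("graphs must be centered on the mutated residue")
  }
  A_mo <- which(wt_graph$atoms$residue_index == position)
  A_no <- setdiff(seq_len(wt_graph$n), A_mo)
  A_mm <- which(mut_graph$atoms$residue_index == position)
  A_nm <- setdiff(seq_len(mut_graph$n), A_mm)
  if (length(A_mo) == 0) stop("mutated residue has no atoms in the graph")
  if (length(A_no) == 0 || length(A_nm) == 0) {
    warning("degenerate structure: empty environment atom set")
  }
  list(A_mo = A_mo, A_no = A_no, A_mm = A_mm, A_nm = A_nm)
}

#' Max/mean pooling over an atom set
#'
#' @param reps Representation matrix (nodes x width).
#' @param atom_set Node indices (non-empty).
#' @return Vector: elementwise maximum concatenated with elementwise mean
#'   (length 2 x width).
#' @export
pool_block <- function(reps, atom_set) {
  if (length(atom_set) == 0) stop("cannot pool an empty atom set")
  sub <- reps[atom_set, , drop = FALSE]
  c(apply(sub, 2, max), colMeans(sub))
}

graph_for_features <- function(structure, position, annotation, radius, cutoff,
                               flag_mode) {
  gr <- build_graph(structure, position, annotation, radius = radius,
                    cutoff = cutoff)
  if (flag_mode == "none") {
    gr$X[, 33] <- 1
    gr$X[, 34] <- 0
  }
  gr
}

# Pooled blocks for one (wt, mut) structure pair; returns per-layer pooled
# pieces so direct and inverse vectors can both be assembled without
# re-encoding.
pooled_blocks <- function(state, wt_structure, mut_structure, position,
                          radius = 12.0, cutoff = 3.0, flag_mode = "site",
                          n_points = 100L) {
  ann_wt <- annotate_structure(wt_structure, n_points = n_points)
  ann_mut <- annotate_structure(mut_structure, n_points = n_points)
  g_wt <- graph_for_features(wt_structure, position, ann_wt, radius, cutoff, flag_mode)
  g_mut <- graph_for_features(mut_structure, position, ann_mut, radius, cutoff, flag_mode)
  sets <- define_atom_sets(g_wt, g_mut, position)
  w <- state$config$n_heads * state$config$head_dim
  rep_wt <- encode(g_wt, state)
  rep_mut <- encode(g_mut, state)
  lapply(c(1, 2), function(L) {
    cols <- (L - 1) * w + seq_len(w)
    list(mo = pool_block(rep_wt[, cols, drop = FALSE], sets$A_mo),
         no = pool_block(rep_wt[, cols, drop = FALSE], sets$A_no),
         mm = pool_block(rep_mut[, cols, drop = FALSE], sets$A_mm),
         nm = pool_block(rep_mut[, cols, drop = FALSE], sets$A_nm))
  })
}

assemble_feature <- function(blocks, inverse = FALSE) {
  unlist(lapply(blocks, function(b) {
    if (inverse) {
      c(b$mm, b$nm, b$mm - b$nm, b$mo, b$no, b$mo - b$no)
    } else {
      c(b$mo, b$no, b$mo - b$no, b$mm, b$nm, b$mm - b$nm)
    }
  }), use.names = FALSE)
}

#' Raw (pre-standardization) ddG feature vector for one mutation
#'
#' Builds wild-type and mutant graphs centered at the mutation site (the
#' mutated residue's atoms carry the perturbed flag in both graphs), encodes
#' both, and concatenates, for layers 3 and 4, the pooled blocks of the
#' mutated residue, its environment, and their difference, for both
#' structures. Length is 24 x (n_heads x head_dim).
#'
#' @param state Trained `EncoderState`.
#' @param wt_structure Wild-type `ProteinStructure`.
#' @param position 0-based residue index.
#' @param wt_aa,mut_aa One-letter codes.
#' @param library Rotamer library for mutant template placement.
#' @param mut_structure Optional externally modelled mutant structure.
#' @param flag_mode "site" flags the mutated residue, "none" flags nothing.
#' @param radius,cutoff,n_points Graph/annotation parameters.
#' @return Numeric feature vector.
#' @export
featurize <- function(state, wt_structure, position, wt_aa, mut_aa,
                      library = default_rotamer_library(),
                      mut_structure = NULL, flag_mode = c("site", "none"),
                      radius = 12.0, cutoff = 3.0, n_points = 100L) {
  flag_mode <- match.arg(flag_mode)
  if (is.null(mut_structure)) {
    mut_structure <- build_mutant_structure(wt_structure, position, wt_aa,
                                            mut_aa, library)
  }
  blocks <- pooled_blocks(state, wt_structure, mut_structure, position,
                          radius, cutoff, flag_mode, n_points)
  assemble_feature(blocks)
}

#' Fit / apply training-set standardization
#'
#' Column means and standard deviations from the training matrix only;
#' zero-variance columns are mapped to 0 and their indices recorded.
#'
#' @param X Training feature matrix (>= 2 rows).
#' @return A `FeatureScaler`.
#' @export
fit_scaler <- function(X) {
  if (nrow(X) < 2) stop("scaler needs >= 2 training rows")
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  dropped <- which(sd_ < 1e-12)
  sd_[dropped] <- 1
  structure(list(mean = mu, sd = sd_, dropped = dropped),
            class = "FeatureScaler")
}

#' @rdname fit_scaler
#' @param scaler A `FeatureScaler`.
#' @param x Feature vector or matrix to transform with the training mean/sd.
#' @export
apply_scaler <- function(scaler, x) {
  if (is.matrix(x)) {
    out <- sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, `/`)
    out[, scaler$dropped] <- 0
    out
  } else {
    out <- (x - scaler$mean) / scaler$sd
    out[scaler$dropped] <- 0
    out
  }
}

#' Featurize a mutation table into direct + inverse rows
#'
#' For each direct record the wild-type and mutant structures are encoded
#' once; the direct row and its inverse partner (wild-type/mutant roles
#' swapped, label negated) are assembled from the same pooled blocks.
#'
#' @param records data.frame with `structure_id`, `position`, `wt_aa`,
#'   `mut_aa`, and optionally `ddg_exp`.
#' @param structures Named list of wild-type `ProteinStructure`s.
#' @param state Trained `EncoderState`.
#' @param library Rotamer library.
#' @param flag_mode,radius,cutoff,n_points Passed to [featurize()].
#' @return List with `X` (feature matrix, 2 rows per record), `meta`
#'   (data.frame: `pair_id`, `is_inverse`, `ddg`, `structure_id`,
#'   `position`, `wt_aa`, `mut_aa`).
#' @export
featurize_dataset <- function(records, structures, state,
                              library = default_rotamer_library(),
                              flag_mode = "site", radius = 12.0, cutoff = 3.0,
                              n_points = 100L) {
  rows <- list()
  meta <- list()
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    wt <- structures[[rec$structure_id]]
    if (is.null(wt)) stop("no structure named ", rec$structure_id)
    mut <- build_mutant_structure(wt, rec$position, rec$wt_aa, rec$mut_aa, library)
    blocks <- pooled_blocks(state, wt, mut, rec$position, radius, cutoff,
                            flag_mode, n_points)
    ddg <- if ("ddg_exp" %in% names(records)) rec$ddg_exp else NA_real_
    rows[[length(rows) + 1L]] <- assemble_feature(blocks, inverse = FALSE)
    meta[[length(meta) + 1L]] <- data.frame(
      pair_id = r, is_inverse = FALSE, ddg = ddg,
      structure_id = rec$structure_id, position = rec$position,
      wt_aa = rec$wt_aa, mut_aa = rec$mut_aa, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- assemble_feature(blocks, inverse = TRUE)
    meta[[length(meta) + 1L]] <- data.frame(
      pair_id = r, is_inverse = TRUE, ddg = -ddg,
      structure_id = rec$structure_id, position = rec$position,
      wt_aa = rec$mut_aa, mut_aa = rec$wt_aa, stringsAsFactors = FALSE)
  }
  list(X = do.call(rbind, rows), meta = do.call(rbind, meta))
}
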
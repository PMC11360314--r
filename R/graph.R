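# Atom graph construction: nodes are heavy atoms near the perturbed (or
# mutated) residue, edges are contacts below a distance cutoff, node
# attributes are the fixed 36-component encoding.

ELEMENT_ORDER <- c("C", "N", "O", "S")
SS8_ORDER <- c("H", "B", "E", "G", "I", "T", "S", "-")
NODE_ATTR_LENGTH <- 36L

#' Structure annotation for node attributes
#'
#' @param structure A `ProteinStructure`.
#' @param ss8 Optional override passed to [assign_secondary_structure()].
#' @param probe_radius,n_points SASA quadrature settings.
#' @return List with `ss8` (per residue) and `sasa` (per atom, in
#'   `atom_table()` order).
#' @export
annotate_structure <- function(structure, ss8 = NULL, probe_radius = 1.4,
                               n_points = 100L) {
  list(ss8 = assign_secondary_structure(structure, override = ss8),
       sasa = compute_sasa(structure, probe_radius, n_points))
}

#' Heavy-atom centroid of a residue
#' @param structure A `ProteinStructure`.
#' @param residue_index 0-based residue index.
#' @return Numeric 3-vector.
#' @export
residue_center <- function(structure, residue_index) {
  colMeans(get_residue(structure, residue_index)$xyz)
}

#' Select atoms around a residue with whole-residue retention
#'
#' A residue contributes all of its atoms when any one of them lies strictly
#' within `radius` of the center point; otherwise none.
#'
#' @param structure A `ProteinStructure`.
#' @param center_residue 0-based residue index defining the center.
#' @param radius Selection radius in Angstrom (strict `<`).
#' @return Integer indices into `atom_table(structure)` rows.
#' @export
select_atoms <- function(structure, center_residue, radius = 12.0) {
  stopifnot(radius > 0)
  ctr <- residue_center(structure, center_residue)
  tab <- atom_table(structure)
  d <- sqrt((tab$x - ctr[1])^2 + (tab$y - ctr[2])^2 + (tab$z - ctr[3])^2)
  keep_res <- unique(tab$residue_index[d < radius])
  which(tab$residue_index %in% keep_res)
}

#' Contact edges below a distance cutoff
#'
#' All unordered atom pairs with Euclidean distance strictly less than
#' `cutoff`, found with a cell-list spatial grid (identical to the all-pairs
#' result).
#'
#' @param xyz Numeric matrix (n x 3) of coordinates.
#' @param cutoff Distance cutoff in Angstrom (strict `<`).
#' @return Two-column integer matrix of pairs (i < j); zero rows if none.
#' @export
build_edges <- function(xyz, cutoff = 3.0) {
  stopifnot(cutoff > 0)
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), 0, 2))
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  buckets <- split(seq_len(n), key)
  cell_of <- lapply(buckets, function(i) cell[i[1], ])
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0)
  out_j <- integer(0)
  c2 <- cutoff^2
  keys <- names(buckets)
  for (b in seq_along(buckets)) {
    ii <- buckets[[b]]
    base <- cell_of[[b]]
    for (o in seq_len(nrow(offs))) {
      nb_key <- paste(base[1] + offs[o, 1], base[2] + offs[o, 2],
                      base[3] + offs[o, 3])
      jj <- buckets[[nb_key]]
      if (is.null(jj)) next
      for (i in ii) {
        cand <- jj[jj > i]
        if (length(cand) == 0) next
        d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
          (xyz[cand, 3] - xyz[i, 3])^2
        hit <- cand[d2 < c2]
        if (length(hit)) {
          out_i <- c(out_i, rep.int(i, length(hit)))
          out_j <- c(out_j, hit)
        }
      }
    }
  }
  if (length(out_i) == 0) return(matrix(integer(0), 0, 2))
  ord <- order(out_i, out_j)
  cbind(out_i[ord], out_j[ord])
}

#' Encode one atom as a 36-component attribute vector
#'
#' Layout: element one-hot (C,N,O,S), residue-type one-hot (alphabetical
#' one-letter order), ss8 one-hot (H,B,E,G,I,T,S,-), perturbed-flag one-hot
#' (not-perturbed, perturbed), SASA>0 bit, is-C-alpha bit.
#'
#' @param element One of C/N/O/S.
#' @param type3 Three-letter residue code.
#' @param ss8 Secondary-structure label.
#' @param sasa SASA in A^2.
#' @param perturbed Logical flag.
#' @param atom_name PDB atom name (for the C-alpha bit).
#' @return Numeric vector of length 36.
#' @export
encode_node <- function(element, type3, ss8, sasa, perturbed, atom_name) {
  v <- numeric(NODE_ATTR_LENGTH)
  ei <- match(element, ELEMENT_ORDER)
  ri <- match(aa_one(type3), AA_ORDER)
  si <- match(ss8, SS8_ORDER)
  if (is.na(ei)) stop("unknown element: ", element)
  if (is.na(si)) stop("unknown ss8 label: ", ss8)
  v[ei] <- 1
  v[4 + ri] <- 1
  v[24 + si] <- 1
  v[if (isTRUE(perturbed)) 34 else 33] <- 1
  v[35] <- as.numeric(sasa > 0)
  v[36] <- as.numeric(atom_name == "CA")
  v
}

#' Build the atom graph around a perturbed residue
#'
#' Nodes are the atoms selected by the 12 A whole-residue rule around the
#' perturbed residue's centroid; edges are contacts below 3 A; attributes
#' follow the fixed 36-component layout with the perturbed flag set on all
#' atoms of the perturbed residue (or only its chi-moving atoms with
#' `flag_moving_only`).
#'
#' @param structure A `ProteinStructure`.
#' @param perturbed_residue 0-based residue index.
#' @param annotation Output of [annotate_structure()] for this structure.
#' @param radius Selection radius (A).
#' @param cutoff Edge cutoff (A).
#' @param flag_moving_only Flag only chi-moving side-chain atoms.
#' @return A `ProteinGraph`: list with `atoms` (node table), `X` (n x 36
#'   attribute matrix), `edges` (2-column pairs), `perturbed_nodes`,
#'   `center_residue`, `n`.
#' @export
build_graph <- function(structure, perturbed_residue, annotation,
                        radius = 12.0, cutoff = 3.0,
                        flag_moving_only = FALSE) {
  tab <- atom_table(structure)
  if (nrow(tab) != length(annotation$sasa)) {
    stop("annotation was not computed on this structure (atom count differs)")
  }
  sel <- select_atoms(structure, perturbed_residue, radius)
  sub <- tab[sel, , drop = FALSE]
  sasa <- annotation$sasa[sel]
  res_idx_all <- vapply(structure$residues, `[[`, 0L, "index")
  ss_of <- stats::setNames(annotation$ss8, res_idx_all)
  flagged <- sub$residue_index == perturbed_residue
  if (flag_moving_only) {
    topo <- residue_topology(get_residue(structure, perturbed_residue)$type3)
    mv <- unique(unlist(topo$moving_sets))
    flagged <- flagged & sub$atom %in% mv
  }
  X <- matrix(0, nrow(sub), NODE_ATTR_LENGTH)
  for (i in seq_len(nrow(sub))) {
    X[i, ] <- encode_node(sub$element[i], sub$type3[i],
                          ss_of[[as.character(sub$residue_index[i])]],
                          sasa[i], flagged[i], sub$atom[i])
  }
  edges <- build_edges(as.matrix(sub[, c("x", "y", "z")]), cutoff)
  structure(list(atoms = sub, X = X, edges = edges,
                 perturbed_nodes = which(sub$residue_index == perturbed_residue),
                 center_residue = perturbed_residue, n = nrow(sub)),
            class = "ProteinGraph")
}

#' @export
print.ProteinGraph <- function(x, ...) {
  cat(sprintf("ProteinGraph: %d nodes, %d edges, %d perturbed atoms (residue %d)\n",
              x$n, nrow(x$edges), length(x$perturbed_nodes), x$center_residue))
  invisible(x)
}

#' Serialize / load a protein graph
#'
#' Portable JSON container: node table, edge list, perturbed-node indices
#' and metadata, for dataset caching.
#'
#' @param graph A `ProteinGraph`.
#' @param path File path.
#' @return `read_protein_graph` returns the `ProteinGraph`.
#' @export
write_protein_graph <- function(graph, path) {
  jsonlite::write_json(list(atoms = graph$atoms,
                            X = graph$X,
                            edges = graph$edges,
                            perturbed_nodes = graph$perturbed_nodes,
                            center_residue = graph$center_residue,
                            n = graph$n),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_protein_graph
#' @export
read_protein_graph <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(raw$edges)) matrix(as.integer(raw$edges), ncol = 2)
           else matrix(integer(0), 0, 2)
  structure(list(atoms = as.data.frame(raw$atoms), X = as.matrix(raw$X),
                 edges = edges,
                 perturbed_nodes = as.integer(raw$perturbed_nodes),
                 center_residue = as.integer(raw$center_residue),
                 n = as.integer(raw$n)),
            class = "ProteinGraph")
}
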
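# Protein structures: ordered residues of heavy atoms (C/N/O/S only).
# Residue indices are sequential 0-based chain positions; the author's PDB
# numbering is kept as metadata (`resno`).

new_residue <- function(type3, index, atom_names, xyz, resno = index + 1L) {
  stopifnot(length(atom_names) == nrow(xyz))
  if (anyDuplicated(atom_names)) stop("duplicate atom names in residue ", index)
  if (!all(BACKBONE_ATOMS %in% atom_names)) {
    stop("residue ", index, " (", type3, ") is missing backbone atoms")
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates in residue ", index)
  atom_element(atom_names)  # validates C/N/O/S
  rownames(xyz) <- atom_names
  structure(list(type3 = toupper(type3), index = as.integer(index),
                 resno = as.integer(resno), atom_names = atom_names,
                 xyz = xyz),
            class = "gatddg_residue")
}

#' Construct a protein structure
#'
#' @param residues List of residues (internal representation).
#' @param id Free-text label.
#' @return A `ProteinStructure` object.
#' @export
protein_structure <- function(residues, id = "protein") {
  idx <- vapply(residues, `[[`, 0L, "index")
  if (length(idx) && any(diff(idx) <= 0)) stop("residue indices must strictly increase")
  structure(list(id = id, residues = residues), class = "ProteinStructure")
}

#' @export
print.ProteinStructure <- function(x, ...) {
  cat(sprintf("ProteinStructure '%s': %d residues, %d heavy atoms\n",
              x$id, length(x$residues), nrow(atom_table(x))))
  cat(" sequence:", paste(aa_one(vapply(x$residues, `[[`, "", "type3")),
                          collapse = ""), "\n")
  invisible(x)
}

#' @export
length.ProteinStructure <- function(x) length(x$residues)

#' Sequence of a structure as one-letter codes
#' @param structure A `ProteinStructure`.
#' @return Character scalar.
#' @export
structure_sequence <- function(structure) {
  paste(aa_one(vapply(structure$residues, `[[`, "", "type3")), collapse = "")
}

get_residue <- function(structure, index) {
  for (r in structure$residues) if (r$index == index) return(r)
  stop("no residue with index ", index)
}

res_coord <- function(res, name) {
  if (!name %in% res$atom_names) {
    stop("atom ", name, " not present in residue ", res$index, " (", res$type3, ")")
  }
  res$xyz[name, ]
}

#' Flat atom table of a structure
#'
#' @param structure A `ProteinStructure`.
#' @return data.frame with one row per heavy atom: `residue_index`, `type3`,
#'   `resno`, `atom`, `element`, `x`, `y`, `z`.
#' @export
atom_table <- function(structure) {
  rows <- lapply(structure$residues, function(r) {
    data.frame(residue_index = r$index, type3 = r$type3, resno = r$resno,
               atom = r$atom_names, element = atom_element(r$atom_names),
               x = r$xyz[, 1], y = r$xyz[, 2], z = r$xyz[, 3],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

coord_matrix <- function(structure) {
  tab <- atom_table(structure)
  as.matrix(tab[, c("x", "y", "z")])
}

# Rebuild a structure from an atom table (inverse of atom_table)
structure_from_table <- function(tab, id = "protein") {
  res <- lapply(split(seq_len(nrow(tab)), tab$residue_index), function(i) {
    sub <- tab[i, ]
    new_residue(sub$type3[1], sub$residue_index[1], sub$atom,
                as.matrix(sub[, c("x", "y", "z")]), sub$resno[1])
  })
  res <- res[order(vapply(res, `[[`, 0L, "index"))]
  protein_structure(unname(res), id = id)
}

# Apply a function to all coordinates (rigid transforms in tests)
transform_structure <- function(structure, fun) {
  structure$residues <- lapply(structure$residues, function(r) {
    xyz <- fun(r$xyz)
    rownames(xyz) <- r$atom_names
    r$xyz <- xyz
    r
  })
  structure
}

#' Read a protein structure from a PDB file
#'
#' Loads heavy atoms (C/N/O/S) of the first model. Waters, ligands and
#' hydrogens are dropped; only the first alternate-location indicator is
#' kept. Residues with missing backbone or missing canonical side-chain
#' atoms are dropped with a warning (the training-set convention admits only
#' complete residues).
#'
#' @param path PDB file path.
#' @param chain Chain identifier; default first chain in the file.
#' @param skip_unknown Drop non-canonical residues instead of failing.
#' @return A `ProteinStructure`.
#' @export
read_pdb <- function(path, chain = NULL, skip_unknown = FALSE) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse failure: ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no ATOM records")
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: chain ", chain, " has no atoms")
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  # heavy atoms only
  clean <- toupper(sub("^[0-9]+", "", at$elety))
  keep <- substr(clean, 1, 1) %in% c("C", "N", "O", "S") & substr(clean, 1, 1) != "" &
    !grepl("^H", clean)
  at <- at[keep, , drop = FALSE]
  key <- paste(at$resno, at$insert)
  residues <- list()
  idx <- 0L
  for (k in unique(key)) {
    sub <- at[key == k, , drop = FALSE]
    type3 <- toupper(sub$resid[1])
    if (!type3 %in% names(SIDE_CHAIN_ZMAT)) {
      if (skip_unknown) next
      stop("unsupported residue type: ", type3)
    }
    topo <- residue_topology(type3)
    sub <- sub[sub$elety %in% topo$atoms, , drop = FALSE]
    sub <- sub[!duplicated(sub$elety), , drop = FALSE]
    if (!all(topo$atoms %in% sub$elety)) {
      warning("dropping residue ", sub$resno[1], " (", type3,
              "): incomplete heavy atoms")
      next
    }
    ord <- match(topo$atoms, sub$elety)
    xyz <- as.matrix(sub[ord, c("x", "y", "z")])
    residues[[length(residues) + 1L]] <-
      new_residue(type3, idx, topo$atoms, xyz, sub$resno[1])
    idx <- idx + 1L
  }
  if (length(residues) == 0) stop("empty structure: no complete canonical residues")
  protein_structure(residues, id = sub("\\.pdb$", "", basename(path)))
}

#' Write a protein structure to a PDB file
#'
#' Standard ATOM records, 3-decimal coordinates, occupancy 1.00, serials
#' from 1.
#'
#' @param structure A `ProteinStructure`.
#' @param path Output file path.
#' @param chain Chain identifier to write.
#' @export
write_pdb <- function(structure, path, chain = "A") {
  tab <- atom_table(structure)
  if (nrow(tab) == 0) stop("cannot write an empty structure")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(tab[, c("x", "y", "z")]))),
                   resno = tab$resno, resid = tab$type3,
                   eleno = seq_len(nrow(tab)), elety = tab$atom,
                   chain = rep(chain, nrow(tab)),
                   o = rep(1, nrow(tab)), b = rep(0, nrow(tab)),
                   elesy = tab$element)
  invisible(path)
}
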
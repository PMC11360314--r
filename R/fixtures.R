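# Synthetic fixtures: ideal-geometry peptide builder, the structure-quality
# filter predicate, and a synthetic ddG-labelled mutation-set generator with
# a declared generative rule so recovery tests have ground truth.

IDEAL_BACKBONE <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5, omega = 180
)

BACKBONE_CONFORMATIONS <- list(alpha = c(phi = -57, psi = -47),
                               extended = c(phi = -135, psi = 135))

# Kyte-Doolittle hydropathy and mean residue volumes (A^3)
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                   E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2)
RESIDUE_VOLUME <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
                    Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
                    L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
                    S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

#' Build an ideal-geometry peptide
#'
#' Backbone from ideal bond lengths/angles (N-CA 1.458, CA-C 1.525, C-N
#' 1.329 A, omega 180) at a named (phi, psi) conformation; side chains
#' attached from the topology templates at each type's highest-probability
#' rotamer. Deterministic given the arguments.
#'
#' @param sequence One-letter amino-acid string.
#' @param backbone "alpha" (phi -57, psi -47) or "extended" (phi -135,
#'   psi 135), or a length-2 numeric `c(phi, psi)`.
#' @param library Rotamer library for the template side chains.
#' @param id Structure label.
#' @return A `ProteinStructure`.
#' @export
make_peptide <- function(sequence, backbone = "alpha",
                         library = default_rotamer_library(),
                         id = NULL) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) < 1) stop("empty sequence")
  types <- aa_three(aa)  # validates letters
  bb <- if (is.character(backbone)) {
    if (!backbone %in% names(BACKBONE_CONFORMATIONS)) {
      stop("unknown backbone conformation: ", backbone)
    }
    BACKBONE_CONFORMATIONS[[backbone]]
  } else {
    c(phi = backbone[1], psi = backbone[2])
  }
  ib <- IDEAL_BACKBONE
  n <- length(aa)
  N <- CA <- C <- O <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(ib$n_ca, 0, 0)
  th <- ib$ang_n_ca_c * DEG
  C[1, ] <- CA[1, ] + ib$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           ib$c_n, ib$ang_ca_c_n, bb["psi"])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            ib$n_ca, ib$ang_c_n_ca, ib$omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           ib$ca_c, ib$ang_n_ca_c, bb["phi"])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         ib$c_o, ib$ang_ca_c_o, bb["psi"] - 180)
  }
  residues <- vector("list", n)
  for (i in seq_len(n)) {
    chi <- top_rotamer_safe(library, types[i])
    side <- place_side_chain(N[i, ], CA[i, ], C[i, ], types[i], chi)
    topo <- residue_topology(types[i])
    xyz <- rbind(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ], side)
    residues[[i]] <- new_residue(types[i], i - 1L, topo$atoms,
                                 xyz[topo$atoms, , drop = FALSE])
  }
  if (is.null(id)) {
    id <- paste0("pep_", substr(sequence, 1, 8), "_",
                 if (is.character(backbone)) backbone else "custom")
  }
  protein_structure(residues, id = id)
}

top_rotamer_safe <- function(library, type3) {
  if (n_chi(type3) == 0) numeric(0) else top_rotamer(library, type3)
}

#' Structure-quality filter criteria
#' @return The default criteria list (X-ray, R < 0.25, resolution < 2.0 A,
#'   length 40-500, sequence identity < 25%).
#' @export
filter_criteria <- function() {
  list(method = "X-ray", r_value_max = 0.25, resolution_max = 2.0,
       length_range = c(40L, 500L), identity_max = 25)
}

#' Does a structure's metadata pass the training-set quality filter?
#'
#' Conjunction of: X-ray method, R-value < 0.25, resolution strictly below
#' 2.0 A, chain length within 40-500, sequence identity below 25%. The
#' identity check is a metadata comparison only. A missing field fails with
#' a warning.
#'
#' @param metadata List with `method`, `r_value`, `resolution`, `length`,
#'   `identity`.
#' @param criteria Criteria list from [filter_criteria()].
#' @return Logical scalar.
#' @export
passes_filters <- function(metadata, criteria = filter_criteria()) {
  need <- c("method", "r_value", "resolution", "length", "identity")
  for (f in need) {
    v <- metadata[[f]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) {
      warning("missing metadata field: ", f)
      return(FALSE)
    }
  }
  isTRUE(metadata$method == criteria$method) &&
    metadata$r_value < criteria$r_value_max &&
    metadata$resolution < criteria$resolution_max &&
    metadata$length >= criteria$length_range[1] &&
    metadata$length <= criteria$length_range[2] &&
    metadata$identity < criteria$identity_max
}

#' Synthetic ddG-labelled mutation dataset
#'
#' Generates ideal peptides (alternating alpha/extended backbones, lengths
#' 10-30) and random single-point substitutions labelled by a declared
#' generative rule: ddg = w_h * d(hydropathy)/4.5 + w_v * d(volume)/100 +
#' w_b * burial + noise, with burial the fraction of wild-type residue
#' atoms with zero SASA and noise ~ N(0, sd). Rule parameters are returned
#' so recovery tests have ground truth.
#'
#' @param n_proteins Number of peptides.
#' @param muts_per_protein Direct mutations per peptide.
#' @param seed RNG seed.
#' @param noise_sd Label noise standard deviation (kcal/mol).
#' @return List with `structures` (named list), `records` (data.frame:
#'   `structure_id`, `chain`, `wt_aa`, `position`, `mut_aa`, `ddg_exp`),
#'   and `truth` (generative weights and seed).
#' @export
make_synthetic_ddg_dataset <- function(n_proteins, muts_per_protein,
                                       seed = 1L, noise_sd = 0.25) {
  stopifnot(n_proteins >= 1, muts_per_protein >= 1)
  set.seed(seed)
  w <- c(hydropathy = 1.0, volume = 1.5, burial = 0.8)
  aas <- names(AA_THREE)
  structures <- list()
  recs <- list()
  for (p in seq_len(n_proteins)) {
    len <- sample(10:30, 1)
    seq_ <- paste(sample(aas, len, replace = TRUE), collapse = "")
    conf <- if (p %% 2 == 1) "alpha" else "extended"
    sid <- sprintf("syn%03d", p)
    st <- make_peptide(seq_, conf, id = sid)
    structures[[sid]] <- st
    sasa <- compute_sasa(st)
    tab <- atom_table(st)
    aa_vec <- strsplit(seq_, "")[[1]]
    for (m in seq_len(muts_per_protein)) {
      pos <- sample(seq_len(len), 1) - 1L
      wt <- aa_vec[pos + 1]
      mut <- sample(setdiff(aas, wt), 1)
      burial <- mean(sasa[tab$residue_index == pos] == 0)
      ddg <- w["hydropathy"] * (KD_HYDROPATHY[mut] - KD_HYDROPATHY[wt]) / 4.5 +
        w["volume"] * (RESIDUE_VOLUME[mut] - RESIDUE_VOLUME[wt]) / 100 +
        w["burial"] * burial + stats::rnorm(1, 0, noise_sd)
      recs[[length(recs) + 1L]] <- data.frame(
        structure_id = sid, chain = "A", wt_aa = wt, position = pos,
        mut_aa = mut, ddg_exp = as.numeric(ddg), stringsAsFactors = FALSE)
    }
  }
  list(structures = structures, records = do.call(rbind, recs),
       truth = list(weights = w, seed = seed, noise_sd = noise_sd))
}

#' Read / write a mutation list TSV
#'
#' Columns: structure_id, chain, wt_aa, position, mut_aa, ddg_exp.
#'
#' @param path File path.
#' @return data.frame of mutation records.
#' @export
read_mutations <- function(path) {
  # read as character first: bare T/F amino-acid codes must not become logicals
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if ("position" %in% names(tab)) tab$position <- as.integer(tab$position)
  for (nm in intersect(c("ddg_exp", "ddg", "pred"), names(tab))) {
    tab[[nm]] <- as.numeric(tab[[nm]])
  }
  if ("is_inverse" %in% names(tab)) tab$is_inverse <- as.logical(tab$is_inverse)
  if ("pair_id" %in% names(tab)) tab$pair_id <- as.integer(tab$pair_id)
  tab
}

#' @rdname read_mutations
#' @param records data.frame of mutation records.
#' @export
write_mutations <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
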
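# Rotamer library: a compact backbone-independent table ships with the
# package (1-3 rotamers per chi-bearing residue, means/sigmas in degrees,
# probabilities summing to 1); a loader accepts full backbone-dependent
# Dunbrack-format files for fidelity runs.

rot <- function(prob, mean, sigma) {
  list(prob = prob, mean = mean, sigma = sigma)
}

default_rotamer_table <- function() {
  s1 <- 10  # sigma for chi1
  s2 <- 12
  list(
    SER = list(rot(0.48, 62, s1), rot(0.30, -65, s1), rot(0.22, 180, s1)),
    CYS = list(rot(0.55, -65, s1), rot(0.25, 180, s1), rot(0.20, 62, s1)),
    THR = list(rot(0.48, 62, s1), rot(0.45, -60, s1), rot(0.07, 180, s1)),
    VAL = list(rot(0.73, 175, s1), rot(0.20, -60, s1), rot(0.07, 62, s1)),
    ILE = list(rot(0.60, c(-65, 170), c(s1, s2)),
               rot(0.25, c(-65, -65), c(s1, s2)),
               rot(0.15, c(62, 170), c(s1, s2))),
    LEU = list(rot(0.60, c(-65, 175), c(s1, s2)),
               rot(0.30, c(180, 65), c(s1, s2)),
               rot(0.10, c(-85, 65), c(s1, s2))),
    ASP = list(rot(0.50, c(-70, -15), c(s1, 20)),
               rot(0.30, c(180, 5), c(s1, 20)),
               rot(0.20, c(62, -10), c(s1, 20))),
    ASN = list(rot(0.50, c(-65, -40), c(s1, 20)),
               rot(0.30, c(180, -60), c(s1, 20)),
               rot(0.20, c(62, -75), c(s1, 20))),
    GLU = list(rot(0.50, c(-67, 180, -10), c(s1, s2, 20)),
               rot(0.35, c(180, 180, 0), c(s1, s2, 20)),
               rot(0.15, c(62, 180, 0), c(s1, s2, 20))),
    GLN = list(rot(0.50, c(-67, 180, -25), c(s1, s2, 20)),
               rot(0.35, c(180, 180, 0), c(s1, s2, 20)),
               rot(0.15, c(62, 180, 0), c(s1, s2, 20))),
    MET = list(rot(0.40, c(-65, -65, -70), c(s1, s2, 15)),
               rot(0.35, c(-65, 180, 180), c(s1, s2, 15)),
               rot(0.25, c(180, 180, 180), c(s1, s2, 15))),
    LYS = list(rot(0.55, c(-67, 180, 180, 180), c(s1, s2, s2, s2)),
               rot(0.35, c(180, 180, 180, 180), c(s1, s2, s2, s2)),
               rot(0.10, c(62, 180, 180, 180), c(s1, s2, s2, s2))),
    ARG = list(rot(0.45, c(-67, 180, 180, 180), c(s1, s2, s2, 15)),
               rot(0.35, c(180, 180, 180, 180), c(s1, s2, s2, 15)),
               rot(0.20, c(62, 180, 180, 180), c(s1, s2, s2, 15))),
    HIS = list(rot(0.50, c(-65, -70), c(s1, 15)),
               rot(0.30, c(180, 60), c(s1, 15)),
               rot(0.20, c(62, 80), c(s1, 15))),
    PHE = list(rot(0.55, c(-65, 90), c(s1, 15)),
               rot(0.30, c(180, 75), c(s1, 15)),
               rot(0.15, c(62, 90), c(s1, 15))),
    TYR = list(rot(0.55, c(-65, 90), c(s1, 15)),
               rot(0.30, c(180, 75), c(s1, 15)),
               rot(0.15, c(62, 90), c(s1, 15))),
    TRP = list(rot(0.50, c(-65, 95), c(s1, 15)),
               rot(0.30, c(180, -105), c(s1, 15)),
               rot(0.20, c(62, 90), c(s1, 15))),
    PRO = list(rot(0.55, c(30, -35), c(8, 8)),
               rot(0.45, c(-25, 35), c(8, 8)))
  )
}

validate_rotamers <- function(tab, where = "rotamer table") {
  for (res in names(tab)) {
    p <- vapply(tab[[res]], `[[`, 0, "prob")
    if (abs(sum(p) - 1) > 1e-6) {
      stop(where, ": probabilities for ", res, " sum to ", sum(p))
    }
    nc <- n_chi(res)
    for (r in tab[[res]]) {
      if (length(r$mean) != nc || length(r$sigma) != nc) {
        stop(where, ": chi count mismatch for ", res)
      }
    }
  }
  invisible(tab)
}

#' Built-in backbone-independent rotamer library
#' @return A rotamer library object.
#' @export
default_rotamer_library <- function() {
  tab <- validate_rotamers(default_rotamer_table(), "built-in library")
  structure(list(backbone_dependent = FALSE, rotamers = tab),
            class = "RotamerLibrary")
}

#' Read a Dunbrack-style backbone-dependent rotamer library
#'
#' Whitespace-delimited rows: residue type, phi, psi, count, r1-r4 bin ids,
#' probability, chi1-chi4 means, chi1-chi4 sigmas (the bbdep02/10 layout).
#' Probabilities are renormalized per (residue, phi, psi) bin.
#'
#' @param path File path.
#' @return A rotamer library object keyed by 10-degree (phi, psi) bins.
#' @export
read_rotamer_library <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 17) stop("not a Dunbrack-format rotamer file (", ncol(tab), " columns)")
  names(tab)[c(1:3, 9:17)] <- c("res", "phi", "psi", "prob",
                                paste0("chi", 1:4), paste0("sig", 1:4))
  bins <- list()
  for (key in unique(paste(tab$res, tab$phi, tab$psi))) {
    sub <- tab[paste(tab$res, tab$phi, tab$psi) == key, , drop = FALSE]
    res <- toupper(sub$res[1])
    if (!res %in% names(CHI_ATOMS) || n_chi(res) == 0) next
    nc <- n_chi(res)
    p <- sub$prob / sum(sub$prob)
    rots <- lapply(seq_len(nrow(sub)), function(i) {
      rot(p[i],
          as.numeric(sub[i, paste0("chi", seq_len(nc))]),
          as.numeric(sub[i, paste0("sig", seq_len(nc))]))
    })
    bins[[paste(res, sub$phi[1], sub$psi[1], sep = "_")]] <- rots
  }
  structure(list(backbone_dependent = TRUE, bins = bins,
                 bin_phi = sort(unique(tab$phi)), bin_psi = sort(unique(tab$psi))),
            class = "RotamerLibrary")
}

get_rotamers <- function(library, residue_type, phi = NA, psi = NA) {
  residue_type <- toupper(residue_type)
  if (n_chi(residue_type) == 0) {
    stop("residue type ", residue_type, " has no chi angles")
  }
  if (!isTRUE(library$backbone_dependent)) {
    rots <- library$rotamers[[residue_type]]
    if (is.null(rots)) stop("no rotamers for residue type ", residue_type)
    return(rots)
  }
  nearest_bin <- function(x, centers) {
    if (is.na(x)) return(centers[1])
    centers[which.min(abs(wrap_angle(x - centers)))]
  }
  bp <- nearest_bin(phi, library$bin_phi)
  bq <- nearest_bin(psi, library$bin_psi)
  rots <- library$bins[[paste(residue_type, bp, bq, sep = "_")]]
  if (is.null(rots)) stop("no rotamers for ", residue_type, " at bin (", bp, ",", bq, ")")
  rots
}

#' Sample chi angles from a rotamer library
#'
#' Picks a rotamer with probability proportional to its library probability
#' (nearest (phi, psi) bin for backbone-dependent libraries), then draws
#' each chi from a normal with that rotamer's mean/sigma, wrapped to
#' (-180, 180]. Uses R's RNG; seed with `set.seed()` for reproducibility.
#'
#' @param library A rotamer library.
#' @param residue_type Three-letter code.
#' @param phi,psi Backbone dihedrals in degrees (used only for
#'   backbone-dependent libraries).
#' @return Numeric chi vector in degrees.
#' @export
sample_rotamer <- function(library, residue_type, phi = NA, psi = NA) {
  rots <- get_rotamers(library, residue_type, phi, psi)
  p <- vapply(rots, `[[`, 0, "prob")
  k <- sample.int(length(rots), 1L, prob = p)
  r <- rots[[k]]
  wrap_angle(stats::rnorm(length(r$mean), r$mean, r$sigma))
}

# Highest-probability rotamer means (template placement)
top_rotamer <- function(library, residue_type, phi = NA, psi = NA) {
  if (n_chi(residue_type) == 0) return(numeric(0))
  rots <- get_rotamers(library, residue_type, phi, psi)
  p <- vapply(rots, `[[`, 0, "prob")
  rots[[which.max(p)]]$mean
}
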
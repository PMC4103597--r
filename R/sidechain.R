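# Ideal-geometry side-chain construction and backbone dihedrals.
#
# Side chains are built from tabulated ideal bond lengths and angles by
# internal-coordinate placement; the chi dihedrals are free variables.
# Measuring the chi angles of a placed side chain returns the inputs exactly,
# which is what the repacking and evaluation layers rely on; ring closure for
# TRP/HIS is approximate at the far end of the ring (sub-0.1 Angstrom), a
# documented idealisation.

# Each recipe row: atom, ref1, ref2, ref3, bond length to ref3, angle
# ref2-ref3-atom, dihedral ref1-ref2-ref3-atom ("chi<k>" optionally +/- an
# offset, or a fixed number in degrees).
#' @noRd
SIDECHAIN_RECIPES <- list(
  ALA = list(),
  SER = list(c("OG", "N", "CA", "CB", 1.417, 110.8, "chi1")),
  CYS = list(c("SG", "N", "CA", "CB", 1.808, 113.8, "chi1")),
  THR = list(c("OG1", "N", "CA", "CB", 1.433, 109.6, "chi1"),
             c("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-120")),
  VAL = list(c("CG1", "N", "CA", "CB", 1.527, 110.7, "chi1"),
             c("CG2", "N", "CA", "CB", 1.527, 110.7, "chi1+122")),
  LEU = list(c("CG", "N", "CA", "CB", 1.530, 116.3, "chi1"),
             c("CD1", "CA", "CB", "CG", 1.521, 110.7, "chi2"),
             c("CD2", "CA", "CB", "CG", 1.521, 110.7, "chi2+122")),
  ILE = list(c("CG1", "N", "CA", "CB", 1.530, 110.4, "chi1"),
             c("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-122"),
             c("CD1", "CA", "CB", "CG1", 1.513, 113.8, "chi2")),
  MET = list(c("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
             c("SD", "CA", "CB", "CG", 1.803, 112.7, "chi2"),
             c("CE", "CB", "CG", "SD", 1.791, 100.9, "chi3")),
  PRO = list(c("CG", "N", "CA", "CB", 1.495, 104.5, "chi1"),
             c("CD", "CA", "CB", "CG", 1.507, 105.4, "chi2")),
  ASP = list(c("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
             c("OD1", "CA", "CB", "CG", 1.249, 118.5, "chi2"),
             c("OD2", "CA", "CB", "CG", 1.249, 118.5, "chi2+180")),
  ASN = list(c("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
             c("OD1", "CA", "CB", "CG", 1.231, 120.8, "chi2"),
             c("ND2", "CA", "CB", "CG", 1.328, 116.4, "chi2+180")),
  GLU = list(c("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
             c("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
             c("OE1", "CB", "CG", "CD", 1.249, 118.5, "chi3"),
             c("OE2", "CB", "CG", "CD", 1.249, 118.5, "chi3+180")),
  GLN = list(c("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
             c("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
             c("OE1", "CB", "CG", "CD", 1.231, 120.8, "chi3"),
             c("NE2", "CB", "CG", "CD", 1.328, 116.4, "chi3+180")),
  LYS = list(c("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
             c("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
             c("CE", "CB", "CG", "CD", 1.520, 111.3, "chi3"),
             c("NZ", "CG", "CD", "CE", 1.489, 111.9, "chi4")),
  ARG = list(c("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
             c("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
             c("NE", "CB", "CG", "CD", 1.461, 112.0, "chi3"),
             c("CZ", "CG", "CD", "NE", 1.329, 124.2, "chi4"),
             c("NH1", "CD", "NE", "CZ", 1.326, 120.0, "0"),
             c("NH2", "CD", "NE", "CZ", 1.326, 120.0, "180")),
  HIS = list(c("CG", "N", "CA", "CB", 1.497, 113.8, "chi1"),
             c("ND1", "CA", "CB", "CG", 1.378, 122.7, "chi2"),
             c("CD2", "CA", "CB", "CG", 1.356, 131.2, "chi2+180"),
             c("CE1", "CB", "CG", "ND1", 1.321, 109.3, "180"),
             c("NE2", "CB", "CG", "CD2", 1.374, 107.2, "180")),
  PHE = list(c("CG", "N", "CA", "CB", 1.500, 113.8, "chi1"),
             c("CD1", "CA", "CB", "CG", 1.391, 120.8, "chi2"),
             c("CD2", "CA", "CB", "CG", 1.391, 120.8, "chi2+180"),
             c("CE1", "CB", "CG", "CD1", 1.391, 120.8, "180"),
             c("CE2", "CB", "CG", "CD2", 1.391, 120.8, "180"),
             c("CZ", "CG", "CD1", "CE1", 1.391, 120.0, "0")),
  TYR = list(c("CG", "N", "CA", "CB", 1.500, 113.8, "chi1"),
             c("CD1", "CA", "CB", "CG", 1.391, 120.8, "chi2"),
             c("CD2", "CA", "CB", "CG", 1.391, 120.8, "chi2+180"),
             c("CE1", "CB", "CG", "CD1", 1.391, 120.8, "180"),
             c("CE2", "CB", "CG", "CD2", 1.391, 120.8, "180"),
             c("CZ", "CG", "CD1", "CE1", 1.391, 120.0, "0"),
             c("OH", "CD1", "CE1", "CZ", 1.377, 119.9, "180")),
  TRP = list(c("CG", "N", "CA", "CB", 1.498, 113.6, "chi1"),
             c("CD1", "CA", "CB", "CG", 1.365, 126.9, "chi2"),
             c("CD2", "CA", "CB", "CG", 1.433, 126.6, "chi2+180"),
             c("NE1", "CB", "CG", "CD1", 1.374, 110.2, "180"),
             c("CE2", "CB", "CG", "CD2", 1.409, 107.2, "180"),
             c("CE3", "CB", "CG", "CD2", 1.398, 133.9, "0"),
             c("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, "180"),
             c("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, "180"),
             c("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, "0"))
)

# CB placement: improper dihedral C-N-CA-CB fixed by L-chirality.
#' @noRd
CB_GEOMETRY <- c(length = 1.53, angle = 110.4, improper = 122.55)

#' @noRd
eval_dih_expr <- function(expr, chi) {
  if (grepl("^chi", expr)) {
    k <- as.integer(substr(expr, 4, 4))
    off <- 0
    rest <- substr(expr, 5, nchar(expr))
    if (nzchar(rest)) off <- as.numeric(rest)
    chi[k] + off
  } else {
    as.numeric(expr)
  }
}

#' Build side-chain heavy atoms from backbone atoms and chi angles
#'
#' Places CB and all further side-chain heavy atoms of `resname` from ideal
#' internal geometry. Measuring the chi angles of the result returns the
#' inputs to within numerical precision, and identical inputs give bitwise
#' identical coordinates.
#'
#' @param resname three-letter residue type.
#' @param N,CA,C backbone coordinates (3-vectors, Angstrom).
#' @param chi numeric vector of chi angles (degrees); its length must equal
#'   [n_chi()] of the type.
#' @return Matrix of side-chain atom coordinates with atom-name rownames
#'   (empty 0 x 3 matrix for GLY).
#' @export
place_side_chain <- function(resname, N, CA, C, chi = numeric(0)) {
  if (!resname %in% AA3) stop("unknown residue type: ", resname)
  if (resname == "GLY")
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  if (length(chi) != n_chi(resname))
    stop(sprintf("%s takes %d chi angle(s), got %d", resname,
                 n_chi(resname), length(chi)))
  pos <- list(N = N, CA = CA, C = C)
  pos$CB <- place_atom(C, N, CA, CB_GEOMETRY["length"], CB_GEOMETRY["angle"],
                       CB_GEOMETRY["improper"])
  for (row in SIDECHAIN_RECIPES[[resname]]) {
    nm <- row[1]
    pos[[nm]] <- place_atom(pos[[row[2]]], pos[[row[3]]], pos[[row[4]]],
                            as.numeric(row[5]), as.numeric(row[6]),
                            eval_dih_expr(row[7], chi))
  }
  nms <- c("CB", vapply(SIDECHAIN_RECIPES[[resname]], `[`, character(1), 1))
  out <- do.call(rbind, pos[nms])
  rownames(out) <- nms
  colnames(out) <- c("x", "y", "z")
  out
}

#' Backbone phi/psi dihedrals
#'
#' @param model a `memqa_structure`.
#' @return data.frame with res_ord, chain, resno, phi, psi (degrees; NA at
#'   chain termini or where backbone atoms are missing).
#' @export
backbone_dihedrals <- function(model) {
  rt <- residue_table(model)
  N <- atom_coords_by_residue(model, "N")
  CA <- atom_coords_by_residue(model, "CA")
  C <- atom_coords_by_residue(model, "C")
  n <- nrow(rt)
  phi <- psi <- rep(NA_real_, n)
  safe_dih <- function(a, b, c, d) {
    if (anyNA(c(a, b, c, d))) return(NA_real_)
    tryCatch(dihedral(a, b, c, d), error = function(e) NA_real_)
  }
  for (i in seq_len(n)) {
    if (i > 1 && rt$chain[i - 1] == rt$chain[i])
      phi[i] <- safe_dih(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    if (i < n && rt$chain[i + 1] == rt$chain[i])
      psi[i] <- safe_dih(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
  }
  data.frame(res_ord = rt$res_ord, chain = rt$chain, resno = rt$resno,
             phi = phi, psi = psi, stringsAsFactors = FALSE)
}

# Sequential backbone construction from phi/psi (omega fixed trans).
# Returns a list of per-residue matrices with rows N, CA, C, O.
#' @noRd
build_backbone <- function(phi, psi, origin = c(0, 0, 0)) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  b <- list()
  # first residue in a canonical pose
  N1 <- origin
  CA1 <- N1 + c(1.458, 0, 0)
  C1 <- place_atom(N1 + c(0, 1, 0), N1, CA1, 1.525, 111.2, 55)
  b[[1]] <- rbind(N = N1, CA = CA1, C = C1, O = c(0, 0, 0))
  for (i in seq_len(n)[-1]) {
    Np <- b[[i - 1]]["N", ]; CAp <- b[[i - 1]]["CA", ]; Cp <- b[[i - 1]]["C", ]
    psi_p <- if (is.na(psi[i - 1])) 180 else psi[i - 1]
    Ni <- place_atom(Np, CAp, Cp, 1.329, 116.2, psi_p)
    CAi <- place_atom(CAp, Cp, Ni, 1.458, 121.7, 180)  # omega trans
    phi_i <- if (is.na(phi[i])) -120 else phi[i]
    Ci <- place_atom(Cp, Ni, CAi, 1.525, 111.2, phi_i)
    b[[i]] <- rbind(N = Ni, CA = CAi, C = Ci, O = c(0, 0, 0))
  }
  # carbonyl O: anti to the next N (dihedral psi+180), last residue arbitrary
  for (i in seq_len(n)) {
    psi_i <- if (is.na(psi[i])) 180 else psi[i]
    b[[i]]["O", ] <- place_atom(b[[i]]["N", ], b[[i]]["CA", ], b[[i]]["C", ],
                                1.231, 120.5, psi_i + 180)
  }
  b
}
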
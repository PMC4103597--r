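# Side-chain chi dihedrals and the chi1/chi2 correctness metric.

# Atom quadruplets defining chi1..chi4 per residue type.
#' @noRd
CHI_ATOMS <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1"))
)

# chi angles whose terminal group is two-fold symmetric, so the measured
# angle is only defined modulo 180 degrees: ASP/PHE/TYR chi2, GLU chi3.
#' @noRd
CHI_SYMMETRIC <- list(ASP = 2L, PHE = 2L, TYR = 2L, GLU = 3L)

#' Number of chi angles of a residue type
#' @param resname three-letter code.
#' @return Integer 0..4.
#' @export
n_chi <- function(resname) {
  vapply(resname, function(r) {
    if (is.null(CHI_ATOMS[[r]])) 0L else length(CHI_ATOMS[[r]])
  }, integer(1))
}

#' Side-chain chi angles of every residue
#'
#' Measures chi1..chi4 from heavy-atom coordinates. A chi whose defining
#' atoms are missing is reported as NA (absence is represented, not raised);
#' GLY and ALA rows are all NA. Symmetric terminal groups (ASP, PHE, TYR
#' chi2; GLU chi3) are flagged: for those the angle is only meaningful
#' modulo 180 degrees.
#'
#' @param model a `memqa_structure`.
#' @return data.frame, one row per residue: res_ord, chain, resno, icode,
#'   resname, chi1..chi4 (degrees, NA where undefined), sym1..sym4 (logical).
#' @export
compute_chi_angles <- function(model) {
  rt <- residue_table(model)
  a <- heavy_atoms(model)
  out <- cbind(rt[, c("res_ord", "chain", "resno", "icode", "resname")],
               chi1 = NA_real_, chi2 = NA_real_, chi3 = NA_real_,
               chi4 = NA_real_, sym1 = FALSE, sym2 = FALSE, sym3 = FALSE,
               sym4 = FALSE)
  for (i in seq_len(nrow(rt))) {
    defs <- CHI_ATOMS[[rt$resname[i]]]
    if (is.null(defs)) next
    sub <- a[a$res_ord == rt$res_ord[i], , drop = FALSE]
    for (k in seq_along(defs)) {
      j <- match(defs[[k]], sub$atom)
      if (anyNA(j)) next
      p <- as.matrix(sub[j, c("x", "y", "z")])
      out[[paste0("chi", k)]][i] <-
        tryCatch(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 error = function(e) NA_real_)
    }
    symk <- CHI_SYMMETRIC[[rt$resname[i]]]
    if (!is.null(symk)) out[[paste0("sym", symk)]][i] <- TRUE
  }
  out
}

#' @noRd
circular_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Fraction of chi1/chi2 angles within a threshold of the reference
#'
#' The side-chain quality metric: chi1 and chi2 angles of all residues in
#' correspondence are pooled, and the fraction whose circular difference to
#' the reference is below `threshold` (default 40 degrees) is reported. For
#' symmetric angles (ASP/PHE/TYR chi2) the minimum over the 180-degree flip
#' is used. Angles missing in either structure are excluded.
#'
#' @param model,reference `memqa_structure` objects sharing residue
#'   numbering.
#' @param threshold degrees, default 40.
#' @param pooled if TRUE (default) pool all chi1/chi2 angles; if FALSE,
#'   average the per-residue fractions instead.
#' @param chi_model,chi_reference optional precomputed [compute_chi_angles()]
#'   tables (useful when one structure is compared against many).
#' @return Fraction in \[0, 1\].
#' @export
chi_correctness <- function(model, reference, threshold = 40, pooled = TRUE,
                            chi_model = NULL, chi_reference = NULL) {
  cm <- if (is.null(chi_model)) compute_chi_angles(model) else chi_model
  cr <- if (is.null(chi_reference)) compute_chi_angles(reference)
        else chi_reference
  key_m <- paste(cm$chain, cm$resno, cm$icode)
  key_r <- paste(cr$chain, cr$resno, cr$icode)
  i <- match(key_r, key_m)
  keep <- !is.na(i)
  cm <- cm[i[keep], , drop = FALSE]
  cr <- cr[keep, , drop = FALSE]

  hits_per_res <- integer(nrow(cm))
  tot_per_res <- integer(nrow(cm))
  for (k in 1:2) {
    am <- cm[[paste0("chi", k)]]
    ar <- cr[[paste0("chi", k)]]
    sym <- cm[[paste0("sym", k)]] | cr[[paste0("sym", k)]]
    ok <- !is.na(am) & !is.na(ar) & cm$resname == cr$resname
    d <- circular_diff(am, ar)
    d[sym] <- pmin(d[sym], 180 - d[sym])
    hits_per_res <- hits_per_res + as.integer(ok & d < threshold)
    tot_per_res <- tot_per_res + as.integer(ok)
  }
  if (sum(tot_per_res) == 0) stop("no comparable chi1/chi2 angles")
  if (pooled) return(sum(hits_per_res) / sum(tot_per_res))
  has <- tot_per_res > 0
  mean(hits_per_res[has] / tot_per_res[has])
}
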
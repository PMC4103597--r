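# Structural features: accessible surface area, hydrogen-bond secondary
# structure, contact counts, membrane depth, and the windowed feature matrix
# fed to the scorer.

#' Shrake-Rupley solvent accessible surface area
#'
#' Quasi-uniform points are sampled on each heavy atom's inflated sphere
#' (radius + probe); a point is accessible if it lies outside every
#' neighbour's inflated sphere. Atom SASA is the accessible fraction of
#' 4 pi (r + probe)^2; residue SASA sums its atoms; relative accessibility
#' divides by the residue type's Gly-X-Gly maximum (capped at 1).
#' Hydrogens are ignored.
#'
#' @param model a `memqa_structure`.
#' @param probe probe radius, Angstrom (water: 1.4).
#' @param n_points sample points per atom.
#' @return List with `atom` (data.frame res_ord, atom, sasa) and `residue`
#'   (data.frame res_ord, resname, sasa, rel_acc).
#' @export
shrake_rupley_sasa <- function(model, probe = 1.4, n_points = 960) {
  a <- heavy_atoms(model)
  radii <- atom_radius(a$element, a$atom)
  sasa <- cpp_sasa(as.matrix(a[, c("x", "y", "z")]), radii, probe,
                   as.integer(n_points))
  res <- residue_table(model)
  per_res <- as.numeric(tapply(sasa, factor(a$res_ord, levels = res$res_ord),
                               sum, default = 0))
  per_res[is.na(per_res)] <- 0
  rel <- pmin(1, per_res / unname(MAX_SASA[res$resname]))
  list(atom = data.frame(res_ord = a$res_ord, atom = a$atom, sasa = sasa),
       residue = data.frame(res_ord = res$res_ord, resname = res$resname,
                            sasa = per_res, rel_acc = rel))
}

#' Hydrogen-bond secondary structure assignment
#'
#' Three-state assignment in the Kabsch-Sander style. Backbone amide
#' hydrogens are reconstructed geometrically (1 Angstrom from N, anti to the
#' preceding carbonyl); the H-bond energy between donor NH(i) and acceptor
#' CO(j) is E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN) kcal/mol, a
#' bond being E < -0.5. A residue is H when it sits in a run of at least two
#' consecutive i -> i+4 turns, E when it forms a parallel or antiparallel
#' bridge, else C. Residues with missing backbone atoms are labelled C.
#'
#' @param model a `memqa_structure`.
#' @return Character vector of labels in {"H","E","C"}, one per residue.
#' @export
assign_secondary_structure <- function(model) {
  rt <- residue_table(model)
  n <- nrow(rt)
  N <- atom_coords_by_residue(model, "N")
  CA <- atom_coords_by_residue(model, "CA")
  C <- atom_coords_by_residue(model, "C")
  O <- atom_coords_by_residue(model, "O")
  ok <- !(is.na(N[, 1]) | is.na(CA[, 1]) | is.na(C[, 1]) | is.na(O[, 1]))
  if (n < 3) return(rep("C", n))

  # reconstructed amide H (none for chain-leading residues or after a gap)
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (!ok[i] || !ok[i - 1] || rt$chain[i] != rt$chain[i - 1]) next
    if (rt$resname[i] == "PRO") next            # proline has no amide H
    v <- C[i - 1, ] - O[i - 1, ]
    H[i, ] <- N[i, ] + v / sqrt(sum(v^2))
  }

  # hbond[i, j]: CO of residue i accepts from NH of residue j
  hb <- matrix(FALSE, n, n)
  q <- 0.084 * 332
  don <- which(!is.na(H[, 1]))
  acc <- which(ok)
  for (j in don) {
    rON <- sqrt(rowSums((O[acc, , drop = FALSE] -
                           matrix(N[j, ], length(acc), 3, byrow = TRUE))^2))
    rCH <- sqrt(rowSums((C[acc, , drop = FALSE] -
                           matrix(H[j, ], length(acc), 3, byrow = TRUE))^2))
    rOH <- sqrt(rowSums((O[acc, , drop = FALSE] -
                           matrix(H[j, ], length(acc), 3, byrow = TRUE))^2))
    rCN <- sqrt(rowSums((C[acc, , drop = FALSE] -
                           matrix(N[j, ], length(acc), 3, byrow = TRUE))^2))
    e <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    bonded <- acc[e < -0.5 & abs(acc - j) > 1]
    hb[bonded, j] <- TRUE
  }

  ss <- rep("C", n)
  same_chain <- function(i, j) rt$chain[i] == rt$chain[j]
  # helix: two consecutive i -> i+4 turns mark residues i+1 .. i+4
  turn4 <- vapply(seq_len(n), function(i) {
    i + 4 <= n && same_chain(i, i + 4) && hb[i, i + 4]
  }, logical(1))
  for (i in seq_len(n - 1)) {
    if (turn4[i] && turn4[i + 1]) ss[(i + 1):(i + 4)] <- "H"
  }
  # bridges (Kabsch-Sander ladder patterns; hb[a, b] = CO(a) to NH(b))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 3) next
      para <- (i - 1 >= 1 && i + 1 <= n && hb[i - 1, j] && hb[j, i + 1]) ||
              (j - 1 >= 1 && j + 1 <= n && hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
              (i - 1 >= 1 && i + 1 <= n && j - 1 >= 1 && j + 1 <= n &&
                 hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if ((para || anti) && ss[i] != "H") ss[i] <- "E"
    }
  }
  ss[!ok] <- "C"
  ss
}

#' Atom-atom contact counts by atom class
#'
#' For each residue, counts of heavy atoms of other residues within `cutoff`
#' of any of its heavy atoms, binned by a 13-class atom typing (aliphatic,
#' aromatic, carbonyl and carboxylate carbon; amide, charged and aromatic
#' nitrogen; carbonyl, carboxylate and hydroxyl oxygen; sulfur; GLY CA;
#' other). Contacts with sequence neighbours (same chain, |Dseq| <= 1) are
#' excluded; the distance interval is half-open, [0, cutoff).
#'
#' @param model a `memqa_structure`.
#' @param cutoff Angstrom, default 4.5.
#' @return Integer matrix, residues x 13 classes.
#' @export
atom_contact_counts <- function(model, cutoff = 4.5) {
  a <- heavy_atoms(model)
  n <- n_residues(model)
  cls <- classify_atom(a$resname, a$atom)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  seqid <- chain_seqid(a)
  out <- cpp_atom_contact_counts(xyz, as.integer(a$res_ord),
                                 as.integer(seqid),
                                 match(cls, ATOM_CLASSES), n,
                                 length(ATOM_CLASSES), cutoff)
  dimnames(out) <- list(NULL, ATOM_CLASSES)
  out
}

# chain-aware sequence id: |diff| <= 1 identifies same-chain sequence
# neighbours by residue numbering (models may skip residues)
#' @noRd
chain_seqid <- function(atoms) {
  chain_idx <- match(atoms$chain, unique(atoms$chain))
  chain_idx * 1000000L + atoms$resno
}

#' Residue-residue contact counts by partner amino-acid type
#'
#' Contact: CB-CB distance (CA for GLY) below `cutoff`, same chain sequence
#' separation |Dseq| > 1. Counts are binned by the partner residue type.
#'
#' @param model a `memqa_structure`.
#' @param cutoff Angstrom, default 8.
#' @return Integer matrix, residues x 20 amino-acid types.
#' @export
residue_contact_counts <- function(model, cutoff = 8.0) {
  rt <- residue_table(model)
  n <- nrow(rt)
  cb <- atom_coords_by_residue(model, "CB")
  ca <- atom_coords_by_residue(model, "CA")
  gly <- rt$resname == "GLY" | is.na(cb[, 1])
  cb[gly, ] <- ca[gly, ]
  out <- matrix(0L, n, length(AA3), dimnames = list(NULL, AA3))
  okr <- which(!is.na(cb[, 1]))
  if (length(okr) < 2) return(out)
  pr <- cpp_pairs_within(cb[okr, , drop = FALSE], cb[okr, , drop = FALSE], cutoff)
  if (nrow(pr) == 0) return(out)
  i <- okr[pr[, 1]]; j <- okr[pr[, 2]]
  sep <- ifelse(rt$chain[i] == rt$chain[j], abs(rt$resno[i] - rt$resno[j]), 999L)
  keep <- i != j & sep > 1
  i <- i[keep]; j <- j[keep]
  for (k in seq_along(i))
    out[i[k], rt$resname[j[k]]] <- out[i[k], rt$resname[j[k]]] + 1L
  out
}

#' Membrane slab specification
#'
#' A flat slab normal to an axis: the hydrophobic core spans `center` plus or
#' minus `half_thickness` along the normal, an interface shell extends a
#' further 6 Angstrom, everything beyond is water. Models are assumed
#' pre-oriented with the membrane normal along z.
#'
#' @param normal_axis unit 3-vector, default z.
#' @param center Angstrom along the normal, default 0.
#' @param half_thickness Angstrom, default 15.
#' @return Object of class `memqa_membrane`.
#' @export
membrane_spec <- function(normal_axis = c(0, 0, 1), center = 0,
                          half_thickness = 15) {
  stopifnot(half_thickness > 0)
  normal_axis <- normal_axis / sqrt(sum(normal_axis^2))
  structure(list(normal_axis = normal_axis, center = center,
                 half_thickness = half_thickness, interface_width = 6),
            class = "memqa_membrane")
}

#' Membrane depth and region of every residue
#'
#' @param model a `memqa_structure`.
#' @param spec a [membrane_spec()].
#' @return data.frame with res_ord, depth (Angstrom, absolute distance of CA
#'   from the membrane center plane) and region in {"core", "interface",
#'   "water"}.
#' @export
membrane_depth <- function(model, spec = membrane_spec()) {
  ca <- atom_coords_by_residue(model, "CA")
  proj <- as.numeric(ca %*% spec$normal_axis) - spec$center
  depth <- abs(proj)
  region <- ifelse(depth < spec$half_thickness, "core",
                   ifelse(depth < spec$half_thickness + spec$interface_width,
                          "interface", "water"))
  region[is.na(depth)] <- "water"
  depth[is.na(depth)] <- spec$half_thickness + spec$interface_width + 10
  data.frame(res_ord = seq_len(nrow(ca)), depth = depth, region = region,
             stringsAsFactors = FALSE)
}
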
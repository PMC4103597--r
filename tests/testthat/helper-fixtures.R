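# Shared fixtures, built once per test run and memoised.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, maker) {
  if (is.null(.fx[[key]])) .fx[[key]] <- maker()
  .fx[[key]]
}

# small 3-helix membrane bundle (46 residues)
fx_bundle <- function(seed = 1) {
  fx_memo(paste0("bundle", seed), function() make_helix_bundle(3, 14, seed = seed))
}

# ~50-residue bundle for the SASA/contact oracle checks
fx_bundle50 <- function() {
  fx_memo("bundle50", function() make_helix_bundle(3, 15, seed = 4))
}

# one-residue structure with given type, chi and backbone pose
fx_residue <- function(resname, chi = numeric(0)) {
  N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
  C <- memqa:::place_atom(N + c(0, 1, 0), N, CA, 1.525, 111.2, 55)
  sc <- place_side_chain(resname, N, CA, C, chi)
  bb <- rbind(N = N, CA = CA, C = C)
  atoms <- data.frame(chain = "A", resno = 1L, icode = " ", resname = resname,
                      atom = c(rownames(bb), rownames(sc)),
                      x = c(bb[, 1], sc[, 1]), y = c(bb[, 2], sc[, 2]),
                      z = c(bb[, 3], sc[, 3]), stringsAsFactors = FALSE)
  new_structure(atoms)
}

# minimal hand-written PDB text (1 ALA residue, 5 atoms)
fx_ala_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "END")
}

# small synthetic training set and a scorer trained on it (targets disjoint
# from every other fixture seed)
fx_scorer <- function() {
  fx_memo("scorer", function() {
    tb <- make_benchmark(2, 6, seed = 900)
    pairs <- make_training_pairs(tb)
    suppressWarnings(train_scorer(pairs, regularization = 10,
                                  metadata = "test fixture"))
  })
}

# independent dihedral oracle: projection onto the plane normal to the
# central bond, signed by the right-hand rule
oracle_dihedral <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  v1 <- (p1 - p2) - sum((p1 - p2) * b) * b
  v2 <- (p4 - p3) - sum((p4 - p3) * b) * b
  x <- sum(v1 * v2)
  y <- sum(memqa:::cross3(b, v1) * v2)
  -atan2(y, x) * 180 / pi
}

# brute-force atom-contact recount (definition: partner heavy atoms of other
# residues within cutoff of any atom of the residue, |Dseq| > 1, counted
# once per partner atom, binned by partner class)
oracle_atom_contacts <- function(model, cutoff = 4.5) {
  a <- memqa:::heavy_atoms(model)
  cls <- memqa:::classify_atom(a$resname, a$atom)
  seqid <- memqa:::chain_seqid(a)
  n <- max(a$res_ord)
  out <- matrix(0L, n, length(memqa:::ATOM_CLASSES),
                dimnames = list(NULL, memqa:::ATOM_CLASSES))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  for (r in seq_len(n)) {
    mine <- which(a$res_ord == r)
    partners <- which(a$res_ord != r & abs(seqid - seqid[mine[1]]) > 1)
    for (j in partners) {
      d2 <- min(colSums((t(xyz[mine, , drop = FALSE]) - xyz[j, ])^2))
      if (d2 < cutoff^2) out[r, cls[j]] <- out[r, cls[j]] + 1L
    }
  }
  out
}

oracle_residue_contacts <- function(model, cutoff = 8) {
  rt <- residue_table(model)
  cb <- memqa:::atom_coords_by_residue(model, "CB")
  ca <- memqa:::atom_coords_by_residue(model, "CA")
  gly <- rt$resname == "GLY" | is.na(cb[, 1])
  cb[gly, ] <- ca[gly, ]
  n <- nrow(rt)
  out <- matrix(0L, n, 20, dimnames = list(NULL, memqa:::AA3))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (rt$chain[i] == rt$chain[j] && abs(rt$resno[i] - rt$resno[j]) <= 1) next
    if (anyNA(cb[i, ]) || anyNA(cb[j, ])) next
    if (sum((cb[i, ] - cb[j, ])^2) < cutoff^2)
      out[i, rt$resname[j]] <- out[i, rt$resname[j]] + 1L
  }
  out
}

# brute-force packing-energy components
oracle_packing_energy <- function(model, params, spec, library) {
  a <- memqa:::heavy_atoms(model)
  radii <- memqa:::atom_radius(a$element, a$atom)
  sidechain <- !(a$atom %in% c("N", "CA", "C", "O", "OXT"))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  e_st <- 0
  for (i in seq_len(nrow(a) - 1)) for (j in (i + 1):nrow(a)) {
    if (a$res_ord[i] == a$res_ord[j]) next
    if (!sidechain[i] && !sidechain[j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    ov <- params$clash_scale * (radii[i] + radii[j]) - d
    if (ov > 0) e_st <- e_st + ov^2
  }
  chis <- compute_chi_angles(model)
  bd <- backbone_dihedrals(model)
  e_rot <- 0
  for (i in seq_len(nrow(chis))) {
    nc <- n_chi(chis$resname[i])
    if (nc == 0) next
    e_rot <- e_rot + memqa:::rotamer_neg_log_prob(
      rotamers_for(library, chis$resname[i], bd$phi[i], bd$psi[i]),
      as.numeric(chis[i, paste0("chi", 1:nc)]))
  }
  md <- membrane_depth(model, spec)
  rt <- residue_table(model)
  e_mem <- sum(memqa:::hydropathy_mismatch(md$region, rt$resname))
  params$steric_weight * e_st + params$rotamer_weight * e_rot +
    params$membrane_weight * e_mem
}

# best attainable sum-Z by exhaustive selection
oracle_max_sum_z <- function(quality) {
  tot <- 0
  for (q in quality) {
    mu <- mean(q); sdev <- sqrt(mean((q - mu)^2))
    tot <- tot + if (sdev == 0) 0 else (max(q) - mu) / sdev
  }
  tot
}
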
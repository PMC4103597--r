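# Synthetic fixture generator: membrane-like helix bundles with full side
# chains, graded-quality backbone decoys, degraded side-chain packings and
# simulated sequence profiles. A statistical stand-in for an external decoy
# benchmark, built for controllable gradation rather than folding realism.

#' @noRd
HYDROPHOBIC_POOL <- c("LEU", "ILE", "VAL", "PHE", "ALA", "MET", "TRP", "GLY")
#' @noRd
POLAR_POOL <- c("SER", "THR", "ASN", "GLN", "LYS", "ARG", "ASP", "GLU",
                "GLY", "PRO", "TYR", "HIS")

#' @noRd
rotation_to_axis <- function(from, to) {
  from <- from / sqrt(sum(from^2)); to <- to / sqrt(sum(to^2))
  v <- cross3(from, to)
  c_ <- sum(from * to)
  if (sqrt(sum(v^2)) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any perpendicular axis
    p <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- cross3(from, p); v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' @noRd
most_probable_chi <- function(library, resname, phi, psi) {
  rots <- rotamers_for(library, resname, phi, psi)
  if (nrow(rots) == 0) return(numeric(0))
  j <- which.max(rots$prob)
  as.numeric(rots[j, paste0("chi", seq_len(n_chi(resname)))])
}

#' @noRd
residue_rows <- function(chain, resno, resname, bb, sc) {
  atoms <- rbind(bb, sc)
  data.frame(chain = chain, resno = resno, icode = " ", resname = resname,
             atom = rownames(atoms), x = atoms[, 1], y = atoms[, 2],
             z = atoms[, 3], occ = 1, b = 0,
             element = element_of(rownames(atoms)), hydrogen = FALSE,
             stringsAsFactors = FALSE)
}

#' Generate an idealised membrane helix bundle
#'
#' Builds `n_helices` ideal alpha-helices (phi = -57, psi = -47) of
#' `helix_len` residues each, placed on a circle whose radius scales with
#' the helix count, alternating up/down along the membrane normal (z) and
#' connected by short loops whose backbone follows an interpolated path
#' (loop geometry is schematic by design). Side chains are placed at the
#' most probable rotamer of each residue's backbone bin. The "auto"
#' sequence is hydrophobic-biased in the membrane core and polar in loops.
#'
#' @param n_helices number of transmembrane helices (>= 1).
#' @param helix_len residues per helix (>= 8).
#' @param sequence "auto" or an explicit one-letter string whose length must
#'   match the generated residue count.
#' @param seed integer; the output is bitwise reproducible per seed.
#' @param library rotamer library for side-chain placement.
#' @return A `memqa_structure` (single chain "A").
#' @export
make_helix_bundle <- function(n_helices, helix_len, sequence = "auto",
                              seed = 1, library = default_rotamer_library()) {
  stopifnot(n_helices >= 1, helix_len >= 8)
  with_seed(seed, {
    # ideal helix template, axis-aligned
    bb <- build_backbone(rep(-57, helix_len), rep(-47, helix_len))
    ca <- t(vapply(bb, function(m) m["CA", ], numeric(3)))
    axis <- ca[helix_len, ] - ca[1, ]
    ctr <- colMeans(ca)
    radius <- if (n_helices == 1) 0 else 10 / (2 * sin(pi / n_helices))

    helices <- list()
    for (k in seq_len(n_helices)) {
      up <- k %% 2 == 1
      R <- rotation_to_axis(axis, if (up) c(0, 0, 1) else c(0, 0, -1))
      th <- 2 * pi * (k - 1) / max(1, n_helices)
      pos <- c(radius * cos(th), radius * sin(th), 0)
      helices[[k]] <- lapply(bb, function(m) {
        out <- sweep(m, 2, ctr) %*% t(R)
        sweep(out, 2, pos, "+")
      })
      for (i in seq_along(helices[[k]])) {
        dimnames(helices[[k]][[i]]) <- list(rownames(bb[[1]]), c("x","y","z"))
      }
    }

    # assemble residue list: helix blocks joined by schematic loops
    pieces <- list()   # per residue: list(kind, bbmat)
    for (k in seq_len(n_helices)) {
      for (i in seq_len(helix_len))
        pieces[[length(pieces) + 1L]] <- list(kind = "helix",
                                              bb = helices[[k]][[i]])
      if (k < n_helices) {
        A <- helices[[k]][[helix_len]]["C", ]
        B <- helices[[k + 1]][[1]]["N", ]
        gap <- B - A
        pathlen <- sqrt(sum(gap^2))
        u <- gap / pathlen
        # Calpha stations along the path with junction margins; a zigzag
        # lateral tilt keeps successive C-N bonds in a peptide-like range
        margin <- 2.2
        n_loop <- max(2L, as.integer(ceiling((pathlen - 2 * margin) / 3.8)) + 1L)
        ds <- (pathlen - 2 * margin) / max(1L, n_loop - 1L)
        mid <- (A + B) / 2
        out_dir <- mid - c(0, 0, mid[3])
        nrm <- sqrt(sum(out_dir^2))
        out_dir <- if (nrm < 1e-6) c(1, 0, 0) else out_dir / nrm
        p <- cross3(u, out_dir)
        p <- if (sqrt(sum(p^2)) < 1e-6) c(0, 0, 1) else p / sqrt(sum(p^2))
        q <- cross3(u, p)
        alpha <- 25 * pi / 180
        for (i in seq_len(n_loop)) {
          t_ <- (margin + (i - 1) * ds) / pathlen
          pi_ <- p * (-1)^(i - 1)
          CA_i <- A + t_ * gap + out_dir * 1.2 * sin(pi * t_)
          Ni <- CA_i + 1.458 * (-cos(alpha) * u + sin(alpha) * pi_)
          Ci <- CA_i + 1.525 * (cos(alpha) * u + sin(alpha) * pi_)
          Oi <- Ci + 1.231 * q
          m <- rbind(N = Ni, CA = CA_i, C = Ci, O = Oi)
          colnames(m) <- c("x", "y", "z")
          pieces[[length(pieces) + 1L]] <- list(kind = "loop", bb = m)
        }
      }
    }
    n_res <- length(pieces)

    # sequence
    if (identical(sequence, "auto")) {
      resnames <- vapply(pieces, function(pc) {
        core <- abs(pc$bb["CA", 3]) < 13
        if (pc$kind == "helix" && core) sample(HYDROPHOBIC_POOL, 1)
        else sample(POLAR_POOL, 1)
      }, character(1))
    } else {
      if (nchar(sequence) != n_res)
        stop(sprintf("sequence length %d does not match %d generated residues",
                     nchar(sequence), n_res))
      a1 <- strsplit(sequence, "")[[1]]
      resnames <- names(AA1)[match(a1, AA1)]
      if (anyNA(resnames)) stop("invalid one-letter code in sequence")
    }

    # phi/psi for rotamer bins, then side chains at most probable rotamer
    rows <- list()
    for (i in seq_len(n_res)) {
      bbm <- pieces[[i]]$bb
      phi <- if (i > 1) dihedral(pieces[[i - 1]]$bb["C", ], bbm["N", ],
                                 bbm["CA", ], bbm["C", ]) else NA
      psi <- if (i < n_res) dihedral(bbm["N", ], bbm["CA", ], bbm["C", ],
                                     pieces[[i + 1]]$bb["N", ]) else NA
      rn <- resnames[i]
      sc <- NULL
      if (rn != "GLY") {
        chi <- if (n_chi(rn) > 0) most_probable_chi(library, rn, phi, psi)
               else numeric(0)
        sc <- place_side_chain(rn, bbm["N", ], bbm["CA", ], bbm["C", ], chi)
      }
      rows[[i]] <- residue_rows("A", i, rn, bbm, sc)
    }
    m <- new_structure(do.call(rbind, rows),
                       target_id = sprintf("bundle%dx%d", n_helices, helix_len),
                       model_id = "native")
    # steric sanity: the generator must not produce an unresolvable overlap
    a <- heavy_atoms(m)
    pr <- cpp_pairs_within(as.matrix(a[, c("x", "y", "z")]),
                           as.matrix(a[, c("x", "y", "z")]), 1.0)
    clash <- sum(a$res_ord[pr[, 1]] != a$res_ord[pr[, 2]])
    if (clash > 2 * n_res)
      stop("generated bundle has unresolvable atomic overlap")
    m
  })
}

#' Perturb a model's backbone by a smooth random displacement field
#'
#' Each residue is displaced rigidly (side chains follow, chi angles are
#' preserved) by a low-frequency sinusoidal field scaled so the expected
#' Calpha RMSD is about `magnitude`; successive C-N bonds are clamped into
#' \[1.2, 1.8\] Angstrom by locally smoothing the field.
#'
#' @param native a `memqa_structure`.
#' @param magnitude target Calpha RMSD, Angstrom (>= 0).
#' @param seed integer.
#' @return A perturbed `memqa_structure`.
#' @export
perturb_backbone <- function(native, magnitude, seed = 1) {
  stopifnot(magnitude >= 0)
  if (magnitude == 0) return(native)
  with_seed(seed, {
    rt <- residue_table(native)
    n <- nrow(rt)
    disp <- matrix(0, n, 3)
    tt <- seq_len(n) / n
    for (ax in 1:3) {
      for (m in 1:2) {
        amp <- stats::rnorm(1)
        ph <- stats::runif(1, 0, 2 * pi)
        disp[, ax] <- disp[, ax] + amp * sin(2 * pi * m * tt + ph)
      }
    }
    rms <- sqrt(mean(rowSums(disp^2)))
    disp <- disp * magnitude / max(rms, 1e-9)

    # clamp successive C-N bonds into [1.2, 1.8] by pulling residue i+1's
    # displacement toward residue i's
    Cc <- atom_coords_by_residue(native, "C")
    Nn <- atom_coords_by_residue(native, "N")
    for (i in seq_len(n - 1)) {
      if (rt$chain[i] != rt$chain[i + 1]) next
      if (anyNA(Cc[i, ]) || anyNA(Nn[i + 1, ])) next
      b0 <- Nn[i + 1, ] - Cc[i, ]
      beta <- 1
      repeat {
        b <- b0 + (disp[i, ] + beta * (disp[i + 1, ] - disp[i, ])) - disp[i, ]
        len <- sqrt(sum(b^2))
        if ((len >= 1.2 && len <= 1.8) || beta < 1e-3) break
        beta <- beta * 0.7
      }
      disp[i + 1, ] <- disp[i, ] + beta * (disp[i + 1, ] - disp[i, ])
    }

    out <- native
    out$atoms$x <- out$atoms$x + disp[out$atoms$res_ord, 1]
    out$atoms$y <- out$atoms$y + disp[out$atoms$res_ord, 2]
    out$atoms$z <- out$atoms$z + disp[out$atoms$res_ord, 3]
    out$model_id <- sprintf("%s_pert%g_s%d", native$model_id, magnitude, seed)
    out
  })
}

#' Randomise a fraction of side chains
#'
#' The chosen residues get chi angles drawn uniformly and their side chains
#' rebuilt; the backbone is untouched bitwise. Emulates a model with a good
#' backbone but poor side-chain packing.
#'
#' @param model a `memqa_structure`.
#' @param fraction fraction of chi-bearing residues to randomise, in \[0,1\].
#' @param seed integer.
#' @return A `memqa_structure`.
#' @export
randomize_side_chains <- function(model, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(model)
  with_seed(seed, {
    rt <- residue_table(model)
    N <- atom_coords_by_residue(model, "N")
    CA <- atom_coords_by_residue(model, "CA")
    C <- atom_coords_by_residue(model, "C")
    eligible <- which(n_chi(rt$resname) > 0 & !is.na(N[, 1]) &
                        !is.na(CA[, 1]) & !is.na(C[, 1]))
    k <- round(fraction * length(eligible))
    if (k == 0) return(model)
    pick <- sort(sample(eligible, k))
    a <- model$atoms
    is_sc <- !(a$atom %in% c(BACKBONE_ATOMS, "OXT"))
    drop <- a$res_ord %in% pick & is_sc
    rows <- list()
    for (i in pick) {
      chi <- stats::runif(n_chi(rt$resname[i]), -180, 180)
      sc <- place_side_chain(rt$resname[i], N[i, ], CA[i, ], C[i, ], chi)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = rt$chain[i], resno = rt$resno[i], icode = rt$icode[i],
        resname = rt$resname[i], atom = rownames(sc), x = sc[, 1],
        y = sc[, 2], z = sc[, 3], occ = 1, b = 0,
        element = element_of(rownames(sc)), hydrogen = FALSE,
        stringsAsFactors = FALSE)
    }
    keep_cols <- c("chain", "resno", "icode", "resname", "atom", "x", "y",
                   "z", "occ", "b", "element", "hydrogen")
    out <- new_structure(rbind(a[!drop, keep_cols, drop = FALSE],
                               do.call(rbind, rows)),
                         target_id = model$target_id,
                         model_id = paste0(model$model_id, "_scr"))
    out
  })
}

#' Simulate a sequence profile for a native structure
#'
#' PSSM: one-hot log-odds of the true sequence blurred by Gaussian noise;
#' predicted secondary structure: one-hot of the assigned structure mixed
#' with uniform by `noise_level`; predicted burial: true relative SASA plus
#' Gaussian noise clamped to \[0,1\]; topology from the true membrane
#' region.
#'
#' @param native a `memqa_structure`.
#' @param noise_level in \[0,1\]; 0 gives noise-free one-hot predictions.
#' @param seed integer.
#' @param spec a [membrane_spec()].
#' @return A `memqa_profile`.
#' @export
make_profile <- function(native, noise_level = 0.3, seed = 1,
                         spec = membrane_spec()) {
  stopifnot(noise_level >= 0, noise_level <= 1)
  with_seed(seed, {
    rt <- residue_table(native)
    n <- nrow(rt)
    pssm <- matrix(-1, n, 20, dimnames = list(NULL, unname(AA1[AA3])))
    pssm[cbind(seq_len(n), match(rt$resname, AA3))] <- 4
    if (noise_level > 0)
      pssm <- pssm + matrix(stats::rnorm(n * 20, 0, 2 * noise_level), n, 20)
    ss <- assign_secondary_structure(native)
    onehot <- matrix(0, n, 3, dimnames = list(NULL, c("H", "E", "C")))
    onehot[cbind(seq_len(n), match(ss, c("H", "E", "C")))] <- 1
    pred_ss <- (1 - noise_level) * onehot + noise_level / 3
    rel <- shrake_rupley_sasa(native, n_points = 240)$residue$rel_acc
    burial <- pmin(1, pmax(0, rel + stats::rnorm(n, 0, 0.2 * noise_level)))
    md <- membrane_depth(native, spec)
    zca <- atom_coords_by_residue(native, "CA") %*% spec$normal_axis
    topo <- ifelse(md$region == "core", "membrane",
                   ifelse(zca[, 1] < spec$center, "inside", "outside"))
    new_profile(paste0(rt$aa, collapse = ""), pssm, pred_ss, burial, topo)
  })
}

#' Generate a synthetic selection benchmark
#'
#' Per target: a fresh helix bundle native, `n_models_per_target` decoys
#' whose backbones are perturbed over the magnitude grid
#' {0.5, 1, 2, 4, 8} Angstrom (cycled) and whose side chains are
#' additionally randomised with a per-decoy fraction drawn in \[0.3, 1\],
#' the true TM-score of every decoy, and a simulated profile. Within each
#' target the decoys must span a TM range of at least 0.2 and a chi1/chi2
#' correctness range of at least 0.2; targets failing this are regenerated
#' with a derived seed (bounded retries).
#'
#' @param n_targets number of targets (>= 1).
#' @param n_models_per_target decoys per target (>= 2).
#' @param seed integer master seed; everything is reproducible from it.
#' @param n_helices,helix_len bundle size per target.
#' @param noise_level profile noise.
#' @param library rotamer library used by the generator.
#' @return List of targets; each is a list with target_id, native, models
#'   (list of `memqa_structure`), true_tm (named numeric), profile,
#'   provenance.
#' @export
make_benchmark <- function(n_targets, n_models_per_target, seed = 1,
                           n_helices = 3, helix_len = 14, noise_level = 0.3,
                           library = default_rotamer_library()) {
  stopifnot(n_targets >= 1, n_models_per_target >= 2)
  grid <- c(0.5, 1, 2, 4, 8)
  out <- list()
  for (t_ in seq_len(n_targets)) {
    for (try_ in 0:4) {
      tseed <- (seed * 1009L + t_ * 101L + try_ * 7919L) %% .Machine$integer.max
      native <- make_helix_bundle(n_helices, helix_len, seed = tseed,
                                  library = library)
      native$target_id <- sprintf("T%03d", t_)
      native$model_id <- "native"
      profile <- make_profile(native, noise_level, seed = tseed + 1L)
      models <- list()
      true_tm <- numeric(0)
      chis <- numeric(0)
      for (d in seq_len(n_models_per_target)) {
        mag <- grid[(d - 1) %% length(grid) + 1]
        dec <- perturb_backbone(native, mag, seed = tseed + 10L + d)
        frac <- with_seed(tseed + 500L + d, stats::runif(1, 0.3, 1.0))
        dec <- randomize_side_chains(dec, frac, seed = tseed + 1000L + d)
        dec$model_id <- sprintf("m%03d", d)
        tm <- tm_score(dec, native)$score
        attr(dec, "true_tm") <- tm
        models[[dec$model_id]] <- dec
        true_tm[dec$model_id] <- tm
        chis[dec$model_id] <- chi_correctness(dec, native)
      }
      # the spread guarantee needs at least one full magnitude-grid cycle
      if (n_models_per_target < length(grid)) break
      if (diff(range(true_tm)) >= 0.2 && diff(range(chis)) >= 0.2) break
      if (try_ == 4) warning("target ", t_, " kept despite narrow spread")
    }
    out[[native$target_id]] <- list(target_id = native$target_id,
                                    native = native, models = models,
                                    true_tm = true_tm, profile = profile,
                                    provenance = list(seed = seed,
                                                      target_seed = tseed,
                                                      n_helices = n_helices,
                                                      helix_len = helix_len))
  }
  out
}
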
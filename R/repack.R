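# Fixed-backbone side-chain repacking.
#
# The packing energy is a declared simplified form (soft-sphere sterics +
# rotamer log-probability + membrane hydropathy mismatch); its role is to be
# "a" packing energy whose greedy minimisation improves side-chain packing,
# not to reproduce any particular force field.
#
# Repacking many decoys of one model shares a precomputed context (candidate
# rotamer coordinates, environment arrays, output template); the greedy
# sweep itself runs in C++ (cpp_repack).

#' Packing energy parameters
#'
#' @param steric_weight weight of the soft-sphere clash term.
#' @param rotamer_weight weight of the -log(rotamer probability) term.
#' @param membrane_weight weight of the hydropathy-mismatch term.
#' @param clash_scale clash onset as a fraction of the summed van der Waals
#'   radii.
#' @param max_sweeps maximum greedy sweeps over all residues.
#' @param jitter_sd if positive, Gaussian jitter (degrees) added to rotamer
#'   chi means per repack run (seeded); off by default.
#' @return Object of class `memqa_packing_params`.
#' @export
packing_params <- function(steric_weight = 1, rotamer_weight = 1,
                           membrane_weight = 0.5, clash_scale = 0.8,
                           max_sweeps = 10, jitter_sd = 0) {
  stopifnot(steric_weight >= 0, rotamer_weight >= 0, membrane_weight >= 0,
            clash_scale > 0, max_sweeps >= 1, jitter_sd >= 0)
  structure(list(steric_weight = steric_weight,
                 rotamer_weight = rotamer_weight,
                 membrane_weight = membrane_weight,
                 clash_scale = clash_scale, max_sweeps = max_sweeps,
                 jitter_sd = jitter_sd),
            class = "memqa_packing_params")
}

#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' @noRd
hydropathy_mismatch <- function(region, resname) {
  kd <- unname(KD_HYDROPATHY[resname])
  ifelse(region == "core", pmax(0, -kd) / 4.5,
         ifelse(region == "water", pmax(0, kd) / 4.5, 0))
}

# -log prob of the library rotamer nearest (circular, over defined chis) to
# the given chi vector.
#' @noRd
rotamer_neg_log_prob <- function(rots, chi) {
  if (nrow(rots) == 0 || length(chi) == 0 || all(is.na(chi))) return(0)
  best <- Inf; bestp <- 1
  for (r in seq_len(nrow(rots))) {
    mu <- as.numeric(rots[r, paste0("chi", seq_along(chi))])
    ok <- !is.na(chi) & !is.na(mu)
    if (!any(ok)) next
    d <- max(circular_diff(chi[ok], mu[ok]))
    if (d < best) { best <- d; bestp <- rots$prob[r] }
  }
  -log(max(bestp, 1e-12))
}

#' Simplified packing energy of a model
#'
#' E = w_st * sum over heavy-atom pairs of different residues with at least
#' one side-chain atom of max(0, s (r_i + r_j) - d_ij)^2
#'   + w_rot * sum over residues of -log p(nearest rotamer)
#'   + w_mem * sum over residues of hydropathy mismatch with the membrane
#' region of the residue's Calpha.
#'
#' @param model a `memqa_structure`.
#' @param params a [packing_params()].
#' @param spec a [membrane_spec()].
#' @param library rotamer library for the probability term.
#' @return Scalar energy (arbitrary units) with attribute `components`.
#' @export
packing_energy <- function(model, params = packing_params(),
                           spec = membrane_spec(),
                           library = default_rotamer_library()) {
  a <- heavy_atoms(model)
  radii <- atom_radius(a$element, a$atom)
  sidechain <- !(a$atom %in% c(BACKBONE_ATOMS, "OXT"))
  e_st <- cpp_steric_energy(as.matrix(a[, c("x", "y", "z")]), radii,
                            as.integer(a$res_ord), sidechain,
                            params$clash_scale)
  chis <- compute_chi_angles(model)
  bd <- backbone_dihedrals(model)
  e_rot <- 0
  for (i in seq_len(nrow(chis))) {
    nc <- n_chi(chis$resname[i])
    if (nc == 0) next
    rots <- rotamers_for(library, chis$resname[i], bd$phi[i], bd$psi[i])
    e_rot <- e_rot +
      rotamer_neg_log_prob(rots, as.numeric(chis[i, paste0("chi", 1:nc)]))
  }
  md <- membrane_depth(model, spec)
  rt <- residue_table(model)
  e_mem <- sum(hydropathy_mismatch(md$region, rt$resname))
  total <- params$steric_weight * e_st + params$rotamer_weight * e_rot +
    params$membrane_weight * e_mem
  attr(total, "components") <- c(steric = e_st, rotamer = e_rot,
                                 membrane = e_mem)
  total
}

# ---------------------------------------------------------------------------
# Repack context: everything about one model that is shared by all of its
# repacked decoys. Internal, but returned invisibly by repack() consumers.

#' @noRd
repack_context <- function(model, library = default_rotamer_library(),
                           params = packing_params(),
                           spec = membrane_spec()) {
  rt <- residue_table(model)
  bd <- backbone_dihedrals(model)
  chis_in <- compute_chi_angles(model)
  N <- atom_coords_by_residue(model, "N")
  CA <- atom_coords_by_residue(model, "CA")
  C <- atom_coords_by_residue(model, "C")
  repackable <- which(n_chi(rt$resname) > 0 & rt$resname != "ALA" &
                        !is.na(N[, 1]) & !is.na(CA[, 1]) & !is.na(C[, 1]))

  a_in <- model$atoms
  is_sc_atom <- !(a_in$atom %in% c(BACKBONE_ATOMS, "OXT"))
  drop <- a_in$res_ord %in% repackable & is_sc_atom
  fixed <- a_in[!drop, , drop = FALSE]
  fixed_hv <- fixed[!fixed$hydrogen, , drop = FALSE]

  blocks <- lapply(repackable, function(i) {
    r <- rt$resname[i]
    c("CB", vapply(SIDECHAIN_RECIPES[[r]], `[`, character(1), 1))
  })
  nb <- vapply(blocks, length, integer(1))
  env_xyz <- rbind(as.matrix(fixed_hv[, c("x", "y", "z")]),
                   matrix(0, sum(nb), 3))
  env_rad <- c(atom_radius(fixed_hv$element, fixed_hv$atom), rep(0, sum(nb)))
  env_seq <- c(fixed_hv$res_ord, rep(0L, sum(nb)))
  slot_of <- integer(nrow(rt))
  off <- nrow(fixed_hv)
  for (k in seq_along(repackable)) {
    i <- repackable[k]
    slot_of[i] <- off
    rows <- off + seq_len(nb[k])
    env_rad[rows] <- atom_radius(element_of(blocks[[k]]), blocks[[k]])
    env_seq[rows] <- i
    off <- off + nb[k]
  }
  env_sc <- c(!(fixed_hv$atom %in% c(BACKBONE_ATOMS, "OXT")),
              rep(TRUE, sum(nb)))

  md <- membrane_depth(model, spec)
  e_mem <- sum(hydropathy_mismatch(md$region, rt$resname))
  fixed_chi <- setdiff(which(n_chi(rt$resname) > 0), repackable)
  nlp_fixed <- 0
  for (i in fixed_chi) {
    nc <- n_chi(rt$resname[i])
    nlp_fixed <- nlp_fixed +
      rotamer_neg_log_prob(rotamers_for(library, rt$resname[i], bd$phi[i],
                                        bd$psi[i]),
                           as.numeric(chis_in[i, paste0("chi", seq_len(nc))]))
  }

  build_sc <- function(i, chi) place_side_chain(rt$resname[i], N[i, ],
                                                CA[i, ], C[i, ], chi)
  res_rots <- lapply(repackable, function(i)
    rotamers_for(library, rt$resname[i], bd$phi[i], bd$psi[i]))
  cand_list <- lapply(seq_along(repackable), function(k) {
    i <- repackable[k]
    rots <- res_rots[[k]]
    nc <- n_chi(rt$resname[i])
    mus <- lapply(seq_len(nrow(rots)), function(r)
      as.numeric(rots[r, paste0("chi", seq_len(nc))]))
    probs <- rots$prob
    chin <- as.numeric(chis_in[i, paste0("chi", seq_len(nc))])
    if (!anyNA(chin)) {
      mus <- c(mus, list(chin))
      probs <- c(probs, exp(-rotamer_neg_log_prob(rots, chin)))
    }
    list(mus = mus, xyzs = lapply(mus, function(mu) build_sc(i, mu)),
         nlp = -log(pmax(probs, 1e-12)))
  })
  init_idx <- vapply(seq_along(repackable), function(k)
    which.max(res_rots[[k]]$prob), integer(1))

  # output template: untouched atoms + one rebuilt side-chain block per
  # repackable residue; per decoy only the block coordinates change
  keep_cols <- c("chain", "resno", "icode", "resname", "atom", "x", "y", "z",
                 "occ", "b", "element", "hydrogen")
  new_rows <- lapply(seq_along(repackable), function(k) {
    i <- repackable[k]
    nm <- blocks[[k]]
    data.frame(chain = rt$chain[i], resno = rt$resno[i], icode = rt$icode[i],
               resname = rt$resname[i], atom = nm, x = 0, y = 0, z = 0,
               occ = 1, b = 0, element = element_of(nm), hydrogen = FALSE,
               stringsAsFactors = FALSE)
  })
  template_atoms <- rbind(fixed[, keep_cols, drop = FALSE],
                          do.call(rbind, new_rows))
  template <- new_structure(template_atoms, target_id = model$target_id,
                            model_id = model$model_id)
  # map env block rows to template atom rows (template was re-sorted)
  key_env <- c(paste(fixed_hv$res_ord, fixed_hv$atom),
               unlist(lapply(seq_along(repackable), function(k)
                 paste(repackable[k], blocks[[k]]))))
  key_tmpl <- paste(template$atoms$res_ord, template$atoms$atom)
  env_to_tmpl <- match(key_env, key_tmpl)

  list(model = model, rt = rt, repackable = repackable, blocks = blocks,
       nb = nb, slot_of = slot_of, env_xyz = env_xyz, env_rad = env_rad,
       env_seq = env_seq, env_sc = env_sc, cand_list = cand_list,
       init_idx = init_idx, e_mem = e_mem, nlp_fixed = nlp_fixed,
       CA = CA, template = template, env_to_tmpl = env_to_tmpl,
       params = params, spec = spec, library = library,
       cand_xyz = if (length(repackable))
         do.call(rbind, unlist(lapply(cand_list, `[[`, "xyzs"),
                               recursive = FALSE)) else matrix(0, 0, 3),
       cand_rad = unlist(lapply(seq_along(repackable), function(k)
         rep(atom_radius(element_of(blocks[[k]]), blocks[[k]]),
             length(cand_list[[k]]$xyzs)))),
       cand_n = vapply(cand_list, function(cl) length(cl$xyzs), integer(1)))
}

# run the greedy sweeps for one seed; returns chosen candidate indices,
# trace and final energy
#' @noRd
repack_run <- function(ctx, seed) {
  n_rep <- length(ctx$repackable)
  params <- ctx$params
  with_seed(seed, {
    orders <- matrix(0L, params$max_sweeps, n_rep)
    for (s in seq_len(params$max_sweeps))
      orders[s, ] <- sample.int(n_rep)
    cand_list <- ctx$cand_list
    cand_xyz <- ctx$cand_xyz
    if (params$jitter_sd > 0) {
      # re-derive jittered candidate coordinates for this run
      rt <- ctx$rt
      N <- atom_coords_by_residue(ctx$model, "N")
      CAm <- atom_coords_by_residue(ctx$model, "CA")
      C <- atom_coords_by_residue(ctx$model, "C")
      for (k in seq_len(n_rep)) {
        i <- ctx$repackable[k]
        cand_list[[k]]$mus <- lapply(cand_list[[k]]$mus, function(m)
          m + stats::rnorm(length(m), 0, params$jitter_sd))
        cand_list[[k]]$xyzs <- lapply(cand_list[[k]]$mus, function(mu)
          place_side_chain(rt$resname[i], N[i, ], CAm[i, ], C[i, ], mu))
      }
      cand_xyz <- do.call(rbind, unlist(lapply(cand_list, `[[`, "xyzs"),
                                        recursive = FALSE))
    }
    cand_off <- cumsum(c(1L, (ctx$cand_n * ctx$nb)[-max(1L, n_rep)]))
    nlp_vec <- unlist(lapply(cand_list, `[[`, "nlp"), use.names = FALSE)
    nlp_off <- cumsum(c(1L, ctx$cand_n[-max(1L, n_rep)]))
    const_e <- params$membrane_weight * ctx$e_mem +
      params$rotamer_weight * ctx$nlp_fixed
    cr <- cpp_repack(ctx$env_xyz, ctx$env_rad, as.integer(ctx$env_seq),
                     ctx$env_sc,
                     vapply(ctx$repackable, function(i) ctx$slot_of[i] + 1L,
                            integer(1)),
                     ctx$nb, as.integer(ctx$repackable),
                     cand_xyz, ctx$cand_rad,
                     as.integer(cand_off), as.integer(ctx$cand_n),
                     nlp_vec, as.integer(nlp_off), as.integer(ctx$init_idx),
                     ctx$CA[ctx$repackable, , drop = FALSE], orders,
                     params$steric_weight, params$rotamer_weight,
                     params$clash_scale, const_e)
    list(idx = cr$idx + 1L, trace = cr$trace, energy = cr$energy,
         chi = lapply(seq_len(n_rep), function(k)
           cand_list[[k]]$mus[[cr$idx[k] + 1L]]),
         xyz = lapply(seq_len(n_rep), function(k)
           cand_list[[k]]$xyzs[[cr$idx[k] + 1L]]))
  })
}

# decoy coordinates on the environment-array layout
#' @noRd
repack_env_coords <- function(ctx, run) {
  xyz <- ctx$env_xyz
  for (k in seq_along(ctx$repackable)) {
    i <- ctx$repackable[k]
    xyz[ctx$slot_of[i] + seq_len(ctx$nb[k]), ] <- run$xyz[[k]]
  }
  xyz
}

#' @noRd
repack_materialize <- function(ctx, run, seed) {
  out <- ctx$template
  xyz <- repack_env_coords(ctx, run)
  # hydrogens of untouched residues are absent from the env arrays and keep
  # their template (input) coordinates
  out$atoms$x[ctx$env_to_tmpl] <- xyz[, 1]
  out$atoms$y[ctx$env_to_tmpl] <- xyz[, 2]
  out$atoms$z[ctx$env_to_tmpl] <- xyz[, 3]
  out$model_id <- paste0(ctx$model$model_id, "_repack", seed)
  out
}

#' Repack the side chains of a model on its fixed backbone
#'
#' Greedy fixed-backbone repacking: every chi-bearing residue is initialised
#' at the most probable rotamer of its (phi, psi) bin, then residues are
#' swept in seeded random order; for each residue all library rotamers of
#' its bin plus its input conformation are evaluated under the packing
#' energy and the minimum is accepted. Sweeps repeat until nothing changes
#' or `max_sweeps` is reached. Backbone heavy atoms (and GLY/ALA residues)
#' are untouched bit-for-bit; repacked side chains are rebuilt with ideal
#' geometry, so their hydrogens are dropped.
#'
#' @param model a `memqa_structure`.
#' @param library a rotamer library.
#' @param params a [packing_params()].
#' @param spec a [membrane_spec()].
#' @param seed integer; fixes the sweep order (and chi jitter if enabled).
#' @param initial_energy optional precomputed [packing_energy()] of the
#'   input model; avoids recomputation when generating many decoys.
#' @return Object of class `memqa_repack`: list with `model`, `energy`
#'   (final total packing energy), `initial_energy` (input model), `trace`
#'   (total energy after initialisation and after each sweep,
#'   non-increasing), `seed`.
#' @export
repack <- function(model, library = default_rotamer_library(),
                   params = packing_params(), spec = membrane_spec(),
                   seed = 1, initial_energy = NULL) {
  if (is.null(initial_energy))
    initial_energy <- as.numeric(packing_energy(model, params, spec, library))
  ctx <- repack_context(model, library, params, spec)
  if (length(ctx$repackable) == 0L) {
    out <- model
    out$model_id <- paste0(model$model_id, "_repack", seed)
    return(structure(list(model = out, energy = initial_energy,
                          initial_energy = initial_energy,
                          trace = initial_energy, seed = seed),
                     class = "memqa_repack"))
  }
  run <- repack_run(ctx, seed)
  structure(list(model = repack_materialize(ctx, run, seed),
                 energy = run$energy, initial_energy = initial_energy,
                 trace = run$trace, seed = seed),
            class = "memqa_repack")
}

#' @export
print.memqa_repack <- function(x, ...) {
  cat(sprintf("repacked model (seed %d): energy %.3f -> %.3f, %d sweep(s)\n",
              x$seed, x$initial_energy, x$energy, length(x$trace) - 1L))
  invisible(x)
}

#' Generate repacked side-chain decoys of a model
#'
#' Decoy i is `repack(model, seed = base_seed + i)`; the decoy set is
#' deterministic given `base_seed` and all decoys share the input backbone
#' exactly.
#'
#' @param model a `memqa_structure`.
#' @param n number of decoys, default 10.
#' @param base_seed integer seed base.
#' @param library,params,spec as in [repack()].
#' @return List of `memqa_repack` objects of length `n`.
#' @export
generate_decoys <- function(model, n = 10, base_seed = 1,
                            library = default_rotamer_library(),
                            params = packing_params(),
                            spec = membrane_spec()) {
  if (n < 1) stop("n must be at least 1")
  e0 <- as.numeric(packing_energy(model, params, spec, library))
  ctx <- repack_context(model, library, params, spec)
  lapply(seq_len(n), function(i) {
    seed <- base_seed + i
    if (length(ctx$repackable) == 0L) {
      out <- model
      out$model_id <- paste0(model$model_id, "_repack", seed)
      return(structure(list(model = out, energy = e0, initial_energy = e0,
                            trace = e0, seed = seed),
                       class = "memqa_repack"))
    }
    run <- repack_run(ctx, seed)
    structure(list(model = repack_materialize(ctx, run, seed),
                   energy = run$energy, initial_energy = e0,
                   trace = run$trace, seed = seed),
              class = "memqa_repack")
  })
}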
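# Fast scoring of repacked decoys.
#
# All decoys of one model share the backbone, the atom composition and the
# sequence profile; only side-chain coordinates differ. This path computes
# the dynamic features (SASA, contacts) directly on the repack context's
# flat atom arrays, skipping structure/data.frame reconstruction. It
# produces exactly the features build_feature_matrix() would on the
# materialised decoy (asserted in the test suite).

#' @noRd
decoy_feature_context <- function(ctx, profile, spec = membrane_spec(),
                                  window = 9, sasa_points = 240) {
  rt <- ctx$rt
  n <- nrow(rt)
  # env array layout: fixed heavy atoms then side-chain blocks
  fixed_hv_atoms <- ctx$template$atoms[ctx$env_to_tmpl[
    seq_len(length(ctx$env_seq) - sum(ctx$nb))], , drop = FALSE]
  block_atoms <- unlist(ctx$blocks, use.names = FALSE)
  a_atom <- c(fixed_hv_atoms$atom, block_atoms)
  a_res <- ctx$env_seq
  a_resname <- rt$resname[a_res]
  cls <- match(classify_atom(a_resname, a_atom), ATOM_CLASSES)
  chain_idx <- match(rt$chain, unique(rt$chain))
  seqid_res <- chain_idx * 1000000L + rt$resno
  a_seqid <- seqid_res[a_res]
  # one representative atom per residue for residue-residue contacts
  cb_row <- integer(n)
  for (i in seq_len(n)) {
    rows <- which(a_res == i)
    hit <- rows[a_atom[rows] == "CB"]
    if (rt$resname[i] == "GLY" || length(hit) == 0)
      hit <- rows[a_atom[rows] == "CA"]
    cb_row[i] <- if (length(hit) > 0) hit[1] else NA_integer_
  }
  bc <- backbone_feature_cache(ctx$model, spec)
  ss1 <- matrix(0, n, 3)
  ss1[cbind(seq_len(n), match(bc$ss, c("H", "E", "C")))] <- 1
  reg1 <- matrix(0, n, 3)
  reg1[cbind(seq_len(n), match(bc$md$region,
                               c("core", "interface", "water")))] <- 1
  static <- cbind(profile$pssm, profile$pred_ss,
                  burial = profile$pred_burial,
                  obs_H = ss1[, 1], obs_E = ss1[, 2], obs_C = ss1[, 3],
                  rel_sasa = 0, depth = bc$md$depth,
                  reg_core = reg1[, 1], reg_if = reg1[, 2],
                  reg_wat = reg1[, 3],
                  matrix(0, n, length(ATOM_CLASSES)),
                  matrix(0, n, length(AA3)))
  colnames(static) <- feature_base_names()
  list(ctx = ctx, n = n, cls = cls, a_res = as.integer(a_res),
       a_seqid = as.integer(a_seqid), cb_row = cb_row,
       resname_code = match(rt$resname, AA3), chains = rt$chain,
       static = static, max_sasa = unname(MAX_SASA[rt$resname]),
       window = window, sasa_points = sasa_points,
       rad = ctx$env_rad, backbone_cache = bc)
}

#' @noRd
decoy_features_fast <- function(fc, coords) {
  n <- fc$n
  sasa <- cpp_sasa(coords, fc$rad, 1.4, as.integer(fc$sasa_points))
  res_sasa <- as.numeric(rowsum(sasa, fc$a_res, reorder = TRUE))
  rel <- pmin(1, res_sasa / fc$max_sasa)
  ac <- cpp_atom_contact_counts(coords, fc$a_res, fc$a_seqid, fc$cls, n,
                                length(ATOM_CLASSES), 4.5)
  # residue-residue contacts on representative atoms
  rc <- matrix(0L, n, length(AA3))
  okr <- which(!is.na(fc$cb_row))
  cb <- coords[fc$cb_row[okr], , drop = FALSE]
  pr <- cpp_pairs_within(cb, cb, 8.0)
  if (nrow(pr) > 0) {
    i <- okr[pr[, 1]]; j <- okr[pr[, 2]]
    keep <- i != j & abs(fc$a_seqid[fc$cb_row[i]] - fc$a_seqid[fc$cb_row[j]]) > 1
    i <- i[keep]; j <- j[keep]
    for (k in seq_along(i))
      rc[i[k], fc$resname_code[j[k]]] <- rc[i[k], fc$resname_code[j[k]]] + 1L
  }
  per_pos <- fc$static
  per_pos[, "rel_sasa"] <- rel
  per_pos[, paste0("ac_", ATOM_CLASSES)] <- ac
  per_pos[, paste0("rc_", AA3)] <- rc
  window_stack(per_pos, fc$chains, fc$window)
}

# score n repacked decoys of one model; returns global scores, the runs and
# the context (so the best decoy can be materialised cheaply)
#' @noRd
score_decoys_fast <- function(model, profile, scorer, n, base_seed,
                              library, params, spec, window,
                              sasa_points = 240) {
  ctx <- repack_context(model, library, params, spec)
  fc <- decoy_feature_context(ctx, profile, spec, window, sasa_points)
  runs <- vector("list", n)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    if (length(ctx$repackable) == 0L) {
      runs[[i]] <- NULL
      scores[i] <- predict(scorer,
                           build_feature_matrix(model, profile, spec, window,
                                                backbone_cache = fc$backbone_cache))$global
      next
    }
    runs[[i]] <- repack_run(ctx, base_seed + i)
    feats <- decoy_features_fast(fc, repack_env_coords(ctx, runs[[i]]))
    scores[i] <- predict(scorer, feats)$global
  }
  list(ctx = ctx, runs = runs, scores = scores,
       backbone_cache = fc$backbone_cache)
}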
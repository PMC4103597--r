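# The resampling protocol: repack each model's side chains n times, rescore
# every decoy, assign each model its best resampled score, rank models per
# target, and evaluate selection with per-target Z-scores. A Pcons-style
# consensus baseline (mean pairwise TM-score) is included for comparison.

#' Resample one model and score every decoy
#'
#' Generates `n` repacked decoys of the model, scores the original and each
#' decoy with the quality predictor (structural features recomputed per
#' decoy, the sequence profile fixed), and assigns the model the aggregate
#' of these scores: the maximum by default, so a good backbone with poor
#' side-chain packing can be rescued by a well-packed decoy.
#'
#' @param model a `memqa_structure`.
#' @param profile matching `memqa_profile`.
#' @param scorer a `memqa_scorer`.
#' @param n decoys per model, default 10.
#' @param base_seed integer; decoy i uses seed `base_seed + i`.
#' @param library,params,spec repacking setup, as in [repack()].
#' @param aggregate "max" (default) or "mean" over the original and decoy
#'   scores.
#' @param window feature window width (must match the scorer's training).
#' @return List with model_id, original_score, decoy_scores, assigned_score,
#'   best_decoy (id of the best-scoring decoy or "original"), and
#'   best_model (the corresponding structure).
#' @export
resample_and_score <- function(model, profile, scorer, n = 10, base_seed = 1,
                               library = default_rotamer_library(),
                               params = packing_params(),
                               spec = membrane_spec(),
                               aggregate = c("max", "mean"), window = 9) {
  aggregate <- match.arg(aggregate)
  if (n < 1) stop("n must be at least 1")
  sd_ <- score_decoys_fast(model, profile, scorer, n, base_seed,
                           library, params, spec, window)
  # the backbone is fixed throughout, so SS and membrane depth are shared
  orig <- score_model(model, profile, scorer, spec, window,
                      backbone_cache = sd_$backbone_cache)$global
  dscore <- stats::setNames(sd_$scores, paste0("decoy", seq_len(n)))
  all_scores <- c(original = orig, dscore)
  assigned <- if (aggregate == "max") max(all_scores) else mean(all_scores)
  best_id <- names(all_scores)[which.max(all_scores)]
  materialize <- function(i) {
    if (is.null(sd_$runs[[i]])) {
      out <- model
      out$model_id <- paste0(model$model_id, "_repack", base_seed + i)
      out
    } else repack_materialize(sd_$ctx, sd_$runs[[i]], base_seed + i)
  }
  best_decoy_model <- materialize(which.max(dscore))
  best_model <- if (best_id == "original") model else best_decoy_model
  list(model_id = model$model_id, original_score = orig,
       decoy_scores = dscore, assigned_score = assigned,
       best_decoy = best_id, best_model = best_model,
       best_decoy_model = best_decoy_model)
}

#' Rank the models of one target
#'
#' Descending by assigned score, ties broken by lexicographically smallest
#' model id.
#'
#' @param scores named numeric vector of selection scores (>= 2 models).
#' @return data.frame with rank, model_id, score; row 1 is the selected
#'   model.
#' @export
rank_models <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 models to rank")
  o <- order(-scores, names(scores))
  data.frame(rank = seq_along(scores), model_id = names(scores)[o],
             score = unname(scores[o]), stringsAsFactors = FALSE)
}

#' Pcons-style consensus score
#'
#' Scores each model by its mean TM-score against all other models of the
#' same target (the model under evaluation is the reference of each pairwise
#' comparison).
#'
#' @param models named list of `memqa_structure` objects (>= 2).
#' @return Named numeric vector of consensus scores.
#' @export
consensus_score <- function(models) {
  if (length(models) < 2) stop("need at least 2 models for consensus")
  ids <- names(models)
  out <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    others <- setdiff(seq_along(ids), i)
    out[i] <- mean(vapply(others, function(j)
      tm_score(models[[j]], models[[i]])$score, numeric(1)))
  }
  out
}

#' Run the full selection benchmark
#'
#' For every target: scores all models as-is (no-resample selection),
#' resamples and rescores them (resampled selection), and computes the
#' consensus baseline; evaluates each selection rule with per-target
#' Z-scores of the true TM-score. Side-chain chi1/chi2 correctness of every
#' model is measured before resampling and for its best-scoring decoy after,
#' and targets are partitioned into sets with and without backbone
#' improvement (resampled selection picked a higher-TM model than
#' no-resample selection), mirroring the usual before/after summary table.
#'
#' @param targets benchmark as from [make_benchmark()]: per target a list
#'   with native, models, true_tm, profile.
#' @param scorer a `memqa_scorer`.
#' @param n decoys per model.
#' @param base_seed integer seed base; model j of target t uses an offset
#'   seed derived from it.
#' @param library,params,spec repacking setup.
#' @param consensus if FALSE, skip the consensus baseline (it is quadratic
#'   in models per target).
#' @param aggregate decoy-score combiner, see [resample_and_score()].
#' @param window feature window width.
#' @return Object of class `memqa_benchmark`.
#' @export
run_benchmark <- function(targets, scorer, n = 10, base_seed = 1,
                          library = default_rotamer_library(),
                          params = packing_params(), spec = membrane_spec(),
                          consensus = TRUE, aggregate = "max", window = 9) {
  score_orig <- list(); score_res <- list(); score_cons <- list()
  quality <- list()
  chi_before <- list(); chi_after <- list()
  for (tg in names(targets)) {
    t_ <- targets[[tg]]
    if (is.null(t_$native)) stop("target ", tg, " has no reference structure")
    if (length(t_$models) < 2) stop("target ", tg, " has fewer than 2 models")
    so <- sr <- cb <- ca_ <- stats::setNames(numeric(length(t_$models)),
                                             names(t_$models))
    chi_native <- compute_chi_angles(t_$native)
    for (j in seq_along(t_$models)) {
      m <- t_$models[[j]]
      rec <- resample_and_score(
        m, t_$profile, scorer, n = n,
        base_seed = base_seed + 1000L * match(tg, names(targets)) + 50L * j,
        library = library, params = params, spec = spec,
        aggregate = aggregate, window = window)
      so[j] <- rec$original_score
      sr[j] <- rec$assigned_score
      cb[j] <- chi_correctness(m, t_$native, chi_reference = chi_native)
      # "after resampling": side chains of the best-scoring repacked decoy
      ca_[j] <- chi_correctness(rec$best_decoy_model, t_$native,
                                chi_reference = chi_native)
    }
    score_orig[[tg]] <- so
    score_res[[tg]] <- sr
    chi_before[[tg]] <- cb
    chi_after[[tg]] <- ca_
    quality[[tg]] <- t_$true_tm
    if (consensus) score_cons[[tg]] <- consensus_score(t_$models)
  }
  z_orig <- z_scores(score_orig, quality)
  z_res <- z_scores(score_res, quality)
  z_cons <- if (consensus) z_scores(score_cons, quality) else NULL

  sel_tm_orig <- vapply(names(targets), function(tg)
    quality[[tg]][[z_orig$selected[tg]]], numeric(1))
  sel_tm_res <- vapply(names(targets), function(tg)
    quality[[tg]][[z_res$selected[tg]]], numeric(1))
  improved_targets <- names(targets)[sel_tm_res > sel_tm_orig]

  chi_b <- unlist(chi_before); chi_a <- unlist(chi_after)
  in_set <- rep(names(targets), times = lengths(chi_before))
  set_stats <- function(sel) {
    b <- chi_b[in_set %in% sel]; a <- chi_a[in_set %in% sel]
    c(before = mean(b), before_sd = stats::sd(b),
      after = mean(a), after_sd = stats::sd(a),
      n_targets = length(sel), n_models = length(b))
  }
  chi_table <- rbind(
    All = set_stats(names(targets)),
    `No improvement` = set_stats(setdiff(names(targets), improved_targets)),
    Improvement = set_stats(improved_targets))

  structure(list(
    z_no_resample = z_orig, z_resample = z_res, z_consensus = z_cons,
    sum_z = c(no_resample = z_orig$sum, resample = z_res$sum,
              consensus = if (consensus) z_cons$sum else NA_real_),
    selected_tm = data.frame(target = names(targets),
                             no_resample = sel_tm_orig,
                             resample = sel_tm_res),
    improved_targets = improved_targets,
    chi_before = chi_before, chi_after = chi_after,
    chi_table = chi_table,
    fraction_models_improved = mean(chi_a > chi_b),
    scores = list(no_resample = score_orig, resample = score_res,
                  consensus = score_cons)),
    class = "memqa_benchmark")
}

#' @export
print.memqa_benchmark <- function(x, ...) {
  cat("memqa selection benchmark\n")
  cat(sprintf("  sum-Z  no-resample %.3f | resample %.3f | consensus %s\n",
              x$sum_z["no_resample"], x$sum_z["resample"],
              ifelse(is.na(x$sum_z["consensus"]), "-",
                     sprintf("%.3f", x$sum_z["consensus"]))))
  cat(sprintf("  chi1/chi2 within 40 deg: %.1f%% -> %.1f%% (%.0f%% of models improved)\n",
              100 * x$chi_table["All", "before"],
              100 * x$chi_table["All", "after"],
              100 * x$fraction_models_improved))
  cat(sprintf("  targets with backbone improvement: %d of %d\n",
              length(x$improved_targets), length(x$z_no_resample$per_target)))
  invisible(x)
}
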
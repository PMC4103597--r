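# The trainable per-residue quality predictor. A linear model (ridge
# regression) stands in for the original linear SVM: it is closed-form,
# exactly reproducible, and retrainable from any (features, S-score) pairs.

#' S-score: distance to per-residue quality
#'
#' The regression target of the per-residue predictor:
#' s = 1 / (1 + (d/d0)^2), so a residue on top of its native position scores
#' 1 and one d0 away scores 0.5.
#'
#' @param distance Calpha deviation, Angstrom (>= 0).
#' @param d0 distance scale, Angstrom, default 3.
#' @return Value in (0, 1].
#' @export
s_score <- function(distance, d0 = 3.0) {
  if (any(distance < 0)) stop("negative distance")
  1 / (1 + (distance / d0)^2)
}

#' Per-residue true quality of a model against its native structure
#'
#' Superposes the model onto the native (Kabsch over all common Calpha
#' atoms) and transforms the per-residue deviations with [s_score()].
#' Residues absent from the native get NA.
#'
#' @param model,native `memqa_structure` objects sharing residue numbering.
#' @param d0 S-score distance scale.
#' @return Numeric vector, one value per model residue.
#' @export
residue_s_scores <- function(model, native, d0 = 3.0) {
  cc <- common_ca(model, native)
  if (nrow(cc$model) < 3) stop("fewer than 3 common Calpha atoms")
  tr <- kabsch_superpose(cc$model, cc$reference)
  d <- sqrt(rowSums((apply_transform(cc$model, tr) - cc$reference)^2))
  rt <- residue_table(model)
  key <- paste(rt$chain, rt$resno, rt$icode)
  out <- rep(NA_real_, nrow(rt))
  out[match(cc$key, key)] <- s_score(d, d0)
  out
}

#' Train the linear quality scorer
#'
#' Fits ridge regression of per-residue S-scores on feature rows pooled over
#' all training pairs. Columns are z-normalised with constants fitted here
#' and stored on the model; all-constant columns are dropped (weight zero)
#' with a warning. The fit is closed-form, hence deterministic.
#'
#' @param training_pairs list of pairs; each a list with `features` (matrix
#'   from [build_feature_matrix()]) and `targets` (numeric vector of true
#'   per-residue S-scores, NA rows skipped).
#' @param regularization positive ridge penalty, default 1.
#' @param metadata free-text provenance string stored on the model.
#' @return Object of class `memqa_scorer` with elements weights, bias,
#'   feature_spec, center, scale, metadata.
#' @export
train_scorer <- function(training_pairs, regularization = 1, metadata = "") {
  if (length(training_pairs) == 0) stop("no training pairs")
  stopifnot(regularization > 0)
  spec <- attr(training_pairs[[1]]$features, "feature_spec")
  X <- do.call(rbind, lapply(training_pairs, function(p) {
    if (!identical(attr(p$features, "feature_spec"), spec))
      stop("inconsistent feature_spec across training pairs")
    p$features
  }))
  y <- unlist(lapply(training_pairs, `[[`, "targets"), use.names = FALSE)
  if (length(y) != nrow(X)) stop("targets do not match feature rows")
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- pmin(1, pmax(0, y[keep]))          # target space is clamped too
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  dead <- scl == 0 | !is.finite(scl)
  if (any(dead)) {
    warning(sum(dead), " constant feature column(s) dropped from the fit")
    scl[dead] <- 1
  }
  Xn <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Xn[, dead] <- 0
  p <- ncol(Xn)
  yc <- y - mean(y)
  A <- crossprod(Xn) + diag(regularization, p)
  w <- solve(A, crossprod(Xn, yc))
  w[dead] <- 0
  b <- mean(y)                             # features are centred
  structure(list(weights = as.numeric(w), bias = b, feature_spec = spec,
                 center = as.numeric(ctr), scale = as.numeric(scl),
                 metadata = metadata),
            class = "memqa_scorer")
}

#' @export
print.memqa_scorer <- function(x, ...) {
  cat(sprintf("memqa linear scorer: %d features, bias %.4f, |w| %.4f\n",
              length(x$weights), x$bias, sqrt(sum(x$weights^2))))
  if (nzchar(x$metadata)) cat("  ", x$metadata, "\n")
  invisible(x)
}

#' @export
coef.memqa_scorer <- function(object, ...) {
  stats::setNames(c(object$bias, object$weights),
                  c("(bias)", object$feature_spec))
}

#' Predict per-residue and global model quality
#'
#' @param object a `memqa_scorer`.
#' @param features matrix from [build_feature_matrix()]; its feature_spec
#'   must match the scorer's.
#' @param ... unused.
#' @return Object of class `memqa_prediction`: list with `per_residue`
#'   (clamped to \[0,1\]) and `global` (their mean).
#' @export
predict.memqa_scorer <- function(object, features, ...) {
  spec <- attr(features, "feature_spec")
  if (!identical(spec, object$feature_spec)) {
    bad <- c(setdiff(object$feature_spec, spec), setdiff(spec, object$feature_spec))
    stop("feature_spec mismatch; divergent columns: ",
         paste(utils::head(unique(bad), 5), collapse = ", "))
  }
  Xn <- sweep(sweep(features, 2, object$center), 2, object$scale, "/")
  raw <- as.numeric(Xn %*% object$weights) + object$bias
  pr <- pmin(1, pmax(0, raw))
  structure(list(per_residue = pr, global = mean(pr), raw = raw),
            class = "memqa_prediction")
}

#' @export
print.memqa_prediction <- function(x, ...) {
  cat(sprintf("predicted quality: global %.4f over %d residues\n",
              x$global, length(x$per_residue)))
  invisible(x)
}

#' Score a structural model
#'
#' Convenience wrapper: build the feature matrix and run the scorer.
#'
#' @param model a `memqa_structure`.
#' @param profile matching `memqa_profile`.
#' @param scorer a `memqa_scorer`.
#' @param spec a [membrane_spec()].
#' @param window feature window width (must match training).
#' @param backbone_cache see [build_feature_matrix()].
#' @return A `memqa_prediction`.
#' @export
score_model <- function(model, profile, scorer, spec = membrane_spec(),
                        window = 9, backbone_cache = NULL) {
  predict(scorer, build_feature_matrix(model, profile, spec, window,
                                       backbone_cache = backbone_cache))
}

#' @noRd
SCORER_HEADER <- "# MEMQA-MODEL v1"

#' Save a scorer to its text format
#' @param scorer a `memqa_scorer`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
save_scorer <- function(scorer, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  num <- function(x) sprintf("%.17g", x)
  writeLines(c(SCORER_HEADER,
               paste0("metadata\t", scorer$metadata),
               paste0("bias\t", num(scorer$bias)),
               paste0("feature\t", scorer$feature_spec, "\t",
                      num(scorer$center), "\t", num(scorer$scale), "\t",
                      num(scorer$weights))), con)
  invisible(path)
}

#' Load a scorer saved by [save_scorer()]
#'
#' Reading back reproduces predictions bit-identically.
#'
#' @param path file path.
#' @return A `memqa_scorer`.
#' @export
load_scorer <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2 || trimws(lines[1]) != SCORER_HEADER)
    stop("not a MEMQA-MODEL v1 file: ", path)
  meta <- sub("^metadata\t", "", lines[grepl("^metadata\t", lines)][1])
  bias <- as.numeric(sub("^bias\t", "", lines[grepl("^bias\t", lines)][1]))
  if (is.na(bias)) stop("malformed scorer file: missing bias")
  fl <- lines[grepl("^feature\t", lines)]
  if (length(fl) == 0) stop("malformed scorer file: no feature lines")
  parts <- strsplit(fl, "\t", fixed = TRUE)
  if (any(lengths(parts) != 5)) stop("malformed scorer file: truncated feature line")
  m <- do.call(rbind, parts)
  vals <- apply(m[, 3:5, drop = FALSE], 2, as.numeric)
  vals <- matrix(vals, ncol = 3)
  if (anyNA(vals)) stop("malformed scorer file: non-numeric weight")
  structure(list(weights = vals[, 3], bias = bias, feature_spec = m[, 2],
                 center = vals[, 1], scale = vals[, 2],
                 metadata = if (is.na(meta)) "" else meta),
            class = "memqa_scorer")
}

#' Build scorer training pairs from a benchmark of targets
#'
#' For every model of every target, computes the feature matrix and the true
#' per-residue S-scores against the native — the direct analog of training
#' an MQAP on a set of models with known natives. With `balance_packing`
#' each model additionally contributes one repacked variant labelled with
#' the same backbone targets, covering both packing states; off by default,
#' matching the convention of training on the models as they come.
#'
#' @param targets benchmark list as from [make_benchmark()] (or any list of
#'   targets with `native`, `models`, `profile`).
#' @param balance_packing include a repacked variant of each model.
#' @param repack_seed seed for the repacked variants.
#' @param library,params,spec repacking setup, see [repack()].
#' @param window feature window width.
#' @return List of training pairs for [train_scorer()].
#' @export
make_training_pairs <- function(targets, balance_packing = FALSE,
                                repack_seed = 1,
                                library = default_rotamer_library(),
                                params = packing_params(),
                                spec = membrane_spec(), window = 9) {
  pairs <- list()
  for (tg in names(targets)) {
    t_ <- targets[[tg]]
    for (m in t_$models) {
      y <- residue_s_scores(m, t_$native)
      pairs[[length(pairs) + 1]] <-
        list(features = build_feature_matrix(m, t_$profile, spec, window),
             targets = y, target_id = tg)
      if (balance_packing) {
        rp <- repack(m, library, params, spec, seed = repack_seed)$model
        pairs[[length(pairs) + 1]] <-
          list(features = build_feature_matrix(rp, t_$profile, spec, window),
               targets = y, target_id = tg)
      }
    }
  }
  pairs
}

#' Cross-validation folds that never split a target
#'
#' Assigns targets to `k` folds round-robin; all residues/models of one
#' target share a fold, the convention for quality-assessment training.
#'
#' @param target_ids character vector, one id per training pair.
#' @param k number of folds, default 5.
#' @return Integer fold labels, one per pair.
#' @export
cv_folds_by_target <- function(target_ids, k = 5) {
  u <- unique(target_ids)
  fold_of <- stats::setNames(rep_len(seq_len(k), length(u)), u)
  unname(fold_of[target_ids])
}

#' Cross-validated scorer performance
#'
#' Trains on k-1 folds of targets and reports the Pearson correlation
#' between predicted and true per-residue S-scores on the held-out fold.
#'
#' @param training_pairs as in [train_scorer()], each pair additionally
#'   carrying a `target_id`.
#' @param k folds, default 5.
#' @param regularization ridge penalty.
#' @return data.frame with fold and correlation.
#' @export
cv_scorer <- function(training_pairs, k = 5, regularization = 1) {
  ids <- vapply(training_pairs, function(p) as.character(p$target_id), character(1))
  folds <- cv_folds_by_target(ids, k)
  out <- data.frame(fold = integer(0), cor = numeric(0))
  for (f in sort(unique(folds))) {
    fit <- train_scorer(training_pairs[folds != f], regularization)
    pred <- true <- numeric(0)
    for (p in training_pairs[folds == f]) {
      pr <- predict(fit, p$features)
      ok <- !is.na(p$targets)
      pred <- c(pred, pr$per_residue[ok])
      true <- c(true, p$targets[ok])
    }
    out <- rbind(out, data.frame(fold = f, cor = stats::cor(pred, true)))
  }
  out
}
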
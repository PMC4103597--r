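# The linear quality predictor: S-score targets, training, prediction,
# persistence, cross-validation.

toy_features <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  attr(X, "feature_spec") <- colnames(X)
  X
}

test_that("the S-score transform hits its closed-form anchors", {
  expect_equal(s_score(0), 1)
  expect_equal(s_score(3, d0 = 3), 0.5)
  expect_equal(s_score(9, d0 = 3), 0.1)
  expect_equal(s_score(1.7, d0 = 3), 1 / (1 + (1.7 / 3)^2))
  expect_error(s_score(-1), "negative")
})

test_that("prediction applies the linear map with clamping", {
  X <- toy_features(50, 8, 1)
  m <- structure(list(weights = rep(0, 8), bias = 0.5,
                      feature_spec = colnames(X), center = rep(0, 8),
                      scale = rep(1, 8), metadata = ""),
                 class = "memqa_scorer")
  pr <- predict(m, X)
  expect_true(all(pr$per_residue == 0.5))
  expect_equal(pr$global, 0.5)
  m$bias <- 2
  expect_true(all(predict(m, X)$per_residue == 1))
  m$bias <- -1
  expect_true(all(predict(m, X)$per_residue == 0))
  # feature_spec mismatch errors and names the divergence
  X2 <- X
  colnames(X2)[3] <- "zz"
  attr(X2, "feature_spec") <- colnames(X2)
  expect_error(predict(m, X2), "feature_spec mismatch")
})

test_that("training recovers a planted linear rule without noise", {
  p <- 30
  X <- toy_features(4000, p, 2)
  w_star <- runif(p, -0.02, 0.02)   # small enough that clamping never bites
  b_star <- 0.5
  y <- as.numeric(X %*% w_star) + b_star
  y <- pmin(1, pmax(0, y))
  fit <- train_scorer(list(list(features = X, targets = y)),
                      regularization = 1e-8)
  # compare on the normalised scale the model stores
  w_native <- fit$weights / fit$scale
  expect_lt(max(abs(w_native - w_star)) / max(abs(w_star)), 1e-3)
  pr <- predict(fit, X)
  expect_lt(max(abs(pr$raw - y)), 1e-4)
})

test_that("strong regularisation shrinks weights toward the mean response", {
  X <- toy_features(300, 10, 3)
  set.seed(4)
  y <- runif(300)
  fit <- train_scorer(list(list(features = X, targets = y)),
                      regularization = 1e8)
  expect_lt(sqrt(sum(fit$weights^2)), 1e-4)
  expect_equal(predict(fit, X)$global, mean(y), tolerance = 1e-3)
})

test_that("regularisation monotonically decreases the weight norm", {
  X <- toy_features(200, 12, 5)
  set.seed(6)
  y <- pmin(1, pmax(0, as.numeric(X %*% runif(12, -0.1, 0.1)) + 0.5 +
                      rnorm(200, 0, 0.05)))
  norms <- vapply(c(0.01, 1, 100, 1e4), function(lam)
    sqrt(sum(train_scorer(list(list(features = X, targets = y)),
                          regularization = lam)$weights^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("constant columns are dropped with a warning, NA targets skipped", {
  X <- toy_features(100, 6, 7)
  X[, 2] <- 3
  attr(X, "feature_spec") <- colnames(X)
  y <- runif(100)
  y[1:5] <- NA
  expect_warning(fit <- train_scorer(list(list(features = X, targets = y))),
                 "constant")
  expect_equal(fit$weights[2], 0)
  expect_error(train_scorer(list()), "no training pairs")
})

test_that("save/load round trip reproduces predictions bit-identically", {
  sc <- fx_scorer()
  f <- withr::local_tempfile(fileext = ".tsv")
  save_scorer(sc, f)
  sc2 <- load_scorer(f)
  expect_identical(sc2$weights, sc$weights)
  expect_identical(sc2$bias, sc$bias)
  expect_identical(sc2$center, sc$center)
  b <- fx_bundle()
  p <- make_profile(b, 0.2, seed = 8)
  fm <- build_feature_matrix(b, p)
  expect_identical(predict(sc, fm)$per_residue, predict(sc2, fm)$per_residue)
  # truncated files error
  lines <- readLines(f)
  lines[5] <- paste(strsplit(lines[5], "\t")[[1]][1:3], collapse = "\t")
  writeLines(lines, f)
  expect_error(load_scorer(f), "truncated")
})

test_that("per-residue targets come from superposed Calpha deviations", {
  b <- fx_bundle()
  expect_equal(residue_s_scores(b, b), rep(1, nrow(residue_table(b))),
               tolerance = 1e-9)
  d <- perturb_backbone(b, 2, seed = 9)
  s <- residue_s_scores(d, b)
  expect_true(all(s > 0 & s <= 1))
  expect_lt(mean(s), 1)
})

test_that("cross-validation folds never split a target", {
  ids <- rep(paste0("t", 1:7), times = c(3, 2, 4, 1, 2, 3, 5))
  folds <- cv_folds_by_target(ids, k = 5)
  expect_true(all(tapply(folds, ids, function(x) length(unique(x))) == 1))
  expect_lte(max(folds), 5)
})

test_that("cross-validated correlations are finite and positive on easy data", {
  tb <- make_benchmark(3, 3, seed = 910, helix_len = 12)
  pairs <- list()
  for (tg in names(tb)) for (m in tb[[tg]]$models)
    pairs[[length(pairs) + 1]] <-
      list(features = build_feature_matrix(m, tb[[tg]]$profile),
           targets = residue_s_scores(m, tb[[tg]]$native), target_id = tg)
  cv <- suppressWarnings(cv_scorer(pairs, k = 3, regularization = 10))
  expect_equal(nrow(cv), 3)
  expect_true(all(is.finite(cv$cor)))
})

test_that("the global score is the mean of per-residue scores", {
  sc <- fx_scorer()
  b <- fx_bundle()
  p <- make_profile(b, 0.2, seed = 8)
  pr <- score_model(b, p, sc)
  expect_equal(pr$global, mean(pr$per_residue), tolerance = 1e-12)
  expect_true(all(pr$per_residue >= 0 & pr$per_residue <= 1))
})
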
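# Dihedrals, Kabsch superposition, TM-score, Z-scores.

test_that("dihedral matches planar references and the vector-algebra oracle", {
  expect_equal(dihedral(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)), 0)
  expect_equal(dihedral(c(0,0,0), c(1,0,0), c(1,1,0), c(2,1,0)), 180)
  # out-of-plane case fixed by the independent projection oracle
  got <- dihedral(c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,1))
  expect_equal(abs(got), 90)
  expect_equal(got, oracle_dihedral(c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,1)))
  set.seed(7)
  for (i in 1:25) {
    p <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral(p[1,], p[2,], p[3,], p[4,]),
                 oracle_dihedral(p[1,], p[2,], p[3,], p[4,]),
                 tolerance = 1e-9)
  }
})

test_that("dihedral symmetries and degenerate input errors", {
  set.seed(8)
  for (i in 1:10) {
    p <- matrix(rnorm(12), 4, 3)
    d <- dihedral(p[1,], p[2,], p[3,], p[4,])
    # a torsion angle is invariant under reversing the atom order ...
    expect_equal(dihedral(p[4,], p[3,], p[2,], p[1,]), d, tolerance = 1e-9)
    # ... and negated by mirror reflection
    m <- p %*% diag(c(1, 1, -1))
    expect_equal(dihedral(m[1,], m[2,], m[3,], m[4,]), -d, tolerance = 1e-9)
  }
  expect_error(dihedral(c(0,0,0), c(0,0,0), c(1,1,0), c(1,1,1)), "degenerate")
})

test_that("kabsch recovers constructed rigid transforms exactly", {
  set.seed(1)
  X <- matrix(rnorm(45), 15, 3)
  # identity
  r0 <- kabsch_superpose(X, X)
  expect_lt(r0$rmsd, 1e-9)
  expect_equal(r0$rotation, diag(3), tolerance = 1e-9)
  # 90 degrees about z plus translation
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  Y <- X %*% t(R90) + matrix(c(3, -2, 5), 15, 3, byrow = TRUE)
  r <- kabsch_superpose(X, Y)
  expect_lt(r$rmsd, 1e-9)
  expect_equal(r$rotation, R90, tolerance = 1e-6)
  expect_lt(max(abs(apply_transform(X, r) - Y)), 1e-9)
  expect_equal(det(r$rotation), 1, tolerance = 1e-6)
})

test_that("kabsch rmsd on noisy data matches a numerical optimiser", {
  set.seed(2)
  X <- matrix(rnorm(150), 50, 3)
  Y <- X + matrix(rnorm(150, sd = 0.1), 50, 3)
  r <- kabsch_superpose(X, Y)
  # independent oracle: direct minimisation over angle-axis + translation
  obj <- function(par) {
    th <- sqrt(sum(par[1:3]^2))
    K <- matrix(c(0, par[3], -par[2], -par[3], 0, par[1],
                  par[2], -par[1], 0), 3, 3)
    R <- if (th < 1e-12) diag(3) else {
      k <- K / th
      diag(3) + sin(th) * k + (1 - cos(th)) * k %*% k
    }
    sqrt(mean(rowSums((X %*% t(R) + matrix(par[4:6], 50, 3, byrow = TRUE) - Y)^2)))
  }
  opt <- stats::optim(rep(0, 6), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  expect_equal(r$rmsd, opt$value, tolerance = 1e-6)
  expect_lte(r$rmsd, opt$value + 1e-8)   # kabsch is the global minimum
  expect_error(kabsch_superpose(X[1:2, ], Y[1:2, ]), "3 points")
})

test_that("tm_score is 1 on self and invariant under rigid motion", {
  b <- fx_bundle()
  expect_equal(tm_score(b, b)$score, 1, tolerance = 1e-9)
  th <- 1.1
  tr <- list(rotation = matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0,
                                 0, 0, 1), 3, 3),
             translation = c(10, -4, 2))
  br <- memqa:::rigid_transform_structure(b, tr)
  expect_equal(tm_score(br, b)$score, 1, tolerance = 1e-6)
  d <- perturb_backbone(b, 3, seed = 5)
  s1 <- tm_score(d, b)$score
  dr <- memqa:::rigid_transform_structure(d, tr)
  expect_equal(tm_score(dr, b)$score, s1, tolerance = 1e-6)
})

test_that("tm_score d0 follows the closed form and score respects bounds", {
  for (L in c(20, 50, 126))
    expect_equal(tm_d0(L), max(0.5, 1.24 * (L - 15)^(1/3) - 1.8),
                 tolerance = 1e-12)
  expect_equal(tm_d0(126), 1.24 * 111^(1/3) - 1.8)
  expect_equal(tm_d0(5), 0.5)   # floored for short chains
  b <- fx_bundle()
  for (mag in c(1, 4)) {
    d <- perturb_backbone(b, mag, seed = 3)
    r <- tm_score(d, b)
    expect_gt(r$score, 0)
    expect_lte(r$score, 1)
    # internal consistency: score recomputable from per-residue distances
    expect_equal(r$score,
                 sum(1 / (1 + (r$per_residue_d / r$d0)^2)) / r$n_common,
                 tolerance = 1e-9)
  }
})

test_that("the tm_score search never does worse than one global superposition", {
  b <- fx_bundle()
  for (seed in 1:5) {
    d <- perturb_backbone(b, 4, seed = seed)
    r <- tm_score(d, b)
    cc <- memqa:::common_ca(d, b)
    tr <- kabsch_superpose(cc$model, cc$reference)
    dist <- sqrt(rowSums((apply_transform(cc$model, tr) - cc$reference)^2))
    single <- sum(1 / (1 + (dist / r$d0)^2)) / cc$L_ref
    expect_gte(r$score, single - 1e-9)
  }
})

test_that("tm_score requires at least 5 common residues", {
  m <- fx_residue("ALA")
  expect_error(tm_score(m, m), "fewer than 5")
})

test_that("z_scores standardises the selected model per target", {
  q <- list(t1 = setNames(c(1, 2, 3, 4, 5), paste0("m", 1:5)))
  s <- list(t1 = setNames(c(0.1, 0.2, 0.3, 0.4, 0.9), paste0("m", 1:5)))
  z <- z_scores(s, q)
  expect_equal(z$per_target[["t1"]], sqrt(2), tolerance = 1e-12)
  expect_equal(z$sum, sqrt(2), tolerance = 1e-12)
  # degenerate spread
  q0 <- list(t1 = setNames(rep(0.5, 4), paste0("m", 1:4)))
  s0 <- list(t1 = setNames(1:4 / 4, paste0("m", 1:4)))
  expect_equal(z_scores(s0, q0)$sum, 0)
  # ties go to the lexicographically smallest id
  st <- list(t1 = setNames(c(0.5, 0.5), c("b", "a")))
  qt <- list(t1 = setNames(c(0.2, 0.9), c("b", "a")))
  expect_equal(unname(z_scores(st, qt)$selected["t1"]), "a")
  expect_error(z_scores(list(t1 = c(m1 = 1)), list(t1 = c(m1 = 1))), "fewer than 2")
})

test_that("z_scores is invariant to per-target affine rescaling of quality", {
  set.seed(3)
  q <- list(t1 = setNames(runif(6), paste0("m", 1:6)),
            t2 = setNames(runif(6), paste0("m", 1:6)))
  s <- list(t1 = setNames(runif(6), paste0("m", 1:6)),
            t2 = setNames(runif(6), paste0("m", 1:6)))
  z1 <- z_scores(s, q)
  q2 <- list(t1 = q$t1 * 3.7 + 0.2, t2 = q$t2)
  expect_equal(z_scores(s, q2)$sum, z1$sum, tolerance = 1e-9)
})

test_that("perfect selection attains the exhaustive maximum sum-Z", {
  set.seed(9)
  q <- lapply(1:4, function(i) setNames(runif(8), paste0("m", 1:8)))
  names(q) <- paste0("t", 1:4)
  z <- z_scores(q, q)           # selection score = true quality
  expect_equal(z$sum, oracle_max_sum_z(q), tolerance = 1e-9)
})
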
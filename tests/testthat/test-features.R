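# Structural features: SASA, secondary structure, contacts, membrane depth,
# profile I/O and the windowed feature matrix.

test_that("an isolated atom's SASA matches the analytic sphere area", {
  m <- new_structure(data.frame(chain = "A", resno = 1L, icode = " ",
                                resname = "GLY", atom = "CA",
                                x = 0, y = 0, z = 0))
  s <- shrake_rupley_sasa(m, n_points = 960)
  analytic <- 4 * pi * (1.87 + 1.4)^2
  expect_equal(s$atom$sasa, analytic, tolerance = 0.01 * analytic)
})

test_that("SASA is additive for non-interacting atoms and zero when buried", {
  two <- new_structure(data.frame(chain = "A", resno = c(1L, 5L),
                                  icode = " ", resname = "GLY", atom = "CA",
                                  x = c(0, 100), y = 0, z = 0))
  s2 <- shrake_rupley_sasa(two, n_points = 960)
  analytic <- 4 * pi * (1.87 + 1.4)^2
  expect_equal(sum(s2$atom$sasa), 2 * analytic, tolerance = 0.02 * analytic)
  # atom caged inside a tight shell of neighbours
  shell <- as.data.frame(t(sapply(1:30, function(i) {
    u <- memqa:::cpp_sphere_points(30)[i, ]
    2.2 * u
  })))
  names(shell) <- c("x", "y", "z")
  cage <- new_structure(rbind(
    data.frame(chain = "A", resno = 1L, icode = " ", resname = "GLY",
               atom = "CA", x = 0, y = 0, z = 0),
    data.frame(chain = "A", resno = 3L, icode = " ", resname = "GLY",
               atom = "CA", shell)))
  s3 <- shrake_rupley_sasa(cage, n_points = 960)
  expect_equal(s3$atom$sasa[1], 0)
})

test_that("SASA agrees with a brute-force point-test oracle on a bundle", {
  b <- fx_bundle50()
  a <- memqa:::heavy_atoms(b)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- memqa:::atom_radius(a$element)
  got <- shrake_rupley_sasa(b, n_points = 240)$atom$sasa
  pts <- memqa:::cpp_sphere_points(240)
  want <- vapply(seq_len(nrow(a)), function(i) {
    ri <- radii[i] + 1.4
    p <- sweep(pts * ri, 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(p))
    for (j in seq_len(nrow(a))) {
      if (j == i) next
      rj <- radii[j] + 1.4
      free <- free & (rowSums(sweep(p, 2, xyz[j, ])^2) >= rj^2)
    }
    mean(free) * 4 * pi * ri^2
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("SASA sampling has converged at the default resolution", {
  b <- fx_bundle()
  t1 <- sum(shrake_rupley_sasa(b, n_points = 960)$residue$sasa)
  t2 <- sum(shrake_rupley_sasa(b, n_points = 1920)$residue$sasa)
  expect_lt(abs(t1 - t2) / t1, 0.005)
})

test_that("SASA is monotone non-increasing as neighbours are added", {
  one <- fx_residue("LEU", c(-60, 180))
  s1 <- sum(shrake_rupley_sasa(one, n_points = 960)$residue$sasa)
  a2 <- one$atoms
  a2$resno <- 5L
  a2$x <- a2$x + 4
  both <- new_structure(rbind(one$atoms, a2))
  s2 <- shrake_rupley_sasa(both, n_points = 960)$residue$sasa[1]
  expect_lt(s2, s1)
})

test_that("an ideal helix is assigned H and short peptides C", {
  h <- make_helix_bundle(1, 20, seed = 2)
  ss <- assign_secondary_structure(h)
  expect_gte(sum(ss == "H"), 14)
  two <- new_structure(fx_bundle()$atoms[fx_bundle()$atoms$res_ord <= 2, ])
  expect_true(all(assign_secondary_structure(two) == "C"))
})

test_that("an ideal antiparallel two-strand sheet is assigned E", {
  # strand A from the backbone generator; strand B is the same strand
  # rotated 180 degrees about z (antiparallel) and slid over a small grid
  # of registrations to pair the backbone hydrogen bonds
  bb1 <- memqa:::build_backbone(rep(-139, 8), rep(135, 8))
  flatten <- function(bb, chain, rot, shift) {
    rows <- lapply(seq_along(bb), function(i) {
      m <- bb[[i]] %*% t(rot)
      m <- sweep(m, 2, shift, "+")
      data.frame(chain = chain, resno = i, icode = " ", resname = "GLY",
                 atom = rownames(bb[[i]]), x = m[, 1], y = m[, 2], z = m[, 3])
    })
    do.call(rbind, rows)
  }
  s1 <- flatten(bb1, "A", diag(3), c(0, 0, 0))
  ca <- t(vapply(bb1, function(m) m["CA", ], numeric(3)))
  u <- ca[8, ] - ca[1, ]; u <- u / sqrt(sum(u^2))   # strand axis
  w <- c(-u[2], u[1], 0); w <- w / sqrt(sum(w^2))   # one perpendicular
  uw <- memqa:::cross3(u, w)
  ctr <- colMeans(ca)
  best <- 0
  for (th in seq(0, 150, by = 30) * pi / 180) {
    v <- cos(th) * w + sin(th) * uw
    R <- 2 * outer(v, v) - diag(3)                  # 180 degrees about v
    for (du in seq(-4, 4, by = 1)) for (dv in c(4.4, 4.8, 5.2)) {
      shift <- ctr - as.numeric(R %*% ctr) + du * u + dv * v
      s2 <- flatten(bb1, "B", R, shift)
      ss <- assign_secondary_structure(new_structure(rbind(s1, s2)))
      best <- max(best, sum(ss == "E"))
      if (best >= 4) break
    }
    if (best >= 4) break
  }
  expect_gte(best, 4)
})

test_that("atom contacts respect the half-open cutoff and neighbour exclusion", {
  mk2 <- function(d) new_structure(data.frame(
    chain = "A", resno = c(1L, 5L), icode = " ", resname = "GLY",
    atom = "CA", x = c(0, d), y = 0, z = 0))
  expect_equal(sum(atom_contact_counts(mk2(100))), 0)
  expect_equal(sum(atom_contact_counts(mk2(4.49))), 2)  # mutual
  expect_equal(sum(atom_contact_counts(mk2(4.51))), 0)
  # sequence neighbours excluded
  mk_adj <- new_structure(data.frame(
    chain = "A", resno = c(1L, 2L), icode = " ", resname = "GLY",
    atom = "CA", x = c(0, 3), y = 0, z = 0))
  expect_equal(sum(atom_contact_counts(mk_adj)), 0)
})

test_that("atom and residue contacts match brute-force recounts on bundles", {
  for (seed in c(1, 4, 6)) {
    b <- fx_memo(paste0("cbundle", seed),
                 function() make_helix_bundle(3, 14, seed = seed))
    expect_identical(unname(atom_contact_counts(b)),
                     unname(oracle_atom_contacts(b)))
    expect_identical(unname(residue_contact_counts(b)),
                     unname(oracle_residue_contacts(b)))
  }
})

test_that("residue contacts use CB (CA for GLY) with an 8 A cutoff", {
  mk <- function(d) {
    r1 <- fx_residue("LEU", c(-60, 180))$atoms
    r2 <- fx_residue("LEU", c(-60, 180))$atoms
    r2$resno <- 5L
    cb1 <- r1[r1$atom == "CB", c("x", "y", "z")]
    r2$x <- r2$x - (r2$x[r2$atom == "CB"] - cb1$x) + d
    r2$y <- r2$y - (r2$y[r2$atom == "CB"] - cb1$y)
    r2$z <- r2$z - (r2$z[r2$atom == "CB"] - cb1$z)
    new_structure(rbind(r1, r2))
  }
  expect_equal(sum(residue_contact_counts(mk(7.9))), 2)
  expect_equal(sum(residue_contact_counts(mk(8.1))), 0)
})

test_that("membrane depth classifies core, interface and water", {
  mk <- function(z) new_structure(data.frame(
    chain = "A", resno = 1L, icode = " ", resname = "GLY", atom = "CA",
    x = 0, y = 0, z = z))
  expect_equal(membrane_depth(mk(0))$region, "core")
  expect_equal(membrane_depth(mk(0))$depth, 0)
  expect_equal(membrane_depth(mk(15.1))$region, "interface")
  expect_equal(membrane_depth(mk(25))$region, "water")
  expect_equal(membrane_depth(mk(-10))$region, "core")
})

test_that("profiles round-trip through their TSV format", {
  b <- fx_bundle()
  p <- make_profile(b, noise_level = 0.3, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(p, f)
  p2 <- read_profile(f, p$sequence)
  expect_equal(p2$pssm, p$pssm, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(p2$pred_ss, p$pred_ss, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(p2$pred_burial, p$pred_burial, tolerance = 1e-5)
  expect_identical(p2$pred_topology, p$pred_topology)
})

test_that("profile validation catches mismatches and renormalises gently", {
  b <- fx_bundle()
  p <- make_profile(b, 0, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(p, f)
  expect_error(read_profile(f, substr(p$sequence, 1, 10)), "length")
  wrong <- paste0(rev(strsplit(p$sequence, "")[[1]]), collapse = "")
  if (wrong != p$sequence) expect_error(read_profile(f, wrong), "match")
  # slightly off-simplex rows are renormalised with a warning
  lines <- readLines(f)
  row <- strsplit(lines[3], "\t")[[1]]
  ih <- which(strsplit(lines[2], "\t")[[1]] == "pH")
  row[ih] <- as.character(as.numeric(row[ih]) + 5e-4)
  lines[3] <- paste(row, collapse = "\t")
  writeLines(lines, f)
  expect_warning(p3 <- read_profile(f, p$sequence), "renormalis")
  expect_equal(sum(p3$pred_ss[1, ]), 1, tolerance = 1e-9)
})

test_that("the feature matrix has the documented shape and padding", {
  b <- fx_bundle()
  p <- make_profile(b, 0.2, seed = 6)
  fm <- build_feature_matrix(b, p, window = 9)
  n <- nrow(residue_table(b))
  expect_equal(nrow(fm), n)
  expect_equal(ncol(fm), 9 * (65 + 1))
  expect_identical(colnames(fm), attr(fm, "feature_spec"))
  # first residue: left half of the window padded
  expect_equal(unname(fm[1, "w-4.pad"]), 1)
  expect_equal(unname(fm[1, "w-4.pssm_A"]), 0)
  expect_equal(unname(fm[1, "w0.pad"]), 0)
  expect_equal(unname(fm[n, "w4.pad"]), 1)
})

test_that("feature rows are invariant under rigid motion of the model", {
  b <- fx_bundle()
  p <- make_profile(b, 0.2, seed = 6)
  fm1 <- build_feature_matrix(b, p)
  th <- 0.6
  tr <- list(rotation = matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0,
                                 0, 0, 1), 3, 3),
             translation = c(0, 0, 0))  # in-plane rotation keeps membrane z
  fm2 <- build_feature_matrix(memqa:::rigid_transform_structure(b, tr), p)
  # contacts, secondary structure and depth are exactly invariant; the SASA
  # feature is invariant up to the fixed sphere-point sampling resolution
  sasa_cols <- grepl("rel_sasa", colnames(fm1))
  expect_identical(fm2[, !sasa_cols], fm1[, !sasa_cols])
  expect_lt(max(abs(fm2[, sasa_cols] - fm1[, sasa_cols])), 0.05)
})
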
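# Rotamer library, side-chain placement, packing energy and the greedy
# fixed-backbone repack protocol.

test_that("the built-in rotamer library satisfies its invariants", {
  lib <- default_rotamer_library()
  key <- paste(lib$aa, lib$phi_bin, lib$psi_bin)
  sums <- tapply(lib$prob, key, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  chi_types <- setdiff(memqa:::AA3, c("GLY", "ALA"))
  expect_setequal(unique(lib$aa), chi_types)
  # every type has a backbone-independent fallback
  expect_setequal(unique(lib$aa[is.na(lib$phi_bin)]), chi_types)
  # lookup falls back for undefined dihedrals and unknown bins
  r1 <- rotamers_for(lib, "LEU", NA, NA)
  expect_true(all(is.na(r1$phi_bin)))
  r2 <- rotamers_for(lib, "LEU", -60, -45)   # helix bin present
  expect_false(any(is.na(r2$phi_bin)))
  r3 <- rotamers_for(lib, "LEU", 120, 120)   # no entry: fallback
  expect_true(all(is.na(r3$phi_bin)))
})

test_that("rotamer library files round trip", {
  lib <- default_rotamer_library()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rotamer_library(lib, f)
  lib2 <- read_rotamer_library(f)
  expect_equal(as.data.frame(lib2)[, names(as.data.frame(lib))],
               as.data.frame(lib), tolerance = 1e-9, ignore_attr = TRUE)
  writeLines(c("# NOT-A-ROTLIB", "x"), f)
  expect_error(read_rotamer_library(f), "MEMQA-ROTLIB")
})

test_that("place_side_chain is deterministic and validates chi counts", {
  N <- c(0, 0, 0); CA <- c(1.458, 0, 0); C <- c(2.0, 1.4, 0)
  a1 <- place_side_chain("LEU", N, CA, C, c(-60, 180))
  a2 <- place_side_chain("LEU", N, CA, C, c(-60, 180))
  expect_identical(a1, a2)
  expect_equal(rownames(place_side_chain("ALA", N, CA, C)), "CB")
  expect_equal(nrow(place_side_chain("GLY", N, CA, C)), 0)
  expect_error(place_side_chain("LEU", N, CA, C, c(-60)), "2 chi")
})

test_that("backbone dihedrals of an ideal helix recover phi/psi within 1 degree", {
  h <- make_helix_bundle(1, 12, seed = 3)
  bd <- backbone_dihedrals(h)
  mid <- 3:10
  expect_true(all(abs(bd$phi[mid] + 57) < 1))
  expect_true(all(abs(bd$psi[mid] + 47) < 1))
  one <- fx_residue("ALA")
  bd1 <- backbone_dihedrals(one)
  expect_true(is.na(bd1$phi) && is.na(bd1$psi))
})

test_that("phi/psi round trip through the backbone builder", {
  set.seed(12)
  phi <- c(NA, runif(8, -150, -50))
  psi <- c(runif(8, -60, 150), NA)
  bb <- memqa:::build_backbone(phi, psi)
  rows <- lapply(seq_along(bb), function(i)
    data.frame(chain = "A", resno = i, icode = " ", resname = "GLY",
               atom = rownames(bb[[i]]), x = bb[[i]][, 1], y = bb[[i]][, 2],
               z = bb[[i]][, 3]))
  m <- new_structure(do.call(rbind, rows))
  bd <- backbone_dihedrals(m)
  expect_equal(bd$phi[-1], phi[-1], tolerance = 1e-3)
  expect_equal(bd$psi[-length(psi)], psi[-length(psi)], tolerance = 1e-3)
})

test_that("packing energy components match closed forms and a brute-force oracle", {
  params <- packing_params()
  # two distant atoms: zero steric
  far <- new_structure(data.frame(chain = "A", resno = c(1L, 5L), icode = " ",
                                  resname = "GLY", atom = "CA",
                                  x = c(0, 50), y = 0, z = 0))
  e_far <- packing_energy(far, params)
  expect_equal(unname(attr(e_far, "components")["steric"]), 0)
  # two carbons at half their summed radii: closed-form quadratic penalty
  d <- 0.5 * (1.87 + 1.87)
  near <- new_structure(data.frame(chain = "A", resno = c(1L, 5L), icode = " ",
                                   resname = "ALA", atom = "CB",
                                   x = c(0, d), y = 0, z = 0))
  e_near <- packing_energy(near, params)
  expect_equal(unname(attr(e_near, "components")["steric"]),
               (params$clash_scale * 2 * 1.87 - d)^2, tolerance = 1e-9)
  # full model equals the brute-force oracle
  b <- randomize_side_chains(fx_bundle(), 0.7, seed = 13)
  spec <- membrane_spec()
  lib <- default_rotamer_library()
  expect_equal(as.numeric(packing_energy(b, params, spec, lib)),
               oracle_packing_energy(b, params, spec, lib), tolerance = 1e-9)
})

test_that("repack preserves the backbone bit-for-bit and never raises TM", {
  b <- fx_bundle()
  scrambled <- randomize_side_chains(b, 1, seed = 14)
  rp <- repack(scrambled, seed = 3)
  bb <- function(m) {
    a <- m$atoms[m$atoms$atom %in% c("N", "CA", "C", "O"), ]
    a <- a[order(a$res_ord, a$atom), c("x", "y", "z")]
    as.matrix(a)
  }
  expect_identical(bb(rp$model), bb(scrambled))
  expect_equal(tm_score(rp$model, b)$score, tm_score(scrambled, b)$score,
               tolerance = 1e-9)
})

test_that("the greedy energy trace is non-increasing and beats clashed inputs", {
  b <- fx_bundle()
  for (seed in 1:3) {
    scrambled <- randomize_side_chains(b, 1, seed = 20 + seed)
    rp <- repack(scrambled, seed = seed)
    expect_true(all(diff(rp$trace) <= 1e-9))
    expect_lt(rp$energy, rp$initial_energy)
  }
})

test_that("a model at the library optimum is a fixed point", {
  b <- fx_bundle()   # built at most-probable rotamers
  rp1 <- repack(b, seed = 5)
  rp2 <- repack(rp1$model, seed = 9)
  expect_equal(rp2$model$atoms$x, rp1$model$atoms$x, tolerance = 1e-9)
  expect_equal(rp2$energy, rp1$energy, tolerance = 1e-6)
})

test_that("decoy generation is deterministic and reduces to single repack", {
  b <- randomize_side_chains(fx_bundle(), 0.8, seed = 30)
  d1 <- generate_decoys(b, n = 3, base_seed = 7)
  d2 <- generate_decoys(b, n = 3, base_seed = 7)
  expect_identical(lapply(d1, function(d) d$model$atoms),
                   lapply(d2, function(d) d$model$atoms))
  single <- repack(b, seed = 8)
  expect_identical(d1[[1]]$model$atoms, single$model$atoms)
  expect_error(generate_decoys(b, n = 0), "at least 1")
  # all decoys share the input backbone exactly
  bbx <- function(m) m$atoms$x[m$atoms$atom %in% c("N", "CA", "C", "O")]
  for (d in d1) expect_identical(bbx(d$model), bbx(b))
})

test_that("repacking improves side-chain packing on scrambled models", {
  b <- fx_bundle()
  chi_nat <- compute_chi_angles(b)
  improved <- 0
  for (i in 1:20) {
    scrambled <- randomize_side_chains(b, 1, seed = 100 + i)
    before <- chi_correctness(scrambled, b, chi_reference = chi_nat)
    after <- chi_correctness(repack(scrambled, seed = i)$model, b,
                             chi_reference = chi_nat)
    if (after > before) improved <- improved + 1
  }
  expect_gte(improved, 16)   # >= 80% of models improve
})

test_that("repacking the native keeps side-chain quality above the library floor", {
  b <- fx_bundle()
  rp <- repack(b, seed = 11)
  expect_gte(chi_correctness(rp$model, b), 0.6)
})
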
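# PDB reading, writing, validation and sequence extraction.

test_that("a minimal one-residue file parses to the expected structure", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fx_ala_pdb_lines(), f)
  m <- read_pdb(f)
  expect_s3_class(m, "memqa_structure")
  rt <- residue_table(m)
  expect_equal(nrow(rt), 1)
  expect_equal(rt$resname, "ALA")
  expect_equal(nrow(m$atoms), 5)
  expect_equal(unname(extract_sequence(m)), "A")
})

test_that("only the first MODEL block is read", {
  f <- withr::local_tempfile(fileext = ".pdb")
  block <- fx_ala_pdb_lines()[1:5]
  shifted <- sub("   0\\.000   0\\.000", "  99.000  99.000", block)
  writeLines(c("MODEL        1", block, "ENDMDL",
               "MODEL        2", shifted, "ENDMDL", "END"), f)
  m <- read_pdb(f)
  expect_equal(nrow(m$atoms), 5)
  expect_equal(m$atoms$x[1], 0)
})

test_that("HETATM records and unknown residues are dropped", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(fx_ala_pdb_lines()[1:5],
               "HETATM    6  O   HOH A   2      10.000  10.000  10.000  1.00  0.00           O",
               "ATOM      7  C1  LIG A   3      11.000  11.000  11.000  1.00  0.00           C",
               "END"), f)
  expect_warning(m <- read_pdb(f), "non-standard")
  expect_equal(nrow(m$atoms), 5)
})

test_that("alternate locations resolve to the highest occupancy copy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- fx_ala_pdb_lines()
  altA <- sub("^(ATOM      2  CA )(.)(ALA)", "\\1A\\3", lines[2])
  altA <- sub("1\\.00", "0.40", altA)
  altB <- sub("^(ATOM      2  CA )(.)(ALA)", "\\1B\\3", lines[2])
  altB <- sub("   1\\.458", "   9.999", altB)
  altB <- sub("1\\.00", "0.60", altB)
  writeLines(c(lines[1], altA, altB, lines[3:6]), f)
  m <- read_pdb(f)
  ca <- m$atoms[m$atoms$atom == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 9.999)
})

test_that("malformed coordinates raise an error naming the line", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- fx_ala_pdb_lines()
  lines[2] <- sub("   1\\.458", "   xx.xx", lines[2])
  writeLines(lines, f)
  expect_error(read_pdb(f), "line 2")
})

test_that("a file with no ATOM records is a parse error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER junk", "END"), f)
  expect_error(read_pdb(f), "no ATOM records")
})

test_that("write/read round trip preserves structure to 3 decimals", {
  b <- fx_bundle()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(b, f)
  b2 <- read_pdb(f)
  expect_equal(nrow(b2$atoms), nrow(b$atoms))
  expect_identical(b2$atoms$atom, b$atoms$atom)
  expect_identical(b2$atoms$resno, b$atoms$resno)
  expect_identical(unname(extract_sequence(b2)), unname(extract_sequence(b)))
  expect_lt(max(abs(as.matrix(b2$atoms[, c("x", "y", "z")]) -
                      as.matrix(b$atoms[, c("x", "y", "z")]))), 5.01e-4)
})

test_that("write_pdb emits 5 ATOM lines for one residue and TER per chain", {
  m1 <- fx_residue("ALA")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m1, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "ATOM")), 4)   # N, CA, C, CB built here
  a2 <- m1$atoms
  a2$chain <- "B"
  two <- new_structure(rbind(m1$atoms, a2))
  write_pdb(two, f)
  expect_equal(sum(startsWith(readLines(f), "TER")), 2)
})

test_that("read_pdb agrees with an independent PDB reader on coordinates", {
  skip_if_not_installed("bio3d")
  b <- fx_bundle()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(b, f)
  ours <- read_pdb(f)
  ref <- bio3d::read.pdb(f)
  expect_equal(nrow(ours$atoms), nrow(ref$atom))
  expect_equal(ours$atoms$x, ref$atom$x, tolerance = 1e-9)
  expect_equal(ours$atoms$atom, ref$atom$elety)
})

test_that("validate_model reports missing backbone, chain breaks, duplicates", {
  b <- fx_bundle()
  expect_equal(nrow(validate_model(b)), 0)

  # residue with only CB
  a <- b$atoms
  drop <- a$res_ord == 5 & a$atom != "CB"
  m <- new_structure(a[!drop, ])
  v <- validate_model(m)
  expect_true("missing_backbone" %in% v$type)

  # translate the second half of the chain far away: one chain break
  a2 <- b$atoms
  far <- a2$res_ord > 20
  a2$x[far] <- a2$x[far] + 100
  v2 <- validate_model(new_structure(a2))
  expect_true("chain_break" %in% v2$type)

  # same residue id with conflicting residue names
  a3 <- fx_residue("ALA")$atoms
  a4 <- fx_residue("SER", -60)$atoms
  a4 <- a4[a4$atom == "OG", ]
  v3 <- validate_model(new_structure(rbind(a3, a4)))
  expect_true("duplicate_residue" %in% v3$type)
})
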
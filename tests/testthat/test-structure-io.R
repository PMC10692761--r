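make_test_pdb <- function(path) {
  writeLines(c(
    "HEADER    SYNTHETIC TEST ENTRY",
    "SEQRES   1 A    6  MET LYS ALA MSE LEU VAL",
    "ATOM      1  N   MET A   1      10.000   5.000  -6.000  1.00  0.00           N",
    "ATOM      2  CA  MET A   1      11.104   6.134  -6.504  1.00  0.00           C",
    "ATOM      3  CA  LYS A   2      12.500   8.500  -4.000  1.00  0.00           C",
    "ATOM      4  CA AALA A   3      14.000  10.000  -2.000  0.50  0.00           C",
    "ATOM      5  CA BALA A   3      14.900  10.900  -2.900  0.50  0.00           C",
    "HETATM    6  CA  MSE A   4      16.000  12.000   0.000  1.00  0.00           C",
    "ATOM      7  CA  GLY B   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      8  CA  ALA B   2       4.000   5.000   6.000  1.00  0.00           C",
    "ATOM      9  CA  SER B   3       7.000   8.000   9.000  1.00  0.00           C",
    "TER",
    "END"
  ), path)
  path
}

test_that("multi-chain files split into per-chain records in file order", {
  f <- make_test_pdb(withr::local_tempfile(fileext = ".pdb"))
  recs <- read_chains(f)
  expect_length(recs, 2L)
  expect_identical(vapply(recs, function(r) r$chain_id, ""), c("A", "B"))
  # repeated reads are identical (stable splitting)
  expect_identical(recs, read_chains(f))
})

test_that("nonstandard residues map to parents, altlocs collapse, SEQRES feeds deposited", {
  f <- make_test_pdb(withr::local_tempfile(fileext = ".pdb"))
  recs <- read_chains(f)
  a <- recs[[1]]
  # selenomethionine resolved as M; first altloc of residue 3 kept
  expect_identical(a$resolved_seq, "MKAM")
  expect_equal(unname(a$ca_coords[3, ]), c(14, 10, -2))
  # deposited from SEQRES: 6 residues incl. MSE -> M
  expect_identical(a$deposited_seq, "MKAMLV")
  expect_equal(chain_size(a), 6L)
  # chain B has no SEQRES: falls back to resolved
  expect_identical(recs[[2]]$deposited_seq, recs[[2]]$resolved_seq)
})

test_that("deposited sequences from FASTA override SEQRES", {
  dir <- withr::local_tempdir()
  f <- make_test_pdb(file.path(dir, "1abc.pdb"))
  fa <- file.path(dir, "seqs.fasta")
  writeLines(c(">1abc_A deposited record", "MKAMLVWWXY",
               ">1abc_B", "GASGG"), fa)
  recs <- read_chains(f, fasta = fa)
  expect_identical(recs[[1]]$deposited_seq, "MKAMLVWWXY")
  expect_equal(chain_size(recs[[1]]), 10L)
  expect_identical(recs[[2]]$deposited_seq, "GASGG")
})

test_that("files with no usable polymer chain are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       1.000   2.000   3.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2       4.000   5.000   6.000  1.00  0.00           O",
    "END"
  ), f)
  expect_error(suppressWarnings(read_chains(f)))
  expect_error(read_chains(file.path(tempdir(), "nope.pdb")), "no such file")
})

test_that("size filter acts on deposited length, preserving order", {
  mk <- function(dep, nres, entry) {
    ch <- coil_chain(nres, seed = 3L, entry = entry)
    ch$deposited_seq <- random_seq(dep, seed = dep)
    ch
  }
  chains <- list(mk(49L, 40L, "a001"), mk(50L, 40L, "a002"),
                 mk(51L, 40L, "a003"), mk(55L, 40L, "a004"))
  kept <- filter_chains(chains, 50L)
  expect_identical(vapply(kept, function(c) c$entry_id, ""),
                   c("a002", "a003", "a004"))
  expect_identical(filter_chains(chains, 1L), chains)
  expect_length(filter_chains(list(), 50L), 0L)
  # chain_size definition: deposited length, resolved fallback, empty zero
  expect_equal(chain_size(chains[[4]]), 55L)
  ch <- coil_chain(60L, seed = 4L, entry = "a005")
  expect_equal(chain_size(ch), 60L)
})

test_that("superposed pairs round-trip through PDB format", {
  a <- two_helix_chain(seed = 1L, entry = "s001")
  b <- two_helix_chain(seed = 2L, entry = "s002")
  f <- withr::local_tempfile(fileext = ".pdb")

  # identity transform leaves coordinates unchanged
  write_superposition(a, b, structure(list(rotation = diag(3),
                                           translation = c(0, 0, 0)),
                                      class = "Superposition"), f)
  recs <- read_chains(f)
  expect_equal(recs[[2]]$ca_coords, b$ca_coords, tolerance = 1e-3,
               ignore_attr = TRUE)

  # a known 90-degree rotation about z plus shift is applied verbatim
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  tr <- c(1, 2, 3)
  write_superposition(a, b, structure(list(rotation = R, translation = tr),
                                      class = "Superposition"), f)
  recs <- read_chains(f)
  hand <- b$ca_coords %*% t(R) + matrix(tr, nrow(b$ca_coords), 3, byrow = TRUE)
  expect_equal(recs[[2]]$ca_coords, hand, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(recs[[1]]$ca_coords, a$ca_coords, tolerance = 1e-3,
               ignore_attr = TRUE)

  # improper rotations are rejected before writing
  bad <- structure(list(rotation = diag(c(1, 1, -1)),
                        translation = c(0, 0, 0)), class = "Superposition")
  expect_error(write_superposition(a, b, bad, f), "orthonormal")
})
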
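test_that("Qscore follows its closed form and bounds", {
  expect_equal(qscore(80, 0, 80, 80), 1.0)
  expect_equal(qscore(50, 3.0, 50, 50, r0 = 3.0), 0.5)
  expect_equal(qscore(50, 3.0, 100, 100, r0 = 3.0), 0.125)
  expect_equal(qscore(0, 2.5, 30, 40), 0)
  expect_error(qscore(60, 1, 50, 50), "invalid")
  expect_error(qscore(10, -1, 50, 50), "invalid")
  # monotonicity: decreasing in rmsd, increasing in n_aligned
  r <- seq(0, 10, by = 0.5)
  q_r <- vapply(r, function(x) qscore(40, x, 50, 60), numeric(1))
  expect_true(all(diff(q_r) < 0))
  na <- 1:50
  q_n <- vapply(na, function(x) qscore(x, 2, 50, 60), numeric(1))
  expect_true(all(diff(q_n) > 0))
  expect_true(all(q_r >= 0 & q_r <= 1))
  expect_true(all(q_n >= 0 & q_n <= 1))
})

test_that("seed enumeration covers self-pairs and respects SSE kinds", {
  ch <- two_helix_chain(seed = 1L)
  sses <- assign_sse(ch)
  expect_gte(length(sses), 2L)
  seeds <- seed_transforms(sses, sses, ch$ca_coords, ch$ca_coords)
  expect_gt(length(seeds), 0L)
  dev <- vapply(seeds, function(s) {
    max(abs(s$rotation - diag(3))) + max(abs(s$translation))
  }, numeric(1))
  expect_lt(min(dev), 1e-6)  # self-pairing contains the identity

  # single-SSE chains fall back to sliding-window seeding even across kinds
  helix <- synth_chain(chain_spec(data.frame(kind = "helix", n = 30),
                                  seed = 2L), "s002", "A")
  strand <- synth_chain(chain_spec(data.frame(kind = "strand", n = 30),
                                   seed = 3L), "s003", "A")
  sw <- seed_transforms(assign_sse(helix), assign_sse(strand),
                        helix$ca_coords, strand$ca_coords)
  expect_gt(length(sw), 0L)

  # no secondary structure at all -> no seeds
  co <- coil_chain(60L, seed = 7L)
  expect_length(seed_transforms(assign_sse(helix), assign_sse(co),
                                helix$ca_coords, co$ca_coords), 0L)
})

test_that("self-alignment is exact: full diagonal correspondence, Qscore 1", {
  ch <- two_helix_chain(seed = 1L)
  res <- refine_alignment(ch$ca_coords, ch$ca_coords,
                          strucphylo:::identity_transform())
  expect_identical(res$status, "OK")
  expect_equal(res$qscore, 1.0, tolerance = 1e-9)
  expect_equal(res$n_aligned, nrow(ch$ca_coords))
  expect_equal(res$correspondence[, 1], res$correspondence[, 2])

  full <- align_structures(ch, ch)
  expect_equal(full$qscore, 1.0, tolerance = 1e-9)
  expect_equal(full$rmsd, 0, tolerance = 1e-6)
  expect_equal(full$n_aligned, full$n1)
})

test_that("perturbed copies realign with high Qscore and full coverage", {
  ch <- two_helix_chain(seed = 1L, entry = "s001")
  pp <- perturb_chain(ch, 0.3, seed = 4L)
  pp$entry_id <- "s002"
  res <- align_structures(ch, pp)
  expect_identical(res$status, "OK")
  expect_gt(res$qscore, 0.9)
  expect_equal(res$n_aligned, res$n1)
  expect_equal(res$n1, res$n2)
})

test_that("rigid-transformed copies are recovered almost exactly", {
  ch <- two_helix_chain(seed = 1L, entry = "s001")
  R <- strucphylo:::rotation_between(c(0, 0, 1), c(1, 1, 1) / sqrt(3))
  moved <- ch
  moved$entry_id <- "s002"
  moved$ca_coords <- ch$ca_coords %*% t(R) +
    matrix(c(12, -7, 3), nrow(ch$ca_coords), 3, byrow = TRUE)
  res <- align_structures(ch, moved)
  expect_gt(res$qscore, 0.99)
  back <- apply_transform(moved$ca_coords, res$transform)
  expect_lt(sqrt(mean(rowSums((back - ch$ca_coords)^2))), 1e-3)
})

test_that("structurally unrelated pairs give the NO_SIMILARITY sentinel", {
  helix60 <- synth_chain(chain_spec(data.frame(kind = "helix", n = 60),
                                    seed = 1L), "s001", "A")
  co <- coil_chain(60L, seed = 7L, entry = "c001")
  res <- align_structures(helix60, co)
  expect_identical(res$status, "NO_SIMILARITY")
  expect_identical(res$qscore, -1)

  co2 <- coil_chain(60L, seed = 8L, entry = "c002")
  expect_identical(align_structures(co, co2)$status, "NO_SIMILARITY")

  # two-helix vs multi-strand chains: no same-kind SSE pairs
  strands <- synth_chain(
    chain_spec(data.frame(kind = c("strand", "coil", "strand", "coil",
                                   "strand"),
                          n = c(12, 4, 12, 4, 12)), seed = 3L), "e001", "A")
  res2 <- align_structures(two_helix_chain(seed = 1L), strands)
  expect_identical(res2$status, "NO_SIMILARITY")
  expect_identical(res2$qscore, -1)

  # degenerate stub
  stub <- ch <- two_helix_chain(seed = 1L)
  stub$ca_coords <- stub$ca_coords[1:2, ]
  stub$resolved_seq <- substr(stub$resolved_seq, 1, 2)
  stub$author_numbers <- stub$author_numbers[1:2]
  expect_identical(align_structures(stub, ch)$status, "NO_SIMILARITY")
})

test_that("alignment is symmetric and correspondences are monotone", {
  a <- two_helix_chain(seed = 1L, entry = "s001")
  b <- perturb_chain(two_helix_chain(seed = 1L, entry = "zzzz"), 0.5,
                     seed = 6L)
  ab <- align_structures(a, b)
  ba <- align_structures(b, a)
  expect_identical(ab$qscore, ba$qscore)  # exact, canonical-order evaluation
  expect_identical(ab$n_aligned, ba$n_aligned)
  expect_identical(ab$n1, ba$n2)
  # transforms are mutual inverses
  expect_equal(apply_transform(apply_transform(b$ca_coords, ab$transform),
                               ba$transform),
               b$ca_coords, tolerance = 1e-9)
  # strictly increasing correspondence in both components
  expect_true(all(diff(ab$correspondence[, 1]) > 0))
  expect_true(all(diff(ab$correspondence[, 2]) > 0))
  expect_lte(ab$n_aligned, min(ab$n1, ab$n2))
})

test_that("the self-check accepts structured chains and rejects coils", {
  expect_true(self_check(two_helix_chain(seed = 1L)))
  expect_false(self_check(coil_chain(60L, seed = 7L)))
  stub <- coil_chain(10L, seed = 2L)
  stub$ca_coords <- stub$ca_coords[1:4, ]
  stub$resolved_seq <- substr(stub$resolved_seq, 1, 4)
  stub$author_numbers <- stub$author_numbers[1:4]
  stub$deposited_seq <- stub$resolved_seq
  expect_false(self_check(stub))
})
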
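test_that("distance matrices come from scores with zero diagonal", {
  db <- study_db()
  cents <- vapply(db$clusters, `[[`, "", "centroid_id")
  D <- build_distance_matrix(db, cents)
  expect_identical(rownames(D), cents)
  expect_identical(diag(D), stats::setNames(rep(0, length(cents)), cents))
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 1))
  # sentinel pairs map to distance 1
  sc <- db$scores
  sent <- sc[sc$qscore == -1, ][1, ]
  expect_identical(D[sent$id1, sent$id2], 1)
  # single taxon: 1x1 zero matrix; unknown taxa rejected
  expect_identical(build_distance_matrix(db, cents[1]),
                   matrix(0, 1, 1, dimnames = list(cents[1], cents[1])))
  expect_error(build_distance_matrix(db, "qqqq_A"), "unknown")
})

test_that("two taxa split their distance into equal branches", {
  D <- matrix(c(0, 0.6, 0.6, 0), 2, 2, dimnames = list(c("A", "B"),
                                                       c("A", "B")))
  tree <- neighbor_joining(D)
  expect_setequal(tree$tip.label, c("A", "B"))
  expect_equal(sort(tree$edge.length), c(0.3, 0.3))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, f)
  expect_identical(readLines(f), "(A:0.3,B:0.3);")
})

test_that("neighbour joining recovers a known additive quartet exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> additive leaf-to-leaf distances
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- neighbor_joining(D)
  expect_equal(tree_path_distances(tree)[LETTERS[1:4], LETTERS[1:4]], D,
               tolerance = 1e-9)
  # AB|CD topology: A and B are sisters
  pair <- ape::getMRCA(tree, c("A", "B"))
  expect_identical(sort(ape::extract.clade(tree, pair)$tip.label),
                   c("A", "B"))
})

test_that("neighbour joining is exact on random additive matrices", {
  for (seed in 1:8) {
    n <- 4L + (seed %% 9L)
    D <- random_additive_matrix(n, seed)
    tree <- neighbor_joining(D)
    expect_setequal(tree$tip.label, rownames(D))
    expect_equal(tree_path_distances(tree)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
    expect_true(all(tree$edge.length >= 0))
  }
})

test_that("degenerate and invalid matrices are handled", {
  Z <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- neighbor_joining(Z)
  expect_true(all(tree$edge.length == 0))
  expect_setequal(tree$tip.label, LETTERS[1:4])
  bad <- Z; bad[1, 2] <- 0.5
  expect_error(neighbor_joining(bad), "symmetric")
  neg <- Z; neg[1, 2] <- neg[2, 1] <- -0.1
  expect_error(neighbor_joining(neg), "non-negative")
})

test_that("NEXUS distance matrices round-trip", {
  db <- study_db()
  cents <- vapply(db$clusters, `[[`, "", "centroid_id")
  D <- build_distance_matrix(db, cents)
  f <- withr::local_tempfile(fileext = ".nex")
  write_nexus(D, f)
  lines <- readLines(f)
  expect_identical(lines[1], "#NEXUS")
  expect_true(any(grepl("TRIANGLE=BOTH DIAGONAL", lines)))
  D2 <- read_nexus_dist(f)
  expect_identical(rownames(D2), cents)  # labels already sanitary
  expect_equal(D2, D, tolerance = 1e-9)
  # asymmetric input refused before any write
  bad <- D; bad[1, 2] <- bad[1, 2] + 1e-3
  f2 <- withr::local_tempfile(fileext = ".nex")
  expect_error(write_nexus(bad, f2), "symmetric")
  expect_false(file.exists(f2))
})

test_that("newick trees round-trip and labels sanitize consistently", {
  D <- random_additive_matrix(6, 3)
  rownames(D) <- colnames(D) <- c("a b", "c:d", "e;f", "g(h", "i)j", "k,l")
  tree <- neighbor_joining(D)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, sanitize_label(rownames(D)))
  expect_identical(sort(back$tip.label), sort(unique(back$tip.label)))
  # lengths preserved to the 6-decimal serialization
  o <- match(back$tip.label, tree$tip.label)
  expect_equal(tree_path_distances(back),
               tree_path_distances(tree)[back$tip.label, back$tip.label],
               tolerance = 1e-5)
})
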
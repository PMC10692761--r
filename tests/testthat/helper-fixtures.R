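# Shared fixture builders and independent oracles.

# Study-set database shared across test files (built once per run).
study_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) {
      db <<- suppressMessages(build_db(synth_study_set(1)))
    }
    db
  }
})

two_helix_chain <- function(seed = 1L, entry = "s001", chain = "A") {
  synth_chain(
    chain_spec(data.frame(kind = c("helix", "coil", "helix"),
                          n = c(20, 5, 20)), seed = seed),
    entry, chain
  )
}

coil_chain <- function(n = 60L, seed = 7L, entry = "c001", chain = "A") {
  synth_chain(chain_spec(data.frame(kind = "coil", n = n), seed = seed),
              entry, chain)
}

# Chain with a given sequence on a coil scaffold (for sequence-level tests
# where geometry is irrelevant).
seq_chain <- function(seq1, entry, chain = "A", seed = 1L) {
  synth_chain(chain_spec(data.frame(kind = "coil", n = nchar(seq1)),
                         sequence_mode = seq1, seed = seed),
              entry, chain)
}

random_seq <- function(n, seed) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed_local(seed, paste(sample(aa, n, replace = TRUE), collapse = ""))
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Independent rigid-fit oracle: numerical minimization of RMSD over an
# Euler-angle parameterization of the rotation, multi-start. Used to verify
# the closed-form Kabsch solution; deliberately ignorant of SVD.
euler_rotation <- function(ang) {
  ca <- cos(ang[1]); sa <- sin(ang[1])
  cb <- cos(ang[2]); sb <- sin(ang[2])
  cg <- cos(ang[3]); sg <- sin(ang[3])
  Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
  Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

brute_force_fit_rmsd <- function(P, Q) {
  # centre both sets: the optimal translation aligns the centroids, so only
  # the rotation needs to be searched
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  obj <- function(ang) {
    M <- Q0 %*% t(euler_rotation(ang))
    sqrt(mean(rowSums((P0 - M)^2)))
  }
  starts <- as.matrix(expand.grid(a = c(0, pi / 2, pi, 3 * pi / 2),
                                  b = c(0.01, pi / 2, pi - 0.01),
                                  g = c(0, pi / 2, pi, 3 * pi / 2)))
  best <- Inf
  for (k in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[k, ], obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-15))
    best <- min(best, fit$value, fit2$value)
  }
  best
}

# Additive distance matrix from a random binary tree with positive branch
# lengths, plus the generating tree's leaf-to-leaf path metric (identical by
# construction). Oracle for neighbour joining.
random_additive_matrix <- function(n_taxa, seed) {
  with_seed_local(seed, {
    tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.1, 1))
    tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
    D <- ape::cophenetic.phylo(tr)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    D
  })
}
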
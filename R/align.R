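#' Default structural-alignment parameters
#'
#' @param r0 Qscore scaling factor in Angstrom (default 3.0).
#' @param d_cut distance cutoff (A) for keeping a residue pair during
#'   refinement (default 5.0).
#' @param min_aligned minimum aligned pairs for a reportable alignment
#'   (default 10); below it the comparison is NO_SIMILARITY.
#' @param max_iter maximum refinement iterations per seed (default 50).
#' @param max_seeds number of seed transforms refined (default 100).
#' @param seed_angle_tol inter-SSE angle compatibility tolerance in degrees
#'   (default 30).
#' @param seed_dist_tol inter-SSE midpoint-distance compatibility tolerance in
#'   Angstrom (default 5).
#' @param window sliding-window seed length in residues (default 15).
#' @return named list of parameters.
#' @export
align_params <- function(r0 = 3.0, d_cut = 5.0, min_aligned = 10L,
                         max_iter = 50L, max_seeds = 100L,
                         seed_angle_tol = 30, seed_dist_tol = 5,
                         window = 15L) {
  list(r0 = r0, d_cut = d_cut, min_aligned = min_aligned,
       max_iter = max_iter, max_seeds = max_seeds,
       seed_angle_tol = seed_angle_tol, seed_dist_tol = seed_dist_tol,
       window = window)
}

#' Superposition quality score (Qscore)
#'
#' `Q = n_aligned^2 / ((1 + (rmsd/r0)^2) * n1 * n2)`, the SSM/GESAMT-family
#' similarity in \[0, 1\]: 1 for identical structures, near 0 for unrelated
#' ones. It rewards both alignment quality (low RMSD) and alignment coverage
#' relative to both structure sizes, so a short well-fitting core of a large
#' protein does not score highly.
#'
#' @param n_aligned number of aligned residue pairs.
#' @param rmsd C-alpha RMSD (A) over the aligned pairs.
#' @param n1,n2 resolved residue counts of the two structures.
#' @param r0 scaling factor in Angstrom (default 3.0).
#' @return Qscore in \[0, 1\].
#' @export
qscore <- function(n_aligned, rmsd, n1, n2, r0 = 3.0) {
  if (n1 < 1 || n2 < 1 || r0 <= 0 || rmsd < 0 ||
      n_aligned < 0 || n_aligned > min(n1, n2)) {
    stop("invalid qscore arguments")
  }
  n_aligned^2 / ((1 + (rmsd / r0)^2) * n1 * n2)
}

sse_angle <- function(s1, s2) {
  d <- abs(sum(s1$axis_direction * s2$axis_direction))
  acos(min(max(d, -1), 1)) * 180 / pi
}

sse_mid <- function(s) colMeans(s$endpoints)

#' Enumerate seed transforms for structural alignment
#'
#' For every ordered pair of distinct SSEs in A and every same-kind ordered
#' pair in B whose inter-element angle and midpoint distance are compatible
#' (within `seed_angle_tol` degrees and `seed_dist_tol` Angstrom), a candidate
#' rigid transform is computed by Kabsch on the four axis endpoints. When
#' either chain has exactly one SSE, exhaustive gapless sliding-window
#' seeding is used instead (one Kabsch fit per relative offset of a
#' `window`-residue window). A chain with no detected SSE at all cannot seed
#' a superposition: the seed list is empty and the comparison downstream is
#' NO_SIMILARITY, mirroring aligners that fail on structures whose secondary
#' structure they cannot analyse. Seeds are returned sorted by their
#' preliminary fit RMSD (best first).
#'
#' @param ssesA,ssesB SSE lists from [assign_sse()].
#' @param coordsA,coordsB n x 3 C-alpha coordinate matrices.
#' @param params [align_params()].
#' @return list of `Superposition` seed transforms (possibly empty).
#' @export
seed_transforms <- function(ssesA, ssesB, coordsA, coordsB,
                            params = align_params()) {
  seeds <- list(); quality <- numeric(0)
  # a chain without any analysable secondary structure cannot seed a
  # superposition: no seeds, hence NO_SIMILARITY downstream
  if (length(ssesA) == 0L || length(ssesB) == 0L) return(seeds)
  add_seed <- function(s) {
    seeds[[length(seeds) + 1L]] <<- s
    quality <<- c(quality, s$rmsd)
  }
  if (length(ssesA) >= 2L && length(ssesB) >= 2L) {
    pa <- which(upper.tri(matrix(0, length(ssesA), length(ssesA))),
                arr.ind = TRUE)
    for (r in seq_len(nrow(pa))) {
      a1 <- ssesA[[pa[r, 1]]]; a2 <- ssesA[[pa[r, 2]]]
      angA <- sse_angle(a1, a2)
      dA <- euclid(sse_mid(a1), sse_mid(a2))
      for (j1 in seq_along(ssesB)) for (j2 in seq_along(ssesB)) {
        if (j1 == j2) next
        b1 <- ssesB[[j1]]; b2 <- ssesB[[j2]]
        if (b1$kind != a1$kind || b2$kind != a2$kind) next
        if (abs(sse_angle(b1, b2) - angA) > params$seed_angle_tol) next
        if (abs(euclid(sse_mid(b1), sse_mid(b2)) - dA) > params$seed_dist_tol) next
        P <- rbind(a1$endpoints, a2$endpoints)
        Q <- rbind(b1$endpoints, b2$endpoints)
        add_seed(kabsch(P, Q))
      }
    }
    # per-element correspondence seeds: slide each same-kind SSE segment of
    # B along its counterpart in A (robust when detected element boundaries
    # shrink differently in the two chains)
    for (a in ssesA) for (b in ssesB) {
      if (a$kind != b$kind) next
      ia <- a$start:a$end; ib <- b$start:b$end
      w <- min(length(ia), length(ib))
      if (w < 3L) next
      offs <- if (length(ia) >= length(ib)) {
        lapply(0:(length(ia) - w), function(k) list(ia[k + seq_len(w)],
                                                    ib[seq_len(w)]))
      } else {
        lapply(0:(length(ib) - w), function(k) list(ia[seq_len(w)],
                                                    ib[k + seq_len(w)]))
      }
      for (o in offs) {
        add_seed(kabsch(coordsA[o[[1]], , drop = FALSE],
                        coordsB[o[[2]], , drop = FALSE]))
      }
    }
  } else {
    w <- params$window
    n <- nrow(coordsA); m <- nrow(coordsB)
    if (n >= w && m >= w) {
      for (k in seq(-(m - w), n - w)) {
        i0 <- max(1L, k + 1L); j0 <- i0 - k
        add_seed(kabsch(coordsA[i0:(i0 + w - 1L), , drop = FALSE],
                        coordsB[j0:(j0 + w - 1L), , drop = FALSE]))
      }
    } else if (n >= 3L && m >= 3L) {
      w2 <- min(n, m)
      add_seed(kabsch(coordsA[1:w2, , drop = FALSE],
                      coordsB[1:w2, , drop = FALSE]))
    }
  }
  seeds[order(quality)]
}

no_similarity_result <- function(n1, n2) {
  structure(list(correspondence = matrix(integer(0), 0, 2),
                 n_aligned = 0L, n1 = n1, n2 = n2, rmsd = NA_real_,
                 qscore = -1, transform = NULL, status = "NO_SIMILARITY"),
            class = "AlignmentResult")
}

#' Refine a seeded alignment by iterative correspondence / superposition
#'
#' Iterates: (1) under the current transform, build the order-preserving
#' correspondence by dynamic programming maximizing the sum of
#' `1/(1+(d_ij/r0)^2)` with zero gap penalty; (2) drop pairs farther apart
#' than `d_cut`; (3) re-fit the rigid transform by Kabsch on the surviving
#' pairs. Stops when the correspondence set repeats or after `max_iter`
#' iterations, and returns the iterate with the highest Qscore.
#'
#' @param coordsA,coordsB n x 3 C-alpha matrices (A fixed, B moving).
#' @param seed a `Superposition` to start from.
#' @param params [align_params()].
#' @return an `AlignmentResult`: `correspondence` (k x 2, 1-based, strictly
#'   increasing in both columns), `n_aligned`, `n1`, `n2`, `rmsd`, `qscore`,
#'   `transform`, `status` ("OK" or "NO_SIMILARITY").
#' @export
refine_alignment <- function(coordsA, coordsB, seed, params = align_params()) {
  n1 <- nrow(coordsA); n2 <- nrow(coordsB)
  cur <- seed
  best <- NULL
  seen <- character(0)
  for (it in seq_len(params$max_iter)) {
    Bt <- apply_transform(coordsB, cur)
    corr <- dp_correspondence(coordsA, Bt, params$r0)
    if (nrow(corr) > 0L) {
      d <- row_dist(coordsA[corr[, 1], , drop = FALSE],
                    Bt[corr[, 2], , drop = FALSE])
      corr <- corr[d <= params$d_cut, , drop = FALSE]
    }
    if (nrow(corr) < 3L) break
    fit <- kabsch(coordsA[corr[, 1], , drop = FALSE],
                  coordsB[corr[, 2], , drop = FALSE])
    q <- qscore(nrow(corr), fit$rmsd, n1, n2, params$r0)
    if (is.null(best) || q > best$qscore) {
      best <- structure(list(correspondence = corr, n_aligned = nrow(corr),
                             n1 = n1, n2 = n2, rmsd = fit$rmsd, qscore = q,
                             transform = fit, status = "OK"),
                        class = "AlignmentResult")
    }
    h <- paste(corr[, 1], corr[, 2], collapse = ";")
    if (h %in% seen) break
    seen <- c(seen, h)
    cur <- fit
  }
  if (is.null(best)) no_similarity_result(n1, n2) else best
}

#' Align two chain structures and compute their Qscore
#'
#' Runs SSE assignment, seed enumeration and iterative refinement over the
#' best `max_seeds` seeds, returning the result with maximal Qscore. Results
#' are symmetric: the pair is always evaluated with the two chains in
#' lexicographic `(entry_id, chain_id)` order, and the transform inverted when
#' the caller passed them in reverse. When no seed yields at least
#' `min_aligned` aligned residues the result is `NO_SIMILARITY` with the
#' Qscore sentinel -1.
#'
#' @param chainA,chainB [chain_record()] objects (>= 3 resolved residues for
#'   a meaningful result).
#' @param params [align_params()].
#' @return an `AlignmentResult` (see [refine_alignment()]); its `transform`
#'   maps `chainB` coordinates onto `chainA`.
#' @export
align_structures <- function(chainA, chainB, params = align_params()) {
  swapped <- chain_key(chainB) < chain_key(chainA)
  a <- if (swapped) chainB else chainA
  b <- if (swapped) chainA else chainB
  res <- align_structures_ordered(a, b, params)
  if (swapped && res$status == "OK") {
    res$correspondence <- res$correspondence[, c(2L, 1L), drop = FALSE]
    tmp <- res$n1; res$n1 <- res$n2; res$n2 <- tmp
    res$transform <- invert_transform(res$transform)
  }
  res
}

align_structures_ordered <- function(chainA, chainB, params) {
  A <- chainA$ca_coords; B <- chainB$ca_coords
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 3L || n2 < 3L) return(no_similarity_result(n1, n2))
  seeds <- seed_transforms(assign_sse(chainA), assign_sse(chainB), A, B,
                           params)
  if (length(seeds) > params$max_seeds) seeds <- seeds[seq_len(params$max_seeds)]
  best <- no_similarity_result(n1, n2)
  for (s in seeds) {
    res <- refine_alignment(A, B, s, params)
    if (res$status == "OK" && res$n_aligned >= params$min_aligned &&
        res$qscore > best$qscore) {
      best <- res
    }
    if (best$qscore >= 1 - 1e-9) break
  }
  best
}

#' Centroid self-comparison check
#'
#' A chain passes when the SSE detector finds at least one element and
#' aligning the chain with itself yields an OK result with Qscore >= 0.99.
#' Chains failing this check are considered structurally incomprehensible to
#' the aligner and are not usable as cluster centroids.
#'
#' @param chain a [chain_record()].
#' @param params [align_params()].
#' @return logical pass/fail.
#' @export
self_check <- function(chain, params = align_params()) {
  if (length(assign_sse(chain)) < 1L) return(FALSE)
  res <- align_structures(chain, chain, params)
  res$status == "OK" && res$qscore >= 0.99
}

#' @export
print.AlignmentResult <- function(x, ...) {
  if (x$status == "OK") {
    cat(sprintf(
      "<AlignmentResult: Qscore %.3f, %d/%d x %d residues aligned, rmsd %.2f A>\n",
      x$qscore, x$n_aligned, x$n1, x$n2, x$rmsd))
  } else {
    cat("<AlignmentResult: NO_SIMILARITY (Qscore sentinel -1)>\n")
  }
  invisible(x)
}
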
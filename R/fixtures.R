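#' Ideal secondary-structure element trace
#'
#' Generates an idealized C-alpha trace for a single secondary-structure
#' element. Helices use a 1.5 A rise and 100 degree twist per residue on a
#' 2.3 A radius (the canonical alpha-helix C-alpha geometry, consecutive
#' C-alpha distance about 3.8 A). Strands use a 3.3 A rise along the axis with
#' an alternating +/- 25 degree zig-zag. Both satisfy the distance criteria of
#' [assign_sse()].
#'
#' @param kind "helix" or "strand".
#' @param n_res number of residues (>= 4).
#' @return numeric matrix (n_res x 3) of coordinates in Angstrom.
#' @export
make_ideal_sse <- function(kind = c("helix", "strand"), n_res) {
  kind <- match.arg(kind)
  if (n_res < 4L) stop("n_res must be >= 4")
  i <- seq_len(n_res) - 1L
  if (kind == "helix") {
    theta <- i * 100 * pi / 180
    cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  } else {
    y <- rep_len(c(0, 3.3 * tan(25 * pi / 180)), n_res)
    cbind(3.3 * i, y, 0)
  }
}

#' Synthetic-chain specification
#'
#' @param segments data.frame (or list coercible to one) with columns `kind`
#'   ("helix", "strand" or "coil") and `n` (residue counts, total >= 1).
#' @param sequence_mode "random" for a uniformly drawn sequence, or a fixed
#'   one-letter string of the total length.
#' @param seed integer seed; identical specs and seeds give bit-identical
#'   chains.
#' @return an object of class `ChainSpec`.
#' @export
chain_spec <- function(segments, sequence_mode = "random", seed = 1L) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("kind", "n") %in% names(segments)),
            all(segments$kind %in% c("helix", "strand", "coil")),
            sum(segments$n) >= 1L)
  structure(list(segments = segments, sequence_mode = sequence_mode,
                 seed = as.integer(seed)),
            class = "ChainSpec")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Uniform random unit vector.
rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Rotation matrix sending unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Generate a synthetic chain
#'
#' Concatenates ideal segment geometries ([make_ideal_sse()] for helix/strand,
#' a 3.8 A random-walk for coil), joining consecutive segments with a 3.8 A
#' step and a randomly drawn orientation for each new segment. The deposited
#' sequence equals the resolved sequence. Fully deterministic given the spec's
#' seed.
#'
#' @param spec a [chain_spec()].
#' @param entry_id,chain_id identifiers for the resulting record.
#' @param path optional file path: when given, the chain is also written as a
#'   PDB file.
#' @return a [chain_record()].
#' @export
synth_chain <- function(spec, entry_id = "s000", chain_id = "A", path = NULL) {
  stopifnot(inherits(spec, "ChainSpec"))
  coords <- with_seed(spec$seed, {
    pts <- NULL
    for (k in seq_len(nrow(spec$segments))) {
      kind <- spec$segments$kind[k]
      n <- spec$segments$n[k]
      seg <- if (kind == "coil") {
        # self-similar random walk, fixed 3.8 A steps
        steps <- t(replicate(max(n - 1L, 1L), 3.8 * rand_unit()))
        if (n == 1L) matrix(0, 1, 3) else rbind(0, apply(steps, 2, cumsum))
      } else {
        make_ideal_sse(kind, n)
      }
      # random orientation for the segment as a whole
      R <- rotation_between(c(0, 0, 1), rand_unit())
      seg <- seg %*% t(R)
      if (is.null(pts)) {
        pts <- seg
      } else {
        dir <- rand_unit()
        shift <- pts[nrow(pts), ] + 3.8 * dir - seg[1L, ]
        pts <- rbind(pts, sweep(seg, 2, shift, "+"))
      }
    }
    pts
  })
  n_tot <- nrow(coords)
  seq1 <- if (identical(spec$sequence_mode, "random")) {
    with_seed(spec$seed + 104729L,
              paste(sample(AA20, n_tot, replace = TRUE), collapse = ""))
  } else {
    stopifnot(nchar(spec$sequence_mode) == n_tot)
    spec$sequence_mode
  }
  rec <- chain_record(entry_id, chain_id, seq1, coords)
  if (!is.null(path)) write_chain_pdb(rec, path)
  rec
}

#' Perturb a chain's coordinates
#'
#' Adds i.i.d. Gaussian noise with standard deviation `sigma` (Angstrom) to
#' every coordinate of every C-alpha; the sequence is unchanged.
#'
#' @param chain a [chain_record()].
#' @param sigma noise standard deviation per coordinate (>= 0).
#' @param seed integer seed.
#' @return a perturbed [chain_record()].
#' @export
perturb_chain <- function(chain, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(chain)
  noise <- with_seed(seed, matrix(stats::rnorm(length(chain$ca_coords),
                                               sd = sigma),
                                  nrow(chain$ca_coords), 3))
  chain$ca_coords <- chain$ca_coords + noise
  chain
}

#' Mutate a sequence
#'
#' Substitutes each position independently with probability `rate` by a
#' uniformly drawn different residue. Length is preserved.
#'
#' @param seq one-letter amino-acid string.
#' @param rate substitution probability in \[0, 1\].
#' @param seed integer seed.
#' @return mutated sequence string.
#' @export
mutate_seq <- function(seq, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  chars <- strsplit(seq, "")[[1]]
  with_seed(seed, {
    hit <- stats::runif(length(chars)) < rate
    for (i in which(hit)) {
      chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
    }
  })
  paste(chars, collapse = "")
}
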
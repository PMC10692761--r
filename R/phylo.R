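#' Pairwise distance matrix over database taxa
#'
#' Entry (i, j) is `to_distance(qscore(i, j))` with zero diagonal. Pairs
#' missing from the persisted score table (e.g. involving a taxon outside the
#' original all-pairs set) are computed on demand.
#'
#' @param db a `StructureDB` from [build_db()].
#' @param taxa character vector of vetted-centroid `entry_chain` labels.
#' @return a `DistanceMatrix`: symmetric numeric matrix with `taxa` as
#'   dimnames, entries in \[0, 1\], diagonal 0.
#' @export
build_distance_matrix <- function(db, taxa) {
  missing <- setdiff(taxa, names(db$chains))
  if (length(missing) > 0) stop("unknown taxa: ", paste(missing, collapse = ", "))
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      row <- score_lookup(db, taxa[i], taxa[j])
      q <- if (!is.null(row)) {
        row$qscore
      } else {
        align_structures(db$chains[[taxa[i]]], db$chains[[taxa[j]]],
                         db$params %||% align_params())$qscore
      }
      D[i, j] <- D[j, i] <- to_distance(q)
    }
  }
  D
}

validate_dist <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distance matrix entries must be non-negative")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
  invisible(D)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic Saitou-Nei neighbour joining (via `ape::nj`), with negative branch
#' lengths clamped to zero and the two-taxon case resolved as a single edge
#' split equally. NJ exactly recovers any additive matrix. The returned tree
#' is unrooted; newick serialization uses an arbitrary trifurcating root,
#' which carries no evolutionary meaning.
#'
#' @param D symmetric distance matrix with taxon dimnames (>= 2 taxa).
#' @return an [ape::ape-package] `phylo` tree with non-negative branch
#'   lengths.
#' @export
neighbor_joining <- function(D) {
  validate_dist(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa")
  labs <- sanitize_label(rownames(D))
  if (n == 2L) {
    tree <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                          labs[1], D[1, 2] / 2,
                                          labs[2], D[1, 2] / 2))
    return(tree)
  }
  dimnames(D) <- list(labs, labs)
  tree <- ape::nj(D)
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Write a distance matrix in NEXUS format
#'
#' Emits a `#NEXUS` file with a TAXA block and a DISTANCES block
#' (`FORMAT TRIANGLE=BOTH DIAGONAL`, full matrix). Labels are sanitized to
#' `[A-Za-z0-9_]`.
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_nexus <- function(D, path) {
  validate_dist(D)
  labs <- sanitize_label(rownames(D))
  n <- nrow(D)
  rows <- vapply(seq_len(n), function(i) {
    paste(labs[i], paste(formatC(D[i, ], digits = 10, format = "g"),
                         collapse = " "))
  }, character(1))
  writeLines(c(
    "#NEXUS", "",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", n),
    paste0("  TAXLABELS ", paste(labs, collapse = " "), ";"),
    "END;", "",
    "BEGIN DISTANCES;",
    "  FORMAT TRIANGLE=BOTH DIAGONAL;",
    "  MATRIX",
    paste0("    ", rows),
    "  ;",
    "END;"
  ), path)
  invisible(path)
}

#' Read a NEXUS distance matrix written by [write_nexus()]
#'
#' @param path NEXUS file path.
#' @return labelled symmetric distance matrix.
#' @export
read_nexus_dist <- function(path) {
  lines <- readLines(path)
  if (!grepl("^#NEXUS", lines[1])) stop("not a NEXUS file: ", path)
  i0 <- grep("MATRIX", lines, fixed = TRUE)[1]
  i1 <- which(trimws(lines) == ";")
  i1 <- i1[i1 > i0][1]
  rows <- trimws(lines[(i0 + 1L):(i1 - 1L)])
  rows <- rows[nzchar(rows)]
  parts <- strsplit(rows, "\\s+")
  labs <- vapply(parts, `[`, "", 1L)
  D <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(length(labs))))
  dimnames(D) <- list(labs, labs)
  D
}

#' Write a tree in newick format
#'
#' Branch lengths are written with 6 decimal places; leaf labels are
#' sanitized consistently with [write_nexus()].
#'
#' @param tree an `ape` `phylo` object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  tree$tip.label <- sanitize_label(tree$tip.label)
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, 6)
  }
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Leaf-to-leaf path distances of a tree
#'
#' Sums branch lengths along the path between every pair of leaves; on a tree
#' built from an additive matrix these reproduce the matrix exactly.
#'
#' @param tree an `ape` `phylo` object.
#' @return symmetric matrix of patristic distances, leaf-labelled.
#' @export
tree_path_distances <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}
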
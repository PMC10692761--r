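#' Vet cluster centroids by structural self-comparison
#'
#' Each cluster's centroid is compared with itself ([self_check()]). When the
#' centroid fails, remaining members are tried in decreasing [chain_size()]
#' order (ties lexicographic) until one passes and replaces it; if none
#' passes — including failing singletons — the cluster is removed. Every
#' replacement and removal is logged.
#'
#' @param clusters list of `Cluster` objects from [greedy_cluster()].
#' @param chains the chain list the clusters were built from.
#' @param params [align_params()].
#' @return list with `clusters` (vetted, centroids possibly replaced),
#'   `removed` (character vector of removed cluster ids) and `log`
#'   (data.frame of events: `cluster_id`, `action`, `old_centroid`,
#'   `new_centroid`).
#' @export
vet_centroids <- function(clusters, chains, params = align_params()) {
  keys <- vapply(chains, chain_key, character(1))
  log <- data.frame(cluster_id = character(0), action = character(0),
                    old_centroid = character(0), new_centroid = character(0),
                    stringsAsFactors = FALSE)
  removed <- character(0)
  kept <- list()
  for (cl in clusters) {
    ord <- order(-cl$member_sizes, cl$member_ids)
    cand <- cl$member_ids[ord]
    cand <- c(cl$centroid_id, setdiff(cand, cl$centroid_id))
    new_centroid <- NA_character_
    for (id in cand) {
      if (self_check(chains[[match(id, keys)]], params)) {
        new_centroid <- id
        break
      }
    }
    if (is.na(new_centroid)) {
      removed <- c(removed, cl$cluster_id)
      log <- rbind(log, data.frame(cluster_id = cl$cluster_id,
                                   action = "removed",
                                   old_centroid = cl$centroid_id,
                                   new_centroid = NA_character_))
    } else {
      if (new_centroid != cl$centroid_id) {
        log <- rbind(log, data.frame(cluster_id = cl$cluster_id,
                                     action = "replaced",
                                     old_centroid = cl$centroid_id,
                                     new_centroid = new_centroid))
        cl$centroid_id <- new_centroid
      }
      kept[[length(kept) + 1L]] <- cl
    }
  }
  list(clusters = kept, removed = removed, log = log)
}

#' All-pairs centroid comparison table
#'
#' Computes the structural ([align_structures()]) and sequence
#' ([local_align_stats()]) comparison for every unordered pair of vetted
#' centroids, in canonical (lexicographic) pair order. NO_SIMILARITY outcomes
#' are encoded as -1 in the numeric columns.
#'
#' @param centroids list of [chain_record()] centroid chains (>= 2).
#' @param params [align_params()].
#' @return data.frame with one row per unordered pair: `id1`, `id2`
#'   (`id1 < id2`), `qscore`, `rmsd`, `n_aligned`, `n1`, `n2`,
#'   `identity_pct`, `similarity_pct`, `bit_score`, `evalue`.
#' @export
all_pairs_scores <- function(centroids, params = align_params()) {
  stopifnot(length(centroids) >= 2L)
  keys <- vapply(centroids, chain_key, character(1))
  centroids <- centroids[order(keys)]
  keys <- sort(keys)
  rows <- list()
  for (i in seq_len(length(centroids) - 1L)) {
    for (j in seq(i + 1L, length(centroids))) {
      st <- align_structures(centroids[[i]], centroids[[j]], params)
      sq <- local_align_stats(centroids[[i]]$deposited_seq,
                              centroids[[j]]$deposited_seq)
      rows[[length(rows) + 1L]] <- data.frame(
        id1 = keys[i], id2 = keys[j],
        qscore = st$qscore,
        rmsd = if (st$status == "OK") st$rmsd else -1,
        n_aligned = if (st$status == "OK") st$n_aligned else -1L,
        n1 = st$n1, n2 = st$n2,
        identity_pct = sq$identity_pct, similarity_pct = sq$similarity_pct,
        bit_score = sq$bit_score, evalue = sq$evalue,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert a Qscore to a phylogenetic distance
#'
#' `distance = 1 - Qscore` for Qscore in \[0, 1\]; the NO_SIMILARITY sentinel
#' -1 is treated as Qscore 0, i.e. distance 1.
#'
#' @param q numeric vector of Qscores in \[0, 1\] or the sentinel -1.
#' @return numeric vector of distances in \[0, 1\].
#' @export
to_distance <- function(q) {
  bad <- !((q >= 0 & q <= 1) | q == -1)
  if (any(bad)) stop("qscore out of domain [0,1] U {-1}: ", q[which(bad)[1]])
  1 - pmax(q, 0)
}

#' Build a structural-phylogenetics database
#'
#' Runs the full assembly: size filter on deposited length, greedy identity
#' clustering, centroid vetting by structural self-comparison, and all-pairs
#' centroid comparison. Per-stage counts are logged to `stderr`.
#'
#' @param chains list of [chain_record()] objects, or a directory of
#'   PDB-format files (read with [read_chains()]).
#' @param fasta optional FASTA file of deposited sequences (headers
#'   `ENTRYID_CHAIN`), used when `chains` is a directory.
#' @param min_length deposited-size inclusion threshold (default 50).
#' @param identity clustering identity threshold (default 0.90).
#' @param params [align_params()].
#' @param annotations optional data.frame keyed by `member_id` with
#'   annotation columns (e.g. SCOP/CATH labels), joined into hit lists;
#'   missing entries appear as "N/A".
#' @return a `StructureDB` list: `chains` (named by `entry_chain` key),
#'   `clusters`, `removed`, `vet_log`, `scores` (see [all_pairs_scores()]),
#'   `annotations`.
#' @export
build_db <- function(chains, fasta = NULL, min_length = 50L, identity = 0.90,
                     params = align_params(), annotations = NULL) {
  if (is.character(chains) && length(chains) == 1L) {
    files <- sort(list.files(chains, pattern = "\\.(pdb|ent)$",
                             full.names = TRUE, ignore.case = TRUE))
    if (length(files) == 0L) stop("no structure files in ", chains)
    chains <- unlist(lapply(files, function(f) read_chains(f, fasta)),
                     recursive = FALSE)
  }
  message(sprintf("chains read: %d", length(chains)))
  kept <- filter_chains(chains, min_length)
  message(sprintf("chains >= %d aa: %d", min_length, length(kept)))
  clusters <- greedy_cluster(kept, identity)
  message(sprintf("clusters at %.0f%% identity: %d", 100 * identity,
                  length(clusters)))
  vet <- vet_centroids(clusters, kept, params)
  message(sprintf("clusters after centroid vetting: %d (removed %d)",
                  length(vet$clusters), length(vet$removed)))
  keys <- vapply(kept, chain_key, character(1))
  names(kept) <- keys
  cent_ids <- vapply(vet$clusters, function(cl) cl$centroid_id, character(1))
  scores <- if (length(cent_ids) >= 2L) {
    all_pairs_scores(kept[cent_ids], params)
  } else {
    NULL
  }
  message(sprintf("pairwise centroid comparisons: %d",
                  if (is.null(scores)) 0L else nrow(scores)))
  structure(list(chains = kept, clusters = vet$clusters,
                 removed = vet$removed, vet_log = vet$log, scores = scores,
                 params = params, annotations = annotations),
            class = "StructureDB")
}

#' @export
print.StructureDB <- function(x, ...) {
  cat(sprintf("<StructureDB: %d chains, %d clusters, %d pair scores>\n",
              length(x$chains), length(x$clusters),
              if (is.null(x$scores)) 0L else nrow(x$scores)))
  invisible(x)
}

# Resolve a query entry_chain key to the Cluster it belongs to.
resolve_cluster <- function(db, query) {
  for (cl in db$clusters) {
    if (query %in% cl$member_ids) return(cl)
  }
  stop("query id not found in database: ", query)
}

score_lookup <- function(db, a, b) {
  s <- db$scores
  if (is.null(s)) return(NULL)
  lo <- pmin(a, b); hi <- pmax(a, b)
  i <- which(s$id1 == lo & s$id2 == hi)
  if (length(i) == 0L) NULL else s[i[1L], ]
}

#' Ranked structural neighbourhood of a query chain
#'
#' Resolves the query to its cluster centroid and returns every other vetted
#' centroid with Qscore at least `min_qscore` against it, ranked by Qscore
#' (descending, ties by id), truncated to the `top_n` best. Comparisons below
#' `min_qscore` (default 0.1, the structural "twilight zone" floor) and
#' NO_SIMILARITY sentinels are omitted. The query centroid itself is excluded
#' from the hits but is always a taxon in matrix/tree export.
#'
#' @param db a `StructureDB` from [build_db()].
#' @param query `entry_chain` key (e.g. `"1p3m_A"`); may be any cluster
#'   member.
#' @param min_qscore minimum reported Qscore (default 0.1).
#' @param top_n maximum number of hits (default 50).
#' @return a `HitList`: list with `query`, `centroid_id` (the query's
#'   centroid) and `hits`, a data.frame with `centroid_id`, `qscore`,
#'   `distance` (= 1 - Qscore), sequence statistics and an `annotation`
#'   column ("N/A" when absent).
#' @export
neighbours <- function(db, query, min_qscore = 0.1, top_n = 50L) {
  cl <- resolve_cluster(db, query)
  cid <- cl$centroid_id
  s <- db$scores
  hits <- if (is.null(s)) {
    s
  } else {
    sel <- (s$id1 == cid | s$id2 == cid) & s$qscore >= min_qscore
    h <- s[sel, , drop = FALSE]
    h$centroid_id <- ifelse(h$id1 == cid, h$id2, h$id1)
    h
  }
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- data.frame(centroid_id = character(0), qscore = numeric(0))
  }
  hits <- hits[order(-hits$qscore, hits$centroid_id), , drop = FALSE]
  if (nrow(hits) > top_n) hits <- hits[seq_len(top_n), , drop = FALSE]
  ann <- rep("N/A", nrow(hits))
  if (!is.null(db$annotations) && nrow(hits) > 0L) {
    m <- match(hits$centroid_id, db$annotations$member_id)
    found <- !is.na(m)
    acol <- setdiff(names(db$annotations), "member_id")
    if (length(acol) > 0) {
      ann[found] <- apply(db$annotations[m[found], acol, drop = FALSE], 1,
                          paste, collapse = "; ")
    }
  }
  out <- data.frame(
    centroid_id = hits$centroid_id,
    qscore = hits$qscore,
    distance = to_distance(hits$qscore),
    rmsd = hits$rmsd %||% numeric(0),
    n_aligned = hits$n_aligned %||% integer(0),
    identity_pct = hits$identity_pct %||% numeric(0),
    similarity_pct = hits$similarity_pct %||% numeric(0),
    bit_score = hits$bit_score %||% numeric(0),
    evalue = hits$evalue %||% numeric(0),
    annotation = ann,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(query = query, centroid_id = cid, hits = out),
            class = "HitList")
}

#' @export
print.HitList <- function(x, ...) {
  cat(sprintf("<HitList for %s (centroid %s): %d hit(s)>\n", x$query,
              x$centroid_id, nrow(x$hits)))
  if (nrow(x$hits) > 0) print(utils::head(x$hits, 10))
  invisible(x)
}

#' Cluster membership view for a query chain
#'
#' Lists the members of the cluster to which the query belongs, with each
#' member's size, confidence flag, and its structural alignment against the
#' cluster centroid (Qscore 1 for the centroid itself).
#'
#' @param db a `StructureDB` from [build_db()].
#' @param query `entry_chain` key.
#' @param params [align_params()].
#' @return data.frame with `member_id`, `chain_size`, `confidence`, `qscore`
#'   (vs the centroid; -1 when no similarity is found), plus an invisible
#'   `transforms` attribute holding the per-member superpositions for export.
#' @export
cluster_view <- function(db, query, params = db$params %||% align_params()) {
  cl <- resolve_cluster(db, query)
  cent <- db$chains[[cl$centroid_id]]
  q <- numeric(length(cl$member_ids))
  transforms <- vector("list", length(cl$member_ids))
  for (k in seq_along(cl$member_ids)) {
    res <- align_structures(cent, db$chains[[cl$member_ids[k]]], params)
    q[k] <- res$qscore
    transforms[k] <- list(res$transform)
  }
  out <- data.frame(member_id = cl$member_ids,
                    chain_size = cl$member_sizes,
                    confidence = unname(cl$confidence),
                    qscore = q, stringsAsFactors = FALSE)
  attr(out, "transforms") <- stats::setNames(transforms, cl$member_ids)
  out
}

#' Persist a database as plain-text tables
#'
#' Writes `chains.tsv`, `clusters.tsv`, `scores.tsv`, `vetting.tsv` and
#' per-chain C-alpha PDB files under `dir/chains/`. The representation is
#' deterministic: rebuilding from the same input yields byte-identical
#' tables.
#'
#' @param db a `StructureDB`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_db <- function(db, dir) {
  dir.create(file.path(dir, "chains"), recursive = TRUE, showWarnings = FALSE)
  keys <- names(db$chains)
  chain_tab <- data.frame(
    key = keys,
    entry_id = vapply(db$chains, function(c) c$entry_id, character(1)),
    chain_id = vapply(db$chains, function(c) c$chain_id, character(1)),
    size = vapply(db$chains, chain_size, integer(1)),
    n_resolved = vapply(db$chains, function(c) nchar(c$resolved_seq),
                        integer(1)),
    deposited_seq = vapply(db$chains, function(c) c$deposited_seq,
                           character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  wr <- function(x, f) {
    num <- vapply(x, is.double, logical(1))
    x[num] <- lapply(x[num], function(v) formatC(v, digits = 10,
                                                 format = "g"))
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(chain_tab, "chains.tsv")
  wr(cluster_table(db$clusters), "clusters.tsv")
  if (!is.null(db$scores)) wr(db$scores, "scores.tsv")
  if (nrow(db$vet_log) > 0) wr(db$vet_log, "vetting.tsv")
  for (k in keys) {
    write_chain_pdb(db$chains[[k]], file.path(dir, "chains",
                                              paste0(k, ".pdb")))
  }
  invisible(dir)
}

#' Load a database persisted by [write_db()]
#'
#' @param dir database directory.
#' @param params [align_params()] to use for on-demand comparisons.
#' @return a `StructureDB`.
#' @export
load_db <- function(dir, params = align_params()) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    utils::read.delim(p, colClasses = "character")
  }
  chain_tab <- rd("chains.tsv")
  if (is.null(chain_tab)) stop("not a database directory: ", dir)
  chains <- lapply(seq_len(nrow(chain_tab)), function(i) {
    key <- chain_tab$key[i]
    rec <- read_chains(file.path(dir, "chains", paste0(key, ".pdb")))[[1]]
    rec$entry_id <- chain_tab$entry_id[i]
    rec$chain_id <- chain_tab$chain_id[i]
    rec$deposited_seq <- chain_tab$deposited_seq[i]
    rec
  })
  names(chains) <- chain_tab$key
  clu_tab <- rd("clusters.tsv")
  clusters <- lapply(split(seq_len(nrow(clu_tab)), clu_tab$cluster_id),
                     function(idx) {
    structure(list(
      cluster_id = clu_tab$cluster_id[idx[1L]],
      centroid_id = clu_tab$centroid_id[idx[1L]],
      member_ids = clu_tab$member_id[idx],
      member_sizes = as.integer(clu_tab$member_size[idx]),
      confidence = stats::setNames(clu_tab$confidence[idx],
                                   clu_tab$member_id[idx])
    ), class = "Cluster")
  })
  names(clusters) <- NULL
  scores <- rd("scores.tsv")
  if (!is.null(scores)) {
    num <- setdiff(names(scores), c("id1", "id2"))
    scores[num] <- lapply(scores[num], as.numeric)
    scores$n_aligned <- as.integer(scores$n_aligned)
  }
  vet_log <- rd("vetting.tsv")
  if (is.null(vet_log)) {
    vet_log <- data.frame(cluster_id = character(0), action = character(0),
                          old_centroid = character(0),
                          new_centroid = character(0))
  }
  structure(list(chains = chains, clusters = clusters,
                 removed = unique(vet_log$cluster_id[
                   vet_log$action == "removed"]),
                 vet_log = vet_log, scores = scores, params = params,
                 annotations = NULL),
            class = "StructureDB")
}

#' Export a query's neighbourhood as table, NEXUS matrix and newick tree
#'
#' Writes `<prefix>_hits.csv`, `<prefix>_top<k>.nex` (the distance matrix
#' over the query centroid plus its top hits) and `<prefix>_top<k>.nwk` (the
#' neighbour-joining tree of that matrix).
#'
#' @param db a `StructureDB`.
#' @param query `entry_chain` key.
#' @param out_prefix output path prefix.
#' @param min_qscore,top_n see [neighbours()].
#' @param include_self logical: count the query centroid within `top_n`
#'   (default `FALSE`: it is added as an extra taxon).
#' @return invisible list of written paths.
#' @export
export_neighbourhood <- function(db, query, out_prefix, min_qscore = 0.1,
                                 top_n = 50L, include_self = FALSE) {
  hl <- neighbours(db, query,
                   min_qscore = min_qscore,
                   top_n = if (include_self) top_n - 1L else top_n)
  taxa <- unique(c(hl$centroid_id, hl$hits$centroid_id))
  paths <- c(hits = paste0(out_prefix, "_hits.csv"),
             nexus = sprintf("%s_top%d.nex", out_prefix, top_n),
             newick = sprintf("%s_top%d.nwk", out_prefix, top_n))
  utils::write.csv(hl$hits, paths[["hits"]], row.names = FALSE)
  D <- build_distance_matrix(db, taxa)
  write_nexus(D, paths[["nexus"]])
  if (length(taxa) >= 2L) {
    write_newick(neighbor_joining(D), paths[["newick"]])
  }
  invisible(as.list(paths))
}
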
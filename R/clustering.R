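#' Greedy sequence-identity clustering
#'
#' Processes chains in decreasing [chain_size()] order (ties broken
#' lexicographically by `entry_chain` key). Each chain joins the first
#' existing cluster whose centroid it matches at [semi_global_identity()]
#' `>= threshold`, otherwise it founds a new cluster with itself as centroid.
#' This mirrors the greedy length-sorted first-hit semantics of usearch-style
#' clustering and is fully deterministic. Cluster ids are zero-padded
#' 5-digit ordinals in founding order.
#'
#' @param chains nonempty list of [chain_record()] objects.
#' @param threshold identity threshold in (0, 1\] (default 0.90).
#' @param assign "first" (default: first centroid meeting the threshold) or
#'   "best" (highest-identity centroid meeting it).
#' @return list of `Cluster` objects: `cluster_id`, `centroid_id`,
#'   `member_ids`, `member_sizes`, `confidence` (per-member "high"/"low", see
#'   [flag_confidence()]).
#' @export
greedy_cluster <- function(chains, threshold = 0.90,
                           assign = c("first", "best")) {
  assign <- match.arg(assign)
  stopifnot(length(chains) > 0, threshold > 0, threshold <= 1)
  keys <- unname(vapply(chains, chain_key, character(1)))
  sizes <- unname(vapply(chains, chain_size, integer(1)))
  ord <- order(-sizes, keys)
  cent_seq <- character(0)   # centroid deposited sequences, founding order
  members <- list()
  for (i in ord) {
    seq_i <- chains[[i]]$deposited_seq
    hit <- 0L
    if (length(cent_seq) > 0) {
      ids <- vapply(cent_seq, function(cs) semi_global_identity(cs, seq_i),
                    numeric(1), USE.NAMES = FALSE)
      if (assign == "first") {
        h <- which(ids >= threshold)
        if (length(h) > 0) hit <- h[1L]
      } else {
        h <- which.max(ids)
        if (length(h) > 0 && ids[h] >= threshold) hit <- h
      }
    }
    if (hit == 0L) {
      cent_seq <- c(cent_seq, seq_i)
      members[[length(members) + 1L]] <- i
    } else {
      members[[hit]] <- c(members[[hit]], i)
    }
  }
  lapply(seq_along(members), function(k) {
    idx <- members[[k]]
    cl <- structure(list(
      cluster_id = sprintf("%05d", k),
      centroid_id = keys[idx[1L]],
      member_ids = keys[idx],
      member_sizes = sizes[idx],
      confidence = NULL
    ), class = "Cluster")
    cl$confidence <- flag_confidence(cl, sizes[idx])
    cl
  })
}

#' Flag cluster members by size confidence
#'
#' Because clustering is identity-based with free terminal gaps, members of a
#' cluster are expected to have (nearly) the same size; strong deviation
#' signals a clustering artefact. A member is flagged `"low"` when its size
#' deviates from the cluster median by more than one population standard
#' deviation of the member sizes; with zero SD any nonzero deviation flags
#' low. Singletons are always `"high"`.
#'
#' @param cluster a `Cluster` (used for member names; may be `NULL`).
#' @param sizes numeric vector of member sizes, aligned with
#'   `cluster$member_ids`.
#' @return character vector of `"high"`/`"low"` flags, named by member id
#'   when a cluster is supplied.
#' @export
flag_confidence <- function(cluster, sizes) {
  sizes <- as.numeric(sizes)
  med <- stats::median(sizes)
  sd_pop <- sqrt(mean((sizes - mean(sizes))^2))
  flags <- ifelse(abs(sizes - med) > sd_pop, "low", "high")
  if (!is.null(cluster)) names(flags) <- cluster$member_ids
  flags
}

#' @export
print.Cluster <- function(x, ...) {
  cat(sprintf("<Cluster %s: centroid %s, %d member(s)>\n",
              x$cluster_id, x$centroid_id, length(x$member_ids)))
  invisible(x)
}

#' Cluster list as a per-member table
#'
#' @param clusters list of `Cluster` objects from [greedy_cluster()].
#' @return data.frame with one row per member: `cluster_id`, `centroid_id`,
#'   `member_id`, `member_size`, `confidence`.
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, centroid_id = cl$centroid_id,
               member_id = unname(cl$member_ids),
               member_size = unname(cl$member_sizes),
               confidence = unname(cl$confidence),
               stringsAsFactors = FALSE)
  }))
}
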
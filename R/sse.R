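#' Assign secondary-structure elements from C-alpha geometry
#'
#' Marks residue `i` as a helix candidate when the C-alpha distances
#' `d(i, i+3)` lie in \[4.5, 6.0\] A and `d(i, i+4)` in \[5.7, 7.0\] A, and as
#' a strand candidate when `d(i, i+2)` lies in \[6.2, 7.2\] A and `d(i, i+3)`
#' in \[9.3, 10.8\] A (C-alpha-only distance criteria in the style of P-SEA).
#' Runs of at least 5 (helix) / 3 (strand) consecutive candidates become
#' elements; the element extends to the last residue probed by its final
#' candidate. Each element's axis is fit by least squares (principal axis of
#' the segment's C-alpha trace), oriented from the first residue towards the
#' last.
#'
#' @param chain a [chain_record()] (or bare n x 3 coordinate matrix).
#' @return list of `SSE` objects: `kind`, `start`, `end` (1-based inclusive
#'   resolved-residue indices), `axis_origin`, `axis_direction` (unit vector)
#'   and `endpoints` (2 x 3: projections of the terminal residues onto the
#'   axis). Elements are non-overlapping and sorted by `start`. Fewer than 5
#'   resolved residues yield an empty list.
#' @export
assign_sse <- function(chain) {
  X <- if (inherits(chain, "ChainRecord")) chain$ca_coords else as.matrix(chain)
  n <- nrow(X)
  if (n < 5L) return(list())
  d <- function(i, k) row_dist(X[i, , drop = FALSE], X[i + k, , drop = FALSE])
  i3 <- seq_len(n - 3L); i4 <- seq_len(n - 4L); i2 <- seq_len(n - 2L)
  d2 <- rep(NA_real_, n); d3 <- rep(NA_real_, n); d4 <- rep(NA_real_, n)
  d2[i2] <- d(i2, 2L); d3[i3] <- d(i3, 3L); d4[i4] <- d(i4, 4L)
  helix_cand <- !is.na(d3) & !is.na(d4) &
    d3 >= 4.5 & d3 <= 6.0 & d4 >= 5.7 & d4 <= 7.0
  strand_cand <- !is.na(d2) & !is.na(d3) &
    d2 >= 6.2 & d2 <= 7.2 & d3 >= 9.3 & d3 <= 10.8

  runs <- function(cand, min_run, reach, kind) {
    r <- rle(cand)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (!any(keep)) return(NULL)
    data.frame(kind = kind, start = starts[keep],
               end = pmin(ends[keep] + reach, n))
  }
  segs <- rbind(runs(helix_cand, 5L, 4L, "helix"),
                runs(strand_cand, 3L, 3L, "strand"))
  if (is.null(segs) || nrow(segs) == 0L) return(list())
  segs <- segs[order(segs$start, segs$end), , drop = FALSE]
  # trim any overlap introduced by extending runs to their last probed residue
  if (nrow(segs) > 1L) {
    for (k in 2:nrow(segs)) {
      if (segs$start[k] <= segs$end[k - 1L]) {
        segs$start[k] <- segs$end[k - 1L] + 1L
      }
    }
    min_len <- ifelse(segs$kind == "helix", 5L, 3L)
    segs <- segs[segs$end - segs$start + 1L >= min_len, , drop = FALSE]
  }
  lapply(seq_len(nrow(segs)), function(k) {
    s <- segs$start[k]; e <- segs$end[k]
    seg <- X[s:e, , drop = FALSE]
    ctr <- colMeans(seg)
    sv <- svd(sweep(seg, 2, ctr))
    ax <- sv$v[, 1L]
    span <- seg[nrow(seg), ] - seg[1L, ]
    if (sum(ax * span) < 0) ax <- -ax
    proj <- function(p) ctr + sum((p - ctr) * ax) * ax
    structure(list(kind = segs$kind[k], start = s, end = e,
                   axis_origin = ctr, axis_direction = ax,
                   endpoints = rbind(proj(seg[1L, ]), proj(seg[nrow(seg), ]))),
              class = "SSE")
  })
}
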
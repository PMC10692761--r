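#' Construct a chain record
#'
#' A `ChainRecord` holds one protein chain: its identifiers, the deposited
#' (full) one-letter sequence, the resolved one-letter sequence (residues with
#' coordinates), the ordered C-alpha coordinates in Angstrom and the author
#' residue numbering (with insertion codes) for output.
#'
#' The deposited sequence is the chain's "protein size" authority: size-based
#' filtering uses the number of amino acids in the deposited record, not the
#' number of residues with structural data. When no deposited record is
#' available the resolved sequence stands in for it.
#'
#' @param entry_id structure accession (lower-cased on construction).
#' @param chain_id author chain identifier.
#' @param resolved_seq one-letter string of residues with coordinates.
#' @param ca_coords numeric matrix (n x 3) of C-alpha positions in Angstrom,
#'   one row per resolved residue.
#' @param deposited_seq one-letter string of the deposited sequence record, or
#'   `NULL` to fall back to `resolved_seq`.
#' @param author_numbers character vector of author residue numbers (may carry
#'   insertion codes); defaults to `1..n`.
#' @return an object of class `ChainRecord`.
#' @export
chain_record <- function(entry_id, chain_id, resolved_seq, ca_coords,
                         deposited_seq = NULL, author_numbers = NULL) {
  ca_coords <- as.matrix(ca_coords)
  n <- nrow(ca_coords)
  if (is.null(author_numbers)) author_numbers <- as.character(seq_len(n))
  rec <- structure(
    list(
      entry_id = tolower(entry_id),
      chain_id = as.character(chain_id),
      deposited_seq = if (is.null(deposited_seq)) resolved_seq else deposited_seq,
      resolved_seq = resolved_seq,
      ca_coords = ca_coords,
      author_numbers = as.character(author_numbers)
    ),
    class = "ChainRecord"
  )
  validate_chain(rec)
  rec
}

validate_chain <- function(rec) {
  n <- nrow(rec$ca_coords)
  if (ncol(rec$ca_coords) != 3L) {
    stop("ca_coords must have 3 columns")
  }
  if (nchar(rec$resolved_seq) != n || length(rec$author_numbers) != n) {
    stop("resolved_seq, ca_coords and author_numbers must have equal length")
  }
  if (n >= 2L) {
    d <- row_dist(rec$ca_coords[-n, , drop = FALSE],
                  rec$ca_coords[-1L, , drop = FALSE])
    if (any(d < 1e-6)) stop("duplicated consecutive C-alpha coordinates")
  }
  invisible(rec)
}

#' @export
print.ChainRecord <- function(x, ...) {
  cat(sprintf("<ChainRecord %s_%s: %d resolved / %d deposited residues>\n",
              x$entry_id, x$chain_id, nchar(x$resolved_seq),
              nchar(x$deposited_seq)))
  invisible(x)
}

#' Chain size (deposited amino-acid count)
#'
#' The size of a chain is the number of amino acids in its deposited sequence
#' record — the complete protein sequence — not the number of residues for
#' which there are structural data.
#'
#' @param chain a [chain_record()].
#' @return integer amino-acid count.
#' @export
chain_size <- function(chain) nchar(chain$deposited_seq)

#' Filter chains by deposited size
#'
#' Keeps exactly the chains whose deposited sequence has at least `min_len`
#' amino acids (default 50), preserving input order. Short peptides carry too
#' little regular secondary structure for meaningful structural comparison.
#'
#' @param chains list of [chain_record()] objects.
#' @param min_len minimum deposited length (>= 1).
#' @return the retained sublist.
#' @export
filter_chains <- function(chains, min_len = 50L) {
  stopifnot(min_len >= 1L)
  chains[vapply(chains, chain_size, integer(1)) >= min_len]
}
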
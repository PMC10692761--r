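#' @useDynLib strucphylo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Sanitize a taxon label
#'
#' Replaces every character outside `[A-Za-z0-9_]` with an underscore so that
#' the same label is legal in NEXUS and newick output.
#'
#' @param x character vector of labels.
#' @return character vector of sanitized labels.
#' @export
sanitize_label <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

# Canonical entry_chain key, e.g. "1p3m_A".
chain_key <- function(chain) paste0(chain$entry_id, "_", chain$chain_id)

`%||%` <- function(a, b) if (is.null(a)) b else a

euclid <- function(p, q) sqrt(sum((p - q)^2))

# Pairwise row distances between the i-th rows of two n x 3 matrices.
row_dist <- function(A, B) sqrt(rowSums((A - B)^2))
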
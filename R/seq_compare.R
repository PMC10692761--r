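# +1/-1 substitution matrix over the Biostrings amino-acid alphabet, used for
# the clustering identity alignment.
identity_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters <- Biostrings::AA_ALPHABET
      mm <- matrix(-1, length(letters), length(letters),
                   dimnames = list(letters, letters))
      diag(mm) <- 1
      m <<- mm
    }
    m
  }
})

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Semi-global sequence identity
#'
#' Aligns the shorter sequence globally against the longer with free
#' (unpenalized) terminal gaps on the longer sequence only (match +1,
#' mismatch -1, gap open -2, gap extend -1) and returns the fraction of
#' identical columns over the alignment columns, terminal-gap columns
#' excluded. This is the identity used for greedy clustering: terminal
#' overhangs (e.g. expression tags, truncated constructs) do not count
#' against identity, but the shorter sequence must align over its whole
#' length, so unrelated sequences cannot score highly on a short chance
#' overlap.
#'
#' @param a,b nonempty one-letter amino-acid strings.
#' @return identity fraction in \[0, 1\].
#' @export
semi_global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  # deterministic symmetric orientation: shorter (ties: lexicographically
  # smaller) sequence is the globally aligned pattern
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global-local", substitutionMatrix = identity_submat(),
    gapOpening = 2, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  if (length(p) == 0L) return(0)
  sum(p == s & p != "-") / length(p)
}

#' Local alignment statistics (BLOSUM62 Smith-Waterman)
#'
#' Smith-Waterman local alignment with BLOSUM62, gap open 11 / extend 1 (the
#' standard protein-BLAST scoring), with Karlin-Altschul statistics from the
#' published gapped BLOSUM62/11-1 constants lambda = 0.267, K = 0.041:
#' `bit = (lambda * raw - ln K) / ln 2` and `evalue = m * n * 2^(-bit)` with
#' `m`, `n` the sequence lengths (a configurable search-space stands in for a
#' database-scale search). Identity and similarity percentages are over the
#' reported local alignment length; similarity counts positive-scoring
#' (BLOSUM62 > 0) columns. When no positive-scoring local alignment exists
#' the result is NO_SIMILARITY, with every score field carrying the
#' sentinel -1.
#'
#' @param a,b nonempty one-letter amino-acid strings.
#' @param search_space optional effective search-space size; default
#'   `nchar(a) * nchar(b)`.
#' @return a `SeqStats` list: `identity_pct`, `similarity_pct`, `raw_score`,
#'   `bit_score`, `evalue`, `aln_len`, `status`.
#' @export
local_align_stats <- function(a, b, search_space = NULL) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  B62 <- blosum62()
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = B62,
    gapOpening = 11, gapExtension = 1
  )
  raw <- Biostrings::score(aln)
  if (raw <= 0) {
    return(structure(list(identity_pct = -1, similarity_pct = -1,
                          raw_score = -1, bit_score = -1, evalue = -1,
                          aln_len = -1, status = "NO_SIMILARITY"),
                     class = "SeqStats"))
  }
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  len <- length(p)
  resid <- p != "-" & s != "-"
  ident <- sum(p == s & resid)
  idx <- cbind(match(p, rownames(B62)), match(s, colnames(B62)))
  colscore <- rep(-Inf, len)
  ok <- resid & !is.na(idx[, 1]) & !is.na(idx[, 2])
  colscore[ok] <- B62[idx[ok, , drop = FALSE]]
  pos <- sum(colscore > 0)
  lambda <- 0.267; K <- 0.041
  bit <- (lambda * raw - log(K)) / log(2)
  mn <- search_space %||% (nchar(a) * nchar(b))
  structure(list(identity_pct = 100 * ident / len,
                 similarity_pct = 100 * pos / len,
                 raw_score = raw, bit_score = bit,
                 evalue = mn * 2^(-bit), aln_len = len, status = "OK"),
            class = "SeqStats")
}

#' @export
print.SeqStats <- function(x, ...) {
  if (x$status == "OK") {
    cat(sprintf(
      "<SeqStats: %.1f%% identity, %.1f%% similarity, bit %.1f, E %.3g over %d columns>\n",
      x$identity_pct, x$similarity_pct, x$bit_score, x$evalue, x$aln_len))
  } else {
    cat("<SeqStats: NO_SIMILARITY (sentinel -1)>\n")
  }
  invisible(x)
}
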
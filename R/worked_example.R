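#' Histone-fold worked example
#'
#' Reproduces the histone-fold comparison walkthrough: given locally supplied
#' structures of the H3 histone query 4uuz (chain A), its cluster centroid
#' 1p3m (chain A), and the H2A-type centroid 6m4g (chain C), computes (i) the
#' parsed deposited chain sizes, (ii) the 4uuz_A vs 1p3m_A sequence identity
#' and structural alignment, and (iii) the 6m4g_C vs 1p3m_A Qscore, aligned
#' residue count and local-alignment similarity. Because the structural
#' engine here is a re-implementation of the Qscore family of aligners rather
#' than GESAMT itself, alignment-dependent numbers carry engine tolerance;
#' the returned object therefore includes the raw values for a side-by-side
#' tolerance report.
#'
#' @param dir directory containing `4uuz.pdb`, `1p3m.pdb`, `6m4g.pdb` and a
#'   FASTA file `sequences.fasta` of deposited sequences with headers
#'   `ENTRYID_CHAIN` (obtainable from RCSB PDB).
#' @param params [align_params()].
#' @return list with `sizes` (named deposited sizes), `identity_4uuz_1p3m`
#'   (fraction), `aln_4uuz_1p3m` and `aln_6m4g_1p3m` (`AlignmentResult`s) and
#'   `seqstats_6m4g_1p3m` (`SeqStats`).
#' @export
worked_example <- function(dir, params = align_params()) {
  fasta <- file.path(dir, "sequences.fasta")
  if (!file.exists(fasta)) fasta <- NULL
  pick <- function(entry, ch) {
    f <- file.path(dir, paste0(entry, ".pdb"))
    if (!file.exists(f)) {
      stop("worked-example structure not found: ", f,
           " (download the entry from RCSB PDB)")
    }
    recs <- read_chains(f, fasta)
    ids <- vapply(recs, function(r) r$chain_id, character(1))
    if (!ch %in% ids) stop("chain ", ch, " not found in ", f)
    recs[[match(ch, ids)]]
  }
  h3_query <- pick("4uuz", "A")
  h3_centroid <- pick("1p3m", "A")
  h2a <- pick("6m4g", "C")
  list(
    sizes = c(`4uuz_A` = chain_size(h3_query),
              `1p3m_A` = chain_size(h3_centroid),
              `6m4g_C` = chain_size(h2a)),
    identity_4uuz_1p3m = semi_global_identity(h3_query$deposited_seq,
                                              h3_centroid$deposited_seq),
    aln_4uuz_1p3m = align_structures(h3_query, h3_centroid, params),
    aln_6m4g_1p3m = align_structures(h2a, h3_centroid, params),
    seqstats_6m4g_1p3m = local_align_stats(h2a$deposited_seq,
                                           h3_centroid$deposited_seq)
  )
}
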
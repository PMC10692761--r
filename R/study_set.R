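#' Synthetic study set of chains for an end-to-end database build
#'
#' Generates a deterministic set of 28 chains emulating the redundancy
#' structure of a real archive slice:
#' \itemize{
#'   \item family `h` — 10 copies of a 100-residue three-helix fold
#'     (entries `h001`..`h010`), sequences mutated at 2% per position and
#'     coordinates perturbed at 0.3 A per coordinate: one 90%-identity
#'     cluster.
#'   \item family `g` — 8 copies (`g001`..`g008`) of the same fold with a
#'     sequence mutated at 60%: a second cluster, sequence-divergent but a
#'     close structural relative of `h` (the planted neighbour).
#'   \item family `e` — 8 copies (`e001`..`e008`) of an unrelated 60-residue
#'     four-strand fold: a third cluster, structurally unrelated to `h`/`g`.
#'   \item `c001` — a 60-residue random-coil singleton with no secondary
#'     structure: its cluster is removed at centroid vetting.
#'   \item `t001` — a 30-residue helix: removed by the 50-residue size
#'     filter.
#' }
#'
#' @param seed integer master seed; all member seeds derive from it.
#' @return named list of [chain_record()] objects with attribute `families`
#'   (named list of entry_chain keys per planted group).
#' @export
synth_study_set <- function(seed = 1L) {
  base_seed <- as.integer(seed) * 1000L
  fold_h <- chain_spec(data.frame(kind = c("helix", "coil", "helix", "coil",
                                           "helix"),
                                  n = c(30, 6, 30, 6, 28)),
                       seed = base_seed + 11L)
  fold_e <- chain_spec(data.frame(kind = c("strand", "coil", "strand", "coil",
                                           "strand", "coil", "strand"),
                                  n = c(12, 4, 12, 4, 12, 4, 12)),
                       seed = base_seed + 21L)
  base_h <- synth_chain(fold_h, "h000", "A")
  base_g <- perturb_chain(base_h, 0.5, seed = base_seed + 31L)
  seq_g <- mutate_seq(base_h$deposited_seq, 0.6, seed = base_seed + 32L)
  base_g$deposited_seq <- seq_g
  base_g$resolved_seq <- seq_g
  base_e <- synth_chain(fold_e, "e000", "A")

  family <- function(base, n, prefix, seed_off) {
    lapply(seq_len(n), function(i) {
      ch <- perturb_chain(base, 0.3, seed = base_seed + seed_off + i)
      ch$entry_id <- sprintf("%s%03d", prefix, i)
      s <- mutate_seq(base$deposited_seq, 0.02,
                      seed = base_seed + seed_off + 100L + i)
      ch$deposited_seq <- s
      ch$resolved_seq <- s
      ch
    })
  }
  chains <- c(
    family(base_h, 10L, "h", 200L),
    family(base_g, 8L, "g", 400L),
    family(base_e, 8L, "e", 600L),
    list(synth_chain(chain_spec(data.frame(kind = "coil", n = 60), seed = 7L),
                     "c001", "A"),
         synth_chain(chain_spec(data.frame(kind = "helix", n = 30),
                                seed = base_seed + 41L), "t001", "A"))
  )
  names(chains) <- vapply(chains, chain_key, character(1))
  attr(chains, "families") <- list(
    h = sprintf("h%03d_A", 1:10),
    g = sprintf("g%03d_A", 1:8),
    e = sprintf("e%03d_A", 1:8),
    coil = "c001_A",
    short = "t001_A"
  )
  chains
}
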
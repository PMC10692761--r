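# Parent one-letter codes for common nonstandard residues; anything else
# (that is not a standard amino acid) becomes 'X'.
NONSTD_PARENT <- c(
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S", TPO = "T",
  PTR = "Y", CSO = "C", CSD = "C", CME = "C", CMT = "C", KCX = "K",
  MLY = "K", M3L = "K", LLP = "K", PCA = "Q", FME = "M", AIB = "A",
  ABA = "A", DAL = "A", NLE = "L", ORN = "A", SAR = "G", MVA = "V"
)

STD3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

NUCLEIC_RESID <- c("A", "C", "G", "U", "T", "I",
                   "DA", "DC", "DG", "DT", "DU", "DI")

res3to1 <- function(res3) {
  out <- STD3TO1[res3]
  miss <- is.na(out)
  out[miss] <- NONSTD_PARENT[res3[miss]]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Read and split a structure file into per-chain records
#'
#' Reads a PDB-format file and returns one [chain_record()] per distinct
#' polymer chain, in file order. Only the first model and the first alternate
#' location per atom are used; nonstandard residues with a known parent are
#' mapped to the parent one-letter code, unknowns become `X`. Nucleic-acid
#' chains and chains without any C-alpha atom are skipped with a warning.
#'
#' The deposited sequence for each chain is taken, in order of preference,
#' from: (i) a FASTA file whose headers are `ENTRYID_CHAIN`, (ii) the file's
#' SEQRES records, (iii) the resolved sequence itself.
#'
#' @param path path to a PDB-format structure file.
#' @param fasta optional path to a FASTA file of deposited sequences with
#'   headers formatted `ENTRYID_CHAIN` (e.g. `1p3m_A`).
#' @return list of [chain_record()] objects.
#' @export
read_chains <- function(path, fasta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse structure file '", path, "': ",
                             conditionMessage(e))
  )
  entry <- tolower(substr(tools::file_path_sans_ext(basename(path)), 1L, 8L))
  atoms <- pdb$atom
  ca <- atoms[atoms$elety == "CA" & !is.na(atoms$elety), , drop = FALSE]

  fasta_seqs <- NULL
  if (!is.null(fasta)) {
    ss <- Biostrings::readAAStringSet(fasta)
    names(ss) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
    fasta_seqs <- stats::setNames(as.character(ss), names(ss))
  }

  chains <- unique(atoms$chain[!is.na(atoms$chain)])
  out <- list()
  for (ch in chains) {
    rows <- ca[ca$chain == ch, , drop = FALSE]
    # drop solvent and nucleic residues
    rows <- rows[!(rows$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
    chain_resid <- atoms$resid[atoms$chain == ch]
    if (length(chain_resid) > 0 &&
        mean(chain_resid %in% NUCLEIC_RESID, na.rm = TRUE) > 0.5) {
      warning("skipping nucleic-acid chain ", ch, " in ", basename(path))
      next
    }
    if (nrow(rows) == 0L) {
      warning("skipping chain ", ch, " in ", basename(path),
              ": no C-alpha atoms")
      next
    }
    # one row per residue: first occurrence (read.pdb already keeps altloc A)
    key <- paste(rows$resno, ifelse(is.na(rows$insert), "", rows$insert))
    rows <- rows[!duplicated(key), , drop = FALSE]
    resolved <- paste(res3to1(rows$resid), collapse = "")
    authnum <- paste0(rows$resno, ifelse(is.na(rows$insert), "", rows$insert))

    deposited <- NULL
    k <- paste0(entry, "_", ch)
    if (!is.null(fasta_seqs) && k %in% names(fasta_seqs)) {
      deposited <- fasta_seqs[[k]]
    } else if (!is.null(pdb$seqres)) {
      sr <- pdb$seqres[names(pdb$seqres) == ch]
      if (length(sr) > 0) deposited <- paste(res3to1(unname(sr)), collapse = "")
    }
    out[[length(out) + 1L]] <- chain_record(
      entry_id = entry, chain_id = ch, resolved_seq = resolved,
      ca_coords = as.matrix(rows[, c("x", "y", "z")]),
      deposited_seq = deposited, author_numbers = authnum
    )
  }
  if (length(out) == 0L) {
    stop("no usable polymer chains in ", path)
  }
  out
}

# Write one or more chains' C-alpha traces as a PDB file.
write_ca_pdb <- function(coord_list, chain_ids, seqs, path) {
  xyz <- do.call(rbind, coord_list)
  resid3 <- unlist(lapply(seqs, function(s) {
    one <- strsplit(s, "")[[1]]
    r3 <- names(STD3TO1)[match(one, STD3TO1)]
    r3[is.na(r3)] <- "UNK"
    r3
  }))
  n_per <- vapply(coord_list, nrow, integer(1))
  chain <- rep(chain_ids, n_per)
  resno <- unlist(lapply(n_per, seq_len))
  bio3d::write.pdb(pdb = NULL, file = path, xyz = as.numeric(t(xyz)),
                   resno = resno, resid = resid3, chain = chain,
                   elety = rep("CA", sum(n_per)))
  invisible(path)
}

#' Write a single chain as a C-alpha PDB file
#'
#' @param chain a [chain_record()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_chain_pdb <- function(chain, path) {
  write_ca_pdb(list(chain$ca_coords), chain$chain_id, list(chain$resolved_seq),
               path)
}

#' Write a superposed pair of chains
#'
#' Writes a PDB file containing the fixed chain unchanged and the moving
#' chain with its coordinates transformed by the given rigid superposition.
#' The two chains receive distinct chain identifiers.
#'
#' @param fixed,moving [chain_record()] objects.
#' @param transform a `Superposition` (see [kabsch()]): list with `rotation`
#'   (3 x 3 proper rotation) and `translation` (length-3 vector).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_superposition <- function(fixed, moving, transform, path) {
  check_rotation(transform$rotation)
  moved <- apply_transform(moving$ca_coords, transform)
  ids <- c(fixed$chain_id, moving$chain_id)
  if (ids[1] == ids[2]) ids <- c("A", "B")
  write_ca_pdb(list(fixed$ca_coords, moved), ids,
               list(fixed$resolved_seq, moving$resolved_seq), path)
}

check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != 3L) ||
      max(abs(crossprod(R) - diag(3))) > tol ||
      abs(det(R) - 1) > tol) {
    stop("rotation must be orthonormal with determinant +1")
  }
  invisible(R)
}
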
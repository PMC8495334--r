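#' Trypsin cleavage sites
#'
#' Positions after which trypsin cuts: following K or R, optionally
#' suppressed when the next residue is proline (the Keil rule). Positions
#' are counted in residues from the N-terminus, so a cut at position i
#' separates \code{seq[1..i]} from \code{seq[(i+1)..n]}; a terminal K/R
#' yields a cut at position \code{nchar(seq)}.
#'
#' @param seq Protein or peptide sequence.
#' @param proline_rule Suppress cleavage at K/R-P bonds.
#' @return Strictly increasing integer vector of cut positions.
#' @examples
#' cleavage_sites("AKPLRG")  # 5: the K-P bond is not cut
#' @export
cleavage_sites <- function(seq, proline_rule = TRUE) {
  chars <- strsplit(seq, "")[[1]]
  pos <- which(chars %in% c("K", "R"))
  if (proline_rule && length(pos)) {
    nxt <- pos + 1L
    blocked <- nxt <= length(chars) & chars[pmin(nxt, length(chars))] == "P"
    pos <- pos[!blocked]
  }
  as.integer(pos)
}

#' In-silico tryptic digestion of one protein
#'
#' Cuts the sequence at every tryptic site and emits all peptides spanning
#' up to \code{max_missed + 1} adjacent fragments, within the length window.
#' Protein N- and C-termini count as tryptic termini (a C-terminal peptide
#' need not end in K/R to be "fully tryptic"). Peptides containing
#' ambiguous residues (B, J, O, U, X, Z) are flagged via \code{ambiguous}
#' rather than dropped, so the index keeps full coverage while mass-based
#' steps can skip them.
#'
#' @param protein List or data.frame row with \code{id}, \code{species},
#'   \code{sequence}; a plain string is accepted (id "protein1", species
#'   NA).
#' @param max_missed Maximum internal missed cleavages (default 2, the
#'   usual database-search setting).
#' @param min_len,max_len Peptide length window.
#' @param proline_rule See \code{\link{cleavage_sites}}.
#' @return data.frame with columns \code{sequence}, \code{protein_id},
#'   \code{species}, \code{start}, \code{end}, \code{missed_cleavages},
#'   \code{nterm_tryptic}, \code{cterm_tryptic}, \code{ambiguous}; ordered
#'   by start position then length.
#' @examples
#' digest("MKTAYIAKQR", max_missed = 0)
#' @export
digest <- function(protein, max_missed = 2L, min_len = 1L, max_len = 50L,
                   proline_rule = TRUE) {
  if (is.character(protein))
    protein <- list(id = "protein1", species = NA_character_,
                    sequence = protein)
  stopifnot(max_missed >= 0, min_len >= 1, min_len <= max_len)
  seq <- protein$sequence
  if (!nzchar(seq)) stop("empty protein sequence")
  n <- nchar(seq)
  cuts <- cleavage_sites(seq, proline_rule)
  # fragment boundaries: 0, internal cuts, n
  bounds <- unique(c(0L, cuts[cuts < n], n))
  nfrag <- length(bounds) - 1L
  rows <- vector("list", nfrag * (max_missed + 1L))
  k <- 0L
  for (i in seq_len(nfrag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nfrag) break
      start <- bounds[i] + 1L
      end <- bounds[j + 1L]
      len <- end - start + 1L
      if (len < min_len || len > max_len) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        sequence = substr(seq, start, end),
        protein_id = protein$id, species = protein$species,
        start = start, end = end, missed_cleavages = m,
        nterm_tryptic = TRUE,   # fragment starts at a cut or the N-terminus
        cterm_tryptic = TRUE,   # ends at a cut or the C-terminus
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (k) do.call(rbind, rows[seq_len(k)]) else empty_peptide_frame()
  out$ambiguous <- grepl("[BJOUXZ]", out$sequence)
  out <- out[order(out$start, out$end - out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_peptide_frame <- function() {
  data.frame(sequence = character(), protein_id = character(),
             species = character(), start = integer(), end = integer(),
             missed_cleavages = integer(), nterm_tryptic = logical(),
             cterm_tryptic = logical(), stringsAsFactors = FALSE)
}

#' Digest a collection of proteins
#'
#' Applies \code{\link{digest}} to every protein, preserving provenance.
#'
#' @param proteins data.frame with columns \code{id}, \code{species},
#'   \code{sequence} (one row per protein).
#' @inheritParams digest
#' @return Row-bound peptide data.frame (see \code{\link{digest}}).
#' @export
digest_collection <- function(proteins, max_missed = 2L, min_len = 1L,
                              max_len = 50L, proline_rule = TRUE) {
  if (NROW(proteins) == 0L) {
    out <- empty_peptide_frame()
    out$ambiguous <- logical()
    return(out)
  }
  parts <- lapply(seq_len(nrow(proteins)), function(i) {
    digest(as.list(proteins[i, , drop = FALSE]), max_missed,
           min_len, max_len, proline_rule)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Read a species proteome from FASTA
#'
#' Reads an amino-acid FASTA file; the header up to the first whitespace
#' becomes the protein identifier and every record is assigned the given
#' species label.
#'
#' @param path FASTA file path.
#' @param species Species label for all records in the file.
#' @return data.frame with columns \code{id}, \code{species},
#'   \code{sequence}.
#' @export
read_species_fasta <- function(path, species) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  data.frame(id = ids, species = species,
             sequence = as.character(aas),
             stringsAsFactors = FALSE)
}

#' Read several per-species FASTA files
#'
#' @param fasta_map Named character vector or list: species label ->
#'   FASTA path.
#' @return Combined protein data.frame.
#' @export
read_proteomes <- function(fasta_map) {
  stopifnot(length(fasta_map) >= 1, !is.null(names(fasta_map)))
  out <- do.call(rbind, lapply(names(fasta_map), function(sp) {
    read_species_fasta(fasta_map[[sp]], sp)
  }))
  rownames(out) <- NULL
  out
}
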
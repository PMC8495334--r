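#' Canonical peptide key
#'
#' Uppercases the sequence and, when \code{equate_il} is on, maps both
#' isoleucine and leucine to a common symbol ("J"). Triple-quadrupole
#' instruments cannot distinguish the isobaric pair, so uniqueness
#' screening should not either.
#'
#' @param seq Peptide sequence(s).
#' @param equate_il Treat I and L as equivalent.
#' @return Character vector of canonical keys.
#' @examples
#' peptide_key("LAILENANVLAR") == peptide_key("IAILENANVIAR")
#' @export
peptide_key <- function(seq, equate_il = TRUE) {
  key <- toupper(seq)
  if (equate_il) key <- chartr("IL", "JJ", key)
  key
}

#' Marker filter settings
#'
#' The rules a digested peptide must pass to be an assay-ready marker:
#' length window 9-17 residues, no missed cleavages, tryptic termini, and
#' no excluded residues. Methionine is excluded by default because its
#' variable oxidation splits the MRM signal; cysteine is allowed because
#' carbamidomethylation is applied as a fixed modification.
#'
#' @param min_len,max_len Length window (residues).
#' @param max_missed_for_marker Maximum missed cleavages.
#' @param require_tryptic_termini Demand tryptic (or protein-terminal)
#'   ends.
#' @param exclude_residues Residues that disqualify a peptide.
#' @param equate_il I/L equivalence for the uniqueness key.
#' @return Object of class \code{marker_filter}.
#' @export
marker_filter <- function(min_len = 9L, max_len = 17L,
                          max_missed_for_marker = 0L,
                          require_tryptic_termini = TRUE,
                          exclude_residues = "M",
                          equate_il = TRUE) {
  stopifnot(min_len <= max_len, max_missed_for_marker >= 0)
  structure(list(min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 max_missed_for_marker = as.integer(max_missed_for_marker),
                 require_tryptic_termini = require_tryptic_termini,
                 exclude_residues = exclude_residues,
                 equate_il = equate_il),
            class = "marker_filter")
}

#' Build a cross-species peptide index
#'
#' Maps every digested peptide, under its canonical key, to the set of
#' (species, protein) pairs containing it. Uniqueness of a marker is then
#' a one-species lookup. At least two species are required: specificity
#' against a single proteome is undefined.
#'
#' @param peptides Digested peptide data.frame
#'   (\code{\link{digest_collection}} output) covering all species.
#' @param equate_il I/L equivalence for keys.
#' @return Object of class \code{peptide_index}: a list with \code{table}
#'   (data.frame key/species/protein_id, deduplicated) and
#'   \code{equate_il}.
#' @export
build_index <- function(peptides, equate_il = TRUE) {
  species <- unique(peptides$species)
  if (length(species) < 2L)
    stop("peptide index needs >= 2 species; got ", length(species))
  tab <- data.frame(key = peptide_key(peptides$sequence, equate_il),
                    species = peptides$species,
                    protein_id = peptides$protein_id,
                    stringsAsFactors = FALSE)
  tab <- unique(tab)
  tab <- tab[order(tab$key, tab$species, tab$protein_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, equate_il = equate_il, species = species),
            class = "peptide_index")
}

# species set per key, as a named list
index_species_of <- function(index, keys) {
  hit <- index$table[index$table$key %in% keys, , drop = FALSE]
  split(hit$species, hit$key)
}

#' Find species-specific marker peptides
#'
#' Returns the digested peptides of one species whose canonical key occurs
#' in no other species' digest, restricted to those passing the marker
#' filter. With \code{strict_substring = TRUE} a candidate is additionally
#' rejected if its key occurs as a substring anywhere in another species'
#' protein sequences (guards against homologous context that digestion
#' parameters happened to split differently).
#'
#' @param index \code{peptide_index} from \code{\link{build_index}}.
#' @param peptides The digested peptide data.frame the index was built
#'   from (provides positions/flags for filtering).
#' @param species Species to screen for.
#' @param filter \code{marker_filter} settings.
#' @param strict_substring Also check substring containment in other
#'   species' full protein sequences.
#' @param proteins Protein data.frame; required when
#'   \code{strict_substring} is on.
#' @return data.frame of marker peptides (one row per unique sequence,
#'   protein ids collapsed), sorted by sequence.
#' @export
find_species_specific <- function(index, peptides, species,
                                  filter = marker_filter(),
                                  strict_substring = FALSE,
                                  proteins = NULL) {
  if (!species %in% index$species)
    stop("species '", species, "' not present in index")
  cand <- peptides[peptides$species == species, , drop = FALSE]
  len <- nchar(cand$sequence)
  keep <- len >= filter$min_len & len <= filter$max_len &
    cand$missed_cleavages <= filter$max_missed_for_marker &
    !cand$ambiguous
  if (filter$require_tryptic_termini)
    keep <- keep & cand$nterm_tryptic & cand$cterm_tryptic
  for (res in filter$exclude_residues)
    keep <- keep & !grepl(res, cand$sequence, fixed = TRUE)
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty_marker_frame())

  cand$key <- peptide_key(cand$sequence, filter$equate_il)
  if (filter$equate_il != index$equate_il)
    stop("filter and index disagree on I/L equivalence")
  occ <- index_species_of(index, unique(cand$key))
  unique_key <- vapply(occ, function(s) all(s == species), logical(1))
  cand <- cand[unique_key[cand$key], , drop = FALSE]
  if (!nrow(cand)) return(empty_marker_frame())

  if (strict_substring) {
    if (is.null(proteins))
      stop("strict_substring mode needs the protein data.frame")
    other <- proteins[proteins$species != species, , drop = FALSE]
    other_seq <- peptide_key(other$sequence, filter$equate_il)
    contained <- vapply(unique(cand$key), function(k) {
      any(grepl(k, other_seq, fixed = TRUE))
    }, logical(1))
    cand <- cand[!contained[cand$key], , drop = FALSE]
    if (!nrow(cand)) return(empty_marker_frame())
  }

  # collapse to one row per sequence, keeping provenance
  agg <- split(cand, cand$sequence)
  out <- do.call(rbind, lapply(agg, function(g) {
    data.frame(species = species, sequence = g$sequence[1],
               protein_ids = paste(sort(unique(g$protein_id)),
                                   collapse = ";"),
               length = nchar(g$sequence[1]),
               missed_cleavages = g$missed_cleavages[1],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_marker_frame <- function() {
  data.frame(species = character(), sequence = character(),
             protein_ids = character(), length = integer(),
             missed_cleavages = integer(), stringsAsFactors = FALSE)
}

#' Per-species occurrence table for one peptide
#'
#' Counts, for every species in the index, the proteins whose digest
#' contains the peptide's canonical key. Zero rows are included so the
#' report always covers the full species panel.
#'
#' @inheritParams find_species_specific
#' @param peptide Peptide sequence.
#' @return data.frame with columns \code{species}, \code{n_proteins}.
#' @export
specificity_report <- function(index, peptide) {
  key <- peptide_key(peptide, index$equate_il)
  hit <- index$table[index$table$key == key, , drop = FALSE]
  counts <- table(factor(hit$species, levels = sort(index$species)))
  data.frame(species = names(counts), n_proteins = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Rank markers by empirical response
#'
#' Abundance and signal-to-noise cannot be computed from sequence alone;
#' when an observed intensity table is available (columns \code{sequence},
#' \code{intensity}) it is used to order candidates, highest response
#' first. Markers without an entry sort last, alphabetically.
#'
#' @param markers Marker data.frame from
#'   \code{\link{find_species_specific}}.
#' @param intensities Optional data.frame of observed responses.
#' @return The marker data.frame, reordered, with an \code{intensity}
#'   column appended.
#' @export
rank_markers <- function(markers, intensities = NULL) {
  if (is.null(intensities)) {
    markers$intensity <- NA_real_
    return(markers)
  }
  stopifnot(all(c("sequence", "intensity") %in% names(intensities)))
  markers$intensity <-
    intensities$intensity[match(markers$sequence, intensities$sequence)]
  ord <- order(-ifelse(is.na(markers$intensity), -Inf, markers$intensity),
               markers$sequence)
  out <- markers[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
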
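#' Specification of a toy multi-species proteome fixture
#'
#' Parameters for \code{\link{make_toy_proteomes}}: the number of species
#' and proteins, protein length range, and how many marker-like peptides
#' to plant. Planted peptides are fully tryptic, 9-17 residues,
#' methionine-free and contain no internal cleavage site, so they satisfy
#' the default \code{\link{marker_filter}} by construction. The default
#' mirrors a five-species screening panel at a size where a brute-force
#' oracle is still cheap.
#'
#' @param n_species Number of species.
#' @param n_proteins Proteins per species.
#' @param protein_length Length-2 range of background residues per
#'   protein.
#' @param n_unique Planted species-unique peptides per species.
#' @param n_shared Peptides planted into two species each (never
#'   markers).
#' @param seed Random seed; the fixture is fully reproducible from it.
#' @return Object of class \code{proteome_spec}.
#' @export
proteome_spec <- function(n_species = 5L, n_proteins = 20L,
                          protein_length = c(80L, 200L),
                          n_unique = 3L, n_shared = 2L, seed = 1L) {
  stopifnot(n_species >= 2, n_proteins >= 1, n_unique >= 0, n_shared >= 0)
  structure(list(n_species = as.integer(n_species),
                 n_proteins = as.integer(n_proteins),
                 protein_length = as.integer(protein_length),
                 n_unique = as.integer(n_unique),
                 n_shared = as.integer(n_shared),
                 seed = as.integer(seed)),
            class = "proteome_spec")
}

# residues for planted peptides: no K/R (would add missed cleavages),
# no M (excluded by the default marker filter), no P (could block the
# upstream cleavage site when first)
plant_alphabet <- c("G", "A", "S", "V", "T", "C", "L", "I", "N", "D",
                    "Q", "E", "H", "F", "Y", "W")

# one fully tryptic marker-like peptide, length 9-17, ends in K/R
random_planted_peptide <- function() {
  len <- sample(9:17, 1L)
  body <- sample(plant_alphabet, len - 1L, replace = TRUE)
  paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
}

# Background chunk: a full tryptic peptide (non-K/R body + terminal K/R).
# Designed so background never passes the default marker filter: short
# bodies digest to < 9 residues, long bodies carry a methionine. Never
# starts with P (would suppress the upstream cleavage site). The body
# length mix gives a combined K/R frequency near the natural ~11%.
random_background_chunk <- function() {
  body_len <- if (stats::runif(1) < 0.5) sample(4:7, 1L) else sample(8:14, 1L)
  aa <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q",
          "E", "H", "F", "Y", "W")
  body <- sample(aa, body_len, replace = TRUE)
  if (body[1] == "P") body[1] <- "A"
  if (body_len >= 8L) body[sample(2:body_len, 1L)] <- "M"
  paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
}

#' Generate toy per-species proteomes with planted markers
#'
#' Builds \code{n_species} proteomes of random background sequence with
#' known peptides planted at tryptic positions: per species,
#' \code{n_unique} peptides occurring in that species only (after I/L
#' canonicalization), and \code{n_shared} peptides placed into two
#' species each. Planting collisions (a planted "unique" peptide whose
#' key appears anywhere else, including as a substring of background) are
#' resolved by regenerating the colliding peptide, up to 100 attempts.
#'
#' @param spec \code{proteome_spec}.
#' @param dir Optional directory; when given, one FASTA per species is
#'   written there (\code{<species>.fasta}) and the paths are returned in
#'   the result.
#' @return List with \code{proteins} (data.frame id/species/sequence),
#'   \code{truth} (data.frame species/sequence/kind with kind
#'   "unique"/"shared"), \code{fasta} (named paths or NULL).
#' @export
make_toy_proteomes <- function(spec = proteome_spec(), dir = NULL) {
  set.seed(spec$seed)
  species <- paste0("sp", seq_len(spec$n_species))

  draw_panel <- function() {
    uniq <- lapply(species, function(s)
      replicate(spec$n_unique, random_planted_peptide()))
    names(uniq) <- species
    shared <- replicate(spec$n_shared, random_planted_peptide())
    list(uniq = uniq, shared = as.character(shared))
  }

  # a planted set is feasible iff all keys are pairwise distinct
  panel_ok <- function(panel) {
    keys <- peptide_key(c(unlist(panel$uniq), panel$shared))
    !anyDuplicated(keys)
  }
  panel <- draw_panel()
  tries <- 0L
  while (!panel_ok(panel)) {
    tries <- tries + 1L
    if (tries > 100L) stop("could not draw a collision-free planted panel")
    panel <- draw_panel()
  }

  # assign each shared peptide to two species
  shared_homes <- lapply(seq_along(panel$shared), function(i)
    sample(species, 2L))

  build <- function(attempt) {
    proteins <- list()
    for (si in seq_along(species)) {
      sp <- species[si]
      planted_here <- panel$uniq[[sp]]
      for (j in seq_along(panel$shared))
        if (sp %in% shared_homes[[j]])
          planted_here <- c(planted_here, panel$shared[j])
      # distribute planted peptides over the first proteins, one each
      for (pi in seq_len(spec$n_proteins)) {
        target_len <- sample(spec$protein_length[1]:spec$protein_length[2], 1L)
        chunks <- character(0)
        while (sum(nchar(chunks)) < target_len)
          chunks <- c(chunks, random_background_chunk())
        if (pi <= length(planted_here)) {
          at <- sample(seq_len(length(chunks) + 1L), 1L)
          chunks <- append(chunks, planted_here[pi], after = at - 1L)
        }
        proteins[[length(proteins) + 1L]] <- data.frame(
          id = sprintf("%s_prot%03d", sp, pi), species = sp,
          sequence = paste(chunks, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, proteins)
  }

  # background may accidentally recreate a planted key; rebuild if so
  for (attempt in 1:100) {
    proteins <- build(attempt)
    prot_keys <- peptide_key(proteins$sequence)
    bad <- FALSE
    for (sp in species) {
      for (pep in panel$uniq[[sp]]) {
        k <- peptide_key(pep)
        elsewhere <- proteins$species != sp
        if (any(grepl(k, prot_keys[elsewhere], fixed = TRUE))) {
          bad <- TRUE
          break
        }
      }
      if (bad) break
    }
    if (!bad) break
    if (attempt == 100L) stop("planting collisions persisted after 100 attempts")
  }

  truth <- rbind(
    do.call(rbind, lapply(species, function(sp) {
      if (spec$n_unique == 0L) return(NULL)
      data.frame(species = sp, sequence = panel$uniq[[sp]],
                 kind = "unique", stringsAsFactors = FALSE)
    })),
    if (spec$n_shared > 0L)
      do.call(rbind, lapply(seq_along(panel$shared), function(j) {
        data.frame(species = shared_homes[[j]], sequence = panel$shared[j],
                   kind = "shared", stringsAsFactors = FALSE)
      }))
  )
  rownames(truth) <- NULL

  fasta <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fasta <- vapply(species, function(sp) {
      path <- file.path(dir, paste0(sp, ".fasta"))
      sub <- proteins[proteins$species == sp, , drop = FALSE]
      writeLines(paste0(">", sub$id, "\n", sub$sequence), path)
      path
    }, character(1))
  }
  list(proteins = proteins, truth = truth, fasta = fasta)
}

#' Specification of a simulated mixture-intensity experiment
#'
#' Linear response per peptide with additive Gaussian noise, emulating
#' the transition intensities a calibration dilution series produces.
#'
#' @param peptides Character vector of peptide labels.
#' @param slope,intercept True response parameters, recycled over
#'   peptides.
#' @param noise_sd Additive noise standard deviation (intensity units).
#' @param fractions Design mass fractions.
#' @param replicates Replicates per level.
#' @param seed Random seed.
#' @return Object of class \code{intensity_spec}.
#' @export
intensity_spec <- function(peptides = "PEPTIDE1", slope = 1000,
                           intercept = 50, noise_sd = 10,
                           fractions = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                           replicates = 3L, seed = 1L) {
  stopifnot(noise_sd >= 0, replicates >= 1)
  structure(list(peptides = peptides,
                 slope = rep_len(slope, length(peptides)),
                 intercept = rep_len(intercept, length(peptides)),
                 noise_sd = noise_sd, fractions = fractions,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "intensity_spec")
}

#' Simulate a mixture intensity table
#'
#' intensity = slope * fraction + intercept + N(0, sd), floored at zero.
#'
#' @param spec \code{intensity_spec}.
#' @return data.frame: \code{peptide}, \code{fraction},
#'   \code{replicate}, \code{intensity}.
#' @export
simulate_mixture_intensities <- function(spec = intensity_spec()) {
  set.seed(spec$seed)
  grid <- expand.grid(replicate = seq_len(spec$replicates),
                      fraction = spec$fractions,
                      peptide = spec$peptides,
                      stringsAsFactors = FALSE)
  i <- match(grid$peptide, spec$peptides)
  mu <- spec$slope[i] * grid$fraction + spec$intercept[i]
  grid$intensity <- pmax(mu + stats::rnorm(nrow(grid), 0, spec$noise_sd), 0)
  grid[, c("peptide", "fraction", "replicate", "intensity")]
}
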
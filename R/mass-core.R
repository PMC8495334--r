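#' Monoisotopic residue mass table
#'
#' Returns the mass constants used throughout the package: monoisotopic
#' residue (i.e. dehydrated amino-acid) masses for the 20 standard amino
#' acids, the mass of water and the mass of a proton, all in Daltons.
#' A peptide's neutral monoisotopic mass is the sum of its residue masses
#' plus one water; protonation adds one proton mass per charge.
#'
#' @param residue_mass Optional named numeric vector overriding the default
#'   residue masses (names are one-letter amino-acid codes).
#' @param water_mass Mass of H2O in Da.
#' @param proton_mass Mass of a proton in Da.
#' @return An object of class \code{residue_mass_table} with elements
#'   \code{residue_mass}, \code{water_mass} and \code{proton_mass}.
#' @examples
#' tab <- residue_mass_table()
#' tab$residue_mass[["G"]]  # glycine residue, 57.02146 Da
#' @export
residue_mass_table <- function(residue_mass = NULL,
                               water_mass = 18.0105646,
                               proton_mass = 1.00727646) {
  default <- c(
    G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
    V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
    I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
    K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
    F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
  )
  if (!is.null(residue_mass)) {
    stopifnot(is.numeric(residue_mass), !is.null(names(residue_mass)))
    default[names(residue_mass)] <- residue_mass
  }
  if (any(default <= 0)) stop("all residue masses must be positive")
  structure(
    list(residue_mass = default, water_mass = water_mass,
         proton_mass = proton_mass),
    class = "residue_mass_table"
  )
}

#' Peptide modifications
#'
#' Constructs a modification definition (a mass delta attached to a target
#' residue). The two modifications the assay workflow relies on are provided
#' as ready-made constructors: carbamidomethylation of cysteine (fixed, from
#' iodoacetamide alkylation, +57.02146 Da) and oxidation of methionine
#' (variable, +15.99491 Da).
#'
#' @param name Modification name.
#' @param target One-letter code(s) of the residue(s) the modification
#'   applies to.
#' @param delta_mass Mass shift in Da.
#' @param fixed Logical; \code{TRUE} for a fixed modification applied to
#'   every target residue, \code{FALSE} for a variable one.
#' @return An object of class \code{peptide_modification}.
#' @export
modification <- function(name, target, delta_mass, fixed = FALSE) {
  stopifnot(is.character(name), is.character(target),
            is.numeric(delta_mass), length(delta_mass) == 1L)
  structure(list(name = name, target = target, delta_mass = delta_mass,
                 fixed = fixed),
            class = "peptide_modification")
}

#' @rdname modification
#' @export
mod_carbamidomethyl <- function() {
  modification("Carbamidomethyl", "C", 57.021464, fixed = TRUE)
}

#' @rdname modification
#' @export
mod_oxidation <- function() {
  modification("Oxidation", "M", 15.994915, fixed = FALSE)
}

#' Modified peptide
#'
#' Bundles a peptide sequence with a list of site-specific modifications.
#' Positions are 1-based; each modification's target must match the residue
#' at its position. With \code{fixed_cam = TRUE} (the default convention for
#' alkylated samples) carbamidomethylation is attached to every cysteine
#' automatically.
#'
#' @param sequence Amino-acid string (upper case, standard alphabet).
#' @param mods List of \code{list(position =, mod =)} entries, where
#'   \code{mod} is a \code{peptide_modification}.
#' @param fixed_cam Apply carbamidomethyl to all Cys residues.
#' @return Object of class \code{modified_peptide}.
#' @examples
#' p <- modified_peptide("ECQTLVSDVDYR")        # C2 carbamidomethylated
#' precursor_mz(p, 2)
#' @export
modified_peptide <- function(sequence, mods = list(), fixed_cam = TRUE) {
  check_sequence(sequence)
  if (fixed_cam) {
    cam <- mod_carbamidomethyl()
    cpos <- which(strsplit(sequence, "")[[1]] == "C")
    mods <- c(mods, lapply(cpos, function(i) list(position = i, mod = cam)))
  }
  chars <- strsplit(sequence, "")[[1]]
  for (m in mods) {
    if (m$position < 1L || m$position > length(chars))
      stop("modification position ", m$position, " outside sequence")
    if (!chars[m$position] %in% m$mod$target)
      stop("residue ", chars[m$position], " at position ", m$position,
           " does not match modification target ",
           paste(m$mod$target, collapse = "/"))
  }
  structure(list(sequence = sequence, mods = mods),
            class = "modified_peptide")
}

as_modified_peptide <- function(p, fixed_cam = TRUE) {
  if (inherits(p, "modified_peptide")) p
  else modified_peptide(p, fixed_cam = fixed_cam)
}

check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty peptide sequence")
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(residue_mass_table()$residue_mass))
  if (length(bad))
    stop("unknown residue '", chars[bad[1]], "' at position ", bad[1])
  invisible(TRUE)
}

# per-residue mass vector including site-specific modification deltas
residue_masses_with_mods <- function(p, table) {
  chars <- strsplit(p$sequence, "")[[1]]
  m <- unname(table$residue_mass[chars])
  for (mod in p$mods) m[mod$position] <- m[mod$position] + mod$mod$delta_mass
  m
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses, modification deltas, and one water.
#'
#' @param p A \code{modified_peptide} or plain sequence string (cysteines
#'   are then carbamidomethylated by default).
#' @param table A \code{residue_mass_table}.
#' @return Neutral mass in Da.
#' @export
peptide_neutral_mass <- function(p, table = residue_mass_table()) {
  p <- as_modified_peptide(p)
  sum(residue_masses_with_mods(p, table)) + table$water_mass
}

#' Precursor ion m/z
#'
#' m/z of the protonated peptide: \code{(M + z * proton) / z}. Tryptic
#' peptides are typically observed at charge 2+ in MRM assays.
#'
#' @inheritParams peptide_neutral_mass
#' @param charge Positive integer charge state.
#' @return m/z value.
#' @examples
#' precursor_mz("TLEDQVNELK", 2)  # 594.808967
#' @export
precursor_mz <- function(p, charge = 2L, table = residue_mass_table()) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge))
    stop("charge must be a positive integer")
  (peptide_neutral_mass(p, table) + charge * table$proton_mass) / charge
}

#' Fragment ion m/z (b/y series)
#'
#' y_n retains the C-terminal n residues plus water; b_n the N-terminal n
#' residues without water. Both are reported protonated at the requested
#' charge.
#'
#' @inheritParams precursor_mz
#' @param series \code{"b"} or \code{"y"}.
#' @param index Fragment index, between 1 and \code{nchar(sequence) - 1}.
#' @return m/z value.
#' @examples
#' fragment_mz("TLEDQVNELK", "y", 7)  # 845.436323
#' @export
fragment_mz <- function(p, series = c("y", "b"), index, charge = 1L,
                        table = residue_mass_table()) {
  series <- match.arg(series)
  p <- as_modified_peptide(p)
  if (!is.numeric(charge) || charge < 1 || charge != round(charge))
    stop("charge must be a positive integer")
  n <- nchar(p$sequence)
  if (!is.numeric(index) || index < 1 || index >= n || index != round(index))
    stop("fragment index must lie in [1, ", n - 1L, "] for this peptide")
  m <- residue_masses_with_mods(p, table)
  if (series == "y") {
    neutral <- sum(m[(n - index + 1L):n]) + table$water_mass
  } else {
    neutral <- sum(m[1:index])
  }
  (neutral + charge * table$proton_mass) / charge
}

#' Match an observed m/z against all b/y ions of a peptide
#'
#' Enumerates every b and y ion of the peptide at the requested charge
#' states and returns those within \code{tol} of the observed m/z, closest
#' first. Used to assign the product-ion label of an MRM transition.
#'
#' @inheritParams fragment_mz
#' @param observed_mz Observed product ion m/z.
#' @param tol Match tolerance in m/z units (> 0).
#' @param charges Integer vector of product charge states to consider.
#' @return data.frame with columns \code{series}, \code{index},
#'   \code{charge}, \code{mz}, \code{delta}; zero rows if nothing matches.
#' @examples
#' annotate_fragment("VNVDEVGGEALGR", 887.458121)  # y9
#' @export
annotate_fragment <- function(p, observed_mz, tol = 0.02, charges = 1L,
                              table = residue_mass_table()) {
  if (tol <= 0) stop("tol must be positive")
  p <- as_modified_peptide(p)
  n <- nchar(p$sequence)
  grid <- expand.grid(series = c("b", "y"), index = seq_len(n - 1L),
                      charge = as.integer(charges),
                      stringsAsFactors = FALSE)
  grid$mz <- mapply(function(s, i, z) fragment_mz(p, s, i, z, table),
                    grid$series, grid$index, grid$charge)
  grid$delta <- grid$mz - observed_mz
  hits <- grid[abs(grid$delta) <= tol, , drop = FALSE]
  hits <- hits[order(abs(hits$delta)), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
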
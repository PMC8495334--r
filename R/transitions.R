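#' Collision-energy ramp model
#'
#' Charge-dependent linear ramps CE = slope * (m/z / 100) + offset, the
#' standard way triple-quadrupole methods assign collision energy. The
#' default 2+ ramp (3.1 V per 100 m/z, +1.0 V offset) reproduces the
#' published five-species meat panel's CE column exactly after rounding
#' to one decimal.
#'
#' @param ramps Named list: charge (as character) -> list(slope, offset).
#' @return Object of class \code{ce_model}.
#' @export
ce_model <- function(ramps = list(`2` = list(slope = 3.1, offset = 1.0))) {
  structure(list(ramps = ramps), class = "ce_model")
}

#' Collision energy for a precursor
#'
#' @param precursor_mz Precursor m/z (> 0).
#' @param charge Precursor charge state.
#' @param model \code{ce_model} with a ramp for that charge.
#' @param round_digits Decimals for the reported value (1 by vendor
#'   convention); use \code{NULL} for the unrounded value.
#' @return CE in volts.
#' @examples
#' collision_energy(594.808967, 2)  # 19.4
#' @export
collision_energy <- function(precursor_mz, charge = 2L,
                             model = ce_model(), round_digits = 1L) {
  if (any(precursor_mz <= 0)) stop("precursor_mz must be positive")
  ramp <- model$ramps[[as.character(charge)]]
  if (is.null(ramp))
    stop("no CE ramp configured for charge ", charge)
  ce <- ramp$slope * precursor_mz / 100 + ramp$offset
  if (!is.null(round_digits)) ce <- round(ce, round_digits)
  ce
}

#' Candidate product ions for a marker peptide
#'
#' High-m/z singly charged y-ions are the usual first-choice MRM products
#' for tryptic 2+ precursors. Returns all y-ions with index >=
#' \code{min_index} inside the instrument m/z range, highest m/z first
#' (ties broken by ascending index); b-ions can be appended behind the
#' y-ions as fallbacks.
#'
#' @param p Peptide sequence or \code{modified_peptide}.
#' @param min_index Smallest fragment index to consider.
#' @param mz_range Length-2 numeric, instrument product m/z window.
#' @param include_b Append b-ions after the y-ion block.
#' @param table Mass table.
#' @return data.frame with columns \code{ion} (e.g. "y7"), \code{series},
#'   \code{index}, \code{mz}.
#' @export
candidate_products <- function(p, min_index = 3L, mz_range = c(300, 1400),
                               include_b = FALSE,
                               table = residue_mass_table()) {
  p <- as_modified_peptide(p)
  n <- nchar(p$sequence)
  one_series <- function(series) {
    idx <- seq.int(min_index, n - 1L)
    if (min_index > n - 1L) return(NULL)
    mz <- vapply(idx, function(i) fragment_mz(p, series, i, 1L, table),
                 numeric(1))
    ok <- mz >= mz_range[1] & mz <= mz_range[2]
    if (!any(ok)) return(NULL)
    d <- data.frame(ion = paste0(series, idx[ok]), series = series,
                    index = idx[ok], mz = mz[ok],
                    stringsAsFactors = FALSE)
    d[order(-d$mz, d$index), , drop = FALSE]
  }
  out <- one_series("y")
  if (include_b) out <- rbind(out, one_series("b"))
  if (is.null(out))
    out <- data.frame(ion = character(), series = character(),
                      index = integer(), mz = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build MRM transitions for marker peptides
#'
#' One transition row per marker/product pair: precursor m/z at the
#' configured charge, singly charged y-ion product, collision energy from
#' the ramp model, and empirical retention time when supplied (retention
#' times are never predicted). Two selection modes: \code{"empirical"}
#' takes the product ion named per peptide in \code{empirical} (the mode
#' matching how validated assays record their best-responding product),
#' and \code{"rank"} emits the top \code{k} high-m/z y-ion candidates per
#' marker as a starting panel.
#'
#' @param markers data.frame with at least \code{species} and
#'   \code{sequence} columns.
#' @param model \code{ce_model}.
#' @param selection \code{"empirical"} or \code{"rank"}.
#' @param empirical data.frame \code{sequence}, \code{product_ion} (e.g.
#'   "y9"), optional \code{rt}; required in empirical mode.
#' @param precursor_charge Precursor charge (2+ default).
#' @param k Candidates per marker in rank mode.
#' @param min_index,mz_range Passed to \code{\link{candidate_products}}.
#' @param table Mass table.
#' @return data.frame of transitions: \code{species}, \code{sequence},
#'   \code{precursor_mz}, \code{precursor_charge}, \code{product_ion},
#'   \code{product_mz}, \code{product_charge}, \code{ce}, \code{rt}.
#' @export
build_transitions <- function(markers, model = ce_model(),
                              selection = c("empirical", "rank"),
                              empirical = NULL, precursor_charge = 2L,
                              k = 2L, min_index = 3L,
                              mz_range = c(300, 1400),
                              table = residue_mass_table()) {
  selection <- match.arg(selection)
  if (selection == "empirical" && is.null(empirical))
    stop("empirical selection mode needs an empirical product-ion table")
  rows <- lapply(seq_len(NROW(markers)), function(i) {
    seq <- markers$sequence[i]
    p <- modified_peptide(seq)
    pre <- precursor_mz(p, precursor_charge, table)
    ce <- collision_energy(pre, precursor_charge, model)
    if (selection == "empirical") {
      e <- empirical[empirical$sequence == seq, , drop = FALSE]
      if (!nrow(e))
        stop("no empirical product ion recorded for ", seq)
      ion <- e$product_ion[1]
      series <- substr(ion, 1, 1)
      index <- as.integer(substring(ion, 2))
      prod_mz <- fragment_mz(p, series, index, 1L, table)
      rt <- if ("rt" %in% names(e)) e$rt[1] else NA_real_
      data.frame(species = markers$species[i], sequence = seq,
                 precursor_mz = pre, precursor_charge = precursor_charge,
                 product_ion = ion, product_mz = prod_mz,
                 product_charge = 1L, ce = ce, rt = rt,
                 stringsAsFactors = FALSE)
    } else {
      cands <- candidate_products(p, min_index, mz_range, table = table)
      cands <- utils::head(cands, k)
      if (!nrow(cands)) return(NULL)
      data.frame(species = markers$species[i], sequence = seq,
                 precursor_mz = pre, precursor_charge = precursor_charge,
                 product_ion = cands$ion, product_mz = cands$mz,
                 product_charge = 1L, ce = ce, rt = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_transition_frame()
  rownames(out) <- NULL
  out
}

empty_transition_frame <- function() {
  data.frame(species = character(), sequence = character(),
             precursor_mz = numeric(), precursor_charge = integer(),
             product_ion = character(), product_mz = numeric(),
             product_charge = integer(), ce = numeric(), rt = numeric(),
             stringsAsFactors = FALSE)
}

#' Export / import a transition list
#'
#' Vendor-neutral CSV: m/z to six decimals, CE to one, RT to three (blank
#' when absent); stable row order as given. The written file re-imports to
#' the same values at the declared precision.
#'
#' @param transitions Transition data.frame (see
#'   \code{\link{build_transitions}}).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
export_transition_list <- function(transitions, path) {
  fmt <- transitions
  fmt$precursor_mz <- sprintf("%.6f", transitions$precursor_mz)
  fmt$product_mz <- sprintf("%.6f", transitions$product_mz)
  fmt$ce <- sprintf("%.1f", transitions$ce)
  fmt$rt <- ifelse(is.na(transitions$rt), "",
                   sprintf("%.3f", transitions$rt))
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_transition_list
#' @export
read_transition_list <- function(path) {
  if (!file.exists(path)) stop("transition list not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(rt = "character"))
  out$rt <- suppressWarnings(as.numeric(out$rt))
  out
}

#' Published five-species meat-speciation MRM panel
#'
#' The 15-peptide reference panel for beef, chicken, duck, pork and lamb
#' speciation: sequences with their published 2+ precursor m/z, product
#' ion m/z, retention time (empirical, minutes) and collision energy, plus
#' the y-ion index assigned by \code{\link{annotate_fragment}}. One row
#' (FLEELLTTQC) carries a product-ion label of \code{NA}: its printed
#' precursor cannot be reconciled with the printed sequence under any
#' standard cysteine modification, so its masses are not reproducible from
#' sequence and only its CE and length enter verification.
#'
#' @return data.frame with columns \code{species}, \code{sequence},
#'   \code{precursor_mz}, \code{product_mz}, \code{rt}, \code{ce},
#'   \code{product_ion}, \code{mass_verifiable}.
#' @export
meat_panel <- function() {
  path <- system.file("extdata", "meat_panel.csv", package = "mrmarker",
                      mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$mass_verifiable <- !is.na(out$product_ion)
  out
}
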
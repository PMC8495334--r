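#' Read and validate a run configuration
#'
#' YAML configuration naming the per-species FASTA files, digestion
#' parameters, marker filter, transition parameters (CE ramps, charge,
#' product window, selection mode), quantification inputs and the output
#' directory. All referenced paths are checked before any stage runs.
#'
#' Recognised keys (all optional unless a stage needs them):
#' \preformatted{
#' species:            {beef: beef.fasta, pork: pork.fasta, ...}
#' digestion:          {max_missed: 2, min_len: 1, max_len: 50,
#'                      proline_rule: true}
#' marker_filter:      {min_len: 9, max_len: 17, max_missed: 0,
#'                      exclude_residues: [M], equate_il: true}
#' transitions:        {precursor_charge: 2, min_product_index: 3,
#'                      product_mz_range: [300, 1400],
#'                      selection: empirical, k: 2,
#'                      ce_model: {"2": {slope: 3.1, offset: 1.0}}}
#' empirical_products: products.csv     # sequence, product_ion[, rt]
#' design:             {target: pork, background: beef,
#'                      fractions: [0, 0.2, 0.4, 0.6, 0.8, 1]}
#' intensity_table:    intensities.csv
#' out_dir:            results/
#' seed:               1
#' }
#'
#' @param path YAML file path.
#' @return Validated configuration list (class \code{run_config}).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  if (!is.null(cfg$species)) {
    cfg$species <- lapply(cfg$species, resolve)
    missing <- !vapply(cfg$species, file.exists, logical(1))
    if (any(missing))
      stop("FASTA file(s) not found: ",
           paste(unlist(cfg$species[missing]), collapse = ", "))
  }
  for (key in c("empirical_products", "intensity_table")) {
    if (!is.null(cfg[[key]])) {
      cfg[[key]] <- resolve(cfg[[key]])
      if (!file.exists(cfg[[key]]))
        stop(key, " file not found: ", cfg[[key]])
    }
  }
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

config_marker_filter <- function(cfg) {
  mf <- cfg$marker_filter
  marker_filter(
    min_len = mf$min_len %||% 9L,
    max_len = mf$max_len %||% 17L,
    max_missed_for_marker = mf$max_missed %||% 0L,
    exclude_residues = unlist(mf$exclude_residues) %||% "M",
    equate_il = mf$equate_il %||% TRUE
  )
}

config_ce_model <- function(cfg) {
  cm <- cfg$transitions$ce_model
  if (is.null(cm)) return(ce_model())
  ce_model(lapply(cm, function(r) list(slope = r$slope, offset = r$offset)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the marker screen end to end
#'
#' Digests every configured species proteome, builds the cross-species
#' index, screens each species for specific markers and writes
#' \code{markers.csv} to the output directory.
#'
#' @param config \code{run_config} (or path to one).
#' @param quiet Suppress per-species count messages.
#' @return The marker data.frame, invisibly; path in
#'   \code{attr(, "path")}.
#' @export
run_screen <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$species) || length(config$species) < 2L)
    stop("config must map >= 2 species to FASTA files")
  dg <- config$digestion
  proteins <- read_proteomes(config$species)
  peptides <- digest_collection(
    proteins,
    max_missed = dg$max_missed %||% 2L,
    min_len = dg$min_len %||% 1L,
    max_len = dg$max_len %||% 50L,
    proline_rule = dg$proline_rule %||% TRUE
  )
  filt <- config_marker_filter(config)
  index <- build_index(peptides, equate_il = filt$equate_il)
  markers <- do.call(rbind, lapply(names(config$species), function(sp) {
    m <- find_species_specific(index, peptides, sp, filt)
    if (!quiet)
      message(sprintf("%s: %d specific marker peptide(s)", sp, nrow(m)))
    m
  }))
  rownames(markers) <- NULL
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  path <- file.path(config$out_dir, "markers.csv")
  utils::write.csv(markers, path, row.names = FALSE)
  attr(markers, "path") <- path
  invisible(markers)
}

#' Build and export the transition list
#'
#' Takes a marker table (from \code{\link{run_screen}} or a CSV path),
#' builds transitions per the configured CE model and selection mode, and
#' writes \code{transitions.csv}.
#'
#' @param config \code{run_config} (or path).
#' @param markers Marker data.frame or CSV path; defaults to
#'   \code{markers.csv} in the configured output directory.
#' @return Transition data.frame, invisibly; path in
#'   \code{attr(, "path")}.
#' @export
run_design <- function(config, markers = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(markers))
    markers <- file.path(config$out_dir, "markers.csv")
  if (is.character(markers)) {
    if (!file.exists(markers)) stop("marker table not found: ", markers)
    markers <- utils::read.csv(markers, stringsAsFactors = FALSE)
  }
  tr_cfg <- config$transitions
  empirical <- NULL
  if (!is.null(config$empirical_products))
    empirical <- utils::read.csv(config$empirical_products,
                                 stringsAsFactors = FALSE)
  selection <- tr_cfg$selection %||%
    (if (is.null(empirical)) "rank" else "empirical")
  if (nrow(markers) == 0L) {
    warning("empty marker list; writing header-only transition file")
    transitions <- empty_transition_frame()
  } else {
    transitions <- build_transitions(
      markers, model = config_ce_model(config), selection = selection,
      empirical = empirical,
      precursor_charge = tr_cfg$precursor_charge %||% 2L,
      k = tr_cfg$k %||% 2L,
      min_index = tr_cfg$min_product_index %||% 3L,
      mz_range = unlist(tr_cfg$product_mz_range) %||% c(300, 1400)
    )
  }
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  path <- file.path(config$out_dir, "transitions.csv")
  export_transition_list(transitions, path)
  attr(transitions, "path") <- path
  invisible(transitions)
}

#' Fit curves and quantify unknown samples
#'
#' The intensity table (long CSV: \code{sample_id}, \code{species},
#' \code{peptide}, \code{fraction}, \code{intensity}) holds both
#' calibration rows (known \code{fraction}) and unknowns
#' (\code{fraction} empty/NA). Standard curves are fitted per peptide
#' from the calibration rows; every unknown sample is then screened and
#' quantified, and \code{quantification.csv} plus a text log are
#' written.
#'
#' @param config \code{run_config} (or path).
#' @param intensity_table Optional data.frame overriding the configured
#'   CSV.
#' @return data.frame of per-sample per-species calls, invisibly.
#' @export
run_quantify <- function(config, intensity_table = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(intensity_table)) {
    if (is.null(config$intensity_table))
      stop("config names no intensity_table")
    intensity_table <- utils::read.csv(config$intensity_table,
                                       stringsAsFactors = FALSE)
  }
  need <- c("sample_id", "species", "peptide", "fraction", "intensity")
  if (!all(need %in% names(intensity_table)))
    stop("intensity table must have columns: ", paste(need, collapse = ", "))
  cal <- intensity_table[!is.na(intensity_table$fraction), , drop = FALSE]
  unk <- intensity_table[is.na(intensity_table$fraction), , drop = FALSE]
  if (!nrow(cal)) stop("no calibration rows (known fractions) in table")

  d_cfg <- config$design
  curves <- list()
  thresholds <- numeric(0)
  for (key in unique(paste0(cal$species, ":", cal$peptide))) {
    rows <- cal[paste0(cal$species, ":", cal$peptide) == key, , drop = FALSE]
    fr <- sort(unique(rows$fraction))
    if (length(fr) < 3L) next
    des <- mixture_design(rows$species[1],
                          d_cfg$background %||% "background", fr)
    ints <- vapply(fr, function(f)
      mean(rows$intensity[rows$fraction == f]), numeric(1))
    curves[[key]] <- fit_standard_curve(des, ints, rows$peptide[1])
    blanks <- rows$intensity[rows$fraction == 0]
    if (length(blanks) >= 2L)
      thresholds[key] <- detection_threshold(blanks)
  }

  panel <- unique(unk[, c("species", "peptide")])
  names(panel) <- c("species", "sequence")
  reports <- lapply(unique(unk$sample_id), function(sid) {
    rows <- unk[unk$sample_id == sid, , drop = FALSE]
    obs <- stats::setNames(rows$intensity,
                           paste0(rows$species, ":", rows$peptide))
    rep <- detect_contaminant(obs, panel, curves, thresholds)
    rep$sample_id <- sid
    rep
  })
  out <- do.call(rbind, reports)
  if (!is.null(out)) {
    detected_nocurve <- out$detected & is.na(out$fraction)
    if (any(detected_nocurve))
      warning("species detected without a standard curve: ",
              paste(unique(out$species[detected_nocurve]), collapse = ", "))
    out <- out[, c("sample_id", setdiff(names(out), "sample_id"))]
  }
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  utils::write.csv(out, file.path(config$out_dir, "quantification.csv"),
                   row.names = FALSE)
  log_lines <- c(
    sprintf("curves fitted: %d", length(curves)),
    vapply(names(curves), function(k) {
      cv <- curves[[k]]
      sprintf("  %s  slope=%.4g intercept=%.4g R2=%.4f",
              k, cv$slope, cv$intercept, cv$r_squared)
    }, character(1)),
    sprintf("unknown samples quantified: %d",
            length(unique(unk$sample_id)))
  )
  writeLines(log_lines, file.path(config$out_dir, "quantification.log"))
  attr(out, "curves") <- curves
  invisible(out)
}

#' Verify the built-in published panel
#'
#' Recomputes every mass-verifiable row of the published five-species
#' panel (\code{\link{meat_panel}}): 2+ precursor m/z and the published
#' y-ion product m/z against the printed values at 0.01 m/z, and the
#' collision-energy ramp against all printed CE values at 0.1 V.
#'
#' @param mz_tol,ce_tol Comparison tolerances.
#' @return data.frame with per-row computed values, deltas and a
#'   \code{pass} flag.
#' @export
verify_panel <- function(mz_tol = 0.01, ce_tol = 0.05) {
  panel <- meat_panel()
  res <- lapply(seq_len(nrow(panel)), function(i) {
    row <- panel[i, ]
    if (row$mass_verifiable) {
      pre <- precursor_mz(row$sequence, 2L)
      idx <- as.integer(substring(row$product_ion, 2))
      prod <- fragment_mz(row$sequence, "y", idx, 1L)
      hits <- annotate_fragment(row$sequence, row$product_mz, tol = mz_tol)
      ann_ok <- nrow(hits) > 0 && hits$series[1] == "y" &&
        hits$index[1] == idx
    } else {
      pre <- NA_real_; prod <- NA_real_; ann_ok <- NA
    }
    ce <- collision_energy(row$precursor_mz, 2L)
    mass_ok <- if (row$mass_verifiable) {
      abs(pre - row$precursor_mz) <= mz_tol &&
        abs(prod - row$product_mz) <= mz_tol && isTRUE(ann_ok)
    } else NA
    data.frame(species = row$species, sequence = row$sequence,
               computed_precursor = pre, computed_product = prod,
               computed_ce = ce,
               mass_pass = mass_ok,
               ce_pass = abs(ce - row$ce) <= ce_tol,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
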
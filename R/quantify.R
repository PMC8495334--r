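#' Binary-mixture calibration design
#'
#' The mass fractions of the target species in a two-species dilution
#' series. The default six-level design (0, 20, 40, 60, 80, 100 percent
#' target in background) is the standard layout for meat-adulteration
#' standard curves.
#'
#' @param target,background Species labels.
#' @param fractions Strictly increasing target mass fractions in [0, 1],
#'   at least three levels.
#' @return Object of class \code{mixture_design}.
#' @export
mixture_design <- function(target, background,
                           fractions = c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
  if (length(fractions) < 3L) stop("need >= 3 design levels")
  if (any(fractions < 0 | fractions > 1)) stop("fractions must be in [0, 1]")
  if (any(diff(fractions) <= 0)) stop("fractions must be strictly increasing")
  structure(list(target = target, background = background,
                 fractions = fractions),
            class = "mixture_design")
}

#' Fit a linear standard curve
#'
#' Ordinary least squares of transition intensity on target mass fraction,
#' one curve per peptide. Replicates at a level are averaged before the
#' fit by default (set \code{average_replicates = FALSE} to fit all
#' points). R-squared is the squared correlation of fitted and observed
#' intensities; the residual standard deviation uses n - 2 degrees of
#' freedom.
#'
#' @param design \code{mixture_design}.
#' @param intensities Numeric vector (one per level, or stacked
#'   level-major replicates), or a matrix/data.frame with one row per
#'   level and one column per replicate.
#' @param peptide Marker peptide sequence the curve belongs to.
#' @param average_replicates Average replicate intensities per level
#'   before fitting.
#' @return Object of class \code{standard_curve}: slope, intercept,
#'   r_squared, residual_sd, n_points, target, background, peptide.
#' @examples
#' d <- mixture_design("pork", "beef")
#' fit_standard_curve(d, 1000 * d$fractions, "VNVDEVGGEALGR")
#' @export
fit_standard_curve <- function(design, intensities, peptide,
                               average_replicates = TRUE) {
  x <- design$fractions
  if (is.matrix(intensities) || is.data.frame(intensities)) {
    intensities <- as.matrix(intensities)
    if (nrow(intensities) != length(x))
      stop("intensity matrix must have one row per design level")
    if (average_replicates) {
      y <- rowMeans(intensities)
    } else {
      y <- as.vector(t(intensities))
      x <- rep(x, each = ncol(intensities))
    }
  } else {
    if (length(intensities) == length(x)) {
      y <- as.numeric(intensities)
    } else if (length(intensities) %% length(x) == 0L) {
      reps <- length(intensities) / length(x)
      m <- matrix(intensities, nrow = length(x), byrow = TRUE)
      if (average_replicates) {
        y <- rowMeans(m)
      } else {
        y <- as.vector(t(m))
        x <- rep(x, each = reps)
      }
    } else {
      stop("intensity length is not a multiple of the number of levels")
    }
  }
  if (length(unique(x)) < 2L || stats::var(x) == 0)
    stop("degenerate design: no variance in fractions")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(
    target = design$target, background = design$background,
    peptide = peptide,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    residual_sd = sqrt(ss_res / (length(y) - 2L)),
    slope_se = sqrt(ss_res / (length(y) - 2L)) /
      sqrt(sum((x - mean(x))^2)),
    n_points = length(y),
    x_mean = mean(x), x_ss = sum((x - mean(x))^2)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve: %s in %s (%s)\n  intensity = %.4g * fraction + %.4g   R2 = %.4f  (n = %d)\n",
    x$target, x$background, x$peptide, x$slope, x$intercept,
    x$r_squared, x$n_points))
  invisible(x)
}

#' Inverse prediction of an adulterant fraction
#'
#' Inverts the standard curve at an observed intensity:
#' \code{(I - intercept) / slope}, clipped to [0, 1] with the clipping
#' flagged. The interval is the first-order inverse-prediction interval
#' from the curve's residual standard deviation.
#'
#' @param curve \code{standard_curve}.
#' @param intensity Observed transition intensity.
#' @param level Confidence level for the interval.
#' @return List: \code{fraction}, \code{lower}, \code{upper},
#'   \code{clipped}.
#' @export
estimate_fraction <- function(curve, intensity, level = 0.95) {
  if (abs(curve$slope) < 1e-12)
    stop("curve slope is (near) zero; fraction is unquantifiable")
  raw <- (intensity - curve$intercept) / curve$slope
  # se of x0 for a single new observation (first-order delta method)
  tq <- stats::qt(1 - (1 - level) / 2, df = max(curve$n_points - 2L, 1L))
  se <- (curve$residual_sd / abs(curve$slope)) *
    sqrt(1 + 1 / curve$n_points + (raw - curve$x_mean)^2 / curve$x_ss)
  est <- min(max(raw, 0), 1)
  list(fraction = est,
       lower = min(max(raw - tq * se, 0), 1),
       upper = min(max(raw + tq * se, 0), 1),
       clipped = raw < 0 || raw > 1)
}

#' Consensus fraction across a species' marker panel
#'
#' Median of the per-peptide estimates, with the median absolute
#' deviation as spread. The median keeps a single interfered peptide from
#' dragging the call, which is the point of carrying several markers per
#' species.
#'
#' @param estimates Numeric vector of per-peptide fraction estimates
#'   (length >= 1).
#' @return List: \code{fraction} (median), \code{spread} (MAD),
#'   \code{n}.
#' @export
consensus_estimate <- function(estimates) {
  estimates <- estimates[!is.na(estimates)]
  if (!length(estimates)) stop("no estimates available for consensus")
  list(fraction = stats::median(estimates),
       spread = stats::mad(estimates, constant = 1),
       n = length(estimates))
}

#' Calibration-based limit of detection
#'
#' The standard 3.3 * sigma_blank / slope rule: the smallest target
#' fraction whose expected signal clears the blank noise. Clipped to
#' [0, 1].
#'
#' @param curve \code{standard_curve} with positive slope.
#' @param blanks Numeric vector of blank (0 percent target) intensities,
#'   length >= 3.
#' @return LOD as a mass fraction.
#' @export
lod_estimate <- function(curve, blanks) {
  if (length(blanks) < 3L) stop("need >= 3 blank replicates")
  if (curve$slope <= 0)
    stop("non-positive slope; LOD is unquantifiable")
  min(3.3 * stats::sd(blanks) / curve$slope, 1)
}

#' Detection threshold from blank replicates
#'
#' mean(blank) + 3 * sd(blank), the default per-transition decision rule
#' for calling a species present.
#'
#' @param blanks Numeric vector of blank intensities.
#' @return Intensity threshold.
#' @export
detection_threshold <- function(blanks) {
  mean(blanks) + 3 * stats::sd(blanks)
}

#' Screen a sample for contaminating species
#'
#' For each species in the transition panel: flags detection when any of
#' its marker transitions exceeds its blank-derived threshold, lists the
#' supporting peptides, and (when a standard curve is available) reports
#' the consensus fraction across detected markers.
#'
#' @param sample Named numeric vector of observed intensities, names
#'   formatted \code{"species:sequence"} (one per transition).
#' @param panel Transition data.frame (\code{species}, \code{sequence}
#'   columns used).
#' @param curves Named list of \code{standard_curve} objects, names
#'   \code{"species:sequence"}; may be incomplete or NULL.
#' @param thresholds Named numeric vector of per-transition detection
#'   thresholds (same names as \code{sample}); transitions without a
#'   threshold use \code{default_threshold}.
#' @param default_threshold Fallback intensity threshold (0 = any signal).
#' @return data.frame, one row per species: \code{species},
#'   \code{detected}, \code{fraction} (NA without curves),
#'   \code{spread}, \code{n_supporting}, \code{supporting}
#'   (";"-collapsed peptide list).
#' @export
detect_contaminant <- function(sample, panel, curves = NULL,
                               thresholds = NULL, default_threshold = 0) {
  species <- sort(unique(panel$species))
  rows <- lapply(species, function(sp) {
    seqs <- panel$sequence[panel$species == sp]
    ids <- paste0(sp, ":", seqs)
    obs <- sample[ids]
    names(obs) <- ids
    thr <- rep(default_threshold, length(ids))
    if (!is.null(thresholds)) {
      have <- ids %in% names(thresholds)
      thr[have] <- thresholds[ids[have]]
    }
    hit <- !is.na(obs) & obs > thr
    ests <- numeric(0)
    if (any(hit) && !is.null(curves)) {
      for (id in ids[hit]) {
        cv <- curves[[id]]
        if (!is.null(cv))
          ests <- c(ests, estimate_fraction(cv, sample[[id]])$fraction)
      }
    }
    cons <- if (length(ests)) consensus_estimate(ests) else NULL
    data.frame(
      species = sp, detected = any(hit),
      fraction = if (is.null(cons)) NA_real_ else cons$fraction,
      spread = if (is.null(cons)) NA_real_ else cons$spread,
      n_supporting = sum(hit),
      supporting = paste(seqs[hit], collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
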
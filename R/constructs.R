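#' Nucleosome labeling construct specification
#'
#' Describes a dye-labeled mononucleosome construct: where the donor (Cy3)
#' sits on the histone octamer, where the acceptor (Cy5) sits on the DNA,
#' whether the DNA carries a translocation-blocking 2-nt ssDNA gap, and the
#' geometry needed to interpret FRET changes during remodeling.
#'
#' The construct name follows the field convention
#' `"<donor>/[<placement>,<offset>]"`, e.g. `"H2A/[end,+6]"`: Cy3 on histone
#' H2A, Cy5 at the end of the linker DNA 6 bp outside the nucleosome edge.
#' Backbone placements may have negative offsets (inside the nucleosome).
#'
#' @param name Text identifier, e.g. `"H2A/[end,+6]"`.
#' @param donor_site One of `"H2A"`, `"H2B"`, `"H3"`.
#' @param acceptor_placement `"end"` (linker DNA terminus) or `"backbone"`
#'   (internal sugar-phosphate backbone label).
#' @param offset Signed integer bp of the acceptor site relative to the
#'   nucleosome edge. End placements must be >= 0 (outside the nucleosome);
#'   backbone placements may be negative (inside).
#' @param gap `"none"`, `"SHL-2"`, or `"SHL+2"`. A gap at SHL-2 blocks
#'   ATPase engagement there and forces exit-side movement; a gap at SHL+2
#'   forces entry-side movement.
#' @param initial_linker_bp Non-negative integer, length of the short linker.
#' @param movement_bias Probability in \[0,1\] that an enzyme engagement
#'   produces entry-side movement (ignored when a gap forces the direction).
#' @param invert_classification Logical; `TRUE` for constructs (such as
#'   H2A/\[backbone,-15\]) where the FRET geometry inverts the rise/monotone
#'   to entry/exit mapping.
#' @param classification_threshold FRET rise threshold used when classifying
#'   traces of this construct (0.1 for end-labeled constructs, 0.07 for
#'   H2A/\[backbone,-15\]).
#' @param fret_gate Population gate applied to the initial FRET value:
#'   either a single lower bound or a length-2 window `c(lo, hi)`; `NULL`
#'   means no gate configured (rejected by [select_population()]).
#' @param final_fret FRET level of the fully remodeled product (0 for
#'   exit-side products with the dye far from the octamer; ~0.17 for
#'   entry-side products parked at the SHL-2 site).
#'
#' @return An object of class `construct_spec`.
#' @seealso [construct_registry()] for the built-in constructs.
#' @export
construct_spec <- function(name,
                           donor_site = c("H2A", "H2B", "H3"),
                           acceptor_placement = c("end", "backbone"),
                           offset = 6L,
                           gap = c("none", "SHL-2", "SHL+2"),
                           initial_linker_bp = 6L,
                           movement_bias = 0.5,
                           invert_classification = FALSE,
                           classification_threshold = 0.1,
                           fret_gate = NULL,
                           final_fret = 0) {
  donor_site <- match.arg(donor_site)
  acceptor_placement <- match.arg(acceptor_placement)
  gap <- match.arg(gap)
  offset <- as.integer(offset)
  if (acceptor_placement == "end" && offset < 0L) {
    stop("end-labeled acceptor offsets must be >= 0 (outside the nucleosome)")
  }
  if (!is.numeric(movement_bias) || movement_bias < 0 || movement_bias > 1) {
    stop("movement_bias must lie in [0, 1]")
  }
  if (initial_linker_bp < 0) stop("initial_linker_bp must be non-negative")
  structure(
    list(
      name = name,
      donor_site = donor_site,
      acceptor_placement = acceptor_placement,
      offset = offset,
      gap = gap,
      initial_linker_bp = as.integer(initial_linker_bp),
      movement_bias = movement_bias,
      invert_classification = isTRUE(invert_classification),
      classification_threshold = classification_threshold,
      fret_gate = fret_gate,
      final_fret = final_fret
    ),
    class = "construct_spec"
  )
}

#' @export
print.construct_spec <- function(x, ...) {
  gap <- if (x$gap == "none") "no gap" else paste("gap at", x$gap)
  cat(sprintf(
    "<construct_spec> %s (donor %s, acceptor %s%+d bp, %s, linker %d bp)\n",
    x$name, x$donor_site, x$acceptor_placement, x$offset, gap,
    x$initial_linker_bp
  ))
  invisible(x)
}

#' Registry of the study's nucleosome constructs
#'
#' Returns the named list of built-in [construct_spec()] objects covering
#' the labeling schemes used in the remodeling experiments, including the
#' octamer-octamer photophysics controls (H2A/H2A, H2B/H2B) and the
#' ssDNA-gap variants of the H2A/\[end,+6\] construct.
#'
#' @return Named list of `construct_spec` objects.
#' @export
construct_registry <- function() {
  reg <- list(
    construct_spec("H2A/[end,+6]", "H2A", "end", 6L,
                   initial_linker_bp = 6L, final_fret = 0.17),
    construct_spec("H3/[end,+6]", "H3", "end", 6L,
                   initial_linker_bp = 6L, final_fret = 0.17),
    construct_spec("H2A/[backbone,+6]", "H2A", "backbone", 6L,
                   initial_linker_bp = 6L, final_fret = 0.17),
    construct_spec("H2A/[end,+11]", "H2A", "end", 11L,
                   initial_linker_bp = 11L, final_fret = 0.17),
    construct_spec("H2A/[end,+12]", "H2A", "end", 12L,
                   initial_linker_bp = 12L, final_fret = 0.17),
    construct_spec("H3/[end,+9]", "H3", "end", 9L,
                   initial_linker_bp = 9L, final_fret = 0.17),
    construct_spec("H2B/[end,+0]", "H2B", "end", 0L,
                   initial_linker_bp = 0L, final_fret = 0.17),
    construct_spec("H2A/[backbone,-15]", "H2A", "backbone", -15L,
                   initial_linker_bp = 6L, invert_classification = TRUE,
                   classification_threshold = 0.07, final_fret = 0.23),
    construct_spec("H2A/[end,+6]/gapSHL-2", "H2A", "end", 6L, gap = "SHL-2",
                   initial_linker_bp = 6L, final_fret = 0),
    construct_spec("H2A/[end,+6]/gapSHL+2", "H2A", "end", 6L, gap = "SHL+2",
                   initial_linker_bp = 6L, final_fret = 0.17),
    # octamer-octamer controls gated by FRET, not remodeling substrates
    construct_spec("H2A/H2A", "H2A", "end", 0L, fret_gate = 0.2,
                   final_fret = 0.5),
    construct_spec("H2B/H2B", "H2B", "end", 0L, fret_gate = 0.1,
                   final_fret = 0.2)
  )
  names(reg) <- vapply(reg, `[[`, character(1), "name")
  reg
}

#' Published no-enzyme calibration slopes (FRET per bp)
#'
#' Magnitudes of the linear FRET-versus-linker-length calibration slopes for
#' the five constructs with measured calibration curves, as fitted on free
#' (enzyme-unbound) nucleosomes. Used by default when converting FRET step
#' sizes to base pairs.
#'
#' @return Named numeric vector of slope magnitudes with a `"se"` attribute
#'   carrying the standard errors.
#' @export
reference_slopes <- function() {
  s <- c(
    "H2A/[end,+6]"      = 0.053,
    "H3/[end,+6]"       = 0.059,
    "H2A/[backbone,+6]" = 0.057,
    "H2A/[end,+12]"     = 0.055,
    "H3/[end,+9]"       = 0.048
  )
  attr(s, "se") <- c(0.004, 0.005, 0.002, 0.002, 0.004)
  s
}

#' Linear FRET-versus-linker-length calibration curve
#'
#' A calibration curve maps linker DNA length (bp) to mean FRET through a
#' straight line `FRET = intercept + slope * L`. Its slope magnitude converts
#' FRET step sizes to bp, and its FRET range defines where step detection is
#' trusted (plateaus outside the linear range are discarded).
#'
#' @param slope FRET change per bp (signed as fitted; conversions use the
#'   magnitude).
#' @param intercept FRET at zero linker length.
#' @param fret_range Length-2 numeric, the valid FRET interval spanned by the
#'   calibration points; defaults to \[0, 1\].
#' @param slope_se,intercept_se Standard errors (0 when exact).
#' @param points Optional data frame of calibration points
#'   (`linker_bp`, `mean_fret`, `sd_fret`).
#' @param enzyme_bound Logical; whether the calibration was measured on
#'   enzyme-bound nucleosomes.
#'
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept, fret_range = c(0, 1),
                              slope_se = 0, intercept_se = 0,
                              points = NULL, enzyme_bound = FALSE) {
  stopifnot(is.finite(slope), length(fret_range) == 2)
  fret_range <- sort(as.numeric(fret_range))
  if (fret_range[1] < 0 || fret_range[2] > 1) {
    stop("fret_range must lie within [0, 1]")
  }
  structure(
    list(
      slope = slope, intercept = intercept, fret_range = fret_range,
      slope_se = slope_se, intercept_se = intercept_se,
      points = points, enzyme_bound = isTRUE(enzyme_bound)
    ),
    class = "calibration_curve"
  )
}

#' Predict mean FRET from linker length
#'
#' @param calibration A [calibration_curve()].
#' @param linker_bp Linker lengths in bp.
#' @return Predicted FRET values.
#' @export
calibration_predict <- function(calibration, linker_bp) {
  stopifnot(inherits(calibration, "calibration_curve"))
  calibration$intercept + calibration$slope * linker_bp
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> slope %.4f +/- %.4f FRET/bp, intercept %.3f, range [%.3f, %.3f]%s\n",
    x$slope, x$slope_se, x$intercept, x$fret_range[1], x$fret_range[2],
    if (x$enzyme_bound) ", enzyme-bound" else ""
  ))
  invisible(x)
}
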
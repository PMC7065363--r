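#' Refractive-index to buoyant-density calibration
#'
#' Affine calibration `density = slope * nD + intercept` mapping a
#' refractometer reading to CsCl buoyant density (g/ml). The defaults are
#' the standard linearization used by SIP fractionation protocols for CsCl
#' gradients read on an AR200-type refractometer; both constants are
#' configuration, not fixed behaviour, and should be replaced with the
#' values of the refractometer/gradient medium actually in use.
#'
#' @param slope Density change per refractive-index unit (g/ml per RI).
#' @param intercept Density at nD = 0 (g/ml).
#' @return An object of class `density_calibration`.
#' @export
density_calibration <- function(slope = 10.9276, intercept = -13.593) {
  if (length(slope) != 1L || !is.finite(slope) || slope == 0) {
    stop("calibration error: slope must be a non-zero finite number",
         call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept),
            class = "density_calibration")
}

#' Convert refractive-index readings to CsCl buoyant densities
#'
#' @param refractive_index Numeric vector of refractometer readings (nD).
#' @param calibration A [density_calibration()].
#' @param sanity_window Readings outside this interval trigger a warning
#'   (typo guard), never an error.
#' @return Numeric vector of densities in g/ml.
#' @examples
#' ri_to_density(1.4040) # ~1.74935 g/ml with the default calibration
#' @export
ri_to_density <- function(refractive_index,
                          calibration = density_calibration(),
                          sanity_window = c(1.3, 1.5)) {
  stopifnot(inherits(calibration, "density_calibration"))
  out_of_window <- refractive_index < sanity_window[1] |
    refractive_index > sanity_window[2]
  if (any(out_of_window, na.rm = TRUE)) {
    warning(sum(out_of_window, na.rm = TRUE),
            " refractive-index reading(s) outside the sanity window [",
            sanity_window[1], ", ", sanity_window[2],
            "]; check for transcription errors", call. = FALSE)
  }
  calibration$slope * refractive_index + calibration$intercept
}

#' Density windows defining heavy and light fractions
#'
#' The defaults (heavy 1.725-1.735, light 1.705-1.720 g/ml) bracket the
#' typical banding densities of 13C-labelled and unlabelled DNA in CsCl;
#' both windows are inclusive at both ends and fully configurable because
#' which of the collected fractions count as heavy or light is a
#' per-gradient decision.
#'
#' @param heavy_min,heavy_max Heavy window bounds (g/ml).
#' @param light_min,light_max Light window bounds (g/ml).
#' @return An object of class `fraction_thresholds`.
#' @export
fraction_thresholds <- function(heavy_min = 1.725, heavy_max = 1.735,
                                light_min = 1.705, light_max = 1.720) {
  if (heavy_min > heavy_max || light_min > light_max) {
    stop("configuration error: each density window must be non-empty",
         call. = FALSE)
  }
  if (light_max > heavy_min) {
    stop("configuration error: light and heavy density windows overlap (",
         "light_max = ", light_max, " > heavy_min = ", heavy_min, ")",
         call. = FALSE)
  }
  structure(list(heavy_min = heavy_min, heavy_max = heavy_max,
                 light_min = light_min, light_max = light_max),
            class = "fraction_thresholds")
}

#' Designate gradient fractions as heavy, light or discard
#'
#' Every fraction receives exactly one label: `heavy` if its density lies in
#' the heavy window, `light` if in the light window, `discard` otherwise
#' (including the between-window densities routinely dropped when pooling).
#'
#' @param density Numeric vector of buoyant densities (g/ml), e.g. from
#'   [ri_to_density()].
#' @param thresholds A [fraction_thresholds()].
#' @return Character vector (`"heavy"`, `"light"`, `"discard"`) parallel to
#'   `density`.
#' @examples
#' designate_fractions(c(1.730, 1.710, 1.722))
#' @export
designate_fractions <- function(density,
                                thresholds = fraction_thresholds()) {
  stopifnot(inherits(thresholds, "fraction_thresholds"))
  out <- rep("discard", length(density))
  out[density >= thresholds$heavy_min & density <= thresholds$heavy_max] <- "heavy"
  out[density >= thresholds$light_min & density <= thresholds$light_max] <- "light"
  out
}

#' Annotate a fraction metadata table with densities and designations
#'
#' Convenience wrapper applying [ri_to_density()] and
#' [designate_fractions()] to a fraction metadata table (one row per
#' collected fraction; the protocol collects twelve per gradient).
#'
#' @param fractions Data frame with at least `refractive_index`; typically
#'   also `sample_id`, `gradient_id`, `fraction_index`.
#' @param calibration A [density_calibration()].
#' @param thresholds A [fraction_thresholds()].
#' @return The input with `density` and `designation` columns appended.
#' @export
annotate_fractions <- function(fractions,
                               calibration = density_calibration(),
                               thresholds = fraction_thresholds()) {
  if (!"refractive_index" %in% names(fractions)) {
    stop("fraction metadata must contain a 'refractive_index' column",
         call. = FALSE)
  }
  if ("fraction_index" %in% names(fractions) && "gradient_id" %in% names(fractions)) {
    dup <- duplicated(fractions[c("gradient_id", "fraction_index")])
    if (any(dup)) {
      stop("duplicate fraction_index within a gradient: row(s) ",
           paste(which(dup), collapse = ", "), call. = FALSE)
    }
  }
  fractions$density <- ri_to_density(fractions$refractive_index, calibration)
  fractions$designation <- designate_fractions(fractions$density, thresholds)
  fractions
}
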
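#' Observer visual model
#'
#' Bundles the parameters of the receptor-noise-limited (RNL) observer used
#' throughout the metric chain: peak cone sensitivities, spatial acuity,
#' viewing distance, Weber fractions and relative cone abundances. Defaults
#' describe a violet-sensitive (VS) avian predator viewing a dorsal pattern
#' at 5 m: single cones LW/MW/SW/VS plus a double cone carrying luminance.
#'
#' @param lambda_max Named numeric vector of peak sensitivities (nm) for the
#'   five channels, in the fixed channel order `LW, MW, SW, VS, DBL`.
#' @param acuity Spatial acuity in cycles per degree.
#' @param viewing_distance Viewing distance in mm.
#' @param weber_chromatic Weber fraction of the noisiest single-cone channel.
#' @param weber_luminance Weber fraction of the double-cone (luminance)
#'   channel.
#' @param abundances Relative abundances of the four single-cone classes;
#'   normalised to sum to 1. Channel noise is
#'   `weber_chromatic / sqrt(abundance_i / max(abundance))`, so equal
#'   abundances give every channel the stated Weber fraction.
#' @param floor_value Replacement value for non-positive cone catches.
#'
#' @return An object of class `viewer_model`.
#' @examples
#' v <- viewer_model()
#' v$acuity
#' @export
viewer_model <- function(lambda_max = c(LW = 610, MW = 545, SW = 475,
                                        VS = 415, DBL = 560),
                         acuity = 41,
                         viewing_distance = 5000,
                         weber_chromatic = 0.05,
                         weber_luminance = 0.05,
                         abundances = c(LW = 1, MW = 1, SW = 1, VS = 1) / 4,
                         floor_value = 0.001) {
  stopifnot(length(lambda_max) == 5L, all(lambda_max > 0),
            acuity > 0, viewing_distance > 0,
            weber_chromatic > 0, weber_luminance > 0,
            length(abundances) == 4L, all(abundances > 0),
            floor_value > 0)
  abundances <- abundances / sum(abundances)
  out <- list(lambda_max = lambda_max,
              acuity = acuity,
              viewing_distance = viewing_distance,
              weber_chromatic = weber_chromatic,
              weber_luminance = weber_luminance,
              abundances = abundances,
              floor_value = floor_value)
  class(out) <- "viewer_model"
  out
}

#' @export
print.viewer_model <- function(x, ...) {
  cat("RNL viewer model\n")
  cat("  lambda_max (nm):",
      paste(names(x$lambda_max), x$lambda_max, sep = "=", collapse = ", "),
      "\n")
  cat("  acuity:", x$acuity, "cpd at", x$viewing_distance, "mm\n")
  cat("  Weber fractions: chromatic", x$weber_chromatic,
      "luminance", x$weber_luminance, "\n")
  invisible(x)
}

# Per-channel noise for the single-cone (chromatic) channels.
receptor_noise <- function(viewer) {
  viewer$weber_chromatic / sqrt(viewer$abundances / max(viewer$abundances))
}
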
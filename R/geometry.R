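#' RED device and sample-preparation geometry
#'
#' Describes the volumes that govern a rapid equilibrium dialysis (RED)
#' experiment and the downstream protein-precipitation prep. The defaults
#' correspond to a single-use RED insert loaded with 200 uL plasma against
#' 333 uL PBS, a 25 uL post-dialysis aliquot made up with 25 uL of the
#' complementary matrix, 5 uL of 0.1% formic acid, 2.25 uL of internal
#' standard working solution and 170 uL acetonitrile, with the plasma
#' fraction further diluted 1:4 (one part sample + three parts water,
#' i.e. a factor of 4) before injection.
#'
#' @param v_plasma Plasma chamber volume (uL).
#' @param v_buffer Buffer chamber volume (uL).
#' @param v_aliquot Volume taken from each chamber after dialysis (uL).
#' @param v_complement Complementary matrix added to the aliquot (uL):
#'   blank plasma into the buffer aliquot, PBS into the plasma aliquot,
#'   so both fractions share one matrix background.
#' @param v_acid Acidification volume (uL).
#' @param v_is Internal-standard working-solution volume (uL).
#' @param v_acn Acetonitrile (precipitation) volume (uL).
#' @param plasma_post_dilution_factor Additional dilution factor applied to
#'   the plasma fraction before injection (the "1:4 with water" step,
#'   interpreted as a factor of 4; override if your lab reads 1:4 as 5).
#'
#' @return An object of class `red_geometry`.
#' @examples
#' geom <- red_geometry()
#' chamber_free_partition(geom)
#' dilution_chain("plasma", geom)
#' @export
red_geometry <- function(v_plasma = 200, v_buffer = 333,
                         v_aliquot = 25, v_complement = 25,
                         v_acid = 5, v_is = 2.25, v_acn = 170,
                         plasma_post_dilution_factor = 4) {
  vols <- c(v_plasma = v_plasma, v_buffer = v_buffer, v_aliquot = v_aliquot,
            v_complement = v_complement, v_acid = v_acid, v_is = v_is,
            v_acn = v_acn,
            plasma_post_dilution_factor = plasma_post_dilution_factor)
  if (any(!is.finite(vols)) || any(vols <= 0))
    stop("all RED geometry volumes and factors must be finite and > 0")
  structure(as.list(vols), class = "red_geometry")
}

#' @export
print.red_geometry <- function(x, ...) {
  cat("RED geometry (uL):\n")
  cat(sprintf("  chambers: plasma %g, buffer %g\n", x$v_plasma, x$v_buffer))
  cat(sprintf("  prep: aliquot %g + complement %g + acid %g + IS %g + ACN %g\n",
              x$v_aliquot, x$v_complement, x$v_acid, x$v_is, x$v_acn))
  cat(sprintf("  plasma post-dilution factor: %g\n",
              x$plasma_post_dilution_factor))
  sh <- chamber_free_partition(x)
  cat(sprintf("  free drug partition: %.1f%% plasma / %.1f%% buffer chamber\n",
              100 * sh[["plasma_share"]], 100 * sh[["buffer_share"]]))
  invisible(x)
}

#' Partition of the free drug amount between RED chambers
#'
#' At dialysis equilibrium the free drug concentration is identical on both
#' sides of the membrane, so the free *amount* splits in proportion to the
#' chamber volumes: with 200 uL plasma against 333 uL buffer, the plasma
#' chamber holds 37.5% and the buffer chamber 62.5% of the total free
#' amount (to printed precision; the exact shares are 200/533 and 333/533).
#'
#' @param geometry A [red_geometry()] object.
#' @return Named numeric vector with `plasma_share` and `buffer_share`,
#'   summing to 1.
#' @export
chamber_free_partition <- function(geometry = red_geometry()) {
  stopifnot(inherits(geometry, "red_geometry"))
  v_tot <- geometry$v_plasma + geometry$v_buffer
  c(plasma_share = geometry$v_plasma / v_tot,
    buffer_share = geometry$v_buffer / v_tot)
}

#' Dilution factor from chamber to injected sample
#'
#' Tracks the prep volume chain: a `v_aliquot` uL aliquot is brought to
#' `v_aliquot + v_complement + v_acid + v_is + v_acn` uL, and the plasma
#' fraction is additionally diluted by `plasma_post_dilution_factor`.
#' The injected concentration is the chamber concentration divided by this
#' factor. With default volumes the buffer factor is 227.25/25 = 9.09 and
#' the plasma factor 36.36.
#'
#' @param compartment `"plasma"` or `"buffer"`.
#' @param geometry A [red_geometry()] object.
#' @return Dimensionless dilution factor (>= 1 for physical volumes).
#' @export
dilution_chain <- function(compartment = c("plasma", "buffer"),
                           geometry = red_geometry()) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(geometry, "red_geometry"))
  v_final <- geometry$v_aliquot + geometry$v_complement + geometry$v_acid +
    geometry$v_is + geometry$v_acn
  base <- v_final / geometry$v_aliquot
  if (compartment == "plasma") base * geometry$plasma_post_dilution_factor
  else base
}
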
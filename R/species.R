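#' Gas-specific dry-deposition parameters
#'
#' Bundles the two compound-specific scaling factors of the resistance scheme
#' -- the effective Henry's law constant `H*` (solubility pathway) and the
#' biological reactivity `f0` (surface-reaction pathway) -- together with the
#' ratio of water-vapour to species diffusivity used for the stomatal and
#' quasi-laminar resistances.
#'
#' More soluble (higher `H*`) and/or more reactive (higher `f0`) gases deposit
#' faster because dissolution and reaction act as parallel uptake pathways.
#'
#' @param name Species label.
#' @param henry_const Effective Henry's law constant `H*` (M atm-1), `>= 0`.
#' @param reactivity Biological reactivity `f0`, dimensionless in `[0, 1]`.
#' @param diffusivity_ratio Ratio `D_H2O / D_x` (dimensionless, `> 0`).
#'   For a heavy gas this is approximately `sqrt(M_x / M_H2O)`.
#' @return An object of class `species_params`.
#' @examples
#' species_params("hg0", henry_const = 0.11, reactivity = 1e-5,
#'                diffusivity_ratio = sqrt(200.59 / 18.015))
#' @export
species_params <- function(name, henry_const, reactivity, diffusivity_ratio) {
  check_non_negative(henry_const, "henry_const")
  check_fraction(reactivity, "reactivity")
  check_positive(diffusivity_ratio, "diffusivity_ratio")
  structure(
    list(name = name,
         henry_const = henry_const,
         reactivity = reactivity,
         diffusivity_ratio = diffusivity_ratio),
    class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("<species_params> %s: H* = %g M atm-1, f0 = %g, D_H2O/D = %g\n",
              x$name, x$henry_const, x$reactivity, x$diffusivity_ratio))
  invisible(x)
}

#' Elemental mercury (Hg0) parameters
#'
#' `H* = 0.11` M atm-1; the default reactivity `f0 = 1e-5` corresponds to the
#' historical calibration against North American observations. Higher values
#' (`3e-5`, `9e-5`, `0.2`) correspond to calibrations against flux-tower
#' net-exchange and Amazon litterfall / total-foliar-uptake measurements.
#'
#' @param reactivity Biological reactivity `f0` for Hg0.
#' @return A `species_params` object.
#' @export
hg0_species <- function(reactivity = 1e-5) {
  species_params("Hg0", henry_const = 0.11, reactivity = reactivity,
                 diffusivity_ratio = sqrt(200.59 / 18.015))
}

#' Gaseous divalent mercury (Hg2+) parameters
#'
#' Biologically unreactive (`f0 = 0`) but extremely soluble
#' (`H* = 1e14` M atm-1), so its surface resistance collapses to near zero.
#'
#' @return A `species_params` object.
#' @export
hg2_species <- function() {
  species_params("Hg2+", henry_const = 1e14, reactivity = 0,
                 diffusivity_ratio = sqrt(271 / 18.015))
}
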
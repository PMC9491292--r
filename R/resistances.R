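# Resistance-in-series dry deposition: v_d = 1 / (Ra + Rb + Rc), with the
# surface resistance Rc the parallel combination of stomatal+mesophyll,
# cuticular, lower-canopy and ground pathways. Blocked pathways are the
# IEEE Inf sentinel; 1/Inf = 0 implements the harmonic combination without
# special-casing.

BLOCKED <- Inf

.params_cache <- new.env(parent = emptyenv())

#' Seasonal baseline surface resistances per land category
#'
#' Reads the versioned baseline table (5 seasonal classes x 11 land
#' categories) of minimum stomatal, cuticular, in-canopy aerodynamic,
#' ground and lower-canopy resistances for the SO2 and O3 reference gases.
#' The sentinel 9999 in the file is converted to `Inf` (blocked pathway).
#'
#' @param path Optional path to an alternative baseline CSV with the same
#'   header; defaults to the table shipped with the package.
#' @return A tibble with columns `season`, `category_id`, `ri`, `rlu`,
#'   `rac`, `rgs_so2`, `rgs_o3`, `rcl_so2`, `rcl_o3` (s m-1).
#' @export
land_category_params <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.params_cache$default)) return(.params_cache$default)
    path <- system.file("extdata", "surface_resistance_baselines.csv",
                        package = "hgdep", mustWork = TRUE)
    default <- TRUE
  } else {
    default <- FALSE
  }
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE) |>
    mutate(across(c("ri", "rlu", "rac", "rgs_so2", "rgs_o3", "rcl_so2", "rcl_o3"),
                  ~ ifelse(.x >= 9999, BLOCKED, .x)))
  stopifnot(nrow(tbl) == length(unique(tbl$season)) * length(unique(tbl$category_id)))
  if (default) .params_cache$default <- tbl
  tbl
}

#' Aerodynamic resistance Ra
#'
#' Turbulent transfer resistance between the reference height and the
#' roughness height, `Ra = (ln(zref/z0) - psi_h) / (k u*)` with the
#' Businger-Dyer stability correction `psi_h`; `stability = zref/L = 0`
#' gives the neutral limit `psi_h = 0`.
#'
#' @param friction_velocity Friction velocity `u*` (m s-1), `> 0`.
#' @param z0 Roughness length (m), `> 0`.
#' @param zref Reference height (m), `>= z0`.
#' @param stability Monin-Obukhov stability parameter `zref/L`
#'   (negative = unstable, 0 = neutral, positive = stable).
#' @return Ra (s m-1), floored at 0.
#' @examples
#' aerodynamic_resistance(0.4, z0 = 1, zref = 10)  # ln(10)/0.16 ~ 14.39
#' @export
aerodynamic_resistance <- function(friction_velocity, z0, zref = 10, stability = 0) {
  check_positive(friction_velocity, "friction_velocity")
  check_positive(z0, "z0")
  if (any(zref < z0)) abort("`zref` must be at least `z0`.")
  psi <- psi_h(stability)
  pmax(0, (log(zref / z0) - psi) / (VON_KARMAN * friction_velocity))
}

# Businger-Dyer integrated stability correction for heat/scalars.
# Positive in unstable conditions (reduces Ra), negative when stable.
psi_h <- function(zeta) {
  zeta <- pmin(pmax(zeta, -10), 10)
  out <- numeric(length(zeta))
  un <- zeta < 0
  if (any(un)) {
    x2 <- sqrt(1 - 16 * zeta[un])
    out[un] <- 2 * log((1 + x2) / 2)
  }
  st <- zeta > 0
  out[st] <- -5 * zeta[st]
  out
}

#' Schmidt/Prandtl number ratio for a species
#'
#' `Sc_x / Pr = (Sc_H2O / Pr) * (D_H2O / D_x)`, the factor entering the
#' quasi-laminar boundary resistance.
#'
#' @param species A [species_params()] object.
#' @return Dimensionless `Sc/Pr`.
#' @export
schmidt_prandtl <- function(species) {
  (SCHMIDT_H2O / PRANDTL_AIR) * species$diffusivity_ratio
}

#' Quasi-laminar boundary resistance Rb
#'
#' `Rb = (2 / (k u*)) (Sc/Pr)^(2/3)`. A vanishing friction velocity means no
#' turbulent transfer: the pathway is blocked (`Inf`).
#'
#' @param friction_velocity Friction velocity `u*` (m s-1), `>= 0`.
#' @param sc_pr Schmidt-to-Prandtl number ratio, e.g. [schmidt_prandtl()].
#' @return Rb (s m-1).
#' @examples
#' boundary_resistance(0.4, sc_pr = 1)  # 12.5 s m-1
#' @export
boundary_resistance <- function(friction_velocity, sc_pr) {
  check_non_negative(friction_velocity, "friction_velocity")
  check_positive(sc_pr, "sc_pr")
  ifelse(friction_velocity == 0, BLOCKED,
         2 / (VON_KARMAN * friction_velocity) * sc_pr^(2 / 3))
}

#' Mesophyll resistance
#'
#' `Rm = 1 / (H*/3000 + 100 f0)`: dissolution into and reaction within the
#' leaf interior act in parallel. An inert, insoluble gas has a blocked
#' mesophyll pathway.
#'
#' @param species A [species_params()] object.
#' @return Rm (s m-1).
#' @examples
#' mesophyll_resistance(hg0_species())  # ~ 964 s m-1
#' @export
mesophyll_resistance <- function(species) {
  .mesophyll(species$henry_const, species$reactivity)
}

.mesophyll <- function(henry, f0) {
  1 / (henry / 3000 + 100 * f0)
}

#' Bulk stomatal resistance
#'
#' Minimum stomatal resistance `ri` scaled up at low light and non-optimal
#' leaf temperature, adjusted for the species diffusivity and divided by LAI
#' (a canopy of parallel leaves). Stomata are closed (blocked pathway) at
#' night, outside the 0-40 degC leaf temperature window, at zero LAI, or for
#' categories without vegetation (`ri = Inf`).
#'
#' @param ri Minimum bulk stomatal resistance for the category/season (s m-1).
#' @param solar_radiation Downward solar radiation G (W m-2).
#' @param surface_temp Surface/leaf temperature (K).
#' @param lai Leaf area index (dimensionless, `>= 0`).
#' @param species A [species_params()] object.
#' @return Rs (s m-1).
#' @export
stomatal_resistance <- function(ri, solar_radiation, surface_temp, lai, species) {
  check_non_negative(lai, "lai")
  check_non_negative(solar_radiation, "solar_radiation")
  .stomatal(ri, solar_radiation, surface_temp, lai, species$diffusivity_ratio)
}

.stomatal <- function(ri, g, tsurf, lai, diff_ratio) {
  tc <- tsurf - 273.15
  open <- is.finite(ri) & g > 0 & tc > 0 & tc < 40 & lai > 0
  rs <- rep(BLOCKED, length(open))
  if (any(open)) {
    rs[open] <- ri[open] * (1 + (200 / (g[open] + 0.1))^2) *
      (400 / (tc[open] * (40 - tc[open]))) * diff_ratio / lai[open]
  }
  rs
}

#' Cuticular resistance scaled by species and LAI
#'
#' `Rlu = rlu_base / (1e-5 H* + f0) / lai`: solubility and reactivity open
#' the leaf-surface pathway in parallel; more leaf area exposes more surface.
#' `f0 = 0` with `H* = 0` blocks the pathway (sentinel, never a division
#' error), as does `lai = 0`.
#'
#' @param rlu_base Baseline cuticular resistance for the category/season (s m-1).
#' @param species A [species_params()] object.
#' @param lai Leaf area index; the default 1 gives the unscaled leaf value.
#' @return Rlu (s m-1).
#' @examples
#' cuticular_resistance(2000, hg0_species(reactivity = 0.2))  # ~ 1e4 s m-1
#' @export
cuticular_resistance <- function(rlu_base, species, lai = 1) {
  check_non_negative(lai, "lai")
  .cuticular(rlu_base, species$henry_const, species$reactivity, lai)
}

.cuticular <- function(rlu_base, henry, f0, lai) {
  denom <- 1e-5 * henry + f0
  out <- ifelse(is.finite(rlu_base) & denom > 0 & lai > 0,
                rlu_base / denom / lai, BLOCKED)
  out
}

#' Species-scaled combination of SO2/O3 reference resistances
#'
#' Ground and lower-canopy baselines are tabulated for the highly soluble
#' (SO2) and highly reactive (O3) reference gases; a species' value combines
#' them as `1 / (H*/(1e5 R_SO2) + f0/R_O3)`, strictly decreasing in both
#' `H*` and `f0`.
#'
#' @param r_so2,r_o3 Reference-gas baseline resistances (s m-1, `Inf` allowed).
#' @param species A [species_params()] object.
#' @return Scaled resistance (s m-1).
#' @export
reference_scaled_resistance <- function(r_so2, r_o3, species) {
  .ref_scaled(r_so2, r_o3, species$henry_const, species$reactivity)
}

.ref_scaled <- function(r_so2, r_o3, henry, f0) {
  term_s <- ifelse(is.finite(r_so2) & r_so2 > 0, henry / (1e5 * r_so2),
                   ifelse(is.infinite(r_so2), 0, BLOCKED))
  term_o <- ifelse(is.finite(r_o3) & r_o3 > 0, f0 / r_o3,
                   ifelse(is.infinite(r_o3), 0, BLOCKED))
  1 / (term_s + term_o)   # 1/0 -> Inf sentinel when both pathways closed
}

#' Lower-canopy resistance (Rdc + Rcl)
#'
#' Buoyant-convection transfer to the lower canopy,
#' `Rdc = 100 (1 + 1000/(G + 10))`, in series with the species-scaled
#' lower-canopy surface resistance.
#'
#' @param rcl_so2,rcl_o3 Lower-canopy baselines for the reference gases (s m-1).
#' @param solar_radiation Downward solar radiation G (W m-2).
#' @param species A [species_params()] object.
#' @return Rdc + Rcl (s m-1).
#' @export
lower_canopy_resistance <- function(rcl_so2, rcl_o3, solar_radiation, species) {
  check_non_negative(solar_radiation, "solar_radiation")
  rdc <- 100 * (1 + 1000 / (solar_radiation + 10))
  rdc + .ref_scaled(rcl_so2, rcl_o3, species$henry_const, species$reactivity)
}

#' Ground resistance (Rac + Rgs)
#'
#' In-canopy aerodynamic resistance in series with the species-scaled
#' soil/litter surface resistance.
#'
#' @param rac In-canopy aerodynamic baseline (s m-1).
#' @param rgs_so2,rgs_o3 Ground baselines for the reference gases (s m-1).
#' @param species A [species_params()] object.
#' @return Rac + Rgs (s m-1).
#' @export
ground_resistance <- function(rac, rgs_so2, rgs_o3, species) {
  rac + .ref_scaled(rgs_so2, rgs_o3, species$henry_const, species$reactivity)
}

#' Bulk surface resistance Rc from its parallel pathways
#'
#' `1/Rc = 1/(Rs+Rm) + 1/Rlu + 1/(Rdc+Rcl) + 1/(Rac+Rgs)`. Blocked (`Inf`)
#' pathways contribute nothing; all pathways blocked yields the `Inf`
#' sentinel.
#'
#' @param stomatal_mesophyll,cuticular,lower_canopy,ground Pathway
#'   resistances (s m-1, `>= 0` or `Inf`).
#' @return Rc (s m-1).
#' @export
surface_resistance <- function(stomatal_mesophyll, cuticular, lower_canopy, ground) {
  for (r in list(stomatal_mesophyll, cuticular, lower_canopy, ground)) {
    if (any(r < 0, na.rm = TRUE)) abort("surface pathway resistances must be >= 0.")
  }
  1 / (1 / stomatal_mesophyll + 1 / cuticular + 1 / lower_canopy + 1 / ground)
}

#' Dry-deposition velocity from a resistance triple
#'
#' `v_d = 1 / (Ra + Rb + Rc)` (m s-1); a blocked surface (`Rc = Inf`) gives
#' `v_d = 0`. The surface pathway can only slow deposition, so
#' `v_d <= 1/(Ra + Rb)` always.
#'
#' @param ra,rb Aerodynamic and boundary resistances (s m-1, finite).
#' @param rc Surface resistance (s m-1, `>= 0` or `Inf`).
#' @return v_d (m s-1).
#' @export
deposition_velocity <- function(ra, rb, rc) {
  check_non_negative(ra, "ra")
  check_non_negative(rb, "rb")
  ifelse(is.infinite(rc), 0, 1 / (ra + rb + rc))
}

#' Area-weighted grid-cell deposition velocity
#'
#' A grid cell containing several land-use categories gets the
#' area-fraction-weighted mean of the per-category velocities.
#'
#' @param vd Per-category deposition velocities (any single unit).
#' @param fraction Area fractions, `>= 0`, summing to 1 within `1e-6`.
#' @return The weighted cell velocity, same unit as `vd`.
#' @export
cell_velocity <- function(vd, fraction) {
  check_non_negative(fraction, "fraction")
  s <- sum(fraction)
  if (abs(s - 1) > 1e-6) {
    abort(sprintf("land-use fractions must sum to 1 (got %.8f).", s))
  }
  sum(vd * fraction)
}
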
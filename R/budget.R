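# Deposition budgets: velocity x concentration -> flux maps, regional
# Mg yr-1 integrals, land-cover-change scenario deltas, and the
# deforestation soil-source scaling.

#' Deposition flux map from a velocity map and a concentration field
#'
#' `F = v_d * C` with unit conversion (365-day year): `v_d` in cm s-1, `C`
#' in ng m-3, `F` in ug m-2 yr-1. Exactly inverse to [velocity_from_flux()].
#'
#' @param vd_map Tibble with `cell_id`, `vd_cm_s` (e.g. [annual_mean_vd()])
#'   and, for downstream budgets, `lat`, `lon`.
#' @param conc Either a single concentration (ng m-3) applied everywhere or
#'   a tibble `cell_id`, `conc_ng_m3`.
#' @return The input with `conc_ng_m3` and `flux_ug_m2_yr` columns.
#' @export
deposition_flux <- function(vd_map, conc) {
  check_columns(vd_map, c("cell_id", "vd_cm_s"), "vd_map")
  check_non_negative(vd_map$vd_cm_s, "vd_cm_s")
  if (is.numeric(conc) && length(conc) == 1) {
    out <- vd_map |> mutate(conc_ng_m3 = conc)
  } else {
    check_columns(conc, c("cell_id", "conc_ng_m3"), "conc")
    missing <- setdiff(vd_map$cell_id, conc$cell_id)
    if (length(missing) > 0) {
      abort(sprintf("concentration field missing cell(s): %s.",
                    paste(utils::head(missing, 3), collapse = ", ")))
    }
    out <- vd_map |> inner_join(conc |> select("cell_id", "conc_ng_m3"),
                                by = "cell_id")
  }
  check_positive(out$conc_ng_m3, "conc_ng_m3")
  out |>
    mutate(flux_ug_m2_yr = (.data$vd_cm_s / 100) * .data$conc_ng_m3 *
             SECONDS_PER_YEAR / 1e3)
}

#' Regional deposition budget
#'
#' Area integral of a flux map over a set of cells,
#' `sum(F * area) * 1e-12` Mg yr-1 (ug -> Mg exact).
#'
#' @param flux_map Tibble with `cell_id`, `flux_ug_m2_yr` and `area_m2`
#'   (join your grid areas in beforehand if absent).
#' @param cells Optional character vector of `cell_id`s defining the region;
#'   default all cells.
#' @return Budget in Mg yr-1.
#' @export
regional_budget <- function(flux_map, cells = NULL) {
  check_columns(flux_map, c("cell_id", "flux_ug_m2_yr", "area_m2"), "flux_map")
  if (!is.null(cells)) {
    missing <- setdiff(cells, flux_map$cell_id)
    if (length(missing) > 0) {
      abort(sprintf("region mask not aligned to flux map; unknown cell(s): %s.",
                    paste(utils::head(missing, 3), collapse = ", ")))
    }
    flux_map <- flux_map |> filter(.data$cell_id %in% cells)
  }
  sum(flux_map$flux_ug_m2_yr * flux_map$area_m2) * 1e-12
}

#' Deposition-budget change between two land-cover scenarios
#'
#' Recomputes the velocity field for a base and a scenario surface under the
#' same meteorology and species, converts both to deposition fluxes at a
#' fixed prescribed concentration field, and reports regional budgets and
#' their deltas (scenario minus base). Regions are taken from the surface
#' `region` column, plus `land` (all cells weighted by their non-water
#' fraction) and `total`. Optionally closes the loop through the three-box
#' model: the land-sink change rescales the Hg0 deposition rate, and the
#' re-equilibrated steady state gives the implied extra ocean deposition.
#'
#' @param surface_base,surface_scenario Surface tibbles on the same grid.
#' @param met Met tibble covering the same grid.
#' @param species A [species_params()] object.
#' @param conc Concentration (scalar ng m-3 or per-cell tibble), held fixed
#'   across scenarios.
#' @param box Optional [box_config()] (with `alpha` tuned beforehand) for the
#'   box-model-adjusted ocean estimate.
#' @param alpha Reduction coefficient used with `box`.
#' @param tropics_box Index of the box whose Hg0 deposition rate carries the
#'   land-sink change (default 2, the tropics).
#' @param ... Passed to [velocity_field()] (e.g. `ocean_vd`).
#' @return A tibble `region`, `base_Mg_yr`, `scenario_Mg_yr`, `delta_Mg_yr`.
#'   With `box`, an attribute `"box_adjustment"` holds a one-row tibble with
#'   the implied change in global ocean deposition and Hg0 burden.
#' @export
scenario_delta <- function(surface_base, surface_scenario, met, species, conc,
                           box = NULL, alpha = NULL, tropics_box = 2, ...) {
  base_cells <- sort(unique(surface_base$cell_id))
  scen_cells <- sort(unique(surface_scenario$cell_id))
  if (!identical(base_cells, scen_cells)) {
    abort("base and scenario surfaces must share one grid.")
  }
  areas <- surface_base |> distinct(.data$cell_id, .data$area_m2)
  land_frac <- surface_base |>
    mutate(water = .data$category_id == category_id_of("water")) |>
    group_by(.data$cell_id) |>
    summarise(land_fraction = sum(.data$fraction[!.data$water]),
              .groups = "drop")

  budget_of <- function(surface) {
    fmap <- velocity_field(met, surface, species, ...) |>
      annual_mean_vd() |>
      deposition_flux(conc) |>
      inner_join(areas, by = "cell_id") |>
      inner_join(land_frac, by = "cell_id")
    regions <- surface |> distinct(.data$cell_id, .data$region)
    by_region <- fmap |>
      inner_join(regions, by = "cell_id") |>
      filter(.data$region != "") |>
      group_by(.data$region) |>
      summarise(Mg_yr = sum(.data$flux_ug_m2_yr * .data$area_m2) * 1e-12,
                .groups = "drop")
    bind_rows(
      by_region,
      tibble(region = "land",
             Mg_yr = sum(fmap$flux_ug_m2_yr * fmap$area_m2 *
                           fmap$land_fraction) * 1e-12),
      tibble(region = "total",
             Mg_yr = sum(fmap$flux_ug_m2_yr * fmap$area_m2) * 1e-12))
  }
  base <- budget_of(surface_base) |> rename(base_Mg_yr = "Mg_yr")
  scen <- budget_of(surface_scenario) |> rename(scenario_Mg_yr = "Mg_yr")
  out <- full_join(base, scen, by = "region") |>
    mutate(delta_Mg_yr = .data$scenario_Mg_yr - .data$base_Mg_yr)

  if (!is.null(box)) {
    alpha <- alpha %||% box$alpha0
    land_base <- out$base_Mg_yr[out$region == "land"]
    land_scen <- out$scenario_Mg_yr[out$region == "land"]
    if (land_base <= 0) abort("box adjustment needs a positive base land sink.")
    cfg2 <- box
    cfg2$boxes$k_dep_hg0[tropics_box] <- cfg2$boxes$k_dep_hg0[tropics_box] *
      (land_scen / land_base)
    ocean_dep <- function(cfg) {
      st <- box_steady_state(cfg, alpha)
      sum((1 - cfg$boxes$land_frac) * cfg$boxes$k_dep_hg2 * st$hg2_Mg)
    }
    st_base <- box_steady_state(box, alpha)
    st_scen <- box_steady_state(cfg2, alpha)
    attr(out, "box_adjustment") <- tibble(
      ocean_dep_base_Mg_yr = ocean_dep(box),
      ocean_dep_scenario_Mg_yr = ocean_dep(cfg2),
      ocean_dep_delta_Mg_yr = ocean_dep(cfg2) - ocean_dep(box),
      hg0_burden_delta_Mg = sum(st_scen$hg0_Mg) - sum(st_base$hg0_Mg))
  }
  out
}

#' Soil Hg source from deforestation
#'
#' Scales a per-area first-year post-fire soil emission by an annual
#' deforestation rate: `Mg yr-1 = g ha-1 * ha yr-1 * 1e-6`.
#'
#' @param per_area_emission Soil emission after clearing (g Hg ha-1).
#' @param deforestation_rate Area cleared per year (ha yr-1).
#' @return Source strength (Mg yr-1).
#' @examples
#' soil_source_scaling(2.3, 1.3e6)  # ~ 3.0 Mg yr-1
#' @export
soil_source_scaling <- function(per_area_emission, deforestation_rate) {
  check_non_negative(per_area_emission, "per_area_emission")
  check_non_negative(deforestation_rate, "deforestation_rate")
  per_area_emission * deforestation_rate * 1e-6
}
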
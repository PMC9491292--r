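# Hourly deposition-velocity fields: seasonal class lookup, weekly-LAI
# interpolation, and the vectorised per-cell, per-hour evaluation of the
# resistance scheme over a met series and a surface map.

#' Seasonal resistance class from month and latitude
#'
#' Fixed lookup assigning one of the five seasonal baseline classes:
#' within the tropics (|lat| <= 20 degrees) vegetation is always lush
#' (class 1); elsewhere months map to midsummer (1), autumn (2), late
#' autumn/winter with no snow (3) or spring (5), with the Southern
#' Hemisphere shifted by six months. The snow class (4) is never assigned
#' (dry, snow-free scope).
#'
#' @param month Month of year (1..12).
#' @param lat Latitude (degrees).
#' @return Integer seasonal class in `{1, 2, 3, 5}`.
#' @export
season_class <- function(month, lat) {
  if (any(month < 1 | month > 12)) abort("`month` must be in 1..12.")
  lookup <- c(3, 3, 5, 5, 1, 1, 1, 1, 2, 2, 3, 3)   # NH Jan..Dec
  m <- ifelse(lat >= 0, month, (month + 5) %% 12 + 1)
  out <- lookup[m]
  out[abs(lat) <= 20] <- 1L
  as.integer(out)
}

#' Interpolate a weekly LAI series to a day of year
#'
#' Linear interpolation between week-centre values with wrap-around at the
#' year boundary; week k is centred on day `(k - 0.5) * 365/52`.
#'
#' @param lai_weekly Numeric vector of length 52.
#' @param doy (Fractional) day of year in `[0, 365]`.
#' @return Interpolated LAI (same length as `doy`).
#' @export
lai_at <- function(lai_weekly, doy) {
  if (length(lai_weekly) != 52) abort("`lai_weekly` must have length 52.")
  L <- matrix(lai_weekly, nrow = 1)
  .lai_interp(L, rep(1L, length(doy)), doy)
}

# Matrix version: L is (series x 52); row picks the series for each doy.
.lai_interp <- function(L, row, doy) {
  u <- doy / (365 / 52) + 0.5
  k0 <- floor(u)
  f <- u - k0
  wrap <- function(k) ((k - 1) %% 52) + 1
  L[cbind(row, wrap(k0))] * (1 - f) + L[cbind(row, wrap(k0 + 1))] * f
}

#' Hourly dry-deposition velocity field
#'
#' Evaluates the resistance-in-series scheme for every grid cell and hour:
#' aerodynamic and boundary resistances from the cell meteorology, surface
#' resistance per land category (seasonal baselines, species `H*`/`f0`
#' scaling, interpolated weekly LAI), and the area-weighted cell velocity.
#' Over the water category the scheme is not applied; an externally supplied
#' constant `ocean_vd` (default 0, i.e. air-sea exchange handled elsewhere)
#' is used instead.
#'
#' An optional `f0` column in `surface` overrides the species reactivity per
#' cell-category row (used for regionally calibrated reactivity).
#'
#' @param met Met tibble: `cell_id`, `time` (POSIXct UTC), `air_temp` (K),
#'   `surface_temp` (K), `friction_velocity` (m s-1), `solar_radiation`
#'   (W m-2), `cloud_fraction`, `pressure` (Pa), optional `stability_param`.
#' @param surface Surface tibble: `cell_id`, `lat`, `lon`, `z0` (m),
#'   `category_id`, `fraction`, `lai_weekly` (list of 52-vectors),
#'   optional `f0`.
#' @param species A [species_params()] object.
#' @param zref Reference height (m).
#' @param ocean_vd Deposition velocity over the water category (cm s-1).
#' @param params Baseline resistance table, see [land_category_params()].
#' @param detail If `TRUE`, return per-category rows (before area weighting).
#' @return A tibble `cell_id`, `time`, `vd_cm_s` (plus `lat`, `lon`);
#'   with `detail = TRUE` also `category_id`, `fraction` and the resistances.
#' @export
velocity_field <- function(met, surface, species, zref = 10, ocean_vd = 0,
                           params = land_category_params(), detail = FALSE) {
  check_columns(met, c("cell_id", "time", "air_temp", "surface_temp",
                       "friction_velocity", "solar_radiation"), "met")
  check_columns(surface, c("cell_id", "lat", "lon", "z0", "category_id",
                           "fraction", "lai_weekly"), "surface")
  only_met <- setdiff(unique(met$cell_id), unique(surface$cell_id))
  only_surf <- setdiff(unique(surface$cell_id), unique(met$cell_id))
  if (length(only_met) > 0 || length(only_surf) > 0) {
    abort(sprintf(
      "met and surface grids do not align on the cell axis (met-only: %s; surface-only: %s).",
      paste(utils::head(only_met, 3), collapse = ","),
      paste(utils::head(only_surf, 3), collapse = ",")))
  }
  check_fraction_sums(surface, "surface")

  cells <- surface |> distinct(.data$cell_id, .data$lat, .data$lon, .data$z0)
  m <- met |> inner_join(cells, by = "cell_id")
  if (!"stability_param" %in% names(m)) m$stability_param <- 0
  lt <- as.POSIXlt(m$time, tz = "UTC")
  m$doy <- lt$yday + 1 + lt$hour / 24
  m$season <- season_class(lt$mon + 1, m$lat)
  m$ra <- aerodynamic_resistance(m$friction_velocity, m$z0, zref,
                                 m$stability_param)
  m$rb <- boundary_resistance(m$friction_velocity, schmidt_prandtl(species))

  surf <- surface |> mutate(.sid = dplyr::row_number())
  L <- do.call(rbind, surf$lai_weekly)
  have_f0 <- "f0" %in% names(surf)
  df <- m |>
    select(-"lat", -"lon", -"z0") |>
    inner_join(surf |>
                 select(any_of(c("cell_id", "category_id", "fraction", ".sid", "f0"))),
               by = "cell_id", relationship = "many-to-many") |>
    left_join(params, by = c("category_id", "season"))
  if (anyNA(df$ri)) {
    abort("baseline resistances missing for some (category, season) pair.")
  }
  df$lai <- .lai_interp(L, df$.sid, df$doy)
  f0 <- if (have_f0) coalesce(df$f0, species$reactivity) else
    rep(species$reactivity, nrow(df))
  henry <- species$henry_const
  dr <- species$diffusivity_ratio

  rs <- .stomatal(df$ri, df$solar_radiation, df$surface_temp, df$lai, dr)
  rsm <- rs + .mesophyll(henry, f0)
  rlu <- .cuticular(df$rlu, henry, f0, df$lai)
  rdc_rcl <- 100 * (1 + 1000 / (df$solar_radiation + 10)) +
    .ref_scaled(df$rcl_so2, df$rcl_o3, henry, f0)
  rac_rgs <- df$rac + .ref_scaled(df$rgs_so2, df$rgs_o3, henry, f0)
  rc <- surface_resistance(rsm, rlu, rdc_rcl, rac_rgs)
  vd <- deposition_velocity(df$ra, df$rb, rc)
  water <- df$category_id == category_id_of("water")
  vd[water] <- ocean_vd / 100

  df$vd_m_s <- vd
  if (detail) {
    return(df |>
             mutate(rc = rc, vd_cm_s = 100 * .data$vd_m_s) |>
             select("cell_id", "time", "category_id", "fraction", "season",
                    "lai", "ra", "rb", "rc", "vd_cm_s"))
  }
  out <- df |>
    group_by(.data$cell_id, .data$time) |>
    summarise(vd_cm_s = 100 * sum(.data$fraction * .data$vd_m_s),
              .groups = "drop") |>
    inner_join(cells |> select("cell_id", "lat", "lon"), by = "cell_id")
  class(out) <- c("hg_vd_field", class(out))
  out
}

#' Annual (time) mean of a velocity field
#'
#' @param field Output of [velocity_field()].
#' @return A tibble `cell_id`, `lat`, `lon`, `vd_cm_s` (time mean),
#'   of class `hg_vd_map`.
#' @export
annual_mean_vd <- function(field) {
  check_columns(field, c("cell_id", "time", "vd_cm_s"), "field")
  out <- field |>
    group_by(.data$cell_id, .data$lat, .data$lon) |>
    summarise(vd_cm_s = mean(.data$vd_cm_s), .groups = "drop")
  class(out) <- c("hg_vd_map", class(out))
  out
}
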
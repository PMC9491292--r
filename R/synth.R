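# Synthetic inputs with the statistical structure the analysis assumes:
# diurnal/seasonal meteorology, a mixed land-use map with an Amazon-like
# rainforest block, a savanna reference block and coastal cells, and a site
# measurement database generated around a known true deposition velocity.
# All generators are deterministic given their mandatory seed (R's default
# Mersenne-Twister RNG).

#' Synthetic land-surface map
#'
#' A small rectangular domain with: an all-water western column, coastal
#' mixed water/land cells, an Amazon-like tropical rainforest block (region
#' `"amazon"`), a savanna reference block (region `"savanna_ref"`), and
#' latitude-banded temperate/boreal land uses. Every one of the 11
#' categories occurs somewhere; fractions are normalised per cell; weekly
#' LAI cycles follow the category defaults with a small seeded jitter.
#'
#' @param nlat,nlon Grid dimensions (at least 5 x 4).
#' @param seed Mandatory RNG seed.
#' @param lat_range,lon_range Domain bounds (degrees).
#' @return A surface tibble: `cell_id`, `region`, `lat`, `lon`, `area_m2`,
#'   `z0` (m), `category_id`, `fraction`, `lai_weekly` (list of 52-vectors).
#' @export
generate_surface <- function(nlat = 6, nlon = 6, seed,
                             lat_range = c(-34, 62), lon_range = c(-80, -20)) {
  if (missing(seed)) abort("`seed` is mandatory.")
  if (nlat < 5 || nlon < 4) abort("grid must be at least 5 x 4.")
  set.seed(seed)
  grid <- make_grid(res_lat = diff(lat_range) / nlat,
                    res_lon = diff(lon_range) / nlon,
                    lat_range = lat_range, lon_range = lon_range)
  lons <- sort(unique(grid$lon))
  east_interior <- lons[length(lons)]
  cats <- land_categories()
  water <- category_id_of("water")

  assign_cell <- function(lat, lon) {
    col <- match(lon, lons)
    if (col == 1) {
      return(list(primary = water, secondary = NA, p = 1, region = ""))
    }
    if (abs(lat) <= 14) {
      if (lon == east_interior) {
        main <- list(primary = category_id_of("savanna_grassland"),
                     secondary = category_id_of("shrubland"),
                     region = "savanna_ref")
      } else {
        main <- list(primary = category_id_of("tropical_rainforest"),
                     secondary = category_id_of("savanna_grassland"),
                     region = "amazon")
      }
    } else if (lat <= -14) {
      main <- list(primary = category_id_of("shrubland"),
                   secondary = category_id_of("barren"), region = "")
    } else if (lat <= 30) {
      main <- list(primary = category_id_of("cropland"),
                   secondary = category_id_of("mixed_agriculture"), region = "")
    } else if (lat <= 46) {
      main <- list(primary = category_id_of("deciduous_forest"),
                   secondary = category_id_of("cropland"), region = "")
    } else {
      main <- list(primary = category_id_of("coniferous_forest"),
                   secondary = category_id_of("wetland"), region = "")
    }
    if (col == 2) {       # coastal: water-dominated mixed cell
      return(list(primary = water, secondary = main$primary,
                  p = runif(1, 0.55, 0.75), region = ""))
    }
    c(main, list(p = runif(1, 0.8, 0.9)))
  }

  rows <- vector("list", nrow(grid))
  urban_done <- FALSE
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    a <- assign_cell(g$lat, g$lon)
    # one temperate interior cell is urban so all 11 categories occur
    if (!urban_done && a$region == "" && match(g$lon, lons) > 2 &&
        g$lat > 14 && g$lat <= 30) {
      a$primary <- category_id_of("urban")
      a$secondary <- category_id_of("cropland")
      urban_done <- TRUE
    }
    ids <- c(a$primary, a$secondary)
    frs <- c(a$p, 1 - a$p)
    keep <- !is.na(ids) & frs > 0
    ids <- ids[keep]; frs <- frs[keep] / sum(frs[keep])
    lai <- lapply(ids, function(id) {
      default_lai_weekly(id, g$lat) * exp(rnorm(1, 0, 0.05))
    })
    z0 <- sum(frs * cats$z0_default[match(ids, cats$category_id)])
    rows[[k]] <- tibble(cell_id = g$cell_id, region = a$region,
                        lat = g$lat, lon = g$lon, area_m2 = g$area_m2,
                        z0 = z0, category_id = ids, fraction = frs,
                        lai_weekly = lai)
  }
  out <- bind_rows(rows) |> arrange(.data$cell_id, .data$category_id)
  missing <- setdiff(cats$category_id, unique(out$category_id))
  if (length(missing) > 0) {
    abort(sprintf("internal error: categories missing from layout: %s.",
                  paste(missing, collapse = ", ")))
  }
  out
}

#' Synthetic hourly meteorology
#'
#' Hourly drivers for each cell of a surface map: solar radiation from solar
#' geometry (zero at night) attenuated by cloud, air temperature with
#' latitudinal gradient plus seasonal and diurnal cycles, lognormal friction
#' velocity, and neutral stability by default. Bit-reproducible for a given
#' seed.
#'
#' @param surface A surface tibble (only `cell_id`, `lat`, `lon` are used).
#' @param hours Number of hourly steps (`>= 1`).
#' @param seed Mandatory RNG seed.
#' @param start Start of the series (UTC).
#' @param mean_temp_eq Annual-mean air temperature at the equator (K).
#' @param pole_drop Temperature drop towards the poles (K, times sin^2 lat).
#' @param seasonal_amp Seasonal amplitude at 60 degrees latitude (K).
#' @param diurnal_amp Diurnal temperature amplitude (K).
#' @param ustar_meanlog,ustar_sdlog Lognormal friction-velocity parameters.
#' @param solar_max Clear-sky maximum solar radiation (W m-2).
#' @return A met tibble: `cell_id`, `time`, `air_temp`, `surface_temp` (K),
#'   `friction_velocity`, `wind_speed_10m` (m s-1), `solar_radiation`
#'   (W m-2), `cloud_fraction`, `pressure` (Pa), `stability_param`.
#' @export
generate_met <- function(surface, hours, seed,
                         start = as.POSIXct("2015-01-01 00:00:00", tz = "UTC"),
                         mean_temp_eq = 300, pole_drop = 35, seasonal_amp = 12,
                         diurnal_amp = 5, ustar_meanlog = log(0.35),
                         ustar_sdlog = 0.4, solar_max = 1000) {
  if (missing(seed)) abort("`seed` is mandatory.")
  if (hours < 1) abort("`hours` must be >= 1.")
  set.seed(seed)
  cells <- surface |> distinct(.data$cell_id, .data$lat, .data$lon)
  times <- start + 3600 * (seq_len(hours) - 1)
  df <- tidyr::expand_grid(cells, time = times)
  lt <- as.POSIXlt(df$time, tz = "UTC")
  doy <- lt$yday + 1
  utc_hour <- lt$hour
  d2r <- pi / 180
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365) * d2r
  solar_time <- (utc_hour + df$lon / 15) %% 24
  hour_angle <- (solar_time - 12) * 15 * d2r
  cosz <- sin(df$lat * d2r) * sin(decl) +
    cos(df$lat * d2r) * cos(decl) * cos(hour_angle)
  n <- nrow(df)
  cloud <- rbeta(n, 2, 3)
  solar <- solar_max * pmax(cosz, 0) * (1 - 0.75 * cloud^3)
  season_phase <- cos(2 * pi * (doy - 197) / 365)   # NH summer peak
  seasonal <- seasonal_amp * pmin(abs(df$lat) / 60, 1.2) *
    sign(df$lat) * season_phase
  air_temp <- mean_temp_eq - pole_drop * sin(df$lat * d2r)^2 + seasonal +
    diurnal_amp * cos(2 * pi * (solar_time - 15) / 24) + rnorm(n, 0, 1)
  ustar <- exp(rnorm(n, ustar_meanlog, ustar_sdlog))
  df |>
    mutate(air_temp = air_temp,
           surface_temp = air_temp + 3 * solar / 1000,
           friction_velocity = ustar,
           wind_speed_10m = ustar / 0.07,
           solar_radiation = solar,
           cloud_fraction = cloud,
           pressure = 101325,
           stability_param = 0) |>
    select("cell_id", "time", "air_temp", "surface_temp", "friction_velocity",
           "wind_speed_10m", "solar_radiation", "cloud_fraction", "pressure",
           "stability_param")
}

#' Synthetic site measurement database
#'
#' Builds a site table around a known true deposition velocity: the total
#' annual uptake flux at each site is `v_true * C_local * year` with
#' multiplicative lognormal noise, split into a litterfall component (a
#' fixed fraction of the total, emulating litterfall's under-sampling of
#' total uptake) and a throughfall component; open-field wet deposition is
#' added to the collected throughfall so the total-foliar-uptake identity
#' recovers the full flux. Concentrations are reported at STP with per-site
#' local temperature and pressure, mirroring how the measurement literature
#' reports them.
#'
#' @param n Number of sites.
#' @param true_vd_cm_s True deposition velocity (cm s-1; scalar or length n).
#' @param seed Mandatory RNG seed.
#' @param conc_stp Atmospheric Hg0 concentration at STP (ng m-3).
#' @param sigma Lognormal noise sigma on the total flux (default 0.3).
#' @param litterfall_frac Fraction of total uptake captured by litterfall
#'   (default 0.73, so total/litterfall velocity medians differ by ~36%).
#' @param method_prob Sampling probabilities for the three methods.
#' @param lat_range Latitude band for site locations.
#' @return A site tibble accepted by [derive_velocities()]: `site_id`,
#'   `lat`, `lon`, `elevation`, `year`, `land_class`, `region`, `method`,
#'   `litterfall_flux`, `throughfall_flux`, `openfield_wetdep_flux`,
#'   `nee_flux` (ug m-2 yr-1), `hg0_conc_stp` (ng m-3), `local_temp` (K),
#'   `local_pressure` (atm), and the generator truth `true_vd_cm_s`.
#' @export
generate_site_db <- function(n, true_vd_cm_s, seed, conc_stp = 1.5,
                             sigma = 0.3, litterfall_frac = 0.73,
                             method_prob = c(litterfall = 0.5,
                                             total_foliar = 0.45,
                                             micromet = 0.05),
                             lat_range = c(-15, 60)) {
  if (missing(seed)) abort("`seed` is mandatory.")
  check_non_negative(sigma, "sigma")
  check_fraction(litterfall_frac, "litterfall_frac")
  set.seed(seed)
  lat <- runif(n, lat_range[1], lat_range[2])
  lon <- runif(n, -120, 40)
  elevation <- runif(n, 0, 1500)
  local_temp <- 299 - 0.25 * abs(lat) - 0.0065 * elevation + rnorm(n, 0, 1)
  local_pressure <- exp(-elevation / 8400)
  c_local <- stp_to_local(conc_stp, local_temp, local_pressure)
  total_flux <- (true_vd_cm_s / 100) * c_local * SECONDS_PER_YEAR / 1e3 *
    exp(rnorm(n, 0, sigma))
  litterfall <- litterfall_frac * total_flux
  wetdep <- runif(n, 5, 20)
  throughfall <- (1 - litterfall_frac) * total_flux + wetdep
  method <- sample(names(method_prob), n, replace = TRUE, prob = method_prob)
  land_class <- ifelse(abs(lat) <= 14, "tropical_rainforest",
                       sample(c("deciduous_forest", "coniferous_forest"),
                              n, replace = TRUE))
  tibble(site_id = sprintf("site%03d", seq_len(n)),
         lat = lat, lon = lon, elevation = elevation,
         year = sample(2000:2015, n, replace = TRUE),
         land_class = land_class,
         region = ifelse(abs(lat) <= 14, "amazon", "extratropics"),
         method = method,
         litterfall_flux = litterfall,
         throughfall_flux = throughfall,
         openfield_wetdep_flux = wetdep,
         nee_flux = total_flux,
         hg0_conc_stp = conc_stp,
         local_temp = local_temp,
         local_pressure = local_pressure,
         true_vd_cm_s = true_vd_cm_s)
}
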
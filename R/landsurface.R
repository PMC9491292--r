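# Land-surface handling: the 11 dry-deposition land categories, spherical
# grid geometry, 73->11 source-type aggregation, the site land-type override
# used for model-observation comparison, and the savannization transform.

#' The 11 dry-deposition land categories
#'
#' Category identifiers, labels and default roughness lengths used by the
#' resistance scheme. Tropical rainforest and savanna/grassland are distinct
#' categories so land-cover-change scenarios can convert one to the other.
#'
#' @return A tibble with columns `category_id`, `category`, `z0_default` (m),
#'   `lai_max`, `lai_min` (defaults for the seasonal LAI cycle).
#' @export
land_categories <- function() {
  tibble(
    category_id = 1:11,
    category = c("urban", "cropland", "savanna_grassland", "deciduous_forest",
                 "coniferous_forest", "tropical_rainforest", "water", "barren",
                 "wetland", "mixed_agriculture", "shrubland"),
    z0_default = c(1, 0.1, 0.05, 1, 1, 2, 1e-4, 0.002, 0.1, 0.1, 0.05),
    lai_max = c(0.5, 3, 2, 5, 3.5, 6, 0, 0.05, 2, 2.5, 1),
    lai_min = c(0.2, 0.2, 0.5, 0.5, 2.5, 5.5, 0, 0, 1, 0.5, 0.3))
}

category_id_of <- function(category) {
  cats <- land_categories()
  id <- cats$category_id[match(category, cats$category)]
  if (any(is.na(id))) {
    abort(sprintf("unknown land category: %s.",
                  paste(unique(category[is.na(id)]), collapse = ", ")))
  }
  id
}

#' Spherical area of a latitude-longitude cell
#'
#' Closed-form spherical quadrilateral area
#' `R^2 * dlambda * (sin(phi2) - sin(phi1))`. A partition of the whole
#' sphere sums to `4 pi R^2` exactly (to rounding).
#'
#' @param lat_min,lat_max Latitude bounds (degrees, `-90..90`).
#' @param lon_min,lon_max Longitude bounds (degrees).
#' @param radius Sphere radius (m), default Earth.
#' @return Area (m2).
#' @export
cell_area <- function(lat_min, lat_max, lon_min, lon_max, radius = EARTH_RADIUS) {
  if (any(lat_max <= lat_min) || any(lon_max <= lon_min)) {
    abort("cell bounds must satisfy lat_max > lat_min and lon_max > lon_min.")
  }
  d2r <- pi / 180
  radius^2 * (lon_max - lon_min) * d2r *
    (sin(lat_max * d2r) - sin(lat_min * d2r))
}

#' Build a regular latitude-longitude grid
#'
#' Cell-centre registration on a regular grid with half-open longitude
#' interval `[-180, 180)`; the default 2.0 x 2.5 degree resolution mirrors a
#' typical global-model grid.
#'
#' @param res_lat,res_lon Grid resolution in degrees.
#' @param lat_range,lon_range Domain bounds (degrees).
#' @return A tibble with `cell_id`, `lat`, `lon` (centres) and `area_m2`.
#' @export
make_grid <- function(res_lat = 2, res_lon = 2.5,
                      lat_range = c(-90, 90), lon_range = c(-180, 180)) {
  lat_edges <- seq(lat_range[1], lat_range[2], by = res_lat)
  lon_edges <- seq(lon_range[1], lon_range[2], by = res_lon)
  g <- tidyr::expand_grid(i = seq_len(length(lat_edges) - 1),
                          j = seq_len(length(lon_edges) - 1))
  g |>
    mutate(lat = (lat_edges[.data$i] + lat_edges[.data$i + 1]) / 2,
           lon = (lon_edges[.data$j] + lon_edges[.data$j + 1]) / 2,
           area_m2 = cell_area(lat_edges[.data$i], lat_edges[.data$i + 1],
                               lon_edges[.data$j], lon_edges[.data$j + 1]),
           cell_id = sprintf("c%03d_%03d", .data$i, .data$j)) |>
    select("cell_id", "lat", "lon", "area_m2")
}

#' Default mapping from 73 source land types to the 11 categories
#'
#' A total mapping (every source type mapped exactly once) assigning the 73
#' fine land types to the 11 dry-deposition categories in contiguous blocks.
#' Editable: pass any two-column tibble with the same shape to
#' [map_categories()].
#'
#' @return A tibble with columns `source_type` (1..73) and `category_id`.
#' @export
default_category_mapping <- function() {
  block_sizes <- c(3, 10, 9, 9, 8, 6, 6, 5, 5, 6, 6)
  stopifnot(sum(block_sizes) == 73)
  tibble(source_type = 1:73,
         category_id = rep(1:11, times = block_sizes))
}

#' Aggregate 73-type land fractions onto the 11 dry-deposition categories
#'
#' Scatter-adds source-type fractions into their assigned category; coverage
#' is conserved and the output stays normalised.
#'
#' @param fractions A tibble with columns `cell_id`, `source_type`,
#'   `fraction` (normalised per cell).
#' @param mapping A total mapping tibble (`source_type`, `category_id`),
#'   default [default_category_mapping()].
#' @return A tibble with `cell_id`, `category_id`, `fraction`.
#' @export
map_categories <- function(fractions, mapping = default_category_mapping()) {
  check_columns(fractions, c("cell_id", "source_type", "fraction"), "fractions")
  check_columns(mapping, c("source_type", "category_id"), "mapping")
  if (anyDuplicated(mapping$source_type) > 0) {
    abort("`mapping` must map every source type exactly once.")
  }
  unmapped <- setdiff(unique(fractions$source_type), mapping$source_type)
  if (length(unmapped) > 0) {
    abort(sprintf("source type(s) without mapping: %s.",
                  paste(unmapped, collapse = ", ")))
  }
  check_fraction_sums(fractions, "fractions")
  fractions |>
    inner_join(mapping, by = "source_type") |>
    group_by(.data$cell_id, .data$category_id) |>
    summarise(fraction = sum(.data$fraction), .groups = "drop")
}

#' Default weekly LAI cycle for a land category
#'
#' A 52-week sinusoidal cycle between the category's `lai_min` and `lai_max`,
#' peaking in midsummer of the cell's hemisphere; within the tropics
#' (|lat| <= 20 degrees) the cycle is flat at the category mean.
#'
#' @param category_id Category identifier (1..11).
#' @param lat Latitude of the cell (degrees).
#' @return Numeric vector of length 52.
#' @export
default_lai_weekly <- function(category_id, lat) {
  cats <- land_categories()
  i <- match(category_id, cats$category_id)
  if (is.na(i)) abort(sprintf("unknown category_id %s.", category_id))
  hi <- cats$lai_max[i]; lo <- cats$lai_min[i]
  wk <- 1:52
  if (abs(lat) <= 20) {
    rep((hi + lo) / 2, 52)
  } else {
    peak <- if (lat > 0) 29 else 3   # week of local midsummer
    lo + (hi - lo) * (1 + cos(2 * pi * (wk - peak) / 52)) / 2
  }
}

#' Override a grid cell with the land type observed at a site
#'
#' For comparing the model with a point measurement, the observed category is
#' made to cover 100% of the site's grid cell, the cell LAI becomes the mean
#' LAI of that category within the cell, and the roughness length is floored
#' at 1 m (representative of forest). Idempotent.
#'
#' @param surface A surface tibble (see [generate_surface()]).
#' @param cell_id Cell to override.
#' @param category Target category name or id (one of the 11).
#' @return The modified surface tibble.
#' @export
site_override <- function(surface, cell_id, category) {
  check_columns(surface, c("cell_id", "category_id", "fraction", "lai_weekly", "z0"),
                "surface")
  if (is.character(category)) category <- category_id_of(category)
  if (!category %in% land_categories()$category_id) {
    abort(sprintf("target category %s is not one of the 11 categories.", category))
  }
  if (!cell_id %in% surface$cell_id) {
    abort(sprintf("cell %s not found in surface.", cell_id))
  }
  cell <- surface |> filter(.data$cell_id == !!cell_id)
  target_rows <- cell |> filter(.data$category_id == !!category)
  if (nrow(target_rows) == 0) {
    warn(sprintf(
      "category %d absent from cell %s; using the category-default LAI cycle.",
      category, cell_id))
    lai <- list(default_lai_weekly(category, cell$lat[1]))
  } else {
    # mean weekly LAI of the observed category within the cell
    lai <- list(Reduce(`+`, target_rows$lai_weekly) / nrow(target_rows))
  }
  new_row <- cell[1, ]
  new_row$category_id <- category
  new_row$fraction <- 1
  new_row$lai_weekly <- lai
  new_row$z0 <- max(new_row$z0, 1)
  bind_rows(surface |> filter(.data$cell_id != !!cell_id), new_row) |>
    arrange(.data$cell_id, .data$category_id)
}

#' Convert rainforest land cover to savanna within a region
#'
#' Within the masked cells, all tropical-rainforest coverage is reassigned to
#' the savanna/grassland category and its weekly LAI series is replaced by the
#' mean weekly LAI over current savanna cells in the reference region.
#' Fractions stay normalised; unmasked cells are untouched.
#'
#' @param surface A surface tibble.
#' @param mask Character vector of `cell_id`s to convert (e.g. the Amazon
#'   block), or a logical vector along `unique(surface$cell_id)`.
#' @param reference_region Value of `surface$region` identifying the current
#'   savanna cells whose LAI defines the replacement series.
#' @return The modified surface tibble.
#' @export
savannize <- function(surface, mask, reference_region = "savanna_ref") {
  check_columns(surface, c("cell_id", "region", "category_id", "fraction",
                           "lai_weekly", "z0"), "surface")
  rf <- category_id_of("tropical_rainforest")
  sv <- category_id_of("savanna_grassland")
  cells <- unique(surface$cell_id)
  if (is.logical(mask)) {
    if (length(mask) != length(cells)) {
      abort("logical `mask` must align with the surface grid (one value per cell).")
    }
    mask <- cells[mask]
  }
  missing <- setdiff(mask, cells)
  if (length(missing) > 0) {
    abort(sprintf("mask is not aligned to the grid; unknown cell(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  ref <- surface |>
    filter(.data$region == reference_region, .data$category_id == sv,
           .data$fraction > 0)
  if (nrow(ref) == 0) {
    abort("no savanna reference cells found; cannot define replacement LAI.")
  }
  ref_lai <- Reduce(`+`, ref$lai_weekly) / nrow(ref)

  z0_cat <- land_categories() |> select("category_id", "z0_default")
  out <- surface |>
    mutate(category_id = ifelse(.data$cell_id %in% mask &
                                  .data$category_id == rf, sv, .data$category_id),
           converted = .data$cell_id %in% mask & .data$category_id == sv)
  out$lai_weekly[out$converted] <- rep(list(ref_lai), sum(out$converted))
  # merge duplicate savanna rows created by the swap (fractions add)
  out <- out |>
    group_by(.data$cell_id, .data$region, .data$lat, .data$lon, .data$area_m2,
             .data$category_id) |>
    summarise(lai_weekly = list(Reduce(`+`, Map(`*`, .data$lai_weekly,
                                                .data$fraction / sum(.data$fraction)))),
              fraction = sum(.data$fraction),
              z0 = .data$z0[1], .groups = "drop")
  # refresh cell roughness for converted cells from category defaults
  z0_new <- out |>
    inner_join(z0_cat, by = "category_id") |>
    group_by(.data$cell_id) |>
    summarise(z0_w = sum(.data$fraction * .data$z0_default), .groups = "drop")
  out |>
    left_join(z0_new, by = "cell_id") |>
    mutate(z0 = ifelse(.data$cell_id %in% mask, .data$z0_w, .data$z0)) |>
    select(-"z0_w") |>
    arrange(.data$cell_id, .data$category_id)
}
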
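# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except the package's own parameter table.

EARTH_RADIUS_TEST <- 6.371e6  # m, must match the package constant

cat_id <- function(name) {
  cats <- land_categories()
  cats$category_id[match(name, cats$category)]
}

# A single pure cell of one land category.
one_cell_surface <- function(lat = 42, lon = -72, category = "deciduous_forest",
                             z0 = NULL, cell_id = "cell1", region = "") {
  cats <- land_categories()
  id <- cat_id(category)
  tibble::tibble(
    cell_id = cell_id, region = region, lat = lat, lon = lon,
    area_m2 = cell_area(lat - 1, lat + 1, lon - 1.25, lon + 1.25),
    z0 = if (is.null(z0)) cats$z0_default[id] else z0,
    category_id = id, fraction = 1,
    lai_weekly = list(default_lai_weekly(id, lat)))
}

# A mixed coastal cell: water plus forest.
coastal_surface <- function(water_frac = 0.7, lat = 42, lon = -70,
                            cell_id = "coast1") {
  cats <- land_categories()
  ids <- c(cat_id("water"), cat_id("deciduous_forest"))
  frs <- c(water_frac, 1 - water_frac)
  lai <- lapply(ids, function(id) default_lai_weekly(id, lat))
  tibble::tibble(
    cell_id = cell_id, region = "", lat = lat, lon = lon,
    area_m2 = cell_area(lat - 1, lat + 1, lon - 1.25, lon + 1.25),
    z0 = sum(frs * cats$z0_default[ids]),
    category_id = ids, fraction = frs,
    lai_weekly = lai)
}

# Re-derive a velocity field row by row through the exported scalar
# operations: the vectorisation oracle.
scalar_vd_oracle <- function(met, surface, species, zref = 10, ocean_vd = 0) {
  params <- land_category_params()
  out <- numeric(0)
  key <- character(0)
  for (ci in unique(met$cell_id)) {
    surf_c <- surface[surface$cell_id == ci, ]
    met_c <- met[met$cell_id == ci, ]
    for (r in seq_len(nrow(met_c))) {
      lt <- as.POSIXlt(met_c$time[r], tz = "UTC")
      doy <- lt$yday + 1 + lt$hour / 24
      season <- season_class(lt$mon + 1, surf_c$lat[1])
      ra <- aerodynamic_resistance(met_c$friction_velocity[r], surf_c$z0[1],
                                   zref, met_c$stability_param[r])
      rb <- boundary_resistance(met_c$friction_velocity[r],
                                schmidt_prandtl(species))
      vd_cell <- 0
      for (k in seq_len(nrow(surf_c))) {
        if (surf_c$category_id[k] == cat_id("water")) {
          vd <- ocean_vd / 100
        } else {
          p <- params[params$category_id == surf_c$category_id[k] &
                        params$season == season, ]
          lai <- lai_at(surf_c$lai_weekly[[k]], doy)
          rsm <- stomatal_resistance(p$ri, met_c$solar_radiation[r],
                                     met_c$surface_temp[r], lai, species) +
            mesophyll_resistance(species)
          rlu <- cuticular_resistance(p$rlu, species, lai)
          rdcl <- lower_canopy_resistance(p$rcl_so2, p$rcl_o3,
                                          met_c$solar_radiation[r], species)
          rgnd <- ground_resistance(p$rac, p$rgs_so2, p$rgs_o3, species)
          rc <- surface_resistance(rsm, rlu, rdcl, rgnd)
          vd <- deposition_velocity(ra, rb, rc)
        }
        vd_cell <- vd_cell + surf_c$fraction[k] * vd
      }
      out <- c(out, 100 * vd_cell)
      key <- c(key, paste(ci, format(met_c$time[r], "%Y-%m-%d %H:%M:%S")))
    }
  }
  tibble::tibble(key = key, vd_cm_s = out)
}
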
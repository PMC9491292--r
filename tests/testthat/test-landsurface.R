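# Land-surface geometry, category aggregation, site override and
# savannization.

test_that("cell areas follow the closed form and partition the sphere", {
  a <- cell_area(0, 1, 0, 1)
  d2r <- pi / 180
  expect_equal(a, EARTH_RADIUS_TEST^2 * d2r * (sin(d2r) - 0), tolerance = 1e-12)
  grid <- make_grid(res_lat = 10, res_lon = 15)
  expect_equal(sum(grid$area_m2), 4 * pi * EARTH_RADIUS_TEST^2,
               tolerance = 1e-9)
  # cos-lat weighting: equatorial cell beats polar cell of the same span
  expect_gt(cell_area(0, 10, 0, 10), cell_area(80, 90, 0, 10))
  expect_error(cell_area(10, 0, 0, 10), "bounds")
})

test_that("73->11 aggregation conserves coverage and matches a scatter-add oracle", {
  mapping <- default_category_mapping()
  expect_equal(nrow(mapping), 73)
  expect_equal(anyDuplicated(mapping$source_type), 0)
  expect_true(all(mapping$category_id %in% 1:11))

  one <- tibble::tibble(cell_id = "a", source_type = 5, fraction = 1)
  out1 <- map_categories(one, mapping)
  expect_equal(out1$fraction, 1)
  expect_equal(out1$category_id,
               mapping$category_id[mapping$source_type == 5])

  two <- tibble::tibble(cell_id = "a", source_type = c(20, 21),
                        fraction = c(0.4, 0.6))
  # types 20 and 21 share a category in the default block mapping
  expect_equal(map_categories(two, mapping)$fraction, 1)

  set.seed(8)
  fr <- runif(73); fr <- fr / sum(fr)
  rand <- tibble::tibble(cell_id = "a", source_type = 1:73, fraction = fr)
  got <- map_categories(rand, mapping)
  oracle <- rep(0, 11)
  for (k in 1:73) {
    oracle[mapping$category_id[k]] <- oracle[mapping$category_id[k]] + fr[k]
  }
  expect_equal(got$fraction[order(got$category_id)],
               oracle[sort(unique(mapping$category_id))], tolerance = 1e-12)
  expect_equal(sum(got$fraction), 1, tolerance = 1e-12)

  expect_error(map_categories(
    tibble::tibble(cell_id = "a", source_type = 99, fraction = 1), mapping),
    "without mapping")
})

test_that("site override purifies the cell, floors z0 at 1 m and is idempotent", {
  pure <- one_cell_surface(z0 = 0.3)
  over <- site_override(pure, "cell1", "deciduous_forest")
  expect_equal(over$fraction, 1)
  expect_equal(over$z0, 1)                       # 0.3 m -> 1 m floor
  expect_equal(over$lai_weekly[[1]], pure$lai_weekly[[1]])
  tall <- one_cell_surface(z0 = 2)
  expect_equal(site_override(tall, "cell1", "deciduous_forest")$z0, 2)
  twice <- site_override(over, "cell1", "deciduous_forest")
  expect_equal(twice$fraction, over$fraction)
  expect_equal(twice$z0, over$z0)
  expect_equal(twice$lai_weekly, over$lai_weekly)
})

test_that("overriding a coastal cell raises its velocity towards the forest value", {
  coast <- coastal_surface(water_frac = 0.7)
  met <- generate_met(coast, hours = 48, seed = 21)
  before <- mean(velocity_field(met, coast, hg0_species(3e-5))$vd_cm_s)
  over <- site_override(coast, "coast1", "deciduous_forest")
  after <- mean(velocity_field(met, over, hg0_species(3e-5))$vd_cm_s)
  expect_gt(after, before)
  pure_forest <- coast |>
    dplyr::filter(category_id == cat_id("deciduous_forest")) |>
    dplyr::mutate(fraction = 1, z0 = pmax(z0, 1))
  ref <- mean(velocity_field(met, pure_forest, hg0_species(3e-5))$vd_cm_s)
  expect_equal(after, ref, tolerance = 1e-10)
})

test_that("overriding with an absent category falls back to the default LAI with a warning", {
  pure <- one_cell_surface(category = "cropland")
  expect_warning(out <- site_override(pure, "cell1", "coniferous_forest"),
                 "default LAI")
  expect_equal(out$category_id, cat_id("coniferous_forest"))
  expect_equal(out$lai_weekly[[1]],
               default_lai_weekly(cat_id("coniferous_forest"), pure$lat[1]))
})

test_that("savannization swaps rainforest for savanna with the reference LAI", {
  surface <- generate_surface(seed = 31)
  amazon <- unique(surface$cell_id[surface$region == "amazon"])
  out <- savannize(surface, amazon)
  rf <- cat_id("tropical_rainforest"); sv <- cat_id("savanna_grassland")
  expect_false(any(out$cell_id %in% amazon & out$category_id == rf))
  # untouched cells identical (same rows, fractions, LAI)
  rest_before <- surface |> dplyr::filter(!cell_id %in% amazon) |>
    dplyr::arrange(cell_id, category_id)
  rest_after <- out |> dplyr::filter(!cell_id %in% amazon) |>
    dplyr::arrange(cell_id, category_id)
  expect_equal(rest_after$fraction, rest_before$fraction)
  expect_equal(rest_after$lai_weekly, rest_before$lai_weekly)
  # fractions stay normalised everywhere
  sums <- out |> dplyr::group_by(cell_id) |>
    dplyr::summarise(s = sum(fraction))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  # converted savanna carries the reference-region mean LAI
  ref_rows <- surface |>
    dplyr::filter(region == "savanna_ref", category_id == sv, fraction > 0)
  ref_lai <- Reduce(`+`, ref_rows$lai_weekly) / nrow(ref_rows)
  pure_rf_cells <- surface |>
    dplyr::filter(cell_id %in% amazon) |>
    dplyr::group_by(cell_id) |>
    dplyr::filter(dplyr::n() == 1, category_id == rf) |>
    dplyr::pull(cell_id)
  if (length(pure_rf_cells) > 0) {
    row <- out |> dplyr::filter(cell_id == pure_rf_cells[1])
    expect_equal(row$category_id, sv)
    expect_equal(row$lai_weekly[[1]], ref_lai)
  }
  expect_error(savannize(surface, amazon, reference_region = "nowhere"),
               "reference")
  expect_error(savannize(surface, c(amazon, "ghost_cell")), "aligned")
})

test_that("savannization lowers the deposition velocity over converted cells", {
  surface <- generate_surface(seed = 31)
  amazon <- unique(surface$cell_id[surface$region == "amazon"])
  scen <- savannize(surface, amazon)
  sub_base <- surface |> dplyr::filter(cell_id %in% amazon)
  sub_scen <- scen |> dplyr::filter(cell_id %in% amazon)
  met <- generate_met(sub_base, hours = 96, seed = 32)
  sp <- hg0_species(0.2)
  v_base <- annual_mean_vd(velocity_field(met, sub_base, sp))
  v_scen <- annual_mean_vd(velocity_field(met, sub_scen, hg0_species(3e-5)))
  cmp <- dplyr::inner_join(v_base, v_scen, by = "cell_id",
                           suffix = c("_b", "_s"))
  expect_true(all(cmp$vd_cm_s_s < cmp$vd_cm_s_b))
})
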
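# Unit behaviour of the resistance operations and their closed-form limits.

test_that("aerodynamic resistance matches the neutral closed form and stability ordering", {
  expect_equal(aerodynamic_resistance(0.4, z0 = 1, zref = 10),
               log(10) / (0.4 * 0.4), tolerance = 1e-12)
  expect_equal(aerodynamic_resistance(0.4, z0 = 10, zref = 10), 0)
  ra_neutral <- aerodynamic_resistance(0.4, 1, 10, stability = 0)
  expect_lt(aerodynamic_resistance(0.4, 1, 10, stability = -1), ra_neutral)
  expect_gt(aerodynamic_resistance(0.4, 1, 10, stability = 0.5), ra_neutral)
  expect_error(aerodynamic_resistance(0, 1, 10), "friction_velocity")
  expect_error(aerodynamic_resistance(0.4, -1, 10), "z0")
})

test_that("boundary resistance follows (2/ku*)(Sc/Pr)^(2/3)", {
  expect_equal(boundary_resistance(0.4, sc_pr = 1), 12.5, tolerance = 1e-12)
  expect_equal(boundary_resistance(0.8, sc_pr = 1),
               boundary_resistance(0.4, sc_pr = 1) / 2, tolerance = 1e-12)
  expect_equal(boundary_resistance(0.4, sc_pr = 2.7), 12.5 * 2.7^(2 / 3),
               tolerance = 1e-12)
  expect_identical(boundary_resistance(0, sc_pr = 1), Inf)
})

test_that("mesophyll resistance reproduces the Hg0 value and its limits", {
  expect_equal(mesophyll_resistance(hg0_species()),
               1 / (0.11 / 3000 + 100 * 1e-5), tolerance = 1e-12)
  # extremely soluble gas: pathway opens completely
  expect_lt(mesophyll_resistance(hg2_species()), 1e-9)
  # highly reactive gas: Rm -> 1/100
  expect_equal(mesophyll_resistance(species_params("x", 0, 1, 1)), 0.01)
  # inert, insoluble gas: blocked
  expect_identical(mesophyll_resistance(species_params("inert", 0, 0, 1)), Inf)
})

test_that("stomata close at night, at zero LAI and outside the temperature window", {
  sp <- hg0_species()
  expect_identical(stomatal_resistance(70, 0, 298, 4, sp), Inf)
  expect_identical(stomatal_resistance(70, 400, 298, 0, sp), Inf)
  expect_identical(stomatal_resistance(70, 400, 272, 4, sp), Inf)
  expect_identical(stomatal_resistance(70, 400, 315, 4, sp), Inf)
  rs <- stomatal_resistance(70, 400, 298, 4, sp)
  expect_equal(rs, 70 * (1 + (200 / 400.1)^2) * (400 / (24.85 * (40 - 24.85))) *
                 sp$diffusivity_ratio / 4, tolerance = 1e-12)
  # more light and more leaf area both lower the resistance
  expect_lt(stomatal_resistance(70, 800, 298, 4, sp), rs)
  expect_lt(stomatal_resistance(70, 400, 298, 6, sp), rs)
})

test_that("cuticular scaling opens with H* and f0 and never divides by zero", {
  expect_equal(cuticular_resistance(2000, hg0_species(reactivity = 0.2)),
               2000 / (1e-5 * 0.11 + 0.2), tolerance = 1e-12)
  # Hg2+: base scaled by ~1e-9
  expect_equal(cuticular_resistance(2000, hg2_species()), 2000 / 1e9,
               tolerance = 1e-9)
  inert <- species_params("inert", 0, 0, 1)
  expect_identical(cuticular_resistance(2000, inert), Inf)
  expect_identical(cuticular_resistance(2000, hg0_species(), lai = 0), Inf)
  expect_identical(cuticular_resistance(Inf, hg0_species()), Inf)
})

test_that("reference-gas scaled resistances decrease in H* and f0", {
  f0s <- c(1e-5, 3e-5, 9e-5, 2e-3, 0.2, 1)
  vals <- vapply(f0s, function(f) {
    reference_scaled_resistance(500, 200, species_params("x", 0.11, f, 3))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  hs <- c(0, 0.11, 100, 1e5, 1e14)
  vals_h <- vapply(hs, function(h) {
    reference_scaled_resistance(500, 200, species_params("x", h, 1e-5, 3))
  }, numeric(1))
  expect_true(all(diff(vals_h) < 0))
  inert <- species_params("inert", 0, 0, 1)
  expect_identical(reference_scaled_resistance(500, 200, inert), Inf)
})

test_that("surface resistance equals the harmonic combination of open pathways", {
  expect_equal(surface_resistance(500, Inf, Inf, Inf), 500)
  expect_equal(surface_resistance(1000, 1000, 1000, 1000), 250)
  expect_identical(surface_resistance(Inf, Inf, Inf, Inf), Inf)
  # independent harmonic-sum oracle over random pathway sets with sentinels
  set.seed(42)
  for (i in 1:200) {
    r <- exp(runif(4, log(10), log(1e6)))
    r[runif(4) < 0.3] <- Inf
    oracle <- if (all(is.infinite(r))) Inf else 1 / sum(1 / r[is.finite(r)])
    got <- surface_resistance(r[1], r[2], r[3], r[4])
    if (is.infinite(oracle)) {
      expect_identical(got, Inf)
    } else {
      expect_equal(got, oracle, tolerance = 1e-12)
    }
  }
})

test_that("deposition velocity is bounded by the aerodynamic pathway", {
  expect_equal(deposition_velocity(100, 100, 300), 0.002, tolerance = 1e-12)
  expect_equal(deposition_velocity(100, 100, Inf), 0)
  set.seed(7)
  ra <- runif(500, 1, 200); rb <- runif(500, 1, 100)
  rc <- exp(runif(500, log(1), log(1e7))); rc[runif(500) < 0.1] <- Inf
  vd <- deposition_velocity(ra, rb, rc)
  expect_true(all(vd >= 0))
  expect_true(all(vd <= 1 / (ra + rb) + 1e-15))
})

test_that("velocity rises monotonically through the reactivity ladder", {
  p <- land_category_params()
  p1 <- p[p$category_id == cat_id("tropical_rainforest") & p$season == 1, ]
  vd_of <- function(f0) {
    sp <- hg0_species(reactivity = f0)
    rsm <- stomatal_resistance(p1$ri, 500, 300, 5, sp) + mesophyll_resistance(sp)
    rc <- surface_resistance(
      rsm, cuticular_resistance(p1$rlu, sp, 5),
      lower_canopy_resistance(p1$rcl_so2, p1$rcl_o3, 500, sp),
      ground_resistance(p1$rac, p1$rgs_so2, p1$rgs_o3, sp))
    deposition_velocity(20, 25, rc)
  }
  ladder <- vapply(c(1e-5, 3e-5, 9e-5, 0.2), vd_of, numeric(1))
  expect_true(all(diff(ladder) > 0))
})

test_that("an inert insoluble gas does not deposit on a closed-canopy forest", {
  inert <- species_params("inert", 0, 0, 1)
  p <- land_category_params()
  p1 <- p[p$category_id == cat_id("deciduous_forest") & p$season == 1, ]
  rsm <- stomatal_resistance(p1$ri, 500, 298, 4, inert) +
    mesophyll_resistance(inert)
  rc <- surface_resistance(
    rsm, cuticular_resistance(p1$rlu, inert, 4),
    lower_canopy_resistance(p1$rcl_so2, p1$rcl_o3, 500, inert),
    ground_resistance(p1$rac, p1$rgs_so2, p1$rgs_o3, inert))
  expect_identical(rc, Inf)
  expect_equal(deposition_velocity(20, 25, rc), 0)
})

test_that("the baseline table is complete over seasons and categories", {
  p <- land_category_params()
  expect_equal(sort(unique(p$season)), 1:5)
  expect_equal(sort(unique(p$category_id)), 1:11)
  expect_true(all(p$ri > 0))
  expect_true(all(p$rlu > 0))
})
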
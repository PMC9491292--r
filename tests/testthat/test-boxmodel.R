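# Three-box Hg0/Hg2+ mass balance: conservation, steady state, tuning.

test_that("zero rates and zero emissions give zero tendencies", {
  boxes <- box_config()$boxes |>
    dplyr::mutate(emis_hg0 = 0, k_ox = 0, k_red = 0, k_dep_hg0 = 0,
                  k_dep_hg2 = 0)
  cfg <- box_config(boxes, exchange_tau = c(1e12, 1e12))
  st <- tibble::tibble(box = boxes$box, hg0_Mg = c(100, 200, 300),
                       hg2_Mg = c(10, 20, 30))
  td <- box_tendencies(st, cfg, alpha = 0)
  expect_lt(max(abs(c(td$dhg0_dt, td$dhg2_dt))), 1e-9)
})

test_that("a closed system conserves total mercury under any rates", {
  boxes <- box_config()$boxes |>
    dplyr::mutate(emis_hg0 = 0, k_dep_hg0 = 0, k_dep_hg2 = 0)
  cfg <- box_config(boxes, exchange_tau = c(0.3, 0.3))
  x0 <- c(500, 100, 50, 40, 10, 5)
  tr <- box_transient(cfg, alpha = 0.7, state0 = x0,
                      times = seq(0, 20, 1), rtol = 1e-12, atol = 1e-10)
  totals <- rowSums(tr[, -1])
  expect_true(all(abs(totals - sum(x0)) / sum(x0) < 1e-10))
})

test_that("single-box redox equilibrium matches alpha*k_red/k_ox", {
  boxes <- tibble::tibble(box = "global", trop_mass_kg = 4e18, emis_hg0 = 0,
                          k_ox = 2, k_red = 10, k_dep_hg0 = 0, k_dep_hg2 = 0,
                          land_frac = 0)
  cfg <- box_config(boxes, alpha0 = 0.5, exchange_tau = numeric(0))
  tr <- box_transient(cfg, alpha = 0.5, state0 = c(1000, 0),
                      times = c(0, 200), rtol = 1e-12, atol = 1e-10)
  final <- tr[nrow(tr), ]
  expect_equal(final$hg0_global / final$hg2_global, 0.5 * 10 / 2,
               tolerance = 1e-8)
})

test_that("steady state matches long transient integration from any start", {
  cfg <- box_config()
  st <- box_steady_state(cfg, 0.2)
  target <- c(st$hg0_Mg, st$hg2_Mg)
  for (x0 in list(rep(1, 6), c(5000, 1, 1, 1, 1, 1))) {
    tr <- box_transient(cfg, alpha = 0.2, state0 = x0, times = c(0, 300),
                        rtol = 1e-12, atol = 1e-8)
    expect_equal(as.numeric(tr[nrow(tr), -1]), target, tolerance = 1e-8)
  }
  # residual tendency at steady state is numerically zero
  td <- box_tendencies(st, cfg, 0.2)
  expect_lt(max(abs(c(td$dhg0_dt, td$dhg2_dt))), 1e-8)
})

test_that("symmetric boxes under symmetric forcing carry equal burdens", {
  boxes <- box_config()$boxes |>
    dplyr::mutate(trop_mass_kg = 1e18, emis_hg0 = 1000, k_ox = 2, k_red = 50,
                  k_dep_hg0 = 0.5, k_dep_hg2 = 25, land_frac = 0.4)
  cfg <- box_config(boxes, exchange_tau = c(0.5, 0.5))
  st <- box_steady_state(cfg, 0.2)
  expect_equal(st$hg0_Mg[1], st$hg0_Mg[3], tolerance = 1e-10)
  expect_equal(st$hg2_Mg[1], st$hg2_Mg[3], tolerance = 1e-10)
})

test_that("a stronger Hg0 deposition sink lowers steady-state Hg0", {
  cfg <- box_config()
  st1 <- box_steady_state(cfg, 0.2)
  cfg2 <- cfg
  cfg2$boxes$k_dep_hg0 <- cfg$boxes$k_dep_hg0 * 2
  st2 <- box_steady_state(cfg2, 0.2)
  expect_true(all(st2$hg0_Mg < st1$hg0_Mg))
})

test_that("tuning returns the fixed point and recovers a synthetic truth", {
  cfg <- box_config()
  at_alpha0 <- box_steady_state(cfg, cfg$alpha0)$hg0_conc_ng_m3[1]
  fit0 <- tune_alpha(cfg, at_alpha0)
  expect_equal(fit0$alpha, cfg$alpha0, tolerance = 1e-8)

  alpha_true <- 0.33
  target <- box_steady_state(cfg, alpha_true)$hg0_conc_ng_m3[1]
  fit <- tune_alpha(cfg, target)
  expect_lt(abs(fit$alpha - alpha_true) / alpha_true, 1e-6)
  expect_lt(abs(fit$achieved - target), 1e-6)

  # strengthening the Hg0 land sink requires more reduction for the same target
  cfg2 <- cfg
  cfg2$boxes$k_dep_hg0 <- cfg$boxes$k_dep_hg0 * 2
  fit2 <- tune_alpha(cfg2, target)
  expect_gt(fit2$alpha, fit$alpha)

  expect_error(tune_alpha(cfg, 50), "not bracketed")
})

test_that("budget report balances per box and species and matches tendencies", {
  cfg <- box_config()
  st <- box_steady_state(cfg, 0.25)
  rep <- budget_report(st, cfg, 0.25)
  net <- rep |>
    dplyr::mutate(signed = ifelse(direction == "in", 1, -1) * flux_Mg_yr) |>
    dplyr::group_by(box, species) |>
    dplyr::summarise(net = sum(signed), .groups = "drop")
  scale <- max(rep$flux_Mg_yr)
  expect_true(all(abs(net$net) / scale < 1e-8))

  # at an arbitrary (non-steady) state the signed sums are the tendencies
  st2 <- st |> dplyr::mutate(hg0_Mg = hg0_Mg * c(1.5, 0.5, 1),
                             hg2_Mg = hg2_Mg + 10)
  rep2 <- budget_report(st2, cfg, 0.25)
  net2 <- rep2 |>
    dplyr::mutate(signed = ifelse(direction == "in", 1, -1) * flux_Mg_yr) |>
    dplyr::group_by(species, box) |>
    dplyr::summarise(net = sum(signed), .groups = "drop")
  td <- box_tendencies(st2, cfg, 0.25)
  for (i in seq_len(nrow(td))) {
    expect_equal(net2$net[net2$species == "hg0" & net2$box == td$box[i]],
                 td$dhg0_dt[i], tolerance = 1e-10)
    expect_equal(net2$net[net2$species == "hg2" & net2$box == td$box[i]],
                 td$dhg2_dt[i], tolerance = 1e-10)
  }

  # emissions balance effective deposition at steady state
  emit <- sum(cfg$boxes$emis_hg0)
  dep <- rep |>
    dplyr::filter(process %in% c("drydep_land", "deposition_land",
                                 "deposition_ocean")) |>
    dplyr::pull(flux_Mg_yr) |> sum()
  reem <- rep |> dplyr::filter(process == "prompt_reemission") |>
    dplyr::pull(flux_Mg_yr) |> sum()
  expect_equal(dep - reem, emit, tolerance = 1e-6)
})

test_that("tidy and glance expose the fit in broom style", {
  cfg <- box_config()
  fit <- tune_alpha(cfg, 1.4)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_true(all(c("alpha", "box", "hg0_Mg", "hg0_conc_ng_m3") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$achieved_ng_m3, 1.4, tolerance = 1e-6)
  expect_equal(gl$alpha, fit$alpha)
})
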
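# Three-box atmospheric Hg0/Hg2+ mass balance. The boxes (NH extratropics,
# tropics, SH extratropics) exchange air on fixed timescales; within each
# box first-order oxidation transfers Hg0 -> Hg2+, aqueous photoreduction
# (bulk rate alpha * k_red, with the photolysis-rate and organic-aerosol
# dependence folded into k_red) transfers Hg2+ -> Hg0, Hg0 dry deposition
# removes Hg0 to land, Hg2+ wet+dry deposition removes Hg2+, and a prompt
# re-emission fraction of terrestrial Hg2+ deposition returns as Hg0.
# The system is linear, so the steady state is one dense solve.

#' Three-box model configuration
#'
#' Defaults are illustrative, chosen once to sit at the global scales of the
#' modern Hg cycle: ~8000 Mg yr-1 total emissions, an atmospheric Hg0
#' burden of a few thousand Mg, a land Hg0 dry-deposition sink of order
#' 2000 Mg yr-1, an Hg2+ lifetime of weeks, and a Northern-Hemisphere
#' surface Hg0 concentration near 1.4 ng m-3 once the reduction
#' coefficient is tuned.
#'
#' @param boxes Tibble with one row per box and columns `box`,
#'   `trop_mass_kg` (tropospheric air mass), `emis_hg0` (Mg yr-1), `k_ox`,
#'   `k_red`, `k_dep_hg0`, `k_dep_hg2` (first-order rates, yr-1) and
#'   `land_frac` (fraction of Hg2+ deposition landing on terrestrial
#'   surfaces).
#' @param alpha0 Reference reduction scale factor.
#' @param reemis_frac Prompt re-emission fraction of terrestrial Hg2+
#'   deposition, in `[0, 1]`.
#' @param exchange_tau Inter-box exchange timescales (yr) between adjacent
#'   boxes (length `nrow(boxes) - 1`); the same timescale applies in both
#'   directions, so mass flux is symmetric at equal burdens.
#' @param rho_surface Surface air density (kg m-3) used to convert burdens
#'   to surface concentrations.
#' @return An object of class `hg_box_config`.
#' @export
box_config <- function(boxes = NULL, alpha0 = 0.2, reemis_frac = 0.2,
                       exchange_tau = c(0.3, 0.3), rho_surface = 1.25) {
  if (is.null(boxes)) {
    boxes <- tibble(
      box = c("NH_extratropics", "tropics", "SH_extratropics"),
      trop_mass_kg = c(1.0e18, 2.05e18, 1.0e18),
      emis_hg0 = c(4000, 3000, 1000),
      k_ox = c(4, 4, 4),
      k_red = c(70, 70, 70),
      k_dep_hg0 = c(0.6, 0.8, 0.15),
      k_dep_hg2 = c(25, 25, 25),
      land_frac = c(0.6, 0.4, 0.2))
  }
  check_columns(boxes, c("box", "trop_mass_kg", "emis_hg0", "k_ox", "k_red",
                         "k_dep_hg0", "k_dep_hg2", "land_frac"), "boxes")
  for (col in c("trop_mass_kg", "emis_hg0", "k_ox", "k_red", "k_dep_hg0",
                "k_dep_hg2")) {
    check_non_negative(boxes[[col]], col)
  }
  check_fraction(boxes$land_frac, "land_frac")
  check_fraction(reemis_frac, "reemis_frac")
  check_non_negative(alpha0, "alpha0")
  if (length(exchange_tau) != nrow(boxes) - 1) {
    abort("`exchange_tau` needs one timescale per adjacent box pair.")
  }
  check_positive(exchange_tau, "exchange_tau")
  structure(list(boxes = boxes, alpha0 = alpha0, reemis_frac = reemis_frac,
                 exchange_tau = exchange_tau, rho_surface = rho_surface),
            class = "hg_box_config")
}

# Linear system dx/dt = A x + e for x = (Hg0 burdens, Hg2+ burdens) in Mg.
box_system <- function(config, alpha) {
  b <- config$boxes
  n <- nrow(b)
  A <- matrix(0, 2 * n, 2 * n)
  e <- c(b$emis_hg0, rep(0, n))
  for (i in seq_len(n)) {
    gi <- i; di <- n + i
    A[gi, gi] <- A[gi, gi] - b$k_ox[i] - b$k_dep_hg0[i]
    A[gi, di] <- A[gi, di] + alpha * b$k_red[i] +
      config$reemis_frac * b$land_frac[i] * b$k_dep_hg2[i]
    A[di, gi] <- A[di, gi] + b$k_ox[i]
    A[di, di] <- A[di, di] - alpha * b$k_red[i] - b$k_dep_hg2[i]
  }
  for (i in seq_len(n - 1)) {
    k <- 1 / config$exchange_tau[i]
    for (off in c(0, n)) {         # same exchange for both species
      A[off + i, off + i] <- A[off + i, off + i] - k
      A[off + i, off + i + 1] <- A[off + i, off + i + 1] + k
      A[off + i + 1, off + i + 1] <- A[off + i + 1, off + i + 1] - k
      A[off + i + 1, off + i] <- A[off + i + 1, off + i] + k
    }
  }
  list(A = A, e = e, n = n)
}

state_tibble <- function(x, config) {
  b <- config$boxes
  n <- nrow(b)
  tibble(box = b$box,
         hg0_Mg = x[seq_len(n)],
         hg2_Mg = x[n + seq_len(n)],
         hg0_conc_ng_m3 = x[seq_len(n)] * 1e15 * config$rho_surface /
           b$trop_mass_kg)
}

#' Burden tendencies of the three-box model
#'
#' `d(burden)/dt` (Mg yr-1) for each box and species at a given state:
#' emissions in, deposition out, oxidation Hg0 -> Hg2+, reduction
#' (`alpha * k_red`) Hg2+ -> Hg0, prompt re-emission of a fraction of
#' terrestrial Hg2+ deposition, and mass-conserving inter-box exchange.
#'
#' @param state Tibble with columns `box`, `hg0_Mg`, `hg2_Mg` (burdens), in
#'   the order of `config$boxes`.
#' @param config An [box_config()] object.
#' @param alpha Reduction scale factor (default `config$alpha0`).
#' @return A tibble `box`, `dhg0_dt`, `dhg2_dt` (Mg yr-1).
#' @export
box_tendencies <- function(state, config, alpha = config$alpha0) {
  check_columns(state, c("box", "hg0_Mg", "hg2_Mg"), "state")
  sys <- box_system(config, alpha)
  x <- c(state$hg0_Mg, state$hg2_Mg)
  dx <- as.numeric(sys$A %*% x + sys$e)
  tibble(box = config$boxes$box,
         dhg0_dt = dx[seq_len(sys$n)],
         dhg2_dt = dx[sys$n + seq_len(sys$n)])
}

#' Steady state of the three-box model
#'
#' Solves the linear balance directly; the residual tendency is checked
#' against 1e-10 of the largest process flux.
#'
#' @inheritParams box_tendencies
#' @return A tibble `box`, `hg0_Mg`, `hg2_Mg`, `hg0_conc_ng_m3`.
#' @export
box_steady_state <- function(config, alpha = config$alpha0) {
  sys <- box_system(config, alpha)
  if (all(config$boxes$k_dep_hg0 == 0) && all(config$boxes$k_dep_hg2 == 0)) {
    abort("steady state requires a deposition sink for at least one species.")
  }
  x <- solve(sys$A, -sys$e)
  if (any(x < 0)) abort("steady state has negative burdens; check the rates.")
  resid <- max(abs(sys$A %*% x + sys$e))
  scale <- max(abs(sys$e), max(abs(sys$A)) * max(abs(x)))
  if (resid > 1e-10 * scale) {
    abort(sprintf("steady-state residual %.3e exceeds tolerance.", resid))
  }
  state_tibble(x, config)
}

#' Transient integration of the three-box model
#'
#' Explicit ODE integration (for diagnostics and as an independent check of
#' the steady-state solve; the system is linear so any initial condition
#' relaxes to the same steady state).
#'
#' @inheritParams box_tendencies
#' @param state0 Initial burden vector `(Hg0 boxes, Hg2+ boxes)` in Mg.
#' @param times Output times (yr).
#' @param ... Passed to [deSolve::ode()] (e.g. `rtol`, `atol`).
#' @return A tibble with `time` and one burden column per box/species.
#' @export
box_transient <- function(config, alpha = config$alpha0,
                          state0 = rep(100, 2 * nrow(config$boxes)),
                          times = seq(0, 50, by = 0.5), ...) {
  sys <- box_system(config, alpha)
  rhs <- function(t, x, p) list(as.numeric(sys$A %*% x + sys$e))
  nm <- c(paste0("hg0_", config$boxes$box), paste0("hg2_", config$boxes$box))
  out <- deSolve::ode(y = setNames(state0, nm), times = times, func = rhs,
                      parms = NULL, ...)
  as_tibble(as.data.frame(out))
}

#' Tune the Hg2+ reduction coefficient to a target Hg0 concentration
#'
#' Root-finds the reduction scale factor `alpha` so that the steady-state
#' surface Hg0 concentration in the Northern-Hemisphere box matches the
#' target (annual-mean observed concentration). The response is monotone in
#' `alpha` (more reduction recycles Hg2+ back to Hg0), so the root is
#' bracketed and unique.
#'
#' @param config An [box_config()] object.
#' @param target Target NH surface Hg0 concentration (ng m-3).
#' @param nh_box Index of the NH box (default 1).
#' @param bracket Multiplicative search range around `config$alpha0`.
#' @return An object of class `hg_alpha_fit`: a list with `alpha`, `target`,
#'   `achieved`, `state` (steady-state tibble) and `config`.
#' @export
tune_alpha <- function(config, target, nh_box = 1,
                       bracket = c(1e-3, 1e3)) {
  check_positive(target, "target")
  lo <- config$alpha0 * bracket[1]
  hi <- config$alpha0 * bracket[2]
  f <- function(a) box_steady_state(config, a)$hg0_conc_ng_m3[nh_box] - target
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) {
    abort(sprintf(
      "target %.4g ng m-3 not bracketed: achievable NH Hg0 range is [%.4g, %.4g] ng m-3 for alpha in [%.3g, %.3g].",
      target, target + min(flo, fhi), target + max(flo, fhi), lo, hi))
  }
  root <- uniroot(f, lower = lo, upper = hi, tol = 1e-14 * config$alpha0)
  alpha <- root$root
  state <- box_steady_state(config, alpha)
  achieved <- state$hg0_conc_ng_m3[nh_box]
  if (abs(achieved - target) > 1e-6) {
    abort(sprintf("tuning residual %.3e ng m-3 exceeds 1e-6.", achieved - target))
  }
  structure(list(alpha = alpha, target = target, achieved = achieved,
                 nh_box = nh_box, state = state, config = config,
                 iterations = root$iter),
            class = "hg_alpha_fit")
}

#' Process flux table of the three-box model
#'
#' All process fluxes (Mg yr-1) per box and species at a given state. At
#' steady state, inflows balance outflows per box and species to solver
#' tolerance, and total emissions equal total effective deposition.
#'
#' @inheritParams box_tendencies
#' @return A tibble `box`, `species`, `process`, `flux_Mg_yr`, `direction`
#'   (`"in"`/`"out"`).
#' @export
budget_report <- function(state, config, alpha = config$alpha0) {
  check_columns(state, c("box", "hg0_Mg", "hg2_Mg"), "state")
  b <- config$boxes
  n <- nrow(b)
  G <- state$hg0_Mg; D <- state$hg2_Mg
  rows <- list(
    tibble(box = b$box, species = "hg0", process = "emission",
           flux_Mg_yr = b$emis_hg0, direction = "in"),
    tibble(box = b$box, species = "hg0", process = "reduction",
           flux_Mg_yr = alpha * b$k_red * D, direction = "in"),
    tibble(box = b$box, species = "hg0", process = "prompt_reemission",
           flux_Mg_yr = config$reemis_frac * b$land_frac * b$k_dep_hg2 * D,
           direction = "in"),
    tibble(box = b$box, species = "hg0", process = "oxidation",
           flux_Mg_yr = b$k_ox * G, direction = "out"),
    tibble(box = b$box, species = "hg0", process = "drydep_land",
           flux_Mg_yr = b$k_dep_hg0 * G, direction = "out"),
    tibble(box = b$box, species = "hg2", process = "oxidation",
           flux_Mg_yr = b$k_ox * G, direction = "in"),
    tibble(box = b$box, species = "hg2", process = "reduction",
           flux_Mg_yr = alpha * b$k_red * D, direction = "out"),
    tibble(box = b$box, species = "hg2", process = "deposition_land",
           flux_Mg_yr = b$land_frac * b$k_dep_hg2 * D, direction = "out"),
    tibble(box = b$box, species = "hg2", process = "deposition_ocean",
           flux_Mg_yr = (1 - b$land_frac) * b$k_dep_hg2 * D, direction = "out"))
  for (i in seq_len(n - 1)) {
    k <- 1 / config$exchange_tau[i]
    for (sp in c("hg0", "hg2")) {
      x <- if (sp == "hg0") G else D
      rows <- c(rows, list(
        tibble(box = b$box[i], species = sp,
               process = paste0("exchange_to_", b$box[i + 1]),
               flux_Mg_yr = k * x[i], direction = "out"),
        tibble(box = b$box[i + 1], species = sp,
               process = paste0("exchange_from_", b$box[i]),
               flux_Mg_yr = k * x[i], direction = "in"),
        tibble(box = b$box[i + 1], species = sp,
               process = paste0("exchange_to_", b$box[i]),
               flux_Mg_yr = k * x[i + 1], direction = "out"),
        tibble(box = b$box[i], species = sp,
               process = paste0("exchange_from_", b$box[i + 1]),
               flux_Mg_yr = k * x[i + 1], direction = "in")))
    }
  }
  bind_rows(rows)
}

#' @export
print.hg_alpha_fit <- function(x, ...) {
  cat(sprintf(
    "<hg_alpha_fit> alpha = %.6g (target NH Hg0 %.4g ng m-3, achieved %.8g)\n",
    x$alpha, x$target, x$achieved))
  print(x$state)
  invisible(x)
}
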
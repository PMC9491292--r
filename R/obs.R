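# Observation pipeline: from site flux measurements and STP-referenced Hg0
# concentrations to annual dry-deposition velocities, group statistics and
# model-observation comparison.

#' Total foliar uptake flux
#'
#' `total foliar uptake = litterfall + throughfall - open-field wet
#' deposition`: the total dry-deposited Hg to foliage. A negative result is
#' retained but flagged with a warning (wet deposition exceeding canopy
#' fluxes usually indicates a site mismatch).
#'
#' @param litterfall,throughfall,wetdep Fluxes (ug m-2 yr-1), `>= 0`.
#' @return Total foliar uptake flux (ug m-2 yr-1).
#' @examples
#' foliar_uptake(49, 72, 18)  # 103
#' @export
foliar_uptake <- function(litterfall, throughfall, wetdep) {
  check_non_negative(litterfall, "litterfall")
  check_non_negative(throughfall, "throughfall")
  check_non_negative(wetdep, "wetdep")
  out <- litterfall + throughfall - wetdep
  if (any(out < 0)) {
    warn(sprintf("%d negative total foliar uptake flux(es) retained.",
                 sum(out < 0)))
  }
  out
}

#' Convert an STP-referenced concentration to local conditions
#'
#' Hg0 concentrations are reported at STP (273 K, 1 atm); fluxes are measured
#' under local conditions. At fixed mixing ratio the number density rescales
#' as `c_local = c_stp * (273 / T) * (P / 1 atm)`.
#'
#' @param c_stp Concentration at STP (ng m-3).
#' @param temp Local annual mean temperature (K), `> 0`.
#' @param pressure Local pressure (atm), `> 0`.
#' @return Concentration at local conditions (ng m-3).
#' @export
stp_to_local <- function(c_stp, temp, pressure) {
  check_positive(temp, "temp")
  check_positive(pressure, "pressure")
  c_stp * (STP_TEMPERATURE / temp) * (pressure / STP_PRESSURE)
}

#' Dry-deposition velocity from an annual flux and a concentration
#'
#' `v_d = F / C` with `F` in ug m-2 yr-1, `C` in ng m-3, a 365-day year
#' (3.1536e7 s) and the result in cm s-1. Exactly inverse to
#' [deposition_flux()].
#'
#' @param flux Annual uptake flux (ug m-2 yr-1), `>= 0`.
#' @param c_local Local-condition concentration (ng m-3), `> 0`.
#' @return v_d (cm s-1).
#' @examples
#' velocity_from_flux(103, 0.93)  # ~ 0.351 cm s-1
#' @export
velocity_from_flux <- function(flux, c_local) {
  check_positive(c_local, "c_local")
  (flux * 1e3 / c_local) / SECONDS_PER_YEAR * 100
}

#' Derive annual dry-deposition velocities from a site database
#'
#' For each record: picks the uptake flux for its method (`litterfall` uses
#' the litterfall flux; `total_foliar` computes
#' litterfall + throughfall - wet deposition; `micromet` uses the measured
#' net-exchange flux in `nee_flux`), corrects the STP concentration to local
#' temperature/pressure, and divides. Records without a usable concentration
#' are excluded from the velocity table with a message (they remain valid
#' flux records). Negative fluxes are retained and flagged.
#'
#' @param sites Site tibble with columns `site_id`, `method`
#'   (`"litterfall"`, `"total_foliar"`, `"micromet"`), `litterfall_flux`,
#'   `throughfall_flux`, `openfield_wetdep_flux`, `nee_flux` (each ug m-2
#'   yr-1; unused ones may be `NA`), `hg0_conc_stp` (ng m-3 at STP),
#'   `local_temp` (K), `local_pressure` (atm); extra columns (coordinates,
#'   `land_class`, `region`, `year`) are carried through.
#' @return A tibble of velocity records: the carried-through metadata plus
#'   `uptake_flux` (ug m-2 yr-1), `conc_local` (ng m-3),
#'   `stp_correction` (applied factor), `v_cm_s` and `negative_flux`.
#' @export
derive_velocities <- function(sites) {
  check_columns(sites, c("site_id", "method", "hg0_conc_stp",
                         "local_temp", "local_pressure"), "sites")
  bad_method <- setdiff(unique(sites$method),
                        c("litterfall", "total_foliar", "micromet"))
  if (length(bad_method) > 0) {
    abort(sprintf("unknown method(s): %s.", paste(bad_method, collapse = ", ")))
  }
  tf <- sites$method == "total_foliar"
  if (any(tf)) {
    need <- c("litterfall_flux", "throughfall_flux", "openfield_wetdep_flux")
    check_columns(sites, need, "sites")
    if (anyNA(sites[tf, need])) {
      abort("total_foliar records require litterfall, throughfall and open-field wet deposition fluxes.")
    }
  }
  out <- sites |>
    mutate(uptake_flux = case_when(
      .data$method == "litterfall" ~ .data$litterfall_flux,
      .data$method == "total_foliar" ~
        .data$litterfall_flux + .data$throughfall_flux - .data$openfield_wetdep_flux,
      .data$method == "micromet" ~ .data$nee_flux))
  n_neg <- sum(out$uptake_flux < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warn(sprintf("%d negative uptake flux(es) retained and flagged.", n_neg))
  }
  usable <- !is.na(out$hg0_conc_stp) & out$hg0_conc_stp > 0 &
    !is.na(out$uptake_flux)
  if (any(!usable)) {
    message(sprintf(
      "%d record(s) without usable concentration or flux excluded from velocity derivation.",
      sum(!usable)))
  }
  out |>
    filter(usable) |>
    mutate(stp_correction = (STP_TEMPERATURE / .data$local_temp) *
             (.data$local_pressure / STP_PRESSURE),
           conc_local = .data$hg0_conc_stp * .data$stp_correction,
           v_cm_s = (.data$uptake_flux * 1e3 / .data$conc_local) /
             SECONDS_PER_YEAR * 100,
           negative_flux = .data$uptake_flux < 0) |>
    select(-any_of(c("litterfall_flux", "throughfall_flux",
                     "openfield_wetdep_flux", "nee_flux")))
}

#' Group statistics of derived velocities
#'
#' Median, quartiles (linear-interpolation convention, `stats::quantile`
#' type 7) and counts per group.
#'
#' @param records A tibble, e.g. from [derive_velocities()].
#' @param ... Grouping columns (tidy-select, e.g. `method, region`).
#' @param value Column to summarise (default `v_cm_s`).
#' @return A tibble with `n`, `median`, `q25`, `q75` per group.
#' @export
group_stats <- function(records, ..., value = "v_cm_s") {
  check_columns(records, value, "records")
  records |>
    group_by(...) |>
    summarise(n = dplyr::n(),
              median = median(.data[[value]]),
              q25 = quantile(.data[[value]], 0.25, type = 7, names = FALSE),
              q75 = quantile(.data[[value]], 0.75, type = 7, names = FALSE),
              .groups = "drop")
}

#' Compare modelled and observed site velocities
#'
#' Joins modelled and observed velocity tables on `site_id` and reports
#' per-site ratio and difference; with `group` set, also the per-group
#' median ratio/difference (observation relative to model).
#'
#' @param model Tibble with `site_id` and `v_cm_s` (modelled).
#' @param obs Tibble with `site_id` and `v_cm_s` (observed).
#' @param group Optional character vector of grouping columns (taken from
#'   `obs`).
#' @return With `group = NULL`, a per-site tibble with `v_model`, `v_obs`,
#'   `ratio_obs_model`, `diff_obs_model`; otherwise the per-group summary
#'   (`n`, `median_ratio`, `median_diff`, `median_model`, `median_obs`).
#' @export
model_obs_compare <- function(model, obs, group = NULL) {
  check_columns(model, c("site_id", "v_cm_s"), "model")
  check_columns(obs, c("site_id", "v_cm_s"), "obs")
  per_site <- obs |>
    rename(v_obs = "v_cm_s") |>
    inner_join(model |> select("site_id", v_model = "v_cm_s"), by = "site_id") |>
    mutate(ratio_obs_model = .data$v_obs / .data$v_model,
           diff_obs_model = .data$v_obs - .data$v_model)
  if (nrow(per_site) == 0) abort("no matched site ids between model and obs.")
  if (is.null(group)) return(per_site)
  per_site |>
    group_by(across(all_of(group))) |>
    summarise(n = dplyr::n(),
              median_ratio = median(.data$ratio_obs_model),
              median_diff = median(.data$diff_obs_model),
              median_model = median(.data$v_model),
              median_obs = median(.data$v_obs),
              .groups = "drop")
}
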
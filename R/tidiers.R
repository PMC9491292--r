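# Broom-style accessors for the box-model tuning fit.

#' Tidy a reduction-coefficient fit
#'
#' @param x An `hg_alpha_fit` from [tune_alpha()].
#' @param ... Unused.
#' @return One row per box with the steady-state burdens and surface
#'   concentration at the tuned coefficient.
#' @export
tidy.hg_alpha_fit <- function(x, ...) {
  x$state |> mutate(alpha = x$alpha, .before = 1)
}

#' One-row summary of a reduction-coefficient fit
#'
#' @param x An `hg_alpha_fit` from [tune_alpha()].
#' @param ... Unused.
#' @return A one-row tibble: tuned `alpha`, target and achieved NH Hg0
#'   concentration, total Hg0/Hg2+ burdens and root-finder iterations.
#' @export
glance.hg_alpha_fit <- function(x, ...) {
  tibble(alpha = x$alpha,
         target_ng_m3 = x$target,
         achieved_ng_m3 = x$achieved,
         residual_ng_m3 = x$achieved - x$target,
         hg0_burden_Mg = sum(x$state$hg0_Mg),
         hg2_burden_Mg = sum(x$state$hg2_Mg),
         iterations = x$iterations)
}
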
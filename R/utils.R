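# Internal argument checks. Errors name the offending field so callers can
# trace rejected inputs back to a column in their tables.

check_positive <- function(x, name) {
  if (any(!is.finite(x) | x <= 0)) {
    abort(sprintf("`%s` must be positive and finite (offending values present).", name))
  }
  invisible(x)
}

check_non_negative <- function(x, name, allow_na = FALSE) {
  bad <- if (allow_na) !is.na(x) & x < 0 else is.na(x) | x < 0
  if (any(bad)) {
    abort(sprintf("`%s` must be non-negative.", name))
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (any(is.na(x) | x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Fraction normalisation guard shared by cell_velocity / velocity_field /
# landsurface transforms: sums must be 1 within 1e-6.
check_fraction_sums <- function(df, name, tol = 1e-6) {
  sums <- df |>
    group_by(.data$cell_id) |>
    summarise(s = sum(.data$fraction), .groups = "drop")
  bad <- sums |> filter(abs(.data$s - 1) > tol)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "land-use fractions in `%s` must sum to 1 per cell (worst offender: cell %s, sum %.8f).",
      name, bad$cell_id[1], bad$s[1]))
  }
  invisible(df)
}
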
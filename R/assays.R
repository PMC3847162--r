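#' Fraction-adapted estimator from plate counts
#'
#' The fraction of adapted cells at a time point is the average number of
#' colonies per selective (glucose) plate divided by the total
#' colony-forming units, measured as the average count on the rich-medium
#' (YPD) plates. The ratio is deliberately not clipped at 1: counting
#' fluctuations (and differential plating efficiency) can push it above
#' one, and that is part of the signal. Uncertainty is propagated assuming
#' Poisson-distributed per-plate counts:
#' `SE(f) = f * sqrt(1 / (k_g * mean_g) + 1 / (k_y * mean_y))` with `k` the
#' number of plates of each type.
#'
#' @param data Tibble of per-plate counts with a `medium` column
#'   (`"glucose"` / `"ypd"`) and a `count` column, e.g. from
#'   [gen_plate_counts()]. Any `time_label` column defines grouping, so a
#'   whole time course can be passed at once.
#' @param count_col,medium_col Column names.
#' @return A tibble with one row per time point: `time_label` (if present),
#'   `fraction_adapted`, `se`, `n_glucose_plates`, `n_ypd_plates`,
#'   `mean_glucose`, `mean_ypd`.
#' @export
#' @examples
#' counts <- gen_plate_counts(frac_adapted = 0.1, n_plated = 500, seed = 1)
#' fraction_adapted(counts)
fraction_adapted <- function(data, count_col = "count",
                             medium_col = "medium") {
  stopifnot(all(c(count_col, medium_col) %in% names(data)))
  if (any(data[[count_col]] < 0)) {
    abort("plate counts must be non-negative.",
          class = "growthdyn_config_error")
  }
  grouping <- intersect("time_label", names(data))
  one <- function(df) {
    glu <- df[[count_col]][df[[medium_col]] == "glucose"]
    ypd <- df[[count_col]][df[[medium_col]] == "ypd"]
    if (length(glu) < 1 || length(ypd) < 1) {
      abort("need at least one plate of each type.",
            class = "growthdyn_config_error")
    }
    mg <- mean(glu)
    my <- mean(ypd)
    if (my == 0) {
      abort("mean YPD count is zero: fraction adapted is undefined.",
            class = "growthdyn_degenerate_error")
    }
    f <- mg / my
    se <- if (mg > 0) {
      f * sqrt(1 / (length(glu) * mg) + 1 / (length(ypd) * my))
    } else {
      # zero glucose counts: Poisson upper-bound style error from 1 count
      sqrt(1 / length(glu)) / my
    }
    tibble::tibble(fraction_adapted = f, se = se,
                   n_glucose_plates = length(glu),
                   n_ypd_plates = length(ypd),
                   mean_glucose = mg, mean_ypd = my)
  }
  if (length(grouping) == 0) {
    one(data)
  } else {
    data |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  }
}
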
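#' Pivot a wide volume table to long format
#'
#' @param table Wide volume tibble (columns `subject_id`, `group`,
#'   `site`, `sex`, `age_years`, `ticv_mm3`, `<region>_mm3`...).
#' @return Long tibble with `region` and `volume_mm3` columns.
#' @export
pivot_volumes <- function(table) {
  vol_cols <- setdiff(grep("_mm3$", names(table), value = TRUE), "ticv_mm3")
  if (length(vol_cols) == 0) abort("no `<region>_mm3` volume columns found.")
  tidyr::pivot_longer(table, dplyr::all_of(vol_cols),
                      names_to = "region", values_to = "volume_mm3",
                      names_pattern = "(.*)_mm3")
}

#' Correct a raw volume for head size
#'
#' The proportional method: corrected volume = raw volume / TICV
#' (a unitless ratio). Vectorised.
#'
#' @param volume Raw volume(s), mm^3.
#' @param ticv Total intracranial volume(s), mm^3 (> 0).
#' @return `volume / ticv`.
#' @examples
#' correct_ticv(100, 1000) # 0.1
#' @export
correct_ticv <- function(volume, ticv) {
  if (any(!is.finite(ticv)) || any(ticv <= 0)) {
    abort("`ticv` must be positive and finite.")
  }
  volume / ticv
}

#' TICV-correct a volume table
#'
#' Pivots a wide volume table to long format and adds a `corrected`
#' column plus the integer `age_year` bin used throughout norm building
#' (`floor(age_years)`).
#'
#' The default `"ratio"` method divides each regional volume by the
#' subject's TICV. The opt-in `"residual"` method instead removes the
#' linear TICV effect per region (residuals of volume on TICV, recentred
#' at the region mean, in mm^3); norms and Z-scoring work identically on
#' either scale.
#'
#' @param table Wide volume tibble.
#' @param method `"ratio"` (default) or `"residual"`.
#' @return Long tibble with columns `subject_id`, `group`, `site`,
#'   `sex`, `age_years`, `age_year`, `ticv_mm3`, `region`, `volume_mm3`,
#'   `corrected`.
#' @examples
#' cfg <- generator_config(n_subjects = 60, min_bin_n = 1, seed = 2)
#' head(correct_volumes(generate_normative_cohort(cfg)))
#' @export
correct_volumes <- function(table, method = c("ratio", "residual")) {
  method <- match.arg(method)
  long <- pivot_volumes(table)
  if (method == "ratio") {
    long <- dplyr::mutate(long,
                          corrected = correct_ticv(.data$volume_mm3, .data$ticv_mm3))
  } else {
    long <- long |>
      dplyr::group_by(.data$region) |>
      dplyr::mutate(corrected = mean(.data$volume_mm3) +
                      stats::residuals(lm(volume_mm3 ~ ticv_mm3))) |>
      dplyr::ungroup()
  }
  dplyr::mutate(long, age_year = as.integer(floor(.data$age_years)),
                .after = "age_years")
}
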
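#' Define a regional developmental trajectory preset
#'
#' A trajectory preset describes how one region's TICV-corrected volume
#' develops through adolescence under the generator's linear model:
#' `v(a) = base_fraction * (1 + apr/100 * (a - 8))`, i.e. the region
#' occupies `base_fraction` of total intracranial volume at age 8 and
#' changes by `apr` percent of that age-8 value per year. Observation
#' noise is multiplicative log-normal with log-scale SD `noise_sd`.
#'
#' @param region Region name; becomes the `<region>_mm3` column in
#'   generated volume tables.
#' @param tissue_class `"grey"` or `"white"`.
#' @param base_fraction Fraction of TICV the region occupies at age 8
#'   (unitless, > 0).
#' @param apr Annual percentage rate of change, in percent per year of
#'   the age-8 value (signed, `|apr| < 10`).
#' @param noise_sd Log-scale SD of multiplicative observation noise
#'   (>= 0). The default 0.05 corresponds to roughly a 5% coefficient of
#'   variation, typical of segmentation-derived regional volumes.
#'
#' @return A `trajectory_preset` object (a named list).
#' @examples
#' trajectory_preset("genu_cc", "white", base_fraction = 0.0015, apr = 0.1)
#' @export
trajectory_preset <- function(region, tissue_class = c("grey", "white"),
                              base_fraction, apr, noise_sd = 0.05) {
  tissue_class <- match.arg(tissue_class)
  if (!is.character(region) || length(region) != 1L || !nzchar(region)) {
    abort("`region` must be a single non-empty string.")
  }
  if (!is.numeric(base_fraction) || length(base_fraction) != 1L ||
      !is.finite(base_fraction) || base_fraction <= 0) {
    abort("`base_fraction` must be a single positive number.")
  }
  if (!is.numeric(apr) || length(apr) != 1L || !is.finite(apr) || abs(apr) >= 10) {
    abort("`apr` must be a single number in (-10, 10) percent per year.")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    abort("`noise_sd` must be a single non-negative number.")
  }
  # trajectory must stay positive across the supported age span
  if (base_fraction * (1 + apr / 100 * (22 - 8)) <= 0) {
    abort(paste0("trajectory for `", region, "` becomes non-positive before age 22."))
  }
  structure(
    list(region = region, tissue_class = tissue_class,
         base_fraction = base_fraction, apr = apr, noise_sd = noise_sd),
    class = "trajectory_preset"
  )
}

#' Default region presets calibrated to adolescent development rates
#'
#' Returns the package's default set of trajectory presets: global grey
#' and white matter aggregates plus five regions spanning the range of
#' developmental rates reported for healthy adolescents. On the
#' TICV-corrected scale, grey matter declines through adolescence
#' (posterior cingulate gyrus ~ -1.9%/yr, amygdala ~ -0.8%/yr; global
#' grey ~ -17% between ages 8 and 20) while white matter rises
#' (corticospinal tract ~ +0.8%/yr, body of corpus callosum ~ +0.5%/yr,
#' genu ~ +0.1%/yr; global white ~ +9% between 8 and 20). Global
#' aggregate APRs are the 8-to-20 percent changes divided by 12 years,
#' consistent with the linear trajectory model. Base fractions are
#' order-of-magnitude anatomical shares of TICV at age 8.
#'
#' @param noise_sd Log-scale noise SD applied to every preset.
#' @return Named list of [trajectory_preset()] objects.
#' @examples
#' names(default_presets())
#' @export
default_presets <- function(noise_sd = 0.05) {
  p <- list(
    trajectory_preset("global_grey",  "grey",  0.50,   -17 / 12, noise_sd),
    trajectory_preset("global_white", "white", 0.35,   +9 / 12,  noise_sd),
    trajectory_preset("pcg",          "grey",  0.0040, -1.9,     noise_sd),
    trajectory_preset("amygdala",     "grey",  0.0012, -0.8,     noise_sd),
    trajectory_preset("cst",          "white", 0.0080, +0.8,     noise_sd),
    trajectory_preset("body_cc",      "white", 0.0030, +0.5,     noise_sd),
    trajectory_preset("genu_cc",      "white", 0.0015, +0.1,     noise_sd)
  )
  setNames(p, vapply(p, `[[`, character(1), "region"))
}

#' Tabulate a preset list
#'
#' @param presets Named list of [trajectory_preset()] objects.
#' @return A tibble with one row per region.
#' @export
preset_table <- function(presets) {
  validate_presets(presets)
  purrr::map_dfr(presets, ~ tibble(
    region = .x$region, tissue_class = .x$tissue_class,
    base_fraction = .x$base_fraction, apr = .x$apr, noise_sd = .x$noise_sd
  ))
}

validate_presets <- function(presets) {
  if (!is.list(presets) || length(presets) == 0L ||
      !all(vapply(presets, inherits, logical(1), "trajectory_preset"))) {
    abort("`presets` must be a non-empty list of trajectory_preset objects.")
  }
  regions <- vapply(presets, `[[`, character(1), "region")
  if (anyDuplicated(regions)) {
    abort("duplicate region names in `presets`.")
  }
  invisible(presets)
}

# noiseless trajectory value at a given age (TICV-corrected scale)
preset_line <- function(preset, age) {
  preset$base_fraction * (1 + preset$apr / 100 * (age - 8))
}

# analytic SD of the TICV-corrected volume at a given age under the
# generative model: site-offset mixture x log-normal noise
preset_sd <- function(preset, age, config) {
  l <- preset_line(preset, age)
  m1 <- mean(config$site_offsets)
  m2 <- mean(config$site_offsets^2)
  s2 <- preset$noise_sd^2
  l * sqrt(m2 * exp(2 * s2) - m1^2 * exp(s2))
}
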
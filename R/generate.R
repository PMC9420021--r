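# Core sampler shared by the normative and patient generators. Assumes
# the RNG state has been set by the caller; draw order is fixed so that
# two cohorts with the same config and seed are identical column-wise.
sample_cohort <- function(config, presets, n, id_prefix, group) {
  years <- sample(seq.int(config$age_range[1], config$age_range[2]), n, replace = TRUE)
  age <- years + runif(n)
  site <- sample(seq_len(config$n_sites), n, replace = TRUE)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  ticv <- config$ticv_base *
    (1 + config$ticv_growth * (age - 8)) *
    ifelse(sex == "M", config$sex_ticv_ratio, 1) *
    exp(rnorm(n, 0, config$ticv_noise_sd))

  tab <- tibble(
    subject_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    group = group,
    site = paste0("site", site),
    sex = sex,
    age_years = age,
    ticv_mm3 = ticv
  )

  offsets <- config$site_offsets[site]
  n_out <- round(config$outlier_fraction * n)
  for (preset in presets) {
    v <- ticv * offsets * preset_line(preset, age) *
      exp(rnorm(n, 0, preset$noise_sd))
    if (n_out > 0) {
      idx <- sample.int(n, n_out)
      shift <- sample(c(-1, 1), n_out, replace = TRUE) * runif(n_out, 6, 8)
      v[idx] <- v[idx] * exp(shift * preset$noise_sd)
    }
    tab[[paste0(preset$region, "_mm3")]] <- v
  }
  tab
}

check_bins <- function(age, config) {
  if (config$min_bin_n == 0) return(invisible(NULL))
  lev <- seq.int(config$age_range[1], config$age_range[2])
  counts <- table(factor(floor(age), levels = lev))
  short <- names(counts)[counts < config$min_bin_n]
  if (length(short) > 0) {
    abort(paste0(
      "age-year bin(s) ", paste(short, collapse = ", "),
      " have fewer than min_bin_n = ", config$min_bin_n,
      " subjects; increase `n_subjects` or lower `min_bin_n`."
    ))
  }
  invisible(counts)
}

#' Generate a synthetic normative cohort
#'
#' Simulates a healthy multi-site reference population in the wide
#' volume-table format. For each subject and region,
#' `V = TICV * site_offset * base_fraction * (1 + apr/100 * (age - 8)) * exp(e)`
#' with `e ~ N(0, noise_sd^2)`; a configured fraction of cells is then
#' replaced by gross outliers (6-8 log-SD multiplicative shifts) that
#' the downstream +/-3 SD QC stage is expected to remove. TICV itself
#' is sex-dependent and grows with age, so raw volumes scale with head
#' size while TICV-corrected values follow the preset line exactly in
#' expectation.
#'
#' @param config A [generator_config()].
#' @param presets Named list of [trajectory_preset()]s; must include the
#'   regions you intend to analyse (the defaults include the global
#'   grey/white aggregates).
#' @return A wide tibble with columns `subject_id`, `group`, `site`,
#'   `sex`, `age_years`, `ticv_mm3` and one `<region>_mm3` column per
#'   preset.
#' @examples
#' cohort <- generate_normative_cohort(
#'   generator_config(n_subjects = 150, min_bin_n = 2, seed = 7)
#' )
#' dplyr::glimpse(cohort)
#' @export
generate_normative_cohort <- function(config = generator_config(),
                                      presets = default_presets()) {
  stopifnot(inherits(config, "generator_config"))
  validate_presets(presets)
  tab <- withr::with_seed(
    config$seed,
    sample_cohort(config, presets, config$n_subjects, "HC", "control")
  )
  check_bins(tab$age_years, config)
  tab
}

#' Specify injected deficits for one synthetic patient
#'
#' @param deficits Named numeric vector: region -> deficit magnitude in
#'   population SD units at the patient's age (>= 0). Empty means a
#'   volumetrically normal patient.
#' @param lesion Optional lesion specification, a list with elements
#'   `centre` (voxel coordinates) and `radius` (voxels), carried through
#'   to phantom construction.
#' @return A `deficit_spec` object.
#' @examples
#' deficit_spec(c(genu_cc = 5))
#' @export
deficit_spec <- function(deficits = numeric(), lesion = NULL) {
  if (length(deficits) > 0) {
    if (is.null(names(deficits)) || any(!nzchar(names(deficits)))) {
      abort("`deficits` must be a named vector (region -> SD units).")
    }
    if (any(deficits < 0)) abort("deficit magnitudes must be >= 0.")
  }
  if (!is.null(lesion) &&
      (!is.list(lesion) || is.null(lesion$centre) || is.null(lesion$radius))) {
    abort("`lesion` must be NULL or a list with `centre` and `radius`.")
  }
  structure(list(deficits = deficits, lesion = lesion), class = "deficit_spec")
}

#' Generate a synthetic patient cohort with known regional deficits
#'
#' One patient is generated per [deficit_spec()]. Each patient first
#' receives healthy generative volumes (same model as
#' [generate_normative_cohort()]), then every deficit region is shifted
#' down by `deficit * sigma_{region,age}` on the TICV-corrected scale,
#' where sigma is the analytic population SD at the patient's age under
#' the generative model. Ground truth is returned alongside so recovery
#' can be scored exactly.
#'
#' @param config A [generator_config()]; `n_subjects` is ignored (one
#'   patient per deficit spec).
#' @param presets Named list of [trajectory_preset()]s covering every
#'   deficit region.
#' @param deficits List of [deficit_spec()] objects.
#' @return A list with elements `table` (wide volume tibble, group
#'   `"tbi"`), `truth` (tibble `subject_id`, `region`, `deficit_sd` for
#'   every injected deficit) and `lesions` (named list of lesion specs).
#' @examples
#' pats <- generate_patient_cohort(
#'   generator_config(n_subjects = 10, min_bin_n = 1, seed = 3),
#'   deficits = list(deficit_spec(c(genu_cc = 5)), deficit_spec())
#' )
#' pats$truth
#' @export
generate_patient_cohort <- function(config = generator_config(),
                                    presets = default_presets(),
                                    deficits = list(deficit_spec())) {
  stopifnot(inherits(config, "generator_config"))
  validate_presets(presets)
  if (!is.list(deficits) ||
      !all(vapply(deficits, inherits, logical(1), "deficit_spec"))) {
    abort("`deficits` must be a list of deficit_spec objects.")
  }
  regions <- names(presets)
  wanted <- unique(unlist(lapply(deficits, function(d) names(d$deficits))))
  missing <- setdiff(wanted, regions)
  if (length(missing) > 0) {
    abort(paste0("deficit region(s) not in presets: ",
                 paste(missing, collapse = ", ")))
  }

  n <- length(deficits)
  tab <- withr::with_seed(
    config$seed,
    sample_cohort(config, presets, n, "TBI", "tbi")
  )

  truth <- list()
  for (i in seq_len(n)) {
    d <- deficits[[i]]$deficits
    for (r in names(d)) {
      if (d[[r]] == 0) next
      sig <- preset_sd(presets[[r]], tab$age_years[i], config)
      col <- paste0(r, "_mm3")
      corrected <- tab[[col]][i] / tab$ticv_mm3[i] - d[[r]] * sig
      if (corrected <= 0) {
        abort(paste0("deficit of ", d[[r]], " SD in ", r,
                     " drives subject ", tab$subject_id[i],
                     "'s volume negative."))
      }
      tab[[col]][i] <- corrected * tab$ticv_mm3[i]
      truth[[length(truth) + 1]] <- tibble(
        subject_id = tab$subject_id[i], region = r, deficit_sd = d[[r]]
      )
    }
  }
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble(subject_id = character(), region = character(), deficit_sd = numeric())
  lesions <- setNames(lapply(deficits, `[[`, "lesion"), tab$subject_id)
  list(table = tab, truth = truth, lesions = lesions)
}
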
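#' Z-score one subject against age-matched norms
#'
#' `Z_j = (v_j - mu_{j,a}) / sigma_{j,a}` where `a = floor(age)` and
#' the cell statistics come from usable norm bins. Regions missing from
#' the norms, or whose bin at this age is unusable, are reported as
#' excluded rather than scored. If no region is testable at this age
#' the call errors, pointing at the nearest usable age-year bin.
#'
#' @param volumes Named numeric vector of TICV-corrected regional
#'   values.
#' @param norms An `age_norms` object.
#' @param age Subject's age in years.
#' @return Tibble `region`, `z`, `excluded_reason` (NA when scored).
#' @export
zscore_subject <- function(volumes, norms, age) {
  stopifnot(inherits(norms, "age_norms"))
  if (is.null(names(volumes)) || any(!nzchar(names(volumes)))) {
    abort("`volumes` must be a named vector of corrected values.")
  }
  bin <- as.integer(floor(age))
  cells <- dplyr::filter(norms, .data$age_year == bin)
  usable_here <- dplyr::filter(cells, .data$usable)
  testable <- intersect(names(volumes), usable_here$region)
  if (length(testable) == 0) {
    usable_bins <- unique(norms$age_year[norms$usable])
    nearest <- if (length(usable_bins)) usable_bins[which.min(abs(usable_bins - bin))] else NA
    abort(paste0(
      "age-year bin ", bin, " is not usable for any requested region; ",
      "nearest usable bin is ", nearest,
      " (no nearest-bin fallback is applied by default)."
    ))
  }
  purrr::map_dfr(names(volumes), function(r) {
    cell <- dplyr::filter(usable_here, .data$region == r)
    if (nrow(cell) == 0) {
      in_norms <- r %in% norms$region
      tibble(region = r, z = NA_real_,
             excluded_reason = if (in_norms) "unusable age bin" else "not in norms")
    } else {
      tibble(region = r, z = (volumes[[r]] - cell$mean) / cell$sd,
             excluded_reason = NA_character_)
    }
  })
}

#' Convert a Z-score to a one-sided normal probability
#'
#' @param z Z-score(s), finite.
#' @param side `"lower"` (default; probability of a value this low or
#'   lower -- the low-volume direction), `"upper"`, or `"two"`.
#' @return p-value(s).
#' @examples
#' z_to_p(0)  # 0.5
#' z_to_p(-2) # 0.02275
#' @export
z_to_p <- function(z, side = c("lower", "upper", "two")) {
  side <- match.arg(side)
  if (any(!is.finite(z))) abort("`z` must be finite.")
  switch(side,
         lower = pnorm(z),
         upper = pnorm(z, lower.tail = FALSE),
         two = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values over the tested family (typically the set
#' of regions of interest for one subject).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) abort("`p` must be non-empty.")
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("`p` must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Flag low-volume regions and label a subject
#'
#' Applies one-sided lower-tail testing with BH FDR over the region
#' family: region j is flagged abnormal iff `q_j < alpha`. The subject
#' is labelled `"low volume"` if at least one region is flagged,
#' `"normal volume"` otherwise, and `"untestable"` when every region
#' was excluded (e.g. complete lesion coverage).
#'
#' @param zscores Tibble from [zscore_subject()] (`region`, `z`,
#'   `excluded_reason`), or a named numeric vector of Z-scores.
#' @param alpha FDR level (default 0.05).
#' @param side Test side; the default `"lower"` targets low volume.
#' @param family `"all"` (one family over every tested region, default)
#'   or `"tissue"` (separate BH families for grey and white regions;
#'   needs `tissue_map`).
#' @param tissue_map Named character vector region -> tissue class,
#'   required for `family = "tissue"`.
#' @param provenance Provenance string stored on the result (e.g.
#'   `"standard"` or `"lesion_matched"`).
#' @return A `classification` tibble: `region`, `z`, `p`, `q`, `flag`,
#'   `excluded_reason`; attributes `label`, `alpha`, `side`,
#'   `provenance`.
#' @export
classify_regions <- function(zscores, alpha = 0.05,
                             side = c("lower", "upper", "two"),
                             family = c("all", "tissue"),
                             tissue_map = NULL,
                             provenance = "standard") {
  side <- match.arg(side)
  family <- match.arg(family)
  if (is.numeric(zscores)) {
    zscores <- tibble(region = names(zscores), z = unname(zscores),
                      excluded_reason = NA_character_)
  }
  if (nrow(zscores) == 0) abort("need at least one region.")
  tested <- !is.na(zscores$z)
  if (!any(tested)) {
    res <- dplyr::mutate(zscores, p = NA_real_, q = NA_real_, flag = FALSE)
    return(structure(res, class = c("classification", class(res)),
                     label = "untestable", alpha = alpha, side = side,
                     provenance = provenance))
  }
  res <- dplyr::mutate(zscores,
                       p = dplyr::if_else(tested, z_to_p(dplyr::coalesce(.data$z, 0), side), NA_real_),
                       q = NA_real_)
  if (family == "all") {
    res$q[tested] <- fdr_adjust(res$p[tested])
  } else {
    if (is.null(tissue_map)) abort("`tissue_map` is required for family = \"tissue\".")
    classes <- tissue_map[res$region]
    if (any(is.na(classes[tested]))) abort("`tissue_map` must cover every tested region.")
    for (cl in unique(classes[tested])) {
      sel <- tested & !is.na(classes) & classes == cl
      res$q[sel] <- fdr_adjust(res$p[sel])
    }
  }
  res$flag <- !is.na(res$q) & res$q < alpha
  label <- if (any(res$flag)) "low volume" else "normal volume"
  structure(res, class = c("classification", class(res)),
            label = label, alpha = alpha, side = side,
            provenance = provenance)
}

#' @export
print.classification <- function(x, ...) {
  cat("<classification> label:", attr(x, "label"),
      "| alpha:", attr(x, "alpha"),
      "| norms:", attr(x, "provenance"), "\n")
  NextMethod()
}

#' Classify one subject end to end
#'
#' Convenience wrapper: Z-score a subject's corrected volumes against
#' norms, convert to one-sided p, BH-adjust and flag.
#'
#' @inheritParams zscore_subject
#' @inheritParams classify_regions
#' @export
classify_subject <- function(volumes, norms, age, alpha = 0.05,
                             side = "lower", family = "all",
                             tissue_map = NULL) {
  z <- zscore_subject(volumes, norms, age)
  classify_regions(z, alpha = alpha, side = side, family = family,
                   tissue_map = tissue_map,
                   provenance = attr(norms, "provenance") %||% "standard")
}

#' Classify every subject in a cohort table
#'
#' @param table Long corrected table of the subjects to classify.
#' @param norms An `age_norms` object.
#' @inheritParams classify_regions
#' @return Tibble with one row per subject x region (`subject_id`,
#'   `age_years`, `region`, `z`, `p`, `q`, `flag`, `excluded_reason`,
#'   `label`).
#' @export
classify_cohort <- function(table, norms, alpha = 0.05, side = "lower",
                            family = "all", tissue_map = NULL) {
  split(table, table$subject_id) |>
    purrr::map_dfr(function(df) {
      vols <- setNames(df$corrected, df$region)
      cl <- classify_subject(vols, norms, df$age_years[1], alpha = alpha,
                             side = side, family = family,
                             tissue_map = tissue_map)
      dplyr::mutate(as_tibble(cl),
                    subject_id = df$subject_id[1],
                    age_years = df$age_years[1],
                    label = attr(cl, "label"),
                    .before = 1)
    })
}

#' Build lesion-matched norms for one patient
#'
#' Every control's regional volumes are re-extracted with the patient's
#' lesion mask applied, then TICV-corrected, capped and normed exactly
#' like the standard pipeline, yielding a control reference that shares
#' the patient's tissue exclusion. Regions with lesion coverage at or
#' above `coverage_max` are excluded from the testable set.
#'
#' @param lesion Binary lesion array on the phantom grid.
#' @param control_phantoms List of control `phantom` objects sharing
#'   the lesion's grid geometry.
#' @param metadata Wide table with `subject_id`, `age_years`,
#'   `ticv_mm3` for every control phantom.
#' @param threshold Cap threshold in SD units.
#' @param min_bin_n Norm-bin usability floor.
#' @param coverage_max Lesion-coverage fraction at or above which a
#'   region becomes untestable (default 0.9).
#' @return An `age_norms` object with provenance `"lesion_matched"`
#'   and attribute `excluded_regions`.
#' @export
lesion_matched_norms <- function(lesion, control_phantoms, metadata,
                                 threshold = 3, min_bin_n = 45,
                                 coverage_max = 0.9) {
  if (length(control_phantoms) == 0) abort("no control phantoms supplied.")
  for (ph in control_phantoms) {
    if (!identical(dim(ph$tissue), dim(lesion))) {
      abort("control phantom grid geometry does not match the lesion grid.")
    }
  }
  vols <- purrr::map_dfr(control_phantoms, function(ph) {
    dplyr::mutate(
      extract_roi_volumes(ph, lesion_policy = "mask", lesion = lesion),
      subject_id = ph$subject_id, .before = 1
    )
  })
  coverage <- vols |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(masked_fraction = max(.data$masked_fraction), .groups = "drop")
  excluded <- coverage$region[coverage$masked_fraction >= coverage_max]

  long <- vols |>
    dplyr::left_join(metadata[, c("subject_id", "age_years", "ticv_mm3")],
                     by = "subject_id") |>
    dplyr::mutate(corrected = correct_ticv(.data$volume_mm3, .data$ticv_mm3),
                  age_year = as.integer(floor(.data$age_years))) |>
    dplyr::filter(!.data$region %in% excluded)
  if (nrow(long) == 0) abort("every region is excluded by lesion coverage.")

  capped <- cap_outliers(long, threshold = threshold)
  norms <- build_age_norms(capped$table, min_bin_n = min_bin_n)
  attr(norms, "provenance") <- "lesion_matched"
  attr(norms, "excluded_regions") <- excluded
  norms
}
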
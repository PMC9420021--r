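#' QC a corrected volume table by Z-score capping
#'
#' Within each (region, age-year) cell, observations further than
#' `threshold` cell SDs from the cell mean are removed (exclusion, not
#' winsorising) in a single pass using the original cell statistics.
#' Assuming normality, the default +/-3 SD threshold retains over 99%
#' of genuine data while discarding gross estimation failures. Cells
#' with zero SD trigger a warning and are left untouched.
#'
#' @param table Long corrected table from [correct_volumes()].
#' @param threshold Cap threshold in SD units (default 3).
#' @return List with `table` (rows kept) and `removals` (tibble
#'   `subject_id`, `region`, `age_year`, `corrected`, `z`).
#' @examples
#' cfg <- generator_config(n_subjects = 300, min_bin_n = 5, seed = 11)
#' capped <- cap_outliers(correct_volumes(generate_normative_cohort(cfg)))
#' nrow(capped$removals)
#' @export
cap_outliers <- function(table, threshold = 3) {
  if (threshold <= 0) abort("`threshold` must be positive.")
  need <- c("subject_id", "region", "age_year", "corrected")
  if (!all(need %in% names(table))) {
    abort("`table` must be a long corrected table (see correct_volumes()).")
  }
  cell_n <- dplyr::count(table, .data$region, .data$age_year)
  if (any(cell_n$n < 3)) {
    abort("every (region, age-year) cell needs at least 3 observations.")
  }
  scored <- table |>
    dplyr::group_by(.data$region, .data$age_year) |>
    dplyr::mutate(
      .mu = mean(.data$corrected),
      .sd = sd(.data$corrected),
      z = dplyr::if_else(.data$.sd > 0,
                         (.data$corrected - .data$.mu) / .data$.sd, 0)
    ) |>
    dplyr::ungroup()
  if (any(scored$.sd == 0)) {
    warn("zero-variance (region, age-year) cell(s): no removal performed there.")
  }
  out <- abs(scored$z) > threshold
  removals <- scored[out, c("subject_id", "region", "age_year", "corrected", "z")]
  kept <- scored[!out, setdiff(names(scored), c(".mu", ".sd", "z"))]
  list(table = kept, removals = removals)
}

#' Build per-age-year norms from a capped, corrected table
#'
#' Computes mean, SD and n of the corrected volume per (region,
#' age-year) cell. Bins with fewer than `min_bin_n` subjects are flagged
#' unusable (kept, but never used for Z-scoring); the default floor of
#' 45 enforces "more than 44 controls per year of age".
#'
#' @param table Long corrected table (already capped).
#' @param min_bin_n Usability floor per age-year bin.
#' @param regions Regions to include; default all present.
#' @return An `age_norms` object: tibble `region`, `age_year`, `mean`,
#'   `sd`, `n`, `usable`, with metadata attributes (`min_bin_n`,
#'   `provenance`, `excluded_regions`).
#' @export
build_age_norms <- function(table, min_bin_n = 45, regions = NULL) {
  need <- c("region", "age_year", "corrected")
  if (!all(need %in% names(table))) {
    abort("`table` must be a long corrected table (see correct_volumes()).")
  }
  regions <- regions %||% unique(table$region)
  missing <- setdiff(regions, unique(table$region))
  if (length(missing) > 0) {
    abort(paste0("region(s) absent from table: ", paste(missing, collapse = ", ")))
  }
  norms <- table |>
    dplyr::filter(.data$region %in% regions) |>
    dplyr::group_by(.data$region, .data$age_year) |>
    dplyr::summarise(mean = mean(.data$corrected),
                     sd = sd(.data$corrected),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(usable = .data$n >= min_bin_n & !is.na(.data$sd) & .data$sd > 0)
  if (any(!is.na(norms$sd) & norms$sd == 0)) {
    warn("degenerate zero-SD norm cell(s); flagged unusable.")
  }
  if (!any(norms$n >= min_bin_n)) {
    abort(paste0("no usable age-year bin (all n < min_bin_n = ", min_bin_n,
                 "); cannot build norms."))
  }
  structure(norms, class = c("age_norms", class(norms)),
            min_bin_n = min_bin_n, provenance = "standard",
            excluded_regions = character())
}

#' Serialise age norms to / from JSON
#'
#' JSON layout: `{"metadata": {...}, "regions": {region: {age: {mean,
#' sd, n, usable}}}}`.
#'
#' @param norms An `age_norms` object.
#' @param path File path.
#' @return `write_age_norms()` the path invisibly; `read_age_norms()`
#'   an `age_norms` object.
#' @export
write_age_norms <- function(norms, path) {
  stopifnot(inherits(norms, "age_norms"))
  regions <- split(norms, norms$region)
  payload <- list(
    metadata = list(min_bin_n = attr(norms, "min_bin_n"),
                    provenance = attr(norms, "provenance"),
                    excluded_regions = as.list(attr(norms, "excluded_regions"))),
    regions = lapply(regions, function(df) {
      setNames(lapply(seq_len(nrow(df)), function(i) {
        list(mean = df$mean[i], sd = df$sd[i], n = df$n[i], usable = df$usable[i])
      }), df$age_year)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_age_norms
#' @export
read_age_norms <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::imap_dfr(payload$regions, function(ages, region) {
    purrr::imap_dfr(ages, function(cell, age) {
      tibble(region = region, age_year = as.integer(age),
             mean = cell$mean, sd = cell$sd, n = as.integer(cell$n),
             usable = isTRUE(cell$usable))
    })
  })
  structure(dplyr::arrange(rows, .data$region, .data$age_year),
            class = c("age_norms", class(rows)),
            min_bin_n = payload$metadata$min_bin_n,
            provenance = payload$metadata$provenance,
            excluded_regions = unlist(payload$metadata$excluded_regions) %||% character())
}

#' @export
print.age_norms <- function(x, ...) {
  cat("<age_norms> ", length(unique(x$region)), " regions, ages ",
      min(x$age_year), "-", max(x$age_year),
      " (", attr(x, "provenance"), ", min_bin_n = ", attr(x, "min_bin_n"),
      ")\n", sep = "")
  NextMethod()
}
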
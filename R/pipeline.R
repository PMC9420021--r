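#' Configure an end-to-end pipeline run
#'
#' Collects every parameter that affects results into one object so a
#' run can be reproduced from config + seed alone. Seeds for the three
#' stochastic stages are derived deterministically from `seed`
#' (generator: `seed`; patients: `seed + 1`; battery: `seed + 2`).
#'
#' @param out_dir Output directory for artifacts.
#' @param generator A [generator_config()]; its seed is overridden by
#'   `seed`.
#' @param presets Trajectory presets.
#' @param deficits List of [deficit_spec()]s defining the synthetic
#'   patient cohort.
#' @param cap_threshold QC cap threshold in SD units.
#' @param min_bin_n Norm-bin usability floor.
#' @param alpha FDR level for classification.
#' @param coverage_max Lesion-coverage exclusion threshold.
#' @param n_factors,loading_cutoff Battery-reduction settings.
#' @param cognitive_groups Group sizes for the synthetic battery.
#' @param cognitive_effects Latent group shifts for the battery.
#' @param seed Master seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir,
                            generator = generator_config(),
                            presets = default_presets(),
                            deficits = list(
                              deficit_spec(c(genu_cc = 5)),
                              deficit_spec(c(pcg = 3, amygdala = 3)),
                              deficit_spec()
                            ),
                            cap_threshold = 3,
                            min_bin_n = 45,
                            alpha = 0.05,
                            coverage_max = 0.9,
                            n_factors = 5,
                            loading_cutoff = 0.3,
                            cognitive_groups = c(control = 60, tbi_low = 30,
                                                 tbi_normal = 40),
                            cognitive_effects = list(
                              tbi_low = c(processing_speed = -1)
                            ),
                            seed = 1L) {
  if (missing(out_dir)) abort("`out_dir` is required.")
  seed <- as.integer(seed)
  generator$seed <- seed
  structure(
    list(out_dir = out_dir, generator = generator, presets = presets,
         deficits = deficits, cap_threshold = cap_threshold,
         min_bin_n = min_bin_n, alpha = alpha, coverage_max = coverage_max,
         n_factors = n_factors, loading_cutoff = loading_cutoff,
         cognitive_groups = cognitive_groups,
         cognitive_effects = cognitive_effects, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full normative volumetry pipeline
#'
#' Executes simulate -> TICV-correct -> cap -> norms -> classify ->
#' age curves -> battery reduction -> group comparison -> per-subject
#' reports, writing every artifact under `config$out_dir` and stamping
#' the run with a config hash and seed in `manifest.json`. Any stage
#' error halts the run with the stage name and a remediation hint.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with the in-memory artifacts (`cohort`,
#'   `norms`, `curves`, `classifications`, `reduction`, `comparison`)
#'   and `files`, the written paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  files <- character()

  cohort <- stage("simulate",
                  generate_normative_cohort(config$generator, config$presets))
  pat_cfg <- config$generator
  pat_cfg$seed <- config$seed + 1L
  patients <- stage("simulate",
                    generate_patient_cohort(pat_cfg, config$presets,
                                            config$deficits))
  write.csv(cohort, out("normative_cohort.csv"), row.names = FALSE)
  write.csv(patients$table, out("patient_cohort.csv"), row.names = FALSE)
  files <- c(files, out("normative_cohort.csv"), out("patient_cohort.csv"))

  long <- stage("correct", correct_volumes(cohort))
  capped <- stage("cap", cap_outliers(long, config$cap_threshold))
  write.csv(capped$removals, out("cap_removals.csv"), row.names = FALSE)
  files <- c(files, out("cap_removals.csv"))

  norms <- stage("norms", build_age_norms(capped$table, config$min_bin_n))
  write_age_norms(norms, out("age_norms.json"))
  files <- c(files, out("age_norms.json"))

  pat_long <- stage("correct", correct_volumes(patients$table))
  classifications <- stage("classify",
                           classify_cohort(pat_long, norms,
                                           alpha = config$alpha))
  write.csv(classifications, out("classifications.csv"), row.names = FALSE)
  files <- c(files, out("classifications.csv"))

  curves <- stage("curves", fit_age_curves(capped$table))
  write.csv(curves, out("age_curves.csv"), row.names = FALSE)
  files <- c(files, out("age_curves.csv"))

  battery <- stage("reduce", generate_cognitive_battery(
    n_per_group = config$cognitive_groups,
    group_effects = config$cognitive_effects,
    seed = config$seed + 2L
  ))
  reduction <- stage("reduce",
                     reduce_battery(battery, n_factors = config$n_factors,
                                    cutoff = config$loading_cutoff))
  write.csv(tidy(reduction), out("battery_loadings.csv"), row.names = FALSE)
  write.csv(reduction$selected, out("battery_selection.csv"), row.names = FALSE)
  files <- c(files, out("battery_loadings.csv"), out("battery_selection.csv"))

  comparison <- stage("compare",
                      compare_groups(battery, reduction$selected$measure))
  write.csv(comparison$omnibus, out("group_comparison.csv"), row.names = FALSE)
  write.csv(comparison$pairwise, out("group_pairwise.csv"), row.names = FALSE)
  files <- c(files, out("group_comparison.csv"), out("group_pairwise.csv"))

  report_dir <- out("reports")
  dir.create(report_dir, showWarnings = FALSE)
  for (sid in unique(classifications$subject_id)) {
    cl <- dplyr::filter(classifications, .data$subject_id == sid)
    subj <- dplyr::filter(patients$table, .data$subject_id == sid)
    path <- file.path(report_dir, paste0(sid, ".md"))
    stage("report", writeLines(
      render_report(cl, norms, curves, subj), path
    ))
    files <- c(files, path)
  }

  manifest <- list(
    package = "pednorm",
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    alpha = config$alpha, cap_threshold = config$cap_threshold,
    min_bin_n = config$min_bin_n,
    files = as.list(basename(files))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  files <- c(files, out("manifest.json"))

  invisible(list(cohort = cohort, patients = patients, norms = norms,
                 curves = curves, classifications = classifications,
                 reduction = reduction, comparison = comparison,
                 files = files))
}

#' Render a per-subject markdown report
#'
#' Produces the textual analogue of a per-case clinical panel: subject
#' demographics, norms provenance, and a per-region table of Z, q and
#' flags, with flagged regions highlighted and untestable regions
#' annotated.
#'
#' @param classification Rows of a [classify_cohort()] result for one
#'   subject (or a `classification` object with `subject_id` absent).
#' @param norms The `age_norms` the subject was tested against.
#' @param curves Age-curve tibble from [fit_age_curves()] (regional
#'   APR context), or NULL.
#' @param subject One-row wide table with the subject's demographics.
#' @return Character vector of markdown lines, invisibly printable
#'   with `writeLines()`.
#' @export
render_report <- function(classification, norms, curves = NULL, subject = NULL) {
  fld <- function(df, nm) {
    if (!is.null(df) && nm %in% names(df)) df[[nm]] else NULL
  }
  sid <- fld(subject, "subject_id") %||%
    unique(fld(classification, "subject_id")) %||% "subject"
  label <- attr(classification, "label") %||%
    unique(fld(classification, "label")) %||% "unknown"
  lines <- c(
    paste0("# Volumetric report: ", sid),
    ""
  )
  if (!is.null(subject)) {
    lines <- c(lines, paste0(
      "- ", fld(subject, "sex") %||% "?", ", age ",
      sprintf("%.1f", fld(subject, "age_years") %||% NA_real_), " y, site ",
      fld(subject, "site") %||% "?", ", TICV ",
      format(round(fld(subject, "ticv_mm3") %||% NA_real_), big.mark = ","),
      " mm^3"
    ))
  }
  prov <- attr(norms, "provenance") %||% "standard"
  excl <- attr(norms, "excluded_regions") %||% character()
  lines <- c(lines,
             paste0("- Norms: ", prov, " (min_bin_n = ",
                    attr(norms, "min_bin_n") %||% "?", ")"),
             if (length(excl) > 0) {
               paste0("- Regions excluded by lesion coverage: ",
                      paste(excl, collapse = ", "))
             },
             paste0("- Classification: **", label, "**"),
             "", "| region | z | q | status |", "|---|---|---|---|")
  for (i in seq_len(nrow(classification))) {
    row <- classification[i, ]
    status <- if (!is.na(row$excluded_reason)) {
      paste0("untestable (", row$excluded_reason, ")")
    } else if (isTRUE(row$flag)) "**LOW**" else "normal"
    fmt <- function(x) if (is.na(x)) "-" else sprintf("%.3f", x)
    lines <- c(lines, paste0("| ", row$region, " | ", fmt(row$z), " | ",
                             fmt(row$q), " | ", status, " |"))
  }
  if (!is.null(curves)) {
    lines <- c(lines, "",
               "Population APR context (% per year, TICV-corrected):",
               paste0("- ", curves$region, ": ",
                      sprintf("%+.2f", curves$apr)))
  }
  invisible(lines)
}
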
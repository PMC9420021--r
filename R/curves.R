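#' Fit a developmental age curve for one region
#'
#' Ordinary least squares of the TICV-corrected volume on continuous
#' age. The annual percentage rate of change (APR) is the slope
#' expressed relative to the fitted value at age 8, the youngest
#' reference age: `APR = 100 * slope / V(8)`. Under this convention the
#' fitted percent change between ages 8 and 20 equals `12 * APR`.
#'
#' @param table Long corrected table ([correct_volumes()], usually
#'   after [cap_outliers()]).
#' @param region Region to fit.
#' @param baseline_age Age at which the APR denominator is evaluated
#'   (default 8).
#' @return An `age_curve` object: list with `region`, `intercept`,
#'   `slope`, `apr`, `baseline_age`, `v_baseline`, `n`, `sigma`,
#'   `r_squared` and the fitted `data` (age, corrected).
#' @examples
#' cfg <- generator_config(n_subjects = 400, min_bin_n = 5, seed = 9)
#' tab <- correct_volumes(generate_normative_cohort(cfg))
#' fit_age_curve(tab, "pcg")
#' @export
fit_age_curve <- function(table, region, baseline_age = 8) {
  need <- c("region", "age_years", "corrected")
  if (!all(need %in% names(table))) {
    abort("`table` must be a long corrected table (see correct_volumes()).")
  }
  df <- dplyr::filter(table, .data$region == !!region)
  if (nrow(df) == 0) abort(paste0("region `", region, "` not in table."))
  if (length(unique(df$age_years)) < 2) {
    abort("need at least 2 distinct ages to fit an age curve.")
  }
  fit <- lm(corrected ~ age_years, data = df)
  b <- unname(coef(fit))
  v0 <- b[1] + b[2] * baseline_age
  if (v0 <= 0) {
    abort("fitted volume at the baseline age is non-positive; APR undefined.")
  }
  structure(
    list(region = region, intercept = b[1], slope = b[2],
         apr = 100 * b[2] / v0, baseline_age = baseline_age,
         v_baseline = v0, n = nrow(df),
         sigma = summary(fit)$sigma, r_squared = summary(fit)$r.squared,
         data = df[, c("age_years", "corrected")]),
    class = "age_curve"
  )
}

#' Fit age curves for several regions at once
#'
#' @inheritParams fit_age_curve
#' @param regions Regions to fit; default all in the table.
#' @return Tibble with one row per region: `region`, `intercept`,
#'   `slope`, `apr`, `n`, `sigma`, `r_squared`.
#' @export
fit_age_curves <- function(table, regions = NULL, baseline_age = 8) {
  regions <- regions %||% unique(table$region)
  purrr::map_dfr(regions, function(r) {
    glance(fit_age_curve(table, r, baseline_age))
  })
}

#' Evaluate an age curve
#'
#' @param curve An `age_curve`.
#' @param age Age(s) in years.
#' @return Fitted corrected volume(s).
#' @export
predict_age_curve <- function(curve, age) {
  stopifnot(inherits(curve, "age_curve"))
  curve$intercept + curve$slope * age
}

#' Fitted percent change between two ages
#'
#' `100 * (V(a2) - V(a1)) / V(a1)` along the fitted line. When `a1` is
#' the APR baseline age this equals `APR * (a2 - a1)` exactly.
#'
#' @param curve An `age_curve`.
#' @param a1,a2 Ages with `a1 < a2`.
#' @return Percent change (signed).
#' @examples
#' # a curve with APR -1.9 gives -22.8% between ages 8 and 20
#' @export
percent_change_between <- function(curve, a1, a2) {
  stopifnot(inherits(curve, "age_curve"))
  if (a1 >= a2) abort("`a1` must be less than `a2`.")
  v1 <- predict_age_curve(curve, a1)
  if (v1 <= 0) abort("fitted volume at `a1` is non-positive.")
  100 * (predict_age_curve(curve, a2) - v1) / v1
}

#' @export
print.age_curve <- function(x, ...) {
  cat("<age_curve> ", x$region, ": APR = ", sprintf("%+.3f", x$apr),
      " %/yr (n = ", x$n, ", R^2 = ", sprintf("%.3f", x$r_squared), ")\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.age_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.age_curve <- function(x, ...) {
  tibble(region = x$region, intercept = x$intercept, slope = x$slope,
         apr = x$apr, n = x$n, sigma = x$sigma, r_squared = x$r_squared)
}

#' Decompose variance of a corrected volume into age, sex and cohort
#'
#' Sequential (type-I) sums of squares of the linear model
#' `corrected ~ age + sex + site`, in that fixed order, expressed as
#' percent of total variance. Because regional volumes differ by orders
#' of magnitude, the decomposition operates on a single region; a
#' tissue class is mapped to its global aggregate region
#' (`global_grey` / `global_white`).
#'
#' @param table Long corrected table.
#' @param tissue_class Optional `"grey"`/`"white"`; uses the matching
#'   global aggregate region.
#' @param region Explicit region (overrides `tissue_class`).
#' @return Tibble with columns `term` (`age`, `sex`, `cohort`) and
#'   `pct_variance`. Constant predictors get 0% with a warning.
#' @export
variance_components <- function(table, tissue_class = NULL, region = NULL) {
  if (is.null(region)) {
    if (is.null(tissue_class)) abort("give `tissue_class` or `region`.")
    region <- switch(tissue_class,
                     grey = "global_grey", white = "global_white",
                     abort(paste0("unknown tissue class `", tissue_class, "`.")))
  }
  df <- dplyr::filter(table, .data$region == !!region)
  if (nrow(df) == 0) abort(paste0("region `", region, "` not in table."))
  terms <- c(age = "age_years", sex = "sex", cohort = "site")
  usable <- vapply(terms, function(v) length(unique(df[[v]])) > 1, logical(1))
  if (!all(usable)) {
    warn(paste0("constant predictor(s): ",
                paste(names(terms)[!usable], collapse = ", "),
                "; their variance fraction is 0."))
  }
  out <- setNames(rep(0, 3), names(terms))
  if (any(usable)) {
    rhs <- paste(terms[usable], collapse = " + ")
    fit <- lm(stats::as.formula(paste("corrected ~", rhs)), data = df)
    ss <- anova(fit)
    total <- sum(ss$`Sum Sq`)
    for (nm in names(terms)[usable]) {
      out[nm] <- 100 * ss[terms[[nm]], "Sum Sq"] / total
    }
  }
  tibble(region = region, term = names(out), pct_variance = unname(out))
}
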
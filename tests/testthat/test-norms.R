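toy_table <- function(values, region = "pcg", age_year = 10) {
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_along(values)),
    region = region, age_years = age_year + 0.5,
    age_year = age_year, corrected = values
  )
}

test_that("capping removes exactly the points beyond threshold cell SDs", {
  # cell {0 x 10, 1000}: Z of the 1000 is ~3.015 > 3, so it is removed
  tab <- toy_table(c(rep(0, 10), 1000))
  res <- cap_outliers(tab)
  expect_equal(res$removals$subject_id, "S11")
  expect_equal(res$removals$z, (1000 - mean(c(rep(0, 10), 1000))) /
                 sd(c(rep(0, 10), 1000)))
  expect_gt(res$removals$z, 3)
  expect_equal(nrow(res$table), 10)

  # identical values: zero-variance cell, nothing removed, warning logged
  expect_warning(res0 <- cap_outliers(toy_table(rep(5, 6))), "zero-variance")
  expect_equal(nrow(res0$removals), 0)
})

test_that("capping is a single pass against the original cell statistics", {
  set.seed(14)
  vals <- c(rnorm(60), 8, -9)
  tab <- toy_table(vals)
  res <- cap_outliers(tab, threshold = 3)
  mu <- mean(vals); s <- sd(vals)
  brute_out <- abs(vals - mu) > 3 * s
  expect_setequal(res$removals$subject_id, tab$subject_id[brute_out])
  # one pass only: surviving points may exceed the *recomputed* SD,
  # but never the original one
  kept <- res$table$corrected
  expect_true(all(abs(kept - mu) <= 3 * s))
})

test_that("capping needs 3 observations per cell and a positive threshold", {
  expect_error(cap_outliers(toy_table(c(1, 2))), "at least 3")
  expect_error(cap_outliers(toy_table(1:5), threshold = 0), "positive")
})

test_that("norm cells equal hand-computed means and SDs", {
  tab <- dplyr::bind_rows(
    toy_table(c(1, 2, 3), age_year = 9),
    toy_table(c(10, 30, 50), age_year = 10)
  )
  norms <- build_age_norms(tab, min_bin_n = 3)
  expect_equal(norms$mean, c(2, 30))
  expect_equal(norms$sd, c(1, 20))
  expect_equal(norms$n, c(3L, 3L))
  expect_true(all(norms$usable))
  # under-filled bins flagged unusable
  tab2 <- dplyr::bind_rows(tab, toy_table(c(4, 5, 6, 7), age_year = 11))
  norms2 <- build_age_norms(tab2, min_bin_n = 4)
  expect_equal(norms2$usable, c(FALSE, FALSE, TRUE))
})

test_that("norms validate regions and usability", {
  tab <- toy_table(c(1, 2, 3))
  expect_error(build_age_norms(tab, regions = "missing_region"), "absent")
  expect_error(build_age_norms(tab, min_bin_n = 50), "no usable")
  expect_warning(norms_d <- build_age_norms(toy_table(rep(1, 5)), min_bin_n = 3),
                 "degenerate")
  expect_false(any(norms_d$usable))
  # zero-noise cohort: cell means sit exactly on the preset line
  exact <- correct_volumes(
    generate_normative_cohort(exact_config(n = 80), noise_free_presets())
  )
  norms <- build_age_norms(exact[exact$region == "genu_cc", ], min_bin_n = 1)
  mid <- exact[exact$region == "genu_cc", ] |>
    dplyr::group_by(age_year) |>
    dplyr::summarise(want = mean(line_at(0.0015, 0.1, age_years)))
  expect_equal(norms$mean, mid$want, tolerance = 1e-12)
  # a flat zero-noise trajectory exercises the degenerate-SD path
  flat <- list(flatr = trajectory_preset("flatr", "grey", 0.01, 0, 0))
  exact_flat <- correct_volumes(
    generate_normative_cohort(exact_config(n = 40), flat)
  )
  expect_warning(nf <- build_age_norms(exact_flat, min_bin_n = 1), "degenerate")
  expect_true(all(nf$sd == 0, na.rm = TRUE) && !any(nf$usable))
})

test_that("re-Z-scoring the capped table against its own norms gives mean 0, SD 1", {
  cfg <- small_config(n = 800, seed = 17)
  capped <- cap_outliers(correct_volumes(generate_normative_cohort(cfg)))
  norms <- build_age_norms(capped$table, min_bin_n = 2)
  cells <- dplyr::select(as.data.frame(norms), region, age_year,
                         mu_norm = mean, sd_norm = sd)
  rez <- capped$table |>
    dplyr::inner_join(cells, by = c("region", "age_year")) |>
    dplyr::mutate(z = (corrected - mu_norm) / sd_norm) |>
    dplyr::group_by(region, age_year) |>
    dplyr::summarise(mu = mean(z), s = sd(z), .groups = "drop")
  expect_lt(max(abs(rez$mu)), 1e-6)
  expect_lt(max(abs(rez$s - 1)), 1e-6)
})

test_that("age norms round-trip through JSON", {
  cfg <- small_config(n = 300, seed = 19)
  capped <- cap_outliers(correct_volumes(generate_normative_cohort(cfg)))
  norms <- build_age_norms(capped$table, min_bin_n = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_age_norms(norms, path)
  back <- read_age_norms(path)
  expect_equal(as.data.frame(back), as.data.frame(norms), tolerance = 1e-12)
  expect_equal(attr(back, "min_bin_n"), attr(norms, "min_bin_n"))
  expect_equal(attr(back, "provenance"), "standard")
})

test_that("age curves recover exact lines and reject degenerate input", {
  ages <- rep(seq(8, 22, by = 0.5), each = 2)
  flat <- tibble::tibble(region = "r", age_years = ages, corrected = 0.1)
  expect_equal(suppressWarnings(fit_age_curve(flat, "r"))$apr, 0)
  line <- tibble::tibble(region = "r", age_years = ages,
                         corrected = 0.1 * (1 - 0.019 * (ages - 8)))
  cv <- suppressWarnings(fit_age_curve(line, "r"))
  expect_equal(cv$apr, -1.9, tolerance = 1e-10)
  expect_error(
    fit_age_curve(tibble::tibble(region = "r", age_years = rep(10, 5),
                                 corrected = 1:5), "r"),
    "distinct ages"
  )
  expect_error(fit_age_curve(line, "absent"), "absent")
})

test_that("percent change matches the APR arithmetic identities", {
  ages <- seq(8, 22, by = 0.5)
  line <- tibble::tibble(region = "r", age_years = ages,
                         corrected = 0.1 * (1 - 0.019 * (ages - 8)))
  cv <- suppressWarnings(fit_age_curve(line, "r"))
  expect_equal(percent_change_between(cv, 8, 20), -22.8, tolerance = 1e-9)
  expect_equal(percent_change_between(cv, 8, 20), 12 * cv$apr)
  expect_error(percent_change_between(cv, 20, 8), "less than")
  # APR invariant to a global positive rescaling of volumes
  line2 <- dplyr::mutate(line, corrected = corrected * 7.3)
  expect_equal(suppressWarnings(fit_age_curve(line2, "r"))$apr, cv$apr,
               tolerance = 1e-12)
})

test_that("tidy and glance summarise age curves", {
  cfg <- small_config(n = 200, seed = 23)
  tab <- correct_volumes(generate_normative_cohort(cfg))
  cv <- fit_age_curve(tab, "cst")
  td <- tidy(cv)
  expect_equal(td$term, c("intercept", "slope"))
  gl <- glance(cv)
  expect_equal(gl$region, "cst")
  expect_equal(gl$apr, cv$apr)
  curves <- fit_age_curves(tab, c("cst", "pcg"))
  expect_equal(curves$region, c("cst", "pcg"))
})

test_that("variance components match nested-model R-squared differences", {
  cfg <- small_config(n = 600, seed = 29)
  tab <- correct_volumes(generate_normative_cohort(cfg))
  vc <- variance_components(tab, "grey")
  df <- tab[tab$region == "global_grey", ]
  r2 <- function(f) summary(lm(f, data = df))$r.squared
  want <- 100 * c(r2(corrected ~ age_years),
                  r2(corrected ~ age_years + sex) - r2(corrected ~ age_years),
                  r2(corrected ~ age_years + sex + site) -
                    r2(corrected ~ age_years + sex))
  expect_equal(vc$pct_variance, want, tolerance = 1e-8)
  expect_true(all(vc$pct_variance >= 0) && sum(vc$pct_variance) <= 100)
  # sex acts only through TICV, so its corrected-scale share is tiny
  expect_lt(vc$pct_variance[vc$term == "sex"], 1)
})

test_that("deterministic age trend yields ~100% age variance; constants warn", {
  exact <- correct_volumes(
    generate_normative_cohort(exact_config(n = 100), noise_free_presets())
  )
  # single site => cohort constant; perfect-fit anova warning is benign
  expect_warning(
    vc <- suppressWarnings(variance_components(exact, region = "pcg"),
                           classes = "simpleWarning"),
    "constant predictor"
  )
  expect_equal(vc$pct_variance[vc$term == "age"], 100, tolerance = 0.01)
  expect_equal(vc$pct_variance[vc$term == "cohort"], 0)
})
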
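norms_fixture <- function(regions = c("pcg", "genu_cc"), age_years = 8:12,
                          mean = 1, sd = 0.1, n = 50, min_bin_n = 45) {
  grid <- tidyr::expand_grid(region = regions, age_year = age_years)
  structure(
    dplyr::mutate(grid, mean = mean, sd = sd, n = n, usable = n >= min_bin_n),
    class = c("age_norms", "tbl_df", "tbl", "data.frame"),
    min_bin_n = min_bin_n, provenance = "standard",
    excluded_regions = character()
  )
}

test_that("Z-scores are exact standardized deviations from the age cell", {
  norms <- norms_fixture()
  z <- zscore_subject(c(pcg = 1, genu_cc = 0.8), norms, age = 10.6)
  expect_equal(z$z[z$region == "pcg"], 0)
  expect_equal(z$z[z$region == "genu_cc"], -2)
  # region absent from norms is excluded, not scored
  z2 <- zscore_subject(c(pcg = 1, other = 5), norms, age = 10)
  expect_equal(z2$excluded_reason[z2$region == "other"], "not in norms")
  expect_true(is.na(z2$z[z2$region == "other"]))
})

test_that("an unusable age bin errors and points at the nearest usable one", {
  norms <- norms_fixture()
  expect_error(zscore_subject(c(pcg = 1), norms, age = 20),
               "nearest usable bin is 12")
})

test_that("z_to_p matches the standard-normal CDF", {
  expect_equal(z_to_p(0), 0.5)
  expect_equal(z_to_p(-2), pnorm(-2), tolerance = 1e-12)
  expect_equal(z_to_p(-2), 0.02275, tolerance = 1e-4)
  expect_equal(z_to_p(3), 0.99865, tolerance = 1e-5)
  expect_equal(z_to_p(-1.5, side = "upper"), 1 - pnorm(-1.5))
  expect_equal(z_to_p(-1.5, side = "two"), 2 * pnorm(-1.5))
  expect_error(z_to_p(Inf), "finite")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  set.seed(3)
  for (m in c(2, 5, 8, 12)) {
    for (rep in 1:20) {
      p <- runif(m)
      expect_equal(fdr_adjust(p), bh_brute(p))
    }
  }
  expect_error(fdr_adjust(numeric()), "non-empty")
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("classification flags low-volume regions and labels subjects", {
  all_null <- classify_regions(c(pcg = 0, genu_cc = 0, cst = 0))
  expect_false(any(all_null$flag))
  expect_equal(attr(all_null, "label"), "normal volume")

  hit <- classify_regions(c(pcg = -6, genu_cc = 0))
  expect_true(hit$flag[hit$region == "pcg"])
  expect_false(hit$flag[hit$region == "genu_cc"])
  expect_equal(attr(hit, "label"), "low volume")
  expect_true(all(hit$q >= hit$p))

  # high volume is never flagged under lower-tail testing
  high <- classify_regions(c(pcg = 6, genu_cc = 6))
  expect_false(any(high$flag))
  # but is under the two-sided option
  two <- classify_regions(c(pcg = 6, genu_cc = 6), side = "two")
  expect_true(all(two$flag))
})

test_that("all-excluded subjects are labelled untestable", {
  z <- tibble::tibble(region = c("pcg", "genu_cc"), z = NA_real_,
                      excluded_reason = "unusable age bin")
  res <- classify_regions(z)
  expect_equal(attr(res, "label"), "untestable")
  expect_false(any(res$flag))
})

test_that("per-tissue families adjust separately", {
  z <- c(pcg = -2.5, amygdala = -2.5, cst = 0, body_cc = 0)
  tmap <- c(pcg = "grey", amygdala = "grey", cst = "white", body_cc = "white")
  joint <- classify_regions(z, family = "all")
  split <- classify_regions(z, family = "tissue", tissue_map = tmap)
  # grey p-values compete only with each other in the split family:
  # two tied small p's give q = p there, but q = 2p in the joint family
  p_grey <- z_to_p(-2.5)
  expect_equal(split$q[split$region == "pcg"], p_grey, tolerance = 1e-12)
  expect_equal(joint$q[joint$region == "pcg"], p_grey * 4 / 2,
               tolerance = 1e-12)
  expect_error(classify_regions(z, family = "tissue"), "tissue_map")
})

test_that("flags are monotone in injected deficit size", {
  cfg <- small_config(n = 1200, seed = 51)
  capped <- cap_outliers(correct_volumes(generate_normative_cohort(cfg)))
  norms <- build_age_norms(capped$table, min_bin_n = 45)
  flags_for <- function(d) {
    pats <- generate_patient_cohort(
      small_config(n = 1, seed = 77), default_presets(),
      list(deficit_spec(c(genu_cc = d, pcg = d)))
    )
    long <- correct_volumes(pats$table)
    cl <- classify_cohort(long, norms)
    cl$region[cl$flag]
  }
  sizes <- c(0, 2, 4, 6)
  flag_sets <- lapply(sizes, flags_for)
  for (i in seq_along(sizes)[-1]) {
    expect_true(all(flag_sets[[i - 1]] %in% flag_sets[[i]]))
  }
  expect_true(all(c("genu_cc", "pcg") %in% flag_sets[[4]]))
})

test_that("lesion-matched norms equal standard norms for an empty lesion", {
  presets <- default_presets()[c("pcg", "genu_cc", "cst")]
  pt <- preset_table(presets)
  lay <- parcellation_layout(pt$region, dim = c(8L, 8L, 8L),
                             tissue_class = setNames(pt$tissue_class, pt$region))
  controls <- generate_normative_cohort(small_config(n = 150, seed = 61), presets)
  phantoms <- lapply(seq_len(nrow(controls)), function(i) {
    generate_phantom(controls[i, ], lay)
  })
  empty <- array(0L, c(8L, 8L, 8L))
  lm_norms <- lesion_matched_norms(empty, phantoms, controls, min_bin_n = 2)
  # bitwise identical to the unmasked-extraction pipeline ...
  unmasked <- purrr::map_dfr(phantoms, function(ph) {
    dplyr::mutate(extract_roi_volumes(ph, lesion_policy = "ignore"),
                  subject_id = ph$subject_id)
  }) |>
    dplyr::left_join(controls[, c("subject_id", "age_years", "ticv_mm3")],
                     by = "subject_id") |>
    dplyr::mutate(corrected = correct_ticv(volume_mm3, ticv_mm3),
                  age_year = as.integer(floor(age_years)))
  std_ph <- build_age_norms(cap_outliers(unmasked)$table, min_bin_n = 2)
  expect_identical(lm_norms$mean, std_ph$mean)
  expect_identical(lm_norms$sd, std_ph$sd)
  # ... and equal to the tabular pipeline up to phantom round-off
  std <- build_age_norms(
    cap_outliers(correct_volumes(controls))$table, min_bin_n = 2
  )
  expect_equal(lm_norms$mean, std$mean, tolerance = 1e-10)
  expect_equal(lm_norms$sd, std$sd, tolerance = 1e-6)
  expect_equal(attr(lm_norms, "provenance"), "lesion_matched")
  expect_length(attr(lm_norms, "excluded_regions"), 0)
})

test_that("fully covered regions are excluded; partial coverage scales the mean", {
  presets <- default_presets()[c("pcg", "genu_cc")]
  pt <- preset_table(presets)
  lay <- parcellation_layout(pt$region, dim = c(8L, 8L, 8L),
                             tissue_class = setNames(pt$tissue_class, pt$region))
  # zero-noise controls so the masked mean relation is exact
  controls <- generate_normative_cohort(exact_config(n = 150),
                                        default_presets(noise_sd = 0)[c("pcg", "genu_cc")])
  phantoms <- lapply(seq_len(nrow(controls)), function(i) {
    generate_phantom(controls[i, ], lay)
  })
  lesion <- array(0L, c(8L, 8L, 8L))
  lesion[, , lay$parcellation[1, 1, ] == lay$labels[["pcg"]]] <- 1L  # all of pcg
  lesion[1:4, , lay$parcellation[1, 1, ] == lay$labels[["genu_cc"]]] <- 1L # half genu
  lm_norms <- suppressWarnings(
    lesion_matched_norms(lesion, phantoms, controls, min_bin_n = 2)
  )
  expect_equal(attr(lm_norms, "excluded_regions"), "pcg")
  expect_false("pcg" %in% lm_norms$region)
  std_mean <- correct_volumes(controls) |>
    dplyr::filter(region == "genu_cc") |>
    dplyr::group_by(age_year) |>
    dplyr::summarise(m = mean(corrected))
  genu <- lm_norms[lm_norms$region == "genu_cc", ]
  expect_equal(genu$mean, std_mean$m * 0.5, tolerance = 1e-12)
  # geometry mismatch is rejected
  expect_error(
    lesion_matched_norms(array(0L, c(4, 4, 4)), phantoms, controls,
                         min_bin_n = 2),
    "geometry"
  )
})
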
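#' Define a block factor model for a synthetic cognitive battery
#'
#' Each latent factor loads on a disjoint block of measures with a
#' common loading; unique variance makes every measure unit-variance.
#' The default emulates a paediatric neuropsychology battery with five
#' separable domains (processing speed, IQ, memory, attention,
#' executive function), three measures each.
#'
#' @param factors Named list: factor -> character vector of measure
#'   names (disjoint blocks).
#' @param loading Common standardized loading in `[0, 1)`.
#' @return A `factor_model` object.
#' @export
cognitive_factor_model <- function(factors = NULL, loading = 0.8) {
  if (is.null(factors)) {
    factors <- list(
      processing_speed = c("trails_a", "trails_b", "dkefs_speed"),
      iq = c("fsiq", "vocabulary", "matrix_reasoning"),
      memory = c("cvlt_recall", "cms_immediate", "cms_delayed"),
      attention = c("cpt_rt_change", "cpt_omissions", "cpt_variability"),
      executive = c("dkefs_switching", "digit_span", "brief_gec")
    )
  }
  measures <- unlist(factors, use.names = FALSE)
  if (anyDuplicated(measures)) abort("factor blocks must be disjoint.")
  if (length(factors) > length(measures)) {
    abort("more factors than measures.")
  }
  if (loading < 0 || loading >= 1) abort("`loading` must lie in [0, 1).")
  structure(list(factors = factors, loading = loading),
            class = "factor_model")
}

#' Generate a synthetic standardized cognitive battery
#'
#' Scores follow a block factor model: for subject i in group g,
#' measure m in factor k's block,
#' `x = loading * f_k + sqrt(1 - loading^2) * e`, with
#' `f_k ~ N(shift_g(k), 1)`. Group shifts act on the latent factors, so
#' a -1 SD shift on one factor moves its measures by about
#' `loading * 1` SD. Scores are reported on the standardized population
#' scale (mean 100, SD 15) or in z-units.
#'
#' @param n_per_group Named integer vector group -> size; default 20
#'   controls, 13 low-volume and 26 normal-volume TBI patients.
#' @param model A [cognitive_factor_model()].
#' @param group_effects Named list group -> named numeric vector
#'   (factor -> latent shift in SD units).
#' @param scale `"standard"` (100/15, default) or `"z"`.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return Tibble `subject_id`, `group`, then one column per measure.
#' @examples
#' cog <- generate_cognitive_battery(
#'   group_effects = list(tbi_low = c(processing_speed = -1)), seed = 4
#' )
#' dplyr::count(cog, group)
#' @export
generate_cognitive_battery <- function(n_per_group = c(control = 20,
                                                       tbi_low = 13,
                                                       tbi_normal = 26),
                                       model = cognitive_factor_model(),
                                       group_effects = list(),
                                       scale = c("standard", "z"),
                                       seed = 1L) {
  stopifnot(inherits(model, "factor_model"))
  scale <- match.arg(scale)
  if (is.null(names(n_per_group)) || any(n_per_group < 1)) {
    abort("`n_per_group` must be a named vector of positive counts.")
  }
  bad <- setdiff(names(group_effects), names(n_per_group))
  if (length(bad) > 0) {
    abort(paste0("group_effects for unknown group(s): ", paste(bad, collapse = ", ")))
  }
  lam <- model$loading
  uniq <- sqrt(1 - lam^2)
  withr::with_seed(seed, {
    rows <- purrr::imap(as.list(n_per_group), function(n, g) {
      shifts <- group_effects[[g]] %||% numeric()
      f <- sapply(names(model$factors), function(k) {
        mu <- if (k %in% names(shifts)) shifts[[k]] else 0
        rnorm(n, mean = mu, sd = 1)
      })
      f <- matrix(f, nrow = n,
                  dimnames = list(NULL, names(model$factors)))
      out <- tibble(group = rep(g, n))
      for (k in names(model$factors)) {
        for (m in model$factors[[k]]) {
          out[[m]] <- lam * f[, k] + uniq * rnorm(n)
        }
      }
      out
    })
    tab <- dplyr::bind_rows(rows)
  })
  measures <- unlist(model$factors, use.names = FALSE)
  if (scale == "standard") {
    tab[measures] <- lapply(tab[measures], function(x) 100 + 15 * x)
  }
  dplyr::mutate(tab,
                subject_id = sprintf("S%04d", dplyr::row_number()),
                .before = 1)
}
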
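#' Reduce a neuropsychological battery by exploratory factor analysis
#'
#' Two-step data-driven reduction of a standardized test battery:
#' maximum-likelihood exploratory factor analysis with varimax rotation
#' extracts `n_factors` latent cognitive domains; loadings below
#' `cutoff` in absolute value are zeroed for reporting; then the
#' highest-|loading| measure on each factor is selected as that
#' domain's representative for group comparison. Ties on the maximum
#' loading are broken by measure-name (alphabetical) order, with a
#' message, so the result does not depend on column order.
#'
#' @param table Cognitive tibble (`subject_id`, `group`, measure
#'   columns).
#' @param n_factors Number of factors (default 5).
#' @param cutoff Absolute loading cut-off for reporting/selection
#'   (default 0.3).
#' @param rotation Rotation passed to [stats::factanal()] (default
#'   `"varimax"`).
#' @return A `battery_reduction` object: `loadings` (full matrix),
#'   `retained` (below-cutoff loadings zeroed), `selected` (tibble
#'   `factor`, `measure`, `loading`), `explained_variance` (fraction of
#'   total variance), plus settings.
#' @examples
#' cog <- generate_cognitive_battery(
#'   n_per_group = c(control = 200, tbi = 200), seed = 5
#' )
#' red <- reduce_battery(cog)
#' red$selected
#' @export
reduce_battery <- function(table, n_factors = 5, cutoff = 0.3,
                           rotation = "varimax") {
  measures <- setdiff(names(table), c("subject_id", "group", "site", "sex",
                                      "age_years"))
  measures <- measures[vapply(table[measures], is.numeric, logical(1))]
  if (length(measures) < 2) abort("need at least two numeric measure columns.")
  if (n_factors > length(measures)) {
    abort("more factors requested than measures available.")
  }
  X <- as.matrix(table[measures])
  if (any(!is.finite(X))) abort("measure scores must be finite.")
  const <- apply(X, 2, function(x) sd(x) == 0)
  if (any(const)) {
    abort(paste0("constant measure column(s): ",
                 paste(measures[const], collapse = ", ")))
  }
  if (nrow(X) <= ncol(X)) {
    warn("fewer subjects than measures; factor solution may be unstable.")
  }
  fit <- tryCatch(
    factanal(X, factors = n_factors, rotation = rotation),
    error = function(e) {
      abort(paste0(
        "exploratory factor analysis failed (", conditionMessage(e),
        "); consider pruning collinear measures."
      ))
    }
  )
  L <- unclass(fit$loadings)[measures, , drop = FALSE]
  retained <- L
  retained[abs(retained) < cutoff] <- 0
  empty <- colSums(retained != 0) == 0
  if (any(empty)) {
    abort(paste0("loading cut-off ", cutoff, " leaves factor(s) ",
                 paste(colnames(L)[empty], collapse = ", "),
                 " with no retained measure."))
  }
  selected <- purrr::map_dfr(seq_len(ncol(L)), function(k) {
    cand <- abs(retained[, k])
    top <- max(cand)
    winners <- sort(names(cand)[cand == top]) # alphabetical tie-break
    if (length(winners) > 1) {
      inform(paste0("tie on factor ", colnames(L)[k], " broken by measure-name",
                    " order: ", winners[1]))
    }
    tibble(factor = colnames(L)[k], measure = winners[1],
           loading = L[winners[1], k])
  })
  structure(
    list(loadings = L, retained = retained, selected = selected,
         explained_variance = sum(colSums(L^2)) / nrow(L),
         n_factors = n_factors, cutoff = cutoff, rotation = rotation,
         n_subjects = nrow(X)),
    class = "battery_reduction"
  )
}

#' @export
print.battery_reduction <- function(x, ...) {
  cat("<battery_reduction> ", x$n_factors, " factors explain ",
      sprintf("%.1f%%", 100 * x$explained_variance),
      " of the variance (cutoff ", x$cutoff, ")\n", sep = "")
  print(x$selected)
  invisible(x)
}

#' @export
tidy.battery_reduction <- function(x, ...) {
  as_tibble(x$loadings, rownames = "measure") |>
    tidyr::pivot_longer(-"measure", names_to = "factor",
                        values_to = "loading") |>
    dplyr::mutate(retained = abs(.data$loading) >= x$cutoff)
}

#' @export
glance.battery_reduction <- function(x, ...) {
  tibble(n_factors = x$n_factors, n_measures = nrow(x$loadings),
         n_subjects = x$n_subjects, cutoff = x$cutoff,
         explained_variance = x$explained_variance)
}

cohens_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

#' Compare outcome measures across groups
#'
#' Per measure: one-way ANOVA (F, p, eta squared) when three or more
#' groups are present, or a Welch two-sample t-test (t, p, Cohen's d)
#' for two groups. Omnibus p-values are BH-FDR adjusted over the
#' measure family; pairwise Welch follow-ups are reported with their
#' own BH adjustment over all pairwise tests.
#'
#' @param table Cognitive tibble with a `group` column.
#' @param measures Measure columns to test; default every numeric
#'   non-identifier column.
#' @return A `group_comparison` object: `omnibus` tibble (`measure`,
#'   `test`, `statistic`, `df1`, `df2`, `p`, `q`, `effect_size`) and
#'   `pairwise` tibble (`measure`, `group1`, `group2`, `statistic`,
#'   `p`, `q`, `effect_size`).
#' @export
compare_groups <- function(table, measures = NULL) {
  if (!"group" %in% names(table)) abort("`table` needs a `group` column.")
  measures <- measures %||% {
    cand <- setdiff(names(table), c("subject_id", "group", "site", "sex",
                                    "age_years"))
    cand[vapply(table[cand], is.numeric, logical(1))]
  }
  if (length(measures) == 0) abort("no measures to compare.")
  groups <- unique(table$group)
  sizes <- table(table$group)
  if (length(groups) < 2) abort("need at least 2 groups.")
  if (any(sizes < 2)) {
    abort(paste0("group(s) with fewer than 2 subjects: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }

  omnibus <- purrr::map_dfr(measures, function(m) {
    vals <- split(table[[m]], table$group)
    if (all(vapply(vals, var, numeric(1)) == 0)) {
      abort(paste0("zero within-group variance for measure `", m,
                   "`; test statistic undefined."))
    }
    if (length(groups) >= 3) {
      fit <- aov(stats::as.formula(paste0("`", m, "` ~ group")), data = table)
      ss <- anova(fit)
      tibble(measure = m, test = "anova",
             statistic = ss["group", "F value"],
             df1 = ss["group", "Df"], df2 = ss["Residuals", "Df"],
             p = ss["group", "Pr(>F)"],
             effect_size = ss["group", "Sum Sq"] / sum(ss$`Sum Sq`))
    } else {
      tt <- t.test(vals[[1]], vals[[2]])
      tibble(measure = m, test = "welch_t",
             statistic = unname(tt$statistic),
             df1 = 1, df2 = unname(tt$parameter), p = tt$p.value,
             effect_size = cohens_d(vals[[1]], vals[[2]]))
    }
  })
  omnibus$q <- fdr_adjust(omnibus$p)
  omnibus <- dplyr::relocate(omnibus, "q", .after = "p")

  pairs <- utils::combn(sort(groups), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(measures, function(m) {
    purrr::map_dfr(pairs, function(pr) {
      x <- table[[m]][table$group == pr[1]]
      y <- table[[m]][table$group == pr[2]]
      if (var(x) == 0 && var(y) == 0) {
        return(tibble(measure = m, group1 = pr[1], group2 = pr[2],
                      statistic = NA_real_, p = NA_real_,
                      effect_size = NA_real_))
      }
      tt <- t.test(x, y)
      tibble(measure = m, group1 = pr[1], group2 = pr[2],
             statistic = unname(tt$statistic), p = tt$p.value,
             effect_size = cohens_d(x, y))
    })
  })
  ok <- !is.na(pairwise$p)
  pairwise$q <- NA_real_
  if (any(ok)) pairwise$q[ok] <- fdr_adjust(pairwise$p[ok])
  pairwise <- dplyr::relocate(pairwise, "q", .after = "p")

  structure(list(omnibus = omnibus, pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(x$omnibus)
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) x$omnibus
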
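# Small-cohort config for fast unit tests (clean measurements, one seed).
small_config <- function(n = 300, seed = 1L, ...) {
  generator_config(n_subjects = n, min_bin_n = 0, outlier_fraction = 0,
                   seed = seed, ...)
}

# Noise-free single-site config: corrected values sit exactly on the
# preset lines.
exact_config <- function(n = 60, seed = 1L) {
  generator_config(n_subjects = n, min_bin_n = 0, outlier_fraction = 0,
                   n_sites = 1, site_offsets = 1, ticv_noise_sd = 0,
                   seed = seed)
}

noise_free_presets <- function() default_presets(noise_sd = 0)

# Analytic moments of the generative model, written out independently of
# the package internals so they can serve as oracles.
line_at <- function(base, apr, age) base * (1 + apr / 100 * (age - 8))

analytic_sd <- function(base, apr, age, noise_sd, site_offsets) {
  l <- line_at(base, apr, age)
  m1 <- mean(site_offsets)
  m2 <- mean(site_offsets^2)
  l * sqrt(m2 * exp(2 * noise_sd^2) - m1^2 * exp(noise_sd^2))
}

# Balanced two-group battery on the z scale, default block model.
battery_fixture <- function(n = 400, seed = 13, loading = 0.8) {
  generate_cognitive_battery(c(control = n / 2, tbi = n / 2),
                             model = cognitive_factor_model(loading = loading),
                             scale = "z", seed = seed)
}

# Brute-force Benjamini-Hochberg: q_(i) = min_{j >= i} m * p_(j) / j.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(1, m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force voxel-loop ROI extraction (independent of the package's
# vectorised path).
extract_brute <- function(tissue, parc, lesion, label, voxel_volume) {
  d <- dim(tissue)
  vol <- 0
  n_roi <- 0
  n_hit <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (parc[i, j, k] == label) {
      n_roi <- n_roi + 1
      if (!is.null(lesion) && lesion[i, j, k] == 1) {
        n_hit <- n_hit + 1
      } else {
        vol <- vol + tissue[i, j, k]
      }
    }
  }
  list(volume = vol * voxel_volume,
       masked_fraction = if (n_roi > 0) n_hit / n_roi else NA_real_)
}
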
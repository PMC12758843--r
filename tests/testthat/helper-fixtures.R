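# shared fixtures built in code at test time

# full simulate -> extract -> assign -> fit pipeline on a scattering map
run_scatter_pipeline <- function(strain = "WT", seed = 7, noise_sd = 0.05,
                                 n_boot = 50) {
  cfg <- scenario_config(strain, seed = seed, noise_sd = noise_sd)
  map <- make_goniometry_pair(cfg)$scattering
  peaks <- extract_peaks(map)
  assigned <- assign_orders(peaks, incidence_deg = 60)
  list(
    map = map, peaks = assigned,
    fit = fit_grating_period(assigned, 60, n_boot = n_boot, seed = seed)
  )
}

# exact specular peaks on the Bragg-Snell curve, optional multiplicative jitter
specular_peaks <- function(n_avg, layer_nm, incidence = seq(15, 65, 5),
                           jitter = 0, seed = NULL) {
  lam <- bragg_wavelength(incidence, n_avg, layer_nm)
  if (jitter > 0) {
    lam <- photocolony:::with_seed_if(seed, lam * rlnorm(length(lam), 0, jitter))
  }
  tibble::tibble(incidence_deg = incidence, peak_wavelength_nm = lam)
}

# exact grating spots for given orders/wavelengths
grating_spots <- function(period, incidence, orders, wavelengths) {
  tidyr::expand_grid(order = orders, wavelength_nm = wavelengths) |>
    dplyr::mutate(
      angle_deg = purrr::map2_dbl(
        .data$wavelength_nm, .data$order,
        ~ grating_angle(.x, period, incidence, .y)
      ),
      family_factor = 1,
      intensity = 1
    ) |>
    dplyr::filter(!is.na(.data$angle_deg))
}

# brute-force BH step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}
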
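#' Diffraction grating equation
#'
#' Signed diffraction angle of order m for a surface grating of period d
#' illuminated at theta_i:
#' `theta_m = arcsin(m * lambda / d - sin(theta_i))`.
#' The sign convention is: incidence positive, so the specular reflection
#' (m = 0) appears at `-theta_i` on the detection arm. Orders whose sine
#' argument falls outside \[-1, 1\] are evanescent and return `NA` rather
#' than erroring.
#'
#' @param wavelength_nm Wavelength(s), nm (> 0). Vectorized.
#' @param period_nm Grating period d, nm (> 0).
#' @param incidence_deg Illumination angle theta_i, degrees, |theta_i| < 90.
#' @param order Integer diffraction order m (0 = specular).
#' @return Signed angle(s) in degrees; `NA_real_` where the order is
#'   evanescent.
#' @export
#' @examples
#' grating_angle(550, 410, 60, 1)   # 28.39 deg, the visible green spot
#' grating_angle(500, 410, 60, 0)   # -60 deg, specular reflection
#' grating_angle(700, 410, 60, 2)   # NA, evanescent
grating_angle <- function(wavelength_nm, period_nm, incidence_deg, order) {
  if (any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0)) {
    stop_input("`wavelength_nm` must be positive")
  }
  assert_scalar_num(period_nm, "period_nm", lower = 0, strict_lower = TRUE)
  assert_scalar_num(incidence_deg, "incidence_deg")
  if (abs(incidence_deg) >= 90) stop_input("|incidence_deg| must be < 90")
  if (length(order) != 1L || order != round(order)) {
    stop_input("`order` must be a single integer")
  }
  arg <- order * wavelength_nm / period_nm - sin(deg2rad(incidence_deg))
  out <- rep(NA_real_, length(arg))
  ok <- abs(arg) <= 1
  out[ok] <- rad2deg(asin(arg[ok]))
  out
}

#' Bragg-Snell specular reflection wavelength
#'
#' Peak reflection wavelength of a multilayer of repeat distance d and
#' effective index n_avg under illumination at theta_in, combining Bragg
#' interference with Snell refraction into the effective medium:
#' `lambda_B = 2 * n_avg * d * cos(arcsin(sin(theta_in) / n_avg))`.
#' Strictly decreasing in |theta_in|; at n_avg = 1 it reduces to the vacuum
#' form `2 d cos(theta_in)`.
#'
#' @param incidence_deg Illumination angle(s) theta_in, degrees,
#'   |theta_in| < 90. Vectorized.
#' @param n_avg Effective refractive index (>= 1).
#' @param layer_spacing_nm Multilayer repeat distance d, nm (> 0).
#' @return Peak wavelength(s) lambda_B in nm.
#' @export
#' @examples
#' bragg_wavelength(0, 1.38, 410)    # 1131.6 nm
#' bragg_wavelength(60, 1.38, 410)   # 881.0 nm
bragg_wavelength <- function(incidence_deg, n_avg, layer_spacing_nm) {
  if (any(!is.finite(incidence_deg)) || any(abs(incidence_deg) >= 90)) {
    stop_input("|incidence_deg| must be < 90")
  }
  assert_scalar_num(n_avg, "n_avg", lower = 1)
  assert_scalar_num(layer_spacing_nm, "layer_spacing_nm", lower = 0,
                    strict_lower = TRUE)
  2 * n_avg * layer_spacing_nm *
    cos(asin(sin(deg2rad(incidence_deg)) / n_avg))
}

# invented intensity plumbing: only spot POSITIONS carry scientific weight
spot_intensity <- function(order, family_factor) {
  exp(-0.7 * abs(order)) / family_factor
}

#' Enumerate diffraction spots of a photonic model
#'
#' For every wavelength on the instrument grid, every diffraction order and
#' every grating-row family, computes the grating-equation angle and keeps
#' the propagating solutions that land inside the detection range.
#' Deterministic given its inputs. Intensities follow a simple |m|- and
#' family-decay model; only positions are physically meaningful.
#'
#' @param model A [photonic_model()].
#' @param instrument An [instrument_config()] in `"scattering"` mode.
#' @return A tibble of diffraction spots with columns `wavelength_nm`,
#'   `angle_deg`, `order`, `family_factor`, `intensity`.
#' @export
enumerate_spots <- function(model, instrument) {
  stopifnot(inherits(model, "photonic_model"),
            inherits(instrument, "instrument_config"))
  if (instrument$mode != "scattering") {
    stop_input("enumerate_spots requires a scattering-mode instrument")
  }
  rng <- range(instrument$detection_grid_deg)
  grid <- tidyr::expand_grid(
    order = model$order_set,
    family_factor = model$family_factors
  )
  purrr::pmap_dfr(grid, function(order, family_factor) {
    ang <- grating_angle(instrument$wavelength_grid_nm,
                         family_factor * model$period_a,
                         instrument$incidence_deg, order)
    keep <- !is.na(ang) & ang >= rng[1] & ang <= rng[2]
    tibble::tibble(
      wavelength_nm = instrument$wavelength_grid_nm[keep],
      angle_deg = ang[keep],
      order = as.integer(order),
      family_factor = family_factor,
      intensity = spot_intensity(order, family_factor)
    )
  })
}

#' Simulate an angle-resolved scattering map
#'
#' Renders the diffraction spots of [enumerate_spots()] as Gaussian ridges in
#' angle (width `max(disorder_sigma_deg, grid step)`), adds a constant
#' background, and applies seeded multiplicative log-normal noise. The same
#' seed reproduces the map bit for bit.
#'
#' @param model A [photonic_model()].
#' @param instrument An [instrument_config()] in `"scattering"` mode.
#' @param noise_sd Log-scale sd of the multiplicative log-normal noise
#'   (>= 0; 0 disables noise).
#' @param background Constant background reflectance (>= 0).
#' @param seed Integer seed for the noise stream, or `NULL`.
#' @return A [spectral_map()] with simulation metadata.
#' @export
simulate_scattering_map <- function(model, instrument, noise_sd = 0.05,
                                    background = 0.01, seed = NULL) {
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  assert_scalar_num(background, "background", lower = 0)
  spots <- enumerate_spots(model, instrument)
  wl <- instrument$wavelength_grid_nm
  ang <- instrument$detection_grid_deg
  step <- min(diff(ang))
  sigma <- max(model$disorder_sigma_deg, step)

  refl <- matrix(background, nrow = length(wl), ncol = length(ang))
  if (nrow(spots) > 0) {
    wl_index <- match(spots$wavelength_nm, wl)
    for (k in seq_len(nrow(spots))) {
      i <- wl_index[k]
      refl[i, ] <- refl[i, ] + spots$intensity[k] *
        exp(-(ang - spots$angle_deg[k])^2 / (2 * sigma^2))
    }
  }
  if (noise_sd > 0) {
    refl <- refl * with_seed_if(seed, {
      matrix(rlnorm(length(refl), meanlog = 0, sdlog = noise_sd),
             nrow = nrow(refl))
    })
  }
  spectral_map(
    wl, ang, refl,
    metadata = list(
      mode = "scattering",
      incidence_deg = instrument$incidence_deg,
      period_a = model$period_a,
      n_avg = model$n_avg,
      noise_sd = noise_sd,
      background = background,
      seed = seed %||% NA
    )
  )
}

#' Simulate a specular reflectance map
#'
#' For each incidence angle on the grid, places a Gaussian reflectance peak
#' in wavelength centered on the Bragg-Snell wavelength
#' [bragg_wavelength()], then applies seeded multiplicative log-normal noise
#' to the map values. `center_jitter` optionally applies multiplicative
#' log-normal jitter to the peak center wavelengths themselves, emulating
#' sample-to-sample peak-position noise.
#'
#' @param model A [photonic_model()].
#' @param instrument An [instrument_config()] in `"specular"` mode; its
#'   `detection_grid_deg` enumerates the incidence angles scanned.
#' @param noise_sd Log-scale sd of multiplicative map-value noise (>= 0).
#' @param center_jitter Log-scale sd of multiplicative jitter on the Bragg
#'   peak center wavelength (>= 0, default 0). `0.01` is a 1 percent
#'   position noise.
#' @param peak_width_nm Gaussian peak width (sd) in wavelength, nm.
#' @param background Constant background reflectance (>= 0).
#' @param seed Integer seed, or `NULL`.
#' @return A [spectral_map()] with simulation metadata.
#' @export
simulate_specular_map <- function(model, instrument, noise_sd = 0.02,
                                  center_jitter = 0, peak_width_nm = 30,
                                  background = 0.01, seed = NULL) {
  stopifnot(inherits(model, "photonic_model"),
            inherits(instrument, "instrument_config"))
  if (instrument$mode != "specular") {
    stop_input("simulate_specular_map requires a specular-mode instrument")
  }
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  assert_scalar_num(center_jitter, "center_jitter", lower = 0)
  assert_scalar_num(peak_width_nm, "peak_width_nm", lower = 0, strict_lower = TRUE)
  wl <- instrument$wavelength_grid_nm
  inc <- instrument$detection_grid_deg
  centers <- bragg_wavelength(inc, model$n_avg, model$layer_spacing)

  refl <- with_seed_if(seed, {
    if (center_jitter > 0) {
      centers <- centers * rlnorm(length(centers), 0, center_jitter)
    }
    m <- vapply(seq_along(inc), function(j) {
      background + exp(-(wl - centers[j])^2 / (2 * peak_width_nm^2))
    }, numeric(length(wl)))
    if (noise_sd > 0) {
      m <- m * matrix(rlnorm(length(m), 0, noise_sd), nrow = nrow(m))
    }
    m
  })
  spectral_map(
    wl, inc, refl,
    metadata = list(
      mode = "specular",
      n_avg = model$n_avg,
      layer_spacing = model$layer_spacing,
      noise_sd = noise_sd,
      center_jitter = center_jitter,
      seed = seed %||% NA
    )
  )
}
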
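#' Photonic model of a structurally colored colony
#'
#' Ground-truth description of the colony's photonic lattice: rod-shaped cells
#' hexagonally packed in polycrystalline domains act simultaneously as a
#' surface diffraction grating (in-plane period `period_a`, the grating
#' equation's d) and as a multilayer reflector (vertical repeat
#' `layer_spacing`, the Bragg-Snell relation's d). Because hexagonal rows
#' stack at `sqrt(3)/2` times the in-plane spacing, `layer_spacing` defaults
#' to `period_a * sqrt(3) / 2`; both can be set independently.
#'
#' @param period_a In-plane inter-cell grating period, nm (> 0).
#' @param n_avg Volume-averaged effective refractive index of the
#'   cell/matrix composite (>= 1).
#' @param layer_spacing Multilayer repeat distance, nm. Default
#'   `period_a * sqrt(3) / 2` (hexagonal row stacking).
#' @param disorder_sigma_deg Gaussian angular jitter of diffraction spot
#'   positions, degrees (>= 0). Models lattice disorder; also sets the
#'   angular width of simulated ridges.
#' @param order_set Integer diffraction orders m to simulate; 0 is the
#'   specular reflection.
#' @param family_factors Positive factors scaling `period_a` into additional
#'   grating-row families (secondary spot sets seen in real maps). Default
#'   `1` (primary family only).
#' @return An object of class `photonic_model` (a validated list).
#' @export
#' @examples
#' photonic_model(period_a = 410, n_avg = 1.38)
photonic_model <- function(period_a,
                           n_avg = 1.38,
                           layer_spacing = period_a * sqrt(3) / 2,
                           disorder_sigma_deg = 1.5,
                           order_set = -2:2,
                           family_factors = 1) {
  assert_scalar_num(period_a, "period_a", lower = 0, strict_lower = TRUE)
  assert_scalar_num(n_avg, "n_avg", lower = 1)
  assert_scalar_num(layer_spacing, "layer_spacing", lower = 0, strict_lower = TRUE)
  assert_scalar_num(disorder_sigma_deg, "disorder_sigma_deg", lower = 0)
  if (!is.numeric(order_set) || length(order_set) == 0 ||
      any(order_set != round(order_set))) {
    stop_input("`order_set` must be a non-empty vector of integers")
  }
  if (!is.numeric(family_factors) || length(family_factors) == 0 ||
      any(family_factors <= 0)) {
    stop_input("`family_factors` must all be > 0")
  }
  structure(
    list(
      period_a = period_a,
      layer_spacing = layer_spacing,
      n_avg = n_avg,
      disorder_sigma_deg = disorder_sigma_deg,
      order_set = sort(unique(as.integer(order_set))),
      family_factors = sort(unique(as.numeric(family_factors)))
    ),
    class = "photonic_model"
  )
}

#' @export
print.photonic_model <- function(x, ...) {
  cat("<photonic_model>\n")
  cat(sprintf("  period_a:       %.1f nm\n", x$period_a))
  cat(sprintf("  layer_spacing:  %.1f nm\n", x$layer_spacing))
  cat(sprintf("  n_avg:          %.3f\n", x$n_avg))
  cat(sprintf("  disorder sigma: %.2f deg\n", x$disorder_sigma_deg))
  cat(sprintf("  orders:         {%s}\n", paste(x$order_set, collapse = ", ")))
  cat(sprintf("  families:       {%s}\n", paste(x$family_factors, collapse = ", ")))
  invisible(x)
}

#' Goniometer instrument configuration
#'
#' Describes one angle-resolved reflectance acquisition. In `"scattering"`
#' mode the sample is illuminated at a fixed `incidence_deg` and the detector
#' arm scans `detection_grid_deg`; in `"specular"` mode detection tracks
#' illumination (theta_out = theta_in) and `detection_grid_deg` enumerates the
#' incidence angles scanned.
#'
#' @param mode `"scattering"` or `"specular"`.
#' @param incidence_deg Illumination angle theta_i, degrees, |theta_i| < 90.
#'   Ignored in specular mode.
#' @param detection_grid_deg Strictly increasing detection (or incidence)
#'   angles in (-90, 90); default a 1-degree-resolution arm.
#' @param wavelength_grid_nm Strictly increasing positive wavelengths, nm.
#' @return An object of class `instrument_config`.
#' @export
#' @examples
#' instrument_config("scattering", incidence_deg = 60)
instrument_config <- function(mode = c("scattering", "specular"),
                              incidence_deg = 60,
                              detection_grid_deg = if (match.arg(mode) == "specular")
                                seq(15, 65, by = 5) else seq(-80, 80, by = 1),
                              wavelength_grid_nm = if (match.arg(mode) == "specular")
                                seq(400, 1200, by = 1) else seq(250, 800, by = 1)) {
  mode <- match.arg(mode)
  assert_scalar_num(incidence_deg, "incidence_deg", lower = -90, upper = 90)
  if (abs(incidence_deg) >= 90) stop_input("`incidence_deg` must satisfy |theta_i| < 90")
  if (!is.numeric(detection_grid_deg) || any(diff(detection_grid_deg) <= 0) ||
      any(abs(detection_grid_deg) >= 90)) {
    stop_input("`detection_grid_deg` must be strictly increasing within (-90, 90)")
  }
  if (!is.numeric(wavelength_grid_nm) || any(wavelength_grid_nm <= 0) ||
      any(diff(wavelength_grid_nm) <= 0)) {
    stop_input("`wavelength_grid_nm` must be positive and strictly increasing")
  }
  structure(
    list(
      mode = mode,
      incidence_deg = incidence_deg,
      detection_grid_deg = as.numeric(detection_grid_deg),
      wavelength_grid_nm = as.numeric(wavelength_grid_nm)
    ),
    class = "instrument_config"
  )
}

#' @export
print.instrument_config <- function(x, ...) {
  cat("<instrument_config>\n")
  cat(sprintf("  mode:        %s\n", x$mode))
  if (x$mode == "scattering") {
    cat(sprintf("  incidence:   %.1f deg\n", x$incidence_deg))
  }
  cat(sprintf("  angles:      %g..%g deg (%d)\n",
              min(x$detection_grid_deg), max(x$detection_grid_deg),
              length(x$detection_grid_deg)))
  cat(sprintf("  wavelengths: %g..%g nm (%d)\n",
              min(x$wavelength_grid_nm), max(x$wavelength_grid_nm),
              length(x$wavelength_grid_nm)))
  invisible(x)
}
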
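#' Construct a spectral map
#'
#' A spectral map is the unit of goniometry I/O: a non-negative reflectance
#' matrix on a wavelength (rows) by detection-angle (columns) grid, plus
#' free-text metadata (strain, mode, seed, ...). After white-reference
#' normalization, values are dimensionless ratios and `normalized` is set.
#'
#' @param wavelength_nm Strictly increasing wavelength grid, nm.
#' @param angle_deg Strictly increasing angle grid, degrees.
#' @param reflectance Non-negative numeric matrix, `length(wavelength_nm)` x
#'   `length(angle_deg)`.
#' @param metadata Named list of scalar metadata values.
#' @param normalized Logical flag: has the map been divided by a white
#'   reference?
#' @return An object of class `spectral_map`.
#' @export
spectral_map <- function(wavelength_nm, angle_deg, reflectance,
                         metadata = list(), normalized = FALSE) {
  if (any(diff(wavelength_nm) <= 0) || any(wavelength_nm <= 0)) {
    stop_input("wavelength grid must be positive and strictly increasing")
  }
  if (any(diff(angle_deg) <= 0)) {
    stop_input("angle grid must be strictly increasing")
  }
  reflectance <- as.matrix(reflectance)
  if (!identical(dim(reflectance),
                 c(length(wavelength_nm), length(angle_deg)))) {
    stop_input("reflectance must be a %d x %d matrix to match the grids",
               length(wavelength_nm), length(angle_deg))
  }
  if (any(!is.finite(reflectance)) || any(reflectance < 0)) {
    stop_input("reflectance values must be finite and >= 0")
  }
  dimnames(reflectance) <- NULL
  structure(
    list(
      wavelength_nm = as.numeric(wavelength_nm),
      angle_deg = as.numeric(angle_deg),
      reflectance = reflectance,
      metadata = metadata,
      normalized = isTRUE(normalized)
    ),
    class = "spectral_map"
  )
}

#' @export
print.spectral_map <- function(x, ...) {
  cat("<spectral_map>\n")
  cat(sprintf("  %d wavelengths (%g..%g nm) x %d angles (%g..%g deg)%s\n",
              length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm),
              length(x$angle_deg), min(x$angle_deg), max(x$angle_deg),
              if (x$normalized) ", normalized" else ""))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a spectral map to a long tibble
#'
#' @param x A [spectral_map()].
#' @param ... Unused.
#' @return A tibble with columns `wavelength_nm`, `angle_deg`, `reflectance`.
#' @export
as_tibble.spectral_map <- function(x, ...) {
  tibble::tibble(
    wavelength_nm = rep(x$wavelength_nm, times = length(x$angle_deg)),
    angle_deg = rep(x$angle_deg, each = length(x$wavelength_nm)),
    reflectance = as.vector(x$reflectance)
  )
}

#' Heatmap of a spectral map
#'
#' Renders the wavelength-by-angle reflectance matrix as the familiar
#' goniometry heatmap (wavelength on the y axis, detection angle on the x
#' axis, viridis fill).
#'
#' @param object A [spectral_map()].
#' @param trans Transformation applied to the fill scale, e.g. `"sqrt"` to
#'   compress bright diffraction spots. Default `"identity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectral_map <- function(object, trans = "identity", ...) {
  df <- as_tibble.spectral_map(object)
  mode <- object$metadata$mode %||% ""
  xlab <- if (identical(mode, "specular")) {
    "incidence angle (deg)"
  } else {
    "detection angle (deg)"
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$angle_deg, .data$wavelength_nm,
                                   fill = .data$reflectance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "reflectance") +
    ggplot2::labs(x = xlab, y = "wavelength (nm)",
                  title = object$metadata$strain %||% NULL) +
    ggplot2::theme_minimal()
}

grid_equal <- function(a, b) {
  length(a) == length(b) && all(abs(a - b) < 1e-9)
}

#' Normalize a spectral map against a white reference
#'
#' Goniometry data are reported relative to a white diffuse reference scan;
#' this divides the raw map element-wise by the reference map measured on the
#' same grids and sets the `normalized` flag.
#'
#' @param raw A raw [spectral_map()].
#' @param reference A strictly positive [spectral_map()] on identical grids.
#' @return A normalized `spectral_map`.
#' @export
normalize_to_reference <- function(raw, reference) {
  stopifnot(inherits(raw, "spectral_map"), inherits(reference, "spectral_map"))
  if (!grid_equal(raw$wavelength_nm, reference$wavelength_nm) ||
      !grid_equal(raw$angle_deg, reference$angle_deg)) {
    stop_input("raw and reference maps must share identical grids")
  }
  if (any(reference$reflectance <= 0)) {
    stop_input("reference map must be strictly positive everywhere")
  }
  spectral_map(
    raw$wavelength_nm, raw$angle_deg,
    raw$reflectance / reference$reflectance,
    metadata = raw$metadata,
    normalized = TRUE
  )
}
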
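#' Extract reflectance peaks from a spectral map
#'
#' Digitizes the bright ridges of a goniometry heatmap into discrete peaks.
#' In scattering mode, each wavelength row is scanned for local maxima over
#' detection angle whose height exceeds `prominence` times the map median,
#' separated by at least `min_separation` grid steps. In specular mode, each
#' incidence column contributes its single wavelength of maximum reflectance
#' (if it clears the same threshold). Deterministic.
#'
#' @param map A [spectral_map()].
#' @param prominence Threshold multiplier on the map median (> 0, default 3).
#' @param min_separation Minimum peak separation in grid steps (default 3).
#' @return A tibble of peaks: scattering mode gives `wavelength_nm`,
#'   `angle_deg`, `intensity`; specular mode gives `incidence_deg`,
#'   `peak_wavelength_nm`, `intensity`. The extraction parameters and mode
#'   are attached as attributes.
#' @export
extract_peaks <- function(map, prominence = 3, min_separation = 3) {
  stopifnot(inherits(map, "spectral_map"))
  assert_scalar_num(prominence, "prominence", lower = 0, strict_lower = TRUE)
  mode <- map$metadata$mode %||% "scattering"
  threshold <- max(prominence * median(map$reflectance), 1e-12)

  if (identical(mode, "specular")) {
    peaks <- purrr::map_dfr(seq_along(map$angle_deg), function(j) {
      col <- map$reflectance[, j]
      i <- which.max(col)
      if (col[i] <= threshold) return(NULL)
      tibble::tibble(
        incidence_deg = map$angle_deg[j],
        peak_wavelength_nm = map$wavelength_nm[i],
        intensity = col[i]
      )
    })
  } else {
    peaks <- purrr::map_dfr(seq_along(map$wavelength_nm), function(i) {
      row <- map$reflectance[i, ]
      found <- pracma::findpeaks(row, minpeakheight = threshold,
                                 minpeakdistance = min_separation,
                                 zero = "+")
      if (is.null(found)) return(NULL)
      tibble::tibble(
        wavelength_nm = map$wavelength_nm[i],
        angle_deg = map$angle_deg[found[, 2]],
        intensity = found[, 1]
      )
    })
  }
  if (nrow(peaks) == 0) {
    abort("no peaks found above the prominence threshold",
          class = "photocolony_no_peaks")
  }
  attr(peaks, "mode") <- mode
  attr(peaks, "extraction_params") <- list(prominence = prominence,
                                           min_separation = min_separation)
  peaks
}

#' Initial period guess from the strongest first-order spot
#'
#' Inverts the grating equation at the brightest extracted peak assuming
#' |m| = 1, skipping peaks on the specular locus (where sin(theta_m) +
#' sin(theta_i) is near zero and the period is unidentifiable).
#'
#' @param peaks Scattering-mode peak tibble from [extract_peaks()].
#' @param incidence_deg Illumination angle, degrees.
#' @return Period estimate in nm.
#' @export
initial_period <- function(peaks, incidence_deg) {
  s <- sin(deg2rad(peaks$angle_deg)) + sin(deg2rad(incidence_deg))
  usable <- abs(s) > 0.05
  if (!any(usable)) stop_input("no off-specular peaks to seed the period from")
  k <- which(usable)[which.max(peaks$intensity[usable])]
  abs(peaks$wavelength_nm[k] / s[k])
}

#' Assign diffraction orders to extracted peaks
#'
#' Labels each scattering peak with the diffraction order m and grating-row
#' family whose predicted angle (grating equation at `period_init`) lies
#' closest to the observed angle. Ties break toward smaller |m|, then
#' smaller family factor. Peaks with no candidate within `gate_deg` are
#' flagged unassigned (`order = NA`).
#'
#' @param peaks Scattering-mode peak tibble from [extract_peaks()].
#' @param incidence_deg Illumination angle theta_i, degrees.
#' @param period_init Initial period guess, nm; default
#'   [initial_period()] on the strongest spot.
#' @param order_set Candidate orders (default -3:3).
#' @param family_factors Candidate family factors (default 1).
#' @param gate_deg Maximum |observed - predicted| angle for assignment,
#'   degrees (default 5).
#' @return The peak tibble with `order`, `family_factor` and
#'   `residual_deg` columns added (NA for unassigned peaks).
#' @export
assign_orders <- function(peaks, incidence_deg,
                          period_init = initial_period(peaks, incidence_deg),
                          order_set = -3:3, family_factors = 1,
                          gate_deg = 5) {
  assert_scalar_num(period_init, "period_init", lower = 0, strict_lower = TRUE)
  # drop any pre-existing assignment columns (e.g. generator truth labels)
  peaks <- peaks[setdiff(names(peaks),
                         c("order", "family_factor", "residual_deg"))]
  cand <- tidyr::expand_grid(order = as.integer(order_set),
                             family_factor = as.numeric(family_factors))

  assigned <- purrr::map_dfr(seq_len(nrow(peaks)), function(k) {
    pred <- purrr::map2_dbl(cand$order, cand$family_factor, function(m, f) {
      grating_angle(peaks$wavelength_nm[k], f * period_init,
                    incidence_deg, m)
    })
    dev <- abs(peaks$angle_deg[k] - pred)
    ok <- !is.na(dev) & dev <= gate_deg
    if (!any(ok)) {
      return(tibble::tibble(order = NA_integer_, family_factor = NA_real_,
                            residual_deg = NA_real_))
    }
    # order candidates by closeness, ties toward smaller |m| then smaller f
    pick <- which(ok)[order(dev[ok], abs(cand$order[ok]),
                            cand$family_factor[ok])][1]
    tibble::tibble(order = cand$order[pick],
                   family_factor = cand$family_factor[pick],
                   residual_deg = dev[pick])
  })
  out <- dplyr::bind_cols(peaks, assigned)
  attr(out, "mode") <- attr(peaks, "mode")
  attr(out, "incidence_deg") <- incidence_deg
  attr(out, "period_init") <- period_init
  out
}

new_gonio_fit <- function(parameters, rms_residual, residual_unit,
                          ci95, n_points, method, seed = NULL) {
  structure(
    list(parameters = parameters, rms_residual = rms_residual,
         residual_unit = residual_unit, ci95 = ci95,
         n_points = n_points, method = method, seed = seed),
    class = "gonio_fit"
  )
}

#' @export
print.gonio_fit <- function(x, ...) {
  cat(sprintf("<gonio_fit: %s>\n", x$method))
  for (p in names(x$parameters)) {
    ci <- x$ci95[[p]]
    cat(sprintf("  %-16s %.4g  [95%% CI %.4g, %.4g]\n",
                p, x$parameters[[p]], ci[1], ci[2]))
  }
  cat(sprintf("  rms residual:    %.4g %s on %d points\n",
              x$rms_residual, x$residual_unit, x$n_points))
  invisible(x)
}

#' @describeIn fit_grating_period Tidy per-parameter summary of a
#'   goniometry fit: `term`, `estimate`, `conf.low`, `conf.high`.
#' @param x,object A `gonio_fit` object.
#' @param ... Unused.
#' @export
tidy.gonio_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$parameters),
    estimate = unname(unlist(x$parameters)),
    conf.low = vapply(x$ci95, `[`, numeric(1), 1),
    conf.high = vapply(x$ci95, `[`, numeric(1), 2)
  )
}

#' @describeIn fit_grating_period One-row fit summary: method, rms residual
#'   and its unit, number of points.
#' @export
glance.gonio_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    rms_residual = x$rms_residual,
    residual_unit = x$residual_unit,
    n_points = x$n_points
  )
}

# closed-form least squares for 1/d: sin(theta_obs) + sin(theta_i) = (m*lambda) * x
solve_period <- function(m, wavelength_nm, angle_deg, incidence_deg) {
  a <- m * wavelength_nm
  b <- sin(deg2rad(angle_deg)) + sin(deg2rad(incidence_deg))
  x <- sum(a * b) / sum(a * a)
  1 / x
}

#' Fit the grating period to assigned diffraction spots
#'
#' Least-squares inversion of the grating equation over all assigned,
#' non-specular spots: in sin-space the model is linear in 1/d,
#' `sin(theta_m) + sin(theta_i) = (m * lambda) / d`, giving a closed-form
#' estimate. The RMS angular residual is reported as the lattice disorder
#' metric, and a seeded nonparametric bootstrap over spots gives a 95
#' percent CI.
#'
#' @param peaks Assigned peak tibble from [assign_orders()].
#' @param incidence_deg Illumination angle theta_i, degrees.
#' @param n_boot Bootstrap resamples for the CI (default 200).
#' @param seed Bootstrap seed (default 1; recorded in the result).
#' @return A `gonio_fit` with parameter `period_nm`, the RMS angular
#'   residual in degrees, and bootstrap CI. Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @export
fit_grating_period <- function(peaks, incidence_deg, n_boot = 200, seed = 1) {
  use <- !is.na(peaks$order) & peaks$order != 0
  if (sum(use) == 0 && any(!is.na(peaks$order))) {
    abort("all assigned spots are specular (m = 0); the period is not identifiable",
          class = "photocolony_degenerate_fit")
  }
  if (sum(use) < 2) {
    stop_input("need at least 2 assigned spots with m != 0")
  }
  p <- peaks[use, ]
  d_hat <- solve_period(p$order, p$wavelength_nm, p$angle_deg, incidence_deg)
  pred <- purrr::map_dbl(seq_len(nrow(p)), function(k) {
    grating_angle(p$wavelength_nm[k], d_hat, incidence_deg, p$order[k])
  })
  resid <- p$angle_deg - pred
  rms <- sqrt(mean(resid^2, na.rm = TRUE))

  boot <- with_seed_if(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(nrow(p), replace = TRUE)
      solve_period(p$order[i], p$wavelength_nm[i], p$angle_deg[i],
                   incidence_deg)
    }, numeric(1))
  })
  ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  ci <- c(min(ci[1], d_hat), max(ci[2], d_hat))
  new_gonio_fit(
    parameters = list(period_nm = d_hat),
    rms_residual = rms, residual_unit = "deg",
    ci95 = list(period_nm = ci),
    n_points = nrow(p), method = "grating_period", seed = seed
  )
}

bragg_rss <- function(par, inc, lam) {
  sum((lam - bragg_wavelength(inc, par[["n_avg"]], par[["d"]]))^2)
}

#' Fit the Bragg-Snell dispersion to specular peaks
#'
#' Nonlinear least squares of
#' `lambda_B(theta_in) = 2 n_avg d cos(arcsin(sin(theta_in) / n_avg))`
#' over (n_avg, d), recovering the effective refractive index and multilayer
#' spacing from the specular peak dispersion. Because n and d are
#' near-collinear over small angular spans, the fit requires at least 3
#' points spanning at least `min_span_deg` of incidence, and multi-starts
#' n_avg from `{1.1, 1.3, 1.5}` to escape the shallow valley.
#'
#' @param peaks Specular peak tibble from [extract_peaks()]
#'   (`incidence_deg`, `peak_wavelength_nm`).
#' @param min_span_deg Minimum incidence span, degrees (default 20).
#' @param n_starts Multi-start values for n_avg.
#' @param n_boot Bootstrap resamples (default 200).
#' @param seed Bootstrap seed (default 1).
#' @return A `gonio_fit` with parameters `n_avg` and `layer_spacing_nm`,
#'   RMS wavelength residual in nm, and bootstrap CIs.
#' @export
fit_specular_dispersion <- function(peaks, min_span_deg = 20,
                                    n_starts = c(1.1, 1.3, 1.5),
                                    n_boot = 200, seed = 1) {
  inc <- peaks$incidence_deg
  lam <- peaks$peak_wavelength_nm
  if (length(inc) < 3 || diff(range(inc)) < min_span_deg) {
    abort(sprintf(
      "specular fit needs >= 3 peaks spanning >= %g deg of incidence (n and d are near-collinear below that)",
      min_span_deg), class = "photocolony_insufficient_data")
  }
  fit_once <- function(inc, lam) {
    fits <- purrr::map(n_starts, function(n0) {
      df <- data.frame(inc = inc, lam = lam)
      tryCatch(
        minpack.lm::nlsLM(
          lam ~ 2 * n_avg * d * cos(asin(sin(inc * pi / 180) / n_avg)),
          data = df,
          start = list(n_avg = n0, d = max(lam) / (2 * n0)),
          lower = c(n_avg = 1, d = 1),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
    })
    fits <- purrr::compact(fits)
    if (length(fits) == 0) stop_input("specular dispersion fit failed from all starts")
    rss <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
    stats::coef(fits[[which.min(rss)]])
  }
  est <- fit_once(inc, lam)
  pred <- bragg_wavelength(inc, est[["n_avg"]], est[["d"]])
  rms <- sqrt(mean((lam - pred)^2))

  boot <- with_seed_if(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      i <- sample.int(length(inc), replace = TRUE)
      if (length(unique(inc[i])) < 3 || diff(range(inc[i])) < min_span_deg) {
        return(c(NA_real_, NA_real_))
      }
      tryCatch(fit_once(inc[i], lam[i])[c("n_avg", "d")],
               error = function(e) c(NA_real_, NA_real_))
    }, numeric(2)))
  })
  ci_n <- unname(quantile(boot[, 1], c(0.025, 0.975), na.rm = TRUE))
  ci_d <- unname(quantile(boot[, 2], c(0.025, 0.975), na.rm = TRUE))
  new_gonio_fit(
    parameters = list(n_avg = unname(est[["n_avg"]]),
                      layer_spacing_nm = unname(est[["d"]])),
    rms_residual = rms, residual_unit = "nm",
    ci95 = list(
      n_avg = c(min(ci_n[1], est[["n_avg"]]), max(ci_n[2], est[["n_avg"]])),
      layer_spacing_nm = c(min(ci_d[1], est[["d"]]), max(ci_d[2], est[["d"]]))
    ),
    n_points = length(inc), method = "specular_dispersion", seed = seed
  )
}

#' Lattice disorder metric
#'
#' RMS deviation (degrees) of observed diffraction-spot angles from the
#' angles predicted by a fitted ideal grating: the departure of the colony
#' lattice from perfect periodicity.
#'
#' @param peaks Assigned peak tibble from [assign_orders()].
#' @param fit A `gonio_fit` from [fit_grating_period()].
#' @param incidence_deg Illumination angle, degrees.
#' @return RMS angular deviation in degrees.
#' @export
disorder_metric <- function(peaks, fit, incidence_deg) {
  stopifnot(inherits(fit, "gonio_fit"))
  d <- fit$parameters$period_nm
  use <- !is.na(peaks$order)
  p <- peaks[use, ]
  pred <- purrr::map_dbl(seq_len(nrow(p)), function(k) {
    grating_angle(p$wavelength_nm[k], d * p$family_factor[k],
                  incidence_deg, p$order[k])
  })
  ok <- !is.na(pred)
  sqrt(mean((p$angle_deg[ok] - pred[ok])^2))
}

#' Diagnostic plot of a goniometry fit
#'
#' For a grating fit, plots observed spot angles against wavelength with the
#' fitted grating-equation curves per order; for a specular fit, observed
#' peak wavelengths against incidence with the fitted Bragg-Snell curve.
#'
#' @param object A `gonio_fit`.
#' @param peaks The peak tibble the fit was computed from.
#' @param incidence_deg Illumination angle (grating fits only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gonio_fit <- function(object, peaks, incidence_deg = NULL, ...) {
  if (object$method == "specular_dispersion") {
    inc_grid <- seq(min(peaks$incidence_deg), max(peaks$incidence_deg),
                    length.out = 100)
    curve <- tibble::tibble(
      incidence_deg = inc_grid,
      peak_wavelength_nm = bragg_wavelength(inc_grid,
                                            object$parameters$n_avg,
                                            object$parameters$layer_spacing_nm)
    )
    ggplot2::ggplot(peaks, ggplot2::aes(.data$incidence_deg,
                                        .data$peak_wavelength_nm)) +
      ggplot2::geom_point() +
      ggplot2::geom_line(data = curve, color = "steelblue") +
      ggplot2::labs(x = "incidence angle (deg)", y = "peak wavelength (nm)") +
      ggplot2::theme_minimal()
  } else {
    d <- object$parameters$period_nm
    p <- peaks[!is.na(peaks$order) & peaks$order != 0, ]
    curves <- p |>
      dplyr::distinct(.data$order, .data$family_factor) |>
      purrr::pmap_dfr(function(order, family_factor) {
        wl <- seq(min(p$wavelength_nm), max(p$wavelength_nm), length.out = 200)
        tibble::tibble(
          wavelength_nm = wl,
          angle_deg = grating_angle(wl, d * family_factor, incidence_deg, order),
          order = order, family_factor = family_factor
        )
      })
    ggplot2::ggplot(p, ggplot2::aes(.data$wavelength_nm, .data$angle_deg,
                                    color = factor(.data$order))) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_line(data = curves) +
      ggplot2::labs(x = "wavelength (nm)", y = "detection angle (deg)",
                    color = "order m") +
      ggplot2::theme_minimal()
  }
}
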
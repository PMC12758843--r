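test_that("peak extraction digitizes ridges and rejects featureless maps", {
  # noiseless single ridge: one peak per wavelength, on the ridge
  model <- photonic_model(410, order_set = 1, disorder_sigma_deg = 1.5)
  instr <- instrument_config("scattering", 60,
                             wavelength_grid_nm = seq(450, 650, 10))
  map <- simulate_scattering_map(model, instr, noise_sd = 0, background = 0)
  peaks <- extract_peaks(map)
  expect_equal(nrow(peaks), length(instr$wavelength_grid_nm))
  truth <- grating_angle(peaks$wavelength_nm, 410, 60, 1)
  expect_true(all(abs(peaks$angle_deg - truth) <= 0.5 + 1e-9))

  # constant map has no peaks
  flat <- spectral_map(seq(500, 510, 1), seq(-5, 5, 1),
                       matrix(1, 11, 11), metadata = list(mode = "scattering"))
  expect_error(extract_peaks(flat), class = "photocolony_no_peaks")

  # noisy full map: >= 90% of extracted angles within 1 degree of the truth
  full <- simulate_scattering_map(photonic_model(410),
                                  instrument_config("scattering", 60),
                                  noise_sd = 0.05, seed = 1)
  pk <- extract_peaks(full)
  spots <- enumerate_spots(photonic_model(410),
                           instrument_config("scattering", 60))
  nearest <- vapply(seq_len(nrow(pk)), function(k) {
    s <- spots[spots$wavelength_nm == pk$wavelength_nm[k], ]
    if (nrow(s) == 0) Inf else min(abs(s$angle_deg - pk$angle_deg[k]))
  }, numeric(1))
  expect_gt(mean(nearest <= 1), 0.90)
})

test_that("specular extraction returns one peak per incidence angle", {
  model <- photonic_model(410, n_avg = 1.38)
  map <- simulate_specular_map(model, instrument_config("specular"),
                               noise_sd = 0.02, seed = 4)
  pk <- extract_peaks(map)
  expect_equal(pk$incidence_deg, map$angle_deg)
  expect_equal(pk$peak_wavelength_nm,
               bragg_wavelength(pk$incidence_deg, 1.38, model$layer_spacing),
               tolerance = 0.005)
})

test_that("order assignment labels synthetic spots correctly", {
  # single-order spots with true period_init: all labeled m = 1
  sp <- grating_spots(410, 60, 1, seq(450, 650, 25))
  asg <- assign_orders(sp, 60, period_init = 410)
  expect_true(all(asg$order == 1))
  # specular locus points are labeled m = 0
  sp0 <- grating_spots(410, 60, 0, seq(450, 650, 50))
  asg0 <- assign_orders(sp0, 60, period_init = 410)
  expect_true(all(asg0$order == 0))
  # mixed m in {1, 2}, init within 10% of truth: 100% correct labels
  # (gate widened because a 10% period error shifts second-order UV
  # predictions by up to ~20 deg); verified against a brute-force
  # nearest-candidate search over the label space
  sp12 <- grating_spots(410, 60, 1:2, seq(260, 370, 10))
  asg12 <- assign_orders(sp12, 60, period_init = 410 * 1.1, gate_deg = 30)
  brute <- vapply(seq_len(nrow(sp12)), function(k) {
    cand <- vapply(-3:3, function(m) {
      abs(sp12$angle_deg[k] -
            grating_angle(sp12$wavelength_nm[k], 410 * 1.1, 60, m))
    }, numeric(1))
    (-3:3)[which.min(cand)]
  }, integer(1))
  expect_equal(asg12$order, sp12$order)
  expect_equal(asg12$order, brute)
  # spots far from any candidate are flagged unassigned
  off <- tibble::tibble(wavelength_nm = 550, angle_deg = 70,
                        intensity = 1, family_factor = 1)
  expect_true(is.na(assign_orders(off, 60, period_init = 410)$order[1]))
})

test_that("grating period fit is exact on noiseless spots and matches a grid-search oracle", {
  sp <- grating_spots(410, 60, 1, seq(450, 650, 50)) |>
    assign_orders(60, period_init = 410)
  fit <- fit_grating_period(sp, 60, n_boot = 20, seed = 1)
  expect_equal(fit$parameters$period_nm, 410, tolerance = 1e-12)
  expect_equal(fit$rms_residual, 0, tolerance = 1e-9)
  expect_true(fit$ci95$period_nm[1] <= 410 && fit$ci95$period_nm[2] >= 410)

  # noisy instance, <= 20 spots: closed form equals brute-force grid search
  withr::with_seed(7, {
    sp2 <- grating_spots(365, 60, 1:2, seq(300, 640, 40))
    sp2$angle_deg <- sp2$angle_deg + rnorm(nrow(sp2), 0, 0.5)
  })
  sp2 <- assign_orders(sp2, 60, period_init = 365)
  expect_lte(nrow(sp2), 20)
  fit2 <- fit_grating_period(sp2, 60, n_boot = 20, seed = 1)
  # oracle: minimize sin-space RSS over a fine period grid
  rss <- function(d) {
    with(sp2[sp2$order != 0, ], {
      sum((sin(angle_deg * pi / 180) + sin(pi / 3) -
             order * wavelength_nm / d)^2)
    })
  }
  grid <- seq(330, 400, 0.001)
  d_oracle <- grid[which.min(vapply(grid, rss, numeric(1)))]
  expect_equal(fit2$parameters$period_nm, d_oracle, tolerance = 1e-5)
  expect_equal(fit2$parameters$period_nm, 365, tolerance = 0.01)

  # duplicating every spot leaves the point estimate unchanged
  dup <- dplyr::bind_rows(sp2, sp2)
  fit_dup <- fit_grating_period(dup, 60, n_boot = 20, seed = 1)
  expect_equal(fit_dup$parameters$period_nm, fit2$parameters$period_nm)

  # all-specular spot sets are a degenerate fit
  sp0 <- grating_spots(410, 60, 0, seq(450, 650, 50)) |>
    assign_orders(60, period_init = 410)
  expect_error(fit_grating_period(sp0, 60), class = "photocolony_degenerate_fit")
})

test_that("specular dispersion fit recovers (n, d) and enforces identifiability", {
  # noiseless inversion to 3 significant figures
  pk <- specular_peaks(1.38, 355.1, c(15, 25, 35, 45, 55, 65))
  fit <- fit_specular_dispersion(pk, n_boot = 20, seed = 1)
  expect_equal(fit$parameters$n_avg, 1.38, tolerance = 1e-4)
  expect_equal(fit$parameters$layer_spacing_nm, 355.1, tolerance = 1e-4)
  # vacuum limit: n = 1 data return n = 1.00
  pkv <- specular_peaks(1, 400, c(15, 25, 35, 45, 55, 65))
  fitv <- fit_specular_dispersion(pkv, n_boot = 20, seed = 1)
  expect_equal(fitv$parameters$n_avg, 1, tolerance = 1e-3)
  # 1% multiplicative wavelength noise: n within 0.02 of truth
  pkn <- specular_peaks(1.38, 355.07, jitter = 0.01, seed = 11)
  fitn <- fit_specular_dispersion(pkn, n_boot = 20, seed = 11)
  expect_equal(fitn$parameters$n_avg, 1.38, tolerance = 0.02 / 1.38)
  # insufficient span or points
  expect_error(fit_specular_dispersion(specular_peaks(1.38, 355, c(30, 35, 40))),
               class = "photocolony_insufficient_data")
  expect_error(fit_specular_dispersion(specular_peaks(1.38, 355, c(30, 60))),
               class = "photocolony_insufficient_data")
})

test_that("disorder metric measures rms angular deviation", {
  sp <- grating_spots(410, 60, 1, seq(450, 650, 50)) |>
    assign_orders(60, period_init = 410)
  fit <- fit_grating_period(sp, 60, n_boot = 20, seed = 1)
  expect_equal(disorder_metric(sp, fit, 60), 0, tolerance = 1e-9)

  # sigma = 0.5 deg jitter on 200 spots concentrates the sample rms
  withr::with_seed(3, {
    spj <- grating_spots(410, 60, 1, seq(451, 650, 1))
    spj$angle_deg <- spj$angle_deg + rnorm(nrow(spj), 0, 0.5)
  })
  expect_equal(nrow(spj), 200)
  spj <- assign_orders(spj, 60, period_init = 410)
  fitj <- fit_grating_period(spj, 60, n_boot = 20, seed = 1)
  dm <- disorder_metric(spj, fitj, 60)
  expect_gte(dm, 0.4)
  expect_lte(dm, 0.6)
  # invariant under spot order
  perm <- spj[rev(seq_len(nrow(spj))), ]
  expect_equal(disorder_metric(perm, fitj, 60), dm)
})

test_that("end-to-end recovery holds across a seeded period and index sweep", {
  # scattering: period sweep, 1% recovery
  for (period in c(300, 350, 400, 450, 500)) {
    for (seed in 1:3) {
      cfg_model <- photonic_model(period, n_avg = 1.38)
      map <- simulate_scattering_map(cfg_model,
                                     instrument_config("scattering", 60),
                                     noise_sd = 0.05, seed = seed)
      fit <- extract_peaks(map) |>
        assign_orders(60) |>
        fit_grating_period(60, n_boot = 20, seed = seed)
      expect_lt(abs(fit$parameters$period_nm - period) / period, 0.01)
    }
  }
  # specular: index sweep, 0.02 recovery
  for (n_true in c(1.3, 1.38, 1.45)) {
    for (seed in 1:3) {
      model <- photonic_model(410, n_avg = n_true)
      map <- simulate_specular_map(model, instrument_config("specular"),
                                   noise_sd = 0.02, seed = seed)
      fit <- extract_peaks(map) |>
        fit_specular_dispersion(n_boot = 10, seed = seed)
      expect_lt(abs(fit$parameters$n_avg - n_true), 0.02)
    }
  }
})

test_that("shrinking the period blue-shifts every visible spot at fixed angle", {
  # at fixed (theta_i, theta_m, m) the generated wavelength scales with period
  wt <- grating_spots(410, 60, 1, seq(450, 650, 25))
  mut_lambda <- wt$wavelength_nm * 365 / 410
  recomputed <- vapply(seq_len(nrow(wt)), function(k) {
    365 * (sin(wt$angle_deg[k] * pi / 180) + sin(pi / 3)) / 1
  }, numeric(1))
  expect_equal(recomputed, mut_lambda, tolerance = 1e-12)
  expect_true(all(mut_lambda < wt$wavelength_nm))
})

test_that("tidy and glance summarize goniometry fits", {
  sp <- grating_spots(410, 60, 1, seq(450, 650, 50)) |>
    assign_orders(60, period_init = 410)
  fit <- fit_grating_period(sp, 60, n_boot = 20, seed = 1)
  td <- tidy(fit)
  expect_equal(td$term, "period_nm")
  expect_true(td$conf.low <= td$estimate & td$estimate <= td$conf.high)
  gl <- glance(fit)
  expect_equal(gl$method, "grating_period")
  expect_equal(gl$n_points, nrow(sp))
})
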
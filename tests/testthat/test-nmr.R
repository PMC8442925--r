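test_that("spectrum construction validates the axis", {
  expect_error(nmr_spectrum(c(1, 2, 2, 3), rep(0, 4)), "monotone")
  expect_error(nmr_spectrum(1:3, 1:2))
  sp <- nmr_spectrum(seq(200, 0, length.out = 10), rep(0, 10))
  expect_s3_class(sp, "nmr_spectrum")
})

test_that("synthetic spectra follow the analytic model", {
  empty <- synth_spectrum(data.frame(center = numeric(0),
                                     fwhm = numeric(0),
                                     area = numeric(0)))
  expect_true(all(empty$intensity == 0))
  one <- synth_spectrum(data.frame(center = 23, fwhm = 0.6, area = 1),
                        ppm_range = c(20, 26), n_points = 601)
  expect_equal(one$ppm[which.max(one$intensity)], 23, tolerance = 1e-9)
  # determinism per seed
  a <- synth_spectrum(data.frame(center = 23, fwhm = 0.6, area = 1),
                      noise_sd = 0.01, seed = 3)
  b <- synth_spectrum(data.frame(center = 23, fwhm = 0.6, area = 1),
                      noise_sd = 0.01, seed = 3)
  expect_identical(a, b)
})

test_that("a noiseless Lorentzian is recovered to numerical precision", {
  sp <- synth_spectrum(data.frame(center = 23.0, fwhm = 0.6, area = 1.0,
                                  shape = "lorentzian"),
                       ppm_range = c(18, 28), n_points = 2000)
  fit <- fit_peaks(sp, list(list(window = c(20, 26), n_peaks = 1)),
                   shape = "lorentzian")
  expect_true(fit$regions[[1]]$converged)
  pk <- fit$regions[[1]]$peaks[[1]]
  expect_equal(pk$center, 23.0, tolerance = 1e-6)
  expect_equal(pk$fwhm, 0.6, tolerance = 1e-6)
  expect_equal(pk$area, 1.0, tolerance = 1e-6)
})

test_that("two overlapping Gaussians separated by one FWHM resolve within 2% at SNR 100", {
  truth <- data.frame(center = c(22.7, 23.3), fwhm = c(0.6, 0.6),
                      area = c(1.0, 0.7), shape = "gaussian")
  peak_height <- max(synth_spectrum(truth, ppm_range = c(20, 26),
                                    n_points = 1200)$intensity)
  sp <- synth_spectrum(truth, ppm_range = c(20, 26), n_points = 1200,
                       noise_sd = peak_height / 100, seed = 9)
  fit <- fit_peaks(sp, list(list(window = c(21, 25), n_peaks = 2)),
                   shape = "gaussian")
  expect_true(fit$regions[[1]]$converged)
  areas <- sort(vapply(fit$regions[[1]]$peaks, function(p) p$area,
                       numeric(1)))
  expect_equal(areas, sort(truth$area), tolerance = 0.02)
})

test_that("degenerate flat spectra are reported, not fatal", {
  sp <- nmr_spectrum(seq(0, 200, length.out = 500), rep(0, 500))
  fit <- fit_peaks(sp, list(list(window = c(20, 26), n_peaks = 1)))
  rg <- fit$regions[[1]]
  ok_zero_area <- length(rg$peaks) && rg$peaks[[1]]$area < 1e-6
  expect_true(!rg$converged || ok_zero_area)
})

test_that("area and FWHM recover within 5% for isolated peaks at SNR 50", {
  worst_area <- 0
  worst_fwhm <- 0
  for (seed in 1:20) {
    set.seed(seed)
    truth <- data.frame(center = runif(1, 22, 24),
                        fwhm = runif(1, 0.4, 0.8),
                        area = runif(1, 0.5, 2))
    clean <- synth_spectrum(truth, ppm_range = c(18, 28), n_points = 1000)
    sp <- synth_spectrum(truth, ppm_range = c(18, 28), n_points = 1000,
                         noise_sd = max(clean$intensity) / 50,
                         seed = seed + 1000)
    fit <- fit_peaks(sp, list(list(window = c(20, 26), n_peaks = 1)))
    pk <- fit$regions[[1]]$peaks[[1]]
    worst_area <- max(worst_area, abs(pk$area / truth$area - 1))
    worst_fwhm <- max(worst_fwhm, abs(pk$fwhm / truth$fwhm - 1))
  }
  expect_lt(worst_area, 0.05)
  expect_lt(worst_fwhm, 0.05)
})

test_that("composition ratios normalize by reporter multiplicities", {
  mult <- c(n_K_per_A = 5, n_E_per_B = 4)
  expect_equal(reporter_multiplicities(reference_pair("design4")), mult)
  eq <- composition_from_areas(5, 4, mult)
  expect_equal(eq$ratio_A_to_B, 1.0)
  # doubling both areas leaves the ratio unchanged
  expect_equal(composition_from_areas(10, 8, mult)$ratio_A_to_B, 1.0)
  expect_error(composition_from_areas(1, 1, c(n_K_per_A = 0,
                                              n_E_per_B = 4)),
               "positive")
})

test_that("a synthetic ratio-1.53 spectrum is recovered within 0.05 at SNR 50", {
  mult <- reporter_multiplicities(reference_pair("design4"))
  true_ratio <- 1.53
  area_E <- 1.0
  area_K <- true_ratio * area_E * mult[["n_K_per_A"]] / mult[["n_E_per_B"]]
  truth <- data.frame(center = c(23, 181), fwhm = c(0.52, 0.53),
                      area = c(area_K, area_E))
  clean <- synth_spectrum(truth, ppm_range = c(0, 200), n_points = 8000)
  # SNR 50 relative to the weaker of the two reporter peaks
  h_min <- min(max(clean$intensity[abs(clean$ppm - 23) < 2]),
               max(clean$intensity[abs(clean$ppm - 181) < 2]))
  ratios <- vapply(1:5, function(seed) {
    sp <- synth_spectrum(truth, ppm_range = c(0, 200), n_points = 8000,
                         noise_sd = h_min / 50, seed = seed)
    fit <- fit_peaks(sp, list(list(window = c(20, 26), n_peaks = 1),
                              list(window = c(178, 184), n_peaks = 1)))
    composition_from_areas(fit$regions[[1]]$peaks[[1]],
                           fit$regions[[2]]$peaks[[1]], mult)$ratio_A_to_B
  }, numeric(1))
  expect_lt(abs(mean(ratios) - true_ratio), 0.05)
  sp <- synth_spectrum(truth, ppm_range = c(0, 200), n_points = 8000,
                       noise_sd = h_min / 50, seed = 1)
  fit <- fit_peaks(sp, list(list(window = c(20, 26), n_peaks = 1),
                            list(window = c(178, 184), n_peaks = 1)))
  res <- composition_from_areas(fit$regions[[1]]$peaks[[1]],
                                fit$regions[[2]]$peaks[[1]], mult)
  # invariance to global intensity scaling and axis direction
  sp2 <- nmr_spectrum(sp$ppm, 10 * sp$intensity)
  fit2 <- fit_peaks(sp2, list(list(window = c(20, 26), n_peaks = 1),
                              list(window = c(178, 184), n_peaks = 1)))
  res2 <- composition_from_areas(fit2$regions[[1]]$peaks[[1]],
                                 fit2$regions[[2]]$peaks[[1]], mult)
  expect_equal(res2$ratio_A_to_B, res$ratio_A_to_B, tolerance = 1e-6)
  sp3 <- nmr_spectrum(rev(-sp$ppm), rev(sp$intensity))
  expect_s3_class(sp3, "nmr_spectrum")
})

test_that("reported 1-sigma uncertainties cover the truth at roughly 68%", {
  n_seeds <- 200
  hits <- 0
  n_par <- 0
  for (seed in seq_len(n_seeds)) {
    truth <- data.frame(center = 23, fwhm = 0.6, area = 1)
    clean <- synth_spectrum(truth, ppm_range = c(20, 26), n_points = 400)
    sp <- synth_spectrum(truth, ppm_range = c(20, 26), n_points = 400,
                         noise_sd = max(clean$intensity) / 50,
                         seed = seed)
    fit <- fit_peaks(sp, list(list(window = c(20.5, 25.5), n_peaks = 1)))
    pk <- fit$regions[[1]]$peaks[[1]]
    if (!fit$regions[[1]]$converged || any(is.na(pk$se[c("center", "fwhm",
                                                         "area")]))) next
    for (par in c("center", "fwhm", "area")) {
      n_par <- n_par + 1
      if (abs(pk[[par]] - truth[[par]]) <= pk$se[[par]]) hits <- hits + 1
    }
  }
  expect_gt(n_par, 400)
  coverage <- hits / n_par
  expect_gt(coverage, 0.58)
  expect_lt(coverage, 0.78)
})

test_that("window specifications and spectrum CSVs round trip", {
  rg <- parse_windows("20:26=1,178:184=2")
  expect_equal(length(rg), 2)
  expect_equal(rg[[1]]$window, c(20, 26))
  expect_equal(rg[[2]]$n_peaks, 2L)
  expect_error(parse_windows("20-26"), "bad window")
  sp <- synth_spectrum(data.frame(center = 23, fwhm = 0.6, area = 1),
                       ppm_range = c(18, 28), n_points = 200)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(ppm = sp$ppm, intensity = sp$intensity), f,
                   row.names = FALSE)
  sp2 <- read_spectrum_csv(f)
  expect_equal(sp2$ppm, sp$ppm)
  expect_equal(sp2$intensity, sp$intensity)
  expect_error(fit_peaks(sp, list(list(window = c(10, 20), n_peaks = 1))),
               "outside")
})
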
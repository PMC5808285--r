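test_that("pick_rois places disjoint in-mask squares deterministically", {
  coh <- small_cohort_mem()
  dcis <- coh$patient_01$dcis_stained
  r1 <- pick_rois(dcis, n_regions = 4, side = 8, seed = 5)
  r2 <- pick_rois(dcis, n_regions = 4, side = 8, seed = 5)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 4L)
  for (i in 1:4) {
    sq <- dcis$mask[r1$row0[i]:(r1$row0[i] + 7L),
                    r1$col0[i]:(r1$col0[i] + 7L)]
    expect_true(all(sq == 1L))            # fully inside the cancer mask
    for (j in seq_len(i - 1L))
      expect_true(abs(r1$row0[i] - r1$row0[j]) >= 8L ||
                  abs(r1$col0[i] - r1$col0[j]) >= 8L)   # disjoint
  }
  # normal slides: anywhere in the image, still disjoint
  rn <- pick_rois(coh$patient_01$normal_stained, n_regions = 4, side = 8,
                  seed = 5)
  expect_equal(nrow(rn), 4L)
  # infeasible placement errors name the constraint
  tiny_mask <- matrix(0L, 30, 30); tiny_mask[1:9, 1:9] <- 1L
  expect_error(pick_rois(tiny_mask, "dcis", n_regions = 4, side = 8),
               "infeasible|smaller than")
})

test_that("region_spectrum summarizes measurements with sane edge cases", {
  w <- default_wavelengths(5)
  const <- hypercube(array(0.42, c(20, 20, 5)), w)
  reg <- data.frame(row0 = 3, col0 = 3, side = 10)
  s <- region_spectrum(const, reg, n_measurements = 10, seed = 1)
  expect_equal(s$mean_spectrum, rep(0.42, 5))
  expect_equal(s$sd_spectrum, rep(0, 5))
  # n_measurements = 1: SD undefined, reported as 0 and flagged
  s1 <- region_spectrum(const, reg, n_measurements = 1, seed = 1)
  expect_false(s1$sd_defined)
  expect_equal(s1$sd_spectrum, rep(0, 5))
  # region smaller than the subsample size
  expect_error(region_spectrum(const, data.frame(row0 = 1, col0 = 1,
                                                 side = 4),
                               subsample_size = 25), "impossible")
  expect_error(region_spectrum(const, data.frame(row0 = 15, col0 = 15,
                                                 side = 10)), "outside")
  # i.i.d. N(0.5, 0.01) region: mean within 3 SE of 0.5 per band
  set.seed(8)
  noisy <- hypercube(array(pmin(pmax(rnorm(30 * 30 * 5, 0.5, 0.01), 0), 1),
                           c(30, 30, 5)), w)
  sn <- region_spectrum(noisy, data.frame(row0 = 1, col0 = 1, side = 30),
                        n_measurements = 10, seed = 2)
  se <- 0.01 / sqrt(25)
  expect_true(all(abs(sn$mean_spectrum - 0.5) < 3 * se))
})

test_that("band_separation scores standardized class differences", {
  w <- default_wavelengths(6)
  mk <- function(mu, sd = rep(0.01, 6), n = 10)
    structure(list(mean_spectrum = mu, sd_spectrum = sd,
                   n_measurements = n, wavelengths = w,
                   region = list(row0 = 1, col0 = 1, side = 5),
                   label = NA, sd_defined = TRUE),
              class = "region_spectrum")
  # identical classes: score ~ 0 everywhere
  same <- band_separation(list(mk(rep(0.5, 6))), list(mk(rep(0.5, 6))))
  expect_true(all(same$score < 1e-6))
  # separation injected only at band 4 -> argmax there
  mu2 <- rep(0.5, 6); mu2[4] <- 0.8
  inj <- band_separation(list(mk(mu2)), list(mk(rep(0.5, 6))))
  expect_equal(inj$best_band_index, 4L)
  expect_equal(inj$best_wavelength_nm, w[4])
  # symmetric in class relabeling
  swapped <- band_separation(list(mk(rep(0.5, 6))), list(mk(mu2)))
  expect_equal(inj$score, swapped$score)
  # invariant to a common rescaling of all spectra
  k <- 0.37
  scaled <- band_separation(list(mk(mu2 * k, rep(0.01 * k, 6))),
                            list(mk(rep(0.5 * k, 6), rep(0.01 * k, 6))))
  expect_equal(scaled$score, inj$score, tolerance = 1e-10)
  # mismatched grids rejected
  bad <- mk(rep(0.5, 6)); bad$wavelengths <- w + 1
  expect_error(band_separation(list(mk(mu2)), list(bad)), "common")
})

test_that("select_band is a pure argmax with lower-wavelength ties", {
  w <- c(500, 510, 520)
  sep <- structure(list(wavelengths = w, score = c(1, 3, 3),
                        best_band_index = 2L, best_wavelength_nm = 510),
                   class = "band_separation")
  expect_equal(select_band(sep), 510)
  one <- structure(list(wavelengths = 500, score = 2,
                        best_band_index = 1L, best_wavelength_nm = 500),
                   class = "band_separation")
  expect_equal(select_band(one), 500)
  # argmax consistency on computed separations
  coh <- small_cohort_mem()
  sp <- spectra_stage(coh, n_regions = 3, side = 8, seed = 3)
  s <- sp$separation
  expect_equal(s$score[s$best_band_index], max(s$score))
  expect_equal(select_band(s), s$wavelengths[which.max(s$score)])
})

test_that("higher pixel noise lowers the expected peak separation", {
  peak <- function(noise) {
    coh <- small_cohort_mem(n_patients = 2, pixel_noise_sd = noise,
                            seed = 19)
    max(spectra_stage(coh, n_regions = 3, side = 8,
                      seed = 4)$separation$score)
  }
  p_low <- peak(0.01); p_mid <- peak(0.08); p_high <- peak(0.4)
  expect_gt(p_low, p_mid)
  expect_gt(p_mid, p_high)
})
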
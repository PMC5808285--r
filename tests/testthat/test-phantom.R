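test_that("default spectral model is pure and passes its calibration", {
  m1 <- default_spectral_model()
  m2 <- default_spectral_model()
  w <- m1$reference_wavelengths
  for (st in c("stained", "unstained")) for (cl in c("normal", "cancer")) {
    e1 <- endmember(m1, cl, st)
    expect_identical(e1, endmember(m2, cl, st))
    expect_true(all(e1 > 0 & e1 < 1))
    expect_true(max(abs(diff(e1))) < 0.1)      # smooth
  }
  # exhaustive scan: standardized separation argmax is the band nearest 550
  sep <- abs(endmember(m1, "normal", "stained") -
             endmember(m1, "cancer", "stained")) / m1$pixel_noise_sd
  target <- which.min(abs(w - 550))
  expect_equal(which.max(sep), target)
  expect_equal(w[target], 551)
  # stained separation beats unstained at that band
  sep_u <- abs(endmember(m1, "normal", "unstained") -
               endmember(m1, "cancer", "unstained")) / m1$pixel_noise_sd
  expect_gt(sep[target], sep_u[target])
  # a model violating the calibration is rejected at construction
  expect_error(
    validate_spectral_model_shifted <- local({
      bad <- default_spectral_model()
      bad$endmember_fun <- function(class, staining, w)
        if (class == "cancer" && staining == "stained")
          0.44 - 0.26 * exp(-0.5 * ((w - 600) / 12)^2)
        else default_spectral_model()$endmember_fun(class, staining, w)
      hsikmeans:::validate_spectral_model(bad)
    }), "550")
})

test_that("generate_mask honours class, determinism and area bounds", {
  expect_identical(generate_mask("normal", 30, 20), matrix(0L, 30, 20))
  m1 <- generate_mask("dcis", 80, 60, 0.3, seed = 4)
  m2 <- generate_mask("dcis", 80, 60, 0.3, seed = 4)
  expect_identical(m1, m2)
  expect_true(all(m1 %in% c(0L, 1L)))
  expect_error(generate_mask("dcis", 30, 30, 0.95), "infeasible")
  # fraction within +/-50% relative of target over 20 seeds, full-size image
  fracs <- vapply(1:20, function(s)
    mean(generate_mask("dcis", 443, 313, 0.3, seed = s)), numeric(1))
  expect_true(all(fracs >= 0.15 & fracs <= 0.45))
})

test_that("degenerate noise: cancer pixels equal the cancer endmember", {
  cfg <- phantom_config(n_patients = 1, rows = 40, cols = 30, seed = 2,
                        model = default_spectral_model(pixel_noise_sd = 0,
                                                       patient_gain_sd = 0,
                                                       patient_tilt_sd = 0))
  slides <- generate_patient(cfg, "p1", seed = 9)
  for (st in c("stained", "unstained")) {
    s <- slides[[paste0("dcis_", st)]]
    em <- endmember(cfg$model, "cancer", st, cfg$wavelengths)
    idx <- which(s$mask == 1L, arr.ind = TRUE)
    for (k in head(seq_len(nrow(idx)), 25))
      expect_equal(pixel_spectrum(s$cube, idx[k, 1L], idx[k, 2L]), em)
    # and with zero noise a nearest-endmember classifier is perfect
    pm <- flatten_pixels(s$cube, mask = s$mask)
    d_c <- rowSums(sweep(pm$spectra, 2L, em)^2)
    d_n <- rowSums(sweep(pm$spectra, 2L,
                         endmember(cfg$model, "normal", st,
                                   cfg$wavelengths))^2)
    expect_identical(as.integer(d_c < d_n), pm$labels)
  }
})

test_that("patient cubes have config dims and gain-scaled class means", {
  cfg <- small_config(seed = 21)
  slides <- generate_patient(cfg, "p1", seed = 21)
  expect_named(slides, c("normal_stained", "normal_unstained",
                         "dcis_stained", "dcis_unstained"))
  for (s in slides) {
    expect_identical(dim(s$cube$data),
                     c(cfg$rows, cfg$cols, cfg$bands))
    expect_true(all(s$cube$data >= 0 & s$cube$data <= 1))
  }
  expect_true(all(slides$normal_stained$mask == 0L))
  # Monte-Carlo: mean cancer spectrum within 3 SE of the patient-gain-scaled
  # endmember at every band (gain/tilt recovered from generation internals)
  s <- slides$dcis_stained
  n_cancer <- sum(s$mask)
  pm <- flatten_pixels(s$cube, mask = s$mask)
  mean_cancer <- colMeans(pm$spectra[pm$labels == 1L, ])
  em <- endmember(cfg$model, "cancer", "stained", cfg$wavelengths)
  # gain*(1+tilt*(l-mid)) is shared by all bands of this patient; estimate it
  # per band by regression against the endmember and check consistency
  gain_hat <- mean_cancer / em
  se <- cfg$model$pixel_noise_sd / sqrt(n_cancer)
  expect_true(all(abs(mean_cancer - gain_hat * em) < 3 * se))
  # gain is one smooth scalar field: band-to-band variation must be tiny
  expect_lt(max(abs(diff(gain_hat))), 0.02)
})

test_that("cohort generation writes a reproducible on-disk layout", {
  cfg <- small_config(n_patients = 2L, rows = 50L, cols = 40L, seed = 33)
  d1 <- file.path(tempdir(), "coh_a")
  d2 <- file.path(tempdir(), "coh_b")
  unlink(c(d1, d2), recursive = TRUE)
  mf1 <- generate_cohort(cfg, d1)
  mf2 <- generate_cohort(cfg, d2)
  expect_equal(nrow(mf1), 2L * 4L)              # n_patients x 4 slides
  expect_identical(mf1, mf2)
  # byte-identical files under a fixed (config, seed)
  rel <- list.files(d1, recursive = TRUE)
  expect_setequal(rel, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, rel))
  h2 <- tools::md5sum(file.path(d2, rel))
  expect_identical(unname(h1), unname(h2))
  # manifest describes readable slides that match their in-memory twins
  lc <- load_labeled_cube(d1, mf1[mf1$slide_class == "dcis" &
                                    mf1$staining == "stained", ][1L, ])
  expect_s3_class(lc, "labeled_cube")
  expect_identical(dim(lc$cube$data), c(50L, 40L, 31L))
  frac <- mean(lc$mask)
  expect_true(frac >= 0.15 && frac <= 0.45)
})

test_that("cohort size and dims conform for random valid configs", {
  set.seed(77)
  for (i in 1:3) {
    np <- sample(1:3, 1)
    r <- sample(30:60, 1); cc <- sample(30:60, 1); b <- sample(5:12, 1)
    cfg <- phantom_config(n_patients = np, rows = r, cols = cc, bands = b,
                          seed = i,
                          cancer_area_fraction = runif(1, 0.2, 0.4))
    d <- file.path(tempdir(), paste0("rand_coh_", i))
    unlink(d, recursive = TRUE)
    mf <- generate_cohort(cfg, d)
    expect_equal(nrow(mf), np * 4L)
    lc <- load_labeled_cube(d, mf[1L, ])
    expect_identical(dim(lc$cube$data), c(r, cc, b))
    expect_equal(length(lc$cube$wavelengths), b)
  }
})

test_that("phantom_config validates its arguments", {
  expect_error(phantom_config(cancer_area_fraction = 0.95), "0.05, 0.9")
  expect_error(phantom_config(wavelength_min = 700), "wavelength_min")
  expect_error(phantom_config(n_patients = 0), "n_patients")
})
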
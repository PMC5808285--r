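#' Default spectral class model for the breast-tissue phantom
#'
#' Returns the pure-class ("endmember") reflectance spectra used by the
#' phantom generator, one per combination of tissue class (normal / cancer)
#' and staining (H&E-stained / unstained), plus the noise and per-patient
#' variation parameters. The curves are smooth sums of Gaussian bumps over
#' 461-641 nm, calibrated so that for stained tissue the standardized
#' class separation |normal - cancer| / noise SD peaks at the band nearest
#' 550 nm, and so that stained separation strictly exceeds unstained
#' separation at that band. Stained cancer tissue (hematoxylin-dense nuclei)
#' is modelled darker than normal stroma around 550 nm.
#'
#' This is a pure function: repeated calls return identical models.
#'
#' @param pixel_noise_sd per-band Gaussian pixel noise SD (reflectance
#'   units; default 0.02).
#' @param patient_gain_sd SD of the per-patient multiplicative gain around 1
#'   (default 0.05).
#' @param patient_tilt_sd SD of the per-patient linear spectral tilt, per nm
#'   (default 2e-4).
#' @return object of class `"spectral_class_model"`: a list with
#'   `endmember_fun` (function of `(class, staining, wavelengths)`),
#'   the three noise parameters, and `reference_wavelengths` (the default
#'   31-band grid the calibration is asserted on).
#' @export
default_spectral_model <- function(pixel_noise_sd = 0.02,
                                   patient_gain_sd = 0.05,
                                   patient_tilt_sd = 2e-4) {
  gauss <- function(x, mu, s) exp(-0.5 * ((x - mu) / s)^2)
  fun <- function(class, staining, wavelengths) {
    w <- wavelengths
    key <- paste(staining, class, sep = "_")
    switch(key,
      stained_normal   = 0.58 + 0.07 * gauss(w, 625, 45) -
                         0.03 * gauss(w, 480, 30),
      stained_cancer   = 0.44 - 0.26 * gauss(w, 551, 12) +
                         0.06 * gauss(w, 628, 40),
      unstained_normal = 0.62 + 0.05 * gauss(w, 600, 60),
      unstained_cancer = 0.58 + 0.05 * gauss(w, 600, 60) -
                         0.06 * gauss(w, 551, 55),
      stop("unknown class/staining: ", key))
  }
  model <- structure(
    list(endmember_fun = fun,
         pixel_noise_sd = pixel_noise_sd,
         patient_gain_sd = patient_gain_sd,
         patient_tilt_sd = patient_tilt_sd,
         reference_wavelengths = default_wavelengths()),
    class = "spectral_class_model")
  validate_spectral_model(model)
  model
}

#' Default sensor wavelength grid
#'
#' 31 uniformly spaced band centers spanning 461-641 nm (6-nm spacing), the
#' visible-range configuration of the snapshot imager being emulated.
#'
#' @param bands number of bands.
#' @param wavelength_min,wavelength_max range endpoints (nm).
#' @return numeric vector of band centers.
#' @export
default_wavelengths <- function(bands = 31L, wavelength_min = 461,
                                wavelength_max = 641) {
  seq(wavelength_min, wavelength_max, length.out = bands)
}

#' Evaluate a spectral class model on a wavelength grid
#'
#' @param model a [default_spectral_model()]-style model.
#' @param class `"normal"` or `"cancer"`.
#' @param staining `"stained"` or `"unstained"`.
#' @param wavelengths grid (nm); defaults to the model's reference grid.
#' @return numeric reflectance vector.
#' @export
endmember <- function(model, class, staining,
                      wavelengths = model$reference_wavelengths) {
  model$endmember_fun(class, staining, wavelengths)
}

validate_spectral_model <- function(model,
                                    wavelengths = model$reference_wavelengths) {
  em <- lapply(c("stained_normal", "stained_cancer",
                 "unstained_normal", "unstained_cancer"), function(key) {
    parts <- strsplit(key, "_")[[1]]
    model$endmember_fun(parts[2L], parts[1L], wavelengths)
  })
  names(em) <- c("stained_normal", "stained_cancer",
                 "unstained_normal", "unstained_cancer")
  for (key in names(em)) {
    v <- em[[key]]
    if (any(v <= 0 | v >= 1))
      stop("endmember `", key, "` leaves (0, 1)")
    if (length(v) > 1L && max(abs(diff(v))) >= 0.1)
      stop("endmember `", key, "` is not smooth (band-to-band change >= 0.1)")
  }
  # standardized separation: constant per-band noise, so argmax|diff| decides
  sep_stained <- abs(em$stained_normal - em$stained_cancer) /
    max(model$pixel_noise_sd, 1e-9)
  sep_unstained <- abs(em$unstained_normal - em$unstained_cancer) /
    max(model$pixel_noise_sd, 1e-9)
  target <- nearest_band(wavelengths, 550)
  if (which.max(sep_stained) != target)
    stop("stained class separation must peak at the band nearest 550 nm ",
         "(band ", target, "), but peaks at band ", which.max(sep_stained))
  if (sep_stained[target] <= sep_unstained[target])
    stop("stained separation must exceed unstained separation at the ",
         "550-nm band")
  invisible(TRUE)
}

#' Phantom cohort configuration
#'
#' Bundles and validates the generator settings: cohort size, cube geometry,
#' wavelength range, target DCIS area fraction, noise model and seed.
#' Defaults mirror the emulated instrument and study design: 10 patients,
#' 443 x 313 spatial pixels, 31 bands over 461-641 nm.
#'
#' @param n_patients number of patients (default 10).
#' @param rows,cols,bands cube dimensions (defaults 443, 313, 31).
#' @param wavelength_min,wavelength_max spectral range in nm (461, 641).
#' @param cancer_area_fraction target fraction of cancer pixels in DCIS
#'   cubes, in (0.05, 0.9) (default 0.3 — marked regions are high-density
#'   tumor areas).
#' @param seed integer master seed; the whole cohort is a pure function of
#'   `(config, seed)`.
#' @param model a [default_spectral_model()]-style spectral class model.
#' @return object of class `"phantom_config"`.
#' @export
phantom_config <- function(n_patients = 10L, rows = 443L, cols = 313L,
                           bands = 31L, wavelength_min = 461,
                           wavelength_max = 641,
                           cancer_area_fraction = 0.3, seed = 42L,
                           model = default_spectral_model()) {
  stopifnot(n_patients >= 1L, rows >= 1L, cols >= 1L, bands >= 1L)
  if (wavelength_min >= wavelength_max)
    stop("wavelength_min must be < wavelength_max")
  if (cancer_area_fraction <= 0.05 || cancer_area_fraction >= 0.9)
    stop("cancer_area_fraction must lie in (0.05, 0.9)")
  structure(list(
    n_patients = as.integer(n_patients), rows = as.integer(rows),
    cols = as.integer(cols), bands = as.integer(bands),
    wavelength_min = wavelength_min, wavelength_max = wavelength_max,
    wavelengths = default_wavelengths(bands, wavelength_min, wavelength_max),
    cancer_area_fraction = cancer_area_fraction,
    seed = as.integer(seed), model = model), class = "phantom_config")
}

#' Generate a ground-truth tissue mask
#'
#' Normal slides get an all-zero mask (duct structure is rendered only as
#' image texture, never as a label). DCIS slides get a union of 2-6
#' irregular elliptical blobs — carcinoma spreading from ducts — whose total
#' cancer fraction lands within +/-50% (relative) of the target; placement
#' is redrawn (up to 50 times) if clipping or overlap pushes it outside that
#' band.
#'
#' @param slide_class `"normal"` or `"dcis"`.
#' @param rows,cols mask dimensions.
#' @param cancer_area_fraction target cancer pixel fraction (<= 0.9).
#' @param seed optional integer seed (restores the caller's RNG state).
#' @return integer matrix (rows x cols) of 0/1.
#' @export
generate_mask <- function(slide_class = c("dcis", "normal"), rows, cols,
                          cancer_area_fraction = 0.3, seed = NULL) {
  slide_class <- match.arg(slide_class)
  if (slide_class == "normal") return(matrix(0L, rows, cols))
  if (cancer_area_fraction > 0.9)
    stop("cancer_area_fraction > 0.9 is infeasible")
  local_seed(seed, {
    for (attempt in seq_len(50L)) {
      m <- draw_blob_mask(rows, cols, cancer_area_fraction)
      frac <- mean(m)
      if (frac >= 0.5 * cancer_area_fraction &&
          frac <= 1.5 * cancer_area_fraction) return(m)
    }
    stop("could not place blobs within +/-50% of target fraction ",
         cancer_area_fraction, " on a ", rows, " x ", cols, " image")
  })
}

# one attempt at a DCIS blob mask: k irregular ellipses of total area
# ~ fraction * rows * cols
draw_blob_mask <- function(rows, cols, fraction) {
  k <- sample(2:6, 1L)
  weights <- stats::runif(k, 0.5, 1.5)
  areas <- fraction * rows * cols * weights / sum(weights)
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  m <- matrix(FALSE, rows, cols)
  for (a in areas) {
    q <- stats::runif(1, 0.45, 1)           # aspect ratio
    r1 <- sqrt(a / (pi * q)); r2 <- q * r1
    theta <- stats::runif(1, 0, pi)
    margin1 <- min(1.15 * r1, (rows - 1) / 2)
    margin2 <- min(1.15 * r1, (cols - 1) / 2)
    cy <- stats::runif(1, 1 + margin1, rows - margin1)
    cx <- stats::runif(1, 1 + margin2, cols - margin2)
    dy <- rr - cy; dx <- cc - cx
    u <- cos(theta) * dx + sin(theta) * dy
    v <- -sin(theta) * dx + cos(theta) * dy
    rho <- sqrt((u / r1)^2 + (v / r2)^2)
    phi <- atan2(v / r2, u / r1)
    wobble <- 1 + stats::runif(1, 0.08, 0.2) * sin(2 * phi + stats::runif(1, 0, 2 * pi)) +
                  stats::runif(1, 0.04, 0.12) * sin(3 * phi + stats::runif(1, 0, 2 * pi))
    m <- m | (rho <= wobble)
  }
  matrix(as.integer(m), rows, cols)
}

# smooth multiplicative duct texture (rings) applied to normal-tissue pixels
duct_texture <- function(rows, cols) {
  n_ducts <- sample(3:6, 1L)
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  m <- matrix(1, rows, cols)
  base <- min(rows, cols)
  for (i in seq_len(n_ducts)) {
    r0 <- stats::runif(1, 0.04, 0.09) * base
    cy <- stats::runif(1, 1, rows); cx <- stats::runif(1, 1, cols)
    d <- sqrt((rr - cy)^2 + (cc - cx)^2)
    # bright duct wall, slightly darker lumen
    m <- m + 0.06 * exp(-((d - r0) / (0.3 * r0))^2) -
             0.04 * exp(-(d / (0.5 * r0))^2)
  }
  m
}

#' Generate the four labeled cubes of one synthetic patient
#'
#' Produces \{normal, dcis\} x \{stained, unstained\} hyperspectral cubes
#' with ground-truth masks. One multiplicative gain and one linear spectral
#' tilt are drawn per patient and shared across that patient's four cubes;
#' each pixel spectrum is
#' `gain * (1 + tilt * (lambda - lambda_mid)) * texture * endmember +
#' N(0, pixel_noise_sd)` per band, clipped to \[0, 1\]. Duct-like ring
#' texture modulates normal-tissue pixels only, so with all noise terms at
#' zero every cancer pixel equals the cancer endmember exactly.
#'
#' @param config a [phantom_config()].
#' @param patient_id identifier string such as `"patient_03"`.
#' @param seed optional integer seed for this patient.
#' @param model spectral model (defaults to `config$model`).
#' @return list of four `"labeled_cube"` objects (fields `cube`, `mask`,
#'   `patient_id`, `staining`, `slide_class`), named
#'   `normal_stained`, `normal_unstained`, `dcis_stained`,
#'   `dcis_unstained`.
#' @export
generate_patient <- function(config, patient_id, seed = NULL,
                             model = config$model) {
  local_seed(seed, {
    w <- config$wavelengths
    wmid <- (config$wavelength_min + config$wavelength_max) / 2
    gain <- stats::rnorm(1, 1, model$patient_gain_sd)
    tilt <- stats::rnorm(1, 0, model$patient_tilt_sd)
    gain_vec <- gain * (1 + tilt * (w - wmid))
    out <- list()
    for (slide_class in c("normal", "dcis")) {
      for (staining in c("stained", "unstained")) {
        mask <- generate_mask(slide_class, config$rows, config$cols,
                              config$cancer_area_fraction)
        tex <- duct_texture(config$rows, config$cols)
        tex[mask == 1L] <- 1          # texture never touches cancer pixels
        em <- rbind(endmember(model, "normal", staining, w),
                    endmember(model, "cancer", staining, w))
        lab <- as.vector(mask)        # column-major, matches array layout
        n_pix <- length(lab)
        X <- em[lab + 1L, , drop = FALSE] * as.vector(tex)
        X <- X * matrix(gain_vec, n_pix, config$bands, byrow = TRUE)
        if (model$pixel_noise_sd > 0)
          X <- X + stats::rnorm(length(X), 0, model$pixel_noise_sd)
        X <- pmin(pmax(X, 0), 1)
        cube <- hypercube(array(X, c(config$rows, config$cols, config$bands)),
                          w, metadata = list(patient_id = patient_id,
                                             slide_class = slide_class,
                                             staining = staining,
                                             section_thickness_um = "5",
                                             field_of_view_um = "100x80"))
        out[[paste(slide_class, staining, sep = "_")]] <-
          labeled_cube(cube, mask, patient_id, staining, slide_class)
      }
    }
    out
  })
}

#' Construct (and validate) a labeled cube
#'
#' @param cube a [hypercube].
#' @param mask 0/1 ground-truth matrix matching the cube's spatial shape.
#' @param patient_id,staining,slide_class metadata fields.
#' @return object of class `"labeled_cube"`.
#' @export
labeled_cube <- function(cube, mask, patient_id,
                         staining = c("stained", "unstained"),
                         slide_class = c("normal", "dcis")) {
  staining <- match.arg(staining)
  slide_class <- match.arg(slide_class)
  validate_mask(mask, spatial_dim(cube))
  if (slide_class == "normal" && any(mask != 0L))
    stop("normal slides must carry an all-zero mask")
  structure(list(cube = cube, mask = mask, patient_id = patient_id,
                 staining = staining, slide_class = slide_class),
            class = "labeled_cube")
}

#' @export
print.labeled_cube <- function(x, ...) {
  cat(sprintf("<labeled_cube> %s %s/%s, cancer fraction %.3f\n",
              x$patient_id, x$slide_class, x$staining, mean(x$mask)))
  print(x$cube)
  invisible(x)
}

#' Generate and write a full synthetic patient cohort
#'
#' Writes `n_patients x 4` ENVI cubes and PGM masks under `out_dir` in the
#' layout `patient_<k>/<slide_class>_<staining>.{hdr,img,pgm}`, plus a
#' `manifest.tsv` (patient_id, slide_class, staining, file paths, per-patient
#' seed) and the serialized config (`config.txt`, key=value). The cohort is
#' a pure function of `(config, config$seed)`: per-patient seeds are derived
#' deterministically from the master seed, so a re-run is byte-identical.
#'
#' @param config a [phantom_config()].
#' @param out_dir output directory (created if needed).
#' @param data_type on-disk ENVI sample format; default `"float32"` (ample
#'   for reflectance in \[0, 1\], half the footprint of float64).
#' @return invisibly, the manifest as a data.frame (with paths relative to
#'   `out_dir`).
#' @export
generate_cohort <- function(config, out_dir, data_type = "float32") {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  seeds <- derive_seeds(config$seed, config$n_patients)
  rows <- list()
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("patient_%02d", p)
    pdir <- file.path(out_dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    slides <- generate_patient(config, pid, seed = seeds[p])
    for (nm in names(slides)) {
      s <- slides[[nm]]
      base <- file.path(pdir, nm)
      write_envi(s$cube, base, data_type = data_type)
      write_pgm(s$mask, paste0(base, ".pgm"))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, slide_class = s$slide_class, staining = s$staining,
        hdr = file.path(pid, paste0(nm, ".hdr")),
        img = file.path(pid, paste0(nm, ".img")),
        mask = file.path(pid, paste0(nm, ".pgm")),
        seed = seeds[p], stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg_lines <- c(
    paste0("n_patients=", config$n_patients),
    paste0("rows=", config$rows), paste0("cols=", config$cols),
    paste0("bands=", config$bands),
    paste0("wavelength_min=", config$wavelength_min),
    paste0("wavelength_max=", config$wavelength_max),
    paste0("cancer_area_fraction=", config$cancer_area_fraction),
    paste0("seed=", config$seed),
    paste0("pixel_noise_sd=", config$model$pixel_noise_sd),
    paste0("patient_gain_sd=", config$model$patient_gain_sd),
    paste0("patient_tilt_sd=", config$model$patient_tilt_sd))
  writeLines(cfg_lines, file.path(out_dir, "config.txt"))
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' @param cohort_dir directory written by [generate_cohort()].
#' @return data.frame with one row per slide.
#' @export
read_manifest <- function(cohort_dir) {
  path <- file.path(cohort_dir, "manifest.tsv")
  if (!file.exists(path)) stop("no manifest.tsv in ", cohort_dir)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Load one labeled cube referenced by a manifest row
#'
#' @param cohort_dir cohort directory.
#' @param row one-row data.frame (a slice of [read_manifest()] output).
#' @return a `"labeled_cube"`.
#' @export
load_labeled_cube <- function(cohort_dir, row) {
  cube <- read_envi(file.path(cohort_dir, row$hdr),
                    metadata = list(patient_id = row$patient_id,
                                    slide_class = row$slide_class,
                                    staining = row$staining))
  mask <- read_pgm(file.path(cohort_dir, row$mask))
  labeled_cube(cube, mask, row$patient_id, row$staining, row$slide_class)
}
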
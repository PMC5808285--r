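# shared fixtures: everything is generated in code at test time

# small phantom configuration: full spectral grid, reduced spatial size so a
# whole cohort generates in seconds
small_config <- function(n_patients = 4L, rows = 90L, cols = 70L,
                         seed = 11L, pixel_noise_sd = 0.02) {
  phantom_config(n_patients = n_patients, rows = rows, cols = cols,
                 seed = seed,
                 model = default_spectral_model(pixel_noise_sd = pixel_noise_sd))
}

# deterministic random cube for IO tests
random_cube <- function(rows = 4L, cols = 3L, bands = 31L, seed = 99L) {
  set.seed(seed)
  hypercube(array(runif(rows * cols * bands), c(rows, cols, bands)),
            default_wavelengths(bands))
}

# in-memory cohort: patient_id -> list of labeled cubes (stained only unless
# all_slides); cached per options so several test files can share one build
.cohort_cache <- new.env(parent = emptyenv())
small_cohort_mem <- function(n_patients = 4L, rows = 90L, cols = 70L,
                             seed = 11L, pixel_noise_sd = 0.02,
                             all_slides = FALSE) {
  key <- paste(n_patients, rows, cols, seed, pixel_noise_sd, all_slides,
               sep = "_")
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cfg <- small_config(n_patients, rows, cols, seed, pixel_noise_sd)
  seeds <- hsikmeans:::derive_seeds(cfg$seed, cfg$n_patients)
  coh <- list()
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("patient_%02d", p)
    sl <- generate_patient(cfg, pid, seed = seeds[p])
    coh[[pid]] <- if (all_slides) sl else sl[c("dcis_stained",
                                               "normal_stained")]
  }
  .cohort_cache[[key]] <- coh
  coh
}

# cohort written to disk (tempdir), cached
small_cohort_dir <- function(n_patients = 4L, rows = 90L, cols = 70L,
                             seed = 11L) {
  key <- paste("dir", n_patients, rows, cols, seed, sep = "_")
  if (!is.null(.cohort_cache[[key]]) && dir.exists(.cohort_cache[[key]]))
    return(.cohort_cache[[key]])
  dir <- file.path(tempdir(), paste0("cohort_", key))
  generate_cohort(small_config(n_patients, rows, cols, seed), dir)
  .cohort_cache[[key]] <- dir
  dir
}

# brute-force K-means oracles, independent of the package implementation
brute_assign <- function(points, centroids) {
  apply(points, 1L, function(x) {
    d <- apply(centroids, 1L, function(v) sqrt(sum((x - v)^2)))
    which(d == min(d))[1L]
  })
}

brute_objective <- function(points, centroids, cluster) {
  total <- 0
  for (i in seq_len(nrow(points)))
    total <- total + sum((points[i, ] - centroids[cluster[i], ])^2)
  total
}

# global optimum J over all 2-cluster partitions (exhaustive enumeration,
# n <= 20); centroids at partition means
best_two_partition_J <- function(points) {
  n <- nrow(points)
  stopifnot(n >= 2L, n <= 20L)
  best <- Inf
  for (code in 1:(2^(n - 1L) - 1L)) {
    side <- as.logical(bitwAnd(code, bitwShiftL(1L, 0:(n - 1L))))
    a <- points[side, , drop = FALSE]
    b <- points[!side, , drop = FALSE]
    J <- sum(sweep(a, 2L, colMeans(a))^2) + sum(sweep(b, 2L, colMeans(b))^2)
    if (J < best) best <- J
  }
  best
}

# md5 over a set of files, order-independent content fingerprint
files_md5 <- function(paths) {
  unname(tools::md5sum(sort(paths)))
}
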
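#' Randomly place square regions of interest
#'
#' Emulates the manual ROI protocol: square regions picked at random around
#' normal ducts or inside high-density carcinoma areas. For DCIS slides every
#' square must lie entirely inside the cancer mask; for normal slides the
#' whole image is eligible. Squares are pairwise disjoint. Placement is
#' rejection sampling with a bounded number of attempts.
#'
#' @param x a `"labeled_cube"`, a 0/1 mask matrix, or an image-size vector
#'   `c(rows, cols)` (normal slides only).
#' @param slide_class `"normal"` or `"dcis"`; taken from `x` when it is a
#'   labeled cube.
#' @param n_regions number of squares (default 4).
#' @param side square side length in pixels (default 20).
#' @param seed optional integer seed.
#' @param max_attempts rejection-sampling cap (default 10000).
#' @return object of class `"roi_set"`: a data.frame with columns `row0`,
#'   `col0` (1-based top-left corner) and `side`; attribute `slide_class`.
#' @export
pick_rois <- function(x, slide_class = NULL, n_regions = 4L, side = 20L,
                      seed = NULL, max_attempts = 10000L) {
  if (inherits(x, "labeled_cube")) {
    if (is.null(slide_class)) slide_class <- x$slide_class
    mask <- x$mask
    dims <- spatial_dim(x$cube)
  } else if (is.matrix(x)) {
    mask <- x
    dims <- dim(x)
    if (is.null(slide_class))
      slide_class <- if (any(mask == 1L)) "dcis" else "normal"
  } else {
    dims <- as.integer(x)
    mask <- NULL
    if (is.null(slide_class)) slide_class <- "normal"
  }
  need_mask <- identical(slide_class, "dcis")
  if (need_mask && is.null(mask))
    stop("a cancer mask is required to place ROIs on a dcis slide")
  if (side < 1L || dims[1L] < side || dims[2L] < side)
    stop("image (", dims[1L], " x ", dims[2L],
         ") cannot host a ", side, "-px square")
  eligible_area <- if (need_mask) sum(mask == 1L) else prod(dims)
  if (eligible_area < n_regions * side^2)
    stop("eligible area (", eligible_area, " px) is smaller than ",
         n_regions, " disjoint ", side, "x", side, " squares")
  # enumerate all feasible top-left corners (square fully inside the
  # eligible area), then rejection-sample among them for disjointness
  feasible <- feasible_corners(mask, dims, side, need_mask)
  if (nrow(feasible) < n_regions)
    stop("only ", nrow(feasible), " positions can host a ", side, "x",
         side, " square", if (need_mask) " inside the cancer mask" else "",
         "; ", n_regions, " disjoint squares are infeasible")
  local_seed(seed, {
    acc <- matrix(integer(0), 0L, 2L)
    attempts <- 0L
    while (nrow(acc) < n_regions) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place ", n_regions, " disjoint ", side, "x", side,
             " squares", if (need_mask) " inside the cancer mask" else "",
             " after ", max_attempts, " attempts (overlap constraint)")
      pick <- feasible[sample.int(nrow(feasible), 1L), ]
      r0 <- pick[1L]; c0 <- pick[2L]
      overlap <- nrow(acc) > 0L &&
        any(abs(acc[, 1L] - r0) < side & abs(acc[, 2L] - c0) < side)
      if (overlap) {
        # early placements can block the rest; restart periodically
        if (attempts %% 250L == 0L) acc <- matrix(integer(0), 0L, 2L)
        next
      }
      acc <- rbind(acc, c(r0, c0))
    }
    rois <- data.frame(row0 = acc[, 1L], col0 = acc[, 2L], side = side)
    structure(rois, class = c("roi_set", "data.frame"),
              slide_class = slide_class)
  })
}

# all (row0, col0) where a side x side square fits fully inside the
# eligible region, via an integral image of the mask
feasible_corners <- function(mask, dims, side, need_mask) {
  nr <- dims[1L] - side + 1L
  nc <- dims[2L] - side + 1L
  if (!need_mask) {
    return(cbind(rep(seq_len(nr), times = nc),
                 rep(seq_len(nc), each = nr)))
  }
  ii <- apply(apply(mask, 2L, cumsum), 1L, cumsum)  # ii[c, r] after t
  ii <- t(ii)
  pad <- matrix(0, dims[1L] + 1L, dims[2L] + 1L)
  pad[-1L, -1L] <- ii
  r0 <- seq_len(nr); c0 <- seq_len(nc)
  win <- pad[r0 + side, c0 + side, drop = FALSE] -
         pad[r0, c0 + side, drop = FALSE] -
         pad[r0 + side, c0, drop = FALSE] + pad[r0, c0, drop = FALSE]
  idx <- which(win == side^2, arr.ind = TRUE)
  cbind(idx[, 1L], idx[, 2L])
}

#' Extract the pixel spectra of one ROI
#'
#' @param cube a [hypercube].
#' @param region one-row data.frame (or list) with `row0`, `col0`, `side`.
#' @return matrix `side^2 x bands` of pixel spectra (row-major pixel order).
#' @export
roi_pixels <- function(cube, region) {
  r <- region$row0; c <- region$col0; s <- region$side
  d <- spatial_dim(cube)
  if (r < 1L || c < 1L || r + s - 1L > d[1L] || c + s - 1L > d[2L])
    stop("region [", r, ", ", c, ", side ", s, "] outside a ",
         d[1L], " x ", d[2L], " image")
  sub <- cube$data[r:(r + s - 1L), c:(c + s - 1L), , drop = FALSE]
  # row-major pixel order within the region
  mat <- matrix(aperm(sub, c(2L, 1L, 3L)), s * s, n_bands(cube))
  mat
}

#' Summarize one ROI as mean +/- SD over repeated measurements
#'
#' One "measurement" is the mean spectrum of a random fixed-size pixel
#' subsample of the region (sampled without replacement within each draw).
#' The summary reports, per band, the mean and SD across `n_measurements`
#' such measurements — the error-bar construction of a reflectance plot
#' averaged over repeated readings.
#'
#' @param cube a [hypercube].
#' @param region one-row `roi_set` entry.
#' @param n_measurements number of repeated measurements (default 10).
#' @param subsample_size pixels per measurement (default 25).
#' @param label optional class label (0/1) carried on the summary.
#' @param seed optional integer seed.
#' @return object of class `"region_spectrum"`: list with `mean_spectrum`,
#'   `sd_spectrum`, `n_measurements`, `wavelengths`, `region`, `label`, and
#'   `sd_defined` (`FALSE` when `n_measurements == 1`, in which case the SD
#'   is reported as 0).
#' @export
region_spectrum <- function(cube, region, n_measurements = 10L,
                            subsample_size = 25L, label = NA_integer_,
                            seed = NULL) {
  if (n_measurements < 1L) stop("n_measurements must be >= 1")
  px <- roi_pixels(cube, region)
  if (nrow(px) < subsample_size)
    stop("region holds ", nrow(px), " pixels; subsample of ",
         subsample_size, " is impossible")
  local_seed(seed, {
    meas <- vapply(seq_len(n_measurements), function(i) {
      colMeans(px[sample.int(nrow(px), subsample_size), , drop = FALSE])
    }, numeric(ncol(px)))
    meas <- t(meas)                       # n_measurements x bands
    sd_defined <- n_measurements > 1L
    structure(list(
      mean_spectrum = colMeans(meas),
      sd_spectrum = if (sd_defined) apply(meas, 2L, stats::sd)
                    else rep(0, ncol(meas)),
      n_measurements = as.integer(n_measurements),
      wavelengths = cube$wavelengths,
      region = as.list(region)[c("row0", "col0", "side")],
      label = label, sd_defined = sd_defined),
      class = "region_spectrum")
  })
}

# pool a list of region_spectrum summaries into overall per-band
# mean / variance over all underlying measurements
pool_summaries <- function(summaries) {
  ns <- vapply(summaries, function(s) as.numeric(s$n_measurements),
               numeric(1))
  means <- do.call(rbind, lapply(summaries, function(s) s$mean_spectrum))
  sds <- do.call(rbind, lapply(summaries, function(s) s$sd_spectrum))
  N <- sum(ns)
  M <- colSums(means * ns) / N
  if (N > 1L) {
    within <- colSums(sds^2 * (ns - 1L))
    between <- colSums(ns * sweep(means, 2L, M)^2)
    V <- (within + between) / (N - 1L)
  } else V <- rep(0, ncol(means))
  list(n = N, mean = M, var = V)
}

#' Per-band standardized class separation
#'
#' For each band, computes the absolute standardized mean difference between
#' the cancer and normal measurement pools:
#' `score(b) = |mu_cancer(b) - mu_normal(b)| / pooled_SD(b)`, with the
#' pooled SD floored at a small epsilon. The best band is the argmax, ties
#' resolved toward the lower wavelength. The score is symmetric in the two
#' classes and invariant to a common rescaling of all spectra.
#'
#' @param summaries_cancer,summaries_normal lists of
#'   [region_spectrum()] summaries on a common wavelength grid (at least one
#'   per class).
#' @param epsilon pooled-SD floor (default 1e-9).
#' @return object of class `"band_separation"`: list with `wavelengths`,
#'   `score`, `best_band_index` (1-based) and `best_wavelength_nm`.
#' @export
band_separation <- function(summaries_cancer, summaries_normal,
                            epsilon = 1e-9) {
  if (inherits(summaries_cancer, "region_spectrum"))
    summaries_cancer <- list(summaries_cancer)
  if (inherits(summaries_normal, "region_spectrum"))
    summaries_normal <- list(summaries_normal)
  if (!length(summaries_cancer) || !length(summaries_normal))
    stop("need at least one summary per class")
  w <- summaries_cancer[[1L]]$wavelengths
  for (s in c(summaries_cancer, summaries_normal))
    if (!isTRUE(all.equal(s$wavelengths, w)))
      stop("summaries are not on a common wavelength grid")
  pc <- pool_summaries(summaries_cancer)
  pn <- pool_summaries(summaries_normal)
  df <- max(pc$n + pn$n - 2L, 1L)
  pooled_sd <- sqrt((pmax(pc$n - 1L, 0L) * pc$var +
                     pmax(pn$n - 1L, 0L) * pn$var) / df)
  pooled_sd <- pmax(pooled_sd, epsilon)
  score <- abs(pc$mean - pn$mean) / pooled_sd
  best <- which.max(score)              # first max -> lowest wavelength
  structure(list(wavelengths = w, score = score,
                 best_band_index = best, best_wavelength_nm = w[best]),
            class = "band_separation")
}

#' Select the most discriminative wavelength
#'
#' Pure argmax of the separation score; ties resolve to the lower
#' wavelength.
#'
#' @param separation a [band_separation()] result.
#' @return best wavelength in nm.
#' @export
select_band <- function(separation) {
  stopifnot(inherits(separation, "band_separation"))
  separation$best_wavelength_nm
}

#' Write ROI spectral summaries as TSV
#'
#' One row per (summary, band): region coordinates, class label, wavelength,
#' mean and SD.
#'
#' @param summaries list of [region_spectrum()] objects.
#' @param path output TSV path.
#' @return invisibly, the data.frame written.
#' @export
write_summaries_tsv <- function(summaries, path) {
  rows <- lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    data.frame(summary = i, row0 = s$region$row0, col0 = s$region$col0,
               side = s$region$side, label = s$label,
               n_measurements = s$n_measurements,
               wavelength_nm = s$wavelengths,
               mean = s$mean_spectrum, sd = s$sd_spectrum)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write a band-separation curve as TSV
#'
#' @param separation a [band_separation()] result.
#' @param path output TSV path.
#' @return invisibly, the data.frame written.
#' @export
write_separation_tsv <- function(separation, path) {
  df <- data.frame(wavelength_nm = separation$wavelengths,
                   score = separation$score,
                   best = seq_along(separation$score) ==
                     separation$best_band_index)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
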
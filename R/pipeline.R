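#' Map K-means clusters to tissue labels via ground truth
#'
#' Each cluster receives the majority ground-truth label (0 = non-cancer,
#' 1 = cancer) of its member training points. An exact 50/50 tie is resolved
#' by reflectance: the cluster whose centroid is darker at the selected band
#' is called cancer (stained, hematoxylin-dense carcinoma is modelled darker
#' near 550 nm). If the majority vote hands both clusters the same label
#' (possible with c = 2 and very unbalanced clusters), the cluster with the
#' higher cancer fraction keeps the cancer label and the other reverts, so
#' that with two clusters both labels are always represented.
#'
#' @param model a `"cluster_model"` from [km_fit()].
#' @param points training points (`n x d`).
#' @param labels ground-truth labels of `points`, in \{0, 1\}; both classes
#'   must be present.
#' @param band_index 1-based feature index used by the tie rule; defaults to
#'   the band nearest 550 nm when the model carries wavelengths, else the
#'   mean over features.
#' @param feature_mode `"full_spectrum"` or `"single_band"` (recorded).
#' @param band_nm selected wavelength (recorded when `single_band`).
#' @param training_patients character vector of patient ids (recorded).
#' @return object of class `"labeled_model"`: list with `model`,
#'   `label_of_cluster` (integer vector, one 0/1 label per cluster),
#'   `feature_mode`, `band_nm`, `training_patients`.
#' @export
map_clusters_to_labels <- function(model, points, labels, band_index = NULL,
                                   feature_mode = "full_spectrum",
                                   band_nm = NA_real_,
                                   training_patients = character(0)) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("both ground-truth labels must be present in the training points")
  a <- km_predict(model, points)
  k <- nrow(model$centroids)
  if (any(a$sizes == 0L))
    stop("cluster ", which(a$sizes == 0L)[1L],
         " has zero member points; cannot derive a label")
  darkness <- centroid_darkness(model, band_index)
  cancer_frac <- vapply(seq_len(k), function(i)
    mean(labels[a$cluster == i]), numeric(1))
  lab <- integer(k)
  for (i in seq_len(k)) {
    if (cancer_frac[i] > 0.5) lab[i] <- 1L
    else if (cancer_frac[i] < 0.5) lab[i] <- 0L
    else {
      # exact tie: darker centroid at the selected band -> cancer
      lab[i] <- if (darkness[i] == min(darkness)) 1L else 0L
      message("cluster ", i, " had a 50/50 label tie; resolved by ",
              "reflectance at the selected band")
    }
  }
  if (k == 2L && lab[1L] == lab[2L]) {
    keep <- which.max(cancer_frac)
    lab <- c(0L, 0L); lab[keep] <- 1L
    message("majority vote gave both clusters the same label; ",
            "cluster ", keep, " (higher cancer fraction) labeled cancer")
  }
  structure(list(model = model, label_of_cluster = lab,
                 feature_mode = feature_mode, band_nm = band_nm,
                 training_patients = training_patients),
            class = "labeled_model")
}

centroid_darkness <- function(model, band_index = NULL) {
  if (is.null(band_index)) {
    if (!is.null(model$wavelengths) &&
        length(model$wavelengths) == ncol(model$centroids))
      band_index <- nearest_band(model$wavelengths, 550)
    else return(rowMeans(model$centroids))
  }
  model$centroids[, band_index]
}

# gather labeled ROI training pixels from one patient's stained (or
# unstained) slides: cancer ROIs from the dcis slide, normal ROIs from the
# normal slide
patient_roi_pixels <- function(slides, staining = "stained", n_regions = 4L,
                               side = 20L, seed = NULL) {
  seeds <- derive_seeds(seed, 2L)
  dcis <- slides[[paste0("dcis_", staining)]]
  norm <- slides[[paste0("normal_", staining)]]
  if (is.null(dcis) || is.null(norm))
    stop("patient is missing a ", staining, " dcis or normal slide")
  rois_c <- pick_rois(dcis, n_regions = n_regions, side = side,
                      seed = seeds[1L])
  rois_n <- pick_rois(norm, n_regions = n_regions, side = side,
                      seed = seeds[2L])
  px_c <- do.call(rbind, lapply(seq_len(nrow(rois_c)), function(i)
    roi_pixels(dcis$cube, rois_c[i, ])))
  px_n <- do.call(rbind, lapply(seq_len(nrow(rois_n)), function(i)
    roi_pixels(norm$cube, rois_n[i, ])))
  list(spectra = rbind(px_c, px_n),
       labels = c(rep(1L, nrow(px_c)), rep(0L, nrow(px_n))),
       rois_cancer = rois_c, rois_normal = rois_n,
       wavelengths = dcis$cube$wavelengths)
}

#' Leave-one-patient-out K-means training
#'
#' Pools labeled ROI pixel spectra from every patient except the held-out
#' one, fits K-means with `c = 2` (cancer / non-cancer), and maps clusters
#' to labels by majority ground truth. The held-out patient's pixels never
#' enter training. Each training patient is additionally fitted separately,
#' yielding a per-patient training-accuracy table; those separate fits are
#' reported only and never used for held-out prediction.
#'
#' @param cohort either a cohort directory (written by [generate_cohort()])
#'   or a named list of patients, each a list of `"labeled_cube"`s as
#'   returned by [generate_patient()].
#' @param held_out_patient patient id to exclude (e.g. `"patient_10"`).
#' @param staining slides to use (default `"stained"`).
#' @param feature_mode `"full_spectrum"` (default) or `"single_band"`.
#' @param band_nm wavelength for `single_band` mode (and the label tie
#'   rule); default 550.
#' @param n_regions,side ROI count and side length per slide.
#' @param init K-means initialization (default `"farthest"`).
#' @param seed integer seed driving ROI placement (and random init).
#' @return list with `labeled_model`, `per_patient` (data.frame: one row
#'   per training patient with its separate-fit training accuracy),
#'   `training_patients`, and `n_training_pixels`.
#' @export
train_lopo <- function(cohort, held_out_patient, staining = "stained",
                       feature_mode = c("full_spectrum", "single_band"),
                       band_nm = 550, n_regions = 4L, side = 20L,
                       init = "farthest", seed = NULL) {
  feature_mode <- match.arg(feature_mode)
  patients <- cohort_patients(cohort)
  if (!held_out_patient %in% patients)
    stop("held-out patient `", held_out_patient, "` not in cohort")
  training <- setdiff(patients, held_out_patient)
  if (length(training) < 1L)
    stop("cohort must contain at least 2 patients")
  seeds <- derive_seeds(seed, length(training) + 1L)

  per_pat <- vector("list", length(training))
  X <- NULL; y <- NULL; w <- NULL
  for (i in seq_along(training)) {
    pid <- training[i]
    slides <- cohort_slides(cohort, pid)
    px <- patient_roi_pixels(slides, staining, n_regions, side,
                             seed = seeds[i])
    w <- px$wavelengths
    Xi <- feature_matrix(px$spectra, w, feature_mode, band_nm)
    # separate per-patient fit: the per-patient accuracy table
    fit_i <- km_fit(Xi, c = 2L, init = init, seed = seeds[i],
                    wavelengths = feature_wavelengths(w, feature_mode,
                                                      band_nm))
    lm_i <- map_clusters_to_labels(fit_i$model, Xi, px$labels,
                                   feature_mode = feature_mode,
                                   band_nm = band_nm)
    pred_i <- lm_i$label_of_cluster[km_predict(fit_i$model, Xi)$cluster]
    per_pat[[i]] <- data.frame(
      patient_id = pid,
      n_pixels = nrow(Xi),
      accuracy = 100 * mean(pred_i == px$labels),
      J = fit_i$trace$J[nrow(fit_i$trace)],
      iterations = attr(fit_i$trace, "iterations"))
    X <- rbind(X, Xi); y <- c(y, px$labels)
  }
  fit <- km_fit(X, c = 2L, init = init, seed = seeds[length(seeds)],
                wavelengths = feature_wavelengths(w, feature_mode, band_nm))
  labeled <- map_clusters_to_labels(fit$model, X, y,
                                    feature_mode = feature_mode,
                                    band_nm = band_nm,
                                    training_patients = training)
  list(labeled_model = labeled, per_patient = do.call(rbind, per_pat),
       training_patients = training, n_training_pixels = nrow(X),
       trace = fit$trace)
}

feature_matrix <- function(spectra, wavelengths, feature_mode, band_nm) {
  if (feature_mode == "single_band")
    spectra[, nearest_band(wavelengths, band_nm), drop = FALSE]
  else spectra
}

feature_wavelengths <- function(wavelengths, feature_mode, band_nm) {
  if (feature_mode == "single_band")
    wavelengths[nearest_band(wavelengths, band_nm)]
  else wavelengths
}

# cohort accessors: a cohort is a directory (manifest on disk) or an
# in-memory named list patient_id -> list of labeled_cubes
cohort_patients <- function(cohort) {
  if (is.character(cohort)) unique(read_manifest(cohort)$patient_id)
  else names(cohort)
}

cohort_slides <- function(cohort, patient_id) {
  if (is.character(cohort)) {
    mf <- read_manifest(cohort)
    rows <- mf[mf$patient_id == patient_id, , drop = FALSE]
    out <- lapply(seq_len(nrow(rows)), function(i)
      load_labeled_cube(cohort, rows[i, ]))
    names(out) <- paste(rows$slide_class, rows$staining, sep = "_")
    out
  } else cohort[[patient_id]]
}

#' Classify every pixel of a cube with a labeled model
#'
#' Runs nearest-centroid prediction on each pixel spectrum and maps cluster
#' indices to tissue labels, yielding a predicted binary mask with the
#' cube's spatial shape.
#'
#' @param labeled_model a [map_clusters_to_labels()] result.
#' @param cube a [hypercube].
#' @return integer matrix (rows x cols) of predicted labels 0/1.
#' @export
classify_cube <- function(labeled_model, cube) {
  d <- dim(cube$data)
  X <- matrix(cube$data, d[1L] * d[2L], d[3L])
  X <- feature_matrix(X, cube$wavelengths, labeled_model$feature_mode,
                      labeled_model$band_nm)
  if (ncol(X) != ncol(labeled_model$model$centroids))
    stop("cube bands (", ncol(X), ") do not match model features (",
         ncol(labeled_model$model$centroids), ")")
  cl <- km_predict(labeled_model$model, X)$cluster
  matrix(labeled_model$label_of_cluster[cl], d[1L], d[2L])
}

#' Pixel-level confusion-matrix metrics
#'
#' Cancer is the positive class. Reports the raw counts and the derived
#' percentages: sensitivity `100*TP/(TP+FN)`, specificity `100*TN/(TN+FP)`,
#' TNR (identical to specificity), FPR (`100 - TNR`) and overall accuracy.
#' Rates whose denominator is zero are `NaN`.
#'
#' @param predicted,truth 0/1 matrices (or vectors) of equal shape.
#' @return object of class `"hsi_metrics"`: list with `TP`, `FP`, `TN`,
#'   `FN`, `sensitivity`, `specificity`, `TNR`, `FPR`, `accuracy`.
#' @export
evaluate_masks <- function(predicted, truth) {
  if (!all(dim(as.matrix(predicted)) == dim(as.matrix(truth))))
    stop("predicted and truth masks have different shapes")
  p <- as.integer(predicted); t <- as.integer(truth)
  if (!length(p)) stop("empty masks cannot be evaluated")
  if (!all(p %in% c(0L, 1L)) || !all(t %in% c(0L, 1L)))
    stop("masks must be binary 0/1")
  metrics_from_counts(TP = sum(p == 1L & t == 1L),
                      FP = sum(p == 1L & t == 0L),
                      TN = sum(p == 0L & t == 0L),
                      FN = sum(p == 0L & t == 1L))
}

#' Metrics from raw confusion-matrix counts
#'
#' @param TP,FP,TN,FN non-negative counts (at least one positive and one
#'   negative ground-truth pixel required).
#' @return an `"hsi_metrics"` object; see [evaluate_masks()].
#' @export
metrics_from_counts <- function(TP, FP, TN, FN) {
  if (TP + FP + TN + FN == 0) stop("empty confusion matrix")
  if (TP + FN == 0 && TN + FP == 0)
    stop("confusion matrix has neither positive nor negative ground truth")
  sens <- 100 * TP / (TP + FN)
  spec <- 100 * TN / (TN + FP)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 sensitivity = sens, specificity = spec,
                 TNR = spec, FPR = 100 - spec,
                 accuracy = 100 * (TP + TN) / (TP + FP + TN + FN)),
            class = "hsi_metrics")
}

#' @export
print.hsi_metrics <- function(x, ...) {
  cat(sprintf(paste0("<hsi_metrics> TP=%d FP=%d TN=%d FN=%d | ",
                     "sens %.2f%%  spec %.2f%%  TNR %.2f%%  FPR %.2f%%  ",
                     "acc %.2f%%\n"),
              x$TP, x$FP, x$TN, x$FN, x$sensitivity, x$specificity,
              x$TNR, x$FPR, x$accuracy))
  invisible(x)
}

#' Render a detection overlay image
#'
#' Grayscale band image with predicted cancer pixels tinted red and
#' predicted normal pixels tinted blue; optional ground-truth ROI boxes are
#' outlined in full blue, mirroring pathologist-marked regions.
#'
#' @param cube a [hypercube].
#' @param predicted 0/1 predicted mask.
#' @param truth_rois optional `roi_set` to outline.
#' @param band_nm display wavelength (default 550).
#' @param path optional PNG output path.
#' @param alpha tint strength in \[0, 1\].
#' @return rows x cols x 3 RGB array in \[0, 1\] (invisibly when `path`
#'   is given).
#' @export
render_overlay <- function(cube, predicted, truth_rois = NULL,
                           band_nm = 550, path = NULL, alpha = 0.45) {
  validate_mask(predicted, spatial_dim(cube))
  bi <- band_image(cube, band_nm)
  g <- bi$image
  rng <- range(g)
  g <- if (diff(rng) > 0) (g - rng[1L]) / diff(rng) else g * 0 + 0.5
  tint <- array(0, c(dim(g), 3L))
  tint[, , 1L] <- predicted          # red channel for cancer
  tint[, , 3L] <- 1L - predicted     # blue channel for normal
  rgb <- array(rep(g, 3L), c(dim(g), 3L)) * (1 - alpha) + tint * alpha
  if (!is.null(truth_rois)) {
    for (i in seq_len(nrow(truth_rois))) {
      r0 <- truth_rois$row0[i]; c0 <- truth_rois$col0[i]
      r1 <- r0 + truth_rois$side[i] - 1L; c1 <- c0 + truth_rois$side[i] - 1L
      rgb[c(r0, r1), c0:c1, 1L] <- 0; rgb[c(r0, r1), c0:c1, 2L] <- 0
      rgb[c(r0, r1), c0:c1, 3L] <- 1
      rgb[r0:r1, c(c0, c1), 1L] <- 0; rgb[r0:r1, c(c0, c1), 2L] <- 0
      rgb[r0:r1, c(c0, c1), 3L] <- 1
    }
  }
  rgb <- pmin(pmax(rgb, 0), 1)
  if (!is.null(path)) {
    grDevices::png(path, width = ncol(g), height = nrow(g))
    op <- graphics::par(mar = c(0, 0, 0, 0))
    on.exit({ graphics::par(op); grDevices::dev.off() })
    graphics::plot.new()
    graphics::plot.window(c(0, 1), c(0, 1), xaxs = "i", yaxs = "i")
    graphics::rasterImage(grDevices::as.raster(rgb), 0, 0, 1, 1,
                          interpolate = FALSE)
    return(invisible(rgb))
  }
  rgb
}

#' Run the full detection experiment on a cohort
#'
#' Chains every stage on a cohort directory: (1) ROI spectral summaries on
#' all stained slides and discriminative band selection; (2)
#' leave-one-patient-out K-means training with `c = 2`; (3) per-pixel
#' classification of the held-out patient's stained slides; (4) pixel-level
#' confusion-matrix metrics (pooled over the held-out dcis and normal
#' slides, and per slide) plus region-level metrics by majority vote over
#' fresh ROIs on the held-out dcis slide; (5) overlay PNGs. All outputs are
#' written under `out_dir` (report.json, metrics.tsv,
#' per_patient_accuracy.tsv, centroids.tsv, separation.tsv, overlays).
#'
#' @param cohort_dir cohort directory (see [generate_cohort()]).
#' @param out_dir output directory.
#' @param held_out_patient patient id to hold out; default the last patient
#'   in the manifest.
#' @param feature_mode `"full_spectrum"` (default) or `"single_band"`.
#' @param n_regions,side,n_measurements ROI protocol parameters.
#' @param init K-means initialization.
#' @param seed master seed for every stochastic stage.
#' @return object of class `"experiment_report"` (also serialized as JSON):
#'   selected band, LOPO metrics, per-patient accuracy table, file paths,
#'   configuration echo.
#' @export
run_experiment <- function(cohort_dir, out_dir,
                           held_out_patient = NULL,
                           feature_mode = "full_spectrum",
                           n_regions = 4L, side = 20L, n_measurements = 10L,
                           init = "farthest", seed = 1L) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  mf <- read_manifest(cohort_dir)
  patients <- unique(mf$patient_id)
  if (is.null(held_out_patient))
    held_out_patient <- patients[length(patients)]
  seeds <- derive_seeds(seed, 4L)

  ## stage 1: spectral summaries + band selection (training patients only,
  ## stained slides — the held-out patient influences nothing)
  training <- setdiff(patients, held_out_patient)
  sp <- spectra_stage(cohort_dir, training, n_regions = n_regions,
                      side = side, n_measurements = n_measurements,
                      seed = seeds[1L])
  sum_cancer <- sp$summaries_cancer
  sum_normal <- sp$summaries_normal
  separation <- sp$separation
  band_nm <- sp$band_nm
  write_separation_tsv(separation, file.path(out_dir, "separation.tsv"))
  write_summaries_tsv(c(sum_cancer, sum_normal),
                      file.path(out_dir, "roi_summaries.tsv"))

  ## stage 2: LOPO training
  fit <- train_lopo(cohort_dir, held_out_patient, staining = "stained",
                    feature_mode = feature_mode, band_nm = band_nm,
                    n_regions = n_regions, side = side, init = init,
                    seed = seeds[2L])
  write_centroids_tsv(fit$labeled_model$model,
                      file.path(out_dir, "centroids.tsv"))
  utils::write.table(fit$per_patient,
                     file.path(out_dir, "per_patient_accuracy.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  ## stage 3-4: held-out classification + metrics
  held_slides <- cohort_slides(cohort_dir, held_out_patient)
  dcis <- held_slides$dcis_stained; norm <- held_slides$normal_stained
  pred_dcis <- classify_cube(fit$labeled_model, dcis$cube)
  pred_norm <- classify_cube(fit$labeled_model, norm$cube)
  m_dcis <- evaluate_masks(pred_dcis, dcis$mask)
  pooled <- metrics_from_counts(
    TP = m_dcis$TP, FN = m_dcis$FN,
    FP = m_dcis$FP + sum(pred_norm == 1L),
    TN = m_dcis$TN + sum(pred_norm == 0L))

  # region-level: majority vote over fresh ROIs on the held-out dcis slide
  rseeds <- derive_seeds(seeds[3L], 2L)
  roi_held_c <- pick_rois(dcis, n_regions = n_regions, side = side,
                          seed = rseeds[1L])
  roi_held_n <- pick_rois(norm, n_regions = n_regions, side = side,
                          seed = rseeds[2L])
  vote <- function(pred, rois) vapply(seq_len(nrow(rois)), function(i) {
    r0 <- rois$row0[i]; c0 <- rois$col0[i]; s <- rois$side[i]
    as.integer(mean(pred[r0:(r0 + s - 1L), c0:(c0 + s - 1L)]) > 0.5)
  }, integer(1))
  region_pred <- c(vote(pred_dcis, roi_held_c), vote(pred_norm, roi_held_n))
  region_truth <- c(rep(1L, n_regions), rep(0L, n_regions))
  region_metrics <- evaluate_masks(matrix(region_pred), matrix(region_truth))

  ## stage 5: overlays
  render_overlay(dcis$cube, pred_dcis, roi_held_c, band_nm,
                 path = file.path(out_dir, "overlay_dcis.png"))
  render_overlay(norm$cube, pred_norm, NULL, band_nm,
                 path = file.path(out_dir, "overlay_normal.png"))

  metrics_df <- data.frame(
    level = c("pixel_pooled", "pixel_dcis_slide", "region"),
    rbind(unlist(pooled[c("TP", "FP", "TN", "FN", "sensitivity",
                          "specificity", "TNR", "FPR", "accuracy")]),
          unlist(m_dcis[c("TP", "FP", "TN", "FN", "sensitivity",
                          "specificity", "TNR", "FPR", "accuracy")]),
          unlist(region_metrics[c("TP", "FP", "TN", "FN", "sensitivity",
                                  "specificity", "TNR", "FPR",
                                  "accuracy")])))
  utils::write.table(metrics_df, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  report <- structure(list(
    cohort_dir = cohort_dir, held_out_patient = held_out_patient,
    training_patients = fit$training_patients,
    selected_band_nm = band_nm,
    separation_peak_score = max(separation$score),
    feature_mode = feature_mode,
    metrics = pooled, metrics_dcis_slide = m_dcis,
    metrics_region = region_metrics,
    per_patient = fit$per_patient,
    n_training_pixels = fit$n_training_pixels,
    config = list(n_regions = n_regions, side = side,
                  n_measurements = n_measurements, init = init,
                  seed = seed)), class = "experiment_report")
  json <- jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  writeLines(json, file.path(out_dir, "report.json"))
  report
}

#' ROI spectral summaries and band selection over a set of patients
#'
#' Shared stage behind [run_experiment()] and the CLI: for every listed
#' patient, places cancer ROIs on the stained dcis slide and normal ROIs on
#' the stained normal slide, summarizes each ROI over repeated measurements,
#' and scores the per-band class separation.
#'
#' @param cohort a cohort directory or in-memory cohort list.
#' @param patients patient ids to include (default all).
#' @param n_regions,side,n_measurements ROI protocol parameters.
#' @param staining slides to use (default `"stained"`).
#' @param seed integer seed.
#' @return list with `summaries_cancer`, `summaries_normal`, `separation`
#'   (a [band_separation()] object) and `band_nm` (the selected
#'   wavelength).
#' @export
spectra_stage <- function(cohort, patients = cohort_patients(cohort),
                          n_regions = 4L, side = 20L, n_measurements = 10L,
                          staining = "stained", seed = NULL) {
  spectra_seeds <- derive_seeds(seed, length(patients))
  sum_cancer <- list(); sum_normal <- list()
  for (i in seq_along(patients)) {
    slides <- cohort_slides(cohort, patients[i])
    s2 <- derive_seeds(spectra_seeds[i], 2L)
    dcis <- slides[[paste0("dcis_", staining)]]
    norm <- slides[[paste0("normal_", staining)]]
    rois_c <- pick_rois(dcis, n_regions = n_regions, side = side,
                        seed = s2[1L])
    rois_n <- pick_rois(norm, n_regions = n_regions, side = side,
                        seed = s2[2L])
    rs <- derive_seeds(s2[1L], 2L * n_regions)
    for (j in seq_len(n_regions)) {
      sum_cancer[[length(sum_cancer) + 1L]] <-
        region_spectrum(dcis$cube, rois_c[j, ], n_measurements,
                        label = 1L, seed = rs[j])
      sum_normal[[length(sum_normal) + 1L]] <-
        region_spectrum(norm$cube, rois_n[j, ], n_measurements,
                        label = 0L, seed = rs[n_regions + j])
    }
  }
  separation <- band_separation(sum_cancer, sum_normal)
  list(summaries_cancer = sum_cancer, summaries_normal = sum_normal,
       separation = separation, band_nm = select_band(separation))
}

report_to_list <- function(report) {
  r <- unclass(report)
  r$metrics <- unclass(r$metrics)
  r$metrics_dcis_slide <- unclass(r$metrics_dcis_slide)
  r$metrics_region <- unclass(r$metrics_region)
  r
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat("  held-out patient:", x$held_out_patient, "\n")
  cat("  selected band:", x$selected_band_nm, "nm\n")
  cat("  pooled pixel metrics: "); print(x$metrics)
  cat("  per-patient training accuracy (separate fits):\n")
  print(x$per_patient, row.names = FALSE)
  invisible(x)
}
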
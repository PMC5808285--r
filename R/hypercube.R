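#' Construct a hyperspectral reflectance cube
#'
#' A hypercube is a 3-D array of dimensionless reflectance values with two
#' spatial axes (rows, columns) and one spectral axis (bands), together with
#' the band-center wavelengths in nanometres and free-form string metadata
#' (patient id, staining, tissue class, ...). Each pixel therefore carries a
#' full reflectance spectrum.
#'
#' Reflectance is expected in \[0, 1\]. Values outside that range trigger a
#' warning (other producers' calibrations may overshoot) but are kept;
#' non-finite values are an error.
#'
#' @param data numeric 3-D array, `rows x cols x bands`.
#' @param wavelengths numeric vector of band-center wavelengths (nm),
#'   strictly increasing, one per band.
#' @param metadata named list of character scalars.
#' @return An object of class `"hypercube"` with elements `data`,
#'   `wavelengths` and `metadata`.
#' @examples
#' cube <- hypercube(array(0.5, c(4, 3, 2)), c(500, 510))
#' dim(cube$data)
#' @export
hypercube <- function(data, wavelengths, metadata = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows x cols x bands)")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop("length(wavelengths) [", length(wavelengths),
         "] must equal the number of bands [", dim(data)[3L], "]")
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    stop("`wavelengths` must be finite")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  if (any(!is.finite(data)))
    stop("`data` contains non-finite reflectance values")
  rng <- range(data)
  if (rng[1L] < 0 || rng[2L] > 1)
    warning("reflectance values outside [0, 1] (range ",
            signif(rng[1L], 4), " .. ", signif(rng[2L], 4), ")")
  structure(list(data = data, wavelengths = wavelengths,
                 metadata = as.list(metadata)),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Spatial dimensions of a cube
#' @param cube a [hypercube].
#' @return integer vector `c(rows, cols)`.
#' @export
spatial_dim <- function(cube) dim(cube$data)[1:2]

#' Number of spectral bands
#' @param cube a [hypercube].
#' @return integer scalar.
#' @export
n_bands <- function(cube) dim(cube$data)[3L]

#' Extract the reflectance spectrum of one pixel
#'
#' @param cube a [hypercube].
#' @param row,col pixel indices (1-based).
#' @return numeric vector of length `n_bands(cube)`.
#' @export
pixel_spectrum <- function(cube, row, col) {
  d <- dim(cube$data)
  if (row < 1L || row > d[1L] || col < 1L || col > d[2L])
    stop("pixel (", row, ", ", col, ") out of bounds for ",
         d[1L], " x ", d[2L], " image")
  as.numeric(cube$data[row, col, ])
}

#' Extract the band image nearest a requested wavelength
#'
#' Returns the 2-D reflectance slice of the band whose center wavelength is
#' nearest the request. Ties (a request exactly midway between two centers)
#' resolve to the lower wavelength. Requests farther than half the band
#' spacing outside the sensor range are an error.
#'
#' @param cube a [hypercube].
#' @param wavelength_nm requested wavelength (nm).
#' @return list with `image` (rows x cols matrix), `wavelength_nm` (the
#'   selected band center) and `band` (1-based band index).
#' @examples
#' cube <- hypercube(array(runif(4 * 3 * 31), c(4, 3, 31)),
#'                   seq(461, 641, length.out = 31))
#' band_image(cube, 550)$wavelength_nm  # 551, the nearest center
#' @export
band_image <- function(cube, wavelength_nm) {
  w <- cube$wavelengths
  half <- if (length(w) > 1L) max(diff(w)) / 2 else Inf
  if (wavelength_nm < min(w) - half || wavelength_nm > max(w) + half)
    stop("wavelength ", wavelength_nm, " nm outside sensor range ",
         min(w), "-", max(w), " nm")
  idx <- nearest_band(w, wavelength_nm)
  list(image = cube$data[, , idx], wavelength_nm = w[idx], band = idx)
}

# index of the band center nearest `target`; ties -> lower wavelength
nearest_band <- function(wavelengths, target) {
  which.min(abs(wavelengths - target))
}

#' Flatten cube pixels to a pixel-by-band matrix
#'
#' Produces one row per selected pixel in deterministic row-major order
#' (row 1 left-to-right, then row 2, ...). An optional label mask attaches a
#' class label (0 = non-cancer, 1 = cancer) to each pixel; an optional
#' logical/0-1 `select` matrix restricts which pixels are kept (selecting no
#' pixels yields an empty matrix, not an error).
#'
#' @param cube a [hypercube].
#' @param mask optional label [Mask][read_pgm]: integer matrix in \{0, 1\}
#'   matching the cube's spatial shape.
#' @param select optional logical (or 0/1) matrix matching the spatial shape;
#'   only `TRUE` pixels are returned.
#' @return list of class `"pixel_matrix"` with `spectra` (n x bands),
#'   `coords` (n x 2 matrix of 1-based `(row, col)`), and `labels`
#'   (integer vector or `NULL`).
#' @export
flatten_pixels <- function(cube, mask = NULL, select = NULL) {
  d <- dim(cube$data)
  nr <- d[1L]; nc <- d[2L]; nb <- d[3L]
  if (!is.null(mask)) {
    validate_mask(mask, c(nr, nc))
  }
  if (!is.null(select)) {
    if (!all(dim(select) == c(nr, nc)))
      stop("`select` shape (", paste(dim(select), collapse = " x "),
           ") does not match cube spatial shape (", nr, " x ", nc, ")")
    select <- matrix(as.logical(select), nr, nc)
  }
  # row-major traversal: row varies slowest
  coords <- cbind(row = rep(seq_len(nr), each = nc),
                  col = rep(seq_len(nc), times = nr))
  if (!is.null(select)) {
    keep <- select[coords]
    coords <- coords[keep, , drop = FALSE]
  }
  lin <- (coords[, 2L] - 1L) * nr + coords[, 1L]   # column-major linear index
  all_spec <- matrix(cube$data, nr * nc, nb)
  spectra <- all_spec[lin, , drop = FALSE]
  labels <- if (!is.null(mask)) as.integer(mask[coords]) else NULL
  structure(list(spectra = spectra, coords = coords, labels = labels,
                 wavelengths = cube$wavelengths),
            class = "pixel_matrix")
}

#' Scatter per-pixel values back into an image
#'
#' Inverse of [flatten_pixels()] for a single value per pixel: writes
#' `values[i]` at `coords[i, ]` into a `rows x cols` matrix (others `fill`).
#'
#' @param values vector, one element per coordinate row.
#' @param coords n x 2 matrix of 1-based `(row, col)`.
#' @param rows,cols output dimensions.
#' @param fill value for untouched pixels.
#' @return a `rows x cols` matrix.
#' @export
scatter_pixels <- function(values, coords, rows, cols, fill = NA) {
  if (length(values) != nrow(coords))
    stop("length(values) must equal nrow(coords)")
  out <- matrix(fill, rows, cols)
  out[coords] <- values
  out
}

# validate a binary tissue mask against a spatial shape
validate_mask <- function(mask, spatial, what = "mask") {
  if (!is.matrix(mask))
    stop("`", what, "` must be a matrix")
  if (!all(dim(mask) == spatial))
    stop("`", what, "` shape (", paste(dim(mask), collapse = " x "),
         ") does not match expected (", paste(spatial, collapse = " x "), ")")
  if (!all(mask %in% c(0L, 1L)))
    stop("`", what, "` may only contain values 0 and 1")
  invisible(TRUE)
}

#' Field of view in square centimetres
#'
#' Converts a microscope field of view given in micrometres to cm^2
#' (100 um x 80 um = 8e-5 cm^2 for the 40x snapshot configuration).
#'
#' @param width_um,height_um field dimensions in micrometres.
#' @return area in cm^2.
#' @export
field_of_view_cm2 <- function(width_um, height_um) {
  (width_um * 1e-4) * (height_um * 1e-4)
}

# run code with a temporary RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# derive k child seeds (< 2^31) from one master seed, deterministically
derive_seeds <- function(seed, k) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
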
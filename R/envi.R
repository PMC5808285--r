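#' Read a hyperspectral cube from ENVI files
#'
#' Parses a plain-text ENVI header (`.hdr`) and its companion raw binary
#' file. All three interleaves (`bsq`, `bil`, `bip`), both byte orders, and
#' data types 1 (uint8), 2 (int16), 3 (int32), 4 (float32), 5 (float64) and
#' 12 (uint16) are supported. The header must carry a `wavelength` list;
#' cubes without one are rejected because every downstream step is expressed
#' in nanometres.
#'
#' @param path path to the `.hdr` file, or its basename (the `.hdr`
#'   extension is added if missing). The raw file is looked up as the
#'   basename itself or with one of `.img`, `.dat`, `.raw`, `.bsq`, `.bil`,
#'   `.bip` appended.
#' @param metadata optional named list merged into the cube metadata.
#' @return a [hypercube].
#' @seealso [write_envi()]
#' @export
read_envi <- function(path, metadata = list()) {
  hdr_path <- if (grepl("\\.hdr$", path, ignore.case = TRUE)) path
              else paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    stop("ENVI header not found: ", hdr_path)
  hdr <- parse_envi_header(hdr_path)
  for (key in c("samples", "lines", "bands", "data type", "interleave",
                "byte order")) {
    if (is.null(hdr[[key]]))
      stop("ENVI header ", hdr_path, " is missing required field `", key, "`")
  }
  if (is.null(hdr[["wavelength"]]))
    stop("ENVI header ", hdr_path, " is missing required field `wavelength`")

  samples <- as.integer(hdr[["samples"]])   # columns
  lines   <- as.integer(hdr[["lines"]])     # rows
  bands   <- as.integer(hdr[["bands"]])
  dtype   <- as.integer(hdr[["data type"]])
  interleave <- tolower(hdr[["interleave"]])
  endian <- if (as.integer(hdr[["byte order"]]) == 1L) "big" else "little"
  wavelengths <- as.numeric(strsplit(hdr[["wavelength"]], ",")[[1]])
  if (length(wavelengths) != bands)
    stop("header `wavelength` lists ", length(wavelengths),
         " values but `bands` = ", bands)

  spec <- envi_dtype_spec(dtype)
  raw_path <- find_envi_raw(hdr_path)
  n <- samples * lines * bands
  con <- file(raw_path, "rb")
  on.exit(close(con))
  values <- readBin(con, what = spec$what, n = n, size = spec$size,
                    signed = spec$signed, endian = endian)
  if (length(values) != n)
    stop("raw file ", raw_path, " holds ", length(values),
         " values; expected ", n)
  values <- as.numeric(values)

  # on-disk axis order (fastest first) per interleave; rows = lines,
  # cols = samples; in-memory target is (row, col, band)
  data <- switch(interleave,
    bsq = aperm(array(values, c(samples, lines, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(values, c(samples, bands, lines)), c(3L, 1L, 2L)),
    bip = aperm(array(values, c(bands, samples, lines)), c(3L, 2L, 1L)),
    stop("unsupported interleave `", interleave, "` (expected bsq/bil/bip)")
  )
  hypercube(data, wavelengths, metadata)
}

#' Write a hyperspectral cube as an ENVI header/raw pair
#'
#' @param cube a [hypercube].
#' @param path output basename (or `.hdr` path); `<base>.hdr` and
#'   `<base>.img` are written.
#' @param interleave `"bsq"` (default), `"bil"` or `"bip"`.
#' @param data_type `"float64"` (default, value-exact round trip) or
#'   `"float32"` (half the disk footprint; ~7 significant digits).
#' @param byte_order 0 (little endian, default) or 1 (big endian).
#' @return invisibly, a character vector `c(hdr, img)` of the files written.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = c("float64", "float32"), byte_order = 0L) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  data_type <- match.arg(data_type)
  base <- sub("\\.hdr$", "", path, ignore.case = TRUE)
  hdr_path <- paste0(base, ".hdr")
  img_path <- paste0(base, ".img")

  d <- dim(cube$data)
  dtype_code <- if (data_type == "float64") 5L else 4L
  size <- if (data_type == "float64") 8L else 4L
  endian <- if (byte_order == 1L) "big" else "little"

  hdr <- c(
    "ENVI",
    "description = {hsikmeans hyperspectral reflectance cube}",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", dtype_code),
    paste0("interleave = ", interleave),
    paste0("byte order = ", as.integer(byte_order)),
    "wavelength units = Nanometers",
    paste0("wavelength = {", paste(format(cube$wavelengths, trim = TRUE),
                                   collapse = ", "), "}")
  )
  ok <- tryCatch({
    writeLines(hdr, hdr_path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write ENVI header to ", hdr_path)

  perm <- switch(interleave,
                 bsq = c(2L, 1L, 3L),   # sample fastest, then line, then band
                 bil = c(2L, 3L, 1L),   # sample, band, line
                 bip = c(3L, 2L, 1L))   # band, sample, line
  values <- as.vector(aperm(cube$data, perm))
  con <- file(img_path, "wb")
  on.exit(close(con))
  writeBin(values, con, size = size, endian = endian)
  invisible(c(hdr = hdr_path, img = img_path))
}

# parse an ENVI .hdr into a named list of strings; `{...}` values are
# flattened to one comma-separated string
parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[i]
    if (grepl("=", line, fixed = TRUE)) {
      key <- tolower(trimws(sub("=.*$", "", line)))
      val <- trimws(sub("^[^=]*=", "", line))
      if (startsWith(val, "{")) {
        while (!grepl("\\}", val) && i < length(lines)) {
          i <- i + 1L
          val <- paste(val, trimws(lines[i]))
        }
        val <- gsub("[{}]", "", val)
      }
      out[[key]] <- trimws(val)
    }
    i <- i + 1L
  }
  out
}

envi_dtype_spec <- function(dtype) {
  switch(as.character(dtype),
    "1"  = list(what = integer(), size = 1L, signed = FALSE),
    "2"  = list(what = integer(), size = 2L, signed = TRUE),
    "3"  = list(what = integer(), size = 4L, signed = TRUE),
    "4"  = list(what = numeric(), size = 4L, signed = TRUE),
    "5"  = list(what = numeric(), size = 8L, signed = TRUE),
    "12" = list(what = integer(), size = 2L, signed = FALSE),
    stop("unsupported ENVI `data type` = ", dtype,
         " (supported: 1, 2, 3, 4, 5, 12)")
  )
}

find_envi_raw <- function(hdr_path) {
  base <- sub("\\.hdr$", "", hdr_path, ignore.case = TRUE)
  candidates <- c(base, paste0(base, c(".img", ".dat", ".raw",
                                       ".bsq", ".bil", ".bip")))
  hit <- candidates[file.exists(candidates) & !dir.exists(candidates)]
  if (!length(hit))
    stop("no raw data file found for header ", hdr_path)
  hit[1L]
}

#' Read a binary tissue mask from a PGM file
#'
#' Accepts ASCII (`P2`) and raw (`P5`, 8-bit) portable graymaps. Values must
#' be \{0, 1\}; as a tolerance for other producers, images holding only
#' \{0, 255\} are mapped to \{0, 1\}.
#'
#' @param path path to the `.pgm` file.
#' @return integer matrix (rows x cols) with values 0/1.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("PGM file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5"))
    stop(path, ": unsupported PGM magic `", magic, "` (expected P2 or P5)")
  # read header tokens (width, height, maxval), skipping comments
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (!length(ch) || ch == "") stop(path, ": truncated PGM header")
    if (ch == "#") {            # comment to end of line
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r", "")) break
      }
    } else if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
        buf <- character(0)
      }
    } else buf <- c(buf, ch)
  }
  width <- tokens[1L]; height <- tokens[2L]; maxval <- tokens[3L]
  if (maxval > 255L) stop(path, ": only 8-bit PGM supported (maxval <= 255)")
  n <- width * height
  values <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n))
  } else {
    as.integer(scan(con, what = integer(), n = n, quiet = TRUE))
  }
  if (length(values) != n) stop(path, ": expected ", n, " pixels, got ",
                                length(values))
  u <- unique(values)
  if (all(u %in% c(0L, 255L)) && any(u == 255L)) values <- values %/% 255L
  if (!all(values %in% c(0L, 1L)))
    stop(path, ": mask values must be 0/1 (or 0/255); saw ",
         paste(utils::head(setdiff(u, c(0L, 1L, 255L)), 5), collapse = ", "))
  # PGM stores row by row (row-major); R matrices are column-major
  matrix(values, nrow = height, ncol = width, byrow = TRUE)
}

#' Write a binary tissue mask as a raw PGM file
#'
#' @param mask integer matrix with values 0/1.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pgm <- function(mask, path) {
  validate_mask(mask, dim(mask))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(mask), nrow(mask)), con,
            eos = NULL)
  writeBin(as.raw(as.integer(t(mask))), con)
  invisible(path)
}
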
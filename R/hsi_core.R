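#' @useDynLib dbytk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif cor cov sd smooth.spline predict quantile
#' @importFrom utils head tail
"_PACKAGE"

# Default spectral grid: 400-900 nm in 5 nm steps, 101 bands.
DEFAULT_WAVELENGTHS <- seq(400, 900, by = 5)

#' Construct a hyperspectral reflectance cube
#'
#' A `spectral_cube` holds an H x W x B reflectance array together with its
#' wavelength grid (nm, strictly increasing). Reflectance is stored as
#' floating point and is expected to lie in \[0, 1\]; values up to 1.5 are
#' tolerated on load to allow for specular glint.
#'
#' @param data numeric H x W x B array of reflectance values.
#' @param wavelengths numeric vector of band-center wavelengths in nm,
#'   strictly increasing, of length B.
#' @return An object of class `spectral_cube` with fields `data` and
#'   `wavelengths`.
#' @export
spectral_cube <- function(data, wavelengths = DEFAULT_WAVELENGTHS) {
  if (length(dim(data)) != 3L)
    stop("cube data must be a 3-d array (H x W x B)")
  if (dim(data)[3] != length(wavelengths))
    stop("band count mismatch: data has ", dim(data)[3], " bands, ",
         length(wavelengths), " wavelengths")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (!all(is.finite(data)))
    stop("cube contains non-finite reflectance values")
  if (min(data) < 0 || max(data) > 1.5)
    stop("reflectance outside [0, 1.5]: range ",
         paste(signif(range(data), 4), collapse = " .. "))
  structure(list(data = data, wavelengths = as.numeric(wavelengths)),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube %d x %d px, %d bands %g-%g nm>\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Dimensions of a cube (H, W, B)
#' @param x a [spectral_cube()].
#' @export
dim.spectral_cube <- function(x) dim(x$data)

# ---- ENVI-dialect cube I/O --------------------------------------------------

#' Write a cube as an ENVI-style header + raw binary pair
#'
#' The header is a plain-text `.hdr` with samples/lines/bands, interleave and
#' a wavelength block; the data file holds 32-bit little-endian IEEE floats
#' in BSQ, BIL or BIP order.
#'
#' @param cube a [spectral_cube()].
#' @param path_header path for the text header.
#' @param path_data path for the binary cube; default replaces the `.hdr`
#'   suffix with `.raw`.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type 4 for 32-bit floats (the compact ENVI default) or 5
#'   for 64-bit, which round-trips R doubles exactly.
#' @return `path_header`, invisibly.
#' @export
write_cube <- function(cube, path_header,
                       path_data = sub("\\.hdr$", ".raw", path_header),
                       interleave = c("bsq", "bil", "bip"),
                       data_type = 4L) {
  stopifnot(inherits(cube, "spectral_cube"), data_type %in% c(4L, 5L))
  interleave <- match.arg(interleave)
  d <- dim(cube$data)  # H(lines) x W(samples) x B
  hdr <- c(
    "ENVI",
    "description = { dbytk synthetic hyperspectral cube }",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, trim = TRUE), collapse = ", "),
           " }"))
  writeLines(hdr, path_header)
  # cube$data is [H, W, B] column-major, i.e. H fastest.
  x <- cube$data
  vals <- switch(interleave,
    # BSQ: band sequential, within band row-major (samples fastest)
    bsq = as.numeric(aperm(x, c(2, 1, 3))),
    # BIL: line, then band, then sample
    bil = as.numeric(aperm(x, c(2, 3, 1))),
    # BIP: pixel-interleaved, band fastest
    bip = as.numeric(aperm(x, c(3, 2, 1))))
  con <- file(path_data, "wb")
  on.exit(close(con))
  writeBin(vals, con, size = if (data_type == 4L) 4L else 8L,
           endian = "little")
  invisible(path_header)
}

parse_envi_header <- function(path_header) {
  txt <- paste(readLines(path_header, warn = FALSE), collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexpr(paste0("(?mi)^\\s*", key, "\\s*=\\s*([0-9]+)"),
                                 txt, perl = TRUE))
    if (!length(m)) stop("ENVI header missing '", key, "'")
    as.integer(sub(".*=\\s*", "", m))
  }
  get_str <- function(key) {
    m <- regmatches(txt,
      regexpr(paste0("(?mi)^\\s*", key, "\\s*=\\s*([a-zA-Z0-9]+)"), txt,
              perl = TRUE))
    if (!length(m)) stop("ENVI header missing '", key, "'")
    tolower(sub(".*=\\s*", "", m))
  }
  wl_m <- regmatches(txt, regexpr("(?si)wavelength\\s*=\\s*\\{[^}]*\\}", txt,
                                  perl = TRUE))
  if (!length(wl_m)) stop("no wavelength metadata")
  wl <- as.numeric(strsplit(gsub("(?si).*\\{|\\}", "", wl_m, perl = TRUE),
                            ",")[[1]])
  list(samples = get_num("samples"), lines = get_num("lines"),
       bands = get_num("bands"), interleave = get_str("interleave"),
       data_type = get_num("data type"), wavelengths = wl)
}

#' Read an ENVI-style cube
#'
#' Parses the text header (samples/lines/bands/interleave/wavelengths) and
#' reads the raw 32-bit float cube, reordering to H x W x B regardless of the
#' stored interleave.
#'
#' @param path_header path to the `.hdr` text header.
#' @param path_data path to the binary data file; default replaces `.hdr`
#'   with `.raw`.
#' @return A [spectral_cube()].
#' @export
read_cube <- function(path_header,
                      path_data = sub("\\.hdr$", ".raw", path_header)) {
  h <- parse_envi_header(path_header)
  if (!h$data_type %in% c(4L, 5L))
    stop("unsupported ENVI data type ", h$data_type,
         " (expected 4 or 5 = float)")
  if (length(h$wavelengths) != h$bands)
    stop("band count mismatch: header declares ", h$bands, " bands but ",
         length(h$wavelengths), " wavelengths")
  n <- h$samples * h$lines * h$bands
  bytes <- if (h$data_type == 4L) 4L else 8L
  sz <- file.info(path_data)$size
  if (is.na(sz) || sz != bytes * n)
    stop("band count mismatch: data file holds ", sz %/% bytes,
         " values, header implies ", n)
  con <- file(path_data, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n, size = bytes, endian = "little")
  x <- switch(h$interleave,
    bsq = aperm(array(vals, c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
    bil = aperm(array(vals, c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
    bip = aperm(array(vals, c(h$bands, h$samples, h$lines)), c(3, 2, 1)),
    stop("unknown interleave '", h$interleave, "'"))
  spectral_cube(x, h$wavelengths)
}

# ---- Detection labels -------------------------------------------------------

NTRM_CLASSES <- c(weed = 0L, rubber_ring = 1L, feather = 2L)

validate_boxes <- function(boxes, n_classes = 3L, where = "box") {
  stopifnot(is.data.frame(boxes))
  need <- c("class_id", "cx", "cy", "w", "h")
  if (!all(need %in% names(boxes)))
    stop("boxes need columns ", paste(need, collapse = ", "))
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    if (b$class_id < 0 || b$class_id >= n_classes)
      stop(where, " ", i, ": class_id ", b$class_id,
           " outside [0, ", n_classes - 1, "]")
    if (b$cx < 0 || b$cx > 1 || b$cy < 0 || b$cy > 1)
      stop(where, " ", i, ": center (", b$cx, ", ", b$cy,
           ") outside unit square")
    if (b$w <= 0 || b$w > 1 || b$h <= 0 || b$h > 1)
      stop(where, " ", i, ": size (", b$w, ", ", b$h, ") outside (0, 1]")
  }
  boxes
}

empty_boxes <- function() {
  data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
             w = numeric(0), h = numeric(0))
}

#' Read normalized detection labels
#'
#' One box per line, `class cx cy w h`, all coordinates normalized to the
#' unit square in center format.
#'
#' @param path label file path.
#' @param n_classes number of valid classes; `class_id` must be smaller.
#' @return data frame with columns `class_id`, `cx`, `cy`, `w`, `h`.
#' @export
read_labels <- function(path, n_classes = 3L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_boxes())
  rows <- lapply(seq_along(lines), function(i) {
    f <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
    if (length(f) != 5 || any(!is.finite(f)))
      stop("label line ", i, ": expected 'class cx cy w h', got '",
           lines[i], "'")
    data.frame(class_id = as.integer(f[1]), cx = f[2], cy = f[3],
               w = f[4], h = f[5])
  })
  boxes <- do.call(rbind, rows)
  validate_boxes(boxes, n_classes, where = "label line")
}

#' Write normalized detection labels
#'
#' @param boxes data frame as returned by [read_labels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(boxes, path) {
  lines <- sprintf("%d %.10g %.10g %.10g %.10g", boxes$class_id, boxes$cx,
                   boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

# ---- Band access ------------------------------------------------------------

band_index <- function(wavelengths, lambda, tol = 2.5) {
  if (lambda < min(wavelengths) - tol || lambda > max(wavelengths) + tol)
    stop("wavelength ", lambda, " nm outside grid ",
         min(wavelengths), "-", max(wavelengths), " nm")
  i <- which.min(abs(wavelengths - lambda))
  if (abs(wavelengths[i] - lambda) > tol)
    stop("no band within ", tol, " nm of ", lambda, " nm")
  i
}

#' Extract a single-wavelength grayscale plane
#'
#' Snaps to the nearest band within 2.5 nm (half the default grid step).
#'
#' @param cube a [spectral_cube()].
#' @param lambda requested wavelength in nm.
#' @param as_8bit if `TRUE`, min-max scale the plane to integers 0..255
#'   (a constant plane maps to 0).
#' @return H x W numeric (or integer) matrix.
#' @export
band_slice <- function(cube, lambda, as_8bit = FALSE) {
  stopifnot(inherits(cube, "spectral_cube"))
  i <- band_index(cube$wavelengths, lambda)
  plane <- cube$data[, , i]
  if (as_8bit) plane <- scale_8bit(plane)
  plane
}

# Min-max scale a matrix/array to integers 0..255; constant input -> all 0.
scale_8bit <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(1, abs(rng[2]))) {
    y <- array(0L, dim(x))
  } else {
    y <- round((x - rng[1]) / (rng[2] - rng[1]) * 255)
    storage.mode(y) <- "integer"
  }
  y
}

# ---- Annotated scenes -------------------------------------------------------

#' Construct an annotated scene
#'
#' Bundles the (optional) hyperspectral cube, an 8-bit RGB render, an
#' optional enhanced (DCS) image, normalized boxes and a split tag.
#'
#' @param rgb H x W x 3 array, values 0..255.
#' @param boxes data frame of normalized center-format boxes.
#' @param cube optional [spectral_cube()].
#' @param dcs optional H x W x 3 enhanced image (same H x W as `rgb`).
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @param id scene identifier.
#' @param material_map optional H x W integer matrix of material codes
#'   (0 belt, 1 tobacco, 2 weed, 3 rubber ring, 4 feather).
#' @return An object of class `annotated_scene`.
#' @export
annotated_scene <- function(rgb, boxes, cube = NULL, dcs = NULL,
                            split = c("train", "val", "test"), id = NA,
                            material_map = NULL) {
  split <- match.arg(split)
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  if (!is.null(dcs) && !all(dim(dcs)[1:2] == dim(rgb)[1:2]))
    stop("rgb and dcs must share H x W")
  boxes <- validate_boxes(boxes)
  structure(list(rgb = rgb, dcs = dcs, cube = cube, boxes = boxes,
                 split = split, id = id, material_map = material_map),
            class = "annotated_scene")
}

#' @export
print.annotated_scene <- function(x, ...) {
  cat(sprintf("<annotated_scene %s: %d x %d px, %d boxes, split=%s%s>\n",
              as.character(x$id), dim(x$rgb)[1], dim(x$rgb)[2], nrow(x$boxes),
              x$split, if (is.null(x$cube)) "" else ", with cube"))
  invisible(x)
}

#' Write an image array as PNG
#'
#' @param img H x W (grayscale) or H x W x 3 array with values 0..255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}
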
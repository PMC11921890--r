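# Three-channel image enhancement from the selected characteristic bands:
# pseudo-color composition (PCC) and decorrelation contrast stretch (DCS).

new_enhanced <- function(pixels, kind, band_map, stretch_params = NULL) {
  structure(list(pixels = pixels, kind = kind, band_map = band_map,
                 stretch_params = stretch_params), class = "enhanced_image")
}

#' @export
print.enhanced_image <- function(x, ...) {
  cat(sprintf("<enhanced_image %s %d x %d, bands R/G/B = %s nm>\n", x$kind,
              dim(x$pixels)[1], dim(x$pixels)[2],
              paste(x$band_map, collapse = "/")))
  invisible(x)
}

#' Pseudo-color composition from three characteristic bands
#'
#' Each selected band is independently min-max scaled to 0..255 (a constant
#' band maps to zeros) and the three planes are assigned to channels by
#' descending wavelength, the NIR-as-red false-color convention.
#'
#' @param cube a [spectral_cube()].
#' @param triple three distinct wavelengths (nm) resolvable by
#'   [band_slice()].
#' @return An `enhanced_image` of kind `"PCC"` with `band_map` recording
#'   the (R, G, B) wavelengths.
#' @export
pseudo_color <- function(cube, triple = c(580, 680, 850)) {
  stopifnot(length(triple) == 3)
  if (anyDuplicated(triple)) stop("duplicate wavelengths in triple")
  bm <- sort(triple, decreasing = TRUE)
  d <- dim(cube$data)
  px <- array(0, c(d[1], d[2], 3))
  for (i in 1:3) px[, , i] <- band_slice(cube, bm[i], as_8bit = TRUE)
  new_enhanced(px, "PCC", bm)
}

#' Decorrelation contrast stretch
#'
#' Centers the channels, whitens them with the symmetric inverse square
#' root of the (ridge-regularized) channel covariance, rescales every
#' output channel to `target_sd`, restores the original channel means and
#' clips to 0..255. Whitening in the original channel basis (V L^-1/2 V')
#' preserves channel identity, so hue assignments stay interpretable.
#'
#' @param img H x W x 3 array (any real scale) or an `enhanced_image`.
#' @param target_sd per-channel standard deviation after the stretch.
#' @param ridge relative ridge added to the covariance diagonal
#'   (`ridge * trace/3 * I`) so near-degenerate channels stay invertible.
#' @param clip output range.
#' @return An `enhanced_image` of kind `"DCS"`; `stretch_params` records
#'   channel means, the covariance eigendecomposition and the target SD.
#' @export
decorrelation_stretch <- function(img, target_sd = 60, ridge = 1e-6,
                                  clip = c(0, 255)) {
  band_map <- NULL
  if (inherits(img, "enhanced_image")) {
    band_map <- img$band_map
    img <- img$pixels
  }
  d <- dim(img)
  stopifnot(length(d) == 3, d[3] == 3)
  X <- matrix(as.numeric(img), d[1] * d[2], 3)
  mu <- colMeans(X)
  S <- stats::cov(X)
  tr <- sum(diag(S))
  if (tr <= .Machine$double.eps)
    stop("degenerate covariance: all channels constant")
  S <- S + diag(3) * ridge * tr / 3
  e <- eigen(S, symmetric = TRUE)
  Tm <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  Y <- sweep(X, 2, mu) %*% Tm            # whitened: unit variance per channel
  Y <- sweep(Y, 2, rep(target_sd, 3), `*`)
  Y <- sweep(Y, 2, mu, `+`)
  out <- array(pmin(pmax(round(Y), clip[1]), clip[2]), d)
  storage.mode(out) <- "integer"
  new_enhanced(out, "DCS", band_map,
               stretch_params = list(means = mu, eig = e,
                                     target_sd = target_sd,
                                     pre_clip = Y))
}

#' Mean inter-class color separation of an enhanced scene
#'
#' Averages pixel colors per object class over the scene's material map and
#' returns the mean pairwise Euclidean distance between class colors - a
#' scalar measure of how far apart the classes sit in RGB space.
#'
#' @param pixels H x W x 3 image.
#' @param material_map matching material-code matrix.
#' @return Mean pairwise distance between per-class mean colors.
#' @export
class_color_separation <- function(pixels, material_map) {
  X <- matrix(as.numeric(pixels), length(material_map), 3)
  classes <- intersect(2:4, unique(as.integer(material_map)))
  centers <- t(sapply(classes, function(m)
    colMeans(X[material_map == m, , drop = FALSE])))
  if (length(classes) < 2) return(0)
  mean(stats::dist(centers))
}
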
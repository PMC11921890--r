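# Synthetic hyperspectral belt scenes: conveyor-belt background, stacked
# tobacco leaves, and three NTRM classes (weed, rubber ring, feather) with
# material reflectance templates qualitatively shaped like field ROI curves.

MATERIAL_NAMES <- c("belt", "tobacco", "weed", "rubber_ring", "feather")

spline_curve <- function(anchors_x, anchors_y,
                         grid = DEFAULT_WAVELENGTHS) {
  stats::spline(anchors_x, anchors_y, xout = grid, method = "natural")$y
}

#' Build the material reflectance template bank
#'
#' Five smooth reflectance templates on the default 400-900 nm grid:
#' a dark flat conveyor belt, cured tobacco leaf (green peak near 550 nm,
#' chlorophyll trough near 680 nm, red-edge rise to an NIR plateau), weed
#' (shares the red edge but with a weaker 550 nm peak and a higher NIR
#' plateau), a spectrally flat rubber ring, and a bright feather. Templates
#' are hand-designed shapes, not fits to any measured cultivar; only their
#' ordering/shape properties are contractual.
#'
#' @param seed unused placeholder for interface stability; the bank is
#'   deterministic.
#' @return A list of `material_spectrum` objects with fields `name`,
#'   `curve` (length-101 reflectance) and `jitter_sd`.
#' @export
make_spectra_bank <- function(seed = 0L) {
  mk <- function(name, x, y, jitter_sd) {
    curve <- pmin(pmax(spline_curve(x, y), 0), 1)
    structure(list(name = name, curve = curve, jitter_sd = jitter_sd),
              class = "material_spectrum")
  }
  list(
    belt = mk("belt",
              c(400, 500, 600, 700, 800, 900),
              c(0.080, 0.072, 0.064, 0.056, 0.048, 0.040), 0.02),
    tobacco = mk("tobacco",
                 c(400, 450, 500, 550, 600, 650, 680, 700, 720, 750,
                   800, 850, 900),
                 c(0.08, 0.10, 0.18, 0.35, 0.22, 0.16, 0.14, 0.22, 0.35,
                   0.47, 0.50, 0.51, 0.51), 0.03),
    weed = mk("weed",
              c(400, 450, 500, 550, 600, 650, 680, 700, 720, 750,
                800, 850, 900),
              c(0.05, 0.06, 0.10, 0.18, 0.10, 0.07, 0.06, 0.15, 0.32,
                0.55, 0.62, 0.64, 0.64), 0.03),
    rubber_ring = mk("rubber_ring",
                     c(400, 550, 700, 900),
                     c(0.195, 0.205, 0.215, 0.225), 0.02),
    feather = mk("feather",
                 c(400, 450, 500, 550, 600, 700, 800, 900),
                 c(0.45, 0.55, 0.62, 0.66, 0.69, 0.72, 0.74, 0.75), 0.03))
}

#' Scene generation configuration
#'
#' @param height,width scene size in pixels.
#' @param n_leaves number of tobacco-leaf blobs composited over the belt.
#' @param n_ntrms_per_class integer triple: counts of (weed, rubber ring,
#'   feather) objects to place.
#' @param occlusion_prob probability that a placed NTRM is partially
#'   occluded by an extra leaf painted over it (boxes stay tight to the
#'   pre-occlusion extent).
#' @param blur_px horizontal motion-blur kernel length in pixels (1 = off),
#'   emulating belt transport during exposure.
#' @param seed RNG seed; output is bitwise-reproducible for a fixed
#'   configuration.
#' @param ntrm_frac NTRM characteristic radius as a fraction of the shorter
#'   scene side (range sampled uniformly).
#' @param gain_range global illumination gain range (light-source intensity
#'   variation).
#' @param spectral if `FALSE`, skip the cube and paint the RGB render
#'   directly from per-material colors (cheap annotation-only scenes).
#' @return A `scene_config` list.
#' @export
scene_config <- function(height = 640, width = 640, n_leaves = 30,
                         n_ntrms_per_class = c(1, 1, 1),
                         occlusion_prob = 0.3, blur_px = 1, seed = 1L,
                         ntrm_frac = c(0.05, 0.14),
                         gain_range = c(0.7, 1.3), spectral = TRUE) {
  stopifnot(height >= 16, width >= 16, length(n_ntrms_per_class) == 3,
            occlusion_prob >= 0, occlusion_prob <= 1, blur_px >= 1)
  structure(list(height = height, width = width, n_leaves = n_leaves,
                 n_ntrms_per_class = as.integer(n_ntrms_per_class),
                 occlusion_prob = occlusion_prob, blur_px = blur_px,
                 seed = as.integer(seed), ntrm_frac = ntrm_frac,
                 gain_range = gain_range, spectral = spectral),
            class = "scene_config")
}

# Pixel indices (into an H x W matrix) covered by a rotated ellipse.
ellipse_px <- function(H, W, cy, cx, a, b, theta) {
  ys <- max(1, floor(cy - a - b)):min(H, ceiling(cy + a + b))
  xs <- max(1, floor(cx - a - b)):min(W, ceiling(cx + a + b))
  yy <- matrix(ys, length(ys), length(xs))
  xx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  u <- (xx - cx) * cos(theta) + (yy - cy) * sin(theta)
  v <- -(xx - cx) * sin(theta) + (yy - cy) * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  (xs[col(inside)[inside]] - 1L) * H + ys[row(inside)[inside]]
}

# Mask (pixel indices) for one NTRM object centered at (cy, cx).
ntrm_px <- function(class_id, H, W, cy, cx, r) {
  if (class_id == 0L) {            # weed: clump of overlapping blobs
    px <- integer(0)
    for (k in 1:3) {
      dy <- stats::runif(1, -0.5, 0.5) * r; dx <- stats::runif(1, -0.5, 0.5) * r
      px <- c(px, ellipse_px(H, W, cy + dy, cx + dx,
                             stats::runif(1, 0.5, 0.9) * r,
                             stats::runif(1, 0.35, 0.7) * r,
                             stats::runif(1, 0, pi)))
    }
    unique(px)
  } else if (class_id == 1L) {     # rubber ring: annulus
    th <- stats::runif(1, 0, pi)
    sq <- stats::runif(1, 0.75, 1)
    outer_px <- ellipse_px(H, W, cy, cx, r, sq * r, th)
    inner_px <- ellipse_px(H, W, cy, cx, 0.55 * r, sq * 0.55 * r, th)
    setdiff(outer_px, inner_px)
  } else {                         # feather: elongated thin ellipse
    th <- stats::runif(1, 0, pi)
    ellipse_px(H, W, cy, cx, 1.6 * r, stats::runif(1, 0.22, 0.35) * r, th)
  }
}

bbox_from_px <- function(px, H, W) {
  ys <- ((px - 1L) %% H) + 1L
  xs <- ((px - 1L) %/% H) + 1L
  # tight box in normalized center format (pixel centers at i - 0.5)
  x0 <- min(xs) - 1L; x1 <- max(xs); y0 <- min(ys) - 1L; y1 <- max(ys)
  data.frame(cx = (x0 + x1) / 2 / W, cy = (y0 + y1) / 2 / H,
             w = (x1 - x0) / W, h = (y1 - y0) / H)
}

# Approximate sRGB display colors per material for annotation-only scenes.
MATERIAL_RGB <- rbind(belt = c(40, 40, 45), tobacco = c(180, 150, 60),
                      weed = c(70, 130, 50), rubber_ring = c(60, 60, 60),
                      feather = c(220, 215, 200))

#' Render one synthetic annotated belt scene
#'
#' Composites elliptical tobacco-leaf blobs, weed clumps, ring annuli and
#' elongated feather shapes over a dark belt background. Each pixel receives
#' its material's template spectrum under per-pixel gain and per-band
#' multiplicative jitter, a global illumination gain, and optional
#' horizontal motion blur. The RGB render maps the bands nearest
#' 650/550/450 nm to R/G/B. Bounding boxes are tight to the object mask
#' before any occlusion.
#'
#' @param cfg a [scene_config()].
#' @param bank a spectra bank from [make_spectra_bank()].
#' @return An [annotated_scene()] carrying the cube (unless
#'   `cfg$spectral = FALSE`), RGB render, boxes, material map and a list of
#'   per-object masks in `$objects`.
#' @export
render_scene <- function(cfg, bank = make_spectra_bank()) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed)
  H <- cfg$height; W <- cfg$width
  mat <- matrix(0L, H, W)
  rmin <- cfg$ntrm_frac[1] * min(H, W); rmax <- cfg$ntrm_frac[2] * min(H, W)

  for (i in seq_len(cfg$n_leaves)) {
    a <- stats::runif(1, 0.08, 0.22) * min(H, W)
    px <- ellipse_px(H, W, stats::runif(1, 1, H), stats::runif(1, 1, W),
                     a, stats::runif(1, 0.45, 0.95) * a, stats::runif(1, 0, pi))
    mat[px] <- 1L
  }

  objects <- list(); ntrm_mask <- rep(FALSE, H * W)
  for (cls in 0:2) {
    for (j in seq_len(cfg$n_ntrms_per_class[cls + 1])) {
      placed <- FALSE
      for (try in 1:100) {
        r <- stats::runif(1, rmin, rmax)
        margin <- 1.7 * r + 2   # covers the longest object extent (feather)
        if (H - margin <= margin || W - margin <= margin) next
        cy <- stats::runif(1, margin, H - margin)
        cx <- stats::runif(1, margin, W - margin)
        px <- ntrm_px(cls, H, W, cy, cx, r)
        if (length(px) < 9 || any(ntrm_mask[px])) next
        ntrm_mask[px] <- TRUE
        mat[px] <- cls + 2L
        objects[[length(objects) + 1]] <-
          list(class_id = cls, px = px, bbox = bbox_from_px(px, H, W))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("scene too small to place requested objects ",
             "(100 rejection-sampling attempts exhausted)")
    }
  }

  # Partial occlusion: paint an extra leaf over part of an NTRM. Ground-truth
  # boxes are computed from the pre-occlusion masks and are never removed.
  for (ob in objects) {
    if (stats::runif(1) < cfg$occlusion_prob) {
      b <- ob$bbox
      ecy <- (b$cy + (b$h / 2) * stats::runif(1, -1, 1)) * H
      ecx <- (b$cx + (b$w / 2) * stats::runif(1, -1, 1)) * W
      a <- stats::runif(1, 0.4, 0.8) * max(b$w * W, b$h * H)
      px <- ellipse_px(H, W, ecy, ecx, a, stats::runif(1, 0.5, 1) * a,
                       stats::runif(1, 0, pi))
      mat[px] <- 1L
    }
  }

  boxes <- do.call(rbind, lapply(objects, function(o)
    cbind(data.frame(class_id = o$class_id), o$bbox)))
  if (is.null(boxes)) boxes <- empty_boxes()

  gain <- stats::runif(1, cfg$gain_range[1], cfg$gain_range[2])
  px_gain <- matrix(pmax(stats::rnorm(H * W, 1, 0.08), 0.5), H, W)

  cube <- NULL
  if (cfg$spectral) {
    B <- length(DEFAULT_WAVELENGTHS)
    x <- array(0, c(H, W, B))
    for (m in 0:4) {
      idx <- which(mat == m)
      if (!length(idx)) next
      tmpl <- bank[[m + 1]]$curve
      jit <- matrix(stats::rnorm(length(idx) * B, 1, bank[[m + 1]]$jitter_sd),
                    length(idx), B)
      vals <- (px_gain[idx] %o% tmpl) * jit * gain
      for (b in seq_len(B)) x[idx + (b - 1) * H * W] <- vals[, b]
    }
    x <- pmin(pmax(x, 0), 1.49)
    if (cfg$blur_px > 1) x <- blur_horiz(x, cfg$blur_px)
    cube <- spectral_cube(x, DEFAULT_WAVELENGTHS)
    rgb <- render_rgb(cube)
  } else {
    rgb <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      plane <- MATERIAL_RGB[mat + 1L, ch] * px_gain * gain
      rgb[, , ch] <- matrix(plane, H, W)
    }
    rgb <- pmin(pmax(round(rgb), 0), 255)
  }

  sc <- annotated_scene(rgb = rgb, boxes = boxes, cube = cube,
                        split = "train", id = cfg$seed, material_map = mat)
  sc$objects <- objects
  sc
}

# Horizontal moving-average blur applied per band (motion along the belt).
blur_horiz <- function(x, k) {
  d <- dim(x); half <- (k - 1) %/% 2
  for (b in seq_len(d[3])) {
    plane <- x[, , b]
    cs <- cbind(0, t(apply(plane, 1, cumsum)))
    lo <- pmax(seq_len(d[2]) - half - 1, 0)
    hi <- pmin(seq_len(d[2]) + half, d[2])
    x[, , b] <- (cs[, hi + 1] - cs[, lo + 1]) / (hi - lo)
  }
  x
}

#' Render an 8-bit RGB image from a cube
#'
#' Maps the bands nearest 650/550/450 nm to R/G/B, each min-max scaled.
#'
#' @param cube a [spectral_cube()].
#' @return H x W x 3 array with values 0..255.
#' @export
render_rgb <- function(cube) {
  d <- dim(cube$data)
  rgb <- array(0, c(d[1], d[2], 3))
  for (i in 1:3)
    rgb[, , i] <- band_slice(cube, c(650, 550, 450)[i], as_8bit = TRUE)
  rgb
}

# Largest-remainder allocation of n items to the given proportions.
largest_remainder <- function(n, props) {
  props <- props / sum(props)
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Table-3-shaped default class mix (training-set proportions).
DEFAULT_CLASS_MIX <- c(weed = 2697, rubber_ring = 1944, feather = 2898) / 7539

#' Generate a split synthetic dataset
#'
#' Scenes are assigned to train/val/test in a 6:2:2 ratio by largest
#' remainder. Per-class object totals follow `class_mix` by largest
#' remainder (so realized proportions are within rounding of the request)
#' and are spread as evenly as possible across scenes; when `total_boxes`
#' is given the dataset contains exactly that many boxes.
#'
#' @param n_scenes number of scenes (at least 5).
#' @param class_mix proportions for (weed, rubber ring, feather).
#' @param seed integer seed controlling every scene.
#' @param total_boxes exact total object count; default
#'   `round(4.203 * n_scenes)`, the field average of 4.2 NTRMs per scene.
#' @param size scene side length in pixels.
#' @param ... further arguments passed to [scene_config()].
#' @return List of [annotated_scene()] objects with `$split` set.
#' @export
make_dataset <- function(n_scenes, class_mix = DEFAULT_CLASS_MIX,
                         seed = 1L, total_boxes = round(4.203 * n_scenes),
                         size = 64, ...) {
  stopifnot(n_scenes >= 5)
  split_sizes <- largest_remainder(n_scenes, c(6, 2, 2))
  splits <- rep(c("train", "val", "test"), times = split_sizes)
  per_class <- largest_remainder(total_boxes, class_mix)
  # spread each class across scenes as evenly as possible
  counts <- matrix(0L, n_scenes, 3)
  for (k in 1:3) {
    base <- per_class[k] %/% n_scenes
    extra <- per_class[k] %% n_scenes
    counts[, k] <- base + (seq_len(n_scenes) <= extra)
  }
  scenes <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    # a crowded draw can fail placement; retry deterministically with a
    # bumped seed so the dataset contract (exact counts) still holds
    sc <- NULL
    for (retry in 0:5) {
      cfg <- scene_config(height = size, width = size,
                          n_ntrms_per_class = counts[i, ],
                          seed = (seed * 10007L + i + retry * 7919L) %%
                            .Machine$integer.max, ...)
      sc <- tryCatch(render_scene(cfg), error = function(e) NULL)
      if (!is.null(sc)) break
    }
    if (is.null(sc))
      stop("scene ", i, " could not be placed after 6 seeds; ",
           "reduce object counts or sizes")
    sc$split <- splits[i]
    sc$id <- i
    scenes[[i]] <- sc
  }
  scenes
}

#' Spectral angle between two spectra
#'
#' @param a,b reflectance vectors.
#' @return Angle in radians.
#' @export
spectral_angle <- function(a, b) {
  acos(pmin(pmax(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), -1), 1))
}

#' Classify object mean spectra against the template bank
#'
#' For every object in a scene, computes its ROI mean spectrum over the
#' object mask and assigns the nearest template by spectral angle.
#'
#' @param scene an [annotated_scene()] with a cube and `$objects`.
#' @param bank spectra bank.
#' @return Data frame with `class_id` (truth) and `assigned` (0 weed,
#'   1 rubber ring, 2 feather, or -1 for a non-NTRM template).
#' @export
classify_objects <- function(scene, bank = make_spectra_bank()) {
  stopifnot(!is.null(scene$cube))
  H <- dim(scene$cube$data)[1]; W <- dim(scene$cube$data)[2]
  B <- dim(scene$cube$data)[3]
  flat <- matrix(scene$cube$data, H * W, B)
  tmpl <- sapply(bank, function(m) m$curve)
  rows <- lapply(scene$objects, function(o) {
    # restrict to pixels still visible (not painted over by occlusion)
    vis <- o$px[scene$material_map[o$px] == o$class_id + 2L]
    if (length(vis) < 4) vis <- o$px
    mu <- colMeans(flat[vis, , drop = FALSE])
    ang <- apply(tmpl, 2, spectral_angle, a = mu)
    best <- which.min(ang)  # 1 belt, 2 tobacco, 3 weed, 4 ring, 5 feather
    data.frame(class_id = o$class_id, assigned = best - 3L)
  })
  do.call(rbind, rows)
}
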
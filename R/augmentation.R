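# Tobacco-3000 style dataset construction: clockwise rotations,
# background-occlusion overlay, and per-scene assembly of the original with
# two augmented variants, applied after the train/val/test split.

rot90cw_mat <- function(m) t(m[nrow(m):1, , drop = FALSE])

rot_mat <- function(m, angle) {
  switch(as.character(angle),
         "90" = rot90cw_mat(m),
         "180" = rot90cw_mat(rot90cw_mat(m)),
         "270" = rot90cw_mat(rot90cw_mat(rot90cw_mat(m))),
         stop("rotation angle must be 90, 180 or 270 degrees"))
}

rot_planes <- function(x, angle) {
  if (is.null(x)) return(NULL)
  d <- dim(x)
  planes <- lapply(seq_len(d[3]), function(i) rot_mat(x[, , i], angle))
  out <- array(0, c(dim(planes[[1]]), d[3]))
  for (i in seq_len(d[3])) out[, , i] <- planes[[i]]
  if (is.integer(x)) storage.mode(out) <- "integer"
  out
}

rotate_boxes <- function(boxes, angle) {
  if (!nrow(boxes)) return(boxes)
  with(boxes, switch(as.character(angle),
    "90" = data.frame(class_id = class_id, cx = 1 - cy, cy = cx,
                      w = h, h = w),
    "180" = data.frame(class_id = class_id, cx = 1 - cx, cy = 1 - cy,
                       w = w, h = h),
    "270" = data.frame(class_id = class_id, cx = cy, cy = 1 - cx,
                       w = h, h = w),
    stop("rotation angle must be 90, 180 or 270 degrees")))
}

#' Rotate an annotated scene clockwise
#'
#' Rotates every image plane (RGB, DCS, cube bands, material map) by 90,
#' 180 or 270 degrees clockwise and maps the normalized boxes accordingly:
#' 90 deg CW sends (cx, cy, w, h) to (1-cy, cx, h, w), 180 deg to
#' (1-cx, 1-cy, w, h), 270 deg to (cy, 1-cx, h, w).
#'
#' @param scene an [annotated_scene()].
#' @param angle 90, 180 or 270 (degrees clockwise).
#' @return The rotated scene.
#' @export
rotate_scene <- function(scene, angle) {
  if (!angle %in% c(90, 180, 270))
    stop("rotation angle must be 90, 180 or 270 degrees")
  out <- scene
  out$rgb <- rot_planes(scene$rgb, angle)
  out$dcs <- rot_planes(scene$dcs, angle)
  if (!is.null(scene$material_map))
    out$material_map <- rot_mat(scene$material_map, angle)
  if (!is.null(scene$cube))
    out$cube <- spectral_cube(rot_planes(scene$cube$data, angle),
                              scene$cube$wavelengths)
  out$boxes <- rotate_boxes(scene$boxes, angle)
  out$objects <- NULL  # pixel masks are not carried through rotation
  out
}

rect_intersection <- function(ax0, ay0, ax1, ay1, bx0, by0, bx1, by1) {
  w <- pmin(ax1, bx1) - pmax(ax0, bx0)
  h <- pmin(ay1, by1) - pmax(ay0, by0)
  pmax(w, 0) * pmax(h, 0)
}

boxes_xyxy <- function(boxes) {
  cbind(x0 = boxes$cx - boxes$w / 2, y0 = boxes$cy - boxes$h / 2,
        x1 = boxes$cx + boxes$w / 2, y1 = boxes$cy + boxes$h / 2)
}

#' Overlay a background patch over part of an NTRM
#'
#' Cuts a rectangular patch from a box-free region (found by rejection
#' sampling, at most 200 tries) and pastes it over a random sub-rectangle
#' covering 20-60% of a randomly chosen box. Boxes whose visible fraction
#' drops below `keep_fraction_threshold` are dropped; all others keep their
#' coordinates unchanged, so the model trains against partially invisible
#' targets.
#'
#' @param scene an [annotated_scene()] with at least one box.
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @param keep_fraction_threshold minimum visible fraction for a box to
#'   keep its annotation.
#' @return The modified scene; if no box-free source region is found the
#'   scene is returned unmodified with a warning.
#' @export
occlusion_overlay <- function(scene, seed = 1L,
                              keep_fraction_threshold = 0.3) {
  if (!nrow(scene$boxes)) stop("scene has no boxes to occlude")
  set.seed(seed)
  H <- dim(scene$rgb)[1]; W <- dim(scene$rgb)[2]
  bx <- boxes_xyxy(scene$boxes)
  target <- sample.int(nrow(scene$boxes), 1)
  b <- scene$boxes[target, ]
  f <- stats::runif(1, 0.2, 0.6)
  pw <- b$w * sqrt(f); ph <- b$h * sqrt(f)
  px0 <- b$cx - b$w / 2 + stats::runif(1, 0, b$w - pw)
  py0 <- b$cy - b$h / 2 + stats::runif(1, 0, b$h - ph)
  # integer pixel rect of the paste destination
  dx <- max(1L, 1L + floor(px0 * W)); dy <- max(1L, 1L + floor(py0 * H))
  pwp <- max(1L, round(pw * W)); php <- max(1L, round(ph * H))
  dx1 <- min(W, dx + pwp - 1L); dy1 <- min(H, dy + php - 1L)
  pwp <- dx1 - dx + 1L; php <- dy1 - dy + 1L

  src <- NULL
  for (try in 1:200) {
    sx <- sample.int(W - pwp + 1L, 1); sy <- sample.int(H - php + 1L, 1)
    r <- c((sx - 1) / W, (sy - 1) / H, (sx - 1 + pwp) / W, (sy - 1 + php) / H)
    inter <- rect_intersection(r[1], r[2], r[3], r[4],
                               bx[, 1], bx[, 2], bx[, 3], bx[, 4])
    if (all(inter == 0)) { src <- c(sx, sy); break }
  }
  if (is.null(src)) {
    warning("no box-free source region found; scene returned unmodified")
    return(scene)
  }

  paste_rect <- function(img) {
    if (is.null(img)) return(NULL)
    img[dy:dy1, dx:dx1, ] <-
      img[src[2]:(src[2] + php - 1L), src[1]:(src[1] + pwp - 1L), ]
    img
  }
  scene$rgb <- paste_rect(scene$rgb)
  scene$dcs <- paste_rect(scene$dcs)

  pr <- c((dx - 1) / W, (dy - 1) / H, dx1 / W, dy1 / H)
  covered <- rect_intersection(pr[1], pr[2], pr[3], pr[4],
                               bx[, 1], bx[, 2], bx[, 3], bx[, 4])
  visible <- 1 - covered / (scene$boxes$w * scene$boxes$h)
  scene$boxes <- scene$boxes[visible >= keep_fraction_threshold, ,
                             drop = FALSE]
  scene$overlay_rect <- pr
  scene
}

#' Augmentation plan
#'
#' @param rotations subset of c(90, 180, 270) degrees clockwise.
#' @param pick number of rotated variants joined with each original.
#' @param overlay whether to additionally apply the background-occlusion
#'   overlay to augmented variants.
#' @param overlay_prob per-variant probability of the overlay when
#'   `overlay` is `TRUE`.
#' @param keep_fraction_threshold see [occlusion_overlay()].
#' @param seed plan seed; the same rotation choices are drawn for a given
#'   (seed, scene id), so paired RGB/PCC/DCS variants of one scene receive
#'   identical augmentation.
#' @return An `augmentation_plan` list.
#' @export
augmentation_plan <- function(rotations = c(90, 180, 270), pick = 2L,
                              overlay = FALSE, overlay_prob = 0.5,
                              keep_fraction_threshold = 0.3, seed = 0L) {
  stopifnot(all(rotations %in% c(90, 180, 270)), pick <= length(rotations))
  structure(list(rotations = rotations, pick = as.integer(pick),
                 overlay = overlay, overlay_prob = overlay_prob,
                 keep_fraction_threshold = keep_fraction_threshold,
                 seed = as.integer(seed)), class = "augmentation_plan")
}

#' Build a Tobacco-3000 style augmented dataset
#'
#' Each scene yields itself plus `pick` rotated variants (rotations drawn
#' per scene from the plan seed). Augmentation runs after the split and
#' within it, so no variant of a test scene can reach the training set.
#' With `pick = 2` and the overlay disabled, image and box counts triple
#' exactly.
#'
#' @param scenes list of split [annotated_scene()] objects.
#' @param plan an [augmentation_plan()].
#' @return List of scenes; each carries `$provenance` with the source
#'   scene id, rotation and overlay indicator.
#' @export
build_tobacco3000 <- function(scenes, plan = augmentation_plan()) {
  out <- vector("list", 0)
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    sc$provenance <- list(source_id = sc$id, rotation = 0L, overlay = FALSE)
    out[[length(out) + 1]] <- sc
    scene_seed <- (plan$seed * 131071L + i) %% .Machine$integer.max
    set.seed(scene_seed)
    rots <- sample(plan$rotations, plan$pick)
    do_overlay <- plan$overlay &
      (stats::runif(plan$pick) < plan$overlay_prob) & nrow(sc$boxes) > 0
    for (j in seq_len(plan$pick)) {
      v <- rotate_scene(sc, rots[j])
      if (do_overlay[j])
        v <- occlusion_overlay(v, seed = scene_seed + j,
                               keep_fraction_threshold =
                                 plan$keep_fraction_threshold)
      v$id <- paste0(sc$id, "_r", rots[j], if (do_overlay[j]) "_ov" else "")
      v$provenance <- list(source_id = sc$id, rotation = rots[j],
                           overlay = isTRUE(do_overlay[j]))
      out[[length(out) + 1]] <- v
    }
  }
  out
}

#' Count scenes and boxes per split
#'
#' @param scenes list of annotated scenes.
#' @return Data frame with one row per split plus a `total` row.
#' @export
dataset_counts <- function(scenes) {
  splits <- vapply(scenes, `[[`, "", "split")
  nbox <- vapply(scenes, function(s) nrow(s$boxes), 0L)
  agg <- data.frame(split = c("train", "val", "test"))
  agg$scenes <- vapply(agg$split, function(s) sum(splits == s), 0L)
  agg$boxes <- vapply(agg$split, function(s) sum(nbox[splits == s]), 0L)
  rbind(agg, data.frame(split = "total", scenes = length(scenes),
                        boxes = sum(nbox)))
}
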
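test_that("rotation maps boxes by the exact coordinate formulas", {
  b <- data.frame(class_id = 0L, cx = 0.25, cy = 0.5, w = 0.2, h = 0.1)
  r90 <- dbytk:::rotate_boxes(b, 90)
  expect_equal(unlist(r90[1, 2:5], use.names = FALSE), c(0.5, 0.25, 0.1, 0.2))
  r180 <- dbytk:::rotate_boxes(b, 180)
  expect_equal(unlist(r180[1, 2:5], use.names = FALSE),
               c(0.75, 0.5, 0.2, 0.1))
  r270 <- dbytk:::rotate_boxes(b, 270)
  expect_equal(unlist(r270[1, 2:5], use.names = FALSE),
               c(0.5, 0.75, 0.1, 0.2))
  # a centered box is a fixed point of the 180-degree rotation
  ctr <- data.frame(class_id = 1L, cx = 0.5, cy = 0.5, w = 0.3, h = 0.12)
  expect_equal(dbytk:::rotate_boxes(ctr, 180), ctr)
})

test_that("four 90-degree rotations return the original scene", {
  sc <- fixture_scenes()[[2]]
  r <- sc
  for (i in 1:4) r <- rotate_scene(r, 90)
  expect_equal(r$rgb, sc$rgb)
  expect_equal(r$cube$data, sc$cube$data)
  expect_equal(r$material_map, sc$material_map)
  expect_equal(as.matrix(r$boxes), as.matrix(sc$boxes), tolerance = 1e-12)
  # 90 twice equals 180
  expect_equal(rotate_scene(rotate_scene(sc, 90), 90)$rgb,
               rotate_scene(sc, 180)$rgb)
  expect_error(rotate_scene(sc, 45), "90, 180 or 270")
})

test_that("rotated pixels follow their boxes", {
  sc <- fixture_scenes()[[1]]
  r <- rotate_scene(sc, 90)
  H <- dim(r$material_map)[1]; W <- dim(r$material_map)[2]
  for (i in seq_len(nrow(r$boxes))) {
    b <- r$boxes[i, ]
    ys <- max(1, ceiling((b$cy - b$h / 2) * H)):min(H, floor((b$cy + b$h / 2) * H))
    xs <- max(1, ceiling((b$cx - b$w / 2) * W)):min(W, floor((b$cx + b$w / 2) * W))
    # the box region contains pixels of the box's material
    expect_true(any(r$material_map[ys, xs] == b$class_id + 2))
  }
})

test_that("occlusion overlay drops boxes only below the visibility threshold", {
  sc <- fixture_scenes()[[1]]
  n0 <- nrow(sc$boxes)
  out <- occlusion_overlay(sc, seed = 3)
  # patch covers 20-60% of one box; with threshold 0.3 nothing is dropped
  expect_equal(nrow(out$boxes), n0)
  expect_equal(out$boxes, sc$boxes[rownames(out$boxes), ])
  # a threshold above the guaranteed visible fraction drops the target box
  out2 <- occlusion_overlay(sc, seed = 3, keep_fraction_threshold = 0.95)
  expect_lt(nrow(out2$boxes), n0)
  # determinism
  expect_identical(occlusion_overlay(sc, seed = 3)$rgb, out$rgb)
  expect_error(occlusion_overlay(
    annotated_scene(rgb = array(0, c(8, 8, 3)), boxes = dbytk:::empty_boxes()),
    seed = 1), "no boxes")
})

test_that("augmented datasets triple counts and preserve splits", {
  set.seed(12)
  scenes <- make_dataset(10, seed = 3, size = 32, spectral = FALSE,
                         total_boxes = 7, n_leaves = 2,
                         ntrm_frac = c(0.1, 0.16))
  expect_equal(sum(vapply(scenes, function(s) nrow(s$boxes), 0L)), 7)
  aug <- build_tobacco3000(scenes, augmentation_plan(pick = 2, seed = 9))
  expect_length(aug, 30)
  expect_equal(sum(vapply(aug, function(s) nrow(s$boxes), 0L)), 21)
  counts <- dataset_counts(aug)
  expect_equal(counts$scenes[1:3], c(18, 6, 6))

  # per-class proportions are invariant under rotation-only augmentation
  cls0 <- table(factor(unlist(lapply(scenes, function(s) s$boxes$class_id)),
                       0:2))
  cls1 <- table(factor(unlist(lapply(aug, function(s) s$boxes$class_id)),
                       0:2))
  expect_equal(as.numeric(cls1), 3 * as.numeric(cls0))

  # provenance: no augmented variant crosses its source's split
  for (s in aug) {
    src <- Filter(function(z) identical(z$id, s$provenance$source_id),
                  scenes)[[1]]
    expect_identical(s$split, src$split)
  }

  # identical plan seed reproduces identical augmentation
  aug2 <- build_tobacco3000(scenes, augmentation_plan(pick = 2, seed = 9))
  expect_identical(lapply(aug, `[[`, "rgb"), lapply(aug2, `[[`, "rgb"))
  expect_identical(lapply(aug, `[[`, "boxes"), lapply(aug2, `[[`, "boxes"))
})
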
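test_that("spectra bank satisfies the shape and ordering constraints", {
  bank <- make_spectra_bank()
  wl <- seq(400, 900, by = 5)
  expect_named(bank, c("belt", "tobacco", "weed", "rubber_ring", "feather"))
  for (m in bank) {
    expect_true(all(m$curve >= 0 & m$curve <= 1))
    expect_lt(max(abs(diff(m$curve))), 0.05)  # smoothness
  }
  expect_true(all(bank$belt$curve < 0.1))
  tob <- bank$tobacco$curve
  # green peak near 550 nm and an NIR plateau
  expect_equal(wl[which.max(tob[wl < 650])], 550)
  expect_true(all(tob[wl > 750] >= 0.4))
  expect_lt(sd(bank$rubber_ring$curve), 0.03)
  # red-edge rise shared by tobacco and weed
  red_edge <- function(x) x[wl == 750] - x[wl == 680]
  expect_gt(red_edge(tob), 0.1)
  expect_gt(red_edge(bank$weed$curve), 0.1)
  # tobacco and weed differ at the green peak and the NIR plateau
  expect_gt(abs(tob[wl == 550] - bank$weed$curve[wl == 550]), 0.05)
  expect_gt(abs(mean(tob[wl > 750]) - mean(bank$weed$curve[wl > 750])), 0.05)
  # tobacco-NTRM contrast concentrates in 550-850 nm rather than 455-545 nm
  vis <- wl >= 455 & wl <= 545; nir <- wl >= 550 & wl <= 850
  hits <- vapply(c("weed", "rubber_ring", "feather"), function(nm) {
    d <- abs(tob - bank[[nm]]$curve)
    mean(d[nir]) > mean(d[vis])
  }, TRUE)
  expect_gte(sum(hits), 2)
})

test_that("rendered scenes are deterministic with consistent annotations", {
  cfg <- scene_config(height = 96, width = 96, n_leaves = 8, seed = 7)
  sc <- render_scene(cfg)
  sc2 <- render_scene(cfg)
  expect_identical(sc$cube$data, sc2$cube$data)
  expect_identical(sc$boxes, sc2$boxes)
  expect_identical(sc$rgb, sc2$rgb)

  expect_equal(nrow(sc$boxes), 3)
  expect_setequal(sc$boxes$class_id, 0:2)
  expect_silent(dbytk:::validate_boxes(sc$boxes))

  # every object mask lies inside its (tight) box
  H <- 96; W <- 96
  for (o in sc$objects) {
    ys <- ((o$px - 1) %% H) + 1; xs <- ((o$px - 1) %/% H) + 1
    b <- o$bbox
    expect_gte(min(xs) - 1, (b$cx - b$w / 2) * W - 1e-9)
    expect_lte(max(xs), (b$cx + b$w / 2) * W + 1e-9)
    expect_gte(min(ys) - 1, (b$cy - b$h / 2) * H - 1e-9)
    expect_lte(max(ys), (b$cy + b$h / 2) * H + 1e-9)
    # tightness: the box equals the mask extent
    expect_equal(b$w * W, max(xs) - min(xs) + 1)
    expect_equal(b$h * H, max(ys) - min(ys) + 1)
  }

  expect_error(
    render_scene(scene_config(height = 24, width = 24,
                              n_ntrms_per_class = c(3, 3, 3),
                              ntrm_frac = c(0.2, 0.3))),
    "scene too small")
})

test_that("object spectra are recoverable by nearest-template matching", {
  ok <- 0; tot <- 0
  for (s in 1:12) {
    sc <- render_scene(scene_config(height = 96, width = 96, n_leaves = 8,
                                    seed = s, n_ntrms_per_class = c(2, 2, 2),
                                    ntrm_frac = c(0.07, 0.14)))
    cl <- classify_objects(sc)
    ok <- ok + sum(cl$class_id == cl$assigned)
    tot <- tot + nrow(cl)
  }
  expect_gte(ok / tot, 0.95)
})

test_that("rubber-ring ROI spectra correlate with the template", {
  sc <- fixture_scenes()[[3]]
  bank <- make_spectra_bank()
  o <- Filter(function(o) o$class_id == 1, sc$objects)[[1]]
  flat <- matrix(sc$cube$data, prod(dim(sc$cube$data)[1:2]), 101)
  vis <- o$px[sc$material_map[o$px] == 3]
  mu <- colMeans(flat[vis, , drop = FALSE])
  expect_gt(cor(mu, bank$rubber_ring$curve), 0.95)
})

test_that("datasets split 6:2:2 with the requested class mix", {
  splits10 <- table(vapply(make_dataset(10, seed = 2, size = 64,
                                        spectral = FALSE), `[[`, "", "split"))
  expect_equal(unname(splits10[c("train", "val", "test")]),
               c(6, 2, 2), ignore_attr = TRUE)
  # largest remainder on the minimum size
  splits5 <- vapply(make_dataset(5, seed = 2, size = 64, spectral = FALSE),
                    `[[`, "", "split")
  expect_equal(sum(splits5 == "train"), 3)

  ds <- make_dataset(60, seed = 4, size = 32, spectral = FALSE,
                     n_leaves = 2, ntrm_frac = c(0.08, 0.15))
  cls <- unlist(lapply(ds, function(s) s$boxes$class_id))
  realized <- as.numeric(table(factor(cls, 0:2)) / length(cls))
  requested <- c(2697, 1944, 2898) / 7539
  expect_true(all(abs(realized - requested) / requested < 0.1))
  # exact box totals when requested
  expect_equal(length(cls), round(4.203 * 60))
})
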
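# Shared fixtures: scenes are expensive enough to build once and reuse.

.fixtures <- new.env()

# Small spectral scenes with a few objects per class, used by the
# band-selection and enhancement tests.
fixture_scenes <- function(n = 4, seed_base = 0, size = 96) {
  key <- paste0("scenes_", n, "_", seed_base, "_", size)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- lapply(seed_base + seq_len(n), function(s)
      render_scene(scene_config(height = size, width = size, n_leaves = 8,
                                seed = s, n_ntrms_per_class = c(1, 1, 1))))
  .fixtures[[key]]
}

# "Easy" detection scenes: large unoccluded objects, paired RGB/DCS inputs.
easy_scene <- function(seed, size = 64) {
  sc <- render_scene(scene_config(height = size, width = size, n_leaves = 5,
                                  seed = seed, occlusion_prob = 0,
                                  ntrm_frac = c(0.1, 0.17),
                                  n_ntrms_per_class = c(1, 1, 1)))
  pcc <- pseudo_color(sc$cube, c(550, 670, 850))
  sc$dcs <- decorrelation_stretch(pcc)$pixels
  sc$cube <- NULL
  sc
}

easy_scenes <- function(n = 25) {
  key <- paste0("easy_", n)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- lapply(seq_len(n), easy_scene)
  .fixtures[[key]]
}

# Desk-scale dual-branch spec used for training tests.
small_dual_spec <- function()
  model_spec(widths = c(8, 16, 32, 64, 128),
             neck_hidden = c(n3 = 36, td4 = 36, n4 = 36, n5 = 36))

random_boxes <- function(n) {
  cx <- runif(n, 0.2, 0.8); cy <- runif(n, 0.2, 0.8)
  data.frame(class_id = sample(0:2, n, replace = TRUE), cx = cx, cy = cy,
             w = pmin(runif(n, 0.05, 0.3), 2 * pmin(cx, 1 - cx)),
             h = pmin(runif(n, 0.05, 0.3), 2 * pmin(cy, 1 - cy)))
}
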
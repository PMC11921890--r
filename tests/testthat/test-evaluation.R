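mk_box <- function(class_id, x0, y0, x1, y1, score = NULL) {
  d <- data.frame(class_id = class_id, x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (!is.null(score)) d$score <- score
  d
}

test_that("greedy matching handles the canonical cases", {
  gt <- mk_box(0, 10, 10, 20, 20)
  m <- match_detections(mk_box(0, 10, 10, 20, 20, score = 0.9), gt, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 0, 0))

  # two predictions on one ground truth: one-to-one matching
  p2 <- rbind(mk_box(0, 10, 10, 20, 20, 0.9),
              mk_box(0, 11, 11, 21, 21, 0.8))
  m2 <- match_detections(p2, gt, 0.5)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(1, 1, 0))

  # class mismatch never matches
  m3 <- match_detections(mk_box(1, 10, 10, 20, 20, 0.9), gt, 0.5)
  expect_equal(c(m3$TP, m3$FP, m3$FN), c(0, 1, 1))
})

test_that("greedy matching equals a brute-force oracle on random instances", {
  oracle <- function(preds, gts, thr) {
    # plain re-derivation: walk predictions by descending score, match the
    # best remaining same-class gt by IoU
    ord <- order(-preds$score)
    used <- rep(FALSE, nrow(gts))
    tp <- 0
    for (i in ord) {
      best <- 0; bj <- 0
      for (j in seq_len(nrow(gts))) {
        if (used[j] || gts$class_id[j] != preds$class_id[i]) next
        ix <- max(0, min(preds$x1[i], gts$x1[j]) - max(preds$x0[i], gts$x0[j]))
        iy <- max(0, min(preds$y1[i], gts$y1[j]) - max(preds$y0[i], gts$y0[j]))
        ov <- ix * iy
        un <- (preds$x1[i] - preds$x0[i]) * (preds$y1[i] - preds$y0[i]) +
          (gts$x1[j] - gts$x0[j]) * (gts$y1[j] - gts$y0[j]) - ov
        v <- ov / un
        if (v >= thr && v > best) { best <- v; bj <- j }
      }
      if (bj > 0) { used[bj] <- TRUE; tp <- tp + 1 }
    }
    c(TP = tp, FP = nrow(preds) - tp, FN = nrow(gts) - sum(used))
  }
  set.seed(13)
  for (rep in 1:20) {
    ng <- sample(1:6, 1); np <- sample(1:10, 1)
    gts <- mk_box(sample(0:1, ng, TRUE), runif(ng, 0, 50), runif(ng, 0, 50),
                  runif(ng, 55, 100), runif(ng, 55, 100))
    preds <- mk_box(sample(0:1, np, TRUE), runif(np, 0, 50),
                    runif(np, 0, 50), runif(np, 55, 100),
                    runif(np, 55, 100), score = runif(np))
    m <- match_detections(preds, gts, 0.5)
    expect_identical(unname(c(m$TP, m$FP, m$FN)),
                     unname(as.integer(oracle(preds, gts, 0.5))))
  }
})

test_that("average precision matches threshold-sweep integration", {
  expect_equal(average_precision(c(0.5, 1), c(1, 1)), 1)
  expect_equal(average_precision(c(0, 0), c(0, 0)), 0)

  # 5-detection toy: flags fixed by hand
  tp <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  n_gt <- 4
  rec <- cumsum(tp) / n_gt
  pre <- cumsum(tp) / seq_along(tp)
  ap <- average_precision(rec, pre)
  # oracle: exhaustive sweep over all cutoffs of the ranked list, summing
  # precision over recall steps
  ap_sweep <- 0
  last_rec <- 0
  for (k in seq_along(tp)) {
    if (tp[k]) {
      r <- sum(tp[1:k]) / n_gt
      p_best <- max(vapply(k:length(tp), function(j)
        sum(tp[1:j]) / j, 0))
      ap_sweep <- ap_sweep + (r - last_rec) * p_best
      last_rec <- r
    }
  }
  expect_equal(ap, ap_sweep, tolerance = 1e-12)
})

test_that("mAP@50 bounds mAP@50-95 on random detection sets", {
  set.seed(14)
  for (rep in 1:5) {
    gts <- cbind(scene = sample(1:3, 8, TRUE),
                 mk_box(sample(0:2, 8, TRUE), runif(8, 0, 40),
                        runif(8, 0, 40), runif(8, 50, 100),
                        runif(8, 50, 100)))
    jitter <- function(v) v + rnorm(length(v), 0, 6)
    preds <- cbind(scene = gts$scene,
                   mk_box(gts$class_id, jitter(gts$x0), jitter(gts$y0),
                          jitter(gts$x1), jitter(gts$y1),
                          score = runif(8, 0.3, 1)))
    mp <- map_range(preds, gts)
    expect_gte(mp$map50 + 1e-12, mp$map50_95)
  }
})

test_that("F1 reproduces published precision/recall combinations", {
  expect_equal(round(f1_score(91.8, 87.6), 1), 89.7)
  expect_equal(round(f1_score(88, 82.9), 1), 85.4)
  expect_equal(f1_score(70, 70), 70)     # symmetry fixed point
  expect_equal(f1_score(0, 0), 0)        # degenerate case
})

test_that("FPS harness validates arguments and reports its context", {
  sp <- model_spec(branches = "rgb", widths = c(6, 12, 12, 24, 48))
  m <- build_model(sp, seed = 1)
  expect_error(measure_fps(m, 64, n_warmup = 0, n_timed = 0), "positive")
  r <- measure_fps(m, 64, n_warmup = 1, n_timed = 2)
  expect_true(r$fps > 0)
  expect_equal(r$input_size, 64)
  expect_equal(r$batch, 1)
  expect_true(nzchar(r$hardware))
})
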
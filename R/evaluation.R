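# Detection metrics: greedy IoU matching, all-points interpolated average
# precision, mAP over IoU thresholds, F1, an FPS harness, and the
# end-to-end pipeline driver.

#' Match detections to ground truths
#'
#' Predictions (sorted by descending confidence) are matched greedily,
#' one-to-one, to the highest-IoU unmatched same-class ground truth with
#' IoU at or above the threshold. Unmatched predictions are false
#' positives, unmatched ground truths false negatives.
#'
#' @param preds data frame with `class_id`, `score`, `x0, y0, x1, y1`.
#' @param gts data frame with `class_id`, `x0, y0, x1, y1`.
#' @param iou_thr matching IoU threshold.
#' @return List with logical `tp` per prediction (in descending-score
#'   order), the permutation `order` used, and counts `TP`, `FP`, `FN`.
#' @export
match_detections <- function(preds, gts, iou_thr = 0.5) {
  ord <- order(preds$score, decreasing = TRUE)
  preds <- preds[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(gts))
  tp <- logical(nrow(preds))
  if (nrow(preds) && nrow(gts)) {
    iou <- iou_matrix(as.matrix(preds[, c("x0", "y0", "x1", "y1")]),
                      as.matrix(gts[, c("x0", "y0", "x1", "y1")]))
    for (i in seq_len(nrow(preds))) {
      cand <- which(!used & gts$class_id == preds$class_id[i] &
                    iou[i, ] >= iou_thr)
      if (length(cand)) {
        j <- cand[which.max(iou[i, cand])]
        used[j] <- TRUE
        tp[i] <- TRUE
      }
    }
  }
  list(tp = tp, order = ord, TP = sum(tp), FP = sum(!tp),
       FN = sum(!used))
}

#' Area under the monotone interpolated precision-recall curve
#'
#' All-points interpolation: precision is replaced by its running maximum
#' from the right, and the area is summed over recall increments.
#'
#' @param recall,precision curve samples in score-descending order.
#' @param eleven_point if `TRUE`, use the 11-point variant (mean of
#'   interpolated precision at recall 0, 0.1, ..., 1).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(recall, precision, eleven_point = FALSE) {
  if (!length(recall)) return(0)
  mrec <- c(0, recall, 1)
  mpre <- c(1, precision, 0)
  for (i in rev(seq_len(length(mpre) - 1)))
    mpre[i] <- max(mpre[i], mpre[i + 1])
  if (eleven_point) {
    return(mean(vapply(seq(0, 1, 0.1), function(r)
      max(mpre[mrec >= r]), 0)))
  }
  idx <- which(diff(mrec) > 0)
  sum((mrec[idx + 1] - mrec[idx]) * mpre[idx + 1])
}

# Per-class AP at one IoU threshold over a multi-scene prediction set.
class_ap <- function(preds, gts, class_id, iou_thr) {
  gcl <- gts[gts$class_id == class_id, , drop = FALSE]
  pcl <- preds[preds$class_id == class_id, , drop = FALSE]
  n_gt <- nrow(gcl)
  if (n_gt == 0) return(NA_real_)
  if (nrow(pcl) == 0) return(0)
  pcl <- pcl[order(pcl$score, decreasing = TRUE), , drop = FALSE]
  used <- lapply(unique(gts$scene), function(s)
    rep(FALSE, sum(gcl$scene == s)))
  names(used) <- as.character(unique(gts$scene))
  tp <- logical(nrow(pcl))
  for (i in seq_len(nrow(pcl))) {
    s <- as.character(pcl$scene[i])
    gs <- gcl[gcl$scene == pcl$scene[i], , drop = FALSE]
    if (!nrow(gs)) next
    iou <- iou_matrix(as.matrix(pcl[i, c("x0", "y0", "x1", "y1")]),
                      as.matrix(gs[, c("x0", "y0", "x1", "y1")]))[1, ]
    free <- which(!used[[s]] & iou >= iou_thr)
    if (length(free)) {
      j <- free[which.max(iou[free])]
      used[[s]][j] <- TRUE
      tp[i] <- TRUE
    }
  }
  cum_tp <- cumsum(tp); cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / (cum_tp + cum_fp)
  average_precision(recall, precision)
}

#' Mean average precision over classes and IoU thresholds
#'
#' Classes absent from the ground truth are excluded from the mean.
#'
#' @param preds data frame with `scene`, `class_id`, `score`, pixel
#'   `x0, y0, x1, y1`.
#' @param gts data frame with `scene`, `class_id`, `x0, y0, x1, y1`.
#' @param n_classes total class count.
#' @return List with `map50`, `map50_95` and the per-class AP matrix.
#' @export
map_range <- function(preds, gts, n_classes = 3) {
  thrs <- seq(0.5, 0.95, by = 0.05)
  ap <- sapply(thrs, function(t)
    vapply(seq_len(n_classes) - 1L, class_ap, 0, preds = preds, gts = gts,
           iou_thr = t))
  ap <- matrix(ap, n_classes, length(thrs))
  present <- !is.na(ap[, 1])
  list(map50 = mean(ap[present, 1]),
       map50_95 = mean(rowMeans(ap[present, , drop = FALSE])),
       ap = ap)
}

#' F1 score from precision and recall
#'
#' `F1 = 2 P R / (P + R)` on whatever scale P and R share (fractions or
#' percents); defined as 0 when both are 0.
#'
#' @param P,R precision and recall.
#' @return F1 on the same scale.
#' @export
f1_score <- function(P, R) {
  ifelse(P + R == 0, 0, 2 * P * R / (P + R))
}

#' Precision/recall/F1 at the best operating point
#'
#' Sweeps confidence thresholds over the prediction scores and returns the
#' point maximizing F1 (matching at IoU 0.5), the convention used when a
#' single P/R pair is reported.
#'
#' @inheritParams map_range
#' @param iou_thr matching threshold.
#' @return List with `P`, `R`, `F1` (fractions) and `conf` used.
#' @export
best_f1_point <- function(preds, gts, iou_thr = 0.5) {
  if (!nrow(preds)) return(list(P = 0, R = 0, F1 = 0, conf = NA))
  cands <- unique(stats::quantile(preds$score, seq(0, 0.95, 0.05),
                                  names = FALSE))
  best <- list(P = 0, R = 0, F1 = 0, conf = NA)
  for (ct in cands) {
    sub <- preds[preds$score >= ct, , drop = FALSE]
    tp <- 0; fp <- 0
    for (s in unique(gts$scene)) {
      m <- match_detections(sub[sub$scene == s, , drop = FALSE],
                            gts[gts$scene == s, , drop = FALSE], iou_thr)
      tp <- tp + m$TP; fp <- fp + m$FP
    }
    P <- if (tp + fp == 0) 0 else tp / (tp + fp)
    R <- tp / nrow(gts)
    f1 <- f1_score(P, R)
    if (f1 > best$F1) best <- list(P = P, R = R, F1 = f1, conf = ct)
  }
  best
}

#' Measure inference throughput
#'
#' Median frames/second over timed forward passes after warm-up. The
#' result depends on hardware and is reported with a descriptor; it is
#' never a correctness criterion.
#'
#' @param model built model.
#' @param input_size square input side.
#' @param n_warmup warm-up forward passes before timing.
#' @param n_timed timed passes (must be positive).
#' @return List with `fps`, `input_size`, `batch` and `hardware`.
#' @export
measure_fps <- function(model, input_size = 640, n_warmup = 3000,
                        n_timed = 10) {
  if (n_timed <= 0) stop("n_timed must be positive")
  x <- array(stats::runif(input_size^2 * 3),
             c(input_size, input_size, 3, 1))
  inp <- setNames(rep(list(x), length(model$spec$branches)),
                  model$spec$branches)
  for (i in seq_len(n_warmup)) net_forward(model, inp, train = FALSE)
  times <- vapply(seq_len(n_timed), function(i)
    system.time(net_forward(model, inp, train = FALSE))[["elapsed"]], 0)
  list(fps = 1 / stats::median(times), input_size = input_size, batch = 1,
       hardware = paste(Sys.info()[["sysname"]], Sys.info()[["machine"]]))
}

# Ground-truth table (pixel xyxy + scene index) from a list of scenes.
scenes_to_gts <- function(scenes) {
  rows <- lapply(seq_along(scenes), function(i) {
    b <- scenes[[i]]$boxes
    if (!nrow(b)) return(NULL)
    hw <- dim(scenes[[i]]$rgb)[1:2]
    cbind(scene = i, boxes_to_targets(b, hw))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(scene = integer(0), class_id = integer(0),
                      x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0))
  out
}

#' Evaluate a trained detector on scenes
#'
#' @param model trained model.
#' @param scenes evaluation scenes.
#' @param conf_thr confidence floor for candidate detections.
#' @return List with percentage-scale `P`, `R`, `mAP50`, `mAP50_95`,
#'   `F1`, plus the raw predictions.
#' @export
evaluate_detector <- function(model, scenes, conf_thr = 0.001) {
  preds <- predict_detector(model, scenes, conf_thr = conf_thr)
  gts <- scenes_to_gts(scenes)
  mp <- map_range(preds, gts, model$spec$n_classes)
  op <- best_f1_point(preds, gts)
  list(P = 100 * op$P, R = 100 * op$R, mAP50 = 100 * mp$map50,
       mAP50_95 = 100 * mp$map50_95, F1 = 100 * op$F1,
       conf = op$conf, preds = preds, ap = mp$ap)
}

#' Run the full pipeline at a configured scale
#'
#' Synthesizes scenes, selects characteristic bands, builds PCC/DCS
#' enhancements, augments the training split, trains the configured
#' detector and evaluates on the test split.
#'
#' @param config list with entries `n_scenes`, `size`, `seed`, `input`
#'   (one of `"rgb"`, `"pcc"`, `"dcs"`, `"multi"`), `widths`,
#'   `neck_hidden`, `mb_kernels`, `n_iter`, `batch_size`, `lr`, `pick`,
#'   `augment` (logical), `easy` (logical: large unoccluded objects).
#' @return List with the metrics row (`metrics`), the selected `bands`,
#'   dataset counts and the trained model.
#' @export
run_pipeline <- function(config = list()) {
  cf <- utils::modifyList(list(
    n_scenes = 20, size = 64, seed = 1L, input = "multi",
    widths = c(8, 16, 32, 64, 128), neck_hidden = c(n3 = 36, td4 = 36,
                                                    n4 = 36, n5 = 36),
    mb_kernels = list(c(3, 5, 9), c(3, 5, 9), c(3, 9, 11)),
    n_iter = 100, batch_size = 4, lr = 0.02, pick = 2, augment = FALSE,
    easy = TRUE, pc_index = 1), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  scenes <- stage("synth", {
    make_dataset(cf$n_scenes, seed = cf$seed, size = cf$size,
                 total_boxes = if (cf$easy) 3 * cf$n_scenes
                               else round(4.203 * cf$n_scenes),
                 n_leaves = if (cf$easy) 6 else 20,
                 occlusion_prob = if (cf$easy) 0 else 0.3,
                 ntrm_frac = if (cf$easy) c(0.1, 0.17) else c(0.05, 0.14))
  })
  # On synthetic scenes the material contrast concentrates in the leading
  # component, so the pipeline defaults to PC 1 (see the methods vignette);
  # PC 4 remains the package default for field data.
  bsel <- stage("select-bands", select_bands(scenes,
                                             pc_index = cf$pc_index))
  scenes <- stage("enhance", lapply(scenes, function(sc) {
    pcc <- pseudo_color(sc$cube, bsel$bands)
    sc$pcc <- pcc$pixels
    sc$dcs <- decorrelation_stretch(pcc)$pixels
    sc$cube <- NULL  # cubes are no longer needed; free the memory
    sc
  }))
  if (cf$augment)
    scenes <- stage("augment",
                    build_tobacco3000(scenes,
                                      augmentation_plan(pick = cf$pick,
                                                        seed = cf$seed)))
  branches <- switch(cf$input, rgb = "rgb", pcc = "pcc", dcs = "dcs",
                     multi = c("rgb", "dcs"),
                     stop("unknown input regime ", cf$input))
  spec <- model_spec(branches = branches, widths = cf$widths,
                     neck_hidden = cf$neck_hidden,
                     mb_kernels = cf$mb_kernels)
  model <- build_model(spec, seed = cf$seed)
  splits <- vapply(scenes, `[[`, "", "split")
  train_scenes <- scenes[splits == "train"]
  test_scenes <- scenes[splits == "test"]
  stage("train", train_detector(model, train_scenes, n_iter = cf$n_iter,
                                batch_size = cf$batch_size, lr = cf$lr,
                                seed = cf$seed))
  ev <- stage("eval", evaluate_detector(model, test_scenes))
  metrics <- data.frame(
    Method = if (length(branches) > 1) "dual-branch" else "single-branch",
    Input = cf$input, Parameters = count_parameters(model),
    GFLOPs = round(count_flops(model, 32 * (cf$size %/% 32)), 2),
    Precision = round(ev$P, 1), Recall = round(ev$R, 1),
    mAP50 = round(ev$mAP50, 1), mAP50_95 = round(ev$mAP50_95, 1),
    F1 = round(ev$F1, 1))
  list(metrics = metrics, bands = bsel$bands,
       counts = dataset_counts(scenes), model = model, eval = ev)
}
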
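# Detection losses (binary cross-entropy, complete-IoU, distribution focal
# loss), task-aligned target assignment, box decoding with non-maximum
# suppression, and the training loop.

EPS_P <- 1e-7

#' Binary cross-entropy loss
#'
#' `-(q log p + (1-q) log(1-p))`. The printed form uses base-2 logarithms;
#' the natural log (default) differs only by the constant factor
#' `1/log(2)`, which rescales gradients uniformly.
#'
#' @param p predicted positive probability (clamped to `[1e-7, 1-1e-7]`).
#' @param q binary (or soft) label in `[0, 1]`.
#' @param log_base `"e"` or `"2"`.
#' @return Elementwise loss.
#' @export
loss_bce <- function(p, q, log_base = c("e", "2")) {
  log_base <- match.arg(log_base)
  p <- pmin(pmax(p, EPS_P), 1 - EPS_P)
  l <- -(q * log(p) + (1 - q) * log(1 - p))
  if (log_base == "2") l / log(2) else l
}

#' Complete IoU and its loss
#'
#' `CIoU = IoU - rho^2/c^2 - alpha v` with `v = (4/pi^2)
#' (atan(w_gt/h_gt) - atan(w/h))^2` and `alpha = v / ((1 - IoU) + v)`;
#' the loss is `1 - CIoU`.
#'
#' @param box,gt boxes as `c(x0, y0, x1, y1)`.
#' @return `loss_ciou` returns the scalar loss; `ciou` the CIoU value.
#' @export
ciou <- function(box, gt) {
  ix <- max(0, min(box[3], gt[3]) - max(box[1], gt[1]))
  iy <- max(0, min(box[4], gt[4]) - max(box[2], gt[2]))
  inter <- ix * iy
  a1 <- (box[3] - box[1]) * (box[4] - box[2])
  a2 <- (gt[3] - gt[1]) * (gt[4] - gt[2])
  iou <- inter / (a1 + a2 - inter + 1e-12)
  cw <- max(box[3], gt[3]) - min(box[1], gt[1])
  chh <- max(box[4], gt[4]) - min(box[2], gt[2])
  c2 <- cw^2 + chh^2 + 1e-12
  rho2 <- ((box[1] + box[3] - gt[1] - gt[3])^2 +
           (box[2] + box[4] - gt[2] - gt[4])^2) / 4
  w <- box[3] - box[1]; h <- box[4] - box[2]
  wg <- gt[3] - gt[1]; hg <- gt[4] - gt[2]
  v <- (4 / pi^2) * (atan(wg / hg) - atan(w / max(h, 1e-12)))^2
  alpha <- v / ((1 - iou) + v + 1e-12)
  iou - rho2 / c2 - alpha * v
}

#' @rdname ciou
#' @export
loss_ciou <- function(box, gt) 1 - ciou(box, gt)

#' Distribution focal loss for one target
#'
#' Cross-entropy against the two softmax masses flanking the continuous
#' target: `-((y_{i+1} - y) log S_i + (y - y_i) log S_{i+1})`.
#'
#' @param S_i,S_ip1 softmax masses at the bins below/above the target.
#' @param y continuous target; `y_i`, `y_ip1` flanking bin values.
#' @param log_base `"e"` or `"2"`.
#' @return Scalar loss.
#' @export
loss_dfl <- function(S_i, S_ip1, y, y_i, y_ip1, log_base = c("e", "2")) {
  log_base <- match.arg(log_base)
  S_i <- pmax(S_i, EPS_P); S_ip1 <- pmax(S_ip1, EPS_P)
  l <- -((y_ip1 - y) * log(S_i) + (y - y_i) * log(S_ip1))
  if (log_base == "2") l / log(2) else l
}

#' Weighted total detection loss
#'
#' @param l_box,l_cls,l_dfl component losses.
#' @param lambda_box,lambda_cls,lambda_dfl loss weights (reference
#'   one-stage detector defaults).
#' @return Scalar weighted sum.
#' @export
total_loss <- function(l_box, l_cls, l_dfl, lambda_box = 7.5,
                       lambda_cls = 0.5, lambda_dfl = 1.5) {
  lambda_box * l_box + lambda_cls * l_cls + lambda_dfl * l_dfl
}

iou_matrix <- function(a, b) {
  # a: n x 4, b: m x 4 (xyxy); returns n x m IoU matrix
  n <- nrow(a); m <- nrow(b)
  ix <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  iy <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- ix * iy
  aa <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  ab <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (outer(aa, ab, `+`) - inter + 1e-12)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Per-level anchor table for a given input size.
make_anchors <- function(input_hw, strides = c(8, 16, 32)) {
  out <- lapply(strides, function(s) {
    hs <- input_hw[1] %/% s; ws <- input_hw[2] %/% s
    p <- seq_len(hs * ws) - 1L
    data.frame(level = match(s, strides), stride = s,
               ay = (p %% hs) + 0.5, ax = (p %/% hs) + 0.5)
  })
  do.call(rbind, out)
}

# Flatten head outputs of image n into per-anchor matrices.
flatten_outputs <- function(outs, n, reg_max, nc) {
  cls <- NULL; box <- NULL
  for (l in seq_along(outs)) {
    d <- dim(outs[[l]]$cls)
    A <- d[1] * d[2]
    cls <- rbind(cls, matrix(outs[[l]]$cls[, , , n], A, nc))
    box <- rbind(box, matrix(outs[[l]]$box[, , , n], A, 4 * reg_max))
  }
  list(cls = cls, box = box)
}

# Decode per-anchor distribution logits to distances (cells) and boxes (px).
decode_boxes <- function(box_logits, anchors, reg_max) {
  A <- nrow(box_logits)
  d <- matrix(0, A, 4)
  probs <- vector("list", 4)
  proj <- 0:(reg_max - 1)
  for (s in 1:4) {
    z <- box_logits[, (s - 1) * reg_max + seq_len(reg_max), drop = FALSE]
    p <- softmax_rows(z)
    probs[[s]] <- p
    d[, s] <- as.numeric(p %*% proj)
  }
  boxes <- cbind((anchors$ax - d[, 1]) * anchors$stride,
                 (anchors$ay - d[, 2]) * anchors$stride,
                 (anchors$ax + d[, 3]) * anchors$stride,
                 (anchors$ay + d[, 4]) * anchors$stride)
  list(dist = d, probs = probs, boxes = boxes)
}

# Task-aligned assignment: candidates are anchors whose center lies inside
# the ground-truth box; the top-k by cls_score^alpha * IoU^beta are
# assigned, conflicts resolved toward the higher-IoU ground truth.
assign_targets <- function(pred_boxes, cls_prob, gts, anchors, topk = 10,
                           alpha = 0.5, beta = 6) {
  A <- nrow(pred_boxes); G <- nrow(gts)
  assigned <- rep(0L, A)    # 0 = background, else gt index
  tscore <- numeric(A)
  if (G == 0) return(list(assigned = assigned, tscore = tscore))
  axp <- anchors$ax * anchors$stride
  ayp <- anchors$ay * anchors$stride
  iou <- iou_matrix(pred_boxes, as.matrix(gts[, c("x0", "y0", "x1", "y1")]))
  metric <- matrix(0, A, G)
  cand <- matrix(FALSE, A, G)
  for (g in seq_len(G)) {
    inside <- axp > gts$x0[g] & axp < gts$x1[g] &
              ayp > gts$y0[g] & ayp < gts$y1[g]
    if (!any(inside)) {
      # degenerate tiny box: fall back to the nearest anchor
      ctr <- c((gts$x0[g] + gts$x1[g]) / 2, (gts$y0[g] + gts$y1[g]) / 2)
      inside <- seq_len(A) == which.min((axp - ctr[1])^2 + (ayp - ctr[2])^2)
    }
    sc <- cls_prob[, gts$class_id[g] + 1L]
    mt <- (sc^alpha) * (iou[, g]^beta)
    mt[!inside] <- 0
    ord <- order(mt, decreasing = TRUE)
    top <- ord[seq_len(min(topk, sum(inside)))]
    top <- top[mt[top] > 0 | seq_along(top) == 1]
    cand[top, g] <- TRUE
    metric[, g] <- mt
  }
  for (a in which(rowSums(cand) > 0)) {
    gs <- which(cand[a, ])
    g <- gs[which.max(iou[a, gs])]
    assigned[a] <- g
  }
  # normalized target scores: t = metric / max_metric * max_iou per gt
  for (g in seq_len(G)) {
    sel <- which(assigned == g)
    if (!length(sel)) next
    mmax <- max(metric[sel, g]); imax <- max(iou[sel, g])
    tscore[sel] <- if (mmax > 0) metric[sel, g] / mmax * imax
                   else pmax(iou[sel, g], 0.1)
  }
  list(assigned = assigned, tscore = tscore, iou = iou)
}

# Loss and head-output gradients for one batch.
detection_loss <- function(outs, targets, input_hw, nc, reg_max,
                           lambda = c(box = 7.5, cls = 0.5, dfl = 1.5),
                           strides = c(8, 16, 32)) {
  anchors <- make_anchors(input_hw, strides)
  N <- dim(outs[[1]]$cls)[4]
  grads <- lapply(outs, function(o)
    list(box = array(0, dim(o$box)), cls = array(0, dim(o$cls))))
  lv_sizes <- vapply(outs, function(o) dim(o$cls)[1] * dim(o$cls)[2], 0)
  lv_off <- cumsum(c(0, lv_sizes))
  tot <- c(box = 0, cls = 0, dfl = 0)
  proj <- 0:(reg_max - 1)
  for (n in seq_len(N)) {
    fo <- flatten_outputs(outs, n, reg_max, nc)
    dec <- decode_boxes(fo$box, anchors, reg_max)
    cls_prob <- 1 / (1 + exp(-fo$cls))
    gts <- targets[[n]]
    as <- assign_targets(dec$boxes, cls_prob, gts, anchors)
    tsum <- max(sum(as$tscore), 1)
    Y <- matrix(0, nrow(cls_prob), nc)
    pos <- which(as$assigned > 0)
    for (a in pos) Y[a, gts$class_id[as$assigned[a]] + 1L] <- as$tscore[a]
    tot["cls"] <- tot["cls"] + sum(loss_bce(cls_prob, Y)) / tsum / N
    dcls <- (cls_prob - Y) / tsum / N * lambda[["cls"]]
    dbox <- matrix(0, nrow(fo$box), 4 * reg_max)
    for (a in pos) {
      g <- as$assigned[a]
      wgt <- as$tscore[a] / tsum / N
      s <- anchors$stride[a]
      gt_cells <- c(anchors$ax[a] - gts$x0[g] / s,
                    anchors$ay[a] - gts$y0[g] / s,
                    gts$x1[g] / s - anchors$ax[a],
                    gts$y1[g] / s - anchors$ay[a])
      gt_cells <- pmin(pmax(gt_cells, 0), reg_max - 1 - 0.01)
      gtbox <- c(anchors$ax[a] - gt_cells[1], anchors$ay[a] - gt_cells[2],
                 anchors$ax[a] + gt_cells[3], anchors$ay[a] + gt_cells[4])
      d <- dec$dist[a, ]
      pbox <- c(anchors$ax[a] - d[1], anchors$ay[a] - d[2],
                anchors$ax[a] + d[3], anchors$ay[a] + d[4])
      lb <- loss_ciou(pbox, gtbox)
      tot["box"] <- tot["box"] + wgt * lb
      # numeric gradient of the CIoU loss w.r.t. the four distances
      gdist <- numeric(4)
      hstep <- 1e-3
      sgn <- c(-1, -1, 1, 1)  # how each distance moves its box edge
      for (k in 1:4) {
        for (pm in c(1, -1)) {
          pb <- pbox
          pb[k] <- pb[k] + pm * hstep * sgn[k]
          gdist[k] <- gdist[k] + pm * loss_ciou(pb, gtbox) / (2 * hstep)
        }
      }
      for (k in 1:4) {
        p <- dec$probs[[k]][a, ]
        idx <- (k - 1) * reg_max + seq_len(reg_max)
        # chain through the softmax expectation
        dbox[a, idx] <- dbox[a, idx] +
          wgt * lambda[["box"]] * gdist[k] * p * (proj - d[k])
        # distribution focal term on the flanking bins
        yl <- floor(gt_cells[k]); yh <- yl + 1
        wl <- yh - gt_cells[k]; wh <- gt_cells[k] - yl
        tgt <- numeric(reg_max)
        tgt[yl + 1] <- wl
        if (yh < reg_max) tgt[yh + 1] <- wh
        tot["dfl"] <- tot["dfl"] - wgt *
          (wl * log(max(p[yl + 1], EPS_P)) +
           if (yh < reg_max) wh * log(max(p[yh + 1], EPS_P)) else 0)
        dbox[a, idx] <- dbox[a, idx] +
          wgt * lambda[["dfl"]] * (p * sum(tgt) - tgt)
      }
    }
    # scatter flat gradients back to per-level arrays
    for (l in seq_along(outs)) {
      sel <- lv_off[l] + seq_len(lv_sizes[l])
      dl <- dim(outs[[l]]$cls)
      grads[[l]]$cls[, , , n] <- array(dcls[sel, ], c(dl[1], dl[2], nc))
      grads[[l]]$box[, , , n] <-
        array(dbox[sel, ], c(dl[1], dl[2], 4 * reg_max))
    }
  }
  loss <- total_loss(tot[["box"]], tot[["cls"]], tot[["dfl"]])
  list(loss = loss, parts = tot, grads = grads)
}

# Normalized center-format boxes -> pixel xyxy targets.
boxes_to_targets <- function(boxes, input_hw) {
  data.frame(class_id = boxes$class_id,
             x0 = (boxes$cx - boxes$w / 2) * input_hw[2],
             y0 = (boxes$cy - boxes$h / 2) * input_hw[1],
             x1 = (boxes$cx + boxes$w / 2) * input_hw[2],
             y1 = (boxes$cy + boxes$h / 2) * input_hw[1])
}

scene_input <- function(scene, kind) {
  img <- switch(kind, rgb = scene$rgb, dcs = scene$dcs, pcc = scene$pcc,
                stop("unknown input kind ", kind))
  if (is.null(img)) stop("scene ", scene$id, " lacks ", kind, " image")
  img / 255
}

batch_inputs <- function(scenes, branches) {
  d <- dim(scenes[[1]]$rgb)
  out <- list()
  for (br in branches) {
    x <- array(0, c(d[1], d[2], 3, length(scenes)))
    for (i in seq_along(scenes)) x[, , , i] <- scene_input(scenes[[i]], br)
    out[[br]] <- x
  }
  out
}

#' Full-scale training configuration
#'
#' Holds the published full-scale training hyperparameters: batch size 16,
#' no pretrained weights, 300 epochs with early-stopping patience 50
#' (monitored on validation mAP@50-95), 4 data workers, 640-pixel inputs.
#' Desk-scale runs (tests, [run_pipeline()]) use reduced sizes; this
#' object records the reference settings a full run would use.
#'
#' @param batch_size,epochs,patience,workers,input_size positive integers.
#' @param pretrained logical; start from pretrained weights.
#' @param seed RNG seed.
#' @return A validated `train_config` list.
#' @export
train_config <- function(batch_size = 16, pretrained = FALSE,
                         epochs = 300, patience = 50, workers = 4,
                         input_size = 640, seed = 0L) {
  vals <- c(batch_size, epochs, patience, workers, input_size)
  if (any(vals <= 0)) stop("all training sizes must be positive")
  structure(list(batch_size = batch_size, pretrained = pretrained,
                 epochs = epochs, patience = patience, workers = workers,
                 input_size = input_size, seed = as.integer(seed)),
            class = "train_config")
}

#' Train a detector on annotated scenes
#'
#' Plain Adam training with a short linear warmup; batch statistics drive
#' batch norm, and every loss component follows the combined BCE + CIoU +
#' DFL objective with task-aligned assignment.
#'
#' @param model built model.
#' @param scenes list of annotated scenes (all the same size, divisible
#'   by 32) carrying the branch images the spec requires.
#' @param n_iter number of optimizer iterations.
#' @param batch_size scenes per iteration.
#' @param lr peak learning rate.
#' @param warmup iterations of linear warmup.
#' @param seed RNG seed for batch sampling.
#' @param verbose print running loss every 20 iterations.
#' @return The loss history (numeric vector), invisibly; the model is
#'   updated in place.
#' @export
train_detector <- function(model, scenes, n_iter = 200, batch_size = 4,
                           lr = 0.01, warmup = 10, seed = 0L,
                           verbose = FALSE) {
  spec <- model$spec
  input_hw <- dim(scenes[[1]]$rgb)[1:2]
  set.seed(seed)
  history <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    idx <- sample.int(length(scenes), min(batch_size, length(scenes)))
    batch <- scenes[idx]
    inputs <- batch_inputs(batch, spec$branches)
    targets <- lapply(batch, function(s) boxes_to_targets(s$boxes, input_hw))
    outs <- net_forward(model, inputs, train = TRUE)
    dl <- detection_loss(outs, targets, input_hw, spec$n_classes,
                         spec$reg_max)
    history[it] <- dl$loss
    zero_grads(model)
    net_backward(model, dl$grads)
    lr_it <- if (it <= warmup) lr * it / warmup
             else lr * (0.05 + 0.95 * 0.5 *
                          (1 + cos(pi * (it - warmup) / (n_iter - warmup))))
    adam_step(model, lr = lr_it)
    if (verbose && it %% 20 == 0)
      message(sprintf("iter %d loss %.4f (box %.3f cls %.3f dfl %.3f)", it,
                      dl$loss, dl$parts["box"], dl$parts["cls"],
                      dl$parts["dfl"]))
  }
  invisible(history)
}

# Greedy per-class non-maximum suppression; boxes xyxy, descending score.
nms_class <- function(boxes, scores, iou_thr = 0.7) {
  keep <- integer(0)
  ord <- order(scores, decreasing = TRUE)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1) break
    rest <- ord[-1]
    iou <- iou_matrix(boxes[i, , drop = FALSE],
                      boxes[rest, , drop = FALSE])[1, ]
    ord <- rest[iou <= iou_thr]
  }
  keep
}

#' Run detection on scenes
#'
#' @param model trained model.
#' @param scenes list of annotated scenes.
#' @param conf_thr minimum class confidence kept before NMS.
#' @param iou_thr NMS IoU threshold.
#' @param max_det maximum detections per image.
#' @return Data frame with `scene`, `class_id`, `score` and pixel
#'   `x0, y0, x1, y1`.
#' @export
predict_detector <- function(model, scenes, conf_thr = 0.25,
                             iou_thr = 0.7, max_det = 300) {
  spec <- model$spec
  input_hw <- dim(scenes[[1]]$rgb)[1:2]
  anchors <- make_anchors(input_hw)
  res <- list()
  for (i in seq_along(scenes)) {
    inputs <- batch_inputs(scenes[i], spec$branches)
    outs <- net_forward(model, inputs, train = FALSE)
    fo <- flatten_outputs(outs, 1, spec$reg_max, spec$n_classes)
    dec <- decode_boxes(fo$box, anchors, spec$reg_max)
    prob <- 1 / (1 + exp(-fo$cls))
    for (cl in seq_len(spec$n_classes) - 1L) {
      sc <- prob[, cl + 1]
      sel <- which(sc >= conf_thr)
      if (!length(sel)) next
      keep <- nms_class(dec$boxes[sel, , drop = FALSE], sc[sel], iou_thr)
      keep <- keep[seq_len(min(length(keep), max_det))]
      res[[length(res) + 1]] <- data.frame(
        scene = i, class_id = cl, score = sc[sel][keep],
        x0 = dec$boxes[sel[keep], 1], y0 = dec$boxes[sel[keep], 2],
        x1 = dec$boxes[sel[keep], 3], y1 = dec$boxes[sel[keep], 4])
    }
  }
  if (!length(res))
    return(data.frame(scene = integer(0), class_id = integer(0),
                      score = numeric(0), x0 = numeric(0), y0 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0)))
  do.call(rbind, res)
}
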
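# Detector architectures. The single-branch baseline is the standard
# small-scale anchor-free one-stage layout (stem + C2f backbone + SPPF,
# FPN/PAN neck, decoupled head with distribution-focal box regression).
# The dual-branch model runs two such backbones over RGB and DCS inputs,
# fuses P3/P4/P5 per scale by concatenation + pointwise reduction, and
# replaces the neck with a BELFPN: BiFPN-style normalized weighted fusion
# nodes followed by C2f_EL blocks (MBModule inner blocks with multi-kernel
# depthwise branches and channel shuffle).

#' Declarative detector configuration
#'
#' The defaults instantiate the full-size dual-branch detector: widths
#' (16, 32, 64, 128, 256) and repeats (1, 2, 2, 1) are the 0.25/0.33
#' width/depth multiples of the reference (64, ..., 1024) x (3, 6, 6, 3)
#' layout, and the BELFPN hidden widths/kernels are the searched
#' configuration whose parameter count matches the published total.
#'
#' @param n_classes number of object classes.
#' @param branches `c("rgb", "dcs")` for the dual-branch model or
#'   `"rgb"` for the single-branch baseline.
#' @param widths backbone channel widths at strides 2/4/8/16/32.
#' @param repeats C2f repeat counts for the four backbone stages.
#' @param reg_max distribution-focal-loss bin count per box side.
#' @param mb_kernels list of 3 odd kernel-size triples for the MBModule at
#'   strides 8/16/32.
#' @param shuffle_groups channel-shuffle group count inside MBModule.
#' @param neck_hidden C2f_EL hidden widths for the (N3, td4, N4, N5)
#'   fusion nodes; each must be divisible by `3 * shuffle_groups`.
#' @param down_kernels depthwise kernel sizes of the two down-adapters.
#' @return A `model_spec` list.
#' @export
model_spec <- function(n_classes = 3, branches = c("rgb", "dcs"),
                       widths = c(16, 32, 64, 128, 256),
                       repeats = c(1, 2, 2, 1), reg_max = 16,
                       mb_kernels = list(c(3, 5, 9), c(3, 5, 9),
                                         c(3, 9, 11)),
                       shuffle_groups = 3,
                       neck_hidden = c(n3 = 126, td4 = 36, n4 = 36,
                                       n5 = 45),
                       down_kernels = c(3, 3)) {
  stopifnot(length(widths) == 5, length(repeats) == 4,
            all(vapply(mb_kernels, function(k)
              length(k) == 3 && all(k %% 2 == 1), TRUE)))
  structure(list(n_classes = as.integer(n_classes), branches = branches,
                 widths = as.integer(widths), repeats = as.integer(repeats),
                 reg_max = as.integer(reg_max), mb_kernels = mb_kernels,
                 shuffle_groups = as.integer(shuffle_groups),
                 neck_hidden = neck_hidden,
                 down_kernels = as.integer(down_kernels)),
            class = "model_spec")
}

#' Single-branch baseline spec
#' @param ... overrides passed to [model_spec()].
#' @return A `model_spec` with `branches = "rgb"`.
#' @export
baseline_spec <- function(...) model_spec(branches = "rgb", ...)

mk_backbone <- function(w, r) {
  list(l0 = mk_conv(3, w[1], 3, 2, first = TRUE),
       l1 = mk_conv(w[1], w[2], 3, 2),
       l2 = mk_c2f(w[2], w[2], r[1]),
       l3 = mk_conv(w[2], w[3], 3, 2),
       l4 = mk_c2f(w[3], w[3], r[2]),
       l5 = mk_conv(w[3], w[4], 3, 2),
       l6 = mk_c2f(w[4], w[4], r[3]),
       l7 = mk_conv(w[4], w[5], 3, 2),
       l8 = mk_c2f(w[5], w[5], r[4]),
       l9 = mk_sppf(w[5], w[5]))
}

#' Build a detector network from a spec
#'
#' @param spec a [model_spec()].
#' @param seed seed for weight initialization.
#' @return A model environment with the module tree, usable with
#'   [count_parameters()], [count_flops()], [net_forward()] and the
#'   training functions.
#' @export
build_model <- function(spec, seed = 0L) {
  set.seed(seed)
  w <- spec$widths
  net <- new.env(parent = emptyenv())
  net$spec <- spec
  net$type <- if (length(spec$branches) >= 2) "dual" else "single"
  if (net$type == "single") {
    bb <- mk_backbone(w, spec$repeats)
    neck <- list(
      n12 = mk_c2f(w[5] + w[4], w[4], spec$repeats[1], shortcut = FALSE),
      n15 = mk_c2f(w[4] + w[3], w[3], spec$repeats[1], shortcut = FALSE),
      n16 = mk_conv(w[3], w[3], 3, 2),
      n18 = mk_c2f(w[3] + w[4], w[4], spec$repeats[1], shortcut = FALSE),
      n19 = mk_conv(w[4], w[4], 3, 2),
      n21 = mk_c2f(w[4] + w[5], w[5], spec$repeats[1], shortcut = FALSE))
    head <- mk_head(w[3:5], spec$n_classes, spec$reg_max)
    net$bb <- bb; net$neck <- neck; net$head <- head
    net$mods <- c(bb, neck, list(head))
  } else {
    bb1 <- mk_backbone(w, spec$repeats)
    bb2 <- mk_backbone(w, spec$repeats)
    fus <- list(f3 = mk_conv(2 * w[3], w[3], 1),
                f4 = mk_conv(2 * w[4], w[4], 1),
                f5 = mk_conv(2 * w[5], w[5], 1))
    h <- spec$neck_hidden; mk <- spec$mb_kernels; g <- spec$shuffle_groups
    neck <- list(
      a5 = mk_conv(w[5], w[4], 1),
      fu_td4 = mk_fuse(2),
      td4 = mk_c2fel(w[4], w[4], h[["td4"]], 1, mk[[2]], g),
      a4 = mk_conv(w[4], w[3], 1),
      fu_n3 = mk_fuse(2),
      n3 = mk_c2fel(w[3], w[3], h[["n3"]], 1, mk[[1]], g),
      d3 = mk_down(w[3], w[4], spec$down_kernels[1]),
      fu_n4 = mk_fuse(3),
      n4 = mk_c2fel(w[4], w[4], h[["n4"]], 1, mk[[2]], g),
      d4 = mk_down(w[4], w[5], spec$down_kernels[2]),
      fu_n5 = mk_fuse(2),
      n5 = mk_c2fel(w[5], w[5], h[["n5"]], 1, mk[[3]], g))
    head <- mk_head(w[3:5], spec$n_classes, spec$reg_max)
    net$bb1 <- bb1; net$bb2 <- bb2; net$fus <- fus; net$neck <- neck
    net$head <- head
    net$mods <- c(bb1, bb2, fus, neck, list(head))
  }
  class(net) <- "dby_model"
  net
}

#' @export
print.dby_model <- function(x, ...) {
  cat(sprintf("<%s-branch detector: %s parameters>\n", x$type,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

backbone_fwd <- function(bb, x, train) {
  x0 <- m_fwd(bb$l0, x, train);  x1 <- m_fwd(bb$l1, x0, train)
  x2 <- m_fwd(bb$l2, x1, train); x3 <- m_fwd(bb$l3, x2, train)
  x4 <- m_fwd(bb$l4, x3, train); x5 <- m_fwd(bb$l5, x4, train)
  x6 <- m_fwd(bb$l6, x5, train); x7 <- m_fwd(bb$l7, x6, train)
  x8 <- m_fwd(bb$l8, x7, train); x9 <- m_fwd(bb$l9, x8, train)
  list(p3 = x4, p4 = x6, p5 = x9)
}

#' Forward pass of a built model
#'
#' @param model built model.
#' @param inputs list with `rgb` (and `dcs` for the dual model):
#'   H x W x 3 x N arrays scaled to 0..1, H and W divisible by 32.
#' @param train if `TRUE`, batch norm uses batch statistics and caches are
#'   kept for [net_backward()].
#' @return List of per-scale head outputs (`box` distribution logits,
#'   `cls` logits) with strides 8/16/32.
#' @export
net_forward <- function(model, inputs, train = FALSE) {
  br <- model$spec$branches
  x <- inputs[[br[1]]]
  if (is.null(x)) stop("inputs lack the '", br[1], "' branch image")
  if (any(dim(x)[1:2] %% 32 != 0))
    stop("input size must be divisible by 32, got ",
         paste(dim(x)[1:2], collapse = "x"))
  if (model$type == "single") {
    p <- backbone_fwd(model$bb, x, train)
    nk <- model$neck
    u1 <- cpp_upsample2_fwd(p$p5)
    x12 <- m_fwd(nk$n12, cat_c(list(u1, p$p4)), train)
    u2 <- cpp_upsample2_fwd(x12)
    x15 <- m_fwd(nk$n15, cat_c(list(u2, p$p3)), train)
    d1 <- m_fwd(nk$n16, x15, train)
    x18 <- m_fwd(nk$n18, cat_c(list(d1, x12)), train)
    d2 <- m_fwd(nk$n19, x18, train)
    x21 <- m_fwd(nk$n21, cat_c(list(d2, p$p5)), train)
    m_fwd(model$head, list(x15, x18, x21), train)
  } else {
    x2 <- inputs[[br[2]]]
    if (is.null(x2)) stop("inputs lack the '", br[2], "' branch image")
    pa <- backbone_fwd(model$bb1, x, train)
    pb <- backbone_fwd(model$bb2, x2, train)
    fs <- model$fus
    f3 <- m_fwd(fs$f3, cat_c(list(pa$p3, pb$p3)), train)
    f4 <- m_fwd(fs$f4, cat_c(list(pa$p4, pb$p4)), train)
    f5 <- m_fwd(fs$f5, cat_c(list(pa$p5, pb$p5)), train)
    nk <- model$neck
    a5 <- m_fwd(nk$a5, f5, train)
    u5 <- cpp_upsample2_fwd(a5)
    td4 <- m_fwd(nk$td4, m_fwd(nk$fu_td4, list(f4, u5), train), train)
    a4 <- m_fwd(nk$a4, td4, train)
    u4 <- cpp_upsample2_fwd(a4)
    n3 <- m_fwd(nk$n3, m_fwd(nk$fu_n3, list(f3, u4), train), train)
    d3 <- m_fwd(nk$d3, n3, train)
    n4 <- m_fwd(nk$n4, m_fwd(nk$fu_n4, list(f4, td4, d3), train), train)
    d4 <- m_fwd(nk$d4, n4, train)
    n5 <- m_fwd(nk$n5, m_fwd(nk$fu_n5, list(f5, d4), train), train)
    model$cache <- list(ch3 = dim(pa$p3)[3], ch4 = dim(pa$p4)[3],
                        ch5 = dim(pa$p5)[3])
    m_fwd(model$head, list(n3, n4, n5), train)
  }
}

#' Backward pass from head-output gradients
#'
#' Accumulates parameter gradients for every module; call [zero_grads()]
#' first and an optimizer step after.
#'
#' @param model built model (after a `train = TRUE` forward).
#' @param dhead per-scale gradients matching the [net_forward()] output.
#' @export
net_backward <- function(model, dhead) {
  dxs <- m_bwd(model$head, dhead)
  if (model$type == "single") {
    nk <- model$neck
    w <- model$spec$widths
    w3 <- w[3]; w4 <- w[4]; w5 <- w[5]
    s21 <- split_c(m_bwd(nk$n21, dxs[[3]]), c(w4, w5))   # (d2, p5)
    dx18 <- dxs[[2]] + m_bwd(nk$n19, s21[[1]])
    s18 <- split_c(m_bwd(nk$n18, dx18), c(w3, w4))       # (d1, x12)
    dx15 <- dxs[[1]] + m_bwd(nk$n16, s18[[1]])
    s15 <- split_c(m_bwd(nk$n15, dx15), c(w4, w3))       # (u2, p3)
    dx12 <- s18[[2]] + cpp_upsample2_bwd(s15[[1]])
    s12 <- split_c(m_bwd(nk$n12, dx12), c(w5, w4))       # (u1, p4)
    dp5 <- s21[[2]] + cpp_upsample2_bwd(s12[[1]])
    single_backbone_bwd(model$bb, s15[[2]], s12[[2]], dp5)
  } else {
    nk <- model$neck; fs <- model$fus
    dn5 <- m_bwd(nk$n5, dxs[[3]])
    dfu5 <- m_bwd(nk$fu_n5, dn5)
    df5 <- dfu5[[1]]
    dn4 <- m_bwd(nk$n4, dxs[[2]] + m_bwd(nk$d4, dfu5[[2]]))
    dfu4 <- m_bwd(nk$fu_n4, dn4)
    df4 <- dfu4[[1]]
    dtd4 <- dfu4[[2]]
    dn3 <- m_bwd(nk$n3, dxs[[1]] + m_bwd(nk$d3, dfu4[[3]]))
    dfu3 <- m_bwd(nk$fu_n3, dn3)
    df3 <- dfu3[[1]]
    dtd4 <- dtd4 + m_bwd(nk$a4, cpp_upsample2_bwd(dfu3[[2]]))
    dtd <- m_bwd(nk$td4, dtd4)
    dfu_td <- m_bwd(nk$fu_td4, dtd)
    df4 <- df4 + dfu_td[[1]]
    df5 <- df5 + m_bwd(nk$a5, cpp_upsample2_bwd(dfu_td[[2]]))
    ch3 <- model$cache$ch3; ch4 <- model$cache$ch4; ch5 <- model$cache$ch5
    s3 <- split_c(m_bwd(fs$f3, df3), c(ch3, ch3))
    s4 <- split_c(m_bwd(fs$f4, df4), c(ch4, ch4))
    s5 <- split_c(m_bwd(fs$f5, df5), c(ch5, ch5))
    single_backbone_bwd(model$bb1, s3[[1]], s4[[1]], s5[[1]])
    single_backbone_bwd(model$bb2, s3[[2]], s4[[2]], s5[[2]])
  }
  invisible()
}

single_backbone_bwd <- function(bb, dp3, dp4, dp5) {
  d8 <- m_bwd(bb$l9, dp5)
  d7 <- m_bwd(bb$l8, d8)
  d6 <- m_bwd(bb$l7, d7) + dp4
  d5 <- m_bwd(bb$l6, d6)
  d4 <- m_bwd(bb$l5, d5) + dp3
  d3 <- m_bwd(bb$l4, d4)
  d2 <- m_bwd(bb$l3, d3)
  d1 <- m_bwd(bb$l2, d2)
  d0 <- m_bwd(bb$l1, d1)
  m_bwd(bb$l0, d0)
  invisible()
}

#' Count model compute at a given input size
#'
#' Convolution multiply-accumulates (including depthwise and head
#' convolutions) times two, summed over both branches for the dual model;
#' batch norm, activations and resampling are excluded.
#'
#' @param model built model.
#' @param input_size square input side in pixels (divisible by 32).
#' @return GFLOPs (1e9 floating-point operations per forward pass).
#' @export
count_flops <- function(model, input_size = 640) {
  s <- input_size
  bb_macs <- function(bb) {
    h <- s; w <- s; macs <- 0
    for (l in bb) {
      f <- m_flops(l, h, w)
      macs <- macs + f$macs; h <- f$h; w <- f$w
    }
    macs
  }
  hw <- function(stride) c(s %/% stride, s %/% stride)
  at <- function(mod, stride) m_flops(mod, s %/% stride, s %/% stride)$macs
  if (model$type == "single") {
    nk <- model$neck
    macs <- bb_macs(model$bb) +
      at(nk$n12, 16) + at(nk$n15, 8) + at(nk$n16, 8) +
      at(nk$n18, 16) + at(nk$n19, 16) + at(nk$n21, 32) +
      m_flops(model$head, list(hw(8), hw(16), hw(32)))
  } else {
    nk <- model$neck; fs <- model$fus
    macs <- bb_macs(model$bb1) + bb_macs(model$bb2) +
      at(fs$f3, 8) + at(fs$f4, 16) + at(fs$f5, 32) +
      at(nk$a5, 32) + at(nk$td4, 16) + at(nk$a4, 16) + at(nk$n3, 8) +
      at(nk$d3, 8) + at(nk$n4, 16) + at(nk$d4, 16) + at(nk$n5, 32) +
      m_flops(model$head, list(hw(8), hw(16), hw(32)))
  }
  2 * macs / 1e9
}
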
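# A compact CNN engine backing the detector: layer modules are environments
# holding weights, gradients and forward caches; composites (C2f, SPPF,
# MBModule, C2f_EL, BiFPN fusion nodes, detect head) recurse into children.
# Heavy kernels (convolution, batch norm, pooling) live in src/nn_ops.cpp.

BN_MOMENTUM <- 0.03
BN_EPS <- 1e-3

new_mod <- function(.cls, ...) {
  e <- new.env(parent = emptyenv())
  l <- list(...)
  for (n in names(l)) assign(n, l[[n]], envir = e)
  class(e) <- c(.cls, "dbx_mod")
  e
}

he_init <- function(k, c1, c2) {
  array(stats::rnorm(k * k * c1 * c2, 0, sqrt(2 / (k * k * c1))),
        c(k, k, c1, c2))
}

silu <- function(x) x / (1 + exp(-x))
silu_grad <- function(x, dy) {
  s <- 1 / (1 + exp(-x))
  dy * s * (1 + x * (1 - s))
}

acc_grad <- function(m, name, val) {
  g <- paste0("d", name)
  cur <- get0(g, envir = m, inherits = FALSE)
  assign(g, if (is.null(cur)) val else cur + val, envir = m)
}

cat_c <- function(xs) {
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], 0)
  y <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0
  for (x in xs) {
    y[, , at + seq_len(dim(x)[3]), ] <- x
    at <- at + dim(x)[3]
  }
  y
}

split_c <- function(x, sizes) {
  out <- vector("list", length(sizes))
  at <- 0
  for (i in seq_along(sizes)) {
    out[[i]] <- x[, , at + seq_len(sizes[i]), , drop = FALSE]
    at <- at + sizes[i]
  }
  out
}

# ---- primitive modules ------------------------------------------------------

mk_conv <- function(c1, c2, k = 1, s = 1, act = TRUE, bn = TRUE,
                    bias = !bn, first = FALSE) {
  m <- new_mod("conv", c1 = c1, c2 = c2, k = k, s = s, p = k %/% 2,
               act = act, bn = bn, first = first,
               W = he_init(k, c1, c2),
               pnames = c("W", if (bias) "b", if (bn) c("gamma", "beta")),
               children = list())
  if (bias) m$b <- numeric(c2)
  if (bn) {
    m$gamma <- rep(1, c2); m$beta <- numeric(c2)
    m$rmean <- numeric(c2); m$rvar <- rep(1, c2)
  }
  m
}

m_fwd <- function(m, x, train = FALSE) UseMethod("m_fwd")
m_bwd <- function(m, dy) UseMethod("m_bwd")
m_flops <- function(m, h, w) UseMethod("m_flops")

out_hw <- function(h, k, s) (h + 2 * (k %/% 2) - k) %/% s + 1

#' @export
m_fwd.conv <- function(m, x, train = FALSE) {
  m$x <- x
  z <- cpp_conv_fwd(x, m$W, if (is.null(m$b)) NULL else m$b, m$s, m$p)
  if (m$bn) {
    m$bn_in <- z
    r <- cpp_bn_fwd(z, m$gamma, m$beta, m$rmean, m$rvar, train,
                    BN_MOMENTUM, BN_EPS)
    if (train) { m$rmean <- r$rmean; m$rvar <- r$rvar }
    m$bn_mean <- r$mean; m$bn_invstd <- r$invstd
    z <- r$y
  }
  if (m$act) { m$act_in <- z; z <- silu(z) }
  z
}

#' @export
m_bwd.conv <- function(m, dy) {
  if (m$act) dy <- silu_grad(m$act_in, dy)
  if (m$bn) {
    r <- cpp_bn_bwd(m$bn_in, dy, m$gamma, m$bn_mean, m$bn_invstd)
    acc_grad(m, "gamma", r$dgamma); acc_grad(m, "beta", r$dbeta)
    dy <- r$dx
  }
  r <- cpp_conv_bwd(m$x, m$W, dy, m$s, m$p, !m$first, !is.null(m$b))
  acc_grad(m, "W", r$dw)
  if (!is.null(m$b)) acc_grad(m, "b", r$db)
  r$dx
}

#' @export
m_flops.conv <- function(m, h, w) {
  ho <- out_hw(h, m$k, m$s); wo <- out_hw(w, m$k, m$s)
  list(macs = as.numeric(m$c1) * m$c2 * m$k^2 * ho * wo, h = ho, w = wo)
}

mk_dwconv <- function(c, k, s = 1) {
  m <- new_mod("dwconv", c = c, k = k, s = s, p = k %/% 2,
               W = array(stats::rnorm(k * k * c, 0, sqrt(2 / (k * k))),
                         c(k, k, c)),
               gamma = rep(1, c), beta = numeric(c),
               rmean = numeric(c), rvar = rep(1, c),
               pnames = c("W", "gamma", "beta"), children = list())
  m
}

#' @export
m_fwd.dwconv <- function(m, x, train = FALSE) {
  m$x <- x
  z <- cpp_dw_fwd(x, m$W, m$s, m$p)
  m$bn_in <- z
  r <- cpp_bn_fwd(z, m$gamma, m$beta, m$rmean, m$rvar, train,
                  BN_MOMENTUM, BN_EPS)
  if (train) { m$rmean <- r$rmean; m$rvar <- r$rvar }
  m$bn_mean <- r$mean; m$bn_invstd <- r$invstd
  m$act_in <- r$y
  silu(r$y)
}

#' @export
m_bwd.dwconv <- function(m, dy) {
  dy <- silu_grad(m$act_in, dy)
  r <- cpp_bn_bwd(m$bn_in, dy, m$gamma, m$bn_mean, m$bn_invstd)
  acc_grad(m, "gamma", r$dgamma); acc_grad(m, "beta", r$dbeta)
  r2 <- cpp_dw_bwd(m$x, m$W, r$dx, m$s, m$p)
  acc_grad(m, "W", r2$dw)
  r2$dx
}

#' @export
m_flops.dwconv <- function(m, h, w) {
  ho <- out_hw(h, m$k, m$s); wo <- out_hw(w, m$k, m$s)
  list(macs = as.numeric(m$c) * m$k^2 * ho * wo, h = ho, w = wo)
}

# ---- composite blocks -------------------------------------------------------

mk_bottleneck <- function(c, shortcut = TRUE) {
  new_mod("bottleneck", add = shortcut,
          cv1 = mk_conv(c, c, 3), cv2 = mk_conv(c, c, 3),
          pnames = character(0), children = c("cv1", "cv2"))
}

#' @export
m_fwd.bottleneck <- function(m, x, train = FALSE) {
  y <- m_fwd(m$cv2, m_fwd(m$cv1, x, train), train)
  if (m$add) y + x else y
}

#' @export
m_bwd.bottleneck <- function(m, dy) {
  dx <- m_bwd(m$cv1, m_bwd(m$cv2, dy))
  if (m$add) dx + dy else dx
}

#' @export
m_flops.bottleneck <- function(m, h, w) {
  f1 <- m_flops(m$cv1, h, w); f2 <- m_flops(m$cv2, f1$h, f1$w)
  list(macs = f1$macs + f2$macs, h = f2$h, w = f2$w)
}

# C2f: split/transform/concat block with accumulated skip concatenations.
# `inner` builds one inner block on `hidden` channels (a Bottleneck for the
# reference layout, an ELModule for C2f_EL).
mk_c2f <- function(c1, c2, n, shortcut = TRUE, hidden = c2 %/% 2,
                   inner = function(h) mk_bottleneck(h, shortcut)) {
  m <- new_mod("c2f", n = n, hidden = hidden,
               cv1 = mk_conv(c1, 2 * hidden, 1),
               cv2 = mk_conv((2 + n) * hidden, c2, 1),
               pnames = character(0),
               children = c("cv1", "cv2", paste0("m", seq_len(n))))
  for (i in seq_len(n)) m[[paste0("m", i)]] <- inner(hidden)
  m
}

#' @export
m_fwd.c2f <- function(m, x, train = FALSE) {
  y1 <- m_fwd(m$cv1, x, train)
  ys <- split_c(y1, c(m$hidden, m$hidden))
  for (i in seq_len(m$n))
    ys[[i + 2]] <- m_fwd(m[[paste0("m", i)]], ys[[i + 1]], train)
  m_fwd(m$cv2, cat_c(ys), train)
}

#' @export
m_bwd.c2f <- function(m, dy) {
  dcat <- m_bwd(m$cv2, dy)
  dys <- split_c(dcat, rep(m$hidden, m$n + 2))
  for (i in rev(seq_len(m$n)))
    dys[[i + 1]] <- dys[[i + 1]] + m_bwd(m[[paste0("m", i)]], dys[[i + 2]])
  m_bwd(m$cv1, cat_c(dys[1:2]))
}

#' @export
m_flops.c2f <- function(m, h, w) {
  macs <- m_flops(m$cv1, h, w)$macs + m_flops(m$cv2, h, w)$macs
  for (i in seq_len(m$n)) macs <- macs + m_flops(m[[paste0("m", i)]], h, w)$macs
  list(macs = macs, h = h, w = w)
}

mk_sppf <- function(c1, c2, k = 5) {
  ch <- c1 %/% 2
  new_mod("sppf", k = k,
          cv1 = mk_conv(c1, ch, 1), cv2 = mk_conv(4 * ch, c2, 1),
          pnames = character(0), children = c("cv1", "cv2"))
}

#' @export
m_fwd.sppf <- function(m, x, train = FALSE) {
  x1 <- m_fwd(m$cv1, x, train)
  p <- k <- m$k
  r1 <- cpp_maxpool_fwd(x1, k, 1L, k %/% 2)
  r2 <- cpp_maxpool_fwd(r1$y, k, 1L, k %/% 2)
  r3 <- cpp_maxpool_fwd(r2$y, k, 1L, k %/% 2)
  m$idx <- list(r1$idx, r2$idx, r3$idx)
  m$xdim <- dim(x1)
  m_fwd(m$cv2, cat_c(list(x1, r1$y, r2$y, r3$y)), train)
}

#' @export
m_bwd.sppf <- function(m, dy) {
  dcat <- m_bwd(m$cv2, dy)
  ch <- m$xdim[3]
  d <- split_c(dcat, rep(ch, 4))
  dm2 <- d[[3]] + cpp_maxpool_bwd(d[[4]], m$idx[[3]], m$xdim)
  dm1 <- d[[2]] + cpp_maxpool_bwd(dm2, m$idx[[2]], m$xdim)
  dx1 <- d[[1]] + cpp_maxpool_bwd(dm1, m$idx[[1]], m$xdim)
  m_bwd(m$cv1, dx1)
}

#' @export
m_flops.sppf <- function(m, h, w) {
  list(macs = m_flops(m$cv1, h, w)$macs + m_flops(m$cv2, h, w)$macs,
       h = h, w = w)
}

# MBModule: split into three channel groups, depthwise-convolve each with
# its own kernel size, concatenate, channel-shuffle, then pointwise fuse.
shuffle_perm <- function(C, groups) {
  as.vector(t(matrix(seq_len(C), nrow = C %/% groups)))
}

mk_mb <- function(c, kernels, groups = 3) {
  if (c %% (3 * groups) != 0)
    stop("MBModule channels (", c, ") must be divisible by 3*groups = ",
         3 * groups)
  g <- c %/% 3
  perm <- shuffle_perm(c, groups)
  new_mod("mb", c = c, g = g, perm = perm, inv = order(perm),
          dw1 = mk_dwconv(g, kernels[1]), dw2 = mk_dwconv(g, kernels[2]),
          dw3 = mk_dwconv(g, kernels[3]), pw = mk_conv(c, c, 1),
          pnames = character(0), children = c("dw1", "dw2", "dw3", "pw"))
}

#' @export
m_fwd.mb <- function(m, x, train = FALSE) {
  xs <- split_c(x, rep(m$g, 3))
  y <- cat_c(list(m_fwd(m$dw1, xs[[1]], train),
                  m_fwd(m$dw2, xs[[2]], train),
                  m_fwd(m$dw3, xs[[3]], train)))
  y <- y[, , m$perm, , drop = FALSE]
  m_fwd(m$pw, y, train)
}

#' @export
m_bwd.mb <- function(m, dy) {
  d <- m_bwd(m$pw, dy)
  d <- d[, , m$inv, , drop = FALSE]
  ds <- split_c(d, rep(m$g, 3))
  cat_c(list(m_bwd(m$dw1, ds[[1]]), m_bwd(m$dw2, ds[[2]]),
             m_bwd(m$dw3, ds[[3]])))
}

#' @export
m_flops.mb <- function(m, h, w) {
  macs <- m_flops(m$dw1, h, w)$macs + m_flops(m$dw2, h, w)$macs +
    m_flops(m$dw3, h, w)$macs + m_flops(m$pw, h, w)$macs
  list(macs = macs, h = h, w = w)
}

# ELModule: MBModule with a residual add.
mk_el <- function(c, kernels, groups = 3) {
  new_mod("el", mb = mk_mb(c, kernels, groups),
          pnames = character(0), children = "mb")
}

#' @export
m_fwd.el <- function(m, x, train = FALSE) x + m_fwd(m$mb, x, train)
#' @export
m_bwd.el <- function(m, dy) dy + m_bwd(m$mb, dy)
#' @export
m_flops.el <- function(m, h, w) m_flops(m$mb, h, w)

mk_c2fel <- function(c1, c2, hidden, n, kernels, groups = 3) {
  mk_c2f(c1, c2, n, hidden = hidden,
         inner = function(h) mk_el(h, kernels, groups))
}

# BiFPN-style normalized weighted fusion of same-shape inputs:
# y = sum_i relu(w_i) x_i / (eps + sum_j relu(w_j)).
mk_fuse <- function(n_inputs, eps = 1e-4) {
  new_mod("fuse", w = rep(1, n_inputs), eps = eps,
          pnames = "w", children = list())
}

#' @export
m_fwd.fuse <- function(m, xs, train = FALSE) {
  r <- pmax(m$w, 0)
  S <- sum(r) + m$eps
  y <- xs[[1]] * (r[1] / S)
  for (i in seq_along(xs)[-1]) y <- y + xs[[i]] * (r[i] / S)
  m$xs <- xs; m$y <- y; m$r <- r; m$S <- S
  y
}

#' @export
m_bwd.fuse <- function(m, dy) {
  dr <- vapply(m$xs, function(x) sum(dy * (x - m$y)) / m$S, 0)
  acc_grad(m, "w", dr * (m$w > 0))
  lapply(seq_along(m$xs), function(i) dy * (m$r[i] / m$S))
}

# DW stride-2 + pointwise down-adapter.
mk_down <- function(c1, c2, k = 3) {
  new_mod("down", dw = mk_dwconv(c1, k, s = 2), pw = mk_conv(c1, c2, 1),
          pnames = character(0), children = c("dw", "pw"))
}

#' @export
m_fwd.down <- function(m, x, train = FALSE)
  m_fwd(m$pw, m_fwd(m$dw, x, train), train)
#' @export
m_bwd.down <- function(m, dy) m_bwd(m$dw, m_bwd(m$pw, dy))
#' @export
m_flops.down <- function(m, h, w) {
  f1 <- m_flops(m$dw, h, w)
  f2 <- m_flops(m$pw, f1$h, f1$w)
  list(macs = f1$macs + f2$macs, h = f2$h, w = f2$w)
}

# ---- detect head ------------------------------------------------------------

# Anchor-free decoupled head: per scale a box branch predicting 4*reg_max
# distribution logits and a class branch predicting nc logits. The DFL
# projection (0..reg_max-1) is a frozen parameter, counted but not trained.
mk_head <- function(ch, nc, reg_max = 16) {
  c2 <- max(16, ch[1] %/% 4, reg_max * 4)
  c3 <- max(ch[1], min(nc, 100))
  m <- new_mod("head", nc = nc, reg_max = reg_max, nl = length(ch),
               proj = as.numeric(0:(reg_max - 1)), frozen_pnames = "proj",
               pnames = character(0), children = character(0))
  for (i in seq_along(ch)) {
    bb <- paste0("box", i); cc <- paste0("cls", i)
    m[[paste0(bb, "_1")]] <- mk_conv(ch[i], c2, 3)
    m[[paste0(bb, "_2")]] <- mk_conv(c2, c2, 3)
    m[[paste0(bb, "_3")]] <- mk_conv(c2, 4 * reg_max, 1, act = FALSE,
                                     bn = FALSE, bias = TRUE)
    m[[paste0(cc, "_1")]] <- mk_conv(ch[i], c3, 3)
    m[[paste0(cc, "_2")]] <- mk_conv(c3, c3, 3)
    m[[paste0(cc, "_3")]] <- mk_conv(c3, nc, 1, act = FALSE, bn = FALSE,
                                     bias = TRUE)
    # bias priors: boxes start near the anchor, classes near rare-positive
    m[[paste0(bb, "_3")]]$b <- rep(1, 4 * reg_max)
    m[[paste0(cc, "_3")]]$b <- rep(-4.6, nc)
    m$children <- c(m$children, paste0(bb, "_", 1:3), paste0(cc, "_", 1:3))
  }
  m
}

#' @export
m_fwd.head <- function(m, xs, train = FALSE) {
  lapply(seq_len(m$nl), function(i) {
    list(box = m_fwd(m[[paste0("box", i, "_3")]],
                     m_fwd(m[[paste0("box", i, "_2")]],
                           m_fwd(m[[paste0("box", i, "_1")]], xs[[i]], train),
                           train), train),
         cls = m_fwd(m[[paste0("cls", i, "_3")]],
                     m_fwd(m[[paste0("cls", i, "_2")]],
                           m_fwd(m[[paste0("cls", i, "_1")]], xs[[i]], train),
                           train), train))
  })
}

#' @export
m_bwd.head <- function(m, dys) {
  lapply(seq_len(m$nl), function(i) {
    db <- m_bwd(m[[paste0("box", i, "_1")]],
                m_bwd(m[[paste0("box", i, "_2")]],
                      m_bwd(m[[paste0("box", i, "_3")]], dys[[i]]$box)))
    dc <- m_bwd(m[[paste0("cls", i, "_1")]],
                m_bwd(m[[paste0("cls", i, "_2")]],
                      m_bwd(m[[paste0("cls", i, "_3")]], dys[[i]]$cls)))
    db + dc
  })
}

#' @export
m_flops.head <- function(m, hws) {
  macs <- 0
  for (i in seq_len(m$nl)) {
    h <- hws[[i]][1]; w <- hws[[i]][2]
    for (nm in c(paste0("box", i, "_", 1:3), paste0("cls", i, "_", 1:3)))
      macs <- macs + m_flops(m[[nm]], h, w)$macs
  }
  macs
}

# ---- parameter walk, optimizer ----------------------------------------------

walk_mods <- function(m, fn) {
  fn(m)
  for (ch in m$children) walk_mods(m[[ch]], fn)
  invisible()
}

net_mods <- function(net) {
  roots <- net$mods
  out <- list()
  for (r in roots) walk_mods(r, function(m) out[[length(out) + 1]] <<- m)
  out
}

#' Count model parameters
#'
#' Sums all parameters: convolution weights and biases, batch-norm affine
#' terms, fusion weights, and the frozen distribution-focal-loss projection
#' (16 values). Batch-norm running statistics are buffers and excluded.
#'
#' @param model a model built with [build_model()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  tot <- 0
  for (m in net_mods(model)) {
    for (p in m$pnames) tot <- tot + length(m[[p]])
    for (p in m$frozen_pnames) tot <- tot + length(m[[p]])
  }
  tot
}

zero_grads <- function(model) {
  for (m in net_mods(model))
    for (p in m$pnames) assign(paste0("d", p), NULL, envir = m)
  invisible()
}

#' Adam optimizer step over all trainable parameters
#'
#' @param model built model.
#' @param lr learning rate.
#' @param betas momentum coefficients.
#' @param eps numerical floor.
#' @keywords internal
adam_step <- function(model, lr = 0.01, betas = c(0.9, 0.999),
                      eps = 1e-8) {
  model$adam_t <- (model$adam_t %||% 0) + 1
  t <- model$adam_t
  b1 <- betas[1]; b2 <- betas[2]
  for (m in net_mods(model)) {
    for (p in m$pnames) {
      g <- m[[paste0("d", p)]]
      if (is.null(g)) next
      mk <- paste0("adam_m_", p); vk <- paste0("adam_v_", p)
      mo <- get0(mk, envir = m, inherits = FALSE) %||% (g * 0)
      vo <- get0(vk, envir = m, inherits = FALSE) %||% (g * 0)
      mo <- b1 * mo + (1 - b1) * g
      vo <- b2 * vo + (1 - b2) * g^2
      assign(mk, mo, envir = m); assign(vk, vo, envir = m)
      mhat <- mo / (1 - b1^t); vhat <- vo / (1 - b2^t)
      m[[p]] <- m[[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
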
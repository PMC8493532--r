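# Minimal CNN engine: plain-R layer objects with explicit forward/backward
# passes and Adam. Feature maps are arrays dim (H, W, C); convolution is
# im2col (C++) + BLAS gemm. This engine backs both the U-Net used for
# segmentation and the CycleGAN-style generators/discriminators.

nn_conv <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = 1L,
                    gain = sqrt(2)) {
  fan_in <- k * k * in_ch
  list(type = "conv",
       W = matrix(stats::rnorm(out_ch * fan_in, sd = gain / sqrt(fan_in)),
                  nrow = out_ch),
       b = numeric(out_ch),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       in_ch = as.integer(in_ch), out_ch = as.integer(out_ch))
}

nn_relu  <- function() list(type = "relu")
nn_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
nn_sigmoid <- function() list(type = "sigmoid")
nn_inorm <- function(ch) {
  list(type = "inorm", gamma = rep(1, ch), beta = numeric(ch), eps = 1e-5)
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      d <- dim(x)
      cols <- .im2col(x, d[1], d[2], d[3], layer$k, layer$stride, layer$pad)
      ho <- (d[1] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
      wo <- (d[2] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
      y <- tcrossprod(cols, layer$W)  # (Ho*Wo) x out_ch
      y <- sweep(y, 2, layer$b, `+`)
      list(out = array(y, c(ho, wo, layer$out_ch)),
           cache = list(cols = cols, dims = d))
    },
    relu = {
      m <- x > 0
      list(out = x * m, cache = m)
    },
    lrelu = {
      m <- x > 0
      list(out = ifelse(m, x, layer$alpha * x), cache = m)
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(out = y, cache = y)
    },
    inorm = {
      d <- dim(x)
      xm <- matrix(x, d[1] * d[2], d[3])
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      va <- colMeans(xc^2)
      isd <- 1 / sqrt(va + layer$eps)
      xhat <- sweep(xc, 2, isd, `*`)
      y <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
      list(out = array(y, d), cache = list(xhat = xhat, isd = isd, dims = d))
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      d <- cache$dims
      n <- prod(dim(dout)[1:2])
      dY <- matrix(dout, n, layer$out_ch)
      dW <- crossprod(dY, cache$cols)
      db <- colSums(dY)
      dcols <- dY %*% layer$W
      dx <- .col2im(dcols, d[1], d[2], d[3], layer$k, layer$stride, layer$pad)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    relu = list(dx = dout * cache, grads = NULL),
    lrelu = list(dx = ifelse(cache, dout, layer$alpha * dout), grads = NULL),
    sigmoid = list(dx = dout * cache * (1 - cache), grads = NULL),
    inorm = {
      d <- cache$dims
      n <- d[1] * d[2]
      dy <- matrix(dout, n, d[3])
      dgamma <- colSums(dy * cache$xhat)
      dbeta <- colSums(dy)
      dxhat <- sweep(dy, 2, layer$gamma, `*`)
      # dx = isd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
      dx <- sweep(t1 - t2, 2, cache$isd, `*`)
      list(dx = array(dx, d), grads = list(gamma = dgamma, beta = dbeta))
    },
    stop("unknown layer type: ", layer$type))
}

seq_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

seq_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)  # keep NULL placeholders for activation layers
  }
  list(dx = dout, grads = grads)
}

up2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

up2_backward <- function(dout) {
  d <- dim(dout)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  dout[i1, j1, , drop = FALSE] + dout[i2, j1, , drop = FALSE] +
    dout[i1, j2, , drop = FALSE] + dout[i2, j2, , drop = FALSE]
}

cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

# ---- U-Net ------------------------------------------------------------------

#' Construct a U-Net
#'
#' Encoder-decoder convolutional network with skip connections; the same
#' architecture serves as the segmentation network and as the generator of
#' the unpaired image transform. `levels` counts the down-sampling steps, so
#' input height and width must be divisible by `2^levels`.
#'
#' @param in_ch,out_ch input / output channel counts.
#' @param levels number of 2x down-sampling levels.
#' @param base channels of the first encoder block; doubled per level and
#'   capped at `8 * base`.
#' @param final `"logits"` (identity), `"sigmoid"` for images in `[0,1]`.
#' @param norm use instance normalisation in the conv blocks.
#' @return an opaque network object for [unet_forward()].
#' @keywords internal
unet_new <- function(in_ch, out_ch, levels = 3L, base = 8L,
                     final = c("logits", "sigmoid"), norm = FALSE) {
  final <- match.arg(final)
  ch <- pmin(base * 2^(seq_len(levels + 1L) - 1L), base * 8L)
  block <- function(ci, co) {
    ly <- list(nn_conv(ci, co))
    if (norm) ly <- c(ly, list(nn_inorm(co)))
    ly <- c(ly, list(nn_relu()), list(nn_conv(co, co)))
    if (norm) ly <- c(ly, list(nn_inorm(co)))
    c(ly, list(nn_relu()))
  }
  enc <- vector("list", levels)
  ci <- in_ch
  for (l in seq_len(levels)) {
    enc[[l]] <- block(ci, ch[l])
    ci <- ch[l]
  }
  dec <- vector("list", levels)
  for (l in seq_len(levels)) {
    dec[[l]] <- list(up = list(nn_conv(ch[l + 1L], ch[l]), nn_relu()),
                     block = block(2L * ch[l], ch[l]))
  }
  structure(list(enc = enc, bottleneck = block(ch[levels], ch[levels + 1L]),
                 dec = dec, head = list(nn_conv(ch[1L], out_ch, k = 1L, pad = 0L,
                                                gain = 1)),
                 levels = levels, in_ch = in_ch, out_ch = out_ch,
                 final = final),
            class = "ef_unet")
}

unet_forward <- function(net, x, want_cache = FALSE) {
  d <- dim(x)
  if (d[1] %% 2^net$levels != 0L || d[2] %% 2^net$levels != 0L)
    stop("input size ", d[1], "x", d[2], " not divisible by 2^",
         net$levels, " (down-sampling levels)")
  if (d[3] != net$in_ch) stop("expected ", net$in_ch, " input channels")
  skips <- vector("list", net$levels)
  ec <- vector("list", net$levels)
  pool_arg <- vector("list", net$levels)
  for (l in seq_len(net$levels)) {
    r <- seq_forward(net$enc[[l]], x)
    skips[[l]] <- r$out
    ec[[l]] <- r$caches
    dp <- dim(r$out)
    mp <- .maxpool2(r$out, dp[1], dp[2], dp[3])
    x <- mp$out
    pool_arg[[l]] <- list(argmax = mp$argmax, dims = dp)
  }
  rb <- seq_forward(net$bottleneck, x)
  x <- rb$out
  dc <- vector("list", net$levels)
  for (l in rev(seq_len(net$levels))) {
    xu <- up2(x)
    ru <- seq_forward(net$dec[[l]]$up, xu)
    xc <- cat_ch(skips[[l]], ru$out)
    rk <- seq_forward(net$dec[[l]]$block, xc)
    x <- rk$out
    dc[[l]] <- list(up = ru$caches, block = rk$caches,
                    skip_ch = dim(skips[[l]])[3])
  }
  rh <- seq_forward(net$head, x)
  out <- rh$out
  sig <- NULL
  if (net$final == "sigmoid") {
    out <- 1 / (1 + exp(-out))
    sig <- out
  }
  if (!want_cache) return(out)
  list(out = out,
       cache = list(ec = ec, pool = pool_arg, bc = rb$caches, dc = dc,
                    hc = rh$caches, sig = sig))
}

unet_backward <- function(net, cache, dout) {
  if (net$final == "sigmoid") dout <- dout * cache$sig * (1 - cache$sig)
  g <- list(enc = vector("list", net$levels), bottleneck = NULL,
            dec = vector("list", net$levels), head = NULL)
  rh <- seq_backward(net$head, cache$hc, dout)
  g$head <- rh$grads
  dx <- rh$dx
  dskip <- vector("list", net$levels)
  for (l in seq_len(net$levels)) {
    rk <- seq_backward(net$dec[[l]]$block, cache$dc[[l]]$block, dx)
    sc <- cache$dc[[l]]$skip_ch
    dd <- dim(rk$dx)
    dskip[[l]] <- rk$dx[, , seq_len(sc), drop = FALSE]
    dup <- rk$dx[, , sc + seq_len(dd[3] - sc), drop = FALSE]
    ru <- seq_backward(net$dec[[l]]$up, cache$dc[[l]]$up, dup)
    dx <- up2_backward(ru$dx)
    g$dec[[l]] <- list(up = ru$grads, block = rk$grads)
  }
  rb <- seq_backward(net$bottleneck, cache$bc, dx)
  g$bottleneck <- rb$grads
  dx <- rb$dx
  for (l in rev(seq_len(net$levels))) {
    pa <- cache$pool[[l]]
    dpool <- .maxpool2_backward(dx, pa$argmax, pa$dims[1], pa$dims[2],
                                pa$dims[3])
    re <- seq_backward(net$enc[[l]], cache$ec[[l]], dpool + dskip[[l]])
    g$enc[[l]] <- re$grads
    dx <- re$dx
  }
  list(dx = dx, grads = g)
}

# ---- patch discriminator ----------------------------------------------------

disc_new <- function(in_ch, base = 8L, n_down = 2L) {
  ly <- list(nn_conv(in_ch, base, k = 4L, stride = 2L, pad = 1L), nn_lrelu())
  ch <- base
  for (i in seq_len(n_down - 1L)) {
    ly <- c(ly, list(nn_conv(ch, 2L * ch, k = 4L, stride = 2L, pad = 1L),
                     nn_lrelu()))
    ch <- 2L * ch
  }
  structure(list(layers = c(ly, list(nn_conv(ch, 1L, k = 1L, pad = 0L,
                                             gain = 1)))),
            class = "ef_disc")
}

disc_forward <- function(net, x, want_cache = FALSE) {
  r <- seq_forward(net$layers, x)
  if (!want_cache) return(r$out)
  r
}

disc_backward <- function(net, caches, dout) {
  r <- seq_backward(net$layers, caches, dout)
  list(dx = r$dx, grads = list(layers = r$grads))
}

# ---- losses -----------------------------------------------------------------

ce_loss <- function(logits, labels) {
  d <- dim(logits)
  n <- d[1] * d[2]
  lm <- matrix(logits, n, d[3])
  lm <- lm - apply(lm, 1, max)
  el <- exp(lm)
  p <- el / rowSums(el)
  idx <- cbind(seq_len(n), as.integer(labels) + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dp <- p
  dp[idx] <- dp[idx] - 1
  list(loss = loss, dlogits = array(dp / n, d))
}

l1_loss <- function(a, b) {
  n <- length(a)
  list(loss = mean(abs(a - b)), da = array(sign(a - b) / n, dim(a)))
}

mse_loss <- function(a, target) {
  n <- length(a)
  list(loss = mean((a - target)^2), da = array(2 * (a - target) / n, dim(a)))
}

# ---- recursive parameter utilities (Adam, grad accumulation) ----------------

is_param_layer <- function(x) {
  is.list(x) && !is.null(x$type) && x$type %in% c("conv", "inorm")
}

param_names <- function(layer) {
  if (layer$type == "conv") c("W", "b") else c("gamma", "beta")
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  # a[i] <- list(...) keeps NULL placeholders (a[[i]] <- NULL would drop them)
  for (i in seq_along(a)) a[i] <- list(grads_add(a[[i]], b[[i]]))
  a
}

grads_scale <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.numeric(g)) return(g * s)
  for (i in seq_along(g)) g[i] <- list(grads_scale(g[[i]], s))
  g
}

adam_state <- function() list(t = 0L, m = NULL, v = NULL)

# One Adam step over every param layer of `net` using a grads tree that
# mirrors the net structure (NULL where a node has no parameters).
adam_step <- function(net, grads, state, lr = 2e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(node, g, m, v) {
    if (is.null(g)) return(list(node = node, m = m, v = v))
    if (is_param_layer(node)) {
      for (p in param_names(node)) {
        if (is.null(g[[p]])) next
        gm <- if (is.null(m[[p]])) 0 * node[[p]] else m[[p]]
        gv <- if (is.null(v[[p]])) 0 * node[[p]] else v[[p]]
        gm <- beta1 * gm + (1 - beta1) * g[[p]]
        gv <- beta2 * gv + (1 - beta2) * g[[p]]^2
        node[[p]] <- node[[p]] - lr * (gm / bc1) / (sqrt(gv / bc2) + eps)
        if (is.null(m)) m <- list()
        if (is.null(v)) v <- list()
        m[[p]] <- gm
        v[[p]] <- gv
      }
      return(list(node = node, m = m, v = v))
    }
    if (is.list(node)) {
      if (is.null(m)) m <- vector("list", length(node))
      if (is.null(v)) v <- vector("list", length(node))
      for (i in seq_along(g)) {
        nm <- if (!is.null(names(g))) names(g)[i] else NULL
        j <- if (!is.null(nm) && nzchar(nm)) nm else i
        if (is.null(g[[i]])) next
        r <- upd(node[[j]], g[[i]], m[[j]], v[[j]])
        node[[j]] <- r$node
        m[[j]] <- r$m
        v[[j]] <- r$v
      }
      return(list(node = node, m = m, v = v))
    }
    list(node = node, m = m, v = v)
  }
  r <- upd(unclass(net), grads, state$m, state$v)
  state$m <- r$m
  state$v <- r$v
  net2 <- r$node
  class(net2) <- class(net)
  list(net = net2, state = state)
}
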
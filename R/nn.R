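# Minimal differentiable CNN machinery.
#
# All tensors are (H, W, C) arrays for one 2D slice. Convolutions are 3x3,
# stride 1, zero-padded ("same"), implemented as im2col matrix products so
# that both the forward pass and the exact reverse-mode gradients (with
# respect to weights AND input) are plain BLAS calls. The input gradient is
# what the adversarial-noise generator ascends.

# Cache of im2col index matrices keyed by geometry (they only depend on
# H, W, Cin).
.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(H, W, C) {
  key <- paste(H, W, C, sep = "x")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2L; Wp <- W + 2L
  i <- rep(seq_len(H), times = W)        # output pixel rows
  j <- rep(seq_len(W), each = H)
  cols <- vector("list", 9L * C)
  n <- 0L
  for (cc in seq_len(C)) {
    off_c <- (cc - 1L) * Hp * Wp
    for (dj in 0:2) for (di in 0:2) {
      n <- n + 1L
      cols[[n]] <- (i + di) + (j + dj - 1L) * Hp + off_c
    }
  }
  idx <- do.call(cbind, cols)
  .im2col_cache[[key]] <- idx
  idx
}

pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L, d[2] + 2L, d[3]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  out
}

conv_init <- function(in_ch, out_ch) {
  fan_in <- 9L * in_ch
  list(W = matrix(stats::rnorm(fan_in * out_ch, 0, sqrt(2 / fan_in)),
                  fan_in, out_ch),
       b = numeric(out_ch))
}

conv_forward <- function(x, layer) {
  d <- dim(x)
  X <- pad1(x)
  dim(X) <- NULL
  Xc <- matrix(X[im2col_idx(d[1], d[2], d[3])], d[1] * d[2], 9L * d[3])
  Y <- Xc %*% layer$W
  Y <- sweep(Y, 2L, layer$b, `+`)
  out <- array(Y, dim = c(d[1], d[2], ncol(layer$W)))
  list(out = out, Xc = Xc, in_dim = d)
}

conv_backward <- function(gY, cache, layer) {
  d <- cache$in_dim
  H <- d[1]; W <- d[2]; C <- d[3]
  gYm <- matrix(gY, H * W, dim(gY)[3])
  gW <- crossprod(cache$Xc, gYm)
  gb <- colSums(gYm)
  M <- tcrossprod(gYm, layer$W)                 # (H*W) x (9*C)
  gxp <- array(0, dim = c(H + 2L, W + 2L, C))
  for (dj in 0:2) for (di in 0:2) {
    colsel <- (seq_len(C) - 1L) * 9L + dj * 3L + di + 1L
    gxp[(1:H) + di, (1:W) + dj, ] <-
      gxp[(1:H) + di, (1:W) + dj, , drop = FALSE] +
      array(M[, colsel], dim = c(H, W, C))
  }
  list(gW = gW, gb = gb, gX = gxp[2:(H + 1L), 2:(W + 1L), , drop = FALSE])
}

# leaky ReLU (negative slope 0.1, the nnU-Net convention): keeps a gradient
# path through inactive units so early loss spikes cannot permanently kill
# feature channels.
relu_forward <- function(x) {
  pos <- x > 0
  list(out = ifelse(pos, x, 0.1 * x), mask = pos)
}
relu_backward <- function(gY, cache) gY * ifelse(cache$mask, 1, 0.1)

# 2x2 average pooling; H and W must be even.
pool_forward <- function(x) {
  d <- dim(x)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  x5 <- array(x, dim = c(2L, H2, 2L, W2, d[3]))
  out <- (x5[1, , 1, , , drop = FALSE] + x5[2, , 1, , , drop = FALSE] +
            x5[1, , 2, , , drop = FALSE] + x5[2, , 2, , , drop = FALSE]) / 4
  list(out = array(out, dim = c(H2, W2, d[3])), in_dim = d)
}
pool_backward <- function(gY, cache) {
  d <- cache$in_dim
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  g5 <- array(0, dim = c(2L, H2, 2L, W2, d[3]))
  q <- array(gY / 4, dim = c(1L, H2, 1L, W2, d[3]))
  for (a in 1:2) for (b in 1:2) g5[a, , b, , ] <- q
  array(g5, dim = d)
}

# nearest-neighbour 2x upsampling
upsample_forward <- function(x) {
  d <- dim(x)
  g5 <- array(0, dim = c(2L, d[1], 2L, d[2], d[3]))
  q <- array(x, dim = c(1L, d[1], 1L, d[2], d[3]))
  for (a in 1:2) for (b in 1:2) g5[a, , b, , ] <- q
  list(out = array(g5, dim = c(2L * d[1], 2L * d[2], d[3])), in_dim = d)
}
upsample_backward <- function(gY, cache) {
  d <- cache$in_dim
  g5 <- array(gY, dim = c(2L, d[1], 2L, d[2], d[3]))
  array(g5[1, , 1, , ] + g5[2, , 1, , ] + g5[1, , 2, , ] + g5[2, , 2, , ],
        dim = d)
}

# ---- U-Net: two resolution levels, skip connection -------------------------

# `out_bias` initializes the output layer's bias; a negative value encodes
# a low foreground prior so a detector starts as a confident background
# predictor and learns lesions from the (rebalanced) positive gradients
# instead of first sweeping every logit down.
#' @keywords internal
unet_init <- function(in_ch, out_ch, width, seed, out_bias = 0) {
  w <- as.integer(width)
  params <- with_seed(seed, list(
    conv1 = conv_init(in_ch, w),
    conv2 = conv_init(w, w),
    conv3 = conv_init(w, 2L * w),
    conv4 = conv_init(2L * w, 2L * w),
    conv5 = conv_init(3L * w, w),
    conv6 = conv_init(w, out_ch)))
  params$conv6$b <- rep(out_bias, out_ch)
  params
}

unet_forward <- function(params, x) {
  c1 <- conv_forward(x, params$conv1);  r1 <- relu_forward(c1$out)
  c2 <- conv_forward(r1$out, params$conv2); r2 <- relu_forward(c2$out)
  p1 <- pool_forward(r2$out)
  c3 <- conv_forward(p1$out, params$conv3); r3 <- relu_forward(c3$out)
  c4 <- conv_forward(r3$out, params$conv4); r4 <- relu_forward(c4$out)
  u1 <- upsample_forward(r4$out)
  skip_ch <- dim(r2$out)[3]
  cat <- array(c(r2$out, u1$out),
               dim = c(dim(r2$out)[1], dim(r2$out)[2],
                       skip_ch + dim(u1$out)[3]))
  c5 <- conv_forward(cat, params$conv5); r5 <- relu_forward(c5$out)
  c6 <- conv_forward(r5$out, params$conv6)
  list(out = c6$out,
       cache = list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, p1 = p1, c3 = c3,
                    r3 = r3, c4 = c4, r4 = r4, u1 = u1, skip_ch = skip_ch,
                    c5 = c5, r5 = r5, c6 = c6))
}

unet_backward <- function(params, cache, gOut) {
  b6 <- conv_backward(gOut, cache$c6, params$conv6)
  g <- relu_backward(b6$gX, cache$r5)
  b5 <- conv_backward(g, cache$c5, params$conv5)
  sk <- cache$skip_ch
  g_skip <- b5$gX[, , seq_len(sk), drop = FALSE]
  g_up <- b5$gX[, , (sk + 1L):dim(b5$gX)[3], drop = FALSE]
  g <- upsample_backward(g_up, cache$u1)
  g <- relu_backward(g, cache$r4)
  b4 <- conv_backward(g, cache$c4, params$conv4)
  g <- relu_backward(b4$gX, cache$r3)
  b3 <- conv_backward(g, cache$c3, params$conv3)
  g <- pool_backward(b3$gX, cache$p1)
  g <- g + g_skip
  g <- relu_backward(g, cache$r2)
  b2 <- conv_backward(g, cache$c2, params$conv2)
  g <- relu_backward(b2$gX, cache$r1)
  b1 <- conv_backward(g, cache$c1, params$conv1)
  list(grads = list(conv1 = b1[c("gW", "gb")], conv2 = b2[c("gW", "gb")],
                    conv3 = b3[c("gW", "gb")], conv4 = b4[c("gW", "gb")],
                    conv5 = b5[c("gW", "gb")], conv6 = b6[c("gW", "gb")]),
       gX = b1$gX)
}

# ---- losses ----------------------------------------------------------------

softmax3 <- function(logits) {
  m <- pmax(logits[, , 1], logits[, , 2], logits[, , 3])
  e <- exp(logits - array(m, dim = dim(logits)))
  s <- e[, , 1] + e[, , 2] + e[, , 3]
  e / array(s, dim = dim(logits))
}

# Multi-class loss: cross-entropy + soft-Dice over non-background classes.
# `target` is an integer (H, W) map of class ids 1..3 (1 = background).
# Returns loss value and gradient with respect to the logits.
softmax_dice_ce_loss <- function(logits, target, w_ce = 1, w_dice = 1,
                                 eps = 1) {
  d <- dim(logits)
  p <- softmax3(logits)
  n <- d[1] * d[2]
  onehot <- array(0, dim = d)
  for (k in 1:3) onehot[, , k] <- (target == k)
  ce <- -sum(onehot * log(pmax(p, 1e-12))) / n
  g_ce <- (p - onehot) / n

  # soft Dice per foreground class k: (2*sum(p_k t_k)+eps)/(sum p_k + sum t_k + eps)
  dice_val <- 0; g_p <- array(0, dim = d)
  for (k in 2:3) {
    pk <- p[, , k]; tk <- onehot[, , k]
    num <- 2 * sum(pk * tk) + eps
    den <- sum(pk) + sum(tk) + eps
    dice_val <- dice_val + num / den
    g_p[, , k] <- -(2 * tk * den - num) / den^2 / 2    # d(1 - mean dice)/dp_k
  }
  dice_loss <- 1 - dice_val / 2
  # softmax jacobian: g_logits = p * (g_p - sum_k g_p * p)
  inner <- g_p[, , 1] * p[, , 1] + g_p[, , 2] * p[, , 2] + g_p[, , 3] * p[, , 3]
  g_dice <- p * (g_p - array(inner, dim = d))
  list(loss = w_ce * ce + w_dice * dice_loss,
       grad = w_ce * g_ce + w_dice * g_dice)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Binary loss: class-weighted BCE + soft Dice on a single-channel logit map
# against a logical/0-1 target map. `pos_weight` rebalances the voxel-wise
# cross-entropy toward the (rare) lesion class so that tiny foregrounds are
# not drowned out by the background term. Returns value and gradient wrt
# the logits.
binary_dice_bce_loss <- function(logits, target, w_ce = 1, w_dice = 1,
                                 pos_weight = 1, eps = 1) {
  p <- sigmoid(logits)
  t <- array(as.numeric(target), dim = dim(logits))
  n <- length(p)
  bce <- -sum(pos_weight * t * log(pmax(p, 1e-12)) +
                (1 - t) * log(pmax(1 - p, 1e-12))) / n
  g_bce <- (p * (1 + (pos_weight - 1) * t) - pos_weight * t) / n
  num <- 2 * sum(p * t) + eps
  den <- sum(p) + sum(t) + eps
  dice_loss <- 1 - num / den
  g_dice_p <- -(2 * t * den - num) / den^2
  g_p <- w_dice * g_dice_p
  g_logits <- w_ce * g_bce + g_p * p * (1 - p)
  list(loss = w_ce * bce + w_dice * dice_loss, grad = g_logits)
}

# ---- Adam optimizer --------------------------------------------------------

adam_init <- function(params) {
  st <- lapply(params, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  st$t <- 0L
  st
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    s <- state[[nm]]; g <- grads[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$gW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$gW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$gb
    s$vb <- beta2 * s$vb + (1 - beta2) * g$gb^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / corr1) /
      (sqrt(s$vW / corr2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / corr1) /
      (sqrt(s$vb / corr2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}
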
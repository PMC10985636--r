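# Fixed convolutional feature extractor used by the style / content
# constraints of the noise generator. Three conv-relu blocks with 2x2
# pooling between blocks; the first two blocks are the style layers S
# (shallow, texture-sensitive), the last block is the content layer set C
# (deeper, semantics-sensitive). Weights are frozen, seeded at creation,
# and the extractor is pluggable: any object with the same forward/backward
# contract can stand in.

#' Create a frozen feature extractor
#'
#' @param in_ch number of input channels (3 for T2W/DWI/ADC stacks).
#' @param widths channel widths of the three blocks.
#' @param seed integer; weights are a deterministic function of it.
#' @return an object of class `feature_extractor` with style layers
#'   `c("block1", "block2")` and content layers `"block3"`.
#' @export
feature_extractor <- function(in_ch = 3L, widths = c(8L, 12L, 16L),
                              seed = 42L) {
  stopifnot(length(widths) == 3L)
  params <- with_seed(seed, list(
    conv1 = conv_init(in_ch, widths[1]),
    conv2 = conv_init(widths[1], widths[2]),
    conv3 = conv_init(widths[2], widths[3])))
  structure(list(params = params, in_ch = as.integer(in_ch),
                 widths = as.integer(widths), seed = as.integer(seed),
                 style_layers = c("block1", "block2"),
                 content_layers = "block3"),
            class = "feature_extractor")
}

# Forward pass; returns per-block feature maps and caches for backward.
extractor_forward <- function(ext, x) {
  c1 <- conv_forward(x, ext$params$conv1); r1 <- relu_forward(c1$out)
  p1 <- pool_forward(r1$out)
  c2 <- conv_forward(p1$out, ext$params$conv2); r2 <- relu_forward(c2$out)
  p2 <- pool_forward(r2$out)
  c3 <- conv_forward(p2$out, ext$params$conv3); r3 <- relu_forward(c3$out)
  list(features = list(block1 = r1$out, block2 = r2$out, block3 = r3$out),
       cache = list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                    c3 = c3, r3 = r3))
}

# Backward from per-block feature gradients to the input gradient.
# Any of g1/g2/g3 may be NULL (treated as zero).
extractor_backward <- function(ext, cache, g1 = NULL, g2 = NULL, g3 = NULL) {
  zero_like <- function(a) array(0, dim = dim(a))
  g <- if (is.null(g3)) zero_like(cache$r3$out) else g3
  g <- relu_backward(g, cache$r3)
  g <- conv_backward(g, cache$c3, ext$params$conv3)$gX
  g <- pool_backward(g, cache$p2)
  if (!is.null(g2)) g <- g + g2
  g <- relu_backward(g, cache$r2)
  g <- conv_backward(g, cache$c2, ext$params$conv2)$gX
  g <- pool_backward(g, cache$p1)
  if (!is.null(g1)) g <- g + g1
  g <- relu_backward(g, cache$r1)
  conv_backward(g, cache$c1, ext$params$conv1)$gX
}

# Gram matrix of a (H, W, C) feature map, normalized by the number of
# spatial positions: G = F'F / N with F the (N x C) unrolled features.
gram_matrix <- function(f) {
  d <- dim(f)
  Fm <- matrix(f, d[1] * d[2], d[3])
  crossprod(Fm) / (d[1] * d[2])
}

#' Style distance between an image and a style exemplar
#'
#' Sum over the extractor's style layers of the squared Frobenius distance
#' between position-normalized Gram matrices. Zero iff the Gram matrices
#' agree at every style layer; invariant to spatial permutation of feature
#' positions.
#'
#' @param x_adv `(H, W, C)` image array (normalized intensities).
#' @param style_sample `(H, W, C)` exemplar array, or a `style_sample`
#'   object.
#' @param extractor a [feature_extractor()].
#' @return nonnegative scalar.
#' @export
style_distance <- function(x_adv, style_sample, extractor) {
  if (inherits(style_sample, "style_sample")) style_sample <- style_sample$x
  if (length(extractor$style_layers) == 0L) stopf("empty style layer set")
  fa <- extractor_forward(extractor, x_adv)$features
  fs <- extractor_forward(extractor, style_sample)$features
  tot <- 0
  for (ly in extractor$style_layers)
    tot <- tot + sum((gram_matrix(fa[[ly]]) - gram_matrix(fs[[ly]]))^2)
  tot
}

#' Content distance between two images under the extractor
#'
#' Sum over the content layers of the mean squared difference of deep
#' features; zero iff the deep features are identical.
#'
#' @param x_adv,x_orig same-shape `(H, W, C)` arrays.
#' @param extractor a [feature_extractor()].
#' @return nonnegative scalar.
#' @export
content_distance <- function(x_adv, x_orig, extractor) {
  assert_same_shape(x_adv, x_orig, "content_distance inputs")
  if (length(extractor$content_layers) == 0L) stopf("empty content layer set")
  fa <- extractor_forward(extractor, x_adv)$features
  fo <- extractor_forward(extractor, x_orig)$features
  tot <- 0
  for (ly in extractor$content_layers)
    tot <- tot + mean((fa[[ly]] - fo[[ly]])^2)
  tot
}

# Value + input-gradient of the style term, reusing one forward pass.
# `style_grams` are precomputed Gram matrices of the exemplar.
style_loss_grad <- function(ext, x, style_grams) {
  fw <- extractor_forward(ext, x)
  gfeat <- list(block1 = NULL, block2 = NULL, block3 = NULL)
  val <- 0
  for (ly in ext$style_layers) {
    f <- fw$features[[ly]]
    d <- dim(f); N <- d[1] * d[2]
    Fm <- matrix(f, N, d[3])
    G <- crossprod(Fm) / N
    D <- G - style_grams[[ly]]
    val <- val + sum(D^2)
    gF <- Fm %*% (4 * D / N)          # d sum((G-S)^2) / dF, D symmetric
    gfeat[[ly]] <- array(gF, dim = d)
  }
  gx <- extractor_backward(ext, fw$cache, g1 = gfeat$block1,
                           g2 = gfeat$block2, g3 = gfeat$block3)
  list(value = val, grad = gx)
}

# Value + input-gradient of the content term against precomputed original
# features.
content_loss_grad <- function(ext, x, orig_features) {
  fw <- extractor_forward(ext, x)
  gfeat <- list(block1 = NULL, block2 = NULL, block3 = NULL)
  val <- 0
  for (ly in ext$content_layers) {
    diff <- fw$features[[ly]] - orig_features[[ly]]
    val <- val + mean(diff^2)
    gfeat[[ly]] <- 2 * diff / length(diff)
  }
  gx <- extractor_backward(ext, fw$cache, g1 = gfeat$block1,
                           g2 = gfeat$block2, g3 = gfeat$block3)
  list(value = val, grad = gx)
}

#' Build a style exemplar from a severe-artifact case
#'
#' @param case a `phantom_case`, typically grade 4.
#' @param z slice index.
#' @return a `style_sample` object (normalized 3-channel array + provenance).
#' @export
style_sample_from_case <- function(case, z = 1L) {
  d <- case$volume$shape
  x <- array(0, dim = c(d[2], d[3], 3L))
  x[, , 1] <- norm_channel(case, "t2w")[z, , ]
  x[, , 2] <- norm_channel(case, "dwi")[z, , ]
  x[, , 3] <- norm_channel(case, "adc")[z, , ]
  structure(list(x = x, provenance = case$case_id), class = "style_sample")
}
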
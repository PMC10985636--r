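test_that("style distance: identity, toy Gram value, permutation invariance", {
  ext <- feature_extractor(in_ch = 2L, widths = c(4L, 6L, 8L), seed = 3L)
  x <- tpas:::with_seed(1, array(runif(16 * 16 * 2), dim = c(16, 16, 2)))
  expect_equal(style_distance(x, x, ext), 0)
  expect_gte(style_distance(x, x + 0.3, ext), 0)

  # toy: one 1-channel "layer" with constant features 1 vs 2 over N positions
  # under the 1/N Gram normalization -> (1 - 4)^2 = 9
  f1 <- array(1, dim = c(4, 4, 1))
  f2 <- array(2, dim = c(4, 4, 1))
  expect_equal(sum((tpas:::gram_matrix(f1) - tpas:::gram_matrix(f2))^2), 9)

  # Gram matrices discard position
  perm <- tpas:::with_seed(2, sample(16 * 16))
  fp <- array(0, dim = c(16, 16, 2))
  for (cc in 1:2) {
    ch <- matrix(x[, , cc], 16 * 16)[perm]
    fp[, , cc] <- matrix(ch, 16, 16)
  }
  g_orig <- lapply(list(x), function(a) tpas:::gram_matrix(a))[[1]]
  expect_equal(tpas:::gram_matrix(fp), g_orig, tolerance = 1e-12)
})

test_that("content distance: identity, nonnegativity, growth with noise", {
  ext <- feature_extractor(in_ch = 2L, widths = c(4L, 6L, 8L), seed = 3L)
  x <- tpas:::with_seed(3, array(runif(16 * 16 * 2), dim = c(16, 16, 2)))
  expect_equal(content_distance(x, x, ext), 0)
  d_small <- content_distance(x + 0.01, x, ext)
  d_large <- content_distance(x + 0.10, x, ext)
  expect_gte(d_small, 0)
  expect_gt(d_large, d_small)
  expect_error(content_distance(x, x[1:8, , , drop = FALSE], ext), "shape")
})

test_that("style/content gradients match finite differences", {
  ext <- feature_extractor(in_ch = 2L, widths = c(4L, 6L, 8L), seed = 5L)
  dat <- tpas:::with_seed(6, list(
    x = array(runif(8 * 8 * 2), dim = c(8, 8, 2)),
    s = array(runif(8 * 8 * 2), dim = c(8, 8, 2))))
  sg <- lapply(tpas:::extractor_forward(ext, dat$s)$features,
               tpas:::gram_matrix)
  sl <- tpas:::style_loss_grad(ext, dat$x, sg)
  of <- tpas:::extractor_forward(ext, dat$x)$features
  x2 <- dat$x + 0.05
  cl <- tpas:::content_loss_grad(ext, x2, of)
  eps <- 1e-5
  idx <- tpas:::with_seed(7, sample(length(dat$x), 10))
  for (i in idx) {
    xp <- dat$x; xp[i] <- xp[i] + eps
    xm <- dat$x; xm[i] <- xm[i] - eps
    g <- (style_distance(xp, dat$s, ext) -
            style_distance(xm, dat$s, ext)) / (2 * eps)
    expect_equal(g, sl$grad[i], tolerance = 1e-4)
  }
  for (i in idx[1:5]) {
    xp <- x2; xp[i] <- xp[i] + eps
    xm <- x2; xm[i] <- xm[i] - eps
    g <- (content_distance(xp, dat$x, ext) -
            content_distance(xm, dat$x, ext)) / (2 * eps)
    expect_equal(g, cl$grad[i], tolerance = 1e-4)
  }
})

test_that("clip_to_bounds clamps to the original range and is idempotent", {
  orig <- array(seq(0, 100, length.out = 27), dim = c(3, 3, 3))
  pert <- orig
  pert[1] <- -2     # below the original min (0)
  pert[27] <- 103   # above the original max (100)
  clipped <- clip_to_bounds(orig, pert)
  expect_equal(clipped[1], 0)
  expect_equal(clipped[27], 100)
  expect_identical(clip_to_bounds(orig, clipped), clipped)

  # per-channel behaviour for (H, W, C)
  o3 <- array(0, dim = c(2, 2, 2))
  o3[, , 1] <- c(0, 1, 2, 3); o3[, , 2] <- c(10, 11, 12, 13)
  p3 <- o3 + 100
  c3 <- clip_to_bounds(o3, p3)
  expect_equal(max(c3[, , 1]), 3)
  expect_equal(max(c3[, , 2]), 13)
})

test_that("generated noise respects amplitude and range bounds", {
  fx <- fixture_trained_control()
  ext <- feature_extractor(seed = 8L)
  style <- tpas:::default_style_sample(fx$train$cases, 31L)
  ncfg <- noise_config(eps = 0.02, iters = 4L)
  for (i in 1:3) {
    case <- fx$train$cases[[i]]
    sm <- generate_noise(case, fx$fit$model, ext, style, ncfg)
    for (ch in c("t2w", "dwi", "adc")) {
      rng <- case$volume$ranges[[ch]]
      span <- rng[2] - rng[1]
      expect_lte(max(abs(sm$noise[[ch]])), ncfg$eps * span + 1e-9)
      expect_gte(min(sm$case$volume[[ch]]), min(case$volume[[ch]]) - 1e-9)
      expect_lte(max(sm$case$volume[[ch]]), max(case$volume[[ch]]) + 1e-9)
    }
  }
})

test_that("composite objective never ends above its zero-noise start", {
  fx <- fixture_trained_control()
  ext <- feature_extractor(seed = 8L)
  style <- tpas:::default_style_sample(fx$train$cases, 31L)
  sm <- generate_noise(fx$train$cases[[2]], fx$fit$model, ext, style,
                       noise_config(iters = 6L))
  tr <- sm$trajectory
  expect_lte(min(tr$composite), tr$composite[tr$iter == 0][1])
  # style movement under a positive style weight
  expect_lte(tail(tr$style, 1), tr$style[1])
})

test_that("zero-noise is optimal when the attack term is off and style is the case itself", {
  fx <- fixture_trained_control()
  ext <- feature_extractor(seed = 8L)
  case <- fx$train$cases[[1]]
  self_style <- style_sample_from_case(case)
  ncfg <- noise_config(lambda_adv = 0, iters = 3L)
  sm <- generate_noise(case, fx$fit$model, ext, self_style, ncfg)
  tr <- sm$trajectory
  # J(0) = 0 is the global minimum; the returned best iterate is at most that
  expect_lte(min(tr$composite), tr$composite[1] + 1e-9)
  expect_equal(tr$style[1] + tr$content[1], 0, tolerance = 1e-12)
  expect_lte(max(abs(sm$noise$t2w)), 1e-12)
})

test_that("attack ascends the task loss on a trained model", {
  fx <- fixture_trained_control()
  ext <- feature_extractor(seed = 8L)
  style <- tpas:::default_style_sample(fx$train$cases, 31L)
  up <- 0; n <- 6
  for (i in seq_len(n)) {
    case <- fx$train$cases[[i]]
    sm <- generate_noise(case, fx$fit$model, ext, style,
                         noise_config(iters = 6L))
    tr <- sm$trajectory
    if (tail(tr$adv, 1) >= tr$adv[1]) up <- up + 1
  }
  expect_gte(up, n - 1)
})

test_that("attack_cohort preserves ids, bounds, and logs per-case failures", {
  fx <- fixture_trained_control()
  ext <- feature_extractor(seed = 8L)
  style <- tpas:::default_style_sample(fx$train$cases, 31L)
  coh <- structure(list(cases = fx$train$cases[1:4],
                        manifest = fx$train$manifest[1:4, ]),
                   class = "phantom_cohort")
  atk <- attack_cohort(coh, fx$fit$model, ext, style,
                       noise_config(iters = 2L))
  expect_length(atk$samples, 4)
  expect_identical(atk$manifest$case_id, coh$manifest$case_id)
  expect_true(all(atk$manifest$attacked))
  mean_abs <- mean(abs(atk$samples[[1]]$noise$t2w)) /
    diff(range(coh$cases[[1]]$volume$ranges$t2w))
  expect_lte(mean_abs, noise_config()$eps)
})

test_that("noise_config rejects invalid settings", {
  expect_error(noise_config(eps = 0), "eps")
  expect_error(noise_config(iters = 0), "iters")
  expect_error(noise_config(lambda_adv = -1), "weights")
})
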
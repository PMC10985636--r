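# Rectal-artifact-pattern adversarial noise.
#
# The generator minimizes the composite objective
#   J(delta) = lambda_style   * style_distance(x + delta, style exemplar)
#            + lambda_content * content_distance(x + delta, x)
#            - lambda_adv     * task_loss(model, x + delta, truth)
# by signed-gradient descent with per-step projection onto the amplitude
# ball max|delta| <= eps * channel range, followed by clipping of the
# composed image to the original per-channel min/max. Descending J ascends
# the task loss while keeping the noise artifact-styled and
# content-preserving. The iterate with the lowest composite objective seen
# (including the zero-noise start) is returned, so the final composite value
# never exceeds the initial one.

#' Adversarial noise configuration
#'
#' @param eps per-channel amplitude bound as a fraction of the channel
#'   intensity range (default 0.02: imperceptibly small).
#' @param iters number of projected signed-gradient steps (>= 1).
#' @param alpha step size in normalized intensity units; defaults to
#'   `eps / 4`.
#' @param lambda_style,lambda_content,lambda_adv nonnegative weights of the
#'   three objective terms.
#' @param restrict_to_body when TRUE (default) the noise support is limited
#'   to the body region (no noise in air).
#' @param seed integer seed (the optimizer is deterministic; the seed is
#'   kept for provenance and future stochastic variants).
#' @return an object of class `noise_config`.
#' @export
noise_config <- function(eps = 0.02, iters = 10L, alpha = NULL,
                         lambda_style = 0.05, lambda_content = 0.5,
                         lambda_adv = 1, restrict_to_body = TRUE,
                         seed = 1L) {
  if (eps <= 0) stopf("eps must be positive")
  if (iters < 1) stopf("iters must be >= 1")
  if (is.null(alpha)) alpha <- eps / 4
  if (alpha <= 0) stopf("alpha must be positive")
  if (lambda_style < 0 || lambda_content < 0 || lambda_adv < 0)
    stopf("objective weights must be >= 0")
  structure(list(eps = eps, iters = as.integer(iters), alpha = alpha,
                 lambda_style = lambda_style,
                 lambda_content = lambda_content, lambda_adv = lambda_adv,
                 restrict_to_body = isTRUE(restrict_to_body),
                 seed = as.integer(seed)),
            class = "noise_config")
}

#' Task loss of the detector on a (possibly perturbed) input
#'
#' The exact quantity the attack ascends: the detector's training loss
#' (cross-entropy + soft Dice) evaluated at the given input and csPCa voxel
#' target.
#'
#' @param model a lesion `task_model`.
#' @param x `(H, W, 5)` detector input slice.
#' @param target logical `(H, W)` csPCa voxel map.
#' @param w_ce,w_dice,pos_weight loss weights (must match training to make
#'   the attack faithful).
#' @return scalar loss.
#' @export
adversarial_task_loss <- function(model, x, target, w_ce = 1, w_dice = 1,
                                  pos_weight = 1) {
  stopifnot(model$kind == "lesion")
  if (!identical(dim(x)[1:2], dim(target)[1:2] %||% dim(x)[1:2]))
    stopf("input/target shape mismatch")
  fw <- unet_forward(model$params, x)
  binary_dice_bce_loss(fw$out, target, w_ce, w_dice, pos_weight)$loss
}

# loss + gradient wrt the three image channels of the detector input
task_loss_grad_channels <- function(model, x5, target, w_ce, w_dice,
                                    pos_weight = 1) {
  fw <- unet_forward(model$params, x5)
  ls <- binary_dice_bce_loss(fw$out, target, w_ce, w_dice, pos_weight)
  bw <- unet_backward(model$params, fw$cache, ls$grad)
  list(value = ls$loss, grad = bw$gX[, , 1:3, drop = FALSE])
}

#' Clip a perturbed image to the original's per-channel bounds
#'
#' Values below the original minimum are set to that minimum, values above
#' the original maximum to that maximum, per channel; idempotent.
#'
#' @param x_orig original array; either `(H, W, C)` (clipped per channel) or
#'   any plain numeric array (clipped to its global min/max).
#' @param x_plus_delta same-shape perturbed array.
#' @return the clipped array.
#' @export
clip_to_bounds <- function(x_orig, x_plus_delta) {
  assert_same_shape(x_orig, x_plus_delta, "clip_to_bounds inputs")
  d <- dim(x_orig)
  if (!is.null(d) && length(d) == 3L) {
    out <- x_plus_delta
    for (cc in seq_len(d[3])) {
      ch <- x_orig[, , cc]
      out[, , cc] <- clamp(x_plus_delta[, , cc], min(ch), max(ch))
    }
    out
  } else {
    clamp(x_plus_delta, min(x_orig), max(x_orig))
  }
}

# Composite objective value at a given delta (no gradient); used to pick the
# best iterate.
composite_objective <- function(x_img, delta, detector, zones_x, target,
                                ext, style_grams, orig_feat, config,
                                w_ce, w_dice, pos_weight = 1) {
  x_adv <- x_img + delta
  sv <- if (config$lambda_style > 0) {
    fa <- extractor_forward(ext, x_adv)$features
    s <- 0
    for (ly in ext$style_layers)
      s <- s + sum((gram_matrix(fa[[ly]]) - style_grams[[ly]])^2)
    s
  } else 0
  cv <- if (config$lambda_content > 0) {
    fa <- extractor_forward(ext, x_adv)$features
    s <- 0
    for (ly in ext$content_layers)
      s <- s + mean((fa[[ly]] - orig_feat[[ly]])^2)
    s
  } else 0
  x5 <- zones_x
  x5[, , 1:3] <- x_adv
  av <- adversarial_task_loss(detector, x5, target, w_ce, w_dice,
                              pos_weight)
  list(style = sv, content = cv, adv = av,
       composite = config$lambda_style * sv + config$lambda_content * cv -
         config$lambda_adv * av)
}

#' Generate a proprietary adversarial sample for one case
#'
#' Optimizes bounded per-channel noise fields (T2W, DWI, ADC) against the
#' current detector: the composite objective trades off style match to a
#' severe-artifact exemplar, semantic content preservation, and
#' maximization of the detector's task loss. After every step the noise is
#' projected to `max|delta| <= eps * range` per channel and the composed
#' image is clipped to the original's per-channel bounds, so both amplitude
#' invariants hold exactly for the returned sample. The returned case is
#' the best (lowest-composite) iterate encountered, which includes the
#' zero-noise start.
#'
#' @param case a `phantom_case` (artifact-free cases recommended).
#' @param model a `cspca_model` pipeline (the detector under attack; its
#'   gland stage supplies the fixed zone channels).
#' @param extractor a [feature_extractor()].
#' @param style_sample a [style_sample_from_case()] exemplar.
#' @param config a [noise_config()].
#' @return an object of class `adversarial_sample`: `case` (perturbed copy),
#'   `base_id`, `noise` (raw-unit delta arrays per channel), `trajectory`
#'   (per-iteration style/content/adv/composite losses).
#' @export
generate_noise <- function(case, model, extractor, style_sample, config) {
  stopifnot(inherits(model, "cspca_model"), inherits(config, "noise_config"))
  d <- case$volume$shape
  cfg <- model$config
  zones <- zones_for(case, model$gland, cfg)
  sg <- lapply(extractor_forward(extractor, style_sample$x)$features,
               gram_matrix)
  eps <- config$eps

  delta_raw <- list(t2w = array(0, dim = d), dwi = array(0, dim = d),
                    adc = array(0, dim = d))
  out_case <- case
  traj <- NULL
  for (z in seq_len(d[1])) {
    x_img <- array(0, dim = c(d[2], d[3], 3L))
    x_img[, , 1] <- norm_channel(case, "t2w")[z, , ]
    x_img[, , 2] <- norm_channel(case, "dwi")[z, , ]
    x_img[, , 3] <- norm_channel(case, "adc")[z, , ]
    target <- cspca_target(case, z)
    x5 <- detector_input(case, zones, z)
    orig_feat <- extractor_forward(extractor, x_img)$features
    body <- case$masks$body[z, , ]

    delta <- array(0, dim = dim(x_img))
    evalJ <- function(dl)
      composite_objective(x_img, dl, model$detector, x5, target, extractor,
                          sg, orig_feat, config, cfg$w_ce, cfg$w_dice,
                          cfg$ce_pos_weight %||% 1)
    cur <- evalJ(delta)
    best <- list(delta = delta, J = cur$composite)
    traj_z <- data.frame(z = z, iter = 0L, style = cur$style,
                         content = cur$content, adv = cur$adv,
                         composite = cur$composite)
    for (it in seq_len(config$iters)) {
      x_adv <- x_img + delta
      g <- array(0, dim = dim(delta))
      if (config$lambda_style > 0) {
        sl <- style_loss_grad(extractor, x_adv, sg)
        g <- g + config$lambda_style * sl$grad
      }
      if (config$lambda_content > 0) {
        cl <- content_loss_grad(extractor, x_adv, orig_feat)
        g <- g + config$lambda_content * cl$grad
      }
      if (config$lambda_adv > 0) {
        x5a <- x5
        x5a[, , 1:3] <- x_adv
        tl <- task_loss_grad_channels(model$detector, x5a, target,
                                      cfg$w_ce, cfg$w_dice,
                                      cfg$ce_pos_weight %||% 1)
        g <- g - config$lambda_adv * tl$grad
      }
      if (any(!is.finite(g)))
        stopf("non-finite noise gradient at iteration %d", it)
      delta <- delta - config$alpha * sign(g)
      delta <- clamp(delta, -eps, eps)
      if (config$restrict_to_body)
        delta <- delta * array(as.numeric(body), dim = dim(delta))
      # compose + clip, then re-express as an (only smaller) delta
      x_new <- clip_to_bounds(x_img, x_img + delta)
      delta <- x_new - x_img
      cur <- evalJ(delta)
      traj_z <- rbind(traj_z,
                      data.frame(z = z, iter = it, style = cur$style,
                                 content = cur$content, adv = cur$adv,
                                 composite = cur$composite))
      if (cur$composite < best$J) best <- list(delta = delta, J = cur$composite)
    }
    delta <- best$delta
    traj <- rbind(traj, traj_z)
    for (ci in 1:3) {
      ch <- c("t2w", "dwi", "adc")[ci]
      rng <- case$volume$ranges[[ch]]
      raw <- delta[, , ci] * (rng[2] - rng[1])
      delta_raw[[ch]][z, , ] <- raw
      out_case$volume[[ch]][z, , ] <- case$volume[[ch]][z, , ] + raw
    }
  }
  structure(list(case = out_case, base_id = case$case_id, noise = delta_raw,
                 trajectory = traj, config = config),
            class = "adversarial_sample")
}

#' Attack every case of a cohort
#'
#' Produces the "attacked twin" of a clean cohort: one adversarial sample
#' per case, with a manifest linking clean and attacked ids. Per-case
#' failures are logged and skipped, never fatal for the cohort.
#'
#' @param cohort a `phantom_cohort` (ideally artifact-free, see
#'   [filter_clean()]).
#' @param model a `cspca_model` the noise is optimized against.
#' @param extractor a [feature_extractor()].
#' @param style_sample a severe-artifact exemplar.
#' @param config a [noise_config()].
#' @return an `adversarial_cohort`: `samples`, an attacked `phantom_cohort`
#'   (`cohort`), a manifest with `attacked = TRUE` and `base_id`, and
#'   `errors` (named list of per-case failure messages).
#' @export
attack_cohort <- function(cohort, model, extractor, style_sample, config) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  samples <- list()
  errors <- list()
  for (case in cohort$cases) {
    res <- tryCatch(
      generate_noise(case, model, extractor, style_sample, config),
      error = function(e) e)
    if (inherits(res, "error")) errors[[case$case_id]] <- conditionMessage(res)
    else samples[[case$case_id]] <- res
  }
  atk_cases <- lapply(samples, `[[`, "case")
  names(atk_cases) <- NULL
  keep <- cohort$manifest$case_id %in% names(samples)
  manifest <- cohort$manifest[keep, , drop = FALSE]
  manifest$attacked <- TRUE
  manifest$base_id <- manifest$case_id
  structure(list(samples = samples,
                 cohort = structure(list(cases = atk_cases,
                                         manifest = manifest),
                                    class = "phantom_cohort"),
                 manifest = manifest, errors = errors),
            class = "adversarial_cohort")
}
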
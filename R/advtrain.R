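# Targeted adversarial training: the detector's training stream is
# periodically augmented with proprietary adversarial samples regenerated
# against the current model, so noise generation and parameter optimization
# alternate over the training lifecycle. The control pipeline is the
# identical two-stage training with no adversarial augmentation.

#' Adversarial training schedule
#'
#' @param refresh regeneration interval R in epochs (>= 1): after the warmup,
#'   adversarial samples are regenerated against the current model every R
#'   epochs and appended to each subsequent epoch's training stream.
#' @param rho mixing fraction in [0, 1]: share of the clean training stream
#'   regenerated as adversarial samples (`rho = 0` disables augmentation and
#'   reproduces control training bit-identically; `rho = 1` doubles the
#'   stream).
#' @param warmup clean-only epochs before the first regeneration (>= 0).
#' @param noise a [noise_config()]; required when `rho > 0`.
#' @return an object of class `tpas_schedule`.
#' @export
tpas_schedule <- function(refresh = 5L, rho = 0.5, warmup = 5L,
                          noise = noise_config()) {
  if (refresh < 1) stopf("refresh interval must be >= 1")
  if (rho < 0 || rho > 1) stopf("rho must be in [0, 1]")
  if (warmup < 0) stopf("warmup must be >= 0")
  if (rho > 0 && !inherits(noise, "noise_config"))
    stopf("rho > 0 requires a noise config")
  structure(list(refresh = as.integer(refresh), rho = rho,
                 warmup = as.integer(warmup), noise = noise),
            class = "tpas_schedule")
}

# Default severe-artifact style exemplar: the first training case with a
# grade-4 artifact imprinted (deterministic under the training seed).
default_style_sample <- function(cases, seed) {
  spec <- artifact_spec(4L, pz_affected_fraction = 0.8, tz_involved = TRUE,
                        amplitude = 0.3, band_period = 8,
                        seed = derive_seed(seed, "style"))
  style_sample_from_case(apply_visible_artifact(cases[[1]], spec))
}

tpas_engine <- function(cases, config, schedule, extractor, style_sample) {
  if (length(cases) == 0L) stopf("empty training set")
  labs <- vapply(cases, function(cs) cs$patient_label, TRUE)
  if (schedule$rho > 0 && (all(labs) || !any(labs)))
    stopf("adversarial training needs both csPCa and non-csPCa cases")
  gland <- train_gland_segmenter(cases, config)
  zones_list <- lapply(cases, function(cs) zones_for(cs, gland, config))

  regen_log <- new.env(parent = emptyenv())
  regen_log$events <- integer(0)
  regen_log$adv <- list()

  extra_fn <- NULL
  if (schedule$rho > 0) {
    n_attack <- max(1L, round(schedule$rho * length(cases)))
    extra_fn <- function(ep, params) {
      due <- ep > schedule$warmup &&
        (ep - schedule$warmup) %% schedule$refresh == 0L
      if (due) {
        det_now <- new_task_model(params, "lesion",
                                  list(in_ch = 5L, out_ch = 1L,
                                       width = config$width), config$seed)
        pipe_now <- new_cspca_model(gland, det_now, config)
        pick <- with_seed(derive_seed(config$seed, "attack-pick", ep),
                          sample.int(length(cases), n_attack))
        adv <- list()
        for (ci in pick) {
          ncfg <- schedule$noise
          ncfg$seed <- derive_seed(config$seed, "attack", ep, ci)
          sm <- generate_noise(cases[[ci]], pipe_now, extractor,
                               style_sample, ncfg)
          zc <- zones_list[[ci]]
          for (z in seq_len(sm$case$volume$shape[1]))
            adv[[length(adv) + 1L]] <- list(
              x = detector_input(sm$case, zc, z),
              target = cspca_target(sm$case, z),
              id = sprintf("adv:%s/%d@%d", cases[[ci]]$case_id, z, ep))
        }
        regen_log$events <- c(regen_log$events, ep)
        regen_log$adv <- adv
      }
      regen_log$adv
    }
  }

  samples <- list()
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    zones <- zones_list[[ci]]
    for (z in seq_len(case$volume$shape[1]))
      samples[[length(samples) + 1L]] <- list(
        x = detector_input(case, zones, z),
        target = cspca_target(case, z),
        id = sprintf("%s/%d", case$case_id, z))
  }

  sl <- new.env(parent = emptyenv())
  fit <- train_unet(samples, "lesion", 5L, 1L, config, extra_fn = extra_fn,
                    stream_log_env = sl)
  det <- new_task_model(fit$params, "lesion",
                        list(in_ch = 5L, out_ch = 1L, width = config$width),
                        config$seed)
  attr(det, "history") <- fit$history
  history <- fit$history
  history$regenerated <- history$epoch %in% regen_log$events
  list(model = new_cspca_model(gland, det, config),
       history = history,
       regen_epochs = regen_log$events,
       stream_log = sl$log)
}

#' Targeted adversarial training (TPAS)
#'
#' Trains the two-stage pipeline with alternating adversarial-sample
#' regeneration: every `schedule$refresh` epochs after the warmup, bounded
#' artifact-styled adversarial samples are regenerated against the current
#' detector and appended to the training stream at fraction `schedule$rho`.
#' Clean counterparts always remain in the stream. With `rho = 0` the
#' trajectory is bit-identical to [control_train()] under the same seed.
#'
#' @param cases training cases (must include csPCa and non-csPCa patients
#'   when `rho > 0`).
#' @param config a [train_config()].
#' @param schedule a [tpas_schedule()].
#' @param extractor a [feature_extractor()]; defaults to a seeded extractor
#'   derived from the training seed.
#' @param style_sample severe-artifact exemplar; defaults to the first
#'   training case with a grade-4 artifact imprinted.
#' @return list with `model` (a `cspca_model`), `history` (per-epoch loss,
#'   stream size, regeneration flag), `regen_epochs`, and `stream_log`
#'   (per-epoch presented sample ids, for the equal-exposure audit).
#' @export
tpas_train <- function(cases, config, schedule,
                       extractor = NULL, style_sample = NULL) {
  stopifnot(inherits(config, "train_config"),
            inherits(schedule, "tpas_schedule"))
  if (schedule$rho > 0) {
    if (is.null(extractor))
      extractor <- feature_extractor(seed = derive_seed(config$seed, "ext"))
    if (is.null(style_sample))
      style_sample <- default_style_sample(cases, config$seed)
  }
  tpas_engine(cases, config, schedule, extractor, style_sample)
}

#' Control training (no adversarial augmentation)
#'
#' The identical two-stage pipeline and seed handling as [tpas_train()],
#' with an empty adversarial schedule.
#'
#' @param cases training cases.
#' @param config a [train_config()].
#' @return same structure as [tpas_train()].
#' @export
control_train <- function(cases, config) {
  stopifnot(inherits(config, "train_config"))
  sched <- tpas_schedule(refresh = 1L, rho = 0, warmup = 0L)
  tpas_engine(cases, config, sched, extractor = NULL, style_sample = NULL)
}
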
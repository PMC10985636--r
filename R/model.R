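# Miniature two-stage csPCa detection workflow: a gland zone segmenter
# (T2W -> background/PZ/TZ) followed by a five-channel lesion detector
# (T2W, DWI, ADC, predicted TZ mask, predicted PZ mask -> voxel-wise csPCa
# confidence). Both are small two-level U-Nets trained with a weighted sum
# of soft-Dice and voxel-wise cross-entropy.

#' Training configuration
#'
#' @param epochs training epochs (>= 1), used by both stages.
#' @param lr Adam learning rate.
#' @param w_ce,w_dice nonnegative weights of the cross-entropy and soft-Dice
#'   terms of the task loss.
#' @param ce_pos_weight positive-class weight of the detector's voxel-wise
#'   cross-entropy; rebalances the loss toward the rare lesion voxels so the
#'   detector cannot settle into an all-background prediction.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed integer training seed (initialization + shuffling).
#' @param width base channel width of the U-Nets.
#' @param use_oracle_masks feed ground-truth instead of predicted zone masks
#'   to the detector (ablation switch).
#' @param detection_threshold confidence threshold for lesion candidate
#'   extraction downstream.
#' @param min_candidate_size minimum candidate size in voxels.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 20L, lr = 3e-3, w_ce = 1, w_dice = 1,
                         ce_pos_weight = 16, folds = 5L, seed = 1L, width = 8L,
                         use_oracle_masks = FALSE,
                         detection_threshold = 0.45,
                         min_candidate_size = 1L) {
  if (epochs < 1) stopf("epochs must be >= 1")
  if (folds < 2) stopf("folds must be >= 2")
  if (w_ce < 0 || w_dice < 0 || ce_pos_weight < 0)
    stopf("loss weights must be >= 0")
  if (lr <= 0) stopf("learning rate must be positive")
  if (detection_threshold <= 0 || detection_threshold >= 1)
    stopf("detection_threshold must be in (0, 1)")
  structure(list(epochs = as.integer(epochs), lr = lr, w_ce = w_ce,
                 w_dice = w_dice, ce_pos_weight = ce_pos_weight,
                 folds = as.integer(folds),
                 seed = as.integer(seed), width = as.integer(width),
                 use_oracle_masks = isTRUE(use_oracle_masks),
                 detection_threshold = detection_threshold,
                 min_candidate_size = as.integer(min_candidate_size)),
            class = "train_config")
}

# ---- input construction ----------------------------------------------------

norm_channel <- function(case, ch) {
  rng <- case$volume$ranges[[ch]]
  (case$volume[[ch]] - rng[1]) / (rng[2] - rng[1])
}

# (Y, X, 1) T2W slice for the gland segmenter
gland_input <- function(case, z = 1L) {
  t2 <- norm_channel(case, "t2w")
  array(t2[z, , ], dim = c(dim(t2)[2], dim(t2)[3], 1L))
}

# integer class map 1=background, 2=PZ, 3=TZ
gland_target <- function(case, z = 1L) {
  m <- case$masks
  1L + (m$pz[z, , ] * 1L) + (m$tz[z, , ] * 2L)
}

# (Y, X, 5) detector input: T2W, DWI, ADC plus binary TZ / PZ masks
detector_input <- function(case, zones, z = 1L) {
  d <- case$volume$shape
  out <- array(0, dim = c(d[2], d[3], 5L))
  out[, , 1] <- norm_channel(case, "t2w")[z, , ]
  out[, , 2] <- norm_channel(case, "dwi")[z, , ]
  out[, , 3] <- norm_channel(case, "adc")[z, , ]
  out[, , 4] <- zones$tz[z, , ]
  out[, , 5] <- zones$pz[z, , ]
  out
}

# csPCa voxel target: union of lesions labeled csPCa
cspca_target <- function(case, z = 1L) {
  m <- case$masks
  ids <- which(m$lesion_labels == "csPCa")
  tgt <- array(FALSE, dim = dim(m$lesions))
  if (length(ids)) tgt <- array(m$lesions %in% ids, dim = dim(m$lesions))
  tgt[z, , ]
}

# ---- task models -----------------------------------------------------------

new_task_model <- function(params, kind, arch, seed) {
  structure(list(params = params, kind = kind, arch = arch, seed = seed),
            class = "task_model")
}

#' @export
print.task_model <- function(x, ...) {
  cat(sprintf("<task_model %s: %d->%d channels, width %d>\n",
              x$kind, x$arch$in_ch, x$arch$out_ch, x$arch$width))
  invisible(x)
}

task_loss_fn <- function(kind, config) {
  if (kind == "gland")
    function(logits, target)
      softmax_dice_ce_loss(logits, target, config$w_ce, config$w_dice)
  else
    function(logits, target)
      binary_dice_bce_loss(logits, target, config$w_ce, config$w_dice,
                           config$ce_pos_weight)
}

# Generic SGD/Adam loop over (input, target) samples. `samples` is a list of
# lists with elements x and target; extra samples (e.g. adversarial) can be
# appended per epoch through `extra_fn(epoch)`.
train_unet <- function(samples, kind, in_ch, out_ch, config,
                       extra_fn = NULL, stream_log_env = NULL) {
  if (length(samples) == 0L) stopf("empty training set")
  params <- unet_init(in_ch, out_ch, config$width,
                      derive_seed(config$seed, "init", kind),
                      out_bias = if (kind == "lesion") -4 else 0)
  state <- adam_init(params)
  loss_fn <- task_loss_fn(kind, config)
  if (!is.null(stream_log_env)) stream_log_env$log <- list()
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        n_samples = integer(0))
  for (ep in seq_len(config$epochs)) {
    stream <- samples
    if (!is.null(extra_fn)) {
      extra <- extra_fn(ep, params)
      if (length(extra)) stream <- c(stream, extra)
    }
    ord <- with_seed(derive_seed(config$seed, "shuffle", kind, ep),
                     sample.int(length(stream)))
    if (!is.null(stream_log_env))
      stream_log_env$log[[ep]] <-
        vapply(stream[ord], function(s) s$id %||% "?", "")
    tot <- 0
    for (si in ord) {
      sm <- stream[[si]]
      fw <- unet_forward(params, sm$x)
      ls <- loss_fn(fw$out, sm$target)
      bw <- unet_backward(params, fw$cache, ls$grad)
      upd <- adam_step(params, bw$grads, state, config$lr)
      params <- upd$params; state <- upd$state
      tot <- tot + ls$loss
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = tot / length(stream),
                                n_samples = length(stream)))
  }
  list(params = params, history = history)
}

#' Train the gland zone segmenter
#'
#' Maps a normalized T2W slice to a three-class voxel map (background /
#' peripheral zone / transition zone) with a cross-entropy + soft-Dice loss.
#'
#' @param cases list of `phantom_case` objects (a `phantom_cohort$cases`).
#' @param config a [train_config()].
#' @return a `task_model` of kind `"gland"` with a `history` attribute
#'   (per-epoch training loss).
#' @export
train_gland_segmenter <- function(cases, config) {
  if (length(cases) == 0L) stopf("empty training set")
  samples <- list()
  for (case in cases)
    for (z in seq_len(case$volume$shape[1]))
      samples[[length(samples) + 1L]] <-
        list(x = gland_input(case, z), target = gland_target(case, z))
  if (!any(vapply(samples, function(s) any(s$target > 1L), TRUE)))
    stopf("all-background zone labels: nothing to segment")
  fit <- train_unet(samples, "gland", 1L, 3L, config)
  m <- new_task_model(fit$params, "gland",
                      list(in_ch = 1L, out_ch = 3L, width = config$width),
                      config$seed)
  attr(m, "history") <- fit$history
  m
}

#' Predict PZ/TZ zone masks with a gland model
#'
#' @param model a gland `task_model`.
#' @param case a `phantom_case`.
#' @return list of logical `pz` and `tz` arrays (argmax, ties to background).
#' @export
predict_zones <- function(model, case) {
  stopifnot(model$kind == "gland")
  d <- case$volume$shape
  pz <- array(FALSE, dim = d); tz <- array(FALSE, dim = d)
  for (z in seq_len(d[1])) {
    p <- softmax3(unet_forward(model$params, gland_input(case, z))$out)
    cls <- apply(p, c(1, 2), which.max)
    pz[z, , ] <- cls == 2L
    tz[z, , ] <- cls == 3L
  }
  list(pz = pz, tz = tz)
}

zones_for <- function(case, gland_model, config) {
  if (config$use_oracle_masks) case$masks[c("pz", "tz")]
  else predict_zones(gland_model, case)
}

#' Train the lesion detector
#'
#' Five input channels (T2W, DWI, ADC, predicted TZ mask, predicted PZ
#' mask); supervision is the union of csPCa lesion voxels; output is a
#' voxel-wise confidence in [0, 1].
#'
#' @param cases training cases.
#' @param gland_model a trained gland `task_model` whose predicted zones are
#'   fed to the detector (ground-truth zones when
#'   `config$use_oracle_masks`).
#' @param config a [train_config()].
#' @param extra_fn optional `function(epoch, params)` returning additional
#'   training samples for that epoch (used by adversarial training).
#' @return a `task_model` of kind `"lesion"` with a `history` attribute.
#' @export
train_lesion_detector <- function(cases, gland_model, config,
                                  extra_fn = NULL) {
  if (length(cases) == 0L) stopf("empty training set")
  samples <- list()
  for (case in cases) {
    zones <- zones_for(case, gland_model, config)
    for (z in seq_len(case$volume$shape[1])) {
      x <- detector_input(case, zones, z)
      if (dim(x)[3] != 5L) stopf("detector input must have 5 channels")
      samples[[length(samples) + 1L]] <-
        list(x = x, target = cspca_target(case, z))
    }
  }
  fit <- train_unet(samples, "lesion", 5L, 1L, config, extra_fn = extra_fn)
  m <- new_task_model(fit$params, "lesion",
                      list(in_ch = 5L, out_ch = 1L, width = config$width),
                      config$seed)
  attr(m, "history") <- fit$history
  m
}

#' Voxel-wise lesion confidence map
#'
#' Pure function of (model parameters, input): repeated calls on the same
#' case give identical maps.
#'
#' @param model a lesion `task_model`.
#' @param case a `phantom_case`.
#' @param zones precomputed zone masks (list pz/tz); required unless
#'   `gland_model` is given.
#' @param gland_model gland model used to predict zones when `zones` is
#'   missing.
#' @return a `(z, y, x)` array of confidences in [0, 1].
#' @export
predict_confidence <- function(model, case, zones = NULL,
                               gland_model = NULL) {
  stopifnot(model$kind == "lesion")
  if (is.null(zones)) {
    if (is.null(gland_model)) stopf("need zones or a gland_model")
    zones <- predict_zones(gland_model, case)
  }
  d <- case$volume$shape
  out <- array(0, dim = d)
  for (z in seq_len(d[1])) {
    x <- detector_input(case, zones, z)
    if (dim(x)[3] != model$arch$in_ch)
      stopf("channel mismatch: input has %d, model expects %d",
            dim(x)[3], model$arch$in_ch)
    out[z, , ] <- sigmoid(unet_forward(model$params, x)$out[, , 1])
  }
  out
}

# ---- full pipeline ---------------------------------------------------------

new_cspca_model <- function(gland, detector, config) {
  structure(list(gland = gland, detector = detector, config = config),
            class = "cspca_model")
}

#' Patient-level csPCa score for one case
#'
#' Runs the two-stage pipeline and reduces the confidence map to a scalar
#' through candidate extraction.
#'
#' @param pipeline a `cspca_model` (see [control_train()]).
#' @param case a `phantom_case`.
#' @return list with `score`, `confidence` map, `candidates`.
#' @export
score_case <- function(pipeline, case) {
  stopifnot(inherits(pipeline, "cspca_model"))
  cfg <- pipeline$config
  zones <- zones_for(case, pipeline$gland, cfg)
  cmap <- predict_confidence(pipeline$detector, case, zones = zones)
  cands <- extract_candidates(cmap, threshold = cfg$detection_threshold,
                              min_size = cfg$min_candidate_size)
  list(score = patient_score(cands), confidence = cmap, candidates = cands,
       zones = zones)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file embedding parameters, architecture,
#' config and seed; `load_checkpoint(save_checkpoint(m, p))` restores `m`
#' exactly.
#'
#' @param model a `task_model` or `cspca_model`.
#' @param path file path.
#' @return `path` (write) / the model (read).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("missing checkpoint %s", path)
  readRDS(path)
}

#' k-fold cross-validation with patient-level AUC selection
#'
#' Partitions the cases into k folds (sizes differing by at most one), trains
#' the full two-stage pipeline on each training split, scores the held-out
#' fold, and selects the model with the highest validation patient-level
#' AUC. Folds whose validation split contains a single class get `NA` AUC
#' and cannot be selected.
#'
#' @param cases list of `phantom_case`.
#' @param k number of folds (2 <= k <= number of cases).
#' @param config a [train_config()].
#' @return list with `best` (`cspca_model`), `fold_metrics` data.frame
#'   (fold, n_val, auc), and `fold_assignment` (integer vector, one entry
#'   per case).
#' @export
crossval_select <- function(cases, k, config) {
  n <- length(cases)
  if (k > n) stopf("k = %d exceeds the %d available cases", k, n)
  if (k < 2) stopf("k must be >= 2")
  assign <- with_seed(derive_seed(config$seed, "folds"),
                      sample(rep_len(seq_len(k), n)))
  models <- vector("list", k)
  metrics <- data.frame(fold = seq_len(k), n_val = 0L, auc = NA_real_)
  for (f in seq_len(k)) {
    tr <- cases[assign != f]
    va <- cases[assign == f]
    fold_cfg <- config
    fold_cfg$seed <- derive_seed(config$seed, "fold", f)
    pipe <- control_train(tr, fold_cfg)$model
    scores <- vapply(va, function(cs) score_case(pipe, cs)$score, 0)
    labels <- vapply(va, function(cs) as.integer(cs$patient_label), 0L)
    metrics$n_val[f] <- length(va)
    if (length(unique(labels)) == 2L)
      metrics$auc[f] <- roc_auc(scores, labels)
    models[[f]] <- pipe
  }
  best_f <- if (all(is.na(metrics$auc))) 1L else which.max(metrics$auc)
  list(best = models[[best_f]], fold_metrics = metrics,
       fold_assignment = assign, best_fold = best_f)
}
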
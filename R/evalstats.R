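# Paired-model comparison machinery: patient-level ROC/AUC with the DeLong
# test for correlated curves, lesion-level precision-recall/AUPRC (average
# precision) with case-resampled bootstrap comparison, Dice summaries,
# Cohen weighted kappa, and subgroup reports.

#' Patient-level ROC AUC
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, counting ties as one half.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1 or logical).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Placement values ("structural components"): for each positive, the
# fraction of negatives it beats (ties half); for each negative, the
# fraction of positives it loses to (ties half). Their means both equal the
# AUC.
placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)), 0)
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)), 0)
  list(v10 = v10, v01 = v01)
}

#' DeLong test for two correlated ROC AUCs
#'
#' Both score vectors must be computed on the same cases in the same order.
#' The variance of the AUC difference is estimated from the covariance of
#' the placement values; the two-sided p-value uses the normal
#' approximation.
#'
#' @param scoresA,scoresB paired score vectors.
#' @param labels shared binary labels.
#' @return list with `aucA`, `aucB`, `delta` (A - B), `var_delta`, `z`, `p`,
#'   and per-model AUC variances `varA`, `varB`. When the variance of the
#'   difference is numerically zero (e.g. identical scorers), `z` is NA and
#'   `p` is 1.
#' @export
delong_test <- function(scoresA, scoresB, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scoresA) != length(labels) || length(scoresB) != length(labels))
    stopf("unpaired inputs: scoresA, scoresB and labels must align")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  pa <- placements(scoresA, labels)
  pb <- placements(scoresB, labels)
  aucA <- mean(pa$v10); aucB <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  varA <- s10[1, 1] / n1 + s01[1, 1] / n0
  varB <- s10[2, 2] / n1 + s01[2, 2] / n0
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- aucA - aucB
  if (var_delta <= .Machine$double.eps) {
    z <- NA_real_
    p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(aucA = aucA, aucB = aucB, delta = delta, var_delta = var_delta,
       varA = varA, varB = varB, z = z, p = p)
}

# ---- lesion-level PR -------------------------------------------------------

# A scored lesion cohort is a list with:
#   candidates: data.frame(case_id, cand_id, probability, is_tp)
#   n_gt: total number of ground-truth csPCa lesions in the cohort
as_lesion_cohort <- function(candidates, n_gt) {
  stopifnot(is.data.frame(candidates), n_gt >= 0)
  structure(list(candidates = candidates, n_gt = as.integer(n_gt)),
            class = "lesion_cohort")
}

#' Lesion-level AUPRC (average precision)
#'
#' Candidates pooled over the cohort are sorted by descending probability
#' (ties broken by case id then candidate id, for a stable, reproducible
#' order); AUPRC is average precision: the mean over ground-truth lesions of
#' the precision at each recall increment. Missed lesions contribute zero
#' through the recall denominator.
#'
#' @param cohort a `lesion_cohort` (see [score_cohort()]), or anything with
#'   `$candidates` (case_id, cand_id, probability, is_tp) and `$n_gt`.
#' @return AUPRC in [0, 1].
#' @export
lesion_pr_auprc <- function(cohort) {
  cand <- cohort$candidates
  n_gt <- cohort$n_gt
  if (is.null(n_gt) || n_gt < 1) stopf("cohort has no ground-truth lesions")
  if (nrow(cand) == 0L) return(0)
  ord <- order(-cand$probability, cand$case_id, cand$cand_id)
  tp <- cumsum(cand$is_tp[ord])
  prec <- tp / seq_len(nrow(cand))
  sum(prec[cand$is_tp[ord]]) / n_gt
}

#' Bootstrap comparison of two AUPRCs on the same case set
#'
#' Patients (cases) are resampled with replacement; both models are
#' evaluated on each resample, keeping each patient's candidates together,
#' so the bootstrap respects the pairing. Percentile CI; the two-sided
#' p-value is twice the smaller tail mass of the resampled difference
#' around zero (capped at 1).
#'
#' @param cohortA,cohortB `lesion_cohort`s over the same case ids. Each must
#'   also carry `gt_per_case` (named vector of per-case csPCa lesion
#'   counts).
#' @param B number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @param conf CI coverage level.
#' @return list with `deltaA_B`, `ci`, `p`, `B`, and the resampled deltas.
#' @export
bootstrap_auprc_diff <- function(cohortA, cohortB, B = 1000L, seed = 1L,
                                 conf = 0.95) {
  if (B < 100) stopf("B must be >= 100")
  ids <- names(cohortA$gt_per_case)
  if (is.null(ids) || !identical(sort(ids), sort(names(cohortB$gt_per_case))))
    stopf("cohorts must cover the same case set")
  dA <- split(seq_len(nrow(cohortA$candidates)), cohortA$candidates$case_id)
  dB <- split(seq_len(nrow(cohortB$candidates)), cohortB$candidates$case_id)
  ap_on <- function(cohort, idx_by_case, resample) {
    rows <- unlist(idx_by_case[resample], use.names = FALSE)
    cand <- cohort$candidates[rows, , drop = FALSE]
    n_gt <- sum(cohort$gt_per_case[resample])
    if (n_gt < 1) return(NA_real_)
    if (nrow(cand) == 0L) return(0)
    lesion_pr_auprc(list(candidates = cand, n_gt = n_gt))
  }
  point <- lesion_pr_auprc(cohortA) - lesion_pr_auprc(cohortB)
  deltas <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      rs <- sample(ids, length(ids), replace = TRUE)
      ap_on(cohortA, dA, rs) - ap_on(cohortB, dB, rs)
    }, 0)
  })
  deltas_ok <- deltas[!is.na(deltas)]
  ci <- stats::quantile(deltas_ok, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  p_lo <- mean(deltas_ok <= 0)
  p_hi <- mean(deltas_ok >= 0)
  p <- min(1, 2 * min(p_lo, p_hi))
  list(deltaA_B = point, ci = ci, p = p, B = B, deltas = deltas)
}

#' Dice similarity coefficient
#'
#' `2|A∩B| / (|A| + |B|)`; by convention 1 when both masks are empty (the
#' result then carries attribute `both_empty = TRUE` so reports can flag
#' it).
#'
#' @param maskA,maskB same-shape logical arrays.
#' @return scalar in [0, 1].
#' @export
dice <- function(maskA, maskB) {
  assert_same_shape(maskA, maskB, "dice masks")
  a <- sum(maskA); b <- sum(maskB)
  if (a + b == 0) return(structure(1, both_empty = TRUE))
  2 * sum(maskA & maskB) / (a + b)
}

#' Cohen weighted kappa
#'
#' `kappa = 1 - sum(w * O) / sum(w * E)` with disagreement weights `w`
#' linear in the grade difference by default (quadratic available), `O` the
#' observed contingency table and `E` the chance-expected table from the
#' marginals.
#'
#' @param ratings1,ratings2 equal-length integer ratings on 1..K.
#' @param K number of ordinal categories.
#' @param weights `"linear"` or `"quadratic"`.
#' @return kappa in [-1, 1].
#' @export
weighted_kappa <- function(ratings1, ratings2, K = 4L,
                           weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  if (length(ratings1) != length(ratings2)) stopf("rating length mismatch")
  if (any(!ratings1 %in% 1:K) || any(!ratings2 %in% 1:K))
    stopf("ratings outside 1..%d", K)
  n <- length(ratings1)
  O <- table(factor(ratings1, 1:K), factor(ratings2, 1:K)) / n
  E <- outer(rowSums(O), colSums(O))
  w <- abs(outer(1:K, 1:K, `-`)) / (K - 1)
  if (weights == "quadratic") w <- w^2
  1 - sum(w * O) / sum(w * E)
}

# ---- cohort scoring --------------------------------------------------------

#' Score a cohort with a pipeline
#'
#' Runs the two-stage pipeline on every case, extracts candidates, matches
#' them to ground truth, and assembles everything needed by the statistics
#' layer.
#'
#' @param pipeline a `cspca_model`.
#' @param cohort a `phantom_cohort`.
#' @param min_overlap lesion hit threshold (IoU), default 0.10.
#' @return a `scored_cohort`: `patient` data.frame (case_id, score, label,
#'   grade, site), `lesions` (a `lesion_cohort` with `gt_per_case`), and
#'   per-case `dice` of the thresholded confidence against the csPCa mask
#'   (NA for cases with no csPCa).
#' @export
score_cohort <- function(pipeline, cohort, min_overlap = 0.10) {
  stopifnot(inherits(pipeline, "cspca_model"),
            inherits(cohort, "phantom_cohort"))
  pt <- cohort$manifest
  scores <- numeric(length(cohort$cases))
  cand_all <- NULL
  gt_per_case <- integer(length(cohort$cases))
  dices <- rep(NA_real_, length(cohort$cases))
  for (i in seq_along(cohort$cases)) {
    case <- cohort$cases[[i]]
    sc <- score_case(pipeline, case)
    scores[i] <- sc$score
    mm <- match_lesions(sc$candidates, case$masks$lesions,
                        case$masks$lesion_labels, min_overlap = min_overlap)
    gt_per_case[i] <- mm$n_gt
    tab <- candidates_table(case$case_id, sc$candidates)
    tab$is_tp <- mm$is_tp
    cand_all <- rbind(cand_all, tab)
    if (mm$n_gt > 0) {
      ids <- which(case$masks$lesion_labels == "csPCa")
      gt_mask <- array(case$masks$lesions %in% ids,
                       dim = dim(case$masks$lesions))
      pred_mask <- sc$confidence >= pipeline$config$detection_threshold
      dices[i] <- as.numeric(dice(pred_mask, gt_mask))
    }
  }
  if (is.null(cand_all))
    cand_all <- data.frame(case_id = character(0), cand_id = integer(0),
                           probability = numeric(0), is_tp = logical(0))
  lesions <- as_lesion_cohort(cand_all, sum(gt_per_case))
  lesions$gt_per_case <- stats::setNames(gt_per_case, pt$case_id)
  structure(list(
    patient = data.frame(case_id = pt$case_id, score = scores,
                         label = pt$label, grade = pt$grade, site = pt$site,
                         stringsAsFactors = FALSE),
    lesions = lesions, dice = dices), class = "scored_cohort")
}

#' Per-stratum AUC/AUPRC report
#'
#' Applies the same ROC and PR machinery within each stratum of a grouping
#' tag. Strata with a single patient class get `NA` AUC (never silently
#' dropped); strata with no ground-truth lesions get `NA` AUPRC.
#'
#' @param scored a `scored_cohort`.
#' @param by `"grade"` or `"site"`.
#' @return data.frame with stratum, n, n_pos, auc, auprc.
#' @export
subgroup_report <- function(scored, by = c("grade", "site")) {
  by <- match.arg(by)
  tags <- scored$patient[[by]]
  out <- NULL
  for (tg in sort(unique(tags))) {
    sel <- tags == tg
    pat <- scored$patient[sel, , drop = FALSE]
    auc <- if (length(unique(pat$label)) == 2L)
      roc_auc(pat$score, pat$label) else NA_real_
    cand <- scored$lesions$candidates
    cand <- cand[cand$case_id %in% pat$case_id, , drop = FALSE]
    n_gt <- sum(scored$lesions$gt_per_case[pat$case_id])
    auprc <- if (n_gt >= 1)
      lesion_pr_auprc(list(candidates = cand, n_gt = n_gt)) else NA_real_
    out <- rbind(out, data.frame(stratum = as.character(tg), n = sum(sel),
                                 n_pos = sum(pat$label == 1),
                                 auc = auc, auprc = auprc,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Full paired-model comparison report
#'
#' The headline experiment: evaluates a control and a TPAS pipeline on a
#' clean cohort and its attacked twin, and reports per-model clean/attacked
#' AUC and AUPRC with the within-model deltas, DeLong tests and bootstrap
#' AUPRC comparisons for the between-model contrasts, Dice summaries, and
#' subgroup tables.
#'
#' @param control,tpas `cspca_model` pipelines.
#' @param clean_cohort a `phantom_cohort`.
#' @param attacked_cohort its attacked twin (same case ids; e.g.
#'   `attack_cohort(...)$cohort`).
#' @param B bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @param min_overlap lesion hit threshold.
#' @return an `eval_report` list; see fields in the implementation. All
#'   numbers are plain doubles, serializable with [write_report()].
#' @export
compare_models <- function(control, tpas, clean_cohort, attacked_cohort,
                           B = 1000L, seed = 1L, min_overlap = 0.10) {
  if (!identical(clean_cohort$manifest$case_id,
                 attacked_cohort$manifest$case_id))
    stopf("clean and attacked cohorts must cover the same cases in order")
  sc <- list(
    control_clean = score_cohort(control, clean_cohort, min_overlap),
    control_attacked = score_cohort(control, attacked_cohort, min_overlap),
    tpas_clean = score_cohort(tpas, clean_cohort, min_overlap),
    tpas_attacked = score_cohort(tpas, attacked_cohort, min_overlap))
  labels <- sc$control_clean$patient$label
  auc <- lapply(sc, function(s) roc_auc(s$patient$score, s$patient$label))
  auprc <- lapply(sc, function(s) lesion_pr_auprc(s$lesions))
  dl_clean <- delong_test(sc$tpas_clean$patient$score,
                          sc$control_clean$patient$score, labels)
  dl_attacked <- delong_test(sc$tpas_attacked$patient$score,
                             sc$control_attacked$patient$score, labels)
  bs_clean <- bootstrap_auprc_diff(sc$tpas_clean$lesions,
                                   sc$control_clean$lesions, B = B,
                                   seed = derive_seed(seed, "bs-clean"))
  bs_attacked <- bootstrap_auprc_diff(sc$tpas_attacked$lesions,
                                      sc$control_attacked$lesions, B = B,
                                      seed = derive_seed(seed, "bs-att"))
  bs_clean$deltas <- NULL; bs_attacked$deltas <- NULL
  dice_summary <- function(s) {
    v <- s$dice[!is.na(s$dice)]
    list(mean = if (length(v)) mean(v) else NA_real_,
         sd = if (length(v) > 1) stats::sd(v) else NA_real_, n = length(v))
  }
  structure(list(
    n_cases = length(labels),
    auc = auc,
    delta_auc = list(control = auc$control_attacked - auc$control_clean,
                     tpas = auc$tpas_attacked - auc$tpas_clean),
    auprc = auprc,
    delta_auprc = list(control = auprc$control_attacked - auprc$control_clean,
                       tpas = auprc$tpas_attacked - auprc$tpas_clean),
    delong = list(clean = dl_clean, attacked = dl_attacked),
    bootstrap = list(clean = bs_clean, attacked = bs_attacked),
    dice = lapply(sc, dice_summary),
    subgroups = list(
      control_clean_by_grade = subgroup_report(sc$control_clean, "grade"),
      tpas_clean_by_grade = subgroup_report(sc$tpas_clean, "grade"),
      control_clean_by_site = subgroup_report(sc$control_clean, "site"),
      tpas_clean_by_site = subgroup_report(sc$tpas_clean, "site"))),
    class = "eval_report")
}

#' Serialize an evaluation report
#'
#' Writes the full report as JSON plus flat CSV tables (per-model metrics
#' and subgroup tables).
#'
#' @param report an `eval_report`.
#' @param dir output directory.
#' @return invisibly, the JSON path.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass_deep(report), json_path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  flat <- data.frame(
    model = rep(c("control", "tpas"), each = 2),
    cohort = rep(c("clean", "attacked"), 2),
    auc = unlist(report$auc[c("control_clean", "control_attacked",
                              "tpas_clean", "tpas_attacked")]),
    auprc = unlist(report$auprc[c("control_clean", "control_attacked",
                                  "tpas_clean", "tpas_attacked")]))
  utils::write.csv(flat, file.path(dir, "metrics.csv"), row.names = FALSE)
  for (nm in names(report$subgroups))
    utils::write.csv(report$subgroups[[nm]],
                     file.path(dir, paste0("subgroup_", nm, ".csv")),
                     row.names = FALSE)
  invisible(json_path)
}

# strip S3 classes recursively so jsonlite serializes plainly
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (!is.null(attributes(x)) && !is.null(attr(x, "both_empty")))
    return(as.numeric(x))
  x
}
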
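# From confidence maps to lesion candidates and a patient-level score.

# Face-connected component labeling (6-connectivity in 3D, 4 in 2D) by
# vectorized label propagation: every supra-threshold voxel starts with its
# own label (its linear index) and repeatedly adopts the minimum label among
# face neighbours until a fixed point.
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0, dim = d)
  lab[mask] <- which(mask)
  if (!any(mask)) return(lab)
  shifts <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L),
                 c(0L, 1L, 0L), c(0L, -1L, 0L),
                 c(0L, 0L, 1L), c(0L, 0L, -1L))
  repeat {
    old <- lab
    for (s in shifts) {
      nb <- array(Inf, dim = d)
      src_z <- seq_len(d[1]) - s[1]; ok_z <- src_z >= 1L & src_z <= d[1]
      src_y <- seq_len(d[2]) - s[2]; ok_y <- src_y >= 1L & src_y <= d[2]
      src_x <- seq_len(d[3]) - s[3]; ok_x <- src_x >= 1L & src_x <= d[3]
      nb[ok_z, ok_y, ok_x] <- lab[src_z[ok_z], src_y[ok_y], src_x[ok_x]]
      nb[nb == 0] <- Inf
      upd <- mask & nb < lab
      lab[upd] <- nb[upd]
    }
    if (identical(old, lab)) break
  }
  # relabel 1..k in first-voxel order
  u <- sort(unique(lab[lab > 0]))
  out <- array(0L, dim = d)
  out[lab > 0] <- match(lab[lab > 0], u)
  out
}

#' Extract lesion candidates from a confidence map
#'
#' Candidates are the face-connected components (6-connectivity in 3D, 4 in
#' 2D slices) of the voxel set with confidence at or above the threshold,
#' keeping components of at least `min_size` voxels. Each candidate's
#' detection probability is the maximum confidence over its voxels;
#' candidates are returned sorted by descending probability (stable within
#' ties).
#'
#' @param map `(z, y, x)` array of confidences in [0, 1].
#' @param threshold detection threshold in (0, 1).
#' @param min_size minimum component size in voxels (>= 1).
#' @return list of `lesion_candidate` objects: fields `voxels` (linear
#'   indices), `probability`, `centroid` (0-based z/y/x), `volume`.
#' @export
extract_candidates <- function(map, threshold = 0.45, min_size = 1L) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  if (min_size < 1) stopf("min_size must be >= 1")
  if (any(map < 0 | map > 1)) stopf("confidence map values outside [0, 1]")
  d <- dim(map)
  lab <- label_components(map >= threshold)
  k <- max(lab)
  if (k == 0L) return(list())
  g <- coord_grids(d)
  cands <- list()
  for (i in seq_len(k)) {
    vox <- which(lab == i)
    if (length(vox) < min_size) next
    cands[[length(cands) + 1L]] <- structure(
      list(voxels = vox,
           probability = max(map[vox]),
           centroid = c(z = mean(g$z[vox]), y = mean(g$y[vox]),
                        x = mean(g$x[vox])),
           volume = length(vox)),
      class = "lesion_candidate")
  }
  ord <- order(-vapply(cands, `[[`, 0, "probability"),
               vapply(cands, function(cn) cn$voxels[1], 0))
  cands[ord]
}

#' Patient-level csPCa prediction score
#'
#' The maximum candidate detection probability, or 0 when the case has no
#' candidates.
#'
#' @param candidates a list from [extract_candidates()].
#' @return scalar in [0, 1].
#' @export
patient_score <- function(candidates) {
  if (length(candidates) == 0L) return(0)
  max(vapply(candidates, `[[`, 0, "probability"))
}

#' Match candidates to ground-truth lesions
#'
#' Greedy matching in descending candidate probability against the csPCa
#' ground-truth instances: a candidate is a true positive when its overlap
#' with an as-yet-unmatched csPCa lesion reaches `min_overlap`; each
#' ground-truth lesion is matched at most once. Overlap is
#' intersection-over-union by default (`mode = "iou"`), or intersection
#' over ground-truth size (`mode = "gt_fraction"`).
#'
#' @param candidates list from [extract_candidates()].
#' @param gt_instances integer instance mask (lesion ids > 0).
#' @param gt_labels named label vector (`"csPCa"`/`"nonCS"`), names = ids.
#' @param min_overlap hit threshold in (0, 1]; default 0.10.
#' @param mode overlap definition.
#' @return list with `tp` (data.frame candidate/gt/overlap), `fp` (candidate
#'   indices), `fn` (unmatched csPCa gt ids), and per-candidate logical
#'   `is_tp`.
#' @export
match_lesions <- function(candidates, gt_instances, gt_labels,
                          min_overlap = 0.10, mode = c("iou", "gt_fraction")) {
  mode <- match.arg(mode)
  if (min_overlap <= 0 || min_overlap > 1)
    stopf("min_overlap must be in (0, 1]")
  ids <- sort(unique(as.vector(gt_instances[gt_instances > 0L])))
  cs_ids <- ids[gt_labels[as.character(ids)] == "csPCa"]
  gt_vox <- lapply(cs_ids, function(i) which(gt_instances == i))
  names(gt_vox) <- as.character(cs_ids)
  matched <- setNames(rep(FALSE, length(cs_ids)), as.character(cs_ids))
  is_tp <- logical(length(candidates))
  tp <- data.frame(candidate = integer(0), gt = integer(0),
                   overlap = numeric(0))
  for (ci in seq_along(candidates)) {
    cv <- candidates[[ci]]$voxels
    best <- 0; best_id <- NA_integer_
    for (gi in cs_ids[!matched[as.character(cs_ids)]]) {
      gv <- gt_vox[[as.character(gi)]]
      inter <- length(intersect(cv, gv))
      ov <- if (mode == "iou")
        inter / (length(cv) + length(gv) - inter)
      else inter / length(gv)
      if (ov > best) { best <- ov; best_id <- gi }
    }
    if (!is.na(best_id) && best >= min_overlap) {
      matched[as.character(best_id)] <- TRUE
      is_tp[ci] <- TRUE
      tp <- rbind(tp, data.frame(candidate = ci, gt = best_id,
                                 overlap = best))
    }
  }
  list(tp = tp, fp = which(!is_tp), fn = cs_ids[!matched[as.character(cs_ids)]],
       is_tp = is_tp, n_gt = length(cs_ids))
}

#' Export candidates of a case as a data.frame (CSV-ready)
#'
#' @param case_id the case identifier.
#' @param candidates list from [extract_candidates()].
#' @return data.frame with case_id, cand_id, probability, volume, centroid.
#' @export
candidates_table <- function(case_id, candidates) {
  if (length(candidates) == 0L)
    return(data.frame(case_id = character(0), cand_id = integer(0),
                      probability = numeric(0), volume = integer(0),
                      centroid_z = numeric(0), centroid_y = numeric(0),
                      centroid_x = numeric(0)))
  data.frame(
    case_id = case_id,
    cand_id = seq_along(candidates),
    probability = vapply(candidates, `[[`, 0, "probability"),
    volume = vapply(candidates, `[[`, 0L, "volume"),
    centroid_z = vapply(candidates, function(cn) cn$centroid[["z"]], 0),
    centroid_y = vapply(candidates, function(cn) cn$centroid[["y"]], 0),
    centroid_x = vapply(candidates, function(cn) cn$centroid[["x"]], 0))
}
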
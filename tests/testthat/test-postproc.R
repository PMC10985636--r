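toy_map <- function(vals, shape = c(1L, length(vals), 1L)) {
  array(vals, dim = shape)
}

test_that("candidate extraction handles trivial maps", {
  expect_length(extract_candidates(array(0, dim = c(1, 8, 8))), 0)

  # two disjoint supra-threshold blobs with known max probabilities
  m <- array(0, dim = c(1, 8, 8))
  m[1, 2:3, 2:3] <- c(0.6, 0.7, 0.8, 0.9)
  m[1, 6:7, 6] <- 0.5
  cands <- extract_candidates(m, threshold = 0.45)
  expect_length(cands, 2)
  expect_equal(cands[[1]]$probability, 0.9)
  expect_equal(cands[[2]]$probability, 0.5)
  expect_equal(cands[[1]]$volume, 4L)
  expect_true(all(diff(vapply(cands, `[[`, 0, "probability")) <= 0))

  expect_error(extract_candidates(m, threshold = 0), "threshold")
  expect_error(extract_candidates(m * 3), "outside")
})

test_that("component labeling matches brute-force flood fill on random grids", {
  for (s in 1:12) {
    mask <- tpas:::with_seed(s, array(runif(16^3) < 0.25, dim = c(16, 16, 16)))
    fast <- tpas:::label_components(mask)
    slow <- bruteforce_components(mask)
    expect_equal(max(fast), max(slow))
    # identical partitions: label images agree up to renaming
    expect_equal(length(unique(paste(fast[mask], slow[mask]))), max(slow))
  }
})

test_that("min_size filters small components", {
  m <- array(0, dim = c(1, 8, 8))
  m[1, 1, 1] <- 0.9
  m[1, 4:6, 4] <- 0.8
  expect_length(extract_candidates(m, min_size = 2), 1)
  expect_length(extract_candidates(m, min_size = 1), 2)
})

test_that("patient score is the max candidate probability, 0 when empty", {
  expect_equal(patient_score(list()), 0)
  mk <- function(p) structure(list(voxels = 1L, probability = p,
                                   centroid = c(z = 0, y = 0, x = 0),
                                   volume = 1L), class = "lesion_candidate")
  expect_equal(patient_score(list(mk(0.7))), 0.7)
  expect_equal(patient_score(list(mk(0.3), mk(0.6))), 0.6)
})

test_that("lesion matching implements the 0.10 IoU hit rule exactly", {
  shape <- c(1L, 10L, 10L)
  gt <- array(0L, dim = shape)
  gt[1, 2:5, 2:5] <- 1L            # 16 voxels
  labels <- c(`1` = "csPCa")

  mk_cand <- function(vox, p) structure(
    list(voxels = vox, probability = p, centroid = c(z = 0, y = 0, x = 0),
         volume = length(vox)), class = "lesion_candidate")

  # identical candidate -> IoU 1 -> TP
  mm <- match_lesions(list(mk_cand(which(gt == 1L), 0.9)), gt, labels)
  expect_equal(mm$tp$overlap, 1.0)
  expect_true(mm$is_tp[1])
  expect_length(mm$fn, 0)

  # |I|=1, |U|=20: candidate of 5 voxels, 1 inside -> IoU 0.05 -> FP + FN
  inside <- which(gt == 1L)[1]
  outside <- which(gt == 0L)[1:4]
  mm <- match_lesions(list(mk_cand(c(inside, outside), 0.8)), gt, labels)
  expect_false(mm$is_tp[1])
  expect_equal(mm$fn, 1L)

  # |I|=2, |U|=18: 4-voxel candidate, 2 inside, gt 16 -> IoU 2/18 >= 0.10 -> TP
  cand <- c(which(gt == 1L)[1:2], which(gt == 0L)[1:2])
  mm <- match_lesions(list(mk_cand(cand, 0.8)), gt, labels)
  expect_true(mm$is_tp[1])
  expect_equal(mm$tp$overlap, 2 / 18)
})

test_that("greedy matching pairs each ground-truth lesion at most once", {
  shape <- c(1L, 12L, 12L)
  gt <- array(0L, dim = shape)
  gt[1, 2:4, 2:4] <- 1L
  labels <- c(`1` = "csPCa")
  vox <- which(gt == 1L)
  mk <- function(v, p) structure(
    list(voxels = v, probability = p, centroid = c(z = 0, y = 0, x = 0),
         volume = length(v)), class = "lesion_candidate")
  # two candidates both overlapping the same lesion: higher prob wins, the
  # other becomes FP
  mm <- match_lesions(list(mk(vox[1:5], 0.9), mk(vox[4:9], 0.7)), gt, labels)
  expect_equal(sum(mm$is_tp), 1L)
  expect_equal(mm$fp, 2L)
})

test_that("raising min_overlap never increases the TP count", {
  for (s in 1:25) {
    env <- tpas:::with_seed(s, {
      shape <- c(1L, 12L, 12L)
      gt <- array(0L, dim = shape)
      n_gt <- sample(1:3, 1)
      for (i in seq_len(n_gt)) {
        y <- sample(2:10, 1); x <- sample(2:10, 1)
        gt[1, y + (-1:1), x + (-1:1)] <- i
      }
      labels <- setNames(rep("csPCa", n_gt), seq_len(n_gt))
      cands <- lapply(1:3, function(i) {
        vox <- sample(prod(shape), sample(3:12, 1))
        structure(list(voxels = vox, probability = runif(1),
                       centroid = c(z = 0, y = 0, x = 0),
                       volume = length(vox)), class = "lesion_candidate")
      })
      list(gt = gt, labels = labels, cands = cands)
    })
    tps <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(th)
      sum(match_lesions(env$cands, env$gt, env$labels,
                        min_overlap = th)$is_tp), 0L)
    expect_true(all(diff(tps) <= 0))
  }
})
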
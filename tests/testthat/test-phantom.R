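test_that("case generation is deterministic and structurally valid", {
  cfg <- tiny_phantom_config()
  a <- generate_case(cfg, 7)
  b <- generate_case(cfg, 7)
  expect_identical(a, b)
  expect_true(tpas:::validate_case(a))
  d <- generate_case(cfg, 8)
  expect_false(identical(a$volume$t2w, d$volume$t2w))
})

test_that("zone partition and lesion containment hold across many cases", {
  cfg <- tiny_phantom_config()
  for (s in 1:20) {
    case <- generate_case(cfg, 1000 + s)
    m <- case$masks
    expect_false(any(m$pz & m$tz))
    expect_identical(m$pz | m$tz, m$gland)
    expect_true(all(m$lesions[!m$gland] == 0L))
    expect_false(any(m$rectum & m$gland))
    expect_identical(case$patient_label, any(m$lesion_labels == "csPCa"))
  }
})

test_that("rectum sits posterior-adjacent to the gland", {
  case <- generate_case(phantom_config(), 21)
  g <- tpas:::coord_grids(case$volume$shape)
  sp <- case$volume$spacing
  # minimum surface distance between gland and rectum within the configured gap
  gy <- g$y[case$masks$gland]; gx <- g$x[case$masks$gland]
  ry <- g$y[case$masks$rectum]; rx <- g$x[case$masks$rectum]
  dmin <- min(sqrt(outer(ry, gy, "-")^2 * sp[2]^2 +
                     outer(rx, gx, "-")^2 * sp[3]^2))
  expect_lte(dmin, phantom_config()$rectum_gap_mm + max(sp[2:3]))
  expect_gt(mean(ry), mean(gy))   # posterior
})

test_that("zero prevalence forces negative patients; prevalence is calibrated", {
  cfg0 <- tiny_phantom_config(prevalence = 0)
  for (s in 1:8) {
    case <- generate_case(cfg0, 300 + s)
    expect_false(case$patient_label)
    expect_false(any(case$masks$lesion_labels == "csPCa"))
  }
  # 200 cases at prevalence 0.5: csPCa fraction inside the binomial 99%
  # interval (computed from qbinom)
  coh <- generate_cohort(200, tiny_phantom_config(prevalence = 0.5), seed = 1)
  k <- sum(coh$manifest$label)
  expect_gte(k, qbinom(0.005, 200, 0.5))
  expect_lte(k, qbinom(0.995, 200, 0.5))
})

test_that("cohort generation is deterministic with multinomial grade mix", {
  cfg <- tiny_phantom_config()
  a <- generate_cohort(10, cfg, 3)
  b <- generate_cohort(10, cfg, 3)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$cases[[5]], b$cases[[5]])
  expect_error(generate_cohort(0, cfg, 1), "cohort size")

  # all-grade-1 config: the clean filter keeps everything
  coh1 <- generate_cohort(10, tiny_phantom_config(grade_probs = c(1, 0, 0, 0)), 4)
  expect_equal(nrow(filter_clean(coh1)$manifest), 10)

  # per-grade counts within multinomial 99% bounds (per-margin binomial)
  p <- c(0.7, 0.1, 0.1, 0.1)
  coh <- generate_cohort(1000, tiny_phantom_config(grade_probs = p), 5)
  counts <- tabulate(coh$manifest$grade, 4)
  for (gidx in 1:4) {
    expect_gte(counts[gidx], qbinom(0.005 / 4, 1000, p[gidx]))
    expect_lte(counts[gidx], qbinom(1 - 0.005 / 4, 1000, p[gidx]))
  }
})

test_that("artifact application respects grade semantics and intensity ranges", {
  cfg <- tiny_phantom_config(grade_probs = c(1, 0, 0, 0))
  case <- generate_case(cfg, 55)

  # grade 1: untouched volume, empty mask
  g1 <- apply_visible_artifact(case, artifact_spec(1))
  expect_identical(g1$volume$t2w, case$volume$t2w)
  expect_false(any(g1$artifact_mask))

  # zero amplitude: untouched voxels, nonempty mask allowed
  g2z <- apply_visible_artifact(case, artifact_spec(2, 0.3, amplitude = 0))
  expect_equal(g2z$volume$t2w, case$volume$t2w)
  expect_true(any(g2z$artifact_mask))

  # grade 4 reaches the TZ
  g4 <- apply_visible_artifact(case, artifact_spec(4, 0.6, tz_involved = TRUE))
  expect_true(any(g4$artifact_mask & g4$masks$tz))

  # intensity clipping: ranges unchanged after application
  g3 <- apply_visible_artifact(case, artifact_spec(3, 0.7, amplitude = 0.5))
  for (ch in c("t2w", "dwi", "adc")) {
    rng <- case$volume$ranges[[ch]]
    expect_gte(min(g3$volume[[ch]]), rng[1])
    expect_lte(max(g3$volume[[ch]]), rng[2])
  }

  expect_error(artifact_spec(5), "grade")
  expect_error(artifact_spec(2, 0.7), "inconsistent")
})

test_that("automated grading inverts artifact generation", {
  cfg <- tiny_phantom_config()
  base <- generate_case(tiny_phantom_config(grade_probs = c(1, 0, 0, 0)), 77)
  expect_equal(grade_artifact(base), 1L)
  for (s in 1:24) {
    g <- ((s - 1) %% 4) + 1
    spec <- tpas:::random_artifact_spec(g, cfg, 5000 + s)
    expect_equal(grade_artifact(apply_visible_artifact(base, spec)), g)
  }
  # hand-built fractions at the 0.5 boundary
  expect_equal(grade_artifact(
    apply_visible_artifact(base, artifact_spec(2, 0.3))), 2L)
  expect_equal(grade_artifact(
    apply_visible_artifact(base, artifact_spec(3, 0.7))), 3L)
  expect_equal(grade_artifact(
    apply_visible_artifact(base, artifact_spec(4, 0.7, tz_involved = TRUE))), 4L)
})

test_that("case serialization round-trips exactly through NIfTI + JSON", {
  case <- generate_case(tiny_phantom_config(), 99)
  dir <- withr::local_tempdir()
  write_case(case, dir)
  back <- read_case(dir, case$case_id)
  expect_equal(back$volume$t2w, case$volume$t2w, tolerance = 0)
  expect_equal(back$volume$adc, case$volume$adc, tolerance = 0)
  expect_identical(back$masks$lesions, case$masks$lesions)
  expect_identical(back$masks$pz, case$masks$pz)
  expect_identical(back$masks$lesion_labels, case$masks$lesion_labels)
  expect_identical(back$patient_label, case$patient_label)
  expect_equal(back$artifact, case$artifact)
  expect_identical(back$artifact_mask, case$artifact_mask)

  # corrupt sidecar -> explicit parse error
  writeLines("{not json", file.path(dir, paste0(case$case_id, ".json")))
  expect_error(read_case(dir, case$case_id), "corrupt sidecar")
  # missing file
  expect_error(read_case(dir, "no-such-case"), "missing sidecar")
})

test_that("cohort write/read round-trips with manifest", {
  coh <- generate_cohort(3, tiny_phantom_config(), 12)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$manifest, coh$manifest)
  expect_equal(back$cases[[2]]$volume$dwi, coh$cases[[2]]$volume$dwi,
               tolerance = 0)
})

test_that("degenerate configs are rejected", {
  expect_error(phantom_config(shape = c(0, 64, 64)), "positive")
  expect_error(phantom_config(lesion_radius_mm = c(50, 60)), "exceeds")
  expect_error(phantom_config(prevalence = 2), "prevalence")
})
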
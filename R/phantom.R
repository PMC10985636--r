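# Synthetic biparametric-MRI phantom cohorts.
#
# Coordinate convention (used everywhere in this package): arrays are indexed
# (z, y, x), voxel indices are 0-based in documentation, masks are logical
# arrays over the same grid. y grows toward posterior, so the rectum sits at
# larger y than the gland.

#' Phantom generation configuration
#'
#' Defines the study conditions a generated cohort emulates: grid geometry,
#' per-channel intensity ranges, tissue noise, lesion sizes and contrast,
#' csPCa prevalence, and the artifact-grade distribution.
#'
#' @param shape integer voxel counts per axis, `(z, y, x)`. Default is the
#'   2D-slice desk scale `c(1, 64, 64)`.
#' @param spacing per-axis voxel size in mm, `(z, y, x)`.
#' @param ranges named list of `c(lo, hi)` intensity ranges for `t2w`, `dwi`,
#'   `adc` (arbitrary units).
#' @param noise_sd_frac tissue noise standard deviation as a fraction of each
#'   channel's intensity range.
#' @param contrast_margin lesion contrast in units of the background noise
#'   standard deviation. csPCa lesions get reduced ADC, elevated DWI and
#'   reduced T2W signal by this many sigma; indolent lesions get one third of
#'   the offset.
#' @param lesion_radius_mm range (mm) of lesion radii.
#' @param max_lesions maximum number of lesions per case.
#' @param prevalence probability that a case harbours at least one csPCa
#'   lesion (the patient label).
#' @param grade_probs length-4 probability vector over artifact grades 1-4.
#' @param artifact_amplitude artifact strength as a fraction of channel range.
#' @param band_period_mm spatial period of the alternating artifact bands.
#' @param rectum_gap_mm maximum allowed gland-rectum surface gap.
#' @param sites character vector of site tags cases are assigned to
#'   (uniformly).
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(1L, 64L, 64L),
                           spacing = c(3, 1, 1),
                           ranges = list(t2w = c(0, 1000),
                                         dwi = c(0, 800),
                                         adc = c(400, 2400)),
                           noise_sd_frac = 0.04,
                           contrast_margin = 3,
                           lesion_radius_mm = c(2.5, 5),
                           max_lesions = 2L,
                           prevalence = 0.5,
                           grade_probs = c(0.7, 0.1, 0.1, 0.1),
                           artifact_amplitude = 0.25,
                           band_period_mm = 8,
                           rectum_gap_mm = 2,
                           sites = c("siteA", "siteB")) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stopf("shape must be three positive voxel counts")
  if (any(spacing <= 0)) stopf("spacing must be positive")
  for (ch in c("t2w", "dwi", "adc")) {
    r <- ranges[[ch]]
    if (is.null(r) || length(r) != 2L || r[2] <= r[1])
      stopf("ranges$%s must be c(lo, hi) with hi > lo", ch)
  }
  if (prevalence < 0 || prevalence > 1) stopf("prevalence must be in [0, 1]")
  if (length(grade_probs) != 4L || any(grade_probs < 0) || sum(grade_probs) <= 0)
    stopf("grade_probs must be 4 nonnegative weights")
  # geometric feasibility: a minimal lesion must fit inside the gland
  gland_ry <- 0.22 * shape[2] * spacing[2]
  if (lesion_radius_mm[1] > gland_ry)
    stopf("lesion radius %.1f mm exceeds gland radius %.1f mm",
          lesion_radius_mm[1], gland_ry)
  structure(list(shape = shape, spacing = as.numeric(spacing), ranges = ranges,
                 noise_sd_frac = noise_sd_frac,
                 contrast_margin = contrast_margin,
                 lesion_radius_mm = lesion_radius_mm,
                 max_lesions = as.integer(max_lesions),
                 prevalence = prevalence,
                 grade_probs = grade_probs / sum(grade_probs),
                 artifact_amplitude = artifact_amplitude,
                 band_period_mm = band_period_mm,
                 rectum_gap_mm = rectum_gap_mm,
                 sites = sites),
            class = "phantom_config")
}

#' Artifact severity specification
#'
#' Encodes the four-point clinical severity scale: grade 1 no artifact;
#' grade 2 affecting under half of the peripheral zone; grade 3 affecting
#' half or more of the peripheral zone without the transition zone; grade 4
#' extending into the transition zone.
#'
#' @param grade integer severity 1-4.
#' @param pz_affected_fraction fraction of peripheral-zone voxels affected.
#' @param tz_involved logical, artifact reaches the transition zone.
#' @param amplitude artifact strength (fraction of channel intensity range).
#' @param band_period mm period of the alternating bands.
#' @param seed integer seed for the artifact's random texture.
#' @return an object of class `artifact_spec`.
#' @export
artifact_spec <- function(grade, pz_affected_fraction = 0,
                          tz_involved = FALSE, amplitude = 0.25,
                          band_period = 8, seed = 0L) {
  grade <- as.integer(grade)
  if (is.na(grade) || grade < 1L || grade > 4L)
    stopf("artifact grade must be 1, 2, 3 or 4")
  f <- pz_affected_fraction
  if (f < 0 || f > 1) stopf("pz_affected_fraction must be in [0, 1]")
  ok <- switch(grade,
               `1` = (f == 0 && !tz_involved),
               `2` = (f > 0 && f < 0.5 && !tz_involved),
               `3` = (f >= 0.5 && f <= 1 && !tz_involved),
               `4` = isTRUE(tz_involved))
  if (!isTRUE(ok))
    stopf("inconsistent artifact spec: grade %d with fraction %.3f, tz %s",
          grade, f, tz_involved)
  structure(list(grade = grade, pz_affected_fraction = f,
                 tz_involved = isTRUE(tz_involved), amplitude = amplitude,
                 band_period = band_period, seed = as.integer(seed)),
            class = "artifact_spec")
}

# Draw a random but grade-consistent artifact spec.
random_artifact_spec <- function(grade, config, seed) {
  with_seed(seed, {
    f <- switch(grade,
                `1` = 0,
                `2` = stats::runif(1, 0.08, 0.45),
                `3` = stats::runif(1, 0.5, 0.95),
                `4` = stats::runif(1, 0.4, 0.95))
    artifact_spec(grade, pz_affected_fraction = f,
                  tz_involved = (grade == 4L),
                  amplitude = config$artifact_amplitude,
                  band_period = config$band_period_mm,
                  seed = derive_seed(seed, "texture"))
  })
}

# Ellipsoid mask helper: 0-based centers/semi-axes in voxel units.
ellipsoid_mask <- function(shape, center, semi) {
  g <- coord_grids(shape)
  ((g$z - center[1]) / semi[1])^2 + ((g$y - center[2]) / semi[2])^2 +
    ((g$x - center[3]) / semi[3])^2 <= 1
}

#' Generate one synthetic patient case
#'
#' Builds a three-channel (T2W, DWI, ADC) phantom with an ellipsoidal
#' prostate gland split into transition and peripheral zones, a
#' posterior-adjacent rectum, optional lesions with channel-consistent csPCa
#' contrast (low ADC, high DWI, low T2W), and a rectal artifact drawn from
#' the configured grade distribution.
#'
#' @param config a [phantom_config()].
#' @param seed integer; identical `(config, seed)` yields a bit-identical case.
#' @param case_id case identifier string.
#' @return an object of class `phantom_case` with fields `case_id`, `volume`
#'   (list t2w/dwi/adc arrays plus `spacing`, `shape`, `ranges`), `masks`
#'   (gland, pz, tz, rectum, body logical arrays; `lesions` integer instance
#'   mask; `lesion_labels` named character vector `"csPCa"`/`"nonCS"`),
#'   `artifact` spec, `artifact_mask`, `patient_label`, `site_tag`.
#' @export
generate_case <- function(config, seed, case_id = sprintf("case-%06d", seed)) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape
  with_seed(derive_seed(seed, "case"), {
    Z <- shape[1]; Y <- shape[2]; X <- shape[3]
    # gland geometry with mild per-case jitter
    cy <- 0.52 * Y + stats::runif(1, -1.5, 1.5)
    cx <- 0.50 * X + stats::runif(1, -1.5, 1.5)
    cz <- (Z - 1) / 2
    ry <- 0.22 * Y * stats::runif(1, 0.9, 1.1)
    rx <- 0.28 * X * stats::runif(1, 0.9, 1.1)
    rz <- if (Z == 1L) 1 else 0.45 * Z
    gland <- ellipsoid_mask(shape, c(cz, cy, cx), c(rz, ry, rx))
    tz <- ellipsoid_mask(shape, c(cz, cy - 0.25 * ry, cx),
                         c(max(rz * 0.7, 0.6), 0.58 * ry, 0.62 * rx)) & gland
    pz <- gland & !tz
    # rectum: posterior tube nearly touching the gland
    rr <- 0.10 * Y
    rect_cy <- cy + ry + rr + config$rectum_gap_mm / config$spacing[2] * 0.5
    g <- coord_grids(shape)
    rectum <- ((g$y - rect_cy) / rr)^2 + ((g$x - cx) / rr)^2 <= 1
    rectum <- rectum & !gland
    body <- ellipsoid_mask(shape, c(cz, (Y - 1) / 2, (X - 1) / 2),
                           c(max(rz, 1), 0.48 * Y, 0.48 * X)) | gland | rectum

    # lesions
    is_pos <- stats::runif(1) < config$prevalence
    n_les <- sample.int(config$max_lesions + 1L, 1L) - 1L
    if (is_pos && n_les == 0L) n_les <- 1L
    lesions <- array(0L, dim = shape)
    labels <- character(0)
    gland_idx <- which(gland)
    placed <- 0L
    if (n_les > 0L && length(gland_idx) > 0L) {
      for (li in seq_len(n_les)) {
        for (try in 1:25) {
          ctr_i <- gland_idx[sample.int(length(gland_idx), 1L)]
          ctr <- c(g$z[ctr_i], g$y[ctr_i], g$x[ctr_i])
          r_mm <- stats::runif(1, config$lesion_radius_mm[1],
                               config$lesion_radius_mm[2])
          semi <- pmax(r_mm / config$spacing, 0.51)
          vox <- ellipsoid_mask(shape, ctr, semi) & gland
          if (sum(vox) >= 3 && !any(lesions[vox] > 0L)) {
            placed <- placed + 1L
            lesions[vox] <- placed
            is_cs <- if (is_pos && placed == 1L) TRUE
                     else if (!is_pos) FALSE
                     else stats::runif(1) < 0.5
            labels <- c(labels, if (is_cs) "csPCa" else "nonCS")
            break
          }
        }
      }
    }
    names(labels) <- as.character(seq_along(labels))
    patient_label <- any(labels == "csPCa")

    # tissue intensities per channel: fractions of [lo, hi]
    levels <- list(
      t2w = c(air = 0.02, bg = 0.18, pz = 0.72, tz = 0.45, rectum = 0.30),
      dwi = c(air = 0.02, bg = 0.15, pz = 0.28, tz = 0.32, rectum = 0.20),
      adc = c(air = 0.05, bg = 0.45, pz = 0.78, tz = 0.60, rectum = 0.50))
    # csPCa direction per channel (sign of the sigma offset)
    lesion_dir <- c(t2w = -1, dwi = +1, adc = -1)
    vol <- list()
    for (ch in c("t2w", "dwi", "adc")) {
      rng <- config$ranges[[ch]]
      span <- rng[2] - rng[1]
      sigma <- config$noise_sd_frac * span
      lv <- levels[[ch]]
      base <- array(lv["air"], dim = shape)
      base[body] <- lv["bg"]
      base[pz] <- lv["pz"]
      base[tz] <- lv["tz"]
      base[rectum] <- lv["rectum"]
      img <- rng[1] + base * span
      if (placed > 0L) {
        for (li in seq_len(placed)) {
          m <- config$contrast_margin * (if (labels[li] == "csPCa") 1 else 1 / 3)
          img[lesions == li] <- img[lesions == li] +
            lesion_dir[ch] * m * sigma
        }
      }
      img <- img + stats::rnorm(length(img), 0, sigma)
      vol[[ch]] <- clamp(img, rng[1], rng[2])
    }

    site <- config$sites[sample.int(length(config$sites), 1L)]
    grade <- sample.int(4L, 1L, prob = config$grade_probs)
    case <- structure(list(
      case_id = case_id,
      volume = list(t2w = vol$t2w, dwi = vol$dwi, adc = vol$adc,
                    spacing = config$spacing, shape = shape,
                    ranges = config$ranges),
      masks = list(gland = gland, pz = pz, tz = tz, rectum = rectum,
                   body = body, lesions = lesions, lesion_labels = labels),
      artifact = artifact_spec(1L, seed = derive_seed(seed, "artifact")),
      artifact_mask = array(FALSE, dim = shape),
      patient_label = patient_label,
      site_tag = site), class = "phantom_case")
    spec <- random_artifact_spec(grade, config, derive_seed(seed, "artifact"))
    apply_visible_artifact(case, spec)
  })
}

# Distance (mm) from every voxel to the rectum axis, used to shape the
# artifact's decay away from the rectum.
rectum_distance_mm <- function(case) {
  m <- case$masks$rectum
  sp <- case$volume$spacing
  g <- coord_grids(case$volume$shape)
  if (!any(m)) stopf("case has an empty rectum mask")
  ry <- mean(g$y[m]); rx <- mean(g$x[m])
  sqrt(((g$y - ry) * sp[2])^2 + ((g$x - rx) * sp[3])^2)
}

#' Imprint a graded rectal artifact on a case
#'
#' Adds a structured perturbation emanating from the rectum into the gland:
#' alternating signal bands (period `spec$band_period` mm) that decay with
#' distance from the rectum, plus random Gaussian signal pile-up/dropout
#' blobs. The affected region covers exactly the configured fraction of the
#' peripheral zone (the closest-to-rectum voxels), extends into the
#' transition zone iff the spec is grade 4, and is recorded in
#' `artifact_mask`. Channel intensities are re-clipped to their configured
#' ranges afterwards, so artifact application never violates range
#' invariants.
#'
#' @param case a [generate_case()] result.
#' @param spec an [artifact_spec()].
#' @return the case with perturbed channels, `artifact` and `artifact_mask`
#'   updated. A grade-1 spec returns the input volume unchanged with an
#'   empty artifact mask.
#' @export
apply_visible_artifact <- function(case, spec) {
  stopifnot(inherits(case, "phantom_case"), inherits(spec, "artifact_spec"))
  shape <- case$volume$shape
  case$artifact <- spec
  if (spec$grade == 1L) {
    case$artifact_mask <- array(FALSE, dim = shape)
    return(case)
  }
  d <- rectum_distance_mm(case)
  pz <- case$masks$pz; tz <- case$masks$tz
  npz <- sum(pz)
  if (npz == 0L) stopf("case has an empty peripheral-zone mask")
  k <- round(spec$pz_affected_fraction * npz)
  half <- ceiling(npz / 2)
  k <- switch(as.character(spec$grade),
              "2" = clamp(k, 1L, half - 1L),
              "3" = clamp(k, half, npz),
              "4" = clamp(k, 1L, npz))
  pz_idx <- which(pz)
  sel <- pz_idx[order(d[pz_idx])][seq_len(k)]
  mask <- array(FALSE, dim = shape)
  mask[sel] <- TRUE
  if (spec$tz_involved) {
    tz_idx <- which(tz)
    ktz <- max(1L, round(0.15 * length(tz_idx)))
    mask[tz_idx[order(d[tz_idx])][seq_len(ktz)]] <- TRUE
  }
  # spill into the non-gland tissue between rectum and gland for realism
  dmax <- max(d[mask])
  spill <- case$masks$body & !case$masks$gland & !case$masks$rectum & d <= dmax
  mask <- mask | spill

  pattern <- with_seed(spec$seed, {
    bands <- sin(2 * pi * d / spec$band_period) * exp(-d / 25)
    blob <- array(0, dim = shape)
    midx <- which(mask)
    g <- coord_grids(shape)
    sp <- case$volume$spacing
    for (b in 1:3) {
      ci <- midx[sample.int(length(midx), 1L)]
      sgn <- sample(c(-1, 1), 1L)
      d2 <- ((g$z - g$z[ci]) * sp[1])^2 + ((g$y - g$y[ci]) * sp[2])^2 +
        ((g$x - g$x[ci]) * sp[3])^2
      blob <- blob + sgn * exp(-d2 / (2 * 2.5^2))
    }
    bands + blob
  })
  chan_scale <- c(t2w = 1.0, dwi = 1.3, adc = 1.1)
  for (ch in c("t2w", "dwi", "adc")) {
    rng <- case$volume$ranges[[ch]]
    img <- case$volume[[ch]]
    img[mask] <- img[mask] +
      spec$amplitude * (rng[2] - rng[1]) * chan_scale[ch] * pattern[mask]
    case$volume[[ch]] <- clamp(img, rng[1], rng[2])
  }
  case$artifact_mask <- mask
  case
}

#' Grade the artifact severity of a case
#'
#' Automated counterpart of the radiologists' four-point scale: grade 1 when
#' no voxel is affected; grade 4 when the artifact reaches the transition
#' zone; otherwise grade 2 or 3 according to whether the affected fraction
#' of the peripheral zone is below or at least one half.
#'
#' @param case a `phantom_case` with `artifact_mask` and zone masks.
#' @return integer grade in 1-4.
#' @export
grade_artifact <- function(case) {
  stopifnot(inherits(case, "phantom_case"))
  pz <- case$masks$pz
  if (sum(pz) == 0L) stopf("cannot grade a case with an empty PZ mask")
  mask <- case$artifact_mask
  if (!any(mask)) return(1L)
  if (any(mask & case$masks$tz)) return(4L)
  f <- sum(mask & pz) / sum(pz)
  if (f == 0) return(1L)
  if (f < 0.5) 2L else 3L
}

#' Generate a cohort of phantom cases with a manifest
#'
#' @param n number of cases (>= 1).
#' @param config a [phantom_config()].
#' @param seed integer; per-case seeds are derived from it.
#' @param prefix case-id prefix.
#' @return an object of class `phantom_cohort`: list with `cases` and a
#'   `manifest` data.frame (case_id, label, grade, site).
#' @export
generate_cohort <- function(n, config, seed, prefix = "case") {
  if (n < 1) stopf("cohort size must be >= 1")
  cases <- lapply(seq_len(n), function(i)
    generate_case(config, derive_seed(seed, "cohort", i),
                  case_id = sprintf("%s-%04d", prefix, i)))
  manifest <- data.frame(
    case_id = vapply(cases, `[[`, "", "case_id"),
    label = vapply(cases, function(cs) as.integer(cs$patient_label), 0L),
    grade = vapply(cases, function(cs) cs$artifact$grade, 0L),
    site = vapply(cases, `[[`, "", "site_tag"),
    stringsAsFactors = FALSE)
  structure(list(cases = cases, manifest = manifest), class = "phantom_cohort")
}

#' Keep only artifact-free cases (grade 1)
#'
#' Reproduces the construction of a "clean" external testing set from which
#' adversarial counterparts are later generated.
#'
#' @param cohort a `phantom_cohort`.
#' @return the filtered `phantom_cohort`.
#' @export
filter_clean <- function(cohort) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  keep <- cohort$manifest$grade == 1L
  structure(list(cases = cohort$cases[keep],
                 manifest = cohort$manifest[keep, , drop = FALSE]),
            class = "phantom_cohort")
}

# ---- NIfTI + JSON sidecar serialization -----------------------------------

nifti_write <- function(arr, path, spacing, datatype) {
  attr(arr, "pixdim") <- spacing
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = datatype)
  invisible(path)
}

nifti_read_array <- function(path) {
  a <- RNifti::readNifti(path)
  arr <- array(as.vector(a), dim = dim(a))
  arr
}

#' Write a phantom case to disk
#'
#' Channels are stored as double-precision NIfTI, masks as unsigned integer
#' NIfTI, and all metadata (spec, labels, ranges, spacing) in a JSON
#' sidecar, one file set per case. [read_case()] restores the case exactly.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if missing).
#' @return invisibly, the sidecar path.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- case$case_id
  sp <- case$volume$spacing
  for (ch in c("t2w", "dwi", "adc"))
    nifti_write(case$volume[[ch]], file.path(dir, paste0(id, "_", ch, ".nii.gz")),
                sp, "double")
  for (mk in c("gland", "pz", "tz", "rectum", "body"))
    nifti_write(array(as.integer(case$masks[[mk]]), dim = case$volume$shape),
                file.path(dir, paste0(id, "_", mk, ".nii.gz")), sp, "uint8")
  nifti_write(case$masks$lesions,
              file.path(dir, paste0(id, "_lesions.nii.gz")), sp, "uint16")
  nifti_write(array(as.integer(case$artifact_mask), dim = case$volume$shape),
              file.path(dir, paste0(id, "_artifactmask.nii.gz")), sp, "uint8")
  side <- list(case_id = id, shape = case$volume$shape, spacing = sp,
               ranges = case$volume$ranges,
               artifact = unclass(case$artifact),
               lesion_labels = as.list(case$masks$lesion_labels),
               patient_label = case$patient_label,
               site_tag = case$site_tag)
  path <- file.path(dir, paste0(id, ".json"))
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom case written by [write_case()]
#'
#' @param dir directory holding the case files.
#' @param case_id the case identifier.
#' @return the reconstructed `phantom_case`.
#' @export
read_case <- function(dir, case_id) {
  path <- file.path(dir, paste0(case_id, ".json"))
  if (!file.exists(path)) stopf("missing sidecar %s", path)
  side <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                   error = function(e)
                     stopf("corrupt sidecar %s: %s", path, conditionMessage(e)))
  for (f in c("case_id", "shape", "spacing", "ranges", "artifact",
              "patient_label", "site_tag"))
    if (is.null(side[[f]])) stopf("corrupt sidecar %s: missing field '%s'", path, f)
  shape <- as.integer(side$shape)
  grab <- function(suffix) {
    p <- file.path(dir, paste0(case_id, "_", suffix, ".nii.gz"))
    if (!file.exists(p)) stopf("missing file %s", p)
    arr <- nifti_read_array(p)
    if (!identical(dim(arr), shape))
      stopf("shape mismatch in %s: got %s, sidecar says %s", p,
            paste(dim(arr), collapse = "x"), paste(shape, collapse = "x"))
    arr
  }
  vol <- list(t2w = grab("t2w"), dwi = grab("dwi"), adc = grab("adc"),
              spacing = as.numeric(side$spacing), shape = shape,
              ranges = lapply(side$ranges, as.numeric))
  masks <- list(gland = grab("gland") > 0, pz = grab("pz") > 0,
                tz = grab("tz") > 0, rectum = grab("rectum") > 0,
                body = grab("body") > 0,
                lesions = array(as.integer(grab("lesions")), dim = shape))
  labs <- unlist(side$lesion_labels)
  if (is.null(labs)) labs <- character(0)
  masks$lesion_labels <- labs
  a <- side$artifact
  spec <- artifact_spec(a$grade, a$pz_affected_fraction, a$tz_involved,
                        a$amplitude, a$band_period, a$seed)
  structure(list(case_id = side$case_id, volume = vol, masks = masks,
                 artifact = spec,
                 artifact_mask = grab("artifactmask") > 0,
                 patient_label = isTRUE(side$patient_label),
                 site_tag = side$site_tag),
            class = "phantom_case")
}

#' Write a cohort (cases plus manifest CSV)
#' @param cohort a `phantom_cohort`.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (case in cohort$cases) write_case(case, dir)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(cohort$manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory holding the cohort.
#' @return a `phantom_cohort`.
#' @export
read_cohort <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stopf("missing manifest %s", path)
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  cases <- lapply(manifest$case_id, function(id) read_case(dir, id))
  structure(list(cases = cases, manifest = manifest), class = "phantom_cohort")
}

# Structural validity check used in tests and after deserialization.
validate_case <- function(case) {
  m <- case$masks
  stopifnot(
    !any(m$pz & m$tz),
    identical(m$pz | m$tz, m$gland),
    all(m$lesions[!m$gland] == 0L),
    !any(m$rectum & m$gland),
    all(sort(unique(as.vector(m$lesions[m$lesions > 0L]))) ==
          seq_along(m$lesion_labels) | length(m$lesion_labels) == 0)
  )
  for (ch in c("t2w", "dwi", "adc")) {
    rng <- case$volume$ranges[[ch]]
    v <- case$volume[[ch]]
    stopifnot(all(is.finite(v)), all(v >= rng[1]), all(v <= rng[2]))
  }
  stopifnot(identical(case$patient_label,
                      any(m$lesion_labels == "csPCa")))
  invisible(TRUE)
}
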
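#' Configuration for the synthetic prostate phantom cohort
#'
#' The generator emulates the appearance of an axial T2-weighted prostate
#' volume at the level relevant to the evaluation framework: a bright
#' ellipsoidal peripheral-zone shell around a darker transition-zone core,
#' optional hypointense lesions with smooth margins, a directional
#' high-spatial-frequency texture (so that undersampling one phase-encoding
#' axis produces visible one-directional blur), a smooth multiplicative bias
#' field, and Rician noise (the magnitude-image noise model).
#'
#' @param volume_shape integer length-3, voxels per axis.
#' @param voxel_spacing numeric length-3, mm per axis.
#' @param lesion_prevalence probability in `[0,1]` that a patient carries at
#'   least one lesion. Default 0.48, a csPCa-suspected cohort rate.
#' @param lesions_per_positive integer length-2 `(min, max)` lesions per
#'   positive patient.
#' @param lesion_radius numeric length-2 `(min, max)` largest lesion
#'   semi-axis in mm.
#' @param lesion_contrast relative intensity drop of a lesion at its centre,
#'   as a fraction of the surrounding tissue intensity.
#' @param noise_sigma Rician noise scale as a fraction of the
#'   peripheral-zone intensity. 0 disables noise.
#' @param texture_strength amplitude of the oriented high-frequency texture
#'   (fraction of peripheral-zone intensity). 0 disables texture.
#' @param texture_axis image axis (1 or 2) carrying the high-frequency
#'   content; undersampling this axis blurs the texture.
#' @param bias_strength peak-to-trough amplitude of the smooth multiplicative
#'   bias field (0 disables).
#' @param seed master seed; per-case sub-seeds are derived from it by a
#'   counter scheme so cohort prefixes are stable under changes of `n`.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(volume_shape = c(160L, 160L, 16L),
                           voxel_spacing = c(0.5, 0.5, 3.0),
                           lesion_prevalence = 0.48,
                           lesions_per_positive = c(1L, 2L),
                           lesion_radius = c(2.5, 5),
                           lesion_contrast = 0.5,
                           noise_sigma = 0.04,
                           texture_strength = 0.04,
                           texture_axis = 2L,
                           bias_strength = 0.15,
                           seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(volume_shape) != 3 || any(volume_shape <= 0)) {
    stop("`volume_shape` must be 3 positive integers")
  }
  if (length(voxel_spacing) != 3 || any(voxel_spacing <= 0)) {
    stop("`voxel_spacing` must be 3 positive numbers")
  }
  if (lesion_prevalence < 0 || lesion_prevalence > 1) {
    stop("`lesion_prevalence` must be in [0, 1]")
  }
  if (any(lesion_radius <= 0)) stop("lesion radii must be > 0")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  stopifnot(length(lesions_per_positive) == 2,
            lesions_per_positive[1] >= 1,
            lesions_per_positive[2] >= lesions_per_positive[1],
            texture_axis %in% c(1L, 2L))
  structure(list(
    volume_shape = volume_shape, voxel_spacing = voxel_spacing,
    lesion_prevalence = lesion_prevalence,
    lesions_per_positive = as.integer(lesions_per_positive),
    lesion_radius = as.numeric(lesion_radius),
    lesion_contrast = lesion_contrast, noise_sigma = noise_sigma,
    texture_strength = texture_strength, texture_axis = as.integer(texture_axis),
    bias_strength = bias_strength, seed = as.integer(seed)
  ), class = "phantom_config")
}

# Tissue intensity levels (arbitrary units on a 0..1-ish scale).
.phantom_levels <- list(background = 0.12, pz = 0.85, tz = 0.45)

#' Generate one phantom case
#'
#' Deterministic given `(config, index)`: the case sub-seed is derived from
#' the master seed and the case counter, so case `i` is identical no matter
#' how many cases surround it.
#'
#' @param config a [phantom_config].
#' @param index case counter (>= 0).
#' @return A `phantom_case`: list with `image` ([image_volume]), `lesions`
#'   ([lesion_set]), `patient_label` (0/1) and `patient_id`.
#' @export
generate_case <- function(config, index) {
  stopifnot(inherits(config, "phantom_config"), index >= 0)
  seed <- derive_seed(config$seed, index)
  with_seed(seed, .generate_case_impl(config, index))
}

.generate_case_impl <- function(config, index) {
  d <- config$volume_shape
  sp <- config$voxel_spacing
  lv <- .phantom_levels

  # physical coordinates of voxel centres, origin at the volume centre
  cx <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  cy <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  cz <- (seq_len(d[3]) - (d[3] + 1) / 2) * sp[3]

  ext <- d * sp
  # gland semi-axes: fill ~70% of the in-plane field, ~80% through-plane
  ax_out <- c(0.36 * ext[1], 0.33 * ext[2], 0.42 * ext[3])
  ax_in <- 0.62 * ax_out

  X <- array(rep(cx, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(cz, each = d[1] * d[2]), dim = d)

  r_out <- sqrt((X / ax_out[1])^2 + (Y / ax_out[2])^2 + (Z / ax_out[3])^2)
  r_in <- sqrt((X / ax_in[1])^2 + (Y / ax_in[2])^2 + (Z / ax_in[3])^2)

  # smoothstep from 1 (inside) to 0 (outside) over a band around r = 1
  edge <- function(r, width = 0.12) {
    t <- pmin(pmax((1 + width - r) / (2 * width), 0), 1)
    t * t * (3 - 2 * t)
  }
  m_out <- edge(r_out)   # whole gland
  m_in <- edge(r_in)     # transition zone core

  img <- lv$background +
    (lv$pz - lv$background) * m_out +
    (lv$tz - lv$pz) * m_in

  # lesions: hypointense ellipsoids fully inside the gland (r_out < 0.8)
  has_lesion <- stats::runif(1) < config$lesion_prevalence
  labels <- array(0L, dim = d)
  info <- data.frame(lesion_id = integer(0), grade = integer(0),
                     radius_mm = numeric(0), semi_a_mm = numeric(0),
                     semi_b_mm = numeric(0), semi_c_mm = numeric(0))
  if (has_lesion) {
    k <- if (config$lesions_per_positive[1] == config$lesions_per_positive[2]) {
      config$lesions_per_positive[1]
    } else {
      sample(config$lesions_per_positive[1]:config$lesions_per_positive[2], 1)
    }
    for (li in seq_len(k)) {
      rad <- stats::runif(1, config$lesion_radius[1], config$lesion_radius[2])
      # rejection-sample a centre comfortably inside the gland
      repeat {
        u <- stats::runif(3, -0.6, 0.6)
        ctr <- u * ax_out
        if (sqrt(sum((ctr / ax_out)^2)) < 0.65) break
      }
      semi <- c(rad, rad * stats::runif(1, 0.7, 1), rad * stats::runif(1, 0.6, 0.9))
      rl <- sqrt(((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
                   ((Z - ctr[3]) / semi[3])^2)
      core <- rl <= 1
      # keep the label strictly within the gland
      core <- core & (r_out < 0.95)
      if (!any(core)) next
      prof <- edge(rl, width = 0.25)          # smooth margin
      img <- img * (1 - config$lesion_contrast * prof * m_out)
      labels[core & labels == 0L] <- li
      info <- rbind(info, data.frame(
        lesion_id = li,
        grade = sample(4:5, 1, prob = c(0.7, 0.3)),
        radius_mm = rad,
        semi_a_mm = semi[1], semi_b_mm = semi[2], semi_c_mm = semi[3]
      ))
    }
    # renumber in case a lesion was fully swallowed by an earlier one
    kept <- sort(unique(labels[labels > 0L]))
    info <- info[info$lesion_id %in% kept, , drop = FALSE]
    relab <- array(0L, dim = d)
    for (j in seq_along(kept)) relab[labels == kept[j]] <- j
    labels <- relab
    info$lesion_id <- seq_len(nrow(info))
  }

  # oriented texture: white noise smoothed along every axis EXCEPT the
  # texture axis, leaving high spatial frequencies only along that axis
  if (config$texture_strength > 0) {
    tex <- array(stats::rnorm(prod(d)), dim = d)
    sig <- c(1.5, 1.5, 0.8)
    sig[config$texture_axis] <- 0
    tex <- gaussian_smooth3(tex, sig)
    tex <- tex / stats::sd(tex)
    img <- img + config$texture_strength * lv$pz * tex * m_out
  }

  # smooth multiplicative bias field (coil shading)
  if (config$bias_strength > 0) {
    g <- stats::runif(3, -1, 1)
    bias <- 1 + config$bias_strength *
      (g[1] * X / ext[1] + g[2] * Y / ext[2] + g[3] * Z / ext[3])
    img <- img * bias
  }

  # Rician noise: magnitude of complex Gaussian perturbation
  if (config$noise_sigma > 0) {
    s <- config$noise_sigma * lv$pz
    n1 <- array(stats::rnorm(prod(d), sd = s), dim = d)
    n2 <- array(stats::rnorm(prod(d), sd = s), dim = d)
    img <- sqrt((img + n1)^2 + n2^2)
  }
  img <- pmax(img, 0)

  structure(list(
    image = image_volume(img, spacing = sp),
    lesions = lesion_set(labels, info),
    patient_label = as.integer(nrow(info) > 0),
    patient_id = sprintf("case_%04d", index)
  ), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case> ", x$patient_id, ": label ", x$patient_label, ", ",
      n_lesions(x$lesions), " lesion(s)\n", sep = "")
  invisible(x)
}

#' Generate a phantom cohort
#'
#' Cases are generated with per-case sub-seeds derived from the master seed
#' by a counter scheme, so the cohort is a pure function of `(config, n)` and
#' the first `k` cases are identical for any `n >= k`.
#'
#' @param config a [phantom_config].
#' @param n_cases number of patients (>= 1).
#' @return list of `phantom_case` objects.
#' @export
generate_cohort <- function(config, n_cases) {
  stopifnot(inherits(config, "phantom_config"), n_cases >= 1)
  lapply(seq_len(n_cases) - 1L, function(i) generate_case(config, i))
}

#' Write a phantom cohort to disk
#'
#' Each case is written as two NIfTI files (image and lesion labelmap) plus
#' one cohort manifest CSV with `patient_id`, `label` and `n_lesions`.
#'
#' @param cohort list of `phantom_case` objects.
#' @param dir output directory (created if absent).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(cs) {
    save_volume(cs$image, file.path(dir, paste0(cs$patient_id, "_t2w.nii.gz")))
    lab <- image_volume(cs$lesions$labels + 0, spacing = cs$image$spacing)
    save_volume(lab, file.path(dir, paste0(cs$patient_id, "_lesions.nii.gz")))
    data.frame(patient_id = cs$patient_id, label = cs$patient_label,
               n_lesions = n_lesions(cs$lesions))
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "cohort_manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
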
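#' Resample a volume to a target voxel spacing
#'
#' The output grid spans the same physical extent at the target spacing:
#' `out_dim = round(in_dim * in_spacing / out_spacing)`. Voxel centres follow
#' the pixel-centre convention, so resampling to the input spacing is the
#' identity. `NA` in `target_spacing` leaves that axis unchanged (the
#' through-plane direction is typically not resampled).
#'
#' @param volume an [image_volume].
#' @param target_spacing numeric length-3 in mm; `NA` keeps an axis.
#' @param method `"nearest"` (default; preserves the intensity value set,
#'   mandatory for labelmaps) or `"linear"`.
#' @return An [image_volume] at the target spacing.
#' @export
resample_volume <- function(volume, target_spacing, method = c("nearest", "linear")) {
  stopifnot(inherits(volume, "image_volume"))
  method <- match.arg(method)
  tsp <- as.numeric(target_spacing)
  stopifnot(length(tsp) == 3)
  tsp[is.na(tsp)] <- volume$spacing[is.na(tsp)]
  if (any(tsp <= 0)) stop("target spacing must be > 0")
  d_in <- dim(volume$data)
  if (any(d_in < 1)) stop("degenerate volume")
  d_out <- pmax(1L, round_half_away(d_in * volume$spacing / tsp))
  if (all(d_out == d_in) && all(abs(tsp - volume$spacing) < 1e-12)) {
    return(volume)
  }
  # fractional input index (1-based) of each output voxel centre
  coords <- lapply(1:3, function(ax) {
    x_mm <- (seq_len(d_out[ax]) - 0.5) * tsp[ax]        # physical centre
    x_mm / volume$spacing[ax] + 0.5                     # input index space
  })
  if (method == "nearest") {
    idx <- lapply(1:3, function(ax) {
      pmin(pmax(round_half_away(coords[[ax]]), 1L), d_in[ax])
    })
    out <- volume$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dim(out) <- d_out
  } else {
    out <- .trilinear(volume$data, coords[[1]], coords[[2]], coords[[3]])
  }
  image_volume(out, spacing = tsp, origin = volume$origin)
}

# Separable trilinear interpolation at a tensor-product grid of fractional
# indices, clamped at the borders.
.trilinear <- function(arr, ix, iy, iz) {
  d <- dim(arr)
  gather <- function(i, n) {
    lo <- pmin(pmax(floor(i), 1L), n)
    hi <- pmin(lo + 1L, n)
    w <- pmin(pmax(i - lo, 0), 1)
    list(lo = as.integer(lo), hi = as.integer(hi), w = w)
  }
  gx <- gather(ix, d[1]); gy <- gather(iy, d[2]); gz <- gather(iz, d[3])
  out <- array(0, dim = c(length(ix), length(iy), length(iz)))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    sel <- arr[if (cx) gx$hi else gx$lo,
               if (cy) gy$hi else gy$lo,
               if (cz) gz$hi else gz$lo, drop = FALSE]
    wx <- if (cx) gx$w else 1 - gx$w
    wy <- if (cy) gy$w else 1 - gy$w
    wz <- if (cz) gz$w else 1 - gz$w
    w3 <- outer(outer(wx, wy), wz)
    dim(sel) <- dim(w3)
    out <- out + sel * w3
  }
  out
}

#' Centre-crop (or pad) a volume to a fixed voxel size
#'
#' Output has exactly the requested size, centred on the input grid. Inputs
#' smaller than the crop are symmetrically zero-padded first. When a margin
#' is odd, the extra voxel is taken from (or added on) the high-index side —
#' a fixed tie-break so images and labelmaps stay aligned.
#'
#' @param volume an [image_volume].
#' @param size integer length-3 target size.
#' @return An [image_volume] of dimension `size`.
#' @export
center_crop <- function(volume, size) {
  stopifnot(inherits(volume, "image_volume"))
  size <- as.integer(size)
  if (length(size) != 3 || any(size <= 0)) stop("`size` must be 3 positive integers")
  d <- dim(volume$data)
  arr <- volume$data
  # pad where needed
  if (any(size > d)) {
    pad_lo <- pmax((size - d) %/% 2L, 0L)
    padded <- array(0, dim = pmax(d, size))
    padded[pad_lo[1] + seq_len(d[1]),
           pad_lo[2] + seq_len(d[2]),
           pad_lo[3] + seq_len(d[3])] <- arr
    arr <- padded
    d <- dim(arr)
  }
  lo <- (d - size) %/% 2L   # low margin; extra voxel removed from high side
  out <- arr[lo[1] + seq_len(size[1]),
             lo[2] + seq_len(size[2]),
             lo[3] + seq_len(size[3]), drop = FALSE]
  image_volume(out, spacing = volume$spacing, origin = volume$origin)
}

#' Min/max intensity normalisation
#'
#' Rescales to `[0, 1]` with min 0 and max 1, instance-wise. A constant
#' volume maps to all zeros.
#' @param volume an [image_volume].
#' @return normalised [image_volume].
#' @export
minmax_normalize <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  rng <- range(volume$data)
  out <- if (diff(rng) == 0) {
    array(0, dim = dim(volume$data))
  } else {
    (volume$data - rng[1]) / diff(rng)
  }
  image_volume(out, spacing = volume$spacing, origin = volume$origin)
}

#' Z-score intensity normalisation
#'
#' Standardises to mean 0 and standard deviation 1, instance-wise. A floor of
#' 1e-8 on the standard deviation guards constant (e.g. zero-padded) inputs.
#' @param volume an [image_volume].
#' @return standardised volume (a list with `data`, `spacing`, `origin`;
#'   values may be negative so it is not a magnitude [image_volume]).
#' @export
z_normalize <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  mu <- mean(volume$data)
  sd_ <- max(stats::sd(as.vector(volume$data)), 1e-8)
  out <- (volume$data - mu) / sd_
  structure(list(data = out, spacing = volume$spacing, origin = volume$origin),
            class = "image_volume")
}

#' Reconstruction-model preprocessing chain
#'
#' Resample in-plane (nearest neighbour, z unchanged), centre-crop, min/max
#' normalise. Grid defaults follow the reconstruction stage: 0.5 x 0.5 mm
#' in-plane at a (256, 256, 16) crop; both are configurable for desk-scale
#' runs.
#'
#' @param volume an [image_volume].
#' @param target_spacing in-plane target spacing, `NA` keeps the z axis.
#' @param crop_size crop in voxels.
#' @return preprocessed [image_volume].
#' @export
recon_preprocess <- function(volume,
                             target_spacing = c(0.5, 0.5, NA),
                             crop_size = c(256L, 256L, 16L)) {
  v <- resample_volume(volume, target_spacing, method = "nearest")
  v <- center_crop(v, crop_size)
  minmax_normalize(v)
}

#' Detection-model preprocessing chain
#'
#' Resample to (0.5, 0.5, 3.0) mm, centre-crop to (180, 180, 16), z-score
#' normalise; configurable for desk-scale runs.
#'
#' @param volume an [image_volume].
#' @param target_spacing target spacing (mm).
#' @param crop_size crop in voxels.
#' @return preprocessed volume.
#' @export
detect_preprocess <- function(volume,
                              target_spacing = c(0.5, 0.5, 3.0),
                              crop_size = c(180L, 180L, 16L)) {
  v <- resample_volume(volume, target_spacing, method = "nearest")
  v <- center_crop(v, crop_size)
  z_normalize(v)
}

#' Apply the geometric part of a preprocessing chain to a lesion labelmap
#'
#' Labelmaps always use nearest-neighbour resampling so labels stay integral,
#' and share the crop tie-break with the image chain so voxel alignment is
#' preserved.
#'
#' @param lesions a [lesion_set].
#' @param spacing source voxel spacing of the labelmap grid (mm).
#' @param target_spacing as in the image chain.
#' @param crop_size as in the image chain.
#' @return a [lesion_set] on the preprocessed grid.
#' @export
preprocess_lesions <- function(lesions, spacing,
                               target_spacing = c(0.5, 0.5, 3.0),
                               crop_size = c(180L, 180L, 16L)) {
  stopifnot(inherits(lesions, "lesion_set"))
  v <- image_volume(lesions$labels + 0, spacing = spacing)
  v <- resample_volume(v, target_spacing, method = "nearest")
  v <- center_crop(v, crop_size)
  labels <- array(as.integer(round(v$data)), dim = dim(v$data))
  kept <- sort(unique(labels[labels > 0L]))
  info <- lesions$info[lesions$info$lesion_id %in% kept, , drop = FALSE]
  lesion_set(labels, info)
}
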
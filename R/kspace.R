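#' Configuration for a variable-density Cartesian undersampling mask
#'
#' The mask samples phase-encoding lines: a contiguous central band around
#' the DC line (low spatial frequencies, 20% of the sampled lines by
#' default) plus peripheral lines drawn without replacement with a
#' probability that decays exponentially with distance from the centre.
#'
#' @param acceleration acceleration factor R (>= 1); R = 4 samples 25% of
#'   the lines.
#' @param central_fraction fraction of the *sampled* lines taken contiguously
#'   at the k-space centre (default 0.20).
#' @param peripheral_decay_scale e-folding distance (in lines) of the
#'   peripheral sampling density; `NULL` means `n_lines / 6`.
#' @param seed RNG seed for the peripheral draw.
#' @param axis image axis (1 or 2) that is phase-encoded, i.e. the axis along
#'   which resolution is lost. Default 2 so blur appears along the horizontal
#'   image axis.
#' @return A `mask_config` list.
#' @export
mask_config <- function(acceleration = 4,
                        central_fraction = 0.2,
                        peripheral_decay_scale = NULL,
                        seed = 1L,
                        axis = 2L) {
  if (acceleration < 1) stop("`acceleration` must be >= 1")
  if (central_fraction <= 0 || central_fraction >= 1) {
    stop("`central_fraction` must be in (0, 1)")
  }
  if (!is.null(peripheral_decay_scale) && peripheral_decay_scale <= 0) {
    stop("`peripheral_decay_scale` must be > 0")
  }
  stopifnot(axis %in% c(1L, 2L))
  structure(list(acceleration = acceleration,
                 central_fraction = central_fraction,
                 peripheral_decay_scale = peripheral_decay_scale,
                 seed = as.integer(seed), axis = as.integer(axis)),
            class = "mask_config")
}

#' Build an undersampling mask over phase-encoding lines
#'
#' The sample budget is `round(n_lines / R)` (round half away from zero).
#' `round(central_fraction * budget)` lines form a contiguous band centred on
#' the DC line (index `floor(n/2) + 1`, the FFT-shifted centre); for odd band
#' sizes the extra line falls on the +k side. Remaining lines are drawn from
#' the periphery without replacement with weight `exp(-d / scale)`, `d` the
#' distance to the DC line, symmetric in expectation about DC.
#'
#' @param n_lines total number of phase-encoding lines (>= 8).
#' @param config a [mask_config].
#' @return A `kspace_mask`: list with `n_lines`, `acceleration`,
#'   `central_fraction`, sorted 1-based `sampled_lines`, `seed`, `axis`.
#' @examples
#' m <- make_undersampling_mask(512, mask_config(acceleration = 4, seed = 7))
#' length(m$sampled_lines)  # 128 = 25% of 512
#' @export
make_undersampling_mask <- function(n_lines, config) {
  stopifnot(inherits(config, "mask_config"))
  n_lines <- as.integer(n_lines)
  if (n_lines < 8) stop("`n_lines` must be >= 8")
  R <- config$acceleration
  n_samp <- round_half_away(n_lines / R)
  if (n_samp < 2) stop("n_lines / acceleration must be >= 2")
  dc <- floor(n_lines / 2) + 1L

  if (R == 1) {
    sampled <- seq_len(n_lines)
  } else {
    n_central <- round_half_away(config$central_fraction * n_samp)
    n_central <- max(n_central, 1L)
    if (n_central > n_samp) {
      stop("central band (", n_central, " lines) exceeds the sample budget (",
           n_samp, " lines); lower `acceleration` or `central_fraction`")
    }
    half_lo <- (n_central - 1L) %/% 2L
    half_hi <- n_central - 1L - half_lo  # extra line on the +k side
    band <- (dc - half_lo):(dc + half_hi)
    if (band[1] < 1 || band[length(band)] > n_lines) {
      stop("central band does not fit inside k-space")
    }
    periph <- setdiff(seq_len(n_lines), band)
    n_periph <- n_samp - n_central
    if (n_periph > length(periph)) stop("sample budget exceeds available lines")
    scale <- config$peripheral_decay_scale %||% (n_lines / 6)
    w <- exp(-abs(periph - dc) / scale)
    drawn <- if (n_periph > 0) {
      with_seed(config$seed, sample(periph, n_periph, prob = w))
    } else integer(0)
    sampled <- sort(c(band, drawn))
  }

  structure(list(n_lines = n_lines, acceleration = R,
                 central_fraction = config$central_fraction,
                 sampled_lines = as.integer(sampled),
                 seed = config$seed, axis = config$axis),
            class = "kspace_mask")
}

#' @export
print.kspace_mask <- function(x, ...) {
  cat("<kspace_mask> R", x$acceleration, ": ", length(x$sampled_lines), "/",
      x$n_lines, " lines sampled (axis ", x$axis, ")\n", sep = "")
  invisible(x)
}

#' Pad a mask to mirror zero-filled reconstruction
#'
#' Scanners zero-fill unacquired peripheral k-space before reconstruction to
#' interpolate to a finer grid; the binary mask must be padded the same way.
#' The input mask is placed centred in the padded line range (for an odd
#' difference the extra unsampled line falls on the low-index side so the DC
#' lines of the two grids coincide); all padded lines are unsampled.
#'
#' @param mask a `kspace_mask` over `acquired_lines` lines.
#' @param acquired_lines line count of the input mask (checked).
#' @param padded_lines target line count (>= acquired).
#' @return A `kspace_mask` over `padded_lines` lines with the same number of
#'   sampled lines.
#' @export
pad_mask_for_zero_fill <- function(mask, acquired_lines, padded_lines) {
  stopifnot(inherits(mask, "kspace_mask"))
  if (mask$n_lines != acquired_lines) {
    stop("`acquired_lines` (", acquired_lines, ") does not match the mask (",
         mask$n_lines, ")")
  }
  if (padded_lines < acquired_lines) {
    stop("`padded_lines` must be >= `acquired_lines`")
  }
  # offset aligning DC(acquired) with DC(padded):
  # dc_pad = floor(P/2)+1, dc_acq = floor(A/2)+1
  offset <- (floor(padded_lines / 2) + 1L) - (floor(acquired_lines / 2) + 1L)
  out <- mask
  out$n_lines <- as.integer(padded_lines)
  out$sampled_lines <- as.integer(mask$sampled_lines + offset)
  out
}

#' Retrospectively undersample a magnitude volume
#'
#' Per 2D slice: forward FFT with the DC component shifted to the centre,
#' multiplication by the binary line mask broadcast across the frequency
#' axis, inverse shift, inverse FFT, magnitude. Inputs are magnitude images
#' (zero phase by construction), so with R = 1 the output equals the input to
#' floating-point precision.
#'
#' @param volume an [image_volume].
#' @param mask a `kspace_mask`; `mask$n_lines` must equal the volume extent
#'   along `mask$axis`.
#' @return An [image_volume] of identical shape and spacing.
#' @export
undersample_volume <- function(volume, mask) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "kspace_mask"))
  d <- dim(volume$data)
  if (d[mask$axis] != mask$n_lines) {
    stop("mask covers ", mask$n_lines, " lines but the volume has ",
         d[mask$axis], " along axis ", mask$axis)
  }
  keep <- rep(FALSE, mask$n_lines)
  keep[mask$sampled_lines] <- TRUE
  out <- array(0, dim = d)
  for (z in seq_len(d[3])) {
    K <- fftshift2(stats::fft(volume$data[, , z]))
    if (mask$axis == 1L) K[!keep, ] <- 0 else K[, !keep] <- 0
    out[, , z] <- Mod(stats::fft(ifftshift2(K), inverse = TRUE)) / (d[1] * d[2])
  }
  image_volume(out, spacing = volume$spacing, origin = volume$origin)
}

#' Serialize a mask to compact JSON
#' @param mask a `kspace_mask`.
#' @param path output path; `NULL` returns the JSON string.
#' @return path or JSON string.
#' @export
save_mask <- function(mask, path = NULL) {
  stopifnot(inherits(mask, "kspace_mask"))
  obj <- list(n_lines = mask$n_lines, acceleration = mask$acceleration,
              central_fraction = mask$central_fraction, seed = mask$seed,
              axis = mask$axis, sampled_lines = mask$sampled_lines)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a mask from JSON written by [save_mask()]
#' @param path JSON file path.
#' @return A `kspace_mask`.
#' @export
load_mask <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(n_lines = as.integer(obj$n_lines),
                 acceleration = obj$acceleration,
                 central_fraction = obj$central_fraction,
                 sampled_lines = as.integer(obj$sampled_lines),
                 seed = as.integer(obj$seed), axis = as.integer(obj$axis)),
            class = "kspace_mask")
}
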
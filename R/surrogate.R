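#' Training-free surrogate lesion detector
#'
#' Deterministic blob-evidence map: a multi-scale centre-surround
#' (difference-of-smoothings) response to hypointense blobs. At each scale
#' `s` (mm) the response is `G_surround(x) - G_centre(x)`, positive where a
#' dark blob of roughly that size sits in brighter surroundings; the maximum
#' over scales is clipped at zero and divided by a fixed `response_scale`
#' (an absolute gain, so confidences are comparable across patients), then
#' clipped to `[0, 1]`. A constant volume yields an all-zero heatmap, and
#' the response is monotone in lesion contrast up to the clip.
#'
#' The gland/background boundary would otherwise dominate (a dark exterior
#' next to bright tissue looks like a huge blob), so the response is gated
#' by local tissue brightness: a smoothstep weight on the surround mean
#' between `tissue_gate[1]` and `tissue_gate[2]` keeps only blobs embedded
#' in bright tissue, emulating a detector that attends to the gland.
#'
#' @param volume an [image_volume] (intensities on a `[0, 1]`-normalised
#'   scale, e.g. the reconstruction-chain output).
#' @param scales_mm blob radii probed, in mm.
#' @param response_scale absolute response mapped to confidence 1.
#' @param tissue_gate `(lo, hi)` surround-intensity smoothstep bounds.
#' @param provenance optional string recorded on the heatmap.
#' @return an [image_volume] heatmap in `[0, 1]`.
#' @export
surrogate_detect <- function(volume, scales_mm = c(4, 6),
                             response_scale = 0.16,
                             tissue_gate = c(0.33, 0.48),
                             provenance = NULL) {
  stopifnot(inherits(volume, "image_volume"), all(scales_mm > 0),
            response_scale > 0, length(tissue_gate) == 2,
            tissue_gate[2] > tissue_gate[1])
  x <- volume$data
  sp <- volume$spacing
  best <- array(0, dim = dim(x))
  for (s in scales_mm) {
    # in-plane response only: slices are thick (several mm) relative to the
    # blob scales probed, so the operator works slice-wise like a reader
    sig_c <- c(s / 2 / sp[1], s / 2 / sp[2], 0)   # centre scale, voxels
    sig_s <- 2 * sig_c                            # surround
    smooth_s <- gaussian_smooth3(x, sig_s)
    r <- smooth_s - gaussian_smooth3(x, sig_c)
    t <- pmin(pmax((smooth_s - tissue_gate[1]) /
                     (tissue_gate[2] - tissue_gate[1]), 0), 1)
    best <- pmax(best, r * t * t * (3 - 2 * t))
  }
  hm <- pmin(best / response_scale, 1)
  hm[hm < 0] <- 0
  out <- image_volume(hm, spacing = sp, origin = volume$origin)
  attr(out, "provenance") <- provenance
  out
}
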
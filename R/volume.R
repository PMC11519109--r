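#' 3D magnitude image volume
#'
#' Lightweight container for a 3D magnitude MR image: a non-negative numeric
#' array plus voxel spacing (mm) and a physical origin. All pipeline stages
#' (undersampling, preprocessing, reconstruction, detection) consume and
#' produce this type.
#'
#' @param data 3D numeric array of voxel intensities (non-negative).
#' @param spacing numeric length-3, voxel spacing in mm per axis.
#' @param origin numeric length-3, physical position of the first voxel (mm).
#' @return An object of class `image_volume`.
#' @examples
#' v <- image_volume(array(1, dim = c(8, 8, 4)), spacing = c(0.5, 0.5, 3))
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("`data` must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive numbers (mm)")
  }
  if (any(dim(data) < 1)) stop("all volume dimensions must be >= 1")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "), " mm\n",
      "  intensity range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Read a volume from a NIfTI file
#'
#' Voxel spacing and origin are taken from the NIfTI header. Intensities are
#' returned as a plain numeric array.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("could not read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim = dim(arr))  # drop NIfTI attributes
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3) stop("expected a 3D volume, got ",
                                  length(dim(arr)), " dimensions")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("NIfTI header of '", path, "' has invalid pixdim (voxel spacing)")
  }
  orig <- tryCatch(RNifti::origin(img), error = function(e) c(0, 0, 0))
  image_volume(arr, spacing = sp, origin = as.numeric(orig)[1:3])
}

#' Write a volume to a NIfTI file
#'
#' @param volume an [image_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Per-patient ground-truth lesion set
#'
#' Integer labelmap on the same grid as the image (0 = background, 1..k =
#' lesions) plus a table of per-lesion attributes.
#'
#' @param labels 3D integer array of lesion labels.
#' @param info data.frame with one row per lesion: `lesion_id`, `grade`
#'   (PI-RADS-like 4 or 5), `radius_mm` (largest semi-axis).
#' @return An object of class `lesion_set`.
#' @export
lesion_set <- function(labels, info = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3) {
    stop("`labels` must be a 3D array")
  }
  ids <- sort(unique(labels[labels > 0]))
  if (is.null(info)) {
    info <- data.frame(lesion_id = as.integer(ids),
                       grade = rep(NA_integer_, length(ids)),
                       radius_mm = rep(NA_real_, length(ids)))
  }
  stopifnot(setequal(info$lesion_id, ids))
  structure(list(labels = labels, info = info), class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat("<lesion_set> ", nrow(x$info), " lesion(s), ",
      sum(x$labels > 0), " voxels total\n", sep = "")
  invisible(x)
}

#' Number of lesions in a lesion set
#' @param x a [lesion_set].
#' @return integer count.
#' @export
n_lesions <- function(x) {
  stopifnot(inherits(x, "lesion_set"))
  nrow(x$info)
}
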
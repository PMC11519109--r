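# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic rounding used for sample budgets and central-band counts;
#' base [round()] uses round-half-to-even, which would make line counts depend
#' on parity.
#' @param x numeric vector
#' @return rounded integer vector
#' @keywords internal
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic operations in the package go
# through this so that nothing perturbs or depends on the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Counter-based sub-seed derivation: deterministic, collision-poor over the
# index ranges used here, and kept inside the 32-bit signed range R requires.
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index), index >= 0)
  h <- (as.double(master) %% 2147483647) + 1
  h <- (h * 48271) %% 2147483647
  h <- (h + as.double(index) * 69621) %% 2147483647
  as.integer(h)
}

# Separable Gaussian smoothing of a 3D array, sigma given per axis in voxels.
# Reflection padding at borders; sigma of 0 leaves an axis untouched.
gaussian_smooth3 <- function(arr, sigma_vox) {
  stopifnot(length(dim(arr)) == 3, length(sigma_vox) == 3)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    arr <- convolve_axis3(arr, k, ax)
  }
  arr
}

# 1D convolution of a 3D array along one axis with reflection padding.
convolve_axis3 <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  # reflected index lookup (triangular wrap, valid for any kernel radius)
  reflect <- function(src) {
    if (n == 1L) return(rep(1L, length(src)))
    p <- 2L * n - 2L
    m <- (src - 1L) %% p
    m[m >= n] <- p - m[m >= n]
    m + 1L
  }
  idx <- seq_len(n)
  out <- array(0, dim = d)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    out <- out + kernel[j] * index_axis3(arr, reflect(idx + off), axis)
  }
  out
}

index_axis3 <- function(arr, idx, axis) {
  switch(axis,
    arr[idx, , , drop = FALSE],
    arr[, idx, , drop = FALSE],
    arr[, , idx, drop = FALSE]
  )
}

# fftshift / ifftshift for matrices (2D), moving DC to the centre and back.
fftshift2 <- function(m) {
  d <- dim(m)
  s1 <- floor(d[1] / 2); s2 <- floor(d[2] / 2)
  m[c((s1 + 1):d[1], seq_len(s1)), c((s2 + 1):d[2], seq_len(s2)), drop = FALSE]
}

ifftshift2 <- function(m) {
  d <- dim(m)
  s1 <- ceiling(d[1] / 2); s2 <- ceiling(d[2] / 2)
  m[c((s1 + 1):d[1], seq_len(s1)), c((s2 + 1):d[2], seq_len(s2)), drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
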
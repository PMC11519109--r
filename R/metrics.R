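#' Image-quality metric settings
#'
#' Standard SSIM reference settings: 11 x 11 Gaussian window with sigma 1.5
#' and stabilising constants `C1 = (K1 * L)^2`, `C2 = (K2 * L)^2` with
#' `K1 = 0.01`, `K2 = 0.03` and `L` the reference data range. Settings are
#' attached to every result for auditability.
#'
#' @param win_size odd window side in pixels.
#' @param sigma Gaussian window standard deviation (pixels).
#' @param K1,K2 stabilising constants.
#' @return list of settings.
#' @export
ssim_settings <- function(win_size = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  stopifnot(win_size >= 2, sigma > 0, K1 > 0, K2 > 0)
  list(win_size = as.integer(win_size), sigma = sigma, K1 = K1, K2 = K2)
}

# 1D Gaussian "valid" convolution matrix: (n - w + 1) x n, each row a
# normalised Gaussian window. Local statistics become A %*% X %*% t(B).
.gauss_valid_mat <- function(n, win, sigma) {
  if (n < win) stop("image extent (", n, ") smaller than SSIM window (", win,
                    "); reduce `win_size`")
  g <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  m <- matrix(0, n - win + 1, n)
  for (i in seq_len(n - win + 1)) m[i, i:(i + win - 1)] <- g
  m
}

# Local-statistics SSIM map for one 2D slice; returns the map and, if
# grad = TRUE, the gradient of mean(map) with respect to the test image.
.ssim_slice <- function(x, y, data_range, st, grad = FALSE) {
  A <- .gauss_valid_mat(nrow(x), st$win_size, st$sigma)
  B <- .gauss_valid_mat(ncol(x), st$win_size, st$sigma)
  C1 <- (st$K1 * data_range)^2
  C2 <- (st$K2 * data_range)^2
  f <- function(m) A %*% m %*% t(B)
  mx <- f(x); my <- f(y)
  Exx <- f(x * x); Eyy <- f(y * y); Exy <- f(x * y)
  vx <- Exx - mx^2; vy <- Eyy - my^2; cxy <- Exy - mx * my
  num1 <- 2 * mx * my + C1; den1 <- mx^2 + my^2 + C1
  num2 <- 2 * cxy + C2;     den2 <- vx + vy + C2
  S <- (num1 * num2) / (den1 * den2)
  if (!grad) return(list(map = S))
  # reverse-mode gradient of mean(S) w.r.t. y through mu_y, E[y^2], E[xy]
  n_map <- length(S)
  N <- num1 * num2; D <- den1 * den2
  dS_dmy <- (2 * (mx * (num2 - num1)) * D - N * 2 * (my * (den2 - den1))) / D^2
  dS_dEyy <- -N / (D * den2)
  dS_dExy <- 2 * num1 / D
  ft <- function(m) t(A) %*% m %*% B   # adjoint of the window filter
  gy <- (ft(dS_dmy) + ft(dS_dEyy) * 2 * y + ft(dS_dExy) * x) / n_map
  list(map = S, grad = gy)
}

#' Structural similarity index (SSIM)
#'
#' Wang-style SSIM with a Gaussian window over valid positions; luminance,
#' contrast and structure terms share the stabilising constants derived from
#' the *reference* image's data range. 3D volumes are scored as the mean over
#' 2D slices (recorded in the settings of the result). Equals 1 exactly iff
#' the images are identical.
#'
#' @param reference,test [image_volume]s (or 3D arrays) on identical grids;
#'   the reference must be non-constant.
#' @param settings an [ssim_settings()] list.
#' @param return_details if `TRUE`, returns per-slice values and settings.
#' @return numeric SSIM in `[-1, 1]`, or a detail list.
#' @export
ssim <- function(reference, test, settings = ssim_settings(),
                 return_details = FALSE) {
  x <- if (inherits(reference, "image_volume")) reference$data else reference
  y <- if (inherits(test, "image_volume")) test$data else test
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (is.matrix(y)) dim(y) <- c(dim(y), 1L)
  if (!identical(dim(x), dim(y))) stop("reference and test grids differ")
  data_range <- diff(range(x))
  if (data_range == 0) stop("reference image is constant (zero data range)")
  per_slice <- vapply(seq_len(dim(x)[3]), function(z) {
    mean(.ssim_slice(x[, , z], y[, , z], data_range, settings)$map)
  }, numeric(1))
  val <- mean(per_slice)
  if (!return_details) return(val)
  list(ssim = val, per_slice = per_slice,
       settings = c(settings, list(data_range = data_range,
                                   slice_mode = "mean over 2D slices")))
}

# Gradient of mean SSIM with respect to the test volume (used by the
# SSIM training loss so the train and evaluation metrics coincide).
ssim_with_grad <- function(x, y, settings = ssim_settings(),
                           data_range = NULL) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (is.matrix(y)) dim(y) <- c(dim(y), 1L)
  dr <- data_range %||% diff(range(x))
  if (dr == 0) stop("reference image is constant")
  nz <- dim(x)[3]
  g <- array(0, dim = dim(x))
  vals <- numeric(nz)
  for (z in seq_len(nz)) {
    r <- .ssim_slice(x[, , z], y[, , z], dr, settings, grad = TRUE)
    vals[z] <- mean(r$map)
    g[, , z] <- r$grad / nz
  }
  list(value = mean(vals), grad = g)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(range^2 / MSE)` with the range taken from the reference image.
#' Identical images have infinite PSNR; `Inf` is returned and documented as
#' the sentinel.
#'
#' @param reference,test volumes or arrays on identical grids.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(reference, test) {
  x <- if (inherits(reference, "image_volume")) reference$data else reference
  y <- if (inherits(test, "image_volume")) test$data else test
  if (!identical(dim(x), dim(y))) stop("reference and test grids differ")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  rng <- diff(range(x))
  10 * log10(rng^2 / mse)
}

#' Exact / approximate Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped. For up to 25 non-zero pairs the two-sided
#' p-value is exact, computed from the full signed-rank distribution by
#' generating-function convolution (which remains exact under tied midranks);
#' above 25 the normal approximation with tie correction is used.
#'
#' @param a,b paired numeric vectors.
#' @return list with `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25) {
    # exact null distribution of 2*V via convolution over 2*rank weights
    w <- as.integer(round(2 * r))
    maxs <- sum(w)
    dist <- numeric(maxs + 1); dist[1] <- 1
    for (wi in w) {
      shifted <- c(numeric(wi), dist[seq_len(maxs + 1 - wi)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    support <- 0:maxs
    mu <- sum(w) / 2
    obs_dev <- abs(2 * V - mu)
    p <- sum(dist[abs(support - mu) >= obs_dev - 1e-9])
    method <- "exact (convolution)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation, tie-corrected"
  }
  list(statistic = V, p_value = min(p, 1), n_effective = n, method = method)
}

#' Paired comparison of SSIM (or any per-patient metric) between conditions
#'
#' Summarises each condition as mean +/- sd and tests the paired differences
#' with the two-sided Wilcoxon signed-rank test of
#' [wilcoxon_signed_rank()].
#'
#' @param values_a,values_b per-patient metric values under the two
#'   conditions, aligned by patient.
#' @param label_a,label_b condition names for the summary.
#' @return list with per-condition `mean`/`sd`, `p_value`, `n`, `method`.
#' @export
compare_ssim_paired <- function(values_a, values_b,
                                label_a = "A", label_b = "B") {
  stopifnot(length(values_a) == length(values_b))
  if (length(values_a) < 5) stop("need at least 5 paired values")
  w <- wilcoxon_signed_rank(values_a, values_b)
  out <- list(
    conditions = data.frame(
      condition = c(label_a, label_b),
      mean = c(mean(values_a), mean(values_b)),
      sd = c(stats::sd(values_a), stats::sd(values_b))
    ),
    p_value = w$p_value, statistic = w$statistic,
    n = length(values_a), n_effective = w$n_effective, method = w$method
  )
  class(out) <- "ssim_comparison"
  out
}

#' @export
print.ssim_comparison <- function(x, ...) {
  cat("Paired metric comparison (Wilcoxon signed-rank, two-sided)\n")
  for (i in seq_len(nrow(x$conditions))) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", x$conditions$condition[i],
                x$conditions$mean[i], x$conditions$sd[i]))
  }
  cat(sprintf("  p = %.4g  (n = %d, %s)\n", x$p_value, x$n, x$method))
  invisible(x)
}
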
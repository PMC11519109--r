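# Minimal 2D convolutional encoder-decoder used by the reconstruction and
# detection stages at desk scale. Implemented directly on base matrices with
# im2col + BLAS matrix products; one down/up-sampling level with a skip
# connection (U-Net style), 3x3 kernels, ReLU activations.

# --- im2col / col2im for 3x3 same-padding convolution --------------------

.shift2 <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  ys <- max(1, 1 - dy):min(h, h - dy)
  xs <- max(1, 1 - dx):min(w, w - dx)
  out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

.im2col3x3 <- function(x) {            # x: [H, W, C] -> [H*W, 9C]
  d <- dim(x)
  cols <- matrix(0, d[1] * d[2], 9 * d[3])
  k <- 0
  for (c in seq_len(d[3])) {
    for (dy in -1:1) for (dx in -1:1) {
      k <- k + 1
      cols[, k] <- .shift2(x[, , c], dy, dx)
    }
  }
  cols
}

.col2im3x3 <- function(cols, d) {      # adjoint of .im2col3x3
  x <- array(0, dim = d)
  k <- 0
  for (c in seq_len(d[3])) {
    for (dy in -1:1) for (dx in -1:1) {
      k <- k + 1
      m <- matrix(cols[, k], d[1], d[2])
      x[, , c] <- x[, , c] + .shift2(m, -dy, -dx)
    }
  }
  x
}

.conv_fwd <- function(x, W, b) {       # W: [9*Cin, Cout]
  d <- dim(x)
  cols <- .im2col3x3(x)
  out <- cols %*% W
  out <- sweep(out, 2, b, `+`)
  list(out = array(out, dim = c(d[1], d[2], ncol(W))), cols = cols, dim_in = d)
}

.conv_bwd <- function(dout, cache, W) {
  d_out <- dim(dout)
  dmat <- matrix(dout, prod(d_out[1:2]), d_out[3])
  list(dW = crossprod(cache$cols, dmat),
       db = colSums(dmat),
       dx = .col2im3x3(dmat %*% t(W), cache$dim_in))
}

.pool2 <- function(x) {                # 2x2 mean pool; H, W must be even
  d <- dim(x)
  (x[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
   x[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
   x[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
   x[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]) / 4
}

.pool2_bwd <- function(dout, d_in) {
  dx <- array(0, dim = d_in)
  dx[seq(1, d_in[1], 2), seq(1, d_in[2], 2), ] <- dout / 4
  dx[seq(2, d_in[1], 2), seq(1, d_in[2], 2), ] <- dout / 4
  dx[seq(1, d_in[1], 2), seq(2, d_in[2], 2), ] <- dout / 4
  dx[seq(2, d_in[1], 2), seq(2, d_in[2], 2), ] <- dout / 4
  dx
}

.upsample2 <- function(x) {            # nearest-neighbour x2
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

.upsample2_bwd <- function(dout) {
  .pool2(dout) * 4
}

# --- network -------------------------------------------------------------

# He-normal initialisation; the output layer starts at zero so a residual
# reconstructor is the identity at initialisation.
nn_init <- function(in_ch = 1L, out_ch = 1L, width = 4L, seed = 1L,
                    out_bias = 0) {
  with_seed(seed, {
    mk <- function(cin, cout, zero = FALSE) {
      W <- if (zero) matrix(0, 9 * cin, cout) else
        matrix(stats::rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
               9 * cin, cout)
      list(W = W, b = rep(if (zero) out_bias else 0, cout))
    }
    list(conv1 = mk(in_ch, width),
         conv2 = mk(width, 2L * width),
         conv3 = mk(3L * width, width),
         conv4 = mk(width, out_ch, zero = TRUE),
         in_ch = in_ch, out_ch = out_ch, width = width)
  })
}

nn_forward <- function(params, x) {    # x: [H, W, in_ch], H and W even
  c1 <- .conv_fwd(x, params$conv1$W, params$conv1$b)
  h1 <- pmax(c1$out, 0)
  p <- .pool2(h1)
  c2 <- .conv_fwd(p, params$conv2$W, params$conv2$b)
  h2 <- pmax(c2$out, 0)
  u <- .upsample2(h2)
  cc <- array(c(h1, u), dim = c(dim(h1)[1], dim(h1)[2],
                                dim(h1)[3] + dim(u)[3]))
  c3 <- .conv_fwd(cc, params$conv3$W, params$conv3$b)
  h3 <- pmax(c3$out, 0)
  c4 <- .conv_fwd(h3, params$conv4$W, params$conv4$b)
  list(out = c4$out,
       cache = list(c1 = c1, h1 = h1, p = p, c2 = c2, h2 = h2, u = u,
                    cc = cc, c3 = c3, h3 = h3, c4 = c4))
}

nn_backward <- function(params, cache, dout) {
  g4 <- .conv_bwd(dout, cache$c4, params$conv4$W)
  dh3 <- g4$dx * (cache$c3$out > 0)
  g3 <- .conv_bwd(dh3, cache$c3, params$conv3$W)
  nw <- params$width
  dh1_skip <- g3$dx[, , seq_len(nw), drop = FALSE]
  du <- g3$dx[, , nw + seq_len(2L * nw), drop = FALSE]
  dh2 <- .upsample2_bwd(du) * (cache$c2$out > 0)
  g2 <- .conv_bwd(dh2, cache$c2, params$conv2$W)
  dp <- g2$dx
  dh1 <- dh1_skip + .pool2_bwd(dp, dim(cache$h1))
  dh1 <- dh1 * (cache$c1$out > 0)
  g1 <- .conv_bwd(dh1, cache$c1, params$conv1$W)
  list(conv1 = g1, conv2 = g2, conv3 = g3, conv4 = g4, dx = g1$dx)
}

# --- Adam optimiser ------------------------------------------------------

adam_init <- function(params) {
  st <- list(t = 0)
  for (nm in c("conv1", "conv2", "conv3", "conv4")) {
    st[[nm]] <- list(mW = params[[nm]]$W * 0, vW = params[[nm]]$W * 0,
                     mb = params[[nm]]$b * 0, vb = params[[nm]]$b * 0)
  }
  st
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in c("conv1", "conv2", "conv3", "conv4")) {
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * grads[[nm]]$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * grads[[nm]]$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * grads[[nm]]$db
    s$vb <- beta2 * s$vb + (1 - beta2) * grads[[nm]]$db^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / bc1) /
      (sqrt(s$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) /
      (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

accumulate_grads <- function(acc, g, w = 1) {
  if (is.null(acc)) {
    for (nm in c("conv1", "conv2", "conv3", "conv4")) {
      g[[nm]]$dW <- g[[nm]]$dW * w
      g[[nm]]$db <- g[[nm]]$db * w
    }
    g$dx <- NULL
    return(g)
  }
  for (nm in c("conv1", "conv2", "conv3", "conv4")) {
    acc[[nm]]$dW <- acc[[nm]]$dW + g[[nm]]$dW * w
    acc[[nm]]$db <- acc[[nm]]$db + g[[nm]]$db * w
  }
  acc
}

# --- augmentations (training only) ---------------------------------------

# nearest-neighbour rotation of a 2D slice about its centre, zeros outside
.rotate2 <- function(m, angle_deg) {
  h <- nrow(m); w <- ncol(m)
  th <- angle_deg * pi / 180
  ci <- (h + 1) / 2; cj <- (w + 1) / 2
  i <- matrix(seq_len(h), h, w) - ci
  j <- matrix(seq_len(w), h, w, byrow = TRUE) - cj
  si <- round(ci + cos(th) * i - sin(th) * j)
  sj <- round(cj + sin(th) * i + cos(th) * j)
  ok <- si >= 1 & si <= h & sj >= 1 & sj <= w
  out <- matrix(0, h, w)
  out[ok] <- m[cbind(si[ok], sj[ok])]
  out
}

# Apply a shared geometric + per-image noise augmentation to a list of
# aligned slices. `spec`: list(rot_prob, rot_range, noise_prob, noise_scale,
# flip_prob, noise_multiplicative). Geometric transforms are shared across
# the slices (input/target stay aligned); noise is added to the first slice
# (the model input) only.
augment_slices <- function(slices, spec) {
  if (stats::runif(1) < spec$rot_prob) {
    a <- stats::runif(1, -spec$rot_range, spec$rot_range)
    slices <- lapply(slices, .rotate2, angle_deg = a)
  }
  if (stats::runif(1) < spec$flip_prob) {
    slices <- lapply(slices, function(m) m[, rev(seq_len(ncol(m)))])
  }
  if (stats::runif(1) < spec$noise_prob) {
    s <- stats::runif(1, 0, spec$noise_scale)
    n <- matrix(stats::rnorm(length(slices[[1]]), sd = 1), nrow(slices[[1]]))
    slices[[1]] <- if (isTRUE(spec$noise_multiplicative)) {
      slices[[1]] * (1 + s * n)
    } else {
      slices[[1]] + s * n
    }
  }
  slices
}
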
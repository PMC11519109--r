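# Undersampling-mask construction and the masked-FFT reconstruction.

test_that("mask sample budget, central band and determinism follow the design", {
  cfg <- mask_config(acceleration = 4, central_fraction = 0.2, seed = 11)
  m <- make_undersampling_mask(512, cfg)
  expect_equal(length(m$sampled_lines), 128)          # 25% of 512
  expect_equal(length(m$sampled_lines) / 512, 0.25)
  # contiguous central band of round(0.2 * 128) = 26 lines around DC (257)
  dc <- floor(512 / 2) + 1
  band <- (dc - 12):(dc + 13)
  expect_true(all(band %in% m$sampled_lines))
  expect_false(anyDuplicated(m$sampled_lines) > 0)
  expect_true(all(m$sampled_lines >= 1 & m$sampled_lines <= 512))
  # deterministic given seed; different seed gives a different periphery
  m2 <- make_undersampling_mask(512, cfg)
  expect_identical(m$sampled_lines, m2$sampled_lines)
  m3 <- make_undersampling_mask(512, mask_config(acceleration = 4, seed = 12))
  expect_false(identical(m$sampled_lines, m3$sampled_lines))
})

test_that("R = 1 samples every line and extreme settings are rejected", {
  m <- make_undersampling_mask(512, mask_config(acceleration = 1))
  expect_identical(m$sampled_lines, 1:512)
  expect_error(make_undersampling_mask(4, mask_config(acceleration = 1)),
               ">= 8")
  expect_error(make_undersampling_mask(8, mask_config(acceleration = 8)),
               ">= 2")
  expect_error(mask_config(acceleration = 0.5), ">= 1")
  expect_error(mask_config(central_fraction = 1.2), "central_fraction")
})

test_that("peripheral sampling frequency decays with distance from centre", {
  n <- 128
  freq <- numeric(n)
  for (s in 1:400) {
    m <- make_undersampling_mask(n, mask_config(acceleration = 8, seed = s))
    freq[m$sampled_lines] <- freq[m$sampled_lines] + 1
  }
  dc <- floor(n / 2) + 1
  d <- abs(seq_len(n) - dc)
  # bin distances into quintiles outside the always-sampled central band
  periph <- which(d > 4)
  qs <- cut(d[periph], breaks = quantile(d[periph], seq(0, 1, 0.2)),
            include.lowest = TRUE)
  mean_freq <- tapply(freq[periph], qs, mean)
  expect_true(all(diff(mean_freq) < 0))  # monotone decay across bins
})

test_that("zero-fill padding centres the mask and preserves sample count", {
  m <- make_undersampling_mask(256, mask_config(acceleration = 4, seed = 2))
  p <- pad_mask_for_zero_fill(m, 256, 512)
  expect_equal(p$n_lines, 512)
  expect_equal(length(p$sampled_lines), length(m$sampled_lines))
  expect_true(all(p$sampled_lines > 128 & p$sampled_lines <= 384))
  # inner region reproduces the input mask
  expect_identical(p$sampled_lines - 128L, m$sampled_lines)
  # identity when sizes match
  expect_identical(pad_mask_for_zero_fill(m, 256, 256)$sampled_lines,
                   m$sampled_lines)
  expect_error(pad_mask_for_zero_fill(m, 256, 128), "padded_lines")
})

test_that("full sampling round-trips and constant slices are preserved", {
  v <- ramp_volume(c(16L, 16L, 2L))
  m1 <- make_undersampling_mask(16, mask_config(acceleration = 1))
  out <- undersample_volume(v, m1)
  expect_lt(max(abs(out$data - v$data)), 1e-6 * diff(range(v$data)))
  # constant slice with any mask containing DC stays constant
  vc <- image_volume(array(0.7, dim = c(16, 16, 1)))
  m4 <- make_undersampling_mask(16, mask_config(acceleration = 4, seed = 5))
  outc <- undersample_volume(vc, m4)
  expect_lt(diff(range(outc$data)), 1e-10)
  expect_equal(mean(outc$data), 0.7, tolerance = 1e-10)
})

test_that("masked-FFT reconstruction matches the explicit-summation DFT oracle", {
  v <- ramp_volume(c(16L, 16L, 1L))
  for (axis in 1:2) {
    m <- make_undersampling_mask(16, mask_config(acceleration = 4, seed = 9,
                                                 axis = axis))
    got <- undersample_volume(v, m)$data[, , 1]
    want <- dft_undersample_oracle(v$data[, , 1], m$sampled_lines, axis)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("masking never increases k-space energy; equality only at R = 1", {
  v <- test_phantom_config(seed = 3) |> generate_case(0)
  slice <- v$image$data[, , 4]
  K <- fft(slice)
  e_full <- sum(Mod(K)^2)
  for (R in c(1, 4, 8)) {
    m <- make_undersampling_mask(48, mask_config(acceleration = R, seed = 1))
    keep <- rep(FALSE, 48); keep[m$sampled_lines] <- TRUE
    Ks <- diagqm:::fftshift2(K); Ks[, !keep] <- 0
    e <- sum(Mod(Ks)^2)
    if (R == 1) expect_equal(e, e_full) else expect_lt(e, e_full)
  }
})

test_that("resolution is lost only along the phase-encoding axis", {
  # oriented texture: high frequency along axis 2 only
  cs <- generate_case(test_phantom_config(seed = 5, noise_sigma = 0), 0)
  m <- make_undersampling_mask(48, mask_config(acceleration = 8, seed = 1,
                                               axis = 2))
  out <- undersample_volume(cs$image, m)
  # profiles along axis 1 (orthogonal to the masked axis) change much less
  # than profiles along axis 2
  d1 <- abs(apply(out$data, c(2, 3), mean) - apply(cs$image$data, c(2, 3), mean))
  err_along_masked <- mean(d1)
  d2 <- abs(apply(out$data, c(1, 3), mean) - apply(cs$image$data, c(1, 3), mean))
  err_along_kept <- mean(d2)
  expect_lt(err_along_kept, err_along_masked)
})

test_that("mask JSON serialisation round-trips", {
  m <- make_undersampling_mask(64, mask_config(acceleration = 4, seed = 2))
  f <- withr::local_tempfile(fileext = ".json")
  save_mask(m, f)
  m2 <- load_mask(f)
  expect_identical(m2$sampled_lines, m$sampled_lines)
  expect_equal(m2$acceleration, m$acceleration)
  expect_equal(m2$axis, m$axis)
})
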
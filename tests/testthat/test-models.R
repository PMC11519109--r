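# Split integrity, reconstruction and detection model contracts, and the
# deterministic surrogate detector.

test_that("80/20 split of 1535 patients gives 1229/306 with 5 disjoint folds", {
  ids <- sprintf("pt%04d", 1:1535)
  sp <- make_patient_split(ids, train_fraction = 0.8, n_folds = 5, seed = 42)
  expect_equal(sum(sp$split == "train"), 1229)
  expect_equal(sum(sp$split == "test"), 306)
  # every training patient in exactly one fold; test patients in none
  expect_true(all(!is.na(sp$fold[sp$split == "train"])))
  expect_true(all(is.na(sp$fold[sp$split == "test"])))
  expect_setequal(unique(sp$fold[sp$split == "train"]), 1:5)
  expect_false(anyDuplicated(sp$patient_id) > 0)
  # deterministic given the seed
  sp2 <- make_patient_split(ids, train_fraction = 0.8, n_folds = 5, seed = 42)
  expect_identical(sp, sp2)
})

test_that("zero-epoch reconstructor is the identity and training is deterministic", {
  set.seed(51)
  mkvol <- function() image_volume(array(runif(16 * 16 * 2), dim = c(16, 16, 2)))
  pairs <- lapply(1:4, function(i) {
    v <- mkvol(); list(aliased = v, original = v)
  })
  cfg0 <- recon_train_config(epochs = 0L, ssim_win = 7L, seed = 3)
  m0 <- train_reconstructor(pairs, cfg0)
  out <- reconstruct(m0, pairs[[1]]$aliased)
  # residual net with zero-initialised output layer: identity at init
  expect_equal(out$data, pairs[[1]]$aliased$data, tolerance = 1e-12)
  expect_true(all(out$data >= 0 & out$data <= 1))
  # identical data + config + seed -> identical validation trajectory
  cfg1 <- recon_train_config(epochs = 2L, ssim_win = 7L, seed = 3,
                             batch_size = 4L)
  t1 <- train_reconstructor(pairs, cfg1)$val_loss
  t2 <- train_reconstructor(pairs, cfg1)$val_loss
  expect_identical(t1, t2)
  expect_error(train_reconstructor(pairs[1], cfg1), "at least 2")
})

test_that("a few epochs of SSIM training beat the naive input on held-out phantoms", {
  cfg <- test_phantom_config(seed = 7, lesion_contrast = 0.5,
                             texture_strength = 0.04)
  cohort <- generate_cohort(cfg, 16)
  msk <- make_undersampling_mask(48, mask_config(acceleration = 4, seed = 3))
  v1 <- lapply(cohort, function(cs) minmax_normalize(cs$image))
  v4 <- lapply(cohort, function(cs) minmax_normalize(undersample_volume(cs$image, msk)))
  pairs <- lapply(1:12, function(i) list(aliased = v4[[i]], original = v1[[i]]))
  model <- train_reconstructor(pairs, recon_train_config(
    epochs = 5L, learning_rate = 2e-3, ssim_win = 7L, seed = 5))
  held <- 13:16
  s_naive <- mean(vapply(held, function(i) ssim(v1[[i]], v4[[i]]), numeric(1)))
  s_recon <- mean(vapply(held, function(i) {
    ssim(v1[[i]], reconstruct(model, v4[[i]]))
  }, numeric(1)))
  expect_gt(s_recon, s_naive)
  # output constrained to [0, 1] on the evaluation grid
  r <- reconstruct(model, v4[[13]])
  expect_true(all(r$data >= 0 & r$data <= 1))
  expect_equal(dim(r$data), dim(v4[[13]]$data))
})

test_that("detector training rejects single-class cohorts and partitions folds", {
  cfg <- phantom_config(volume_shape = c(16L, 16L, 2L), voxel_spacing = c(2, 2, 4),
                        lesion_prevalence = 0, seed = 1)
  cohort <- lapply(0:5, function(i) {
    cs <- generate_case(cfg, i)
    list(image = z_normalize(cs$image), lesions = cs$lesions,
         patient_id = cs$patient_id)
  })
  expect_error(train_detector(cohort, detect_train_config(epochs = 0L)),
               "positive and")
})

test_that("a trained detector scores lesion voxels above background", {
  cfg <- phantom_config(volume_shape = c(32L, 32L, 6L),
                        voxel_spacing = c(1.5, 1.5, 3),
                        lesion_contrast = 0.5, texture_strength = 0.04,
                        seed = 7)
  cohort <- generate_cohort(cfg, 26)
  prep <- lapply(cohort, function(cs) list(
    image = z_normalize(cs$image), lesions = cs$lesions,
    patient_id = cs$patient_id))
  ens <- train_detector(prep[1:20], detect_train_config(
    n_folds = 2L, epochs = 6L, learning_rate = 2e-3, seed = 11))
  expect_length(ens$models, 2)
  # fold assignment partitions the training patients
  expect_setequal(unique(ens$folds), 1:2)
  ratio_in <- c(); ratio_out <- c()
  for (i in 21:26) {
    if (n_lesions(cohort[[i]]$lesions) == 0) next
    hm <- predict_heatmap(ens, prep[[i]]$image)
    expect_true(all(hm$data >= 0 & hm$data <= 1))
    ratio_in <- c(ratio_in, mean(hm$data[cohort[[i]]$lesions$labels > 0]))
    ratio_out <- c(ratio_out, mean(hm$data[cohort[[i]]$lesions$labels == 0]))
  }
  expect_gt(mean(ratio_in), mean(ratio_out))
})

test_that("heatmap prediction contracts: range, ensembles, determinism", {
  set.seed(52)
  m <- structure(list(params = diagqm:::nn_init(1, 1, width = 2, seed = 1,
                                                out_bias = -2),
                      val_loss = NA, config = NULL), class = "detect_model")
  v <- image_volume(array(0, dim = c(16, 16, 2)))
  h1 <- predict_heatmap(m, v)
  expect_true(all(is.finite(h1$data)))
  expect_true(all(h1$data >= 0 & h1$data <= 1))
  # ensemble of identical models equals the single model
  ens <- structure(list(models = list(m, m), folds = c(1, 2), ids = c("a", "b"),
                       config = NULL), class = "detect_ensemble")
  v2 <- image_volume(array(runif(16 * 16 * 2), dim = c(16, 16, 2)))
  expect_equal(predict_heatmap(ens, v2)$data, predict_heatmap(m, v2)$data,
               tolerance = 1e-12)
  # deterministic given weights
  expect_identical(predict_heatmap(m, v2)$data, predict_heatmap(m, v2)$data)
})

test_that("surrogate detector: null response, localisation, contrast monotonicity", {
  # constant volume -> all-zero heatmap
  vc <- image_volume(array(0.5, dim = c(24, 24, 4)))
  expect_true(all(surrogate_detect(vc)$data == 0))
  # constructed case: uniform bright tissue with one inserted hypointense
  # blob; the global heatmap maximum must fall inside that blob
  d <- c(32L, 32L, 4L)
  mk <- function(depth) {
    arr <- array(0.8, dim = d)
    for (i in 1:d[1]) for (j in 1:d[2]) {
      arr[i, j, 2] <- arr[i, j, 2] -
        depth * exp(-((i - 12)^2 + (j - 20)^2) / (2 * 2.5^2))
    }
    image_volume(arr, spacing = c(1, 1, 3))
  }
  hm <- surrogate_detect(mk(0.35))
  peak_ijk <- arrayInd(which.max(hm$data), d)
  expect_lte(sqrt((peak_ijk[1] - 12)^2 + (peak_ijk[2] - 20)^2), 2.5)
  expect_equal(peak_ijk[3], 2L)
  # response is monotone in blob contrast (both below the confidence clip)
  hm_lo <- surrogate_detect(mk(0.15))
  expect_gt(max(hm$data), max(hm_lo$data))
  expect_lt(max(hm$data), 1)
})
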
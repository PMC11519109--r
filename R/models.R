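#' Training configuration for the learned reconstructor
#'
#' Defaults are the full-scale training protocol: SSIM loss, batch size
#' 12, Adam at learning rate 4e-4, early stopping, and augmentation by
#' rotation (prob 0.25, +/-30 deg), additive normal noise (prob 0.60, scale
#' 0-0.003) and mirroring (prob 0.50). `model_scale` controls channel width;
#' desk-scale runs use small widths and few epochs.
#'
#' @param loss currently `"ssim"` (1 - mean SSIM, same window and constants
#'   as [ssim()]).
#' @param batch_size slices per optimiser step.
#' @param learning_rate Adam step size.
#' @param epochs training epochs; 0 returns the initialised model.
#' @param patience early-stopping patience in epochs on the validation loss.
#' @param val_fraction fraction of training cases held out for validation.
#' @param augment list of augmentation probabilities/ranges.
#' @param model_scale base channel width of the encoder-decoder.
#' @param ssim_win SSIM window for the loss (reduce for small slices).
#' @param seed RNG seed governing initialisation, shuffling and augmentation.
#' @return a `recon_train_config` list.
#' @export
recon_train_config <- function(loss = "ssim",
                               batch_size = 12L,
                               learning_rate = 4e-4,
                               epochs = 20L,
                               patience = 5L,
                               val_fraction = 0.2,
                               augment = list(rot_prob = 0.25, rot_range = 30,
                                              noise_prob = 0.60,
                                              noise_scale = 0.003,
                                              flip_prob = 0.50,
                                              noise_multiplicative = FALSE),
                               model_scale = 4L,
                               ssim_win = 11L,
                               seed = 1L) {
  stopifnot(loss == "ssim", learning_rate > 0, batch_size >= 1,
            epochs >= 0, val_fraction > 0, val_fraction < 1)
  stopifnot(all(unlist(augment[c("rot_prob", "noise_prob", "flip_prob")]) >= 0),
            all(unlist(augment[c("rot_prob", "noise_prob", "flip_prob")]) <= 1))
  structure(list(loss = loss, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 patience = as.integer(patience), val_fraction = val_fraction,
                 augment = augment, model_scale = as.integer(model_scale),
                 ssim_win = as.integer(ssim_win), seed = as.integer(seed)),
            class = "recon_train_config")
}

#' Training configuration for the lesion detector
#'
#' Defaults are the full-scale training protocol: voxelwise weighted binary
#' cross-entropy with class weights 0.05 (negative) / 0.95 (positive),
#' 5-fold cross-validation inside the 80% training split, and augmentation
#' by rotation (prob 0.10, +/-30 deg), multiplicative noise (prob 0.30,
#' multiplier 0-0.001) and horizontal flipping (prob 0.50).
#'
#' @param class_weights `(negative, positive)` voxel weights summing to 1.
#' @param n_folds cross-validation folds (>= 2).
#' @param train_fraction fraction of patients used for training/validation
#'   (the rest is the held-out test set).
#' @param batch_size,learning_rate,epochs,augment,model_scale,seed as in
#'   [recon_train_config()].
#' @return a `detect_train_config` list.
#' @export
detect_train_config <- function(class_weights = c(0.05, 0.95),
                                n_folds = 5L,
                                train_fraction = 0.80,
                                batch_size = 8L,
                                learning_rate = 1e-3,
                                epochs = 15L,
                                augment = list(rot_prob = 0.10, rot_range = 30,
                                               noise_prob = 0.30,
                                               noise_scale = 0.001,
                                               flip_prob = 0.50,
                                               noise_multiplicative = TRUE),
                                model_scale = 4L,
                                seed = 1L) {
  stopifnot(abs(sum(class_weights) - 1) < 1e-9, n_folds >= 2,
            train_fraction > 0, train_fraction < 1, learning_rate > 0)
  structure(list(class_weights = class_weights, n_folds = as.integer(n_folds),
                 train_fraction = train_fraction,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 augment = augment, model_scale = as.integer(model_scale),
                 seed = as.integer(seed)),
            class = "detect_train_config")
}

#' Patient-level train/test split with cross-validation folds
#'
#' Deterministic given the seed: shuffles patient ids, reserves
#' `1 - train_fraction` as the held-out test set, and partitions the training
#' patients into `n_folds` disjoint validation folds. Test patients never
#' appear in any fold.
#'
#' @param patient_ids character vector of unique ids.
#' @param train_fraction fraction assigned to training/validation.
#' @param n_folds number of cross-validation folds.
#' @param seed RNG seed.
#' @return data.frame with `patient_id`, `split` ("train"/"test"), `fold`
#'   (validation fold 1..n_folds for train patients, NA for test).
#' @export
make_patient_split <- function(patient_ids, train_fraction = 0.80,
                               n_folds = 5L, seed = 1L) {
  stopifnot(!anyDuplicated(patient_ids), n_folds >= 2)
  n <- length(patient_ids)
  # the held-out set gets floor((1 - fraction) * n); the training side keeps
  # the remainder (1535 at 80% -> 1229 train / 306 test)
  n_train <- n - floor((1 - train_fraction) * n)
  with_seed(seed, {
    perm <- sample(patient_ids)
    train_ids <- perm[seq_len(n_train)]
    test_ids <- perm[-seq_len(n_train)]
    fold <- rep(seq_len(n_folds), length.out = n_train)
    df <- rbind(
      data.frame(patient_id = train_ids, split = "train", fold = fold),
      data.frame(patient_id = test_ids, split = "test",
                 fold = rep(NA_integer_, length(test_ids)))
    )
    df[order(match(df$patient_id, patient_ids)), , drop = FALSE]
  })
}

# volumes -> list of [H, W, 1] slice arrays
.vol_slices <- function(vol) {
  d <- dim(vol$data)
  lapply(seq_len(d[3]), function(z) array(vol$data[, , z], dim = c(d[1], d[2], 1L)))
}

#' Train the learned reconstructor
#'
#' Trains the convolutional encoder-decoder to map aliased (undersampled,
#' naively reconstructed) volumes to the fully sampled originals, maximising
#' mean SSIM (loss `1 - SSIM`, identical window and constants to the
#' evaluation metric). The model is residual and its output layer is
#' zero-initialised, so at initialisation it is the identity and training
#' can only improve on the naive input on the validation split (best-epoch
#' weights are kept; early stopping on the validation loss).
#'
#' @param pairs list of cases, each a list with `aliased` and `original`
#'   [image_volume]s on the same `[0,1]`-normalised grid (even in-plane
#'   dimensions).
#' @param config a [recon_train_config()].
#' @return a `recon_model` with the trained parameters, the validation-loss
#'   trajectory and the config.
#' @export
train_reconstructor <- function(pairs, config = recon_train_config()) {
  stopifnot(inherits(config, "recon_train_config"))
  if (length(pairs) < 2) stop("need at least 2 training pairs")
  for (p in pairs) {
    if (!identical(dim(p$aliased$data), dim(p$original$data))) {
      stop("aliased/original pair not voxel-aligned")
    }
  }
  with_seed(config$seed, .train_recon_impl(pairs, config))
}

.train_recon_impl <- function(pairs, config) {
  n <- length(pairs)
  n_val <- max(1L, floor(config$val_fraction * n))
  perm <- sample(n)
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  if (length(tr_idx) == 0) {
    tr_idx <- val_idx  # degenerate 2-case cohorts
  }
  tr <- list(); for (i in tr_idx) {
    xs <- .vol_slices(pairs[[i]]$aliased); ys <- .vol_slices(pairs[[i]]$original)
    for (z in seq_along(xs)) tr[[length(tr) + 1]] <- list(x = xs[[z]], y = ys[[z]])
  }
  va <- list(); for (i in val_idx) {
    xs <- .vol_slices(pairs[[i]]$aliased); ys <- .vol_slices(pairs[[i]]$original)
    for (z in seq_along(xs)) va[[length(va) + 1]] <- list(x = xs[[z]], y = ys[[z]])
  }

  st <- ssim_settings(win_size = config$ssim_win)
  loss_val <- function(params) {
    mean(vapply(va, function(s) {
      o <- nn_forward(params, s$x)$out
      y <- s$x + o
      1 - ssim_with_grad(matrix(s$y, dim(s$y)[1]), matrix(y, dim(y)[1]),
                         settings = st, data_range = 1)$value
    }, numeric(1)))
  }

  params <- nn_init(1L, 1L, width = config$model_scale, seed = sample.int(2^30, 1))
  opt <- adam_init(params)
  best <- params
  best_loss <- loss_val(params)
  trajectory <- best_loss
  wait <- 0L

  if (config$epochs > 0 && length(tr) > 0) {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(tr))
      for (b0 in seq(1, length(tr), by = config$batch_size)) {
        batch <- ord[b0:min(b0 + config$batch_size - 1, length(tr))]
        acc <- NULL
        for (i in batch) {
          s <- augment_slices(list(tr[[i]]$x[, , 1], tr[[i]]$y[, , 1]),
                              config$augment)
          x <- array(s[[1]], dim = dim(tr[[i]]$x))
          yref <- s[[2]]
          fw <- nn_forward(params, x)
          y <- x[, , 1] + fw$out[, , 1]
          sg <- ssim_with_grad(yref, y, settings = st, data_range = 1)
          if (!is.finite(sg$value)) stop("NaN loss during recon training")
          dldo <- array(-sg$grad, dim = dim(fw$out))
          g <- nn_backward(params, fw$cache, dldo)
          acc <- accumulate_grads(acc, g, w = 1 / length(batch))
        }
        stp <- adam_step(params, acc, opt, lr = config$learning_rate)
        params <- stp$params; opt <- stp$state
      }
      vl <- loss_val(params)
      trajectory <- c(trajectory, vl)
      if (vl < best_loss - 1e-7) {
        best_loss <- vl; best <- params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  }
  structure(list(params = best, val_loss = trajectory, config = config),
            class = "recon_model")
}

#' @export
print.recon_model <- function(x, ...) {
  cat("<recon_model> width ", x$config$model_scale, ", best val loss ",
      signif(min(x$val_loss), 4), " (", length(x$val_loss) - 1,
      " epochs)\n", sep = "")
  invisible(x)
}

#' Apply the learned reconstructor
#'
#' Residual prediction per slice; outputs are clipped to `[0, 1]`.
#'
#' @param model a `recon_model`.
#' @param aliased an [image_volume] preprocessed by the reconstruction chain
#'   (values in `[0,1]`, even in-plane dimensions).
#' @return reconstructed [image_volume].
#' @export
reconstruct <- function(model, aliased) {
  stopifnot(inherits(model, "recon_model"), inherits(aliased, "image_volume"))
  d <- dim(aliased$data)
  out <- array(0, dim = d)
  for (z in seq_len(d[3])) {
    x <- array(aliased$data[, , z], dim = c(d[1], d[2], 1L))
    o <- nn_forward(model$params, x)$out
    out[, , z] <- pmin(pmax(aliased$data[, , z] + o[, , 1], 0), 1)
  }
  image_volume(out, spacing = aliased$spacing, origin = aliased$origin)
}

#' Train the lesion-detection model (one model per cross-validation fold)
#'
#' Voxelwise weighted binary cross-entropy (default weights 0.05 negative /
#' 0.95 positive) against the binary lesion mask. Each fold model trains on
#' the other folds and keeps its best-epoch weights by validation loss. The
#' detectors are trained once on fully sampled data and deliberately *not*
#' retrained per acceleration condition.
#'
#' @param cohort list of cases, each a list with `image` (z-normalised
#'   volume, even in-plane dims) and `lesions` ([lesion_set] on the same
#'   grid); must contain both positive and negative cases.
#' @param config a [detect_train_config()].
#' @param split optional data.frame from [make_patient_split()] restricted
#'   to these cases; built internally when `NULL`.
#' @return a `detect_ensemble`: list of per-fold models plus the fold
#'   assignment.
#' @export
train_detector <- function(cohort, config = detect_train_config(),
                           split = NULL) {
  stopifnot(inherits(config, "detect_train_config"))
  labels <- vapply(cohort, function(cs) n_lesions(cs$lesions) > 0, logical(1))
  if (all(labels) || !any(labels)) {
    stop("cohort must contain both lesion-positive and lesion-negative cases")
  }
  ids <- vapply(seq_along(cohort), function(i) {
    cohort[[i]]$patient_id %||% sprintf("case_%04d", i - 1)
  }, character(1))
  if (is.null(split)) {
    split <- data.frame(patient_id = ids, split = "train",
                        fold = with_seed(config$seed,
                                         sample(rep(seq_len(config$n_folds),
                                                    length.out = length(ids)))))
  }
  folds <- split$fold[match(ids, split$patient_id)]
  models <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr_cases <- cohort[!is.na(folds) & folds != f]
    va_cases <- cohort[!is.na(folds) & folds == f]
    if (length(tr_cases) == 0 || length(va_cases) == 0) {
      stop("fold ", f, " has an empty train or validation part")
    }
    models[[f]] <- with_seed(derive_seed(config$seed, f),
                             .train_detect_fold(tr_cases, va_cases, config))
  }
  structure(list(models = models, folds = folds, ids = ids, config = config),
            class = "detect_ensemble")
}

.case_slices_xy <- function(cs) {
  xs <- .vol_slices(cs$image)
  d <- dim(cs$lesions$labels)
  lapply(seq_along(xs), function(z) {
    list(x = xs[[z]],
         t = matrix(as.numeric(cs$lesions$labels[, , z] > 0), d[1], d[2]))
  })
}

.train_detect_fold <- function(tr_cases, va_cases, config) {
  tr <- unlist(lapply(tr_cases, .case_slices_xy), recursive = FALSE)
  va <- unlist(lapply(va_cases, .case_slices_xy), recursive = FALSE)
  w_neg <- config$class_weights[1]; w_pos <- config$class_weights[2]

  bce <- function(p, t) {
    w <- ifelse(t > 0, w_pos, w_neg)
    -mean(w * (t * log(pmax(p, 1e-12)) + (1 - t) * log(pmax(1 - p, 1e-12))))
  }
  loss_val <- function(params) {
    mean(vapply(va, function(s) {
      o <- nn_forward(params, s$x)$out[, , 1]
      bce(1 / (1 + exp(-o)), s$t)
    }, numeric(1)))
  }

  # output bias starts at the logit of the positive-voxel rate
  pos_rate <- mean(vapply(tr, function(s) mean(s$t), numeric(1)))
  b0 <- log(max(pos_rate, 1e-4) / (1 - max(pos_rate, 1e-4)))
  params <- nn_init(1L, 1L, width = config$model_scale,
                    seed = sample.int(2^30, 1), out_bias = b0)
  opt <- adam_init(params)
  best <- params; best_loss <- loss_val(params)

  if (config$epochs > 0) {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(tr))
      for (b0i in seq(1, length(tr), by = config$batch_size)) {
        batch <- ord[b0i:min(b0i + config$batch_size - 1, length(tr))]
        acc <- NULL
        for (i in batch) {
          s <- augment_slices(list(tr[[i]]$x[, , 1], tr[[i]]$t), config$augment)
          x <- array(s[[1]], dim = dim(tr[[i]]$x))
          t <- round(s[[2]])  # rotation keeps the mask binary (nearest), be safe
          fw <- nn_forward(params, x)
          p <- 1 / (1 + exp(-fw$out[, , 1]))
          w <- ifelse(t > 0, w_pos, w_neg)
          dldo <- array(w * (p - t) / length(p), dim = dim(fw$out))
          g <- nn_backward(params, fw$cache, dldo)
          acc <- accumulate_grads(acc, g, w = 1 / length(batch))
        }
        stp <- adam_step(params, acc, opt, lr = config$learning_rate)
        params <- stp$params; opt <- stp$state
      }
      vl <- loss_val(params)
      if (vl < best_loss - 1e-9) { best_loss <- vl; best <- params }
    }
  }
  structure(list(params = best, val_loss = best_loss, config = config),
            class = "detect_model")
}

#' Predict a csPCa likelihood heatmap
#'
#' Sigmoid output per voxel in `[0, 1]` on the input grid. For a
#' `detect_ensemble` the fold models are averaged voxelwise.
#'
#' @param model a `detect_model` or `detect_ensemble`.
#' @param volume preprocessed (detection-chain) volume.
#' @param provenance optional string recorded on the heatmap.
#' @return an [image_volume] heatmap with values in `[0, 1]`.
#' @export
predict_heatmap <- function(model, volume, provenance = NULL) {
  stopifnot(inherits(volume, "image_volume") ||
              is.list(volume) && !is.null(volume$data))
  models <- if (inherits(model, "detect_ensemble")) model$models else list(model)
  d <- dim(volume$data)
  acc <- array(0, dim = d)
  for (m in models) {
    stopifnot(inherits(m, "detect_model"))
    for (z in seq_len(d[3])) {
      x <- array(volume$data[, , z], dim = c(d[1], d[2], 1L))
      o <- nn_forward(m$params, x)$out[, , 1]
      acc[, , z] <- acc[, , z] + 1 / (1 + exp(-o))
    }
  }
  hm <- image_volume(acc / length(models), spacing = volume$spacing,
                     origin = volume$origin)
  attr(hm, "provenance") <- provenance
  hm
}
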
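# End-to-end experiment orchestration: phantom cohort -> k-space
# undersampling -> (naive | learned) reconstruction -> detection heatmaps ->
# visual metrics, FROC/pAUC and the statistical test battery, with a
# reproducible provenance record.

#' Experiment configuration
#'
#' Nested configuration for the full pipeline. The fully sampled condition
#' (R = 1) is the reference and must be present. Defaults are desk-scale:
#' a small phantom grid and the surrogate detector; switch
#' `detector = "learned"` and raise the phantom shape for larger runs.
#'
#' @param accelerations acceleration factors; must contain 1.
#' @param recon_methods subset of `c("naive", "learned")` applied to the
#'   accelerated conditions.
#' @param detector `"surrogate"` (deterministic, training-free) or
#'   `"learned"` (cross-validated ensemble trained on the R1 training split).
#' @param n_cases cohort size.
#' @param phantom a [phantom_config()].
#' @param mask a [mask_config()] (acceleration is overridden per condition).
#' @param recon_train a [recon_train_config()] (used when "learned" is in
#'   `recon_methods`).
#' @param detect_train a [detect_train_config()] (used for the learned
#'   detector and for the patient split).
#' @param candidate_params list passed to [extract_candidates()].
#' @param min_overlap FROC match IoU threshold.
#' @param pauc_window FP/patient window of the pAUC.
#' @param n_boot bootstrap replicates for pAUC CIs.
#' @param n_permutations permutation budget for pairwise pAUC tests.
#' @param split_seed seed of the patient-level train/test split.
#' @param seed master seed for everything else.
#' @param out_dir output directory, or `NULL` for no file output.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(accelerations = c(1, 4, 8),
                              recon_methods = c("naive", "learned"),
                              detector = c("surrogate", "learned"),
                              n_cases = 40L,
                              phantom = phantom_config(
                                volume_shape = c(48L, 48L, 8L),
                                voxel_spacing = c(1, 1, 3)),
                              mask = mask_config(),
                              recon_train = recon_train_config(
                                epochs = 8L, learning_rate = 2e-3,
                                ssim_win = 7L),
                              detect_train = detect_train_config(),
                              candidate_params = list(floor = 0.10,
                                                      relative_threshold = 0.40,
                                                      max_candidates = 10L,
                                                      min_volume = 3L),
                              min_overlap = 0.10,
                              pauc_window = c(0.1, 2.5),
                              n_boot = 200L,
                              n_permutations = 500L,
                              split_seed = 1L,
                              seed = 1L,
                              out_dir = NULL) {
  detector <- match.arg(detector)
  recon_methods <- match.arg(recon_methods, c("naive", "learned"),
                             several.ok = TRUE)
  if (!1 %in% accelerations) {
    stop("`accelerations` must contain 1: R1 is the reference condition")
  }
  structure(as.list(environment()), class = "experiment_config")
}

#' Serialize / restore an experiment configuration
#'
#' The JSON form round-trips losslessly and its MD5 hash identifies the run
#' in the provenance record.
#' @param config an `experiment_config`.
#' @param path file path.
#' @return `path` (`save_experiment_config`) or config (`load_...`).
#' @export
save_experiment_config <- function(config, path) {
  js <- jsonlite::serializeJSON(unclass(config), pretty = TRUE)
  writeLines(js, path)
  invisible(path)
}

#' @rdname save_experiment_config
#' @export
load_experiment_config <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  class(obj) <- "experiment_config"
  cls <- c(phantom = "phantom_config", mask = "mask_config",
           recon_train = "recon_train_config",
           detect_train = "detect_train_config")
  for (nm in names(cls)) class(obj[[nm]]) <- cls[[nm]]
  obj
}

.condition_name <- function(R, method) {
  if (R == 1) "R1" else paste0("R", R, "_", method)
}

#' Run the full evaluation experiment
#'
#' Generates (or reuses) a phantom cohort, simulates each acceleration
#' condition, reconstructs naively and/or with the trained model, runs the
#' detection stage on every condition with *frozen* detector settings,
#' and computes: per-case SSIM/PSNR against the fully sampled reference,
#' per-condition FROC curves with pAUC and bootstrap CI, paired Wilcoxon
#' tests on SSIM, paired permutation tests on pAUC versus R1, and the
#' patient-level ROC with the operating threshold chosen on R1 and frozen
#' elsewhere. Evaluation uses the held-out test split of the cohort.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-stage progress.
#' @return an `experiment_report` list; also written to `config$out_dir`
#'   when set (per-case metrics CSV, FROC points CSV, results JSON, split
#'   manifest CSV, provenance JSON).
#' @export
run_experiment <- function(config = experiment_config(), verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("generating %d phantom cases ...", config$n_cases)
  cohort <- generate_cohort(config$phantom, config$n_cases)
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  split <- make_patient_split(ids,
                              train_fraction = config$detect_train$train_fraction,
                              n_folds = config$detect_train$n_folds,
                              seed = config$split_seed)
  test_idx <- which(split$split[match(ids, split$patient_id)] == "test")
  train_idx <- setdiff(seq_along(cohort), test_idx)
  if (length(test_idx) < 5) stop("test split too small; raise n_cases")

  d <- config$phantom$volume_shape
  crop <- d  # phantoms are generated on the working grid: near-identity chain
  prep <- function(vol) {
    recon_preprocess(vol, target_spacing = c(NA, NA, NA), crop_size = crop)
  }

  # reference (R1) images, preprocessed once
  say("preprocessing reference images ...")
  ref_imgs <- lapply(cohort, function(cs) prep(cs$image))

  # per-condition reconstructed images; every patient's acquisition gets its
  # own mask realisation (deterministically sub-seeded), so cohort-level
  # metrics average over the randomness of the peripheral line draw
  accel <- sort(unique(config$accelerations))
  conditions <- list(R1 = ref_imgs)
  masks <- list()
  for (R in setdiff(accel, 1)) {
    mc <- config$mask
    mc$acceleration <- R
    say("undersampling at R%s ...", R)
    case_masks <- lapply(seq_along(cohort), function(i) {
      mci <- mc
      mci$seed <- derive_seed(mc$seed, 100L * R + i)
      make_undersampling_mask(d[mci$axis], mci)
    })
    masks[[paste0("R", R)]] <- case_masks
    naive <- lapply(seq_along(cohort), function(i) {
      prep(undersample_volume(cohort[[i]]$image, case_masks[[i]]))
    })
    if ("naive" %in% config$recon_methods) {
      conditions[[.condition_name(R, "naive")]] <- naive
    }
    if ("learned" %in% config$recon_methods) {
      say("training reconstructor for R%s ...", R)
      pairs <- lapply(train_idx, function(i) {
        list(aliased = naive[[i]], original = ref_imgs[[i]])
      })
      rt <- config$recon_train
      rt$seed <- derive_seed(config$seed, 1000L + R)
      model <- train_reconstructor(pairs, rt)
      say("reconstructing R%s with the trained model ...", R)
      conditions[[.condition_name(R, "learned")]] <-
        lapply(naive, function(v) reconstruct(model, v))
    }
  }

  # detector (frozen across conditions)
  detector_fun <- if (config$detector == "surrogate") {
    function(vol) surrogate_detect(vol)
  } else {
    say("training the detection ensemble on the R1 training split ...")
    dcohort <- lapply(train_idx, function(i) {
      list(image = z_normalize(ref_imgs[[i]]), lesions = cohort[[i]]$lesions,
           patient_id = ids[i])
    })
    dt <- config$detect_train
    dt$seed <- derive_seed(config$seed, 2000L)
    ensemble <- train_detector(dcohort, dt,
                               split = split[split$split == "train", ])
    function(vol) predict_heatmap(ensemble, z_normalize(vol))
  }

  # evaluation on the held-out split
  say("evaluating %d conditions on %d held-out cases ...",
      length(conditions), length(test_idx))
  imagqm <- list()
  froc_records <- list()
  pat_scores <- list()
  for (cond in names(conditions)) {
    vols <- conditions[[cond]]
    recs <- vector("list", length(test_idx))
    scores <- numeric(length(test_idx))
    rows <- vector("list", length(test_idx))
    for (k in seq_along(test_idx)) {
      i <- test_idx[k]
      v <- vols[[i]]
      rows[[k]] <- data.frame(
        patient_id = ids[i], condition = cond,
        ssim = if (cond == "R1") 1 else ssim(ref_imgs[[i]], v),
        psnr = if (cond == "R1") Inf else psnr(ref_imgs[[i]], v)
      )
      hm <- detector_fun(v)
      cands <- do.call(extract_candidates, c(list(hm), config$candidate_params))
      m <- match_candidates(cands, cohort[[i]]$lesions,
                            min_overlap = config$min_overlap)
      recs[[k]] <- froc_record(m)
      scores[k] <- patient_score(cands)
    }
    imagqm[[cond]] <- do.call(rbind, rows)
    froc_records[[cond]] <- recs
    pat_scores[[cond]] <- scores
  }
  imagqm <- do.call(rbind, imagqm)
  rownames(imagqm) <- NULL

  say("computing FROC, pAUC and statistics ...")
  froc <- lapply(froc_records, froc_curve)
  pauc_val <- vapply(froc, pauc, numeric(1), window = config$pauc_window)
  pauc_ci <- lapply(froc_records, function(r) {
    if (length(r) >= 10) {
      bootstrap_pauc_ci(r, n_boot = config$n_boot, window = config$pauc_window,
                        seed = derive_seed(config$seed, 3000L))$ci
    } else c(NA_real_, NA_real_)
  })

  get_ssim <- function(cond) imagqm$ssim[imagqm$condition == cond]
  cond_names <- names(conditions)
  ssim_tests <- list()
  for (R in setdiff(accel, 1)) {
    a <- .condition_name(R, "learned"); b <- .condition_name(R, "naive")
    if (all(c(a, b) %in% cond_names)) {
      ssim_tests[[paste0(a, "_vs_", b)]] <-
        compare_ssim_paired(get_ssim(a), get_ssim(b), a, b)
    }
  }

  perm_tests <- list()
  for (cond in setdiff(cond_names, "R1")) {
    perm_tests[[paste0("R1_vs_", cond)]] <- permutation_test_pauc(
      froc_records[["R1"]], froc_records[[cond]],
      n_permutations = config$n_permutations,
      seed = derive_seed(config$seed, 4000L), window = config$pauc_window)
  }
  # pAUC comparison between reconstruction methods at matched R
  for (R in setdiff(accel, 1)) {
    a <- .condition_name(R, "learned"); b <- .condition_name(R, "naive")
    if (all(c(a, b) %in% cond_names)) {
      perm_tests[[paste0(a, "_vs_", b)]] <- permutation_test_pauc(
        froc_records[[a]], froc_records[[b]],
        n_permutations = config$n_permutations,
        seed = derive_seed(config$seed, 4001L), window = config$pauc_window)
    }
  }

  labels <- vapply(cohort[test_idx], `[[`, integer(1), "patient_label")
  roc <- list(R1 = patient_roc(pat_scores[["R1"]], labels))
  for (cond in setdiff(cond_names, "R1")) {
    roc[[cond]] <- patient_roc(pat_scores[[cond]], labels,
                               threshold = roc[["R1"]]$threshold)
  }

  report <- structure(list(
    config = config,
    split = split,
    masks = masks,
    imagqm = imagqm,
    froc = froc,
    pauc = pauc_val,
    pauc_ci = pauc_ci,
    ssim_tests = ssim_tests,
    permutation_tests = perm_tests,
    patient_roc = roc,
    patient_scores = pat_scores,
    patient_labels = labels,
    test_ids = ids[test_idx],
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "experiment_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  say("done in %.1f s", report$runtime_s)
  report
}

#' Write an experiment report bundle to disk
#'
#' Emits the per-case image-quality CSV, per-condition FROC operating-point
#' CSVs, a results JSON (pAUC, CIs, test p-values, ROC metrics), the split
#' manifest CSV and a provenance JSON (config hash, seeds, package version)
#' sufficient to rerun the experiment bit-identically.
#'
#' @param report an `experiment_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$imagqm, file.path(dir, "imagqm_per_case.csv"),
                   row.names = FALSE)
  utils::write.csv(report$split, file.path(dir, "split_manifest.csv"),
                   row.names = FALSE)
  froc_pts <- do.call(rbind, lapply(names(report$froc), function(cond) {
    cbind(condition = cond, report$froc[[cond]]$points)
  }))
  utils::write.csv(froc_pts, file.path(dir, "froc_points.csv"),
                   row.names = FALSE)

  results <- list(
    pauc = as.list(report$pauc),
    pauc_ci = report$pauc_ci,
    ssim_mean = lapply(split(report$imagqm$ssim, report$imagqm$condition), mean),
    ssim_sd = lapply(split(report$imagqm$ssim, report$imagqm$condition),
                     stats::sd),
    ssim_tests = lapply(report$ssim_tests, function(t) {
      list(p_value = t$p_value, n = t$n)
    }),
    permutation_tests = lapply(report$permutation_tests, function(t) {
      list(observed_diff = t$observed_diff, p_value = t$p_value,
           exact = t$exact)
    }),
    patient_roc = lapply(report$patient_roc, function(r) {
      r[c("auc", "threshold", "sensitivity", "specificity", "ppv", "npv")]
    })
  )
  jsonlite::write_json(results, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_path <- file.path(dir, "config.json")
  save_experiment_config(report$config, cfg_path)
  provenance <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = report$config$seed,
    split_seed = report$config$split_seed,
    package_version = as.character(utils::packageVersion("diagqm")),
    runtime_s = report$runtime_s
  )
  jsonlite::write_json(provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> ", length(x$test_ids), " held-out cases, ",
      length(x$froc), " conditions\n", sep = "")
  sm <- split(x$imagqm$ssim, x$imagqm$condition)
  for (cond in names(x$pauc)) {
    ci <- x$pauc_ci[[cond]]
    cat(sprintf("  %-12s SSIM %.3f  pAUC %.3f [%s]\n", cond,
                mean(sm[[cond]]), x$pauc[cond],
                if (all(is.finite(ci))) sprintf("%.2f-%.2f", ci[1], ci[2])
                else "-"))
  }
  for (nm in names(x$permutation_tests)) {
    cat(sprintf("  perm %-22s p = %.4g\n", nm,
                x$permutation_tests[[nm]]$p_value))
  }
  invisible(x)
}
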
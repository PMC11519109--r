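# Lesion-level evaluation: candidate extraction from likelihood heatmaps,
# overlap matching against ground truth, FROC curve and partial AUC over a
# false-positive-per-patient window, with bootstrap confidence intervals.

#' Extract lesion candidates from a likelihood heatmap
#'
#' Iterative peak extraction: find the global maximum above `floor`, grow
#' the 6-connected region of voxels above `relative_threshold * peak`
#' containing it, record the region with confidence equal to the peak value,
#' suppress it, and repeat up to `max_candidates`. Regions smaller than
#' `min_volume` voxels are dropped (but still suppressed). Deterministic;
#' an empty candidate list is valid.
#'
#' @param heatmap an [image_volume] with values in `[0, 1]`.
#' @param floor minimum peak likelihood considered (default 0.10).
#' @param relative_threshold region-growing level as a fraction of the peak
#'   (default 0.40).
#' @param max_candidates maximum number of candidates (default 10).
#' @param min_volume minimum region size in voxels (default 3).
#' @return list of `lesion_candidate` objects: `voxels` (linear indices into
#'   the heatmap grid), `confidence`, `centroid_mm`.
#' @export
extract_candidates <- function(heatmap, floor = 0.10,
                               relative_threshold = 0.40,
                               max_candidates = 10L, min_volume = 3L) {
  stopifnot(inherits(heatmap, "image_volume"))
  h <- heatmap$data
  if (min(h) < -1e-9 || max(h) > 1 + 1e-9) {
    stop("heatmap values must lie in [0, 1]")
  }
  d <- dim(h)
  work <- h
  out <- list()
  while (length(out) < max_candidates) {
    peak_idx <- which.max(work)
    peak <- work[peak_idx]
    if (length(peak) == 0 || peak < floor) break
    region <- .flood_fill3(work, peak_idx, level = relative_threshold * peak)
    work[region] <- -Inf
    if (length(region) >= min_volume) {
      ijk <- arrayInd(region, d)
      centroid <- colMeans(ijk) * heatmap$spacing
      out[[length(out) + 1]] <- structure(
        list(voxels = region, confidence = peak, centroid_mm = centroid,
             dim = d),
        class = "lesion_candidate")
    }
  }
  out
}

# 6-connected region of voxels with value >= level containing `start`,
# returned as sorted linear indices. Frontier-based BFS on linear indices.
.flood_fill3 <- function(arr, start, level) {
  d <- dim(arr)
  n1 <- d[1]; n12 <- d[1] * d[2]
  visited <- integer(0)
  inregion <- logical(length(arr))
  inregion[start] <- TRUE
  frontier <- start
  while (length(frontier) > 0) {
    visited <- c(visited, frontier)
    ijk <- arrayInd(frontier, d)
    nbrs <- c(
      frontier[ijk[, 1] > 1] - 1L,
      frontier[ijk[, 1] < d[1]] + 1L,
      frontier[ijk[, 2] > 1] - n1,
      frontier[ijk[, 2] < d[2]] + n1,
      frontier[ijk[, 3] > 1] - n12,
      frontier[ijk[, 3] < d[3]] + n12
    )
    nbrs <- unique(nbrs)
    nbrs <- nbrs[!inregion[nbrs] & arr[nbrs] >= level]
    inregion[nbrs] <- TRUE
    frontier <- nbrs
  }
  sort(visited)
}

#' Match candidates against ground-truth lesions
#'
#' Greedy one-to-one matching in descending candidate confidence (ties
#' broken by candidate order). For each candidate, overlaps with every
#' lesion are computed as intersection-over-union of voxel sets; among
#' lesions with overlap at or above `min_overlap`, the candidate matches the
#' not-yet-matched lesion with the highest overlap (a true positive). If all
#' sufficiently overlapping lesions are already matched, the candidate is
#' discarded as a duplicate (neither TP nor FP — standard FROC practice so
#' split detections are not penalised); with no sufficient overlap it is a
#' false positive. Unmatched lesions are false negatives.
#'
#' @param candidates list from [extract_candidates()].
#' @param lesions a [lesion_set] on the same grid.
#' @param min_overlap IoU threshold (default 0.10).
#' @param overlap one of `"iou"` (default) or `"lesion_fraction"`
#'   (intersection over lesion volume).
#' @return a `match_result`: data.frames `lesion_status` (lesion_id, hit,
#'   candidate, overlap) and `candidate_status` (candidate, confidence,
#'   status in TP/FP/duplicate, matched_lesion, overlap).
#' @export
match_candidates <- function(candidates, lesions, min_overlap = 0.10,
                             overlap = c("iou", "lesion_fraction")) {
  stopifnot(inherits(lesions, "lesion_set"))
  overlap <- match.arg(overlap)
  d <- dim(lesions$labels)
  for (cd in candidates) {
    if (!identical(cd$dim, d)) stop("candidate and lesion grids differ")
  }
  lesion_ids <- lesions$info$lesion_id
  lesion_vox <- lapply(lesion_ids, function(id) which(lesions$labels == id))

  nc <- length(candidates)
  conf <- vapply(candidates, `[[`, numeric(1), "confidence")
  ord <- order(-conf, seq_len(max(nc, 1))[seq_len(nc)])

  matched <- rep(FALSE, length(lesion_ids))
  nl <- length(lesion_ids)
  lesion_status <- data.frame(lesion_id = lesion_ids,
                              hit = rep(FALSE, nl),
                              candidate = rep(NA_integer_, nl),
                              overlap = rep(NA_real_, nl))
  candidate_status <- data.frame(candidate = seq_len(nc),
                                 confidence = conf,
                                 status = rep(NA_character_, nc),
                                 matched_lesion = rep(NA_integer_, nc),
                                 overlap = rep(NA_real_, nc))
  for (ci in ord) {
    cvox <- candidates[[ci]]$voxels
    ovl <- vapply(lesion_vox, function(lv) {
      inter <- length(intersect(cvox, lv))
      if (inter == 0) return(0)
      if (overlap == "iou") {
        inter / (length(cvox) + length(lv) - inter)
      } else {
        inter / length(lv)
      }
    }, numeric(1))
    qual <- which(ovl >= min_overlap)
    if (length(qual) == 0) {
      candidate_status$status[ci] <- "FP"
      candidate_status$overlap[ci] <- if (length(ovl)) max(ovl) else 0
    } else {
      free <- qual[!matched[qual]]
      if (length(free) == 0) {
        candidate_status$status[ci] <- "duplicate"
        candidate_status$overlap[ci] <- max(ovl[qual])
      } else {
        best <- free[which.max(ovl[free])]
        matched[best] <- TRUE
        candidate_status$status[ci] <- "TP"
        candidate_status$matched_lesion[ci] <- lesion_ids[best]
        candidate_status$overlap[ci] <- ovl[best]
        lesion_status$hit[best] <- TRUE
        lesion_status$candidate[best] <- ci
        lesion_status$overlap[best] <- ovl[best]
      }
    }
  }
  structure(list(lesion_status = lesion_status,
                 candidate_status = candidate_status,
                 min_overlap = min_overlap, overlap = overlap),
            class = "match_result")
}

#' Reduce a match result to the per-patient record used by FROC sweeps
#'
#' Because matching is greedy in descending confidence, the matching for any
#' confidence threshold is the full matching restricted to candidates at or
#' above the threshold; one match per patient therefore suffices for the
#' whole curve.
#'
#' @param match a `match_result`.
#' @return a `froc_record`: `n_lesions`, `hit_conf` (confidence of the
#'   matched candidate per hit lesion), `fp_conf` (confidences of false
#'   positives).
#' @export
froc_record <- function(match) {
  stopifnot(inherits(match, "match_result"))
  cs <- match$candidate_status
  structure(list(
    n_lesions = nrow(match$lesion_status),
    hit_conf = cs$confidence[cs$status %in% "TP"],
    fp_conf = cs$confidence[cs$status %in% "FP"]
  ), class = "froc_record")
}

#' FROC curve over a cohort
#'
#' Sweeps the confidence threshold over all observed candidate confidences;
#' at each threshold sensitivity is hit lesions / total lesions (cohort
#' level) and the false-positive rate is total FPs / number of patients
#' (all patients, including lesion-free ones).
#'
#' @param records list of `froc_record` (one per patient, from
#'   [froc_record()]), or of `match_result`s.
#' @return a `froc_result`: data.frame `points` (threshold, sensitivity,
#'   fp_per_patient), `n_patients`, `n_lesions`.
#' @export
froc_curve <- function(records) {
  if (length(records) < 1) stop("need at least one patient")
  records <- lapply(records, function(r) {
    if (inherits(r, "match_result")) froc_record(r) else r
  })
  stopifnot(all(vapply(records, inherits, logical(1), "froc_record")))
  n_pat <- length(records)
  total_lesions <- sum(vapply(records, `[[`, numeric(1), "n_lesions"))
  if (total_lesions == 0) {
    stop("cohort contains no ground-truth lesions; sensitivity is undefined")
  }
  hits <- unlist(lapply(records, `[[`, "hit_conf"))
  fps <- unlist(lapply(records, `[[`, "fp_conf"))
  thr <- sort(unique(c(hits, fps)), decreasing = TRUE)
  if (length(thr) == 0) thr <- 1  # detector produced nothing
  pts <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) sum(hits >= t), numeric(1)) /
      total_lesions,
    fp_per_patient = vapply(thr, function(t) sum(fps >= t), numeric(1)) /
      n_pat
  )
  structure(list(points = pts, n_patients = n_pat, n_lesions = total_lesions),
            class = "froc_result")
}

#' @export
print.froc_result <- function(x, ...) {
  cat("<froc_result> ", x$n_patients, " patients, ", x$n_lesions,
      " lesions, ", nrow(x$points), " operating points\n", sep = "")
  invisible(x)
}

#' Partial area under the FROC curve
#'
#' Trapezoidal integral of lesion sensitivity over false positives per
#' patient on the linear FP axis restricted to `window` (default 0.1-2.5).
#' The curve starts at the implicit operating point (0 FP, 0 sensitivity),
#' uses linear interpolation between operating points (at equal FP counts
#' the highest sensitivity is kept) and is extended right-constant past the
#' last point. A perfect detector spans the whole window at sensitivity 1,
#' giving the maximum 2.4.
#'
#' @param froc a `froc_result`.
#' @param window FP/patient integration window.
#' @return pAUC in `[0, diff(window)]`.
#' @export
pauc <- function(froc, window = c(0.1, 2.5)) {
  stopifnot(inherits(froc, "froc_result"), length(window) == 2,
            window[2] > window[1])
  pts <- froc$points
  fp <- c(0, pts$fp_per_patient)
  se <- c(0, pts$sensitivity)
  # keep the best sensitivity at duplicated FP rates
  agg <- tapply(se, fp, max)
  fx <- as.numeric(names(agg))
  fy <- as.numeric(agg)
  o <- order(fx)
  fx <- fx[o]; fy <- fy[o]
  s_at <- function(f) {
    if (f >= fx[length(fx)]) return(fy[length(fy)])   # right-constant
    stats::approx(fx, fy, xout = f, rule = 2)$y
  }
  knots <- sort(unique(c(window, fx[fx > window[1] & fx < window[2]])))
  if (max(fx) <= window[1] && fy[length(fy)] == 0) {
    warning("FROC curve lies entirely below the integration window")
  }
  vals <- vapply(knots, s_at, numeric(1))
  sum(diff(knots) * (utils::head(vals, -1) + utils::tail(vals, -1)) / 2)
}

#' Bootstrap confidence interval for the pAUC
#'
#' Patient-level resampling with replacement; percentile interval. Resamples
#' without any ground-truth lesion leave sensitivity undefined and are
#' redrawn; their count is reported.
#'
#' @param records list of per-patient `froc_record`s (>= 10 patients).
#' @param n_boot bootstrap replicates.
#' @param level confidence level.
#' @param seed RNG seed.
#' @param window pAUC window.
#' @return list with `ci` (lo, hi), `point` estimate, `n_boot`,
#'   `n_degenerate_redrawn`.
#' @export
bootstrap_pauc_ci <- function(records, n_boot = 1000, level = 0.95,
                              seed = 1L, window = c(0.1, 2.5)) {
  records <- lapply(records, function(r) {
    if (inherits(r, "match_result")) froc_record(r) else r
  })
  n <- length(records)
  if (n < 10) stop("need at least 10 patients for a bootstrap CI")
  point <- pauc(froc_curve(records), window)
  n_les <- vapply(records, `[[`, numeric(1), "n_lesions")
  with_seed(seed, {
    vals <- numeric(n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sum(n_les[idx]) > 0) break
        redrawn <- redrawn + 1L
      }
      vals[b] <- pauc(froc_curve(records[idx]), window)
    }
    alpha <- (1 - level) / 2
    list(ci = unname(stats::quantile(vals, c(alpha, 1 - alpha), type = 7)),
         point = point, n_boot = n_boot, n_degenerate_redrawn = redrawn,
         window = window)
  })
}
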
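# Candidate extraction, overlap matching, FROC curve, pAUC and bootstrap.

test_that("candidate extraction recovers constructed blobs and their level sets", {
  d <- c(20L, 20L, 3L)
  h <- array(0, dim = d)
  # two disjoint unimodal blobs, peaks 0.9 and 0.5, truncated at the 40%
  # relative level so each blob's support is exactly its growth region
  # (an untruncated Gaussian would leave a residual ring after suppression)
  mk_blob <- function(h, ci, cj, z, peak, sigma = 2) {
    for (i in 1:d[1]) for (j in 1:d[2]) {
      g <- exp(-((i - ci)^2 + (j - cj)^2) / (2 * sigma^2))
      if (g >= 0.4) h[i, j, z] <- max(h[i, j, z], peak * g)
    }
    h
  }
  h <- mk_blob(h, 5, 5, 1, 0.9)
  h <- mk_blob(h, 15, 15, 3, 0.5)
  cands <- extract_candidates(as_heatmap(h))
  expect_length(cands, 2)
  expect_equal(vapply(cands, `[[`, numeric(1), "confidence"), c(0.9, 0.5))
  # regions match the 0.4-relative level sets of each blob
  lvl1 <- which(h >= 0.4 * 0.9 & slice.index(h, 3) == 1)
  expect_setequal(cands[[1]]$voxels, lvl1)
  lvl2 <- which(h >= 0.4 * 0.5 & slice.index(h, 3) == 3)
  expect_setequal(cands[[2]]$voxels, lvl2)
})

test_that("degenerate heatmaps produce no candidates", {
  expect_length(extract_candidates(as_heatmap(array(0, dim = c(8, 8, 2)))), 0)
  h <- array(0.05, dim = c(8, 8, 2))  # everything below the floor
  expect_length(extract_candidates(as_heatmap(h)), 0)
  h2 <- array(0, dim = c(8, 8, 1)); h2[4, 4, 1] <- 0.9
  # floor above the global max
  expect_length(extract_candidates(as_heatmap(h2), floor = 0.95), 0)
  # single-voxel peak below min_volume is dropped
  expect_length(extract_candidates(as_heatmap(h2), min_volume = 3), 0)
})

test_that("matching handles perfect overlap, sub-threshold overlap and duplicates", {
  d <- c(10L, 10L, 1L)
  les_vox <- which(array(slice.index(array(0, d), 1) %in% 3:5 &
                           slice.index(array(0, d), 2) %in% 3:5, d))
  les <- lesions_from_voxels(list(les_vox), d)
  cand <- function(vox, conf) structure(
    list(voxels = vox, confidence = conf, centroid_mm = c(0, 0, 0), dim = d),
    class = "lesion_candidate")
  # exact overlap -> TP
  m <- match_candidates(list(cand(les_vox, 0.8)), les)
  expect_equal(m$candidate_status$status, "TP")
  expect_true(all(m$lesion_status$hit))
  # IoU 0.05 -> FP and the lesion stays FN
  far <- which(array(slice.index(array(0, d), 1) == 9, d))[1:20]
  low <- c(les_vox[1], far)  # 1/(9+21-1) << 0.1
  m2 <- match_candidates(list(cand(low, 0.9)), les)
  expect_equal(m2$candidate_status$status, "FP")
  expect_false(any(m2$lesion_status$hit))
  # second candidate on an already-matched lesion is discarded as duplicate
  m3 <- match_candidates(list(cand(les_vox, 0.9), cand(les_vox[1:5], 0.7)), les)
  expect_equal(m3$candidate_status$status, c("TP", "duplicate"))
})

test_that("greedy confidence-ordered matching equals the brute-force assignment", {
  d <- c(12L, 12L, 1L)
  lin <- function(rows, cols) {
    which(array(slice.index(array(0, d), 1) %in% rows &
                  slice.index(array(0, d), 2) %in% cols, d))
  }
  lesA <- lin(1:4, 1:4)    # 16 voxels
  lesB <- lin(8:11, 8:11)  # 16 voxels
  les <- lesions_from_voxels(list(lesA, lesB), d)
  cand <- function(vox, conf) structure(
    list(voxels = vox, confidence = conf, centroid_mm = c(0, 0, 0), dim = d),
    class = "lesion_candidate")
  cands <- list(cand(lin(1:4, 2:5), 0.9),   # overlaps A strongly
                cand(lin(2:5, 1:4), 0.8),   # overlaps A (duplicate after c1)
                cand(lin(8:11, 9:12), 0.7)) # overlaps B
  m <- match_candidates(cands, les)
  expect_equal(m$candidate_status$status, c("TP", "duplicate", "TP"))
  expect_equal(m$candidate_status$matched_lesion, c(1L, NA_integer_, 2L))
  # independent oracle: greedy order enumerated by hand over all one-to-one
  # assignments honouring confidence order gives the same hits
  oracle <- froc_oracle(list(list(cands = cands, lesions = les)))
  expect_equal(oracle$sensitivity[oracle$threshold == 0.7], 1.0)
  expect_equal(oracle$fp_per_patient, c(0, 0, 0))
})

test_that("the FROC sweep equals exhaustive per-threshold re-matching", {
  # constructed 2-patient cohort with overlapping and spurious candidates
  d <- c(12L, 12L, 1L)
  lin <- function(rows, cols) {
    which(array(slice.index(array(0, d), 1) %in% rows &
                  slice.index(array(0, d), 2) %in% cols, d))
  }
  cand <- function(vox, conf) structure(
    list(voxels = vox, confidence = conf, centroid_mm = c(0, 0, 0), dim = d),
    class = "lesion_candidate")
  p1 <- list(cands = list(cand(lin(1:3, 1:3), 0.95), cand(lin(9:11, 9:11), 0.6),
                          cand(lin(5:6, 5:6), 0.3)),
             lesions = lesions_from_voxels(list(lin(1:3, 1:3), lin(9:10, 9:10)), d))
  p2 <- list(cands = list(cand(lin(2:4, 7:9), 0.7), cand(lin(7:8, 2:3), 0.5)),
             lesions = lesions_from_voxels(list(lin(6:8, 1:3)), d))
  patients <- list(p1, p2)
  records <- lapply(patients, function(p) {
    froc_record(match_candidates(p$cands, p$lesions))
  })
  got <- froc_curve(records)
  want <- froc_oracle(patients)
  expect_equal(got$points$threshold, want$threshold)
  expect_equal(got$points$sensitivity, want$sensitivity)
  expect_equal(got$points$fp_per_patient, want$fp_per_patient)
  # monotone as the threshold drops
  expect_true(all(diff(got$points$sensitivity) >= 0))
  expect_true(all(diff(got$points$fp_per_patient) >= 0))
})

test_that("FROC on random small cohorts equals the exhaustive oracle", {
  d <- c(10L, 10L, 2L)
  set.seed(21)
  for (rep in 1:8) {
    patients <- lapply(1:4, function(i) {
      nles <- sample(0:2, 1)
      vox_pool <- seq_len(prod(d))
      lesions <- lesions_from_voxels(
        lapply(seq_len(nles) , function(k) sample(vox_pool, 12)), d)
      ncand <- sample(0:3, 1)
      cands <- lapply(seq_len(ncand), function(k) {
        structure(list(voxels = sample(vox_pool, sample(5:15, 1)),
                       confidence = round(runif(1), 2),
                       centroid_mm = c(0, 0, 0), dim = d),
                  class = "lesion_candidate")
      })
      list(cands = cands, lesions = lesions)
    })
    total_les <- sum(vapply(patients, function(p) n_lesions(p$lesions),
                            numeric(1)))
    if (total_les == 0) next
    records <- lapply(patients, function(p) {
      froc_record(match_candidates(p$cands, p$lesions))
    })
    got <- froc_curve(records)
    want <- froc_oracle(patients)
    if (nrow(want) == 0) next
    expect_equal(got$points$sensitivity, want$sensitivity)
    expect_equal(got$points$fp_per_patient, want$fp_per_patient)
    expect_equal(pauc(got), pauc_oracle(want$fp_per_patient, want$sensitivity))
  }
})

test_that("pAUC closed forms and bounds", {
  # perfect detector: sensitivity 1 at 0 FP/patient for every threshold
  perfect <- froc_curve(list(rec(2, hit_conf = c(1, 1)), rec(1, hit_conf = 1)))
  expect_equal(pauc(perfect), 2.4)
  # constant sensitivity 0.5 across the window
  half <- froc_curve(list(rec(2, hit_conf = c(1))))
  expect_equal(pauc(half), 1.2)
  # piecewise-linear toy curve: hand-computed trapezoid
  toy <- structure(list(points = data.frame(
    threshold = c(0.9, 0.5, 0.2),
    sensitivity = c(0.2, 0.6, 0.8),
    fp_per_patient = c(0.5, 1.5, 3.0))), class = "froc_result")
  # knots at 0.1, 0.5, 1.5, 2.5 with linear interpolation from (0,0)
  s_01 <- 0.2 * 0.1 / 0.5
  s_25 <- 0.6 + (0.8 - 0.6) * (2.5 - 1.5) / (3.0 - 1.5)
  want <- (s_01 + 0.2) / 2 * 0.4 + (0.2 + 0.6) / 2 * 1 + (0.6 + s_25) / 2 * 1
  expect_equal(pauc(toy), want)
  # bounds
  expect_gte(pauc(toy), 0)
  expect_lte(pauc(toy), 2.4)
  # curve entirely below the window warns and returns 0
  nothing <- froc_curve(list(rec(1)))
  expect_warning(p0 <- pauc(nothing), "window")
  expect_equal(p0, 0)
})

test_that("cohorts without lesions are rejected", {
  expect_error(froc_curve(list(rec(0), rec(0, fp_conf = 0.5))), "no ground-truth")
})

test_that("bootstrap CI covers the point estimate and degenerates sensibly", {
  # identical patients -> zero-width CI
  same <- lapply(1:12, function(i) rec(1, hit_conf = 0.8, fp_conf = 0.3))
  ci <- bootstrap_pauc_ci(same, n_boot = 50, seed = 4)
  expect_equal(ci$ci[1], ci$ci[2])
  expect_equal(ci$ci[1], ci$point)
  # mixed cohort: CI contains the point estimate; degenerate redraw counting
  set.seed(5)
  mixed <- lapply(1:12, function(i) {
    if (i <= 3) rec(1, hit_conf = runif(1, 0.5, 1)) else rec(0, fp_conf = runif(1))
  })
  ci2 <- bootstrap_pauc_ci(mixed, n_boot = 100, seed = 6)
  expect_gte(ci2$point, ci2$ci[1])
  expect_lte(ci2$point, ci2$ci[2])
  expect_gte(ci2$n_degenerate_redrawn, 0)
  expect_error(bootstrap_pauc_ci(same[1:5]), "at least 10")
})
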
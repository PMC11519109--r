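# Shared fixtures built in code; everything is seeded and small.

# Desk-scale phantom configuration used across test files.
test_phantom_config <- function(seed = 7, ...) {
  phantom_config(volume_shape = c(48L, 48L, 8L), voxel_spacing = c(1, 1, 3),
                 seed = seed, ...)
}

# A small deterministic ramp volume (no randomness).
ramp_volume <- function(d = c(16L, 16L, 1L), spacing = c(1, 1, 1)) {
  arr <- array(0, dim = d)
  for (z in seq_len(d[3])) {
    arr[, , z] <- outer(seq_len(d[1]), seq_len(d[2]), function(i, j) i + 2 * j) /
      (d[1] + 2 * d[2])
  }
  image_volume(arr, spacing = spacing)
}

# Build a heatmap volume from an array.
as_heatmap <- function(arr, spacing = c(1, 1, 1)) {
  image_volume(arr, spacing = spacing)
}

# Construct a lesion_set from a list of voxel-index matrices (n x 3).
lesions_from_voxels <- function(voxel_list, d) {
  labels <- array(0L, dim = d)
  for (k in seq_along(voxel_list)) labels[voxel_list[[k]]] <- k
  lesion_set(labels)
}

# A hand-built froc_record.
rec <- function(n_lesions, hit_conf = numeric(0), fp_conf = numeric(0)) {
  structure(list(n_lesions = n_lesions, hit_conf = hit_conf,
                 fp_conf = fp_conf), class = "froc_record")
}

# Brute-force 2D DFT of a slice: explicit O(N^4) summation, DC-centred
# masking, inverse by explicit summation. Independent of the fft-based path.
dft_undersample_oracle <- function(slice, sampled_lines, axis) {
  n1 <- nrow(slice); n2 <- ncol(slice)
  K <- matrix(0 + 0i, n1, n2)
  for (u in 0:(n1 - 1)) for (v in 0:(n2 - 1)) {
    s <- 0 + 0i
    for (x in 0:(n1 - 1)) for (y in 0:(n2 - 1)) {
      s <- s + slice[x + 1, y + 1] * exp(-2i * pi * (u * x / n1 + v * y / n2))
    }
    K[u + 1, v + 1] <- s
  }
  # shift DC to centre, zero unsampled lines, shift back
  sh1 <- floor(n1 / 2); sh2 <- floor(n2 / 2)
  Ks <- K[c((sh1 + 1):n1, 1:sh1), c((sh2 + 1):n2, 1:sh2)]
  keep <- rep(FALSE, if (axis == 1) n1 else n2)
  keep[sampled_lines] <- TRUE
  if (axis == 1) Ks[!keep, ] <- 0 else Ks[, !keep] <- 0
  us1 <- ceiling(n1 / 2); us2 <- ceiling(n2 / 2)
  Km <- Ks[c((us1 + 1):n1, 1:us1), c((us2 + 1):n2, 1:us2)]
  out <- matrix(0, n1, n2)
  for (x in 0:(n1 - 1)) for (y in 0:(n2 - 1)) {
    s <- 0 + 0i
    for (u in 0:(n1 - 1)) for (v in 0:(n2 - 1)) {
      s <- s + Km[u + 1, v + 1] * exp(2i * pi * (u * x / n1 + v * y / n2))
    }
    out[x + 1, y + 1] <- Mod(s) / (n1 * n2)
  }
  out
}

# Exhaustive FROC oracle: for every threshold re-runs greedy confidence-
# ordered matching restricted to candidates >= threshold, from scratch.
# `patients`: list of list(cands = list of list(voxels, confidence),
#                          lesions = lesion_set).
froc_oracle <- function(patients, min_overlap = 0.10) {
  all_conf <- sort(unique(unlist(lapply(patients, function(p) {
    vapply(p$cands, `[[`, numeric(1), "confidence")
  }))), decreasing = TRUE)
  total_lesions <- sum(vapply(patients, function(p) n_lesions(p$lesions),
                              numeric(1)))
  pts <- lapply(all_conf, function(thr) {
    hits <- 0; fps <- 0
    for (p in patients) {
      conf <- vapply(p$cands, `[[`, numeric(1), "confidence")
      keep <- which(conf >= thr)
      keep <- keep[order(-conf[keep], keep)]
      ids <- p$lesions$info$lesion_id
      lvox <- lapply(ids, function(id) which(p$lesions$labels == id))
      matched <- rep(FALSE, length(ids))
      for (ci in keep) {
        cv <- p$cands[[ci]]$voxels
        ovl <- vapply(lvox, function(lv) {
          it <- length(intersect(cv, lv))
          if (it == 0) 0 else it / (length(cv) + length(lv) - it)
        }, numeric(1))
        qual <- which(ovl >= min_overlap)
        if (length(qual) == 0) {
          fps <- fps + 1
        } else {
          free <- qual[!matched[qual]]
          if (length(free) > 0) {
            matched[free[which.max(ovl[free])]] <- TRUE
            hits <- hits + 1
          } # else duplicate: ignored
        }
      }
    }
    c(sens = hits / total_lesions, fp = fps / length(patients))
  })
  data.frame(threshold = all_conf,
             sensitivity = vapply(pts, `[`, numeric(1), 1),
             fp_per_patient = vapply(pts, `[`, numeric(1), 2))
}

# Trapezoidal pAUC oracle on explicit (fp, sens) points with the same
# conventions: (0,0) start, max-sens per fp, linear interp, right-constant.
pauc_oracle <- function(fp, sens, window = c(0.1, 2.5)) {
  fp <- c(0, fp); sens <- c(0, sens)
  agg <- tapply(sens, fp, max)
  fx <- as.numeric(names(agg)); fy <- as.numeric(agg)
  o <- order(fx); fx <- fx[o]; fy <- fy[o]
  f <- function(q) {
    if (q >= fx[length(fx)]) return(fy[length(fy)])
    approx(fx, fy, xout = q, rule = 2)$y
  }
  xs <- sort(unique(c(window, fx[fx > window[1] & fx < window[2]])))
  ys <- vapply(xs, f, numeric(1))
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}
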
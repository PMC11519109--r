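# Cohort-level inference: paired permutation test on pAUC differences,
# patient-level ROC with fixed-threshold operating metrics, Cohen's kappa
# for reader concordance, and hallucination-set selection.

#' Paired permutation test on the pAUC difference between two conditions
#'
#' The observed statistic is `pAUC(a) - pAUC(b)` over the same patients
#' under two conditions (paired heatmaps). The null is generated by
#' independently swapping each patient's condition labels (paired exchange)
#' and recomputing both pAUCs. When the number of distinct swap patterns
#' `2^n` does not exceed `n_permutations` the test enumerates all of them
#' (exact); otherwise it samples. The two-sided p-value is
#' `(1 + #{|null| >= |obs|}) / (n_used + 1)` for the sampled test and the
#' exact tail probability for the enumerated one.
#'
#' @param records_a,records_b per-patient `froc_record` lists, aligned by
#'   patient, one per condition.
#' @param n_permutations permutation budget.
#' @param seed RNG seed.
#' @param window pAUC window.
#' @return a `permutation_result`: `observed_diff`, `p_value`, `null_diffs`,
#'   `n_permutations`, `exact`, `seed`.
#' @export
permutation_test_pauc <- function(records_a, records_b,
                                  n_permutations = 1000, seed = 1L,
                                  window = c(0.1, 2.5)) {
  to_rec <- function(r) if (inherits(r, "match_result")) froc_record(r) else r
  records_a <- lapply(records_a, to_rec)
  records_b <- lapply(records_b, to_rec)
  n <- length(records_a)
  if (length(records_b) != n) stop("conditions are not paired: unequal cohorts")
  if (n < 2) stop("need at least 2 patients")

  stat <- function(swap) {
    a <- records_a; b <- records_b
    a[swap] <- records_b[swap]
    b[swap] <- records_a[swap]
    pauc(froc_curve(a), window) - pauc(froc_curve(b), window)
  }
  obs <- stat(rep(FALSE, n))

  exact <- (2^n) <= n_permutations
  if (exact) {
    patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    null_diffs <- apply(patterns, 1, stat)
    p <- mean(abs(null_diffs) >= abs(obs) - 1e-12)
    n_used <- nrow(patterns)
  } else {
    null_diffs <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        stat(stats::runif(n) < 0.5)
      }, numeric(1))
    })
    p <- (1 + sum(abs(null_diffs) >= abs(obs) - 1e-12)) / (n_permutations + 1)
    n_used <- n_permutations
  }
  structure(list(observed_diff = obs, p_value = p, null_diffs = null_diffs,
                 n_permutations = n_used, exact = exact, seed = seed,
                 window = window),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Paired permutation test on pAUC: diff = %.4f, p = %.4g (%s, %d permutations)\n",
              x$observed_diff, x$p_value,
              if (x$exact) "exact" else "sampled", x$n_permutations))
  invisible(x)
}

#' Patient-level ROC analysis with a frozen operating threshold
#'
#' The patient score is the maximum candidate confidence (0 when the
#' detector finds nothing). AUC is the rank (Mann-Whitney) statistic with
#' tie correction. When `threshold` is `NULL` the operating threshold is
#' chosen by the Youden index (sensitivity + specificity - 1) on these data
#' — the reference (fully sampled) condition; pass that threshold back in
#' when evaluating degraded conditions so the operating point is held fixed.
#' Patients are called positive when `score >= threshold`.
#'
#' @param scores per-patient detection scores in `[0, 1]`.
#' @param labels per-patient binary csPCa status (0/1); both classes needed.
#' @param threshold fixed operating threshold, or `NULL` to select by Youden.
#' @return a `patient_roc_result`: `auc`, `threshold`,
#'   `threshold_criterion`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   confusion counts, `scores`, `labels`.
#' @export
patient_roc <- function(scores, labels, threshold = NULL) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties (count 0.5)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  criterion <- "fixed"
  if (is.null(threshold)) {
    cand <- sort(unique(scores))
    youden <- vapply(cand, function(t) {
      mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
    }, numeric(1))
    best <- max(youden)
    threshold <- max(cand[youden >= best - 1e-12])  # tie: most specific
    criterion <- "youden"
  }
  tp <- sum(scores >= threshold & labels == 1)
  fp <- sum(scores >= threshold & labels == 0)
  fn <- n1 - tp
  tn <- n0 - fp
  structure(list(
    auc = auc, threshold = threshold, threshold_criterion = criterion,
    sensitivity = tp / n1, specificity = tn / n0,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
    scores = scores, labels = labels
  ), class = "patient_roc_result")
}

#' @export
print.patient_roc_result <- function(x, ...) {
  cat(sprintf("Patient-level ROC: AUC %.3f; threshold %.3f (%s)\n",
              x$auc, x$threshold, x$threshold_criterion))
  cat(sprintf("  sens %.3f  spec %.3f  PPV %.3f  NPV %.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Cohen's kappa with an asymptotic confidence interval
#'
#' Agreement between two raters over the same cases, corrected for chance.
#' Three-category concordance ratings (`consistent`, `minor`,
#' `inconsistent`) are collapsed to binary by default (`consistent` +
#' `minor` vs `inconsistent`); pass `collapse = "none"` to keep the
#' categories. The 95% CI uses the Fleiss-Cohen-Everitt asymptotic variance
#' of the unweighted kappa.
#'
#' @param rater1,rater2 factors or character vectors of per-case ratings.
#' @param collapse `"binary"` (default) or `"none"`.
#' @param level confidence level.
#' @return list with `kappa`, `ci`, `se`, `po`, `pe`, `table`, `n`.
#' @export
cohens_kappa <- function(rater1, rater2, collapse = c("binary", "none"),
                         level = 0.95) {
  collapse <- match.arg(collapse)
  if (length(rater1) != length(rater2)) stop("raters rated different case sets")
  n <- length(rater1)
  if (n < 2) stop("need at least 2 cases")
  if (collapse == "binary") {
    squash <- function(x) {
      x <- as.character(x)
      known <- x %in% c("consistent", "minor", "inconsistent")
      if (all(known)) {
        ifelse(x == "inconsistent", "inconsistent", "consistent")
      } else x  # already binary or arbitrary labels: leave untouched
    }
    rater1 <- squash(rater1); rater2 <- squash(rater2)
  }
  lev <- sort(unique(c(as.character(rater1), as.character(rater2))))
  tab <- table(factor(rater1, levels = lev), factor(rater2, levels = lev))
  p <- tab / n
  po <- sum(diag(p))
  pr <- rowSums(p); pc <- colSums(p)
  pe <- sum(pr * pc)
  if (1 - pe < 1e-12) {
    warning("degenerate marginals (pe = 1); kappa undefined, returning NA")
    return(list(kappa = NA_real_, ci = c(NA_real_, NA_real_), se = NA_real_,
                po = po, pe = pe, table = tab, n = n))
  }
  k <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt (1969) asymptotic variance of unweighted kappa
  A <- sum(diag(p) * (1 - (pr + pc) * (1 - k))^2)
  B <- 0
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (i != j) B <- B + p[i, j] * (pc[i] + pr[j])^2
  }
  B <- (1 - k)^2 * B
  C <- (k - pe * (1 - k))^2
  var_k <- (A + B - C) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(kappa = k, ci = c(k - z * se, k + z * se), se = se,
       po = po, pe = pe, table = tab, n = n)
}

#' Select the hallucination reader-study case sets
#'
#' Per-case inconsistency is the absolute difference between the patient
#' scores under the reference and the accelerated condition. The `k` cases
#' with the largest differences form the Inconsistent Set and the `k` with
#' the smallest the Consistent Set (ties broken by patient id, ascending,
#' for determinism).
#'
#' @param scores_ref,scores_alt per-patient scores under the two conditions.
#' @param patient_ids ids aligned with the scores.
#' @param k set size (default 15).
#' @return list with `inconsistent` and `consistent` data.frames
#'   (patient_id, difference), each of `k` rows, disjoint.
#' @export
select_inconsistency_sets <- function(scores_ref, scores_alt, patient_ids,
                                      k = 15L) {
  n <- length(patient_ids)
  stopifnot(length(scores_ref) == n, length(scores_alt) == n)
  if (n < 2 * k) stop("need at least 2k = ", 2 * k, " cases")
  diffs <- abs(scores_ref - scores_alt)
  o_desc <- order(-diffs, as.character(patient_ids))
  o_asc <- order(diffs, as.character(patient_ids))
  inc <- o_desc[seq_len(k)]
  con <- setdiff(o_asc, inc)[seq_len(k)]
  list(
    inconsistent = data.frame(patient_id = patient_ids[inc],
                              difference = diffs[inc]),
    consistent = data.frame(patient_id = patient_ids[con],
                            difference = diffs[con])
  )
}

#' Per-patient score from a candidate list
#'
#' The convention in the csPCa detection literature: the patient-level
#' likelihood is the maximum candidate confidence, 0 when the detector
#' reports nothing.
#' @param candidates list from [extract_candidates()].
#' @return numeric score in `[0, 1]`.
#' @export
patient_score <- function(candidates) {
  if (length(candidates) == 0) return(0)
  max(vapply(candidates, `[[`, numeric(1), "confidence"))
}
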
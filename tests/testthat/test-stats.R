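# Permutation inference, patient-level ROC, Cohen's kappa and the
# hallucination-set selection.

test_that("permutation test: identical conditions give diff 0 and p = 1", {
  recs <- lapply(1:6, function(i) rec(1, hit_conf = 0.5 + i / 20,
                                      fp_conf = runif(2)))
  r <- permutation_test_pauc(recs, recs, n_permutations = 200, seed = 1)
  expect_equal(r$observed_diff, 0)
  expect_equal(r$p_value, 1)
})

test_that("small cohorts are enumerated exactly and match an independent oracle", {
  set.seed(31)
  ra <- list(rec(1, hit_conf = 0.9), rec(2, hit_conf = c(0.8, 0.6),
                                         fp_conf = 0.3), rec(1, fp_conf = 0.7))
  rb <- list(rec(1, hit_conf = 0.4, fp_conf = 0.9), rec(2, hit_conf = 0.5),
             rec(1, fp_conf = c(0.8, 0.6)))
  r <- permutation_test_pauc(ra, rb, n_permutations = 1000, seed = 2)
  expect_true(r$exact)
  expect_equal(r$n_permutations, 8)
  # oracle: enumerate all 2^3 swap patterns independently
  stat_or <- function(sw) {
    a <- ra; b <- rb
    a[sw] <- rb[sw]; b[sw] <- ra[sw]
    pauc(froc_curve(a)) - pauc(froc_curve(b))
  }
  nulls <- vapply(0:7, function(k) {
    stat_or(as.logical(intToBits(k)[1:3]))
  }, numeric(1))
  p_or <- mean(abs(nulls) >= abs(stat_or(c(FALSE, FALSE, FALSE))) - 1e-12)
  expect_equal(r$p_value, p_or)
  expect_gte(r$p_value, 1 / 8)
})

test_that("permutation p-values satisfy their structural invariants", {
  set.seed(32)
  ra <- lapply(1:12, function(i) rec(1, hit_conf = runif(1),
                                     fp_conf = runif(sample(0:2, 1))))
  rb <- lapply(1:12, function(i) rec(1, hit_conf = runif(1),
                                     fp_conf = runif(sample(0:2, 1))))
  r <- permutation_test_pauc(ra, rb, n_permutations = 99, seed = 3)
  expect_gt(r$p_value, 0)
  expect_lte(r$p_value, 1)
  expect_gte(r$p_value, 1 / 100)
  expect_error(permutation_test_pauc(ra, rb[1:5]), "paired")
})

test_that("patient ROC: separation, ties, and the Mann-Whitney oracle", {
  r <- patient_roc(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # identical scores: AUC 0.5 by tie correction
  rt <- patient_roc(rep(0.5, 8), c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(rt$auc, 0.5)
  # printed toy with one overlap: oracle by pairwise comparison enumeration
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  lb <- c(1, 1, 1, 0, 0, 0)
  sc2 <- sc; sc2[4] <- 0.7  # one tie across classes
  for (s in list(sc, sc2)) {
    r2 <- patient_roc(s, lb)
    pairs <- expand.grid(p = which(lb == 1), n = which(lb == 0))
    want <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                        ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
    expect_equal(r2$auc, want)
  }
  expect_error(patient_roc(c(1, 2), c(1, 1)), "both classes")
})

test_that("patient ROC AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  sc <- round(runif(40), 2)
  lb <- rbinom(40, 1, 0.5)
  if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
  r <- patient_roc(sc, lb)
  # fix the direction: pROC's "auto" flips AUCs below 0.5
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    lb, sc, levels = c(0, 1), direction = "<"))))
  expect_equal(r$auc, ref, tolerance = 1e-12)
})

test_that("frozen-threshold evaluation reuses the reference operating point", {
  sc1 <- c(seq(0.70, 1.00, length.out = 10),   # positives
           seq(0.00, 0.45, length.out = 10))   # negatives
  lb <- rep(c(1, 0), each = 10)
  r1 <- patient_roc(sc1, lb)
  # degradation raises some negatives past the frozen reference threshold
  degraded <- sc1 + c(rep(0, 10), rep(0.4, 10))
  r4 <- patient_roc(degraded, lb, threshold = r1$threshold)
  expect_equal(r4$threshold, r1$threshold)
  expect_equal(r4$threshold_criterion, "fixed")
  # degradation pattern: sensitivity preserved, specificity drops
  expect_equal(r4$sensitivity, r1$sensitivity)
  expect_lt(r4$specificity, r1$specificity)
})

test_that("Cohen's kappa closed forms and CI behave as documented", {
  # perfect agreement
  k1 <- cohens_kappa(rep(c("a", "b"), 10), rep(c("a", "b"), 10),
                     collapse = "none")
  expect_equal(k1$kappa, 1)
  # hand-evaluated 2x2 table a=10, b=5, c=5, d=10: po = 2/3, pe = 1/2
  r1 <- c(rep("x", 15), rep("y", 15))
  r2 <- c(rep("x", 10), rep("y", 5), rep("x", 5), rep("y", 10))
  k2 <- cohens_kappa(r1, r2, collapse = "none")
  expect_equal(k2$kappa, 1 / 3, tolerance = 1e-12)
  expect_equal(k2$po, 2 / 3)
  expect_equal(k2$pe, 1 / 2)
  expect_true(k2$ci[1] < k2$kappa && k2$kappa < k2$ci[2])
  # three-level concordance ratings collapse to binary by default
  k3 <- cohens_kappa(c("consistent", "minor", "inconsistent", "inconsistent"),
                     c("minor", "consistent", "inconsistent", "consistent"))
  expect_equal(unname(dim(k3$table)), c(2L, 2L))
  # degenerate marginals warn and return NA
  expect_warning(kd <- cohens_kappa(rep("a", 5), rep("a", 5)), "degenerate")
  expect_true(is.na(kd$kappa))
})

test_that("independent raters give near-zero kappa on average", {
  set.seed(35)
  ks <- vapply(1:40, function(i) {
    a <- sample(c("consistent", "inconsistent"), 1000, TRUE, prob = c(0.7, 0.3))
    b <- sample(c("consistent", "inconsistent"), 1000, TRUE, prob = c(0.7, 0.3))
    cohens_kappa(a, b)$kappa
  }, numeric(1))
  expect_lt(abs(mean(ks)), 0.05)
})

test_that("inconsistency sets select the extremes deterministically", {
  s <- select_inconsistency_sets(c(0.9, 0.5, 0.4), c(0.1, 0.5, 0.35),
                                 patient_ids = c("a", "b", "c"), k = 1)
  expect_equal(s$inconsistent$patient_id, "a")
  expect_equal(s$consistent$patient_id, "b")
  # disjointness and agreement with a full sort on larger input
  set.seed(36)
  n <- 40
  ids <- sprintf("p%02d", 1:n)
  d1 <- runif(n); d2 <- runif(n)
  s2 <- select_inconsistency_sets(d1, d2, ids, k = 15)
  expect_length(intersect(s2$inconsistent$patient_id,
                          s2$consistent$patient_id), 0)
  o <- order(-abs(d1 - d2), ids)
  expect_setequal(s2$inconsistent$patient_id, ids[o[1:15]])
  expect_setequal(s2$consistent$patient_id, ids[rev(o)[1:15]])
  expect_error(select_inconsistency_sets(d1[1:10], d2[1:10], ids[1:10], k = 15),
               "2k")
})
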
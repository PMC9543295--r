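test_that("sextant partition covers the prostate exactly with balanced slice thirds", {
  set.seed(11)
  for (i in 1:10) {
    m <- random_prostate_mask(c(24, 24, 8), min_slices = 4)
    pt <- partition_sextants(m)
    expect_equal(sum(pt$sextant > 0L), sum(m))          # exhaustive on mask
    expect_true(all(pt$sextant[!m] == 0L))              # nothing outside
    ztab <- lengths(pt$z_groups)
    expect_lte(max(ztab) - min(ztab), 1L)               # thirds differ <= 1
  }
})

test_that("slice thirds follow the remainder-to-base rule", {
  mk <- function(nz_total, nz_prostate) {
    m <- array(FALSE, c(10, 10, nz_total))
    m[3:8, 3:8, seq_len(nz_prostate)] <- TRUE
    m
  }
  pt12 <- partition_sextants(mk(14, 12))
  expect_equal(unname(lengths(pt12$z_groups)), c(4L, 4L, 4L))
  pt13 <- partition_sextants(mk(15, 13))
  expect_equal(unname(lengths(pt13$z_groups)), c(5L, 4L, 4L))
  pt14 <- partition_sextants(mk(16, 14))
  expect_equal(unname(lengths(pt14$z_groups)), c(5L, 5L, 4L))
  expect_error(partition_sextants(mk(4, 2)), "fewer than 3")
})

test_that("left and right halves of a symmetric prostate are balanced", {
  m <- array(FALSE, c(30, 20, 6))
  for (z in 1:6) m[6:25, 5:16, z] <- TRUE               # symmetric in x
  pt <- partition_sextants(m)
  left <- sum(pt$sextant %in% 1:3)
  right <- sum(pt$sextant %in% 4:6)
  expect_lt(abs(left - right) / sum(m), 0.02)
})

test_that("task masks partition cancer into aggressive and indolent", {
  f <- grade_fixture()
  gm <- f$gm
  gm[6:15, 6:15, 2:4] <- 2L
  gm[6:15, 6:9, 2:4] <- 3L
  lv <- derive_label(gm, "LPixelDPath", prostate_mask = f$pm, spacing = f$spacing)
  ca <- task_positive_mask(lv, "cancer")
  ag <- task_positive_mask(lv, "aggressive")
  ind <- task_positive_mask(lv, "indolent")
  expect_identical(ca, ag | ind)
  expect_false(any(ag & ind))
  expect_true(sum(ag) < sum(ca))
  # all-normal label: empty masks for every task
  lv0 <- derive_label(f$gm, "LLesionDPath", prostate_mask = f$pm,
                      spacing = f$spacing)
  for (tk in c("cancer", "aggressive", "indolent"))
    expect_false(any(task_positive_mask(lv0, tk)))
})

test_that("unit scoring yields positives per lesion and negatives per clean sextant", {
  f <- grade_fixture()
  gm <- f$gm
  gm[6:15, 6:15, 2:4] <- 3L
  lv <- derive_label(gm, "LLesionDPath", prostate_mask = f$pm, spacing = f$spacing)
  pt <- partition_sextants(f$pm)
  # perfect predictor
  rec <- score_units(prob_from_labels(lv), lv, pt, "cancer")
  expect_true(all(rec$score[rec$truth == "positive"] == 1))
  expect_true(all(rec$score[rec$truth == "negative"] == 0))
  # sextants overlapping the lesion yield no negative record
  overlapped <- unique(pt$sextant[task_positive_mask(lv, "cancer")])
  expect_equal(sum(rec$truth == "negative"), 6L - length(overlapped))

  # patient with no lesions: 0 positives, 6 negatives
  lv0 <- derive_label(f$gm, "LLesionDPath", prostate_mask = f$pm,
                      spacing = f$spacing)
  rec0 <- score_units(prob_from_labels(lv0), lv0, pt, "cancer")
  expect_equal(sum(rec0$truth == "positive"), 0L)
  expect_equal(sum(rec0$truth == "negative"), 6L)

  # constant predictor 1/3: every unit scores identically
  pconst <- array(1 / 3, c(dim(f$pm), 3L))
  recc <- score_units(pconst, lv, pt, "cancer")
  expect_equal(length(unique(round(recc$score, 12))), 1L)

  # unnormalized probability volume is rejected
  pbad <- pconst; pbad[, , , 1] <- 0.5
  expect_error(score_units(pbad, lv, pt, "cancer"), "sum to 1")
})

test_that("rank AUC matches canonical cases, tie convention, and invariances", {
  rec <- function(pos, neg)
    data.frame(unit_kind = "x",
               truth = rep(c("positive", "negative"), c(length(pos), length(neg))),
               score = c(pos, neg))
  expect_equal(lesion_roc_auc(rec(c(0.9, 0.8), c(0.1, 0.2))), 1.0)
  expect_equal(lesion_roc_auc(rec(c(0.1, 0.2), c(0.9, 0.8))), 0.0)
  expect_equal(lesion_roc_auc(rec(c(0.5, 0.5), c(0.5, 0.5))), 0.5)
  expect_true(is.na(lesion_roc_auc(rec(numeric(0), c(0.1)))))
  set.seed(3)
  for (i in 1:20) {
    pos <- stats::runif(5); neg <- stats::runif(4)
    a <- lesion_roc_auc(rec(pos, neg))
    expect_equal(a, auc_bruteforce(pos, neg))
    # strictly monotone transform leaves AUC unchanged
    expect_equal(lesion_roc_auc(rec(plogis(3 * pos - 1), plogis(3 * neg - 1))), a)
    # negating scores and swapping classes reflects AUC
    expect_equal(lesion_roc_auc(rec(-neg, -pos)), a)
  }
})

test_that("sensitivity and specificity follow the operating threshold", {
  rec <- data.frame(unit_kind = "x",
                    truth = c(rep("positive", 3), rep("negative", 4)),
                    score = c(0.9, 0.6, 0.2, 0.1, 0.1, 0.3, 0.7))
  ss <- sens_spec(rec, 0.5)
  expect_equal(unname(ss["sensitivity"]), 2 / 3)
  expect_equal(unname(ss["specificity"]), 3 / 4)
  expect_equal(unname(sens_spec(rec, 0)["sensitivity"]), 1)
  ss1 <- sens_spec(rec, 1)
  expect_equal(unname(ss1["sensitivity"]), 0)
  expect_equal(unname(ss1["specificity"]), 1)
  # sensitivity is non-increasing in the threshold
  s <- sapply(seq(0, 1, 0.05), function(t) sens_spec(rec, t)["sensitivity"])
  expect_true(all(diff(s) <= 1e-12))
})

test_that("Dice matches hand counts, is symmetric, and is undefined for two empty masks", {
  a <- array(FALSE, c(6, 6, 3)); a[2:3, 2:3, 1:2] <- TRUE   # 8-voxel cube
  b <- array(FALSE, c(6, 6, 3)); b[3:4, 2:3, 1:2] <- TRUE   # shifted, 4 overlap
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1.0)
  expect_equal(dice(a, !a & FALSE), 0.0)
  expect_equal(dice(a, b), dice(b, a))
  expect_true(is.na(dice(a & FALSE, b & FALSE)))
  set.seed(5)
  for (i in 1:10) {
    x <- array(stats::runif(60) > 0.5, c(5, 4, 3))
    y <- array(stats::runif(60) > 0.5, c(5, 4, 3))
    expect_equal(dice(x, y), dice_bruteforce(as.vector(x), as.vector(y)))
  }
})

test_that("per-patient evaluation is perfect when prediction equals the label", {
  f <- grade_fixture()
  gm <- f$gm
  gm[6:15, 6:15, 2:4] <- 3L
  lv <- derive_label(gm, "LLesionDPath", prostate_mask = f$pm, spacing = f$spacing)
  ev <- evaluate_patient(prob_from_labels(lv), lv, f$pm, "cancer")
  expect_equal(ev$roc_auc, 1)
  expect_equal(ev$dice, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  # all-normal prediction on a patient with lesions
  lv0 <- derive_label(f$gm, "LLesionDPath", prostate_mask = f$pm,
                      spacing = f$spacing)
  ev0 <- evaluate_patient(prob_from_labels(lv0), lv, f$pm, "cancer")
  expect_equal(ev0$sensitivity, 0)
  expect_equal(ev0$dice, 0)
})

test_that("cohort aggregation uses population SD and excludes undefined values", {
  pe <- data.frame(task = "cancer",
                   roc_auc = c(1, 0), dice = c(1, NA),
                   sensitivity = c(0.5, 0.5), specificity = c(NA, NA),
                   n_pos_units = 1, n_neg_units = 1)
  ag <- aggregate_cohort(pe)
  a <- function(m) ag[ag$metric == m, ]
  expect_equal(a("roc_auc")$mean, 0.5)
  expect_equal(a("roc_auc")$sd, 0.5)          # population convention
  expect_equal(a("dice")$mean, 1)
  expect_equal(a("dice")$n, 1L)
  expect_true(is.na(a("specificity")$mean))
  expect_equal(a("specificity")$n, 0L)
})

test_that("argmax hard labels agree with the maximal class probability inside the prostate", {
  set.seed(8)
  d <- c(6, 6, 4)
  pm <- array(stats::runif(prod(d)) > 0.3, d)
  raw <- array(stats::runif(prod(d) * 3), c(d, 3))
  s <- raw[, , , 1] + raw[, , , 2] + raw[, , , 3]
  for (k in 1:3) raw[, , , k] <- raw[, , , k] / s
  hard <- hard_labels_from_prob(raw, pm)
  expect_true(all(hard[!pm] == 0L))
  idx <- which(pm)
  pmat <- matrix(raw, prod(d), 3)
  expect_equal(hard[idx], max.col(pmat, ties.method = "first")[idx])
})
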
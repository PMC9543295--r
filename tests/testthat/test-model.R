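# Shared tiny cohort for model tests (built once per test run).
tiny_cohort <- local({
  sp <- small_spec(seed = 5)
  coh <- generate_cohort(sp, 5, seed = 5)
  labs <- derive_cohort_labels(coh, "LLesionDPath")
  list(coh = coh, labs = labs$LLesionDPath)
})

test_that("class weights are inverse-frequency, normalized, and capped for absent classes", {
  mk <- function(counts) {
    # build a label volume with the requested per-class voxel counts
    codes <- rep(1:3, counts)
    arr <- array(0L, c(8, 8, max(1, ceiling(length(codes) / 64))))
    arr[seq_along(codes)] <- codes
    arr
  }
  w <- class_weights(list(mk(c(800, 100, 100))))
  expect_equal(w / w[1], c(1, 8, 8), tolerance = 1e-12)   # 1.25 : 10 : 10
  expect_equal(mean(w), 1, tolerance = 1e-12)
  wb <- class_weights(list(mk(c(100, 100, 100))))
  expect_equal(unname(wb), c(1, 1, 1))
  expect_warning(wa <- class_weights(list(mk(c(500, 0, 100))), cap = 10),
                 "absent")
  expect_equal(wa[2], 10)
  expect_error(class_weights(list()), "empty")
})

test_that("fold assignment is case-level, balanced, and deterministic", {
  ids <- sprintf("c%02d", 1:75)
  f <- make_folds(ids, 5L, seed = 3)
  expect_equal(as.vector(table(f)), rep(15L, 5))
  expect_identical(f, make_folds(ids, 5L, seed = 3))
  f7 <- make_folds(sprintf("c%d", 1:7), 5L, seed = 1)
  expect_equal(sort(as.vector(table(f7)), decreasing = TRUE), c(2L, 2L, 1L, 1L, 1L))
  expect_equal(length(f7), 7L)                 # every case in exactly one fold
  expect_error(make_folds(sprintf("c%d", 1:3), 5L), "exceeds")
})

test_that("training configs encode per-architecture conventions", {
  cfg <- train_config("unet_like", preset = "full")
  expect_equal(cfg$lr, 1e-5)
  expect_equal(cfg$batch_size, 22L)
  expect_equal(cfg$epochs, 30L)
  expect_equal(train_config("spcnet_like", preset = "full")$lr, 1e-4)
  expect_equal(train_config("branched_unet_like", preset = "full")$lr, 1e-4)
  expect_equal(train_config("deeplab_like_2d", preset = "full")$lr, 1e-3)
  expect_equal(train_config("deeplab_like_2d")$input_mode, "single_slice")
  expect_equal(train_config("spcnet_like")$input_mode, "stack3")
  expect_error(train_config("resnet"))
})

test_that("per-slice predictions are softmax-normalized and argmax-consistent", {
  m <- fit_digital_radiologist(tiny_cohort$coh[1:3], tiny_cohort$labs,
                               train_config("spcnet_like", epochs = 1, seed = 2))
  expect_lte(m$n_params, 2e6)
  pr <- predict(m, tiny_cohort$coh[[4]])
  sums <- pr$prob[, , , 1] + pr$prob[, , , 2] + pr$prob[, , , 3]
  expect_lt(max(abs(sums - 1)), 1e-6)
  pm <- tiny_cohort$coh[[4]]$prostate_mask
  expect_true(all(pr$labels[!pm] == 0L))
  expect_true(all(pr$labels[pm] %in% 1:3))
  idx <- which(pm)
  pmat <- matrix(pr$prob, length(pm), 3)
  expect_equal(pr$labels[idx], max.col(pmat, ties.method = "first")[idx])
})

test_that("training is deterministic under a fixed seed and loss descends on a learnable toy", {
  cfg <- train_config("spcnet_like", epochs = 2, seed = 9)
  m1 <- fit_digital_radiologist(tiny_cohort$coh[1:3], tiny_cohort$labs, cfg)
  m2 <- fit_digital_radiologist(tiny_cohort$coh[1:3], tiny_cohort$labs, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$c1$W, m2$params$c1$W)
  expect_lt(utils::tail(m1$history, 1), m1$history[1])
})

test_that("all-normal supervision collapses predictions to normal tissue", {
  all_normal <- lapply(tiny_cohort$coh[1:3], function(case) {
    codes <- array(0L, dim(case$prostate_mask))
    codes[case$prostate_mask] <- 1L
    codes
  })
  m <- suppressWarnings(          # cancer classes absent by construction
    fit_digital_radiologist(tiny_cohort$coh[1:3], all_normal,
                            train_config("spcnet_like", epochs = 2, seed = 4)))
  pr <- predict(m, tiny_cohort$coh[[5]])
  pm <- tiny_cohort$coh[[5]]$prostate_mask
  expect_true(mean(pr$labels[pm] == 1L) > 0.99)
})

test_that("voxels outside the prostate contribute no loss and no gradient", {
  ai <- prostlab:::arch_info("spcnet_like")
  set.seed(10)
  params <- prostlab:::net_init("spcnet_like", 6, 4)
  cps <- prostlab:::make_cps(8, 8, 1L)
  x <- array(stats::rnorm(8 * 8 * 6), c(8, 8, 6))
  y <- sample(0:3, 64, replace = TRUE)
  keep <- y > 0L
  wc <- c(1, 1.5, 2)
  fw <- prostlab:::net_forward(params, x, ai, cps)
  # perturbing predicted probabilities at ignored pixels leaves the loss
  # unchanged (no loss contribution from outside the prostate)
  loss1 <- prostlab:::ce_loss(fw$probs, y, wc)$loss
  probs2 <- fw$probs
  probs2[!keep, ] <- matrix(stats::runif(sum(!keep) * 3), ncol = 3)
  loss2 <- prostlab:::ce_loss(probs2, y, wc)$loss
  expect_equal(loss1, loss2)
  # gradients are identical whether outside pixels carry code 0 or any code
  # at weight 0: compare against a run where only masked-in pixels exist
  bw <- prostlab:::net_backward(params, fw$cache, fw$probs, y, wc, ai, cps)
  # head bias gradient equals the sum over masked-in pixels of (p - y) scaled
  Y <- matrix(0, 64, 3)
  Y[cbind(which(keep), y[keep])] <- 1
  g <- numeric(64); g[keep] <- wc[y[keep]]
  expected_db <- colSums((g / sum(g)) * (fw$probs - Y))
  expect_equal(unname(bw$grads$head$b), unname(expected_db), tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation for plain and branched heads", {
  for (arch in c("spcnet_like", "branched_unet_like")) {
    ai <- prostlab:::arch_info(arch)
    set.seed(42)
    params <- prostlab:::net_init(arch, 6, 4)
    cps <- prostlab:::make_cps(8, 8, ai$dil)
    x <- array(stats::rnorm(8 * 8 * 6), c(8, 8, 6))
    y <- sample(0:3, 64, replace = TRUE)
    wc <- c(0.5, 2, 1.5)
    fw <- prostlab:::net_forward(params, x, ai, cps)
    bw <- prostlab:::net_backward(params, fw$cache, fw$probs, y, wc, ai, cps)
    loss_fn <- function(p)
      prostlab:::ce_loss(prostlab:::net_forward(p, x, ai, cps)$probs, y, wc)$loss
    for (nm in names(params)) {
      v <- params[[nm]]$W
      for (i in sample(length(v), 3)) {
        eps <- 1e-5
        p1 <- params; p1[[nm]]$W[i] <- v[i] + eps
        p2 <- params; p2[[nm]]$W[i] <- v[i] - eps
        ng <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
        expect_equal(bw$grads[[nm]]$W[i], ng, tolerance = 1e-4)
      }
    }
  }
})

test_that("network initialization is deterministic and sized for the input mode", {
  p1 <- prostlab:::net_init("unet_like", 6, 8)
  set.seed(1); a <- prostlab:::net_init("unet_like", 6, 8)
  set.seed(1); b <- prostlab:::net_init("unet_like", 6, 8)
  expect_identical(a, b)
  # stack3 -> 6 input channels feed the first convolution
  expect_equal(nrow(a$c1$W), 9 * 6)
  p2 <- prostlab:::net_init("deeplab_like_2d", 2, 8)
  expect_equal(nrow(p2$c1$W), 9 * 2)
})
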
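#' Training configuration for a digital radiologist
#'
#' Bundles architecture and optimisation settings. The `"full"` preset uses
#' the full-scale conventions (batch size 22, 30 epochs, five folds, and the
#' per-architecture learning rates 1e-4 for `spcnet_like` and
#' `branched_unet_like`, 1e-5 for `unet_like`, 1e-3 for `deeplab_like_2d`);
#' the `"desk"` preset scales width, epochs and batch size down for CPU
#' training on synthetic cohorts and uses a single learning rate of 1e-3
#' suited to the smaller networks. `deeplab_like_2d` always takes
#' single-slice input; the other architectures take 2.5D three-slice stacks.
#'
#' @param arch one of `"spcnet_like"`, `"unet_like"`, `"branched_unet_like"`,
#'   `"deeplab_like_2d"`.
#' @param preset `"desk"` (default) or `"full"`.
#' @param lr,batch_size,epochs,width,n_folds optional overrides.
#' @param class_weight_cap maximum class weight after normalization.
#' @param seed RNG seed for initialization and batch shuffling.
#' @return List of class `train_config`.
#' @export
train_config <- function(arch = c("spcnet_like", "unet_like",
                                  "branched_unet_like", "deeplab_like_2d"),
                         preset = c("desk", "full"),
                         lr = NULL, batch_size = NULL, epochs = NULL,
                         width = NULL, n_folds = NULL,
                         class_weight_cap = 10, seed = 1L) {
  arch <- match.arg(arch)
  preset <- match.arg(preset)
  full_lr <- c(spcnet_like = 1e-4, unet_like = 1e-5,
                branched_unet_like = 1e-4, deeplab_like_2d = 1e-3)
  cfg <- list(arch = arch, preset = preset,
              input_mode = arch_info(arch)$input_mode,
              lr = if (!is.null(lr)) lr else
                   if (preset == "full") unname(full_lr[arch]) else 1e-3,
              batch_size = if (!is.null(batch_size)) batch_size else
                           if (preset == "full") 22L else 8L,
              epochs = if (!is.null(epochs)) epochs else
                       if (preset == "full") 30L else 3L,
              width = if (!is.null(width)) width else
                      if (preset == "full") 16L else 8L,
              n_folds = if (!is.null(n_folds)) n_folds else 5L,
              class_weight_cap = class_weight_cap,
              seed = as.integer(seed))
  structure(cfg, class = "train_config")
}

#' Class-balancing weights from training labels
#'
#' Weights proportional to inverse class frequency over prostate voxels of
#' the training set (codes 1 normal, 2 indolent, 3 aggressive), normalized
#' to mean 1 over the classes present and capped at `cap`. A class absent
#' from the training set receives the cap, with a warning.
#'
#' @param label_volumes list of `label_volume`s (or integer code arrays).
#' @param cap maximum weight.
#' @return Numeric length-3 weight vector (normal, indolent, aggressive).
#' @export
class_weights <- function(label_volumes, cap = 10) {
  if (!length(label_volumes)) stop("empty training set")
  counts <- c(0, 0, 0)
  for (lv in label_volumes) {
    codes <- if (inherits(lv, "label_volume")) lv$codes else as_vol_array(lv)
    counts <- counts + tabulate(codes[codes >= 1L], nbins = 3L)
  }
  if (sum(counts) == 0) stop("empty training set: no prostate voxels labeled")
  freq <- counts / sum(counts)
  w <- 1 / freq
  present <- is.finite(w)
  w[present] <- w[present] / mean(w[present])
  if (any(!present)) {
    warning("class(es) absent from training labels: weight set to cap")
    w[!present] <- cap
  }
  pmin(w, cap)
}

#' Case-level cross-validation folds
#'
#' Assigns whole cases (never individual slices) to folds, so no patient
#' leaks between training and validation; fold sizes differ by at most one.
#'
#' @param case_ids character vector of case identifiers.
#' @param n_folds number of folds (<= number of cases).
#' @param seed RNG seed.
#' @return Named integer vector: case_id -> fold (1..n_folds).
#' @export
make_folds <- function(case_ids, n_folds = 5L, seed = 1L) {
  n <- length(case_ids)
  if (n_folds > n) stop("n_folds exceeds the number of cases")
  with_seed(seed, {
    perm <- sample(case_ids)
    folds <- stats::setNames(rep(seq_len(n_folds), length.out = n), perm)
    folds[case_ids]
  })
}

# Normalized 2.5D (or single-slice 2D) input channels for one case:
# [x, y, channel, slice]; channels are the T2w stack then the ADC stack.
model_inputs <- function(case, input_mode = c("stack3", "single_slice")) {
  input_mode <- match.arg(input_mode)
  k <- if (input_mode == "stack3") 3L else 1L
  t2 <- normalize_intensity(case$t2w, case$prostate_mask)$data
  ad <- normalize_intensity(case$adc, case$prostate_mask)$data
  st2 <- stack_adjacent_slices(t2, k)
  sad <- stack_adjacent_slices(ad, k)
  d <- dim(st2)
  out <- array(0, c(d[1], d[2], 2L * k, d[4]))
  out[, , seq_len(k), ] <- st2
  out[, , k + seq_len(k), ] <- sad
  out
}

# Per-slice training targets: 0 outside prostate (ignored), else class 1..3.
slice_targets <- function(label_volume, prostate_mask) {
  codes <- if (inherits(label_volume, "label_volume")) label_volume$codes
           else as_vol_array(label_volume)
  y <- array(0L, dim(codes))
  pm <- as_vol_array(prostate_mask) > 0.5
  y[pm] <- pmax(codes[pm], 1L)
  y
}

#' Fit a digital radiologist segmentation model
#'
#' Trains a small encoder-decoder convolutional network to predict the class
#' of every prostate voxel (normal / indolent cancer / aggressive cancer)
#' from co-registered T2w and ADC slices, using class-balanced cross-entropy
#' over prostate voxels only (voxels outside the prostate contribute neither
#' loss nor gradient), the Adam optimizer, and per-slice mini-batches drawn
#' across cases. Intensities are z-score normalized within the prostate
#' before stacking. Training is deterministic for a fixed config seed on a
#' single thread.
#'
#' @param cohort a `phantom_cohort` or named list of cases (each with `t2w`,
#'   `adc`, `prostate_mask`).
#' @param labels named list case_id -> `label_volume` (one label strategy);
#'   every training case must be present.
#' @param config a [train_config()].
#' @param case_ids optional subset of cases to train on (e.g. one fold).
#' @param verbose print per-epoch loss.
#' @return Object of class `digital_radiologist` with elements `params`,
#'   `config`, `class_weights`, `history` (per-epoch mean training loss),
#'   `label_type`, `n_params`.
#' @export
fit_digital_radiologist <- function(cohort, labels, config = train_config(),
                                    case_ids = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (is.null(case_ids)) case_ids <- intersect(names(cohort), names(labels))
  if (!length(case_ids)) stop("no training cases")
  missing_lab <- setdiff(case_ids, names(labels))
  if (length(missing_lab))
    stop("labels missing for cases: ", paste(missing_lab, collapse = ", "))
  ai <- arch_info(config$arch)
  xs <- list(); ys <- list()
  for (cid in case_ids) {
    case <- cohort[[cid]]
    xin <- model_inputs(case, config$input_mode)
    yv <- slice_targets(labels[[cid]], case$prostate_mask)
    for (z in seq_len(dim(xin)[4])) {
      if (!any(yv[, , z] > 0L)) next     # no prostate on this slice
      xs[[length(xs) + 1L]] <- xin[, , , z, drop = TRUE]
      if (length(dim(xs[[length(xs)]])) == 2L)   # k = 1 collapses a dim
        dim(xs[[length(xs)]]) <- c(dim(xin)[1], dim(xin)[2], dim(xin)[3])
      ys[[length(ys) + 1L]] <- as.integer(yv[, , z])
    }
  }
  H <- dim(xs[[1]])[1]; W <- dim(xs[[1]])[2]; cin <- dim(xs[[1]])[3]
  cps <- make_cps(H, W, ai$dil)
  wclass <- class_weights(labels[case_ids], cap = config$class_weight_cap)
  history <- numeric(config$epochs)
  with_seed(config$seed, {
    params <- net_init(config$arch, cin, config$width)
    state <- adam_init(params)
    t_step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(xs))
      losses <- numeric(0)
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        bidx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        acc <- NULL
        bl <- numeric(length(bidx))
        for (m in seq_along(bidx)) {
          i <- bidx[m]
          fw <- net_forward(params, xs[[i]], ai, cps)
          bw <- net_backward(params, fw$cache, fw$probs, ys[[i]], wclass, ai, cps)
          bl[m] <- bw$loss
          if (is.null(acc)) acc <- bw$grads
          else for (nm in names(acc)) {
            acc[[nm]]$W <- acc[[nm]]$W + bw$grads[[nm]]$W
            acc[[nm]]$b <- acc[[nm]]$b + bw$grads[[nm]]$b
          }
        }
        if (any(!is.finite(bl)))
          stop(sprintf("NaN/Inf loss in epoch %d (batch starting at %d): aborting; inspect learning rate and inputs",
                       ep, start))
        for (nm in names(acc)) {
          acc[[nm]]$W <- acc[[nm]]$W / length(bidx)
          acc[[nm]]$b <- acc[[nm]]$b / length(bidx)
        }
        t_step <- t_step + 1L
        upd <- adam_step(params, acc, state, config$lr, t_step)
        params <- upd$params; state <- upd$state
        losses <- c(losses, mean(bl))
      }
      history[ep] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %d/%d: loss %.4f", ep, config$epochs, history[ep]))
    }
    structure(list(params = params, config = config, class_weights = wclass,
                   history = history, label_type = {
                     lt <- labels[[case_ids[1]]]
                     if (inherits(lt, "label_volume")) lt$label_type else NA_character_
                   },
                   case_ids = case_ids, n_params = n_params(params),
                   input_dim = c(H, W, cin)),
              class = "digital_radiologist")
  })
}

#' @export
print.digital_radiologist <- function(x, ...) {
  cat(sprintf("<digital_radiologist> %s (%s preset), trained on %s labels\n",
              x$config$arch, x$config$preset,
              if (is.na(x$label_type)) "?" else x$label_type))
  cat(sprintf("  %d parameters, %d epochs, final loss %.4f\n",
              x$n_params, length(x$history), utils::tail(x$history, 1)))
  invisible(x)
}

#' @export
summary.digital_radiologist <- function(object, ...) {
  cat(sprintf("Digital radiologist: %s\n", object$config$arch))
  cat(sprintf("  input mode: %s (%d channels), width %d, %d parameters\n",
              object$config$input_mode, object$input_dim[3],
              object$config$width, object$n_params))
  cat(sprintf("  trained on %d cases with %s labels; lr %g, batch %d\n",
              length(object$case_ids),
              if (is.na(object$label_type)) "?" else object$label_type,
              object$config$lr, object$config$batch_size))
  cat(sprintf("  class weights (normal/indolent/aggressive): %.3g / %.3g / %.3g\n",
              object$class_weights[1], object$class_weights[2],
              object$class_weights[3]))
  cat("  loss history:", paste(sprintf("%.4f", object$history), collapse = " "), "\n")
  invisible(object)
}

#' @export
plot.digital_radiologist <- function(x, ...) {
  plot(seq_along(x$history), x$history, type = "b", xlab = "epoch",
       ylab = "mean training loss",
       main = sprintf("%s / %s", x$config$arch,
                      if (is.na(x$label_type)) "?" else x$label_type), ...)
  invisible(x)
}

#' Predict class probabilities and hard labels for a case
#'
#' Slice-wise inference assembled into a 3D per-class probability volume
#' plus the hard label volume: each prostate voxel gets the class of maximum
#' predicted probability, voxels outside the prostate are coded 0, and no
#' morphological post-processing is applied. Outside the prostate the
#' probability volume is set to (1, 0, 0).
#'
#' @param object a fitted `digital_radiologist`.
#' @param case a `phantom_case` (or any list with `t2w`, `adc`,
#'   `prostate_mask` on a grid whose in-plane dimensions are divisible by 4).
#' @param ... unused.
#' @return List with `prob` (4D array `[x, y, z, 3]`) and `labels` (integer
#'   array, codes 0/1/2/3).
#' @export
predict.digital_radiologist <- function(object, case, ...) {
  ai <- arch_info(object$config$arch)
  xin <- model_inputs(case, object$config$input_mode)
  d <- dim(xin)
  if (d[3] != object$input_dim[3])
    stop("input channel mismatch: case does not match the trained input mode")
  cps <- make_cps(d[1], d[2], ai$dil)
  prob <- array(0, c(d[1], d[2], d[4], 3L))
  for (z in seq_len(d[4])) {
    x <- xin[, , , z, drop = TRUE]
    if (length(dim(x)) == 2L) dim(x) <- c(d[1], d[2], d[3])
    fw <- net_forward(object$params, x, ai, cps)
    prob[, , z, ] <- array(fw$probs, c(d[1], d[2], 3L))
  }
  pm <- as_vol_array(case$prostate_mask) > 0.5
  if (!all(dim(pm) == d[c(1, 2, 4)])) stop("prostate mask grid mismatch")
  out <- array(0L, dim(pm))
  hard <- hard_labels_from_prob(prob, pm)
  # outside the prostate: probability mass on normal, hard code 0
  for (k in 1:3) {
    pk <- prob[, , , k]
    pk[!pm] <- if (k == 1L) 1 else 0
    prob[, , , k] <- pk
  }
  list(prob = prob, labels = hard)
}
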
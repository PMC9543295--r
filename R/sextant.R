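#' Partition the prostate into sextants
#'
#' Splits the prostate into left and right halves at the x-centroid of the
#' mask, then divides each half into three contiguous slice groups (base,
#' mid, apex) along Z as equally as possible, the remainder going base-first.
#' By convention the base is at low slice index and "left" is low image x;
#' set `laterality = "high-x"` if your volumes are stored the other way.
#' Sextant ids are 1..6 = (side - 1) * 3 + third.
#'
#' @param prostate_mask logical 3D array or `image_volume`.
#' @param laterality `"low-x"` (default) or `"high-x"`: which image side is
#'   anatomical left.
#' @return Object of class `sextant_partition`: list with `sextant` (integer
#'   array, 0 outside prostate), `z_groups` (list of slice-index vectors),
#'   `midline_x`.
#' @export
partition_sextants <- function(prostate_mask, laterality = c("low-x", "high-x")) {
  laterality <- match.arg(laterality)
  m <- as_vol_array(prostate_mask) > 0.5
  if (!any(m)) stop("prostate mask is empty")
  d <- dim(m)
  zs <- which(apply(m, 3, any))
  if (length(zs) < 3L) stop("prostate present on fewer than 3 slices; cannot form sextants")
  n <- length(zs)
  sizes <- rep(n %/% 3L, 3L)
  if (n %% 3L >= 1L) sizes[1] <- sizes[1] + 1L
  if (n %% 3L == 2L) sizes[2] <- sizes[2] + 1L
  z_groups <- split(zs, rep(1:3, times = sizes))
  names(z_groups) <- c("base", "mid", "apex")
  idx <- which(m, arr.ind = TRUE)
  cx <- mean(idx[, 1])
  side <- ifelse(idx[, 1] <= cx, 1L, 2L)
  if (laterality == "high-x") side <- 3L - side
  third <- integer(nrow(idx))
  for (k in 1:3) third[idx[, 3] %in% z_groups[[k]]] <- k
  sext <- array(0L, d)
  sext[m] <- 0L  # ensure integer fill
  sext[cbind(idx)] <- (side - 1L) * 3L + third
  structure(list(sextant = sext, z_groups = z_groups, midline_x = cx),
            class = "sextant_partition")
}

#' @export
print.sextant_partition <- function(x, ...) {
  cat(sprintf("<sextant_partition> midline x = %.1f; slices base/mid/apex: %d/%d/%d\n",
              x$midline_x, length(x$z_groups$base), length(x$z_groups$mid),
              length(x$z_groups$apex)))
  invisible(x)
}

#' Task-positive mask of a label volume
#'
#' The three detection tasks select label codes: `cancer` (combined
#' aggressive and indolent) = codes 2 and 3, `aggressive` = code 3,
#' `indolent` = code 2.
#'
#' @param label_volume a `label_volume`, or an integer-coded array.
#' @param task `"cancer"`, `"aggressive"` or `"indolent"`.
#' @return Logical 3D array.
#' @export
task_positive_mask <- function(label_volume, task = c("cancer", "aggressive", "indolent")) {
  task <- match.arg(task)
  codes <- if (inherits(label_volume, "label_volume")) label_volume$codes
           else as_vol_array(label_volume)
  switch(task,
         cancer = codes >= 2L,
         aggressive = codes == 3L,
         indolent = codes == 2L)
}

# Per-voxel task probability from a [x,y,z,3] class-probability array
# (classes: normal, indolent, aggressive).
task_probability <- function(pred_prob, task) {
  switch(task,
         cancer = pred_prob[, , , 2] + pred_prob[, , , 3],
         aggressive = pred_prob[, , , 3],
         indolent = pred_prob[, , , 2])
}

#' One-hot class probabilities from an integer label volume
#'
#' Turns a hard label volume (codes 0/1/2/3) into a `[x, y, z, 3]`
#' probability array (normal, indolent, aggressive) with probability 1 on the
#' coded class; voxels coded 0 (outside prostate) become normal. Used to
#' score one label type against another in concordance analysis.
#'
#' @param label_volume a `label_volume` or integer array.
#' @return 4D numeric array `[x, y, z, 3]`.
#' @export
prob_from_labels <- function(label_volume) {
  codes <- if (inherits(label_volume, "label_volume")) label_volume$codes
           else as_vol_array(label_volume)
  d <- dim(codes)
  p <- array(0, c(d, 3L))
  p[, , , 1][codes <= 1L] <- 1
  p[, , , 2][codes == 2L] <- 1
  p[, , , 3][codes == 3L] <- 1
  p
}

#' Score detection units for lesion-level evaluation
#'
#' Builds the unit records of the sextant-based lesion-level evaluation:
#' one positive unit per ground-truth lesion of the task (score = summary of
#' the task probability over its voxels), and one negative unit per sextant
#' containing no task-positive ground-truth voxel (score = summary over the
#' sextant). Sextants overlapping any task-positive lesion yield no negative
#' record, so the same territory is never counted both ways.
#'
#' @param pred_prob 4D array `[x, y, z, 3]` of class probabilities; must sum
#'   to 1 (tol 1e-4) inside the prostate.
#' @param label_volume the ground-truth `label_volume`.
#' @param partition a `sextant_partition` for the case.
#' @param task `"cancer"`, `"aggressive"` or `"indolent"`.
#' @param score_fun summary of per-voxel task probability within a unit:
#'   `"max"` (default), `"q95"` or `"mean"`.
#' @param connectivity connectivity for splitting the task mask into lesions.
#' @return data.frame with columns `unit_kind` ("lesion"/"sextant"), `truth`
#'   ("positive"/"negative"), `score`.
#' @export
score_units <- function(pred_prob, label_volume, partition,
                        task = c("cancer", "aggressive", "indolent"),
                        score_fun = c("max", "q95", "mean"),
                        connectivity = 26L) {
  task <- match.arg(task)
  score_fun <- match.arg(score_fun)
  sfun <- switch(score_fun,
                 max = max,
                 q95 = function(v) stats::quantile(v, 0.95, names = FALSE),
                 mean = mean)
  sx <- partition$sextant
  if (!all(dim(pred_prob)[1:3] == dim(sx))) stop("prediction grid mismatch")
  inside <- sx > 0L
  psum <- pred_prob[, , , 1] + pred_prob[, , , 2] + pred_prob[, , , 3]
  if (any(abs(psum[inside] - 1) > 1e-4))
    stop("class probabilities do not sum to 1 inside the prostate")
  tp <- task_probability(pred_prob, task)
  tmask <- task_positive_mask(label_volume, task)
  lab <- label_components(tmask, connectivity)
  nles <- max(lab)
  recs <- list()
  for (i in seq_len(nles)) {
    vox <- lab == i
    recs[[length(recs) + 1L]] <- data.frame(unit_kind = "lesion",
                                            truth = "positive",
                                            score = sfun(tp[vox]))
  }
  for (s in 1:6) {
    svox <- sx == s
    if (!any(svox)) next
    if (any(tmask & svox)) next
    recs[[length(recs) + 1L]] <- data.frame(unit_kind = "sextant",
                                            truth = "negative",
                                            score = sfun(tp[svox]))
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(unit_kind = character(), truth = character(),
                      score = numeric())
  out
}

#' Lesion-level ROC-AUC from unit records
#'
#' Rank-based (Mann-Whitney) area under the ROC curve of positive-unit vs
#' negative-unit scores; ties contribute 1/2. Undefined (`NA`) when either
#' class of units is absent.
#'
#' @param records data.frame from [score_units()].
#' @return AUC in `[0, 1]`, or `NA_real_` when undefined.
#' @export
lesion_roc_auc <- function(records) {
  pos <- records$score[records$truth == "positive"]
  neg <- records$score[records$truth == "negative"]
  np <- length(pos); nn <- length(neg)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Sensitivity and specificity at an operating threshold
#'
#' A positive unit is detected when its score >= threshold; a negative unit
#' is clean when its score < threshold. Either value is `NA` when its
#' denominator (number of positive / negative units) is zero.
#'
#' @param records data.frame from [score_units()].
#' @param threshold operating threshold in `[0, 1]`.
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sens_spec <- function(records, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  pos <- records$score[records$truth == "positive"]
  neg <- records$score[records$truth == "negative"]
  sens <- if (length(pos)) mean(pos >= threshold) else NA_real_
  spec <- if (length(neg)) mean(neg < threshold) else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; `NA` when both masks are empty.
#'
#' @param pred_mask,label_mask logical arrays on the same grid.
#' @return Dice coefficient in `[0, 1]` or `NA_real_`.
#' @export
dice <- function(pred_mask, label_mask) {
  a <- as_vol_array(pred_mask) > 0.5
  b <- as_vol_array(label_mask) > 0.5
  if (!all(dim(a) == dim(b))) stop("masks must share a grid")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}

#' Evaluate one patient on one detection task
#'
#' Composes the sextant partition, unit scoring, ROC-AUC, sensitivity /
#' specificity and Dice for a single case. The operating point is the hard
#' argmax segmentation: sensitivity/specificity are computed from the
#' argmax-derived task mask (a positive lesion is detected when the predicted
#' task mask touches it; a sextant is clean when it contains no predicted
#' task voxel), matching a pipeline in which each prostate voxel is assigned
#' the class of maximum predicted probability and no post-processing is done.
#'
#' @param pred_prob 4D array `[x, y, z, 3]` of class probabilities.
#' @param label_volume ground-truth `label_volume`.
#' @param prostate_mask logical array.
#' @param task detection task.
#' @param partition optional precomputed `sextant_partition`.
#' @param score_fun unit score summary, see [score_units()].
#' @param connectivity lesion connectivity.
#' @return One-row data.frame: task, roc_auc, dice, sensitivity, specificity,
#'   n_pos_units, n_neg_units.
#' @export
evaluate_patient <- function(pred_prob, label_volume, prostate_mask,
                             task = c("cancer", "aggressive", "indolent"),
                             partition = NULL, score_fun = "max",
                             connectivity = 26L) {
  task <- match.arg(task)
  pm <- as_vol_array(prostate_mask) > 0.5
  if (is.null(partition)) partition <- partition_sextants(pm)
  soft <- score_units(pred_prob, label_volume, partition, task,
                      score_fun = score_fun, connectivity = connectivity)
  hard_codes <- hard_labels_from_prob(pred_prob, pm)
  hard_prob <- prob_from_labels(hard_codes)
  hard <- score_units(hard_prob, label_volume, partition, task,
                      score_fun = "max", connectivity = connectivity)
  ss <- sens_spec(hard, 0.5)
  pred_mask <- task_positive_mask(hard_codes, task)
  lab_mask <- task_positive_mask(label_volume, task)
  data.frame(task = task,
             roc_auc = lesion_roc_auc(soft),
             dice = dice(pred_mask, lab_mask),
             sensitivity = ss[["sensitivity"]],
             specificity = ss[["specificity"]],
             n_pos_units = sum(soft$truth == "positive"),
             n_neg_units = sum(soft$truth == "negative"))
}

#' Hard label volume by voxelwise argmax
#'
#' Assigns each prostate voxel the class of maximum predicted probability
#' (ties to the earlier class: normal < indolent < aggressive); voxels
#' outside the prostate are coded 0. No morphological post-processing.
#'
#' @param pred_prob 4D array `[x, y, z, 3]`.
#' @param prostate_mask logical array.
#' @return Integer array with codes 0/1/2/3.
#' @export
hard_labels_from_prob <- function(pred_prob, prostate_mask) {
  pm <- as_vol_array(prostate_mask) > 0.5
  d <- dim(pred_prob)[1:3]
  pmat <- matrix(pred_prob, prod(d), 3L)
  cls <- max.col(pmat, ties.method = "first")
  codes <- array(0L, d)
  codes[pm] <- cls[which(pm)]
  codes
}

#' Aggregate per-patient metrics over a cohort
#'
#' Mean and population standard deviation (ddof = 0) per task and metric,
#' excluding undefined (`NA`) patient values; `n` reports how many patients
#' contributed. A metric undefined for every patient is flagged with
#' `n = 0` and `NA` mean, never silently zero.
#'
#' @param patient_evals data.frame of rows from [evaluate_patient()].
#' @param metrics metric columns to aggregate.
#' @return data.frame with columns task, metric, mean, sd, n.
#' @export
aggregate_cohort <- function(patient_evals,
                             metrics = c("roc_auc", "dice", "sensitivity", "specificity")) {
  out <- list()
  for (tk in unique(patient_evals$task)) {
    sub <- patient_evals[patient_evals$task == tk, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        task = tk, metric = m,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v)) sqrt(mean((v - mean(v))^2)) else NA_real_,
        n = length(v))
    }
  }
  do.call(rbind, out)
}

#' Cross-label evaluation matrix
#'
#' Evaluates each set of predictions (one per training-label type) against
#' each evaluation-label type, producing the train-label x eval-label grid of
#' cohort mean and standard deviation per task and metric (a 4 x 4 grid when
#' all four label types are present, 4 x 1 for a cohort with radiologist
#' labels only). Missing train/eval combinations are marked absent
#' (`n = NA`).
#'
#' @param predictions_by_trainlabel named list: train label type -> named
#'   list case_id -> `[x,y,z,3]` probability array.
#' @param labels_by_type named list: eval label type -> named list case_id ->
#'   `label_volume`.
#' @param prostate_masks named list case_id -> logical array.
#' @param tasks detection tasks to evaluate.
#' @param score_fun unit score summary.
#' @return data.frame with columns train_label, eval_label, task, metric,
#'   mean, sd, n.
#' @export
cross_label_matrix <- function(predictions_by_trainlabel, labels_by_type,
                               prostate_masks,
                               tasks = c("cancer", "aggressive"),
                               score_fun = "max") {
  rows <- list()
  for (tr in names(predictions_by_trainlabel)) {
    preds <- predictions_by_trainlabel[[tr]]
    for (ev in names(labels_by_type)) {
      labs <- labels_by_type[[ev]]
      cases <- intersect(names(preds), names(labs))
      for (tk in tasks) {
        if (!length(cases)) {
          rows[[length(rows) + 1L]] <- data.frame(
            train_label = tr, eval_label = ev, task = tk,
            metric = c("roc_auc", "dice", "sensitivity", "specificity"),
            mean = NA_real_, sd = NA_real_, n = NA_integer_)
          next
        }
        pe <- do.call(rbind, lapply(cases, function(cid)
          evaluate_patient(preds[[cid]], labs[[cid]], prostate_masks[[cid]],
                           task = tk, score_fun = score_fun)))
        ag <- aggregate_cohort(pe)
        ag <- cbind(train_label = tr, eval_label = ev, ag[, -1],
                    row.names = NULL)
        names(ag)[names(ag) == "task"] <- "task"
        ag$task <- tk
        rows[[length(rows) + 1L]] <- ag[, c("train_label", "eval_label",
                                            "task", "metric", "mean", "sd", "n")]
      }
    }
  }
  do.call(rbind, rows)
}
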
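#' Derive all requested label types for every case of a cohort
#'
#' Applies [derive_label()] per case: human label types use the simulated
#' radiologist / pathologist outlines, digital-pathologist types use the
#' grade map directly.
#'
#' @param cohort a `phantom_cohort` (or named list of cases).
#' @param types label types to derive.
#' @param connectivity lesion connectivity.
#' @param min_volume lesion volume threshold (mm^3).
#' @return Named list: label type -> named list case_id -> `label_volume`.
#' @export
derive_cohort_labels <- function(cohort,
                                 types = c("LRad", "LPath", "LLesionDPath", "LPixelDPath"),
                                 connectivity = 26L, min_volume = 250) {
  types <- match.arg(types, several.ok = TRUE)
  out <- list()
  for (tp in types) {
    out[[tp]] <- lapply(cohort, function(case) {
      outline <- switch(tp, LRad = case$rad_outline, LPath = case$path_outline,
                        NULL)
      derive_label(case$truth_grade_map, tp, outline = outline,
                   prostate_mask = case$prostate_mask, spacing = case$spacing,
                   connectivity = connectivity, min_volume = min_volume)
    })
    names(out[[tp]]) <- names(cohort)
  }
  out
}

#' Pairwise concordance analysis between label types
#'
#' Compares label strategies against each other without any model training:
#' for each ordered pair, one label type's hard masks act as the prediction
#' (scores 1/0) and the other as ground truth, yielding per-patient Dice and
#' lesion-level ROC-AUC for the requested tasks, aggregated over the cohort.
#' Also returns the descriptive lesion table (kept and discarded) per label
#' type.
#'
#' @param cohort a `phantom_cohort`.
#' @param labels_by_type output of [derive_cohort_labels()]; derived from
#'   `cohort` if missing.
#' @param tasks detection tasks.
#' @return List of class `concordance_report`: `pairwise` (data.frame:
#'   pred_label, truth_label, task, metric, mean, sd, n) and `lesions`
#'   (data.frame from [lesion_table()]).
#' @export
run_label_concordance <- function(cohort, labels_by_type = NULL,
                                  tasks = c("cancer", "aggressive")) {
  if (is.null(labels_by_type)) labels_by_type <- derive_cohort_labels(cohort)
  types <- names(labels_by_type)
  cases <- names(cohort)
  rows <- list()
  parts <- lapply(cases, function(cid)
    partition_sextants(cohort[[cid]]$prostate_mask))
  names(parts) <- cases
  for (pt in types) {
    for (tt in types) {
      for (tk in tasks) {
        pe <- do.call(rbind, lapply(cases, function(cid) {
          evaluate_patient(prob_from_labels(labels_by_type[[pt]][[cid]]),
                           labels_by_type[[tt]][[cid]],
                           cohort[[cid]]$prostate_mask,
                           task = tk, partition = parts[[cid]])
        }))
        ag <- aggregate_cohort(pe, metrics = c("roc_auc", "dice"))
        ag$task <- tk
        rows[[length(rows) + 1L]] <- cbind(pred_label = pt, truth_label = tt,
                                           ag, row.names = NULL)
      }
    }
  }
  lesions <- do.call(rbind, lapply(types, function(tp)
    lesion_table(labels_by_type[[tp]])))
  structure(list(pairwise = do.call(rbind, rows), lesions = lesions),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  d <- x$pairwise
  for (tk in unique(d$task)) {
    cat(sprintf("  task %s, mean Dice (pred x truth):\n", tk))
    sub <- d[d$task == tk & d$metric == "dice", ]
    m <- stats::xtabs(mean ~ pred_label + truth_label, data = sub)
    print(round(m, 3))
  }
  invisible(x)
}

#' Simulate targeted-biopsy confirmation of radiologist lesions
#'
#' For a cohort whose only human annotation is the radiologist outline,
#' grade assignment comes from targeted biopsy instead of a registered grade
#' map: each outlined lesion's true grade composition determines its true
#' grade group (aggressive -> >= 2, indolent -> 1, benign -> benign), which
#' the simulated biopsy reports correctly with probability
#' `1 - error_rate` (otherwise an adjacent category), and the lesion class
#' follows [classify_from_grade_group()].
#'
#' @param cohort a `phantom_cohort`.
#' @param error_rate probability a lesion's biopsy grade group is
#'   mis-assigned to an adjacent category.
#' @param seed RNG seed.
#' @param connectivity,min_volume lesion formation settings.
#' @return Named list case_id -> `label_volume` (LRad with biopsy-style
#'   confirmation).
#' @export
simulate_biopsy_confirmed_lrad <- function(cohort, error_rate = 0.1, seed = 1L,
                                           connectivity = 26L, min_volume = 250) {
  with_seed(seed, {
    out <- lapply(names(cohort), function(cid) {
      case <- cohort[[cid]]
      lv <- derive_label(case$truth_grade_map, "LRad",
                         outline = case$rad_outline,
                         prostate_mask = case$prostate_mask,
                         spacing = case$spacing, connectivity = connectivity,
                         min_volume = min_volume)
      tab <- lv$lesion_set$table
      codes <- array(0L, dim(case$prostate_mask))
      codes[case$prostate_mask] <- 1L
      for (i in seq_len(nrow(tab))) {
        if (!isTRUE(tab$kept[i])) next
        true_gg <- switch(tab$class[i], aggressive = 2L, indolent = 1L,
                          benign = "benign")
        gg <- true_gg
        if (stats::runif(1) < error_rate) {
          gg <- switch(tab$class[i],
                       aggressive = 1L,               # undergraded
                       indolent = sample(list(2L, "benign"), 1L)[[1]],
                       benign = 1L)                   # overgraded
        }
        cl <- classify_from_grade_group(gg)
        code <- switch(cl, aggressive = 3L, indolent = 2L, normal = 1L)
        if (code >= 2L) codes[lv$lesion_set$voxels[[i]]] <- code
        tab$class[i] <- if (cl == "normal") "benign" else cl
      }
      lv$codes <- codes
      lv$lesion_set$table <- tab
      lv
    })
    names(out) <- names(cohort)
    out
  })
}

#' Study configuration
#'
#' Settings for the full label-comparison study analog: phantom spec, cohort
#' sizes, label types, architectures, tasks and operating conventions.
#'
#' @param spec a [phantom_spec()].
#' @param n_train,n_test_c1,n_test_c2 cohort sizes: training cohort, the
#'   radical-prostatectomy-style test cohort (all four label types
#'   available), and the biopsy-style test cohort (radiologist labels only).
#' @param label_types label strategies to derive and train with.
#' @param archs architectures to train.
#' @param tasks detection tasks to evaluate.
#' @param config a [train_config()] template (its `arch` is overridden per
#'   trained model).
#' @param biopsy_error_rate confirmation error of the biopsy-style cohort.
#' @param connectivity,min_volume lesion formation settings.
#' @param seed master seed.
#' @return List of class `study_config`.
#' @export
study_config <- function(spec = phantom_spec(),
                         n_train = 12L, n_test_c1 = 6L, n_test_c2 = 6L,
                         label_types = c("LRad", "LPath", "LLesionDPath", "LPixelDPath"),
                         archs = "spcnet_like",
                         tasks = c("cancer", "aggressive"),
                         config = train_config(),
                         biopsy_error_rate = 0.1,
                         connectivity = 26L, min_volume = 250,
                         seed = 1L) {
  label_types <- match.arg(label_types, several.ok = TRUE)
  structure(list(spec = spec, n_train = as.integer(n_train),
                 n_test_c1 = as.integer(n_test_c1),
                 n_test_c2 = as.integer(n_test_c2),
                 label_types = label_types, archs = archs, tasks = tasks,
                 config = config, biopsy_error_rate = biopsy_error_rate,
                 connectivity = as.integer(connectivity),
                 min_volume = min_volume, seed = as.integer(seed)),
            class = "study_config")
}

#' Run the full label-comparison study analog
#'
#' Orchestrates the whole pipeline on synthetic cohorts: simulate training
#' and test cohorts, derive every label type, run the label concordance
#' analysis on the first test cohort, train one model per (architecture x
#' training-label type), and evaluate every model against every label type
#' (the cross-label matrix) on the first test cohort and against
#' biopsy-confirmed radiologist labels only on the second. Fully
#' deterministic under the master seed (single-threaded).
#'
#' @param sc a [study_config()].
#' @param out_dir optional directory; if given, reports are written as CSV
#'   and a run manifest as JSON.
#' @param verbose print stage progress.
#' @return List of class `study_report`: `concordance`, `matrix_c1`
#'   (cross-label evaluation), `matrix_c2` (radiologist-label-only
#'   evaluation), `models` (named list of fitted models), `seeds`.
#' @export
run_study <- function(sc = study_config(), out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(sc, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating cohorts (train %d, test-C1 %d, test-C2 %d)",
      sc$n_train, sc$n_test_c1, sc$n_test_c2)
  train_cohort <- generate_cohort(sc$spec, sc$n_train, derive_seed(sc$seed, 1L))
  test_c1 <- generate_cohort(sc$spec, sc$n_test_c1, derive_seed(sc$seed, 2L))
  test_c2 <- generate_cohort(sc$spec, sc$n_test_c2, derive_seed(sc$seed, 3L))

  say("deriving labels")
  train_labels <- derive_cohort_labels(train_cohort, sc$label_types,
                                       sc$connectivity, sc$min_volume)
  c1_labels <- derive_cohort_labels(test_c1, sc$label_types,
                                    sc$connectivity, sc$min_volume)
  c2_lrad <- simulate_biopsy_confirmed_lrad(test_c2, sc$biopsy_error_rate,
                                            derive_seed(sc$seed, 4L),
                                            sc$connectivity, sc$min_volume)

  say("concordance analysis")
  concordance <- run_label_concordance(test_c1, c1_labels, sc$tasks)

  models <- list()
  preds_c1 <- list()
  preds_c2 <- list()
  for (arch in sc$archs) {
    for (lt in sc$label_types) {
      key <- paste(arch, lt, sep = "/")
      say("training %s", key)
      cfg <- sc$config
      cfg$arch <- arch
      cfg$input_mode <- arch_info(arch)$input_mode
      cfg$seed <- derive_seed(sc$seed, 100L + length(models))
      models[[key]] <- fit_digital_radiologist(train_cohort, train_labels[[lt]],
                                               config = cfg)
      preds_c1[[key]] <- lapply(test_c1, function(case)
        predict(models[[key]], case)$prob)
      names(preds_c1[[key]]) <- names(test_c1)
      preds_c2[[key]] <- lapply(test_c2, function(case)
        predict(models[[key]], case)$prob)
      names(preds_c2[[key]]) <- names(test_c2)
    }
  }

  say("cross-label evaluation")
  pm_c1 <- lapply(test_c1, `[[`, "prostate_mask")
  pm_c2 <- lapply(test_c2, `[[`, "prostate_mask")
  matrix_c1 <- cross_label_matrix(preds_c1, c1_labels, pm_c1, sc$tasks)
  matrix_c2 <- cross_label_matrix(preds_c2, list(LRad = c2_lrad), pm_c2,
                                  sc$tasks)

  report <- structure(list(concordance = concordance, matrix_c1 = matrix_c1,
                           matrix_c2 = matrix_c2, models = models,
                           config = sc,
                           seeds = list(master = sc$seed,
                                        train = derive_seed(sc$seed, 1L),
                                        test_c1 = derive_seed(sc$seed, 2L),
                                        test_c2 = derive_seed(sc$seed, 3L))),
                      class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d model(s); cohorts train/C1/C2 = %d/%d/%d\n",
              length(x$models), x$config$n_train, x$config$n_test_c1,
              x$config$n_test_c2))
  cat("cross-label ROC-AUC (cancer task):\n")
  sub <- x$matrix_c1[x$matrix_c1$task == "cancer" &
                     x$matrix_c1$metric == "roc_auc", ]
  print(sub[, c("train_label", "eval_label", "mean", "sd", "n")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a study report to CSV/JSON files
#'
#' Emits `concordance_pairwise.csv`, `lesion_table.csv`,
#' `matrix_c1.csv`, `matrix_c2.csv` and a `run_manifest.json` recording
#' seeds, cohort sizes and training settings, so every table can be
#' regenerated purely from serialized intermediates.
#'
#' @param report a `study_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$concordance$pairwise,
                   file.path(out_dir, "concordance_pairwise.csv"),
                   row.names = FALSE)
  utils::write.csv(report$concordance$lesions,
                   file.path(out_dir, "lesion_table.csv"), row.names = FALSE)
  utils::write.csv(report$matrix_c1, file.path(out_dir, "matrix_c1.csv"),
                   row.names = FALSE)
  utils::write.csv(report$matrix_c2, file.path(out_dir, "matrix_c2.csv"),
                   row.names = FALSE)
  sc <- report$config
  manifest <- list(seed = sc$seed, seeds = report$seeds,
                   n_train = sc$n_train, n_test_c1 = sc$n_test_c1,
                   n_test_c2 = sc$n_test_c2, label_types = sc$label_types,
                   archs = sc$archs, tasks = sc$tasks,
                   std_convention = "population (ddof = 0)",
                   spec = unclass(sc$spec),
                   train = unclass(sc$config))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
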
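#' End-to-end pipeline configuration
#'
#' Bundles every stage configuration: phantom generation, preprocessing,
#' training, segmentation, quantification and evaluation. Every embedded
#' configuration obeys its own invariants; thresholds default to the
#' refined 5/49/95 cutoffs. One global seed drives all stages.
#'
#' @param out_dir output directory for artifacts and results.
#' @param n_cases total phantom cohort size.
#' @param n_test held-out cases segmented and evaluated (the rest train).
#' @param n_val training cases reserved for early-stopping validation.
#' @param phantom a [phantom_spec()] with the per-case defaults.
#' @param model a [model_config()].
#' @param train a [train_config()].
#' @param thresholds a [grade_thresholds()].
#' @param ratio_sampler passed to [generate_cohort()].
#' @param slice_stride train on every `slice_stride`-th axial slice of each
#'   training case (validation and inference always use full volumes).
#' @param align run midline self-alignment during preprocessing.
#' @param prob_threshold operating point for [predict_mask()].
#' @param write_nifti write volumes/masks under `out_dir` as NIfTI.
#' @param seed global pipeline seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("collateralq_run_"),
                            n_cases = 12L, n_test = 4L, n_val = 2L,
                            phantom = phantom_spec(),
                            model = model_config("scaled"),
                            train = train_config(learning_rate = 1e-3,
                                                 max_epochs = 20L,
                                                 patience_epochs = 8L,
                                                 batch_size = 8L,
                                                 augmentation = NULL),
                            thresholds = grade_thresholds(),
                            ratio_sampler = "stratified",
                            slice_stride = 2L,
                            align = FALSE, prob_threshold = 0.5,
                            write_nifti = FALSE, seed = 1L) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(model, "u2net_config"),
            inherits(train, "train_config"),
            inherits(thresholds, "grade_thresholds"),
            n_cases >= 2L, n_test >= 1L, n_val >= 1L,
            n_test + n_val < n_cases)
  structure(list(out_dir = out_dir, n_cases = as.integer(n_cases),
                 n_test = as.integer(n_test), n_val = as.integer(n_val),
                 phantom = phantom, model = model, train = train,
                 thresholds = thresholds, ratio_sampler = ratio_sampler,
                 slice_stride = as.integer(slice_stride),
                 align = align, prob_threshold = prob_threshold,
                 write_nifti = write_nifti, seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_stages <- c("generate", "preprocess", "train", "segment",
                     "quantify", "evaluate")

require_state <- function(state, what, needed_stage) {
  if (is.null(state[[what]]))
    stop(sprintf(
      "stage needs '%s' from the '%s' stage; run it first or provide state",
      what, needed_stage), call. = FALSE)
  state[[what]]
}

#' Run the collateral quantification workflow
#'
#' Generate a phantom cohort, preprocess, train the segmentation network on
#' the training split, segment the held-out cases, quantify the collateral
#' score from both the predicted and the ground-truth masks, and evaluate
#' agreement. Writes `results.csv` (one row per held-out case) and
#' `report.json` under `config$out_dir`. Re-running with the same
#' configuration reproduces identical outputs: every stage is a pure
#' function of (inputs, config, seed).
#'
#' @param config a [pipeline_config()].
#' @param stages subset of `generate, preprocess, train, segment, quantify,
#'   evaluate` to run (in pipeline order). Later stages require state from
#'   earlier ones: pass the returned object as `state` to resume.
#' @param state a previous `run_pipeline()` result to resume from.
#' @return A list of class `pipeline_result` with `cohort`, `split`,
#'   `model`, `predictions`, `results` (per-case data frame) and `report`
#'   (a [metrics_report()]).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = pipeline_stages, state = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            all(stages %in% pipeline_stages))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  st <- state %||% list()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(name, ...)
    message(sprintf("[collateralq %s] %s", name, sprintf(...)))

  if ("generate" %in% stages) {
    log_stage("generate", "cohort of %d phantoms (seed %d)",
              config$n_cases, config$seed)
    st$cohort <- generate_cohort(
      config$n_cases, config$ratio_sampler, base_spec = config$phantom,
      seed = config$seed,
      dir = if (config$write_nifti) file.path(config$out_dir, "data"))
    utils::write.csv(st$cohort$manifest,
                     file.path(config$out_dir, "manifest.csv"),
                     row.names = FALSE)
    # deterministic stratified split: held-out test cases cover the grade
    # intervals in rotation
    ids <- st$cohort$manifest$case_id
    grade <- classify_qcs(100 * st$cohort$manifest$realized_ratio,
                          config$thresholds)$quaternary
    ord <- order(grade, ids)
    test_pick <- ord[round(seq(1, length(ids), length.out = config$n_test))]
    test_ids <- ids[test_pick]
    rest <- setdiff(ids, test_ids)
    val_ids <- with_seed(config$seed + 17L,
                         sample(rest, config$n_val))
    st$split <- list(train = setdiff(rest, val_ids), val = val_ids,
                     test = test_ids)
  }

  if ("preprocess" %in% stages) {
    cohort <- require_state(st, "cohort", "generate")
    log_stage("preprocess", "windowing %d volumes (level %g, width %g)",
              length(cohort$cases), config$train$window_level,
              config$train$window_width)
    st$normalized <- lapply(cohort$cases, function(cs) {
      v <- normalize_window(cs$volume, config$train$window_level,
                            config$train$window_width)
      if (config$align) {
        al <- align_midline(v)
        tfm_path <- file.path(config$out_dir,
                              paste0(cs$case_id, "_transform.json"))
        jsonlite::write_json(as.list(al$transform), tfm_path,
                             auto_unbox = TRUE, digits = NA)
        v <- al$volume
      }
      v
    })
    names(st$normalized) <- vapply(cohort$cases, `[[`, character(1),
                                   "case_id")
  }

  if ("train" %in% stages) {
    cohort <- require_state(st, "cohort", "generate")
    split <- require_state(st, "split", "generate")
    ids <- vapply(cohort$cases, `[[`, character(1), "case_id")
    tr_cases <- cohort$cases[ids %in% split$train]
    val_cases <- cohort$cases[ids %in% split$val]
    sl <- slice_dataset(tr_cases)
    if (config$slice_stride > 1L) {
      keep <- unlist(lapply(unique(sl$case_id), function(cid) {
        ix <- which(sl$case_id == cid)
        ix[seq(1L, length(ix), by = config$slice_stride)]
      }))
      sl <- structure(list(images = sl$images[keep], masks = sl$masks[keep],
                           case_id = sl$case_id[keep], z = sl$z[keep]),
                      class = "slice_dataset")
    }
    log_stage("train", "%d slices from %d cases, val %d cases, seed %d",
              length(sl$images), length(tr_cases), length(val_cases),
              config$train$seed)
    model <- u2net(config$model, seed = config$seed)
    st$model <- train_one(model, sl, val_cases, config$train)
    save_checkpoint(st$model, file.path(config$out_dir, "checkpoint.rds"))
    utils::write.csv(st$model$history,
                     file.path(config$out_dir, "history.csv"),
                     row.names = FALSE)
  }

  if ("segment" %in% stages) {
    cohort <- require_state(st, "cohort", "generate")
    split <- require_state(st, "split", "generate")
    model <- st$model %||% {
      ckpt <- file.path(config$out_dir, "checkpoint.rds")
      if (!file.exists(ckpt))
        stop(sprintf("segment stage needs a trained model; missing %s",
                     ckpt), call. = FALSE)
      load_checkpoint(ckpt)
    }
    ids <- vapply(cohort$cases, `[[`, character(1), "case_id")
    test_cases <- cohort$cases[ids %in% split$test]
    log_stage("segment", "%d held-out cases", length(test_cases))
    st$predictions <- lapply(test_cases, function(cs) {
      v <- normalize_window(cs$volume, config$train$window_level,
                            config$train$window_width)
      predict_mask(model, v, prob_threshold = config$prob_threshold)
    })
    names(st$predictions) <- vapply(test_cases, `[[`, character(1),
                                    "case_id")
    if (config$write_nifti) {
      pdir <- file.path(config$out_dir, "predictions")
      dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
      for (cid in names(st$predictions))
        write_volume(st$predictions[[cid]],
                     file.path(pdir, paste0(cid, "_pred.nii.gz")))
    }
  }

  if ("quantify" %in% stages) {
    cohort <- require_state(st, "cohort", "generate")
    preds <- require_state(st, "predictions", "segment")
    ids <- vapply(cohort$cases, `[[`, character(1), "case_id")
    rows <- lapply(names(preds), function(cid) {
      cs <- cohort$cases[[which(ids == cid)]]
      terr <- list(left = cs$territory_left, right = cs$territory_right)
      qp <- quantify_case(preds[[cid]], cs$affected_side, terr,
                          thresholds = config$thresholds, case_id = cid)
      qg <- quantify_case(cs$gt_vessels, cs$affected_side, terr,
                          thresholds = config$thresholds, case_id = cid)
      data.frame(case_id = cid,
                 v_affected = qp$v_affected_mm3,
                 v_healthy = qp$v_healthy_mm3,
                 qcs = qp$qcs_percent,
                 binary = qp$grade$binary,
                 quaternary = qp$grade$quaternary,
                 six_class = qp$grade$six_class,
                 dsc_vs_gt = as.numeric(dice(preds[[cid]], cs$gt_vessels)),
                 gt_qcs = qg$qcs_percent,
                 gt_binary = qg$grade$binary,
                 gt_quaternary = qg$grade$quaternary,
                 stringsAsFactors = FALSE)
    })
    st$results <- do.call(rbind, rows)
    log_stage("quantify", "%d cases quantified", nrow(st$results))
    utils::write.csv(st$results, file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
  }

  if ("evaluate" %in% stages) {
    res <- require_state(st, "results", "quantify")
    cm_bin <- confusion(res$gt_binary, res$binary,
                        vocabulary = c("poor", "good"))
    cm_q <- confusion(res$gt_quaternary, res$quaternary, vocabulary = 0:3)
    auc <- if (length(unique(res$gt_binary)) == 2L)
      roc_auc(res$qcs, res$gt_binary == "good") else NULL
    sp <- if (nrow(res) >= 3L) spearman_cor(res$qcs, res$gt_qcs) else NULL
    icc <- if (nrow(res) >= 2L) icc21(cbind(res$qcs, res$gt_qcs)) else NULL
    st$report <- metrics_report(dsc_mean = mean(res$dsc_vs_gt),
                                cm = cm_bin, auc = auc, spearman = sp,
                                icc = icc, n = nrow(res),
                                multiclass_cm = cm_q)
    rep_list <- list(
      n = nrow(res), dsc_mean = st$report$dsc_mean,
      binary_accuracy = st$report$binary$accuracy,
      multiclass_accuracy = st$report$multiclass_accuracy,
      mean_abs_qcs_error_pp = mean(abs(res$qcs - res$gt_qcs)),
      seed = config$seed)
    if (!is.null(auc)) rep_list$auc <- auc$auc
    if (!is.null(sp)) rep_list$spearman_rho <- sp$rho
    if (!is.null(icc)) rep_list$icc21 <- icc$icc
    jsonlite::write_json(rep_list, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_stage("evaluate", "mean DSC %.3f, mean |qCS error| %.1f pp",
              st$report$dsc_mean, rep_list$mean_abs_qcs_error_pp)
  }

  structure(st, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$cohort)) cat("  cohort:", nrow(x$cohort$manifest), "cases\n")
  if (!is.null(x$model))
    cat(sprintf("  model: best val DSC %.3f (epoch %d)\n",
                x$model$best_val_dsc, x$model$best_epoch))
  if (!is.null(x$results)) {
    cat("  per-case results:\n")
    print(x$results[, c("case_id", "qcs", "gt_qcs", "quaternary",
                        "gt_quaternary", "dsc_vs_gt")], row.names = FALSE)
  }
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
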
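#' Augmentation policy for training slices
#'
#' Every range contains the identity transform, so augmentation never
#' forces a change: horizontal/vertical flips with probability `flip_prob`
#' each, multiplicative brightness in `1 +/- brightness_delta`, contrast
#' scaling about the slice mean in `contrast_range`, rotation in
#' `+/- rotation_deg` and zoom in `zoom_range`. Geometric transforms apply
#' identically to image and mask (mask via nearest-neighbour); photometric
#' transforms apply to the image only, re-clipped to \[0, 1\].
#'
#' @param flip_prob probability of each of horizontal and vertical flip.
#' @param brightness_delta half-width of the multiplicative brightness
#'   factor interval around 1 (0.2 = +/- 20 percent).
#' @param contrast_range contrast scale interval.
#' @param rotation_deg rotation half-range, degrees.
#' @param zoom_range zoom factor interval.
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(flip_prob = 0.5, brightness_delta = 0.2,
                         contrast_range = c(0.8, 1.2), rotation_deg = 10,
                         zoom_range = c(0.9, 1.1)) {
  stopifnot(flip_prob >= 0, flip_prob <= 1, brightness_delta >= 0,
            contrast_range[1] <= 1, contrast_range[2] >= 1,
            rotation_deg >= 0, zoom_range[1] <= 1, zoom_range[2] >= 1)
  structure(list(flip_prob = flip_prob, brightness_delta = brightness_delta,
                 contrast_range = as.numeric(contrast_range),
                 rotation_deg = rotation_deg,
                 zoom_range = as.numeric(zoom_range)),
            class = "augment_spec")
}

rotate_zoom_2d <- function(img, deg, zoom, nearest = FALSE) {
  d <- dim(img)
  ctr <- (d + 1) / 2
  th <- deg * pi / 180
  g <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2])))
  p <- sweep(g, 2, ctr)
  # inverse map: rotate by -theta, divide by zoom
  src <- cbind(( cos(th) * p[, 1] + sin(th) * p[, 2]) / zoom,
               (-sin(th) * p[, 1] + cos(th) * p[, 2]) / zoom)
  src <- sweep(src, 2, ctr, `+`)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  if (nearest) {
    i <- cl(round(src[, 1]), d[1]); j <- cl(round(src[, 2]), d[2])
    return(array(img[cbind(i, j)], d))
  }
  x <- cl(src[, 1], d[1]); y <- cl(src[, 2], d[2])
  x0 <- floor(x); y0 <- floor(y)
  x1 <- cl(x0 + 1, d[1]); y1 <- cl(y0 + 1, d[2])
  fx <- x - x0; fy <- y - y0
  v <- (1 - fx) * (1 - fy) * img[cbind(x0, y0)] +
    fx * (1 - fy) * img[cbind(x1, y0)] +
    (1 - fx) * fy * img[cbind(x0, y1)] +
    fx * fy * img[cbind(x1, y1)]
  array(v, d)
}

#' Augment one image/mask slice pair
#'
#' Draws one set of augmentation parameters from `spec` under `seed` and
#' applies them. When every drawn parameter is the identity (e.g. a spec
#' with `flip_prob = 0` and collapsed ranges) the output is bit-identical
#' to the input.
#'
#' @param image 2D matrix with values in \[0, 1\].
#' @param mask 2D binary matrix, same shape.
#' @param spec an [augment_spec()].
#' @param seed integer seed for the parameter draw.
#' @return A list with the augmented `image` and `mask`.
#' @export
augment_pair <- function(image, mask, spec = augment_spec(), seed = 1L) {
  stopifnot(all(dim(image) == dim(mask)),
            min(image) >= 0, max(image) <= 1)
  draws <- with_seed(seed, list(
    fh = runif(1) < spec$flip_prob,
    fv = runif(1) < spec$flip_prob,
    rot = runif(1, -spec$rotation_deg, spec$rotation_deg),
    zoom = runif(1, spec$zoom_range[1], spec$zoom_range[2]),
    bright = runif(1, 1 - spec$brightness_delta, 1 + spec$brightness_delta),
    contr = runif(1, spec$contrast_range[1], spec$contrast_range[2])))
  mask <- array(as.numeric(mask), dim(mask))
  if (draws$fh) { image <- image[nrow(image):1, ]; mask <- mask[nrow(mask):1, ] }
  if (draws$fv) { image <- image[, ncol(image):1]; mask <- mask[, ncol(mask):1] }
  if (draws$rot != 0 || draws$zoom != 1) {
    image <- rotate_zoom_2d(image, draws$rot, draws$zoom)
    mask <- rotate_zoom_2d(mask, draws$rot, draws$zoom, nearest = TRUE)
  }
  if (draws$bright != 1) image <- image * draws$bright
  if (draws$contr != 1) {
    m <- mean(image)
    image <- (image - m) * draws$contr + m
  }
  if (draws$bright != 1 || draws$contr != 1)
    image <- pmin(pmax(image, 0), 1)
  list(image = image, mask = mask > 0.5)
}

#' Training configuration
#'
#' Defaults follow the development protocol the package reproduces: Adam at
#' learning rate 1e-4 with batch size 8 (the winning grid cell), up to 500
#' epochs with early stopping after 20 epochs without improvement of the
#' validation Dice coefficient, and 5-fold case-level cross-validation.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size slices per optimization step.
#' @param max_epochs epoch cap.
#' @param patience_epochs early-stopping patience: training stops once the
#'   best validation DSC has not strictly improved for this many
#'   consecutive epochs.
#' @param n_folds cross-validation folds (>= 2).
#' @param augmentation an [augment_spec()], or `NULL` for none.
#' @param window_level,window_width intensity window applied to HU slices
#'   before they enter the network (see [normalize_window()]).
#' @param seed training seed (shuffling, augmentation draws).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 8L,
                         max_epochs = 500L, patience_epochs = 20L,
                         n_folds = 5L, augmentation = augment_spec(),
                         window_level = 100, window_width = 600,
                         seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1L,
            patience_epochs < max_epochs, n_folds >= 2L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience_epochs = as.integer(patience_epochs),
                 n_folds = as.integer(n_folds), augmentation = augmentation,
                 window_level = window_level, window_width = window_width,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Case-level stratified fold assignment
#'
#' Cases (never slices) are partitioned into `n_folds` folds. Within each
#' stratum the shuffled cases are dealt round-robin, with the dealing
#' position carried across strata so overall fold sizes differ by at most
#' one and per-fold stratum counts stay within one case of proportionality.
#'
#' @param case_ids character vector of case identifiers.
#' @param labels optional stratification labels (e.g. collateral grades),
#'   same length; `NULL` for unstratified folds.
#' @param n_folds number of folds.
#' @param seed shuffling seed; the assignment is deterministic given it.
#' @return Integer vector of fold numbers (1..n_folds) named by case id.
#' @export
make_folds <- function(case_ids, labels = NULL, n_folds = 5L, seed = 1L) {
  n <- length(case_ids)
  stopifnot(n >= n_folds, !anyDuplicated(case_ids))
  labels <- labels %||% rep("all", n)
  stopifnot(length(labels) == n)
  fold <- integer(n)
  names(fold) <- case_ids
  ptr <- 0L
  with_seed(seed, {
    for (s in unique(labels)) {
      idx <- which(labels == s)
      if (length(idx) < n_folds && length(unique(labels)) > 1L)
        warning(sprintf(
          "stratum '%s' has fewer cases (%d) than folds (%d); distributed round-robin",
          s, length(idx), n_folds))
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- (ptr + seq_along(idx) - 1L) %% n_folds + 1L
      ptr <- ptr + length(idx)
    }
  })
  fold
}

#' Early-stopping rule on a validation-DSC history
#'
#' "Plateauing" is read as: no strict improvement of the best validation
#' DSC for `patience` consecutive epochs. Returns the epoch at which
#' training stops and the epoch whose weights are kept (the best epoch,
#' never the last).
#'
#' @param val_dsc numeric vector of per-epoch validation DSC values.
#' @param patience patience in epochs.
#' @return List with `stop_epoch`, `best_epoch`, `best_dsc`.
#' @export
early_stop_trace <- function(val_dsc, patience) {
  best <- -Inf; best_epoch <- 0L; since <- 0L
  stop_epoch <- length(val_dsc)
  for (e in seq_along(val_dsc)) {
    if (val_dsc[e] > best) {
      best <- val_dsc[e]; best_epoch <- e; since <- 0L
    } else {
      since <- since + 1L
    }
    if (since >= patience) { stop_epoch <- e; break }
  }
  list(stop_epoch = stop_epoch, best_epoch = best_epoch, best_dsc = best)
}

slices_to_batch <- function(images, masks, level, width) {
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  x <- array(0, c(H, W, length(images)))
  y <- array(0, c(H, W, length(images)))
  lo <- level - width / 2
  for (i in seq_along(images)) {
    x[, , i] <- pmin(pmax((images[[i]] - lo) / width, 0), 1)
    y[, , i] <- as.numeric(masks[[i]])
  }
  list(x = x, y = y)
}

val_mean_dsc <- function(model, val_cases, level, width) {
  mean(vapply(val_cases, function(cs) {
    pred <- predict_mask(model, normalize_window(cs$volume, level, width))
    dice(pred, cs$gt_vessels)
  }, numeric(1)))
}

#' Train a model on slices with early stopping
#'
#' Minimizes the deep-supervision loss with Adam. After each epoch the
#' validation DSC is computed volume-wise (per-case Dice of the restacked
#' predicted mask against ground truth, averaged over validation cases).
#' Training stops when the best validation DSC has not improved for
#' `cfg$patience_epochs` epochs, and the returned model carries the weights
#' of the best epoch, not the last. Fully deterministic for a fixed
#' `cfg$seed`.
#'
#' @param model an initialized [u2net()] model.
#' @param train_slices a [slice_dataset()] (or subset) of training slices.
#' @param val_cases list of phantom cases (volume + ground-truth mask) for
#'   validation; must be disjoint from the training cases and non-empty.
#' @param cfg a [train_config()].
#' @return The trained `u2net_model`, with `history` (data frame: epoch,
#'   train_loss, val_dsc), `best_epoch` and `train_seed` recorded.
#' @export
train_one <- function(model, train_slices, val_cases, cfg = train_config()) {
  stopifnot(inherits(model, "u2net_model"),
            inherits(cfg, "train_config"))
  if (length(val_cases) == 0L)
    stop("validation set is empty; early stopping is undefined")
  val_ids <- vapply(val_cases, `[[`, character(1), "case_id")
  if (any(train_slices$case_id %in% val_ids))
    stop("train and validation case sets overlap")
  n_sl <- length(train_slices$images)
  stopifnot(n_sl >= 1L)
  opt <- adam_state(length(model$weights))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_dsc = numeric())
  best <- -Inf; best_epoch <- 0L; since <- 0L
  best_w <- model$weights; best_r <- model$running
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(cfg$seed + 7919L * epoch, sample.int(n_sl))
    losses <- numeric(0)
    for (b0 in seq(1L, n_sl, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n_sl)]
      imgs <- train_slices$images[idx]
      msks <- train_slices$masks[idx]
      if (!is.null(cfg$augmentation)) {
        for (k in seq_along(idx)) {
          # HU slices are windowed before augmentation (image domain [0,1])
          lo <- cfg$window_level - cfg$window_width / 2
          im <- pmin(pmax((imgs[[k]] - lo) / cfg$window_width, 0), 1)
          aug <- augment_pair(im, msks[[k]], cfg$augmentation,
                              seed = cfg$seed + 104729L * epoch + idx[k])
          imgs[[k]] <- aug$image * cfg$window_width + lo
          msks[[k]] <- aug$mask
        }
      }
      ba <- slices_to_batch(imgs, msks, cfg$window_level, cfg$window_width)
      st <- u2net_train_batch(model, ba$x, ba$y, opt, cfg$learning_rate)
      model <- st$model; opt <- st$opt
      losses <- c(losses, st$loss)
    }
    vd <- val_mean_dsc(model, val_cases, cfg$window_level, cfg$window_width)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_dsc = vd))
    if (vd > best) {
      best <- vd; best_epoch <- epoch; since <- 0L
      best_w <- model$weights; best_r <- model$running
    } else {
      since <- since + 1L
    }
    if (since >= cfg$patience_epochs) break
  }
  model$weights <- best_w
  model$running <- best_r
  model$trained <- TRUE
  model$train_seed <- cfg$seed
  model$history <- history
  model$best_epoch <- best_epoch
  model$best_val_dsc <- best
  model
}

#' Select the winning grid cell and fold from cross-validation summaries
#'
#' The winning cell has the highest mean best-validation-DSC over folds;
#' ties go to the smaller learning rate, then the smaller batch size.
#' Within the winning cell the selected fold is the one with the highest
#' fold-validation DSC. Pure function of the summaries, so selection rules
#' can be verified on constructed histories.
#'
#' @param cells data frame with columns `lr`, `batch`, `mean_val_dsc` and
#'   optionally `failed` (failed cells are excluded).
#' @param folds data frame with columns `lr`, `batch`, `fold`,
#'   `best_val_dsc`.
#' @return List with `lr`, `batch`, `fold`, `mean`.
#' @export
select_winner <- function(cells, folds) {
  if (!is.null(cells$failed)) cells <- cells[!cells$failed, , drop = FALSE]
  cells <- cells[!is.na(cells$mean_val_dsc), , drop = FALSE]
  if (nrow(cells) == 0L) stop("every grid cell failed to train")
  ord <- order(-cells$mean_val_dsc, cells$lr, cells$batch)
  win <- cells[ord[1], ]
  ff <- folds[folds$lr == win$lr & folds$batch == win$batch, , drop = FALSE]
  sel <- ff$fold[which.max(ff$best_val_dsc)]
  list(lr = win$lr, batch = win$batch, fold = sel,
       mean = win$mean_val_dsc)
}

#' Grid search with case-level cross-validation
#'
#' For every (learning rate, batch size) cell, trains one model per fold
#' and scores it by its best validation DSC. The winning cell has the
#' highest mean best-validation-DSC over folds (ties broken toward the
#' smaller learning rate, then the smaller batch size); the final model is
#' the winning cell's fold with the highest fold-validation DSC. Cells in
#' which any fold fails to train are marked failed and excluded.
#'
#' @param cases list of phantom cases (or a `phantom_cohort`).
#' @param grid data frame with columns `lr` and `batch`; defaults to the
#'   protocol grid (1e-3, 1e-4, 1e-5) x (8, 16, 32).
#' @param base_cfg a [train_config()] supplying everything but lr/batch.
#' @param model_cfg a [model_config()] for the per-fold models.
#' @param strata optional per-case stratification labels for
#'   [make_folds()].
#' @return A list of class `cv_report`: `cells` (per-cell summary), `folds`
#'   (per-cell-per-fold best DSC and epoch), `histories` (named list of
#'   training histories), `selected` (winning lr, batch, fold), `folds_map`
#'   (the case-to-fold assignment) and `model` (the selected trained
#'   model).
#' @export
grid_search_cv <- function(cases,
                           grid = expand.grid(lr = c(1e-3, 1e-4, 1e-5),
                                              batch = c(8L, 16L, 32L)),
                           base_cfg = train_config(),
                           model_cfg = model_config("scaled"),
                           strata = NULL) {
  if (inherits(cases, "phantom_cohort")) cases <- cases$cases
  stopifnot(nrow(grid) >= 1L, all(c("lr", "batch") %in% names(grid)))
  ids <- vapply(cases, `[[`, character(1), "case_id")
  folds <- make_folds(ids, labels = strata, n_folds = base_cfg$n_folds,
                      seed = base_cfg$seed)
  all_slices <- slice_dataset(cases)
  fold_rows <- list(); cell_rows <- list(); histories <- list()
  cell_fold_models <- list()
  for (g in seq_len(nrow(grid))) {
    cfg <- base_cfg
    cfg$learning_rate <- grid$lr[g]
    cfg$batch_size <- as.integer(grid$batch[g])
    fold_dsc <- rep(NA_real_, base_cfg$n_folds)
    models <- vector("list", base_cfg$n_folds)
    failed <- FALSE
    for (f in seq_len(base_cfg$n_folds)) {
      val_ids <- ids[folds == f]
      keep <- all_slices$case_id %in% setdiff(ids, val_ids)
      tr <- list(images = all_slices$images[keep],
                 masks = all_slices$masks[keep],
                 case_id = all_slices$case_id[keep], z = all_slices$z[keep])
      class(tr) <- "slice_dataset"
      fit <- tryCatch(
        train_one(u2net(model_cfg, seed = base_cfg$seed),
                  tr, cases[ids %in% val_ids], cfg),
        error = function(e) e)
      if (inherits(fit, "error")) {
        warning(sprintf("cell %d fold %d failed: %s", g, f,
                        conditionMessage(fit)))
        failed <- TRUE
        break
      }
      fold_dsc[f] <- fit$best_val_dsc
      models[[f]] <- fit
      histories[[sprintf("lr%g_b%d_fold%d", cfg$learning_rate,
                         cfg$batch_size, f)]] <- fit$history
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        lr = cfg$learning_rate, batch = cfg$batch_size, fold = f,
        best_val_dsc = fit$best_val_dsc, best_epoch = fit$best_epoch)
    }
    mean_dsc <- if (failed) NA_real_ else mean(fold_dsc)
    cell_rows[[g]] <- data.frame(lr = cfg$learning_rate,
                                 batch = cfg$batch_size,
                                 mean_val_dsc = mean_dsc, failed = failed)
    if (!failed)
      cell_fold_models[[paste(cfg$learning_rate, cfg$batch_size)]] <- models
  }
  cells <- do.call(rbind, cell_rows)
  folds_df <- do.call(rbind, fold_rows)
  selected <- select_winner(cells, folds_df)
  final_model <-
    cell_fold_models[[paste(selected$lr, selected$batch)]][[selected$fold]]
  structure(list(cells = cells, folds = folds_df, histories = histories,
                 selected = selected, folds_map = folds,
                 model = final_model),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>\n")
  print(x$cells, row.names = FALSE)
  cat(sprintf("selected: lr=%g batch=%d fold=%d (mean val DSC %.4f)\n",
              x$selected$lr, x$selected$batch, x$selected$fold,
              x$selected$mean))
  invisible(x)
}
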
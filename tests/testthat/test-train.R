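test_that("fold assignment stratifies exactly when sizes allow", {
  ids <- sprintf("c%02d", 1:10)
  strata <- rep(c("poor", "good"), each = 5)
  f <- make_folds(ids, strata, n_folds = 5, seed = 1)
  for (k in 1:5) {
    expect_equal(sum(f == k), 2L)
    expect_setequal(strata[f == k], c("poor", "good"))
  }
  expect_identical(f, make_folds(ids, strata, n_folds = 5, seed = 1))
  expect_false(identical(f, make_folds(ids, strata, n_folds = 5, seed = 2)))
})

test_that("94 cases in 5 folds yield sizes 18 or 19 with strata balanced", {
  ids <- sprintf("case%03d", 1:94)
  strata <- rep(0:3, times = c(3, 28, 41, 22))  # grade-like imbalance
  # the 3-case stratum is smaller than the fold count: warned, round-robined
  expect_warning(f <- make_folds(ids, strata, n_folds = 5, seed = 7),
                 "round-robin")
  sizes <- tabulate(f, 5)
  expect_true(all(sizes %in% c(18L, 19L)))
  expect_equal(sum(sizes), 94L)
  # per-fold stratum counts within one case of proportionality
  for (s in unique(strata)) {
    per_fold <- tabulate(f[strata == s], 5)
    expect_lte(max(per_fold) - min(per_fold), 1L)
  }
})

test_that("a stratum smaller than the fold count warns and round-robins", {
  ids <- sprintf("c%02d", 1:12)
  strata <- c(rep("big", 10), rep("rare", 2))
  expect_warning(f <- make_folds(ids, strata, n_folds = 5, seed = 3),
                 "round-robin")
  expect_equal(sum(f > 0), 12L)
})

test_that("augmentation identity case is bit-exact", {
  im <- matrix(runif(32 * 32), 32)
  mk <- matrix(runif(32 * 32) > 0.9, 32)
  id_spec <- augment_spec(flip_prob = 0, brightness_delta = 0,
                          contrast_range = c(1, 1), rotation_deg = 0,
                          zoom_range = c(1, 1))
  out <- augment_pair(im, mk, id_spec, seed = 5)
  expect_identical(out$image, im)
  expect_identical(out$mask, array(mk, dim(mk)))
})

test_that("flips are involutions applied jointly to image and mask", {
  im <- matrix(runif(16 * 16), 16)
  mk <- matrix(runif(16 * 16) > 0.8, 16)
  sp <- augment_spec(flip_prob = 1, brightness_delta = 0,
                     contrast_range = c(1, 1), rotation_deg = 0,
                     zoom_range = c(1, 1))
  out <- augment_pair(im, mk, sp, seed = 1)  # both flips drawn (p = 1)
  redo <- out$image[nrow(im):1, ][, ncol(im):1]
  expect_identical(redo, im)
  redo_m <- out$mask[nrow(im):1, ][, ncol(im):1]
  expect_identical(redo_m[TRUE], mk[TRUE])
})

test_that("brightness is multiplicative and contrast preserves the mean", {
  base <- matrix(0.4, 8, 8)
  mk <- matrix(FALSE, 8, 8)
  sp_b <- augment_spec(flip_prob = 0, brightness_delta = 0.2,
                       contrast_range = c(1, 1), rotation_deg = 0,
                       zoom_range = c(1, 1))
  o1 <- augment_pair(base, mk, sp_b, seed = 11)
  o2 <- augment_pair(base / 2, mk, sp_b, seed = 11)  # same factor drawn
  f <- o1$image[1, 1] / base[1, 1]
  expect_gte(f, 0.8); expect_lte(f, 1.2)
  expect_equal(o2$image, o1$image / 2, tolerance = 1e-12)
  # contrast about the slice mean: a constant image is a fixed point
  sp_c <- augment_spec(flip_prob = 0, brightness_delta = 0,
                       contrast_range = c(0.8, 1.2), rotation_deg = 0,
                       zoom_range = c(1, 1))
  oc <- augment_pair(base, mk, sp_c, seed = 4)
  expect_equal(oc$image, base, tolerance = 1e-12)
})

test_that("early stopping keeps the best epoch under the patience rule", {
  # strictly increasing for 30 epochs, then flat: stop at 50, keep epoch 30
  hist <- c(seq(0.01, 0.30, by = 0.01), rep(0.30, 40))
  tr <- early_stop_trace(hist, patience = 20)
  expect_equal(tr$stop_epoch, 50L)
  expect_equal(tr$best_epoch, 30L)
  expect_equal(tr$best_dsc, 0.30)
  # cap: shorter history than patience runs to the end
  tr2 <- early_stop_trace(c(0.1, 0.2, 0.15, 0.19, 0.18), patience = 20)
  expect_equal(tr2$stop_epoch, 5L)
  expect_equal(tr2$best_epoch, 2L)
  # best epoch never has a DSC below any recorded value
  set.seed(1)
  for (i in 1:20) {
    h <- runif(sample(5:40, 1))
    t3 <- early_stop_trace(h, patience = sample(2:10, 1))
    expect_equal(h[t3$best_epoch], max(h[seq_len(t3$stop_epoch)]))
  }
})

test_that("training runs deterministically, stops on patience, keeps best", {
  cases <- list(tiny_phantom(0.9, 21), tiny_phantom(0.6, 22),
                tiny_phantom(0.8, 23))
  sl <- slice_dataset(cases[1:2])
  cfg <- train_config(learning_rate = 1e-3, batch_size = 8,
                      max_epochs = 3, patience_epochs = 2,
                      augmentation = NULL, seed = 5)
  m0 <- u2net(tiny_net_cfg(), seed = 1)
  fit1 <- train_one(m0, sl, cases[3], cfg)
  fit2 <- train_one(m0, sl, cases[3], cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$weights, fit2$weights)
  expect_lte(nrow(fit1$history), 3L)
  # returned weights correspond to the best epoch's validation DSC
  expect_equal(fit1$best_val_dsc, max(fit1$history$val_dsc))
  expect_equal(fit1$history$val_dsc[fit1$best_epoch], fit1$best_val_dsc)
  # empty validation set is an error
  expect_error(train_one(m0, sl, list(), cfg), "empty")
  # leakage is an error
  expect_error(train_one(m0, sl, cases[1], cfg), "overlap")
})

test_that("grid winner selection follows the stated tie-break rules", {
  folds <- data.frame(lr = rep(c(1e-3, 1e-4), each = 2),
                      batch = 8, fold = c(1, 2, 1, 2),
                      best_val_dsc = c(0.6, 0.8, 0.7, 0.7))
  cells <- data.frame(lr = c(1e-3, 1e-4), batch = 8,
                      mean_val_dsc = c(0.7, 0.7), failed = FALSE)
  w <- select_winner(cells, folds)
  expect_equal(w$lr, 1e-4)          # tie on mean: smaller lr wins
  expect_equal(w$fold, 1L)          # argmax fold (ties keep the first)
  # one-cell grid, folds 0.6 / 0.8: the second fold is selected
  w2 <- select_winner(cells[1, ], folds[folds$lr == 1e-3, ])
  expect_equal(w2$fold, 2L)
  # batch tie-break after lr tie
  cells3 <- data.frame(lr = 1e-4, batch = c(32, 8),
                       mean_val_dsc = 0.7, failed = FALSE)
  folds3 <- data.frame(lr = 1e-4, batch = c(32, 8, 32, 8),
                       fold = c(1, 1, 2, 2), best_val_dsc = 0.7)
  expect_equal(select_winner(cells3, folds3)$batch, 8)
  # failed cells are excluded
  cells4 <- data.frame(lr = c(1e-5, 1e-3), batch = 8,
                       mean_val_dsc = c(0.9, 0.5), failed = c(TRUE, FALSE))
  expect_equal(select_winner(cells4, folds)$lr, 1e-3)
})

test_that("cross-validated grid search trains, reports and selects", {
  cases <- lapply(1:4, function(i)
    generate_phantom(tiny_spec(true_ratio = c(0.3, 0.7, 1.0, 0.5)[i],
                               seed = 30 + i),
                     case_id = sprintf("cv%02d", i)))
  base <- train_config(learning_rate = 1e-3, batch_size = 8,
                       max_epochs = 2, patience_epochs = 1, n_folds = 2,
                       augmentation = NULL, seed = 9)
  cvr <- grid_search_cv(cases, grid = data.frame(lr = 1e-3, batch = 8L),
                        base_cfg = base, model_cfg = tiny_net_cfg())
  expect_s3_class(cvr, "cv_report")
  # winning mean equals the independent mean of per-fold bests
  expect_equal(cvr$selected$mean, mean(cvr$folds$best_val_dsc))
  # selected fold attains the fold maximum
  expect_equal(cvr$folds$best_val_dsc[cvr$selected$fold],
               max(cvr$folds$best_val_dsc))
  # per-fold best recomputes from the persisted histories
  for (r in seq_len(nrow(cvr$folds))) {
    h <- cvr$histories[[sprintf("lr%g_b%d_fold%d", cvr$folds$lr[r],
                                cvr$folds$batch[r], cvr$folds$fold[r])]]
    expect_equal(max(h$val_dsc), cvr$folds$best_val_dsc[r])
  }
  # no case appears in both train and validation in any fold: the fold map
  # partitions all cases
  expect_setequal(names(cvr$folds_map), sprintf("cv%02d", 1:4))
  expect_true(all(cvr$folds_map %in% 1:2))
})
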
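#' Configuration of the nested residual-U segmentation network
#'
#' The network is a two-level nested U: an outer encoder-decoder whose every
#' stage is itself a residual U-block (RSU) that pools, convolves and
#' upsamples internally before adding a residual connection, extracting
#' multi-scale features within each stage. Each decoder stage and the
#' deepest encoder stage emit a side probability map (deep supervision); a
#' 1x1 convolution over the side logits yields the fused output.
#'
#' All sizes are configurable so that a scaled-down preset trains on one
#' CPU; the full-size preset mirrors the reference architecture (6 stages,
#' 64 base channels, RSU depths 7-6-5-4 plus two dilated bottom stages).
#'
#' @param preset `"full"` or `"scaled"` (4 stages, 8 base channels).
#' @param n_stages number of encoder stages (>= 2). Input slices must have
#'   spatial sizes divisible by `2^(n_stages - 1)`.
#' @param base_channels channels of the first stage (>= 4, even).
#' @param rsu_depths internal U depth per stage (each >= 2).
#' @param dilated logical per stage: dilated residual U-blocks (no internal
#'   pooling), used in the deepest stages where resolution is low.
#' @param channel_cap stage channels grow as `base * 2^(stage-1)` up to
#'   `base * channel_cap`.
#' @param in_channels input image channels.
#' @return An object of class `u2net_config`.
#' @export
model_config <- function(preset = c("full", "scaled"), n_stages = NULL,
                         base_channels = NULL, rsu_depths = NULL,
                         dilated = NULL, channel_cap = NULL,
                         in_channels = 1L) {
  preset <- match.arg(preset)
  if (preset == "full") {
    n_stages <- n_stages %||% 6L
    base_channels <- base_channels %||% 64L
    channel_cap <- channel_cap %||% 8L
  } else {
    n_stages <- n_stages %||% 4L
    base_channels <- base_channels %||% 8L
    channel_cap <- channel_cap %||% 4L
  }
  n_stages <- as.integer(n_stages)
  base_channels <- as.integer(base_channels)
  if (n_stages < 2L) stop("`n_stages` must be >= 2")
  if (base_channels < 4L || base_channels %% 2L != 0L)
    stop("`base_channels` must be an even number >= 4")
  rsu_depths <- as.integer(rsu_depths %||% if (preset == "full") {
    # 7-6-5-4 encoder descent, dilated bottom stages fixed at depth 4
    pmax(4L, 7L - (seq_len(n_stages) - 1L))
  } else {
    pmax(2L, 5L - (seq_len(n_stages) - 1L))
  })
  if (is.null(dilated)) {
    dilated <- rep(FALSE, n_stages)
    dilated[n_stages] <- TRUE
    if (preset == "full" && n_stages >= 5L) dilated[n_stages - 1L] <- TRUE
  }
  stopifnot(length(rsu_depths) == n_stages, all(rsu_depths >= 2L),
            length(dilated) == n_stages)
  enc_out <- base_channels * pmin(2^(seq_len(n_stages) - 1L), channel_cap)
  enc_mid <- pmax(2L, enc_out %/% 2L)
  enc_mid[1] <- max(2L, base_channels %/% 2L)
  dec_out <- enc_out[pmax(seq_len(n_stages - 1L) - 1L, 1L)]
  dec_mid <- enc_mid[seq_len(n_stages - 1L)]
  structure(list(preset = preset, n_stages = n_stages,
                 in_channels = as.integer(in_channels),
                 base_channels = base_channels,
                 rsu_depths = rsu_depths, dilated = as.integer(dilated),
                 enc_out = as.integer(enc_out), enc_mid = as.integer(enc_mid),
                 dec_out = as.integer(dec_out), dec_mid = as.integer(dec_mid),
                 n_side_outputs = n_stages),
            class = "u2net_config")
}

#' @export
print.u2net_config <- function(x, ...) {
  cat(sprintf(
    "<u2net_config %s> %d stages, base %d ch, RSU depths %s, dilated %s\n",
    x$preset, x$n_stages, x$base_channels,
    paste(x$rsu_depths, collapse = "-"),
    paste(which(x$dilated == 1L), collapse = ",")))
  invisible(x)
}

u2net_layout <- function(cfg) cpp_u2net_layout(unclass(cfg))

param_sizes <- function(lay) {
  lay[, "k"]^2 * lay[, "cin"] * lay[, "cout"] + lay[, "cout"] +
    ifelse(lay[, "bn"] == 1L, 2L * lay[, "cout"], 0L)
}

#' Build a segmentation network
#'
#' Weight initialization is He-normal for convolution kernels, zero biases,
#' unit batch-norm scales; it is a pure function of `(config, seed)`, so two
#' builds from the same arguments have identical parameters.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `u2net_model` holding the configuration, a
#'   flat weight vector, batch-norm running statistics and training
#'   provenance.
#' @export
u2net <- function(config = model_config("scaled"), seed = 1L) {
  stopifnot(inherits(config, "u2net_config"))
  lay <- u2net_layout(config)
  sizes <- param_sizes(lay)
  weights <- numeric(sum(sizes))
  running <- numeric(sum(ifelse(lay[, "bn"] == 1L, 2L * lay[, "cout"], 0L)))
  wpos <- 0L; rpos <- 0L
  with_seed(seed, {
    for (r in seq_len(nrow(lay))) {
      cin <- lay[r, "cin"]; cout <- lay[r, "cout"]; k <- lay[r, "k"]
      nw <- k * k * cin * cout
      weights[wpos + seq_len(nw)] <- rnorm(nw, 0, sqrt(2 / (k * k * cin)))
      wpos <- wpos + nw + cout          # biases stay zero
      if (lay[r, "bn"] == 1L) {
        weights[wpos + seq_len(cout)] <- 1   # gamma
        wpos <- wpos + 2L * cout             # beta stays zero
        running[rpos + cout + seq_len(cout)] <- 1  # running var
        rpos <- rpos + 2L * cout
      }
    }
  })
  structure(list(config = config, weights = weights, running = running,
                 n_parameters = length(weights), init_seed = as.integer(seed),
                 trained = FALSE, train_seed = NULL, history = NULL),
            class = "u2net_model")
}

#' Number of trainable parameters
#' @param model a [u2net_model][u2net()] or [model_config()].
#' @export
n_parameters <- function(model) {
  cfg <- if (inherits(model, "u2net_model")) model$config else model
  as.integer(sum(param_sizes(u2net_layout(cfg))))
}

#' @export
print.u2net_model <- function(x, ...) {
  cat(sprintf("<u2net_model> %s preset, %d parameters, %s\n",
              x$config$preset, x$n_parameters,
              if (x$trained) sprintf("trained (%d epochs)",
                                     nrow(x$history)) else "untrained"))
  invisible(x)
}

as_slice_array <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  x
}

#' Forward pass: per-slice probability maps
#'
#' Runs the network on one or more 2D slices (values in \[0, 1\]) and
#' returns the fused probability map together with every side output
#' upsampled to input size. All probabilities lie strictly in (0, 1).
#'
#' @param model a [u2net()] model.
#' @param images a `H x W` matrix or `H x W x N` array of normalized
#'   intensities.
#' @return A list of class `segmentation_output`: `fused` (`H x W x N`
#'   array) and `sides` (list of `n_stages` arrays).
#' @export
u2net_forward <- function(model, images) {
  x <- as_slice_array(images)
  d <- dim(x)
  out <- cpp_u2net_run(unclass(model$config), model$weights, model$running,
                       as.double(x), as.integer(d), numeric(0), FALSE)
  structure(list(fused = out$fused, sides = out$sides),
            class = "segmentation_output")
}

#' Deep-supervision loss
#'
#' Sum over the fused map and every side map of the per-pixel mean binary
#' cross-entropy against the binary target, with equal weights. Matches the
#' objective minimized during training (which evaluates it on logits for
#' numerical stability).
#'
#' @param output a `segmentation_output` from [u2net_forward()], or any list
#'   with elements `fused` and `sides`.
#' @param target binary mask, same spatial shape as the maps.
#' @param eps probability clamp.
#' @return Scalar loss (>= 0).
#' @export
deep_supervision_loss <- function(output, target, eps = 1e-12) {
  target <- as_slice_array(target)
  if (!all(target %in% c(0, 1))) stop("`target` must be binary")
  maps <- c(list(output$fused), output$sides)
  bce <- function(p) {
    p <- pmin(pmax(as_slice_array(p), eps), 1 - eps)
    if (!all(dim(p) == dim(target))) stop("map/target shape mismatch")
    -mean(target * log(p) + (1 - target) * log(1 - p))
  }
  sum(vapply(maps, bce, numeric(1)))
}

reflect_pad_idx <- function(n, n_to) {
  # symmetric (reflect) index vector extending 1..n to length n_to
  extra <- n_to - n
  lo <- extra %/% 2L
  hi <- extra - lo
  base <- seq_len(n)
  refl <- function(k, from_end) if (k == 0L) integer(0) else {
    if (from_end) rev(n - seq_len(k)) else 1L + rev(seq_len(k))
  }
  c(rev(1L + seq_len(lo)), base, n - seq_len(hi))
}

#' Segment a volume into a binary vessel mask
#'
#' Axial slice-wise inference on the fused output, restacked into a 3D mask
#' with the input's spacing. Voxels with fused probability strictly greater
#' than `prob_threshold` are vessel. Slices whose spatial size is not
#' divisible by `2^(n_stages - 1)` are reflect-padded to the nearest valid
#' size and cropped back.
#'
#' @param model a trained (or initialized) [u2net()] model.
#' @param vol a [volume_grid()] of kind `"normalized"` (see
#'   [normalize_window()]).
#' @param prob_threshold operating point; the conventional 0.5 by default,
#'   with a strict `>` rule so probability exactly at the threshold is
#'   background.
#' @return A [vessel_mask()] with the volume's shape and spacing.
#' @export
predict_mask <- function(model, vol, prob_threshold = 0.5) {
  stopifnot(inherits(model, "u2net_model"), inherits(vol, "volume_grid"))
  if (vol$kind != "normalized")
    stop("`vol` must be normalized; apply normalize_window() first")
  d <- dim(vol$data)
  div <- 2^(model$config$n_stages - 1L)
  Hp <- as.integer(ceiling(d[1] / div) * div)
  Wp <- as.integer(ceiling(d[2] / div) * div)
  x <- vol$data
  if (Hp != d[1] || Wp != d[2]) {
    message(sprintf("predict_mask: reflect-padding slices %dx%d -> %dx%d",
                    d[1], d[2], Hp, Wp))
    x <- x[reflect_pad_idx(d[1], Hp), reflect_pad_idx(d[2], Wp), ,
           drop = FALSE]
  }
  out <- u2net_forward(model, x)
  prob <- out$fused[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
  if (Hp != d[1] || Wp != d[2]) {
    lo1 <- (Hp - d[1]) %/% 2L; lo2 <- (Wp - d[2]) %/% 2L
    prob <- out$fused[lo1 + seq_len(d[1]), lo2 + seq_len(d[2]), ,
                      drop = FALSE]
  }
  vessel_mask(prob > prob_threshold, spacing_mm = vol$spacing_mm)
}

#' @export
predict.u2net_model <- function(object, newdata, prob_threshold = 0.5, ...) {
  predict_mask(object, newdata, prob_threshold = prob_threshold)
}

# One optimization step on a batch of slices. Returns loss and the updated
# model + Adam state.
u2net_train_batch <- function(model, x, y, opt, lr) {
  d <- dim(x)
  out <- cpp_u2net_run(unclass(model$config), model$weights, model$running,
                       as.double(x), as.integer(d), as.double(y), TRUE)
  opt$t <- opt$t + 1L
  opt$m <- opt$beta1 * opt$m + (1 - opt$beta1) * out$grad
  opt$v <- opt$beta2 * opt$v + (1 - opt$beta2) * out$grad^2
  mhat <- opt$m / (1 - opt$beta1^opt$t)
  vhat <- opt$v / (1 - opt$beta2^opt$t)
  model$weights <- model$weights - lr * mhat / (sqrt(vhat) + opt$eps)
  model$running <- out$running
  list(model = model, opt = opt, loss = out$loss)
}

adam_state <- function(n, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = numeric(n), v = numeric(n), t = 0L,
       beta1 = beta1, beta2 = beta2, eps = eps)
}

#' Save / load a model checkpoint
#'
#' The checkpoint carries the configuration, weights, batch-norm running
#' statistics, training seed and history.
#'
#' @param model a [u2net()] model.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "u2net_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  class(obj$config) <- "u2net_config"
  structure(obj, class = "u2net_model")
}
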
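# The learning core: food-region input masking, segmentation pretraining of
# the feature extractor, Siamese pairwise-ranking training, and inference.

#' Mask an image to its food region
#'
#' Pixel-by-pixel multiplication of the image with a binary food mask: pixels
#' inside the food region are kept, everything else becomes exactly 0. All
#' channels are treated identically. Applied to inputs during training only;
#' a trained model scores unmasked images.
#'
#' @param image H x W x 3 array of intensities in `[0, 1]`.
#' @param mask H x W 0/1 matrix (1 = food).
#' @return The masked image array.
#' @examples
#' img <- array(runif(8 * 8 * 3), c(8, 8, 3))
#' all(apply_mask(img, matrix(0L, 8, 8)) == 0)
#' @export
apply_mask <- function(image, mask) {
  d <- dim(image)
  if (length(d) != 3 || !all(dim(mask) == d[1:2])) {
    abort("image (H x W x 3) and mask (H x W) dimensions do not match.")
  }
  image * as.numeric(array(mask, d))
}

#' Pairwise ranking loss
#'
#' For a pair oriented so item i is the ground-truth healthier one, the loss
#' of the score margin m = f_i - f_j is the logistic (RankNet) form
#' \deqn{L(m) = \log(1 + e^{-m}),} which is near 0 when the model orders the
#' pair correctly by a wide margin, equals log 2 at m = 0, and grows linearly
#' for badly reversed pairs. It satisfies L(m) - L(-m) = -m. A hinge
#' alternative `max(0, margin - m)` is available via `form = "hinge"`.
#' Both are evaluated with overflow guards, so |m| in the thousands is safe.
#'
#' @param f_i,f_j Numeric scores of the healthier and less healthy item
#'   (vectorized).
#' @param form `"logistic"` (default) or `"hinge"`.
#' @param margin Hinge margin (ignored for logistic).
#' @return Non-negative loss values.
#' @examples
#' pairwise_loss(0, 0)       # log(2)
#' pairwise_loss(10, 0)      # ~ 4.5e-5
#' @export
pairwise_loss <- function(f_i, f_j, form = c("logistic", "hinge"), margin = 1) {
  form <- match.arg(form)
  if (any(!is.finite(f_i)) || any(!is.finite(f_j))) {
    abort("pairwise_loss requires finite scores.")
  }
  m <- f_i - f_j
  if (form == "logistic") {
    pmax(-m, 0) + log1p(exp(-abs(m)))   # log(1 + e^-m) without overflow
  } else {
    pmax(0, margin - m)
  }
}

# dL/dm for both loss forms
.pairwise_loss_grad <- function(m, form, margin = 1) {
  if (form == "logistic") {
    -1 / (1 + exp(pmin(m, 700)))
  } else {
    -as.numeric(m < margin)
  }
}

.check_images <- function(meals, needs_mask = FALSE, needs_labels = FALSE) {
  stopifnot(is.data.frame(meals), all(c("id", "image") %in% names(meals)))
  if (needs_mask && !("mask" %in% names(meals))) {
    abort("This operation needs a 'mask' column.")
  }
  if (needs_labels && !("labels" %in% names(meals))) {
    abort("This operation needs a 'labels' column.")
  }
  invisible(meals)
}

#' Pretrain the feature extractor on per-pixel food classes
#'
#' Trains the convolutional extractor plus a temporary 1x1 per-pixel
#' classification head with per-pixel cross-entropy against the segmentation
#' labels (background / vegetable / fried / staple), at the feature-map
#' resolution (labels nearest-neighbor downsampled). The classification head
#' is kept on the returned object only to measure pixel accuracy; ranking
#' training uses the convolutional weights alone.
#'
#' @param meals Dataset tibble with `image` and `labels` columns
#'   (see [generate_meals()]).
#' @param config A [meal_config()]; uses `pretrain_epochs`, `batch_size`,
#'   `pretrain_learning_rate`, `conv_channels`, `n_classes`.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return An object of class `meal_extractor`.
#' @export
pretrain_extractor <- function(meals, config = meal_config(), seed = 1L) {
  .check_images(meals, needs_labels = TRUE)
  n <- nrow(meals)
  ylist <- lapply(meals$labels, function(l) as.integer(.downsample_map(l)) + 1L)
  classes <- sort(unique(unlist(ylist)))
  if (length(classes) < 2) {
    warn("Pretraining labels contain a single class; training proceeds but is degenerate.")
  }
  # inverse-frequency class weights: background dominates the pixel counts
  freq <- tabulate(unlist(ylist), nbins = config$n_classes)
  class_w <- ifelse(freq > 0, sum(freq) / (sum(freq > 0) * pmax(freq, 1)), 0)
  net <- .net_new(config, seed)
  opt <- .adam_init(net)
  history <- numeric(0)
  epochs <- config$pretrain_epochs
  bs <- config$batch_size
  if (epochs > 0) {
    withr::with_seed(as.integer(seed) + 1L, {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(n)
        losses <- numeric(0)
        for (start in seq(1, n, by = bs)) {
          take <- ord[start:min(start + bs - 1, n)]
          x <- .stack_images(meals$image[take])
          y <- unlist(ylist[take], use.names = FALSE)
          fw <- .net_pretrain_fwd(net, x)
          ce <- .softmax_ce(fw$logits, y, class_w)
          losses <- c(losses, ce$loss)
          dwp <- crossprod(fw$ft$a2, ce$dlogits)
          dbp <- colSums(ce$dlogits)
          da2 <- tcrossprod(ce$dlogits, net$wp)
          cg <- .net_features_bwd(net, da2, fw$ft$state)
          grads <- c(cg, list(dwp = dwp, dbp = dbp))
          upd <- .adam_step(net, grads, opt, config$pretrain_learning_rate)
          net <- upd$net; opt <- upd$opt
        }
        history <- c(history, mean(losses))
      }
    })
  }
  structure(list(net = net, config = config, seed = as.integer(seed),
                 history = history),
            class = "meal_extractor")
}

#' Per-pixel accuracy of a pretrained extractor
#'
#' @param extractor A `meal_extractor`.
#' @param meals Dataset tibble with `image` and `labels`.
#' @return Fraction of feature-map pixels classified correctly.
#' @export
pretrain_accuracy <- function(extractor, meals) {
  .check_images(meals, needs_labels = TRUE)
  acc_n <- 0; acc_d <- 0
  for (start in seq(1, nrow(meals), by = 64)) {
    take <- start:min(start + 63, nrow(meals))
    x <- .stack_images(meals$image[take])
    y <- unlist(lapply(meals$labels[take],
                       function(l) as.integer(.downsample_map(l)) + 1L))
    fw <- .net_pretrain_fwd(extractor$net, x)
    pred <- max.col(fw$logits, ties.method = "first")
    acc_n <- acc_n + sum(pred == y)
    acc_d <- acc_d + length(y)
  }
  acc_n / acc_d
}

#' Extract pooled feature vectors from a (pretrained) extractor
#'
#' Global-average-pooled convolutional features, used as the frozen
#' representation for the Rank-SVM baseline.
#'
#' @param meals Dataset tibble.
#' @param extractor A `meal_extractor` or `meal_ranker`.
#' @param masked Apply the food mask to inputs first.
#' @return A numeric matrix (items x channels) with row names = item ids.
#' @export
extract_features <- function(meals, extractor, masked = TRUE) {
  .check_images(meals, needs_mask = masked)
  net <- extractor$net
  out <- NULL
  for (start in seq(1, nrow(meals), by = 64)) {
    take <- start:min(start + 63, nrow(meals))
    imgs <- meals$image[take]
    if (masked) imgs <- Map(apply_mask, imgs, meals$mask[take])
    ft <- .net_features(net, .stack_images(imgs))
    pl <- .net_pool(ft$a2, ft$state)
    out <- rbind(out, pl$g)
  }
  rownames(out) <- meals$id
  out
}

#' Train the Siamese ranking network
#'
#' Two weight-shared copies of the scoring network evaluate each training
#' pair; the pairwise ranking loss of their score difference is minimized by
#' Adam over minibatches. With `mask_mode` on, training inputs are masked to
#' the food region ([apply_mask()]); inference never needs masks. With a
#' pretrained extractor, its convolutional weights initialize the feature
#' layers and training proceeds end to end.
#'
#' @param pairs Tibble with `healthier_id`, `less_healthy_id`
#'   (see [extract_pairs()]).
#' @param meals Dataset tibble with `image` (and `mask` if `mask_mode`).
#' @param config A [meal_config()].
#' @param extractor Optional `meal_extractor` for warm-starting.
#' @param seed Seed for initialization and batch shuffling.
#' @return A `meal_ranker` with a per-epoch training log (mean loss and the
#'   fraction of training pairs ordered correctly).
#' @export
train_ranking <- function(pairs, meals, config = meal_config(),
                          extractor = NULL, seed = 1L) {
  .check_images(meals, needs_mask = config$mask_mode)
  if (nrow(pairs) < 1) abort("Need at least one training pair.")
  missing <- setdiff(unique(c(pairs$healthier_id, pairs$less_healthy_id)),
                     meals$id)
  if (length(missing)) {
    abort(paste0("Pair(s) reference missing image(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  imgs <- meals$image
  pool_w_all <- NULL
  if (config$mask_mode && !config$mask_pool) {
    imgs <- Map(apply_mask, imgs, meals$mask)
  } else if (config$mask_mode && config$mask_pool) {
    pool_w_all <- lapply(meals$mask, function(m) as.numeric(.downsample_map(m)))
  }
  ii <- match(pairs$healthier_id, meals$id)
  jj <- match(pairs$less_healthy_id, meals$id)

  net <- .net_new(config, seed)
  if (!is.null(extractor)) {
    for (p in c("w1", "b1", "w2", "b2")) net[[p]] <- extractor$net[[p]]
  }
  opt <- .adam_init(net)
  np <- nrow(pairs)
  bs <- config$batch_size
  history <- NULL
  if (config$epochs > 0) {
    withr::with_seed(as.integer(seed) + 2L, {
      for (ep in seq_len(config$epochs)) {
        ord <- sample.int(np)
        losses <- c(); correct <- 0
        for (start in seq(1, np, by = bs)) {
          take <- ord[start:min(start + bs - 1, np)]
          p <- length(take)
          idx <- c(ii[take], jj[take])
          batch_imgs <- imgs[idx]
          if (config$augment_flips) {
            flip <- sample(c(TRUE, FALSE), 2 * p, replace = TRUE)
            batch_imgs <- Map(function(im, fl) {
              if (fl) im[, rev(seq_len(dim(im)[2])), , drop = FALSE] else im
            }, batch_imgs, flip)
          }
          x <- .stack_images(batch_imgs)
          pw <- if (is.null(pool_w_all)) NULL else
            matrix(unlist(pool_w_all[idx]), ncol = 2 * p)
          fw <- .net_score(net, x, pool_w = pw)
          m <- fw$f[seq_len(p)] - fw$f[p + seq_len(p)]
          losses <- c(losses, mean(pairwise_loss(fw$f[seq_len(p)],
                                                 fw$f[p + seq_len(p)],
                                                 form = config$loss,
                                                 margin = config$hinge_margin)))
          correct <- correct + sum(m > 0)
          dm <- .pairwise_loss_grad(m, config$loss, config$hinge_margin) / p
          df <- c(dm, -dm)
          grads <- .net_score_bwd(net, fw, df)
          upd <- .adam_step(net, grads, opt, config$learning_rate)
          net <- upd$net; opt <- upd$opt
        }
        history <- rbind(history, c(ep, mean(losses), correct / np))
      }
    })
  }
  history <- if (is.null(history)) {
    tibble::tibble(epoch = integer(), loss = numeric(), pair_accuracy = numeric())
  } else {
    tibble::tibble(epoch = as.integer(history[, 1]), loss = history[, 2],
                   pair_accuracy = history[, 3])
  }
  structure(list(net = net, config = config, history = history,
                 pretrained = !is.null(extractor), seed = as.integer(seed)),
            class = "meal_ranker")
}

#' Score a single image
#'
#' Deterministic scalar healthiness estimate f(x). No mask is needed at
#' inference time.
#'
#' @param model A `meal_ranker` (or `meal_extractor` sharing its head shape).
#' @param image H x W x 3 array matching the configured image size.
#' @return A single number (higher = estimated healthier).
#' @export
score_image <- function(model, image) {
  d <- dim(image)
  if (length(d) != 3 || d[1] != model$config$image_size ||
      d[2] != model$config$image_size || d[3] != 3) {
    abort(sprintf("Expected a %d x %d x 3 image.",
                  model$config$image_size, model$config$image_size))
  }
  fw <- .net_score(model$net, array(image, c(d, 1)))
  fw$f[1]
}

#' Score every meal in a dataset
#'
#' The network itself never requires a mask. When the dataset carries food
#' masks and the model was trained with masking, scoring defaults to the
#' food region (mask applied at the input), which keeps the scoring
#' distribution aligned with the training distribution; pass
#' `masked = FALSE` to score raw images.
#'
#' @param meals Dataset tibble with `id` and `image` (and `mask` when scoring
#'   masked).
#' @param model A `meal_ranker`.
#' @param masked Apply stored food masks before scoring. Default: the
#'   model's own `mask_mode` if masks are available, otherwise `FALSE`.
#' @return A tibble with `item_id` and `raw` (the network output f(x)).
#' @export
score_meals <- function(meals, model, masked = NULL) {
  .check_images(meals)
  masked <- masked %||% (isTRUE(model$config$mask_mode) && "mask" %in% names(meals))
  if (masked && !("mask" %in% names(meals))) {
    abort("masked scoring requested but the dataset has no 'mask' column.")
  }
  raw <- numeric(nrow(meals))
  for (start in seq(1, nrow(meals), by = 64)) {
    take <- start:min(start + 63, nrow(meals))
    imgs <- meals$image[take]
    if (masked) imgs <- Map(apply_mask, imgs, meals$mask[take])
    fw <- .net_score(model$net, .stack_images(imgs))
    raw[take] <- fw$f
  }
  tibble::tibble(item_id = meals$id, raw = raw)
}

#' @export
predict.meal_ranker <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) return(score_meals(newdata, object)$raw)
  if (is.array(newdata) && length(dim(newdata)) == 3) {
    return(score_image(object, newdata))
  }
  abort("newdata must be a meals tibble or a single image array.")
}

#' @export
print.meal_ranker <- function(x, ...) {
  acc <- if (nrow(x$history)) sprintf("%.3f", utils::tail(x$history$pair_accuracy, 1)) else "NA"
  cat(sprintf("<meal_ranker> %d epochs, final training pair accuracy %s, %s\n",
              nrow(x$history), acc,
              if (x$pretrained) "pretrained extractor" else "random init"))
  invisible(x)
}

#' Tidy the training history of a ranking model
#'
#' @param x A `meal_ranker`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `pair_accuracy`.
#' @method tidy meal_ranker
#' @export
tidy.meal_ranker <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x A `meal_ranker`.
#' @param ... Unused.
#' @return Tibble with epochs trained, final loss, final training pair
#'   accuracy, masking/pretraining flags and parameter count.
#' @method glance meal_ranker
#' @export
glance.meal_ranker <- function(x, ...) {
  n_par <- sum(vapply(.net_par_names(), function(p) length(x$net[[p]]), numeric(1)))
  tibble::tibble(
    epochs = nrow(x$history),
    final_loss = if (nrow(x$history)) utils::tail(x$history$loss, 1) else NA_real_,
    train_pair_accuracy = if (nrow(x$history)) utils::tail(x$history$pair_accuracy, 1) else NA_real_,
    mask_mode = x$config$mask_mode,
    pretrained = x$pretrained,
    n_parameters = n_par
  )
}

#' Save / load a ranking model
#'
#' Weights are serialized to JSON (text) with a config sidecar block, so
#' checkpoints are portable and diffable.
#'
#' @param model A `meal_ranker`.
#' @param path File path (`.json`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  pars <- .net_par_names()
  payload <- list(
    weights = lapply(stats::setNames(pars, pars), function(p) model$net[[p]]),
    config = unclass(model$config),
    seed = model$seed,
    pretrained = model$pretrained,
    history = model$history
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_fields <- lapply(payload$config, function(v) if (is.list(v)) unlist(v) else v)
  config <- do.call(meal_config, cfg_fields)
  net <- payload$weights
  for (p in c("w1", "w2", "wp", "wf1", "wf2")) net[[p]] <- as.matrix(net[[p]])
  for (p in c("b1", "b2", "bp", "bf1", "bf2")) net[[p]] <- as.numeric(net[[p]])
  net$config <- config
  structure(list(net = net, config = config,
                 history = tibble::as_tibble(payload$history),
                 pretrained = isTRUE(payload$pretrained),
                 seed = payload$seed),
            class = "meal_ranker")
}
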
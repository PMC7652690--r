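# Evaluation suite: pairwise error E_p, order error E_o, rank correlations,
# Bland-Altman agreement, ROC-based unhealthy-meal detection, the Rank-SVM
# baseline on frozen features, and the masking/pretraining ablation grid.

# Accept either (data, truth_col, estimate_col) tidy-eval style or two bare
# numeric vectors; returns aligned truth/estimate plus item ids for
# deterministic tie-breaking.
.two_cols <- function(data, truth, estimate) {
  if (is.data.frame(data)) {
    tq <- eval_tidy(enquo(truth), data)
    eq <- eval_tidy(enquo(estimate), data)
    ids <- data$item_id %||% data$id %||% as.character(seq_len(nrow(data)))
  } else {
    tq <- data
    eq <- estimate
    ids <- as.character(seq_along(tq))
  }
  if (length(tq) != length(eq)) abort("truth and estimate lengths differ.")
  list(truth = as.numeric(tq), estimate = as.numeric(eq), ids = as.character(ids))
}

#' Pairwise comparison error rate E_p
#'
#' Over all unordered pairs whose reference scores differ strictly, the
#' fraction whose estimated order contradicts the reference order.
#' Reference-tied pairs are excluded from the pair set; estimated ties count
#' as errors.
#'
#' @param data Tibble containing the two score columns, or a numeric truth
#'   vector.
#' @param truth,estimate Column names (tidy-eval) when `data` is a tibble,
#'   otherwise `estimate` is the second numeric vector.
#' @return E_p in `[0, 1]`.
#' @examples
#' pairwise_error(c(3, 2, 1), estimate = c(2, 1, 3))  # 2/3
#' @export
pairwise_error <- function(data, truth = NULL, estimate = NULL) {
  v <- .two_cols(data, {{ truth }}, {{ estimate }})
  n <- length(v$truth)
  if (n < 2) abort("Need at least 2 items.")
  ut <- upper.tri(matrix(0, n, n))
  dt <- outer(v$truth, v$truth, "-")[ut]
  de <- outer(v$estimate, v$estimate, "-")[ut]
  strict <- dt != 0
  if (!any(strict)) abort("All reference scores are tied; E_p is undefined.")
  1 - mean(sign(de[strict]) == sign(dt[strict]))
}

# order vector: position after sorting scores descending, ties broken by id
.order_vector <- function(scores, ids) {
  o <- integer(length(scores))
  o[order(-scores, ids)] <- seq_along(scores)
  o
}

#' Average order error E_o
#'
#' Both score vectors are converted to orderings (1 = healthiest, sorted
#' descending, ties broken deterministically by item id); E_o is the mean
#' absolute difference between an item's two positions.
#'
#' @inheritParams pairwise_error
#' @return E_o (>= 0, in units of rank positions).
#' @examples
#' order_error(c(3, 2, 1), estimate = c(1, 2, 3))  # 4/3
#' @export
order_error <- function(data, truth = NULL, estimate = NULL) {
  v <- .two_cols(data, {{ truth }}, {{ estimate }})
  mean(abs(.order_vector(v$estimate, v$ids) - .order_vector(v$truth, v$ids)))
}

#' Rank correlations between estimated and reference scores
#'
#' `pearson_ranks` is the Pearson correlation of the two (tie-broken,
#' mean-0 / unit-variance normalized) order vectors; `spearman` is the
#' Spearman correlation of the raw scores with average-rank ties. Both are
#' reported because "the correlation of the rankings" is ambiguous between
#' them.
#'
#' @inheritParams pairwise_error
#' @return A one-row tibble with `pearson_ranks` and `spearman`.
#' @export
rank_correlations <- function(data, truth = NULL, estimate = NULL) {
  v <- .two_cols(data, {{ truth }}, {{ estimate }})
  if (length(v$truth) < 3) abort("Need at least 3 items.")
  if (sd(v$truth) == 0 || sd(v$estimate) == 0) {
    abort("Zero variance in scores; correlation undefined.")
  }
  tibble::tibble(
    pearson_ranks = cor(.order_vector(v$truth, v$ids),
                        .order_vector(v$estimate, v$ids)),
    spearman = cor(v$truth, v$estimate, method = "spearman")
  )
}

#' Combined ranking evaluation
#'
#' One-row report with E_p, E_o and both rank correlations.
#'
#' @inheritParams pairwise_error
#' @return A one-row tibble.
#' @export
evaluate_ranking <- function(data, truth = NULL, estimate = NULL) {
  v <- .two_cols(data, {{ truth }}, {{ estimate }})
  df <- tibble::tibble(item_id = v$ids, truth = v$truth, estimate = v$estimate)
  dplyr::bind_cols(
    tibble::tibble(E_p = pairwise_error(df, truth, estimate),
                   E_o = order_error(df, truth, estimate)),
    rank_correlations(df, truth, estimate)
  )
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements `a` and `b`: bias = mean(a - b), limits of
#' agreement = bias +- 1.96 SD(a - b), and the proportional-bias slope = the
#' least-squares slope of the differences on the pair means. A slope (or
#' bias) indistinguishable from 0 indicates no proportional (or fixed) bias.
#'
#' @param data Tibble containing the two columns, or a numeric vector `a`.
#' @param a,b Column names (tidy-eval) or the second numeric vector.
#' @return A one-row tibble of class `meal_bland_altman` with `bias`,
#'   `loa_lower`, `loa_upper`, `slope`.
#' @examples
#' bland_altman(c(1, 2, 3), b = c(1, 2, 5))$bias  # -2/3
#' @export
bland_altman <- function(data, a = NULL, b = NULL) {
  if (is.data.frame(data)) {
    av <- eval_tidy(enquo(a), data)
    bv <- eval_tidy(enquo(b), data)
  } else {
    av <- data
    bv <- b
  }
  if (length(av) != length(bv)) abort("a and b must have equal length.")
  if (length(av) < 3) abort("Need at least 3 paired observations.")
  d <- av - bv
  m <- (av + bv) / 2
  s <- sd(d)
  slope <- if (sd(m) == 0) 0 else unname(coef(lm(d ~ m))[2])
  out <- tibble::tibble(bias = mean(d), loa_lower = mean(d) - 1.96 * s,
                        loa_upper = mean(d) + 1.96 * s, slope = slope)
  attr(out, "diffs") <- d
  attr(out, "means") <- m
  class(out) <- c("meal_bland_altman", class(out))
  out
}

#' @method autoplot meal_bland_altman
#' @export
autoplot.meal_bland_altman <- function(object, ...) {
  df <- tibble::tibble(mean = attr(object, "means"), diff = attr(object, "diffs"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, color = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "mean of pair", y = "difference",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Unhealthy-meal detection evaluation
#'
#' An item is predicted unhealthy when its score falls below the threshold
#' (s < Th). The ROC curve is traced by sweeping the threshold over the
#' midpoints between consecutive distinct scores plus the two infinities
#' (bit-reproducible staircase); AUC is the trapezoidal area.
#'
#' @param data Tibble containing the columns, or a logical truth vector
#'   (`TRUE` = unhealthy).
#' @param truth,estimate Column names (tidy-eval) or the score vector.
#' @param th Decision threshold; if `NULL`, derived as the `k`-th percentile
#'   of the scores.
#' @param k Percent defining the screening quantile when `th` is `NULL`.
#' @return A list of class `meal_detection`: `accuracy`, `auc`, `th`, `roc`
#'   (tibble `threshold`, `fpr`, `tpr`).
#' @examples
#' d <- detection_eval(c(TRUE, TRUE, FALSE, FALSE), estimate = 1:4, th = 2.5)
#' d$accuracy
#' @export
detection_eval <- function(data, truth = NULL, estimate = NULL, th = NULL,
                           k = NULL) {
  if (is.data.frame(data)) {
    lab <- as.logical(eval_tidy(enquo(truth), data))
    sc <- as.numeric(eval_tidy(enquo(estimate), data))
  } else {
    lab <- as.logical(data)
    sc <- as.numeric(estimate)
  }
  if (length(lab) != length(sc)) abort("labels and scores lengths differ.")
  if (is.null(th)) {
    if (is.null(k)) abort("Provide a threshold th or a quantile k.")
    th <- unname(quantile(sc, k / 100, type = 7))
  }
  pred <- sc < th
  accuracy <- mean(pred == lab)
  roc <- NULL
  auc <- NA_real_
  if (length(unique(lab)) < 2) {
    warn("Single-class labels: ROC/AUC undefined, accuracy still reported.")
  } else {
    u <- sort(unique(sc))
    thresholds <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
                    Inf)
    # include points between every distinct score; ensure staircase endpoints
    thresholds <- c(thresholds[1], u[1] - 1, thresholds[-1], u[length(u)] + 1)
    thresholds <- sort(unique(thresholds))
    fpr <- vapply(thresholds, function(t) mean(sc[!lab] < t), numeric(1))
    tpr <- vapply(thresholds, function(t) mean(sc[lab] < t), numeric(1))
    roc <- tibble::tibble(threshold = thresholds, fpr = fpr, tpr = tpr)
    auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  }
  structure(list(accuracy = accuracy, auc = auc, th = th, roc = roc),
            class = "meal_detection")
}

#' @export
print.meal_detection <- function(x, ...) {
  cat(sprintf("<meal_detection> accuracy %.3f at Th = %.3f, AUC %s\n",
              x$accuracy, x$th,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' @method autoplot meal_detection
#' @export
autoplot.meal_detection <- function(object, ...) {
  if (is.null(object$roc)) abort("No ROC available (single-class labels).")
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("Unhealthy-meal detection ROC (AUC %.3f)",
                                  object$auc)) +
    ggplot2::theme_minimal()
}

#' Rank-SVM baseline on frozen features
#'
#' Joachims-style pairwise ranking: a linear scorer w phi(x) fit on the
#' feature-difference vectors of the training pairs with an L2-regularized
#' squared-hinge objective
#' \deqn{\tfrac12 \lVert w\rVert^2 + C \sum_k \max(0, 1 - w^\top d_k)^2,}
#' minimized with L-BFGS from w = 0 (deterministic). Features are
#' standardized internally.
#'
#' @param features Numeric matrix (items x feature dims) with item ids as row
#'   names; see [extract_features()].
#' @param pairs Training pairs tibble (`healthier_id`, `less_healthy_id`).
#' @param cost Regularization constant C.
#' @return An object of class `meal_ranksvm`; use `predict(model, features)`
#'   for scores.
#' @export
ranksvm_baseline <- function(features, pairs, cost = 1) {
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  if (nrow(pairs) < 1) abort("Need at least one training pair.")
  ctr <- colMeans(features)
  scl <- apply(features, 2, sd)
  if (any(scl == 0)) {
    warn("Degenerate (zero-variance) feature dimension(s); left unscaled.")
    scl[scl == 0] <- 1
  }
  fs <- sweep(sweep(features, 2, ctr), 2, scl, "/")
  di <- fs[pairs$healthier_id, , drop = FALSE] -
    fs[pairs$less_healthy_id, , drop = FALSE]
  obj <- function(w) {
    m <- drop(di %*% w)
    viol <- pmax(0, 1 - m)
    0.5 * sum(w^2) + cost * sum(viol^2)
  }
  grad <- function(w) {
    m <- drop(di %*% w)
    viol <- pmax(0, 1 - m)
    w - 2 * cost * drop(crossprod(di, viol))
  }
  fit <- optim(numeric(ncol(features)), obj, grad, method = "L-BFGS-B",
               control = list(maxit = 500))
  structure(list(w = fit$par, center = ctr, scale = scl, cost = cost,
                 converged = fit$convergence == 0),
            class = "meal_ranksvm")
}

#' @export
predict.meal_ranksvm <- function(object, newdata, ...) {
  fs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  drop(fs %*% object$w)
}

#' Ablation grid over masking, pretraining and ranking method
#'
#' Trains and evaluates each condition with a shared item split, shared
#' seeds, and identical test items: the four CNN conditions (masking x
#' pretraining) plus Rank-SVM on the frozen pretrained features. Evaluation
#' can use re-rendered test images (`eval_meals`, e.g. from
#' [shuffle_backgrounds()]) so background shortcuts learned during training
#' stop working at test time.
#'
#' @param meals Training dataset tibble from [generate_meals()].
#' @param ranking Reference ranking tibble (`item_id`, `rank`).
#' @param config A [meal_config()].
#' @param seeds Integer vector; the whole grid is repeated per seed.
#' @param eval_meals Dataset used for test-time images (default `meals`).
#' @param conditions Optional tibble (`mask`, `pretrain`, `method`) to
#'   override the default 5-condition grid.
#' @return A tibble of class `meal_ablation`: one row per condition x seed
#'   with `E_p`, `E_o`, `spearman`, `detection_accuracy`, `auc`.
#' @export
run_ablation_grid <- function(meals, ranking, config = meal_config(),
                              seeds = 1L, eval_meals = NULL,
                              conditions = NULL) {
  conditions <- conditions %||% tibble::tibble(
    mask = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    pretrain = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    method = c("cnn", "cnn", "cnn", "cnn", "ranksvm")
  )
  eval_meals <- eval_meals %||% meals
  ref_score <- -ranking$rank  # higher = healthier
  names(ref_score) <- ranking$item_id
  rows <- list()
  for (seed in seeds) {
    pairs <- extract_pairs(ranking, max_pairs = config$max_pairs,
                           seed = stage_seed(seed, "pairs"))
    sp <- split_dataset(pairs, ranking, config$train_fraction,
                        seed = stage_seed(seed, "split"))
    train_meals <- meals[meals$id %in% sp$train_items, ]
    test_meals <- eval_meals[eval_meals$id %in% sp$test_items, ]
    extractor <- NULL
    if (any(conditions$pretrain)) {
      extractor <- pretrain_extractor(train_meals, config,
                                      seed = stage_seed(seed, "pretrain"))
    }
    for (ci in seq_len(nrow(conditions))) {
      cond <- conditions[ci, ]
      cfg <- config
      cfg$mask_mode <- cond$mask
      cfg$pretrain_mode <- cond$pretrain
      if (cond$method == "cnn") {
        model <- train_ranking(sp$train_pairs, train_meals, cfg,
                               extractor = if (cond$pretrain) extractor,
                               seed = stage_seed(seed, "train"))
        est <- score_meals(test_meals, model, masked = cond$mask)
      } else {
        feats <- extract_features(meals, extractor, masked = cond$mask)
        svm <- ranksvm_baseline(feats[sp$train_items, , drop = FALSE],
                                sp$train_pairs)
        test_feats <- extract_features(test_meals, extractor,
                                       masked = cond$mask)
        est <- tibble::tibble(item_id = test_meals$id,
                              raw = predict(svm, test_feats))
      }
      df <- tibble::tibble(item_id = est$item_id,
                           truth = unname(ref_score[est$item_id]),
                           estimate = est$raw)
      ev <- evaluate_ranking(df, truth, estimate)
      n <- nrow(df)
      o_ref <- .order_vector(df$truth, df$item_id)
      unhealthy <- o_ref > n - floor(config$screen_k * n / 100)
      dev <- deviation_scores(tibble::tibble(item_id = df$item_id,
                                             raw = df$estimate))
      th <- threshold_for_quantile(dev$s, config$screen_k)
      det <- detection_eval(unhealthy, estimate = dev$s, th = th)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(seed = seed, mask = cond$mask,
                       pretrain = cond$pretrain, method = cond$method),
        ev,
        tibble::tibble(detection_accuracy = det$accuracy, auc = det$auc,
                       n_test = n)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("meal_ablation", class(out))
  out
}

#' Summarize an ablation grid across seeds
#'
#' @param x A `meal_ablation`.
#' @param ... Unused.
#' @return One row per condition with seed-averaged metrics.
#' @method glance meal_ablation
#' @export
glance.meal_ablation <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$mask, .data$pretrain, .data$method),
    dplyr::across(c("E_p", "E_o", "spearman", "detection_accuracy", "auc"),
                  mean),
    n_seeds = dplyr::n(), .groups = "drop"
  )
}
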
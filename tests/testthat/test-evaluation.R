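# Evaluation metrics: E_p, E_o, rank correlations, Bland-Altman, detection,
# Rank-SVM baseline.

test_that("pairwise error matches hand-enumerated cases", {
  expect_equal(pairwise_error(c(4, 3, 2, 1), estimate = c(8, 7, 6, 5)), 0)
  expect_equal(pairwise_error(c(4, 3, 2, 1), estimate = c(1, 2, 3, 4)), 1)
  expect_equal(pairwise_error(c(3, 2, 1), estimate = c(2, 1, 3)), 2 / 3)
  # reference-tied pairs leave the pair set; estimated ties count as errors
  expect_equal(pairwise_error(c(2, 2, 1), estimate = c(5, 4, 3)), 0)
  expect_equal(pairwise_error(c(2, 1), estimate = c(4, 4)), 1)
  expect_error(pairwise_error(c(1, 1, 1), estimate = c(1, 2, 3)), "tied")
})

test_that("order error matches enumeration and its closed forms", {
  expect_equal(order_error(c(3, 2, 1), estimate = c(3, 2, 1)), 0)
  expect_equal(order_error(c(3, 2, 1), estimate = c(1, 2, 3)), 4 / 3)
  for (n in c(4, 10, 20)) {   # full reversal of n items: E_o = n/2 for even n
    expect_equal(order_error(seq_len(n), estimate = rev(seq_len(n))), n / 2)
  }
})

test_that("metrics equal brute-force oracles on random instances", {
  withr::with_seed(17, {
    for (case in 1:200) {
      n <- sample(3:8, 1)
      truth <- sample(1:4, n, replace = TRUE)   # ties likely
      if (length(unique(truth)) < 2) truth[1] <- truth[1] + 1L
      est <- rnorm(n)
      df <- tibble::tibble(item_id = sprintf("%02d", seq_len(n)),
                           truth = truth, estimate = est)
      expect_equal(pairwise_error(df, truth, estimate),
                   brute_pairwise_error(truth, est))
      expect_equal(order_error(df, truth, estimate),
                   brute_order_error(truth, est, df$item_id))
    }
  })
})

test_that("E_o is tie-break independent on tie-free data", {
  withr::with_seed(23, {
    truth <- rnorm(12); est <- rnorm(12)
    ids_a <- sprintf("a%02d", 1:12)
    ids_b <- sprintf("b%02d", sample(1:12))  # different id ordering
    ea <- order_error(tibble::tibble(item_id = ids_a, truth = truth,
                                     estimate = est), truth, estimate)
    eb <- order_error(tibble::tibble(item_id = ids_b, truth = truth,
                                     estimate = est), truth, estimate)
    expect_equal(ea, eb)
  })
})

test_that("rank correlations behave at the extremes and on the 3-item case", {
  x <- c(5, 3, 1, 0.5)
  expect_equal(rank_correlations(x, estimate = x * 2 + 1)$spearman, 1)
  expect_equal(rank_correlations(x, estimate = -x)$spearman, -1)
  expect_equal(rank_correlations(x, estimate = -x)$pearson_ranks, -1)
  expect_equal(rank_correlations(c(1, 2, 3), estimate = c(1, 3, 2))$spearman, 0.5)
  expect_error(rank_correlations(c(1, 1, 1), estimate = c(1, 2, 3)),
               "Zero variance")
})

test_that("E_p = 0 exactly when Spearman = 1 on tie-free data", {
  withr::with_seed(31, {
    for (case in 1:20) {
      truth <- rnorm(10)
      est <- if (case %% 2) truth else rnorm(10)
      ep <- pairwise_error(truth, estimate = est)
      rho <- rank_correlations(truth, estimate = est)$spearman
      expect_equal(ep == 0, abs(rho - 1) < 1e-12)
    }
  })
})

test_that("Bland-Altman agrees with hand arithmetic", {
  same <- bland_altman(c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_lower, same$loa_upper), c(0, 0))
  expect_equal(same$slope, 0)
  shift <- bland_altman(c(1, 2, 3), b = c(2, 3, 4))   # b = a + 1
  expect_equal(shift$bias, -1)
  expect_equal(bland_altman(c(1, 2, 3), b = c(1, 2, 5))$bias, -2 / 3)
  expect_error(bland_altman(1:3, b = 1:4), "equal length")
})

test_that("detection handles separation, thresholds and ROC validity", {
  d <- detection_eval(c(TRUE, TRUE, FALSE, FALSE), estimate = c(1, 2, 3, 4),
                      th = 2.5)
  expect_equal(d$accuracy, 1)
  expect_equal(d$auc, 1)
  expect_true(all(diff(d$roc$fpr) >= 0))
  expect_true(all(diff(d$roc$tpr) >= 0))
  expect_equal(d$roc$fpr[1], 0); expect_equal(d$roc$tpr[1], 0)
  expect_equal(dplyr::last(d$roc$fpr), 1); expect_equal(dplyr::last(d$roc$tpr), 1)

  # accuracy at a sweep threshold equals 1 - (FP n_neg + (1 - TP) n_pos) / n
  withr::with_seed(41, {
    lab <- rbinom(40, 1, 0.5) == 1
    sc <- rnorm(40)
    sweep_th <- detection_eval(lab, estimate = sc, th = 0)$roc$threshold
    for (i in c(5, 15, 25)) {
      d2 <- detection_eval(lab, estimate = sc, th = sweep_th[i])
      fp <- d2$roc$fpr[i]; tp <- d2$roc$tpr[i]
      n_pos <- sum(lab); n_neg <- sum(!lab)
      expect_equal(d2$accuracy,
                   1 - (fp * n_neg + (1 - tp) * n_pos) / 40, tolerance = 1e-12)
    }
  })

  expect_warning(d3 <- detection_eval(rep(TRUE, 4), estimate = 1:4, th = 2),
                 "Single-class")
  expect_true(is.na(d3$auc))
  expect_equal(d3$accuracy, 0.25)
})

test_that("our staircase ROC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(43, {
    lab <- rbinom(60, 1, 0.4) == 1
    sc <- rnorm(60) - lab  # unhealthy meals score lower
    ours <- detection_eval(lab, estimate = sc, th = 0)
    ref <- pROC::roc(response = lab, predictor = sc, direction = ">",
                     quiet = TRUE)
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  })
})

test_that("label-permuted scores give chance-level AUC", {
  withr::with_seed(47, {
    sc <- rnorm(100)
    lab <- rep(c(TRUE, FALSE), 50)
    aucs <- vapply(1:100, function(k) {
      detection_eval(sample(lab), estimate = sc, th = 0)$auc
    }, numeric(1))
    expect_equal(mean(aucs), 0.5, tolerance = 0.05)
  })
})

test_that("Rank-SVM recovers monotone and anti-monotone 1-D features", {
  lat <- seq(0, 1, length.out = 10)
  ids <- sprintf("m%02d", 1:10)
  ranking <- tibble::tibble(item_id = ids, rank = sort_ranks(lat))
  pairs <- extract_pairs(ranking)
  feats <- matrix(lat, ncol = 1, dimnames = list(ids, NULL))
  m <- ranksvm_baseline(feats, pairs)
  expect_gt(m$w[1], 0)
  expect_equal(pairwise_error(lat, estimate = predict(m, feats)), 0)
  m2 <- ranksvm_baseline(-feats, pairs)
  expect_lt(m2$w[1], 0)
  expect_equal(pairwise_error(lat, estimate = predict(m2, -feats)), 0)
  expect_warning(
    ranksvm_baseline(cbind(feats, 1), pairs), "zero-variance"
  )
})
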
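# Masking, the network core, pretraining and Siamese ranking training.

test_that("apply_mask is pixel-by-pixel multiplication", {
  withr::with_seed(3, {
    img <- array(runif(12 * 12 * 3), c(12, 12, 3))
    ones <- matrix(1L, 12, 12)
    zeros <- matrix(0L, 12, 12)
    expect_identical(apply_mask(img, ones), img * 1)
    expect_true(all(apply_mask(img, zeros) == 0))
    m <- matrix(rbinom(144, 1, 0.5), 12, 12)
    other <- array(runif(12 * 12 * 3), c(12, 12, 3))
    mixed <- img
    mixed[as.logical(array(1 - m, dim(img)))] <-
      other[as.logical(array(1 - m, dim(img)))]
    # two images equal wherever mask = 1 mask to identical outputs
    expect_identical(apply_mask(img, m), apply_mask(mixed, m))
    expect_error(apply_mask(img, matrix(1, 5, 5)), "do not match")
  })
})

test_that("network gradients match finite differences", {
  cfg <- meal_config(image_size = 16L, conv_channels = c(4L, 6L), fc_hidden = 5L)
  net <- mealrank:::.net_new(cfg, 7)
  withr::with_seed(2, {
    x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
    wts <- c(0.7, -1.2)
    fw <- mealrank:::.net_score(net, x)
    g <- mealrank:::.net_score_bwd(net, fw, wts)
    fd <- function(par, idx) {
      eps <- 1e-6
      up <- net; up[[par]][idx] <- up[[par]][idx] + eps
      dn <- net; dn[[par]][idx] <- dn[[par]][idx] - eps
      (sum(mealrank:::.net_score(up, x)$f * wts) -
         sum(mealrank:::.net_score(dn, x)$f * wts)) / (2 * eps)
    }
    for (par in c("w1", "b1", "w2", "b2", "wf1", "bf1", "wf2", "bf2")) {
      for (idx in sample(length(net[[par]]), min(3, length(net[[par]])))) {
        expect_equal(g[[paste0("d", par)]][idx], fd(par, idx),
                     tolerance = 1e-5)
      }
    }
  })
})

test_that("pretraining learns per-pixel food classes on held-out scenes", {
  cfg <- small_config()
  meals <- generate_meals(70, cfg, seed = 201)
  ex <- pretrain_extractor(meals[1:55, ], cfg, seed = 202)
  held <- meals[56:70, ]
  acc <- pretrain_accuracy(ex, held)
  expect_gte(acc, 0.90)
  # must beat the majority-class (background) baseline, i.e. learn food classes
  baseline <- max(prop.table(table(unlist(
    lapply(held$labels, mealrank:::.downsample_map)))))
  expect_gt(acc, baseline)
})

test_that("zero pretraining epochs is a no-op and seeds fix the weights", {
  cfg <- tiny_config(pretrain_epochs = 0L)
  meals <- generate_meals(6, cfg, seed = 77)
  ex0 <- pretrain_extractor(meals, cfg, seed = 5)
  init <- mealrank:::.net_new(cfg, 5)
  expect_identical(ex0$net$w1, init$w1)
  expect_identical(ex0$net$w2, init$w2)

  cfg1 <- tiny_config(pretrain_epochs = 1L)
  ex_a <- pretrain_extractor(meals, cfg1, seed = 6)
  ex_b <- pretrain_extractor(meals, cfg1, seed = 6)
  expect_identical(ex_a$net, ex_b$net)
})

test_that("degenerate single-class labels warn but still train", {
  cfg <- tiny_config(pretrain_epochs = 1L)
  meals <- generate_meals(4, cfg, seed = 3)
  meals$labels <- lapply(meals$labels, function(l) l * 0L)
  expect_warning(pretrain_extractor(meals, cfg, seed = 1), "single class")
})

test_that("training separates a noiseless synthetic ranking task", {
  fx <- cached_masked_model()
  # verified level for this reduced fixture (32 px, 60 items, 6 epochs);
  # the full-scale benchmark in the acceptance suite reaches ~0.94
  expect_gte(dplyr::last(fx$model$history$pair_accuracy), 0.85)
  # epoch-mean loss on separable data decreases over training
  expect_lt(dplyr::last(fx$model$history$loss), fx$model$history$loss[1])
})

test_that("an untrained model scores orientation-balanced pairs at chance", {
  cfg <- tiny_config(epochs = 0L)
  meals <- generate_meals(16, cfg, seed = 91)
  pairs <- extract_pairs(tibble::tibble(item_id = meals$id, rank = 1:16))
  model <- train_ranking(pairs[1, ], meals, cfg, seed = 9)  # 0 epochs: init only
  f <- stats::setNames(score_meals(meals, model, masked = FALSE)$raw, meals$id)
  balanced <- rbind(pairs,
                    stats::setNames(pairs[, 2:1], names(pairs)))
  acc <- mean(f[balanced$healthier_id] > f[balanced$less_healthy_id])
  expect_equal(acc, 0.5, tolerance = 1e-9)
})

test_that("Siamese branches share weights: batch and single scores agree", {
  fx <- cached_masked_model()
  meals <- fx$meals[1:5, ]
  batch <- score_meals(meals, fx$model, masked = FALSE)$raw
  single <- vapply(meals$image, function(im) score_image(fx$model, im),
                   numeric(1))
  expect_equal(batch, single, tolerance = 1e-10)
  # inference determinism, bit for bit
  expect_identical(score_image(fx$model, meals$image[[1]]),
                   score_image(fx$model, meals$image[[1]]))
})

test_that("masked training scores identical masked inputs identically", {
  fx <- cached_masked_model()
  sc <- meal_scene(list(meal_dish(c(14, 20), 6, 0.7, 0.1, 0.2)),
                   background_id = 1, image_size = 32)
  r1 <- render_scene(sc, seed = 1, config = fx$config)
  sc$background_id <- 3
  r2 <- render_scene(sc, seed = 999, config = fx$config)
  m1 <- apply_mask(r1$image, r1$mask)
  m2 <- apply_mask(r2$image, r2$mask)
  expect_identical(score_image(fx$model, m1), score_image(fx$model, m2))
})

test_that("training validates its inputs", {
  cfg <- tiny_config()
  meals <- generate_meals(4, cfg, seed = 2)
  bad <- tibble::tibble(healthier_id = "nope", less_healthy_id = meals$id[1])
  expect_error(train_ranking(bad, meals, cfg), "missing image")
  expect_error(train_ranking(bad[0, ], meals, cfg), "at least one")
  expect_error(score_image(cached_masked_model()$model,
                           array(0, c(8, 8, 3))), "Expected")
})

test_that("models round-trip through the JSON checkpoint", {
  fx <- cached_masked_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fx$model, path)
  back <- load_model(path)
  expect_equal(score_meals(fx$meals[1:3, ], back)$raw,
               score_meals(fx$meals[1:3, ], fx$model)$raw, tolerance = 1e-12)
  expect_identical(back$config$mask_mode, fx$model$config$mask_mode)
  expect_equal(glance(back)$train_pair_accuracy,
               glance(fx$model)$train_pair_accuracy)
})

test_that("training with the same seed reproduces the same model", {
  cfg <- tiny_config(epochs = 2L)
  meals <- generate_meals(10, cfg, seed = 51)
  pairs <- extract_pairs(tibble::tibble(item_id = meals$id, rank = 1:10),
                         max_pairs = 20, seed = 1)
  m1 <- train_ranking(pairs, meals, cfg, seed = 8)
  m2 <- train_ranking(pairs, meals, cfg, seed = 8)
  expect_identical(m1$net, m2$net)
})
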
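# Shared fixtures: all synthetic, generated in code at test time.

# small-image config used by unit tests (fast; the acceptance benchmark uses
# the full 64 px defaults)
tiny_config <- function(...) {
  meal_config(image_size = 16L, dish_radius_range = c(3, 5),
              dish_count_range = c(1L, 2L), conv_channels = c(6L, 8L),
              fc_hidden = 8L, epochs = 4L, pretrain_epochs = 8L,
              learning_rate = 3e-3, max_pairs = 200L, ...)
}

small_config <- function(...) {
  meal_config(image_size = 32L, dish_radius_range = c(4, 7),
              dish_count_range = c(1L, 3L), conv_channels = c(8L, 12L),
              fc_hidden = 16L, epochs = 8L, learning_rate = 3e-3,
              max_pairs = 400L, ...)
}

# independent oracle: competition ranks from a plain comparison sort
sort_ranks <- function(latents) {
  as.integer(rank(-latents, ties.method = "min"))
}

# independent oracle: brute-force E_p by looping over all pairs
brute_pairwise_error <- function(truth, estimate) {
  n <- length(truth)
  total <- 0L; wrong <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (truth[i] == truth[j]) next
    total <- total + 1L
    agree <- (truth[i] - truth[j]) * (estimate[i] - estimate[j]) > 0
    if (!agree) wrong <- wrong + 1L
  }
  wrong / total
}

# independent oracle: brute-force E_o with the same declared id tie-break
brute_order_error <- function(truth, estimate, ids = as.character(seq_along(truth))) {
  pos <- function(s) {
    o <- integer(length(s))
    o[order(-s, ids)] <- seq_along(s)
    o
  }
  mean(abs(pos(estimate) - pos(truth)))
}

# independent oracle: pixel count of a rasterized disc
brute_disc_pixels <- function(center, radius, size) {
  count <- 0L
  for (r in 1:size) for (c in 1:size) {
    if ((r - center[1])^2 + (c - center[2])^2 <= radius^2) count <- count + 1L
  }
  count
}

# cached small trained model shared by several tests (training is the slow part)
.test_cache <- new.env(parent = emptyenv())

cached_masked_model <- function() {
  if (is.null(.test_cache$model)) {
    cfg <- small_config(epochs = 6L)
    meals <- generate_meals(60, cfg, seed = 401)
    oracle <- latent_oracle(stats::setNames(meals$latent, meals$id))
    ses <- run_session(meals$id, oracle, n_c = 4, seed = 402)
    pairs <- extract_pairs(ses, max_pairs = 300, seed = 403)
    ex <- pretrain_extractor(meals, cfg, seed = 404)
    .test_cache$meals <- meals
    .test_cache$config <- cfg
    .test_cache$model <- train_ranking(pairs, meals, cfg, extractor = ex,
                                       seed = 405)
  }
  list(model = .test_cache$model, meals = .test_cache$meals,
       config = .test_cache$config)
}
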
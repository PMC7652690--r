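# Synthetic scenes: latent function, rendering, masks, dataset generation.

test_that("latent healthiness follows the composition/dish-count formula", {
  one <- function(v, f, s) {
    meal_scene(list(meal_dish(c(16, 16), 6, v, f, s)), image_size = 32)
  }
  expect_equal(latent_healthiness(one(0.5, 0, 0.5)), 1.0)
  expect_equal(latent_healthiness(one(0, 1, 0)), -1.5)

  three <- meal_scene(list(
    meal_dish(c(12, 12), 6, 1, 0, 0),
    meal_dish(c(12, 40), 6, 1, 0, 0),
    meal_dish(c(40, 26), 6, 1, 0, 0)
  ), image_size = 52)
  expect_equal(latent_healthiness(three), 2.0 + 1.0)
})

test_that("latent healthiness is monotone in vegetable and fried fractions", {
  withr::with_seed(7, {
    for (case in 1:20) {
      v <- runif(1, 0, 0.5); f <- runif(1, 0, 0.3)
      s <- 1 - v - f
      base <- meal_scene(list(meal_dish(c(16, 16), 6, v, f, s)), image_size = 32)
      eps <- runif(1, 0, s)
      more_veg <- meal_scene(list(meal_dish(c(16, 16), 6, v + eps, f, s - eps)),
                             image_size = 32)
      more_fried <- meal_scene(list(meal_dish(c(16, 16), 6, v, f + eps, s - eps)),
                               image_size = 32)
      expect_gte(latent_healthiness(more_veg), latent_healthiness(base))
      expect_lte(latent_healthiness(more_fried), latent_healthiness(base))
    }
  })
})

test_that("rendering is deterministic and the mask is the exact dish raster", {
  sc <- meal_scene(list(meal_dish(c(20, 14), 5, 0.4, 0.3, 0.3)), image_size = 32)
  r1 <- render_scene(sc, seed = 9)
  r2 <- render_scene(sc, seed = 9)
  expect_identical(r1, r2)
  expect_equal(sum(r1$mask), brute_disc_pixels(c(20, 14), 5, 32))
  expect_true(all(r1$mask %in% c(0L, 1L)))
  expect_true(all(r1$image >= 0 & r1$image <= 1))
})

test_that("background changes never leak into mask or masked image", {
  mk <- function(bg) {
    meal_scene(list(meal_dish(c(16, 16), 6, 0.2, 0.3, 0.5)),
               background_id = bg, image_size = 32)
  }
  ra <- render_scene(mk(1), seed = 5)
  rb <- render_scene(mk(4), seed = 77)
  expect_identical(ra$mask, rb$mask)
  expect_identical(apply_mask(ra$image, ra$mask), apply_mask(rb$image, rb$mask))
})

test_that("invalid scenes are rejected", {
  expect_error(meal_scene(list(), image_size = 32), "between 1 and 6")
  expect_error(meal_scene(list(meal_dish(c(3, 3), 6, 1, 0, 0)), image_size = 32),
               "outside")
  expect_error(meal_scene(list(
    meal_dish(c(16, 14), 5, 1, 0, 0), meal_dish(c(16, 20), 5, 1, 0, 0)
  ), image_size = 32), "overlap")
  expect_error(meal_dish(c(16, 16), 6, 0.5, 0.2, 0.5), "sum to 1")
  expect_error(meal_dish(c(16, 16), 2, 1, 0, 0), "radius")
})

test_that("generate_meals is deterministic and label/mask consistent", {
  cfg <- tiny_config()
  a <- generate_meals(20, cfg, seed = 31)
  b <- generate_meals(20, cfg, seed = 31)
  expect_identical(a$latent, b$latent)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  for (i in seq_len(nrow(a))) {
    expect_identical(a$mask[[i]] == 1L, a$labels[[i]] > 0L)
  }
  expect_error(generate_meals(0), "positive")
})

test_that("default generation produces a wide spread of latent values", {
  meals <- generate_meals(100, meal_config(), seed = 55)
  expect_gte(diff(range(meals$latent)), 2.0)
})

test_that("datasets round-trip through PNG + manifest exactly", {
  cfg <- tiny_config()
  meals <- generate_meals(3, cfg, seed = 13)
  dir <- withr::local_tempdir()
  manifest <- write_meals(meals, dir)
  back <- read_meals(manifest)
  expect_equal(back$id, meals$id)
  expect_equal(back$latent, meals$latent)
  for (i in 1:3) {
    expect_equal(back$image[[i]], meals$image[[i]])
    expect_identical(back$mask[[i]], meals$mask[[i]])
    expect_identical(back$labels[[i]], meals$labels[[i]])
  }
})

test_that("shuffled backgrounds keep dishes, masks and latents", {
  cfg <- tiny_config(background_mode = "confounded")
  meals <- generate_meals(6, cfg, seed = 21)
  shuf <- shuffle_backgrounds(meals, seed = 99)
  expect_identical(shuf$mask, meals$mask)
  expect_identical(shuf$latent, meals$latent)
  changed <- vapply(1:6, function(i) {
    !identical(shuf$image[[i]], meals$image[[i]])
  }, logical(1))
  expect_true(any(changed))
  for (i in 1:6) {
    expect_identical(apply_mask(shuf$image[[i]], shuf$mask[[i]]),
                     apply_mask(meals$image[[i]], meals$mask[[i]]))
  }
})
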
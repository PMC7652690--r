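# Deviation scores and screening.

test_that("self-referenced deviation scores match hand-computed z-scores", {
  out <- deviation_scores(c(1, 2, 3))
  expect_equal(out$z, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(out$s, c(37.75255, 50, 62.24745), tolerance = 1e-6)
  expect_equal(mean(50 + 10 * out$z), 50)
  expect_error(deviation_scores(c(2, 2, 2)), "zero variance")
  expect_error(deviation_scores(c(1)), "at least 2")
})

test_that("deviation scores are monotone and affine invariant", {
  withr::with_seed(4, {
    raw <- rnorm(50)
    a <- deviation_scores(raw)
    expect_equal(order(a$s[!duplicated(a$s)]), order(a$raw[!duplicated(a$s)]))
    expect_true(all(diff(a$s[order(a$raw)]) >= 0))
    b <- deviation_scores(3.7 * raw + 11)
    expect_equal(a$z, b$z, tolerance = 1e-12)
    expect_equal(a$s, b$s, tolerance = 1e-12)
  })
})

test_that("an external reference population is used when given", {
  out <- deviation_scores(c(0, 10), reference = c(0, 5, 10))
  mu <- 5; sigma <- sqrt(mean((c(0, 5, 10) - 5)^2))
  expect_equal(out$z, (c(0, 10) - mu) / sigma)
})

test_that("screening flags exactly the meals below threshold", {
  sc <- tibble::tibble(item_id = c("a", "b", "c"), s = c(40, 50, 60))
  d <- screen_meals(sc, th = 45)
  expect_equal(d$flagged, c(TRUE, FALSE, FALSE))
  expect_equal(attr(d, "n_flagged"), 1L)
  expect_false(any(screen_meals(sc, th = 0)$flagged))
  expect_true(all(screen_meals(sc, th = 101)$flagged))
  # raising the threshold never unflags
  for (th in c(30, 45, 55, 65)) {
    lo <- screen_meals(sc, th)$flagged
    hi <- screen_meals(sc, th + 5)$flagged
    expect_true(all(hi[lo]))
  }
})

test_that("quantile thresholds interpolate and bound the flagged share", {
  expect_equal(threshold_for_quantile(c(10, 20, 30, 40), 50), 25)
  withr::with_seed(12, {
    for (case in 1:10) {
      s <- runif(sample(5:40, 1), 0, 100)
      th <- threshold_for_quantile(s, 50)
      expect_lte(sum(s < th), length(s) / 2)
    }
  })
  expect_error(threshold_for_quantile(numeric(0), 50), "non-empty")
  expect_error(threshold_for_quantile(c(1, 2), 0), "strictly between")
})

test_that("the screening narrative holds: the lower half of 60 meals is flagged", {
  withr::with_seed(8, {
    day <- deviation_scores(rnorm(60))   # one day's upload: 60 meal images
    th <- threshold_for_quantile(day$s, 50)
    expect_equal(attr(screen_meals(day, th), "n_flagged"), 30L)
  })
})

test_that("min-max transform maps the reference range to 0-100", {
  out <- deviation_scores(c(1, 2, 3), transform = "minmax")
  expect_equal(out$s, c(0, 50, 100))
})
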
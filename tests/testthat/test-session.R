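# Pivot-based ranking sessions: correctness against a plain comparison sort,
# tie handling, screen accounting, protocol validation.

test_that("a session on 3 items matches the annotator in a single screen", {
  oracle <- latent_oracle(c(a = 0.1, b = 0.9, c = 0.5))
  s <- run_session(c("a", "b", "c"), oracle, n_c = 4, seed = 1)
  expect_equal(s$ranking$rank[match(c("a", "b", "c"), s$ranking$item_id)],
               c(3L, 1L, 2L))
  expect_equal(nrow(s$log), 1L)
})

test_that("sessions recover the exact order of distinct latents", {
  withr::with_seed(5, {
    for (case in 1:10) {
      n <- sample(c(5, 17, 33, 64), 1)
      lat <- stats::setNames(sample(seq_len(200), n) / 10,
                             sprintf("m%03d", seq_len(n)))
      s <- run_session(names(lat), latent_oracle(lat), n_c = 4,
                       seed = sample.int(1e6, 1))
      expect_equal(s$ranking$rank, sort_ranks(unname(lat[s$ranking$item_id])))
    }
  })
})

test_that("a fully tied item set collapses to a single rank", {
  lat <- stats::setNames(rep(1.5, 20), sprintf("m%02d", 1:20))
  ann <- simulated_annotator(tie_tolerance = 0.1)
  s <- run_session(names(lat), latent_oracle(lat, ann), n_c = 4, seed = 3)
  expect_true(all(s$ranking$rank == 1L))
})

test_that("wider screens never use more screens than pairwise quicksort", {
  withr::with_seed(21, {
    for (case in 1:8) {
      n <- sample(10:40, 1)
      lat <- stats::setNames(runif(n), sprintf("m%02d", seq_len(n)))
      seed <- sample.int(1e6, 1)
      s4 <- run_session(names(lat), latent_oracle(lat), n_c = 4, seed = seed)
      s2 <- run_session(names(lat), latent_oracle(lat), n_c = 2, seed = seed)
      expect_lte(nrow(s4$log), nrow(s2$log))
      expect_equal(s4$ranking, s2$ranking)
    }
  })
})

test_that("a misbehaving oracle raises a protocol error", {
  bad <- function(ids) seq_len(length(ids) - 1)
  expect_error(run_session(c("a", "b", "c"), bad, n_c = 4, seed = 1),
               "Protocol error")
  expect_error(run_session(character(0), function(ids) 1L), "at least one")
  expect_error(run_session(c("a", "a"), function(ids) 1L), "unique")
})

test_that("ties against the pivot adopt the pivot's rank band", {
  # two items equal to the pivot, one better, one worse
  lat <- c(p = 1.0, t1 = 1.0, t2 = 1.0, hi = 2.0, lo = 0.0)
  s <- run_session(names(lat), latent_oracle(lat), n_c = 4, seed = 2)
  r <- stats::setNames(s$ranking$rank, s$ranking$item_id)
  expect_equal(unname(r["hi"]), 1L)
  expect_true(all(r[c("p", "t1", "t2")] == 2L))
  expect_equal(unname(r["lo"]), 5L)
})
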
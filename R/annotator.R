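# Simulated annotator: a noisy stand-in for the registered dietitian. It
# perceives each item's latent healthiness through additive Gaussian noise and
# cannot distinguish items closer than its tie tolerance.

#' Construct a simulated annotator
#'
#' @param noise_sd Standard deviation of the additive Gaussian judgment noise,
#'   on the latent-healthiness scale. 0 gives a perfectly reliable annotator.
#' @param tie_tolerance Minimum perceived difference: items whose (noisy)
#'   values differ by less than this are reported as tied. Exactly equal
#'   values always tie.
#' @param seed Default seed used by [annotator_compare()] when none is given.
#' @return A list of class `simulated_annotator`.
#' @examples
#' ann <- simulated_annotator(noise_sd = 0.3, tie_tolerance = 0.1, seed = 1)
#' @export
simulated_annotator <- function(noise_sd = 0, tie_tolerance = 0, seed = 1L) {
  if (noise_sd < 0 || tie_tolerance < 0) {
    abort("noise_sd and tie_tolerance must be non-negative.")
  }
  structure(list(noise_sd = noise_sd, tie_tolerance = tie_tolerance,
                 seed = as.integer(seed)),
            class = "simulated_annotator")
}

# competition ranks (1 = best) of a vector of perceived values, chaining
# consecutive sorted values closer than tol into tie groups
.preorder_ranks <- function(values, tol) {
  n <- length(values)
  ord <- order(-values)
  sorted <- values[ord]
  grp <- integer(n)
  g <- 1L
  grp[1] <- 1L
  if (n > 1) {
    for (i in 2:n) {
      gap <- sorted[i - 1] - sorted[i]
      if (gap < tol || gap == 0) grp[i] <- g else grp[i] <- (g <- g + 1L)
    }
  }
  first_pos <- match(seq_len(max(grp)), grp)
  ranks_sorted <- first_pos[grp]
  ranks <- integer(n)
  ranks[ord] <- ranks_sorted
  ranks
}

#' Ask the annotator to rank a set of items
#'
#' Each latent value is perturbed once by Gaussian noise, then items are
#' ordered by perturbed value (higher = healthier = better rank). Items whose
#' perturbed values differ by less than the tie tolerance (after
#' single-linkage chaining along the sorted order) share a rank. Ranks use
#' competition ranking: after a t-way tie at rank r the next rank is r + t.
#'
#' @param annotator A [simulated_annotator()].
#' @param latents Numeric vector of true latent healthiness values.
#' @param seed Seed for the noise draw; defaults to the annotator's own seed.
#' @return Integer vector of ranks (1 = healthiest), same length as `latents`.
#' @examples
#' ann <- simulated_annotator()
#' annotator_compare(ann, c(0.1, 0.9, 0.5))  # 3 1 2
#' @export
annotator_compare <- function(annotator, latents, seed = annotator$seed) {
  stopifnot(inherits(annotator, "simulated_annotator"))
  if (length(latents) < 1) abort("latents must be non-empty.")
  perceived <- if (annotator$noise_sd > 0) {
    withr::with_seed(as.integer(seed),
                     latents + rnorm(length(latents), 0, annotator$noise_sd))
  } else {
    latents
  }
  .preorder_ranks(perceived, annotator$tie_tolerance)
}

#' Build a comparison oracle over a fixed item universe
#'
#' Returns a function mapping a character vector of item ids to competition
#' ranks of those items, suitable for [run_session()]. Judgment noise is drawn
#' once per item when the oracle is created (not per screen), so all screens
#' within one session are internally consistent.
#'
#' @param latents Named numeric vector: latent healthiness per item id.
#' @param annotator A [simulated_annotator()], or `NULL` for a noiseless
#'   exact oracle.
#' @param seed Seed for the per-session noise draw.
#' @return A function `(item_ids) -> integer ranks`.
#' @examples
#' oracle <- latent_oracle(c(a = 0.1, b = 0.9, c = 0.5))
#' oracle(c("a", "b", "c"))
#' @export
latent_oracle <- function(latents, annotator = NULL, seed = 1L) {
  stopifnot(!is.null(names(latents)))
  if (is.null(annotator)) annotator <- simulated_annotator()
  perceived <- if (annotator$noise_sd > 0) {
    withr::with_seed(as.integer(seed),
                     latents + rnorm(length(latents), 0, annotator$noise_sd))
  } else {
    latents
  }
  tol <- annotator$tie_tolerance
  function(item_ids) {
    missing <- setdiff(item_ids, names(perceived))
    if (length(missing)) {
      abort(paste0("Oracle asked about unknown item(s): ",
                   paste(missing, collapse = ", ")))
    }
    .preorder_ranks(unname(perceived[item_ids]), tol)
  }
}
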
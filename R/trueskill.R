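# Merging several annotators' ranking sessions into one consensus ranking
# with TrueSkill. Each item carries a Gaussian skill belief N(mu, sigma^2);
# every strict pairwise outcome implied by a session updates the two beliefs
# by the standard two-player moment-matching equations. Ties inside sessions
# are annotation shortcuts, not modeled draws, and are skipped.

# closed-form win update: a beat b
.ts_win_update <- function(mu_a, s2_a, mu_b, s2_b, beta) {
  c2 <- 2 * beta^2 + s2_a + s2_b
  cc <- sqrt(c2)
  t <- (mu_a - mu_b) / cc
  # v and w of the truncated Gaussian; guard the far-left tail
  pt <- pnorm(t)
  v <- if (pt < 1e-300) -t else stats::dnorm(t) / pt
  w <- v * (v + t)
  list(mu_a = mu_a + s2_a / cc * v,
       mu_b = mu_b - s2_b / cc * v,
       s2_a = s2_a * max(1 - s2_a / c2 * w, 1e-12),
       s2_b = s2_b * max(1 - s2_b / c2 * w, 1e-12))
}

#' Merge ranking sessions with TrueSkill
#'
#' Decomposes every session into its strict pairwise outcomes and applies
#' sequential TrueSkill updates (several deterministic sweeps over all
#' outcomes, so late outcomes also inform early beliefs). The merged ranking
#' sorts items by posterior mean skill, descending.
#'
#' @param sessions A list of rankings (tibbles with `item_id`, `rank`, or
#'   `meal_session` objects), each over a subset of a common item universe.
#' @param item_ids Optional full item universe; items never observed in any
#'   session keep their prior rating and are flagged.
#' @param config A [meal_config()] providing `trueskill_mu0`,
#'   `trueskill_sigma0`, `trueskill_beta`, `trueskill_tau`,
#'   `trueskill_sweeps`.
#' @return A list of class `meal_trueskill` with `ranking` (tibble `item_id`,
#'   `rank`) and `ratings` (tibble `item_id`, `mu`, `sigma`, `observed`).
#' @examples
#' r1 <- tibble::tibble(item_id = c("a", "b", "c"), rank = 1:3)
#' trueskill_merge(list(r1, r1))$ranking
#' @export
trueskill_merge <- function(sessions, item_ids = NULL, config = meal_config()) {
  rankings <- lapply(sessions, function(s) {
    if (inherits(s, "meal_session")) s <- s$ranking
    stopifnot(all(c("item_id", "rank") %in% names(s)))
    s
  })
  observed <- unique(unlist(lapply(rankings, `[[`, "item_id")))
  universe <- item_ids %||% observed
  never <- setdiff(universe, observed)
  if (length(never)) {
    warn(paste0("Item(s) never observed in any session: ",
                paste(never, collapse = ", "), " (kept at prior rating)"))
  }
  universe <- union(universe, observed)

  mu <- stats::setNames(rep(config$trueskill_mu0, length(universe)), universe)
  s2 <- stats::setNames(rep(config$trueskill_sigma0^2, length(universe)), universe)
  beta <- config$trueskill_beta
  tau2 <- config$trueskill_tau^2

  outcomes <- dplyr::bind_rows(lapply(rankings, function(r) {
    p <- extract_pairs(r, max_pairs = Inf)
    p
  }))
  for (sweep in seq_len(config$trueskill_sweeps)) {
    for (k in seq_len(nrow(outcomes))) {
      a <- outcomes$healthier_id[k]; b <- outcomes$less_healthy_id[k]
      s2[a] <- s2[a] + tau2
      s2[b] <- s2[b] + tau2
      up <- .ts_win_update(mu[a], s2[a], mu[b], s2[b], beta)
      mu[a] <- up$mu_a; mu[b] <- up$mu_b
      s2[a] <- up$s2_a; s2[b] <- up$s2_b
    }
  }

  ord <- order(-mu, universe)
  ranks <- integer(length(universe))
  sorted_mu <- mu[ord]
  r <- 1L
  for (i in seq_along(ord)) {
    if (i > 1 && sorted_mu[i] < sorted_mu[i - 1]) r <- i
    ranks[ord[i]] <- r
  }
  structure(list(
    ranking = tibble::tibble(item_id = universe, rank = ranks),
    ratings = tibble::tibble(item_id = universe, mu = unname(mu),
                             sigma = sqrt(unname(s2)),
                             observed = universe %in% observed)
  ), class = "meal_trueskill")
}

#' @export
print.meal_trueskill <- function(x, ...) {
  cat(sprintf("<meal_trueskill> %d items, %d unobserved\n",
              nrow(x$ratings), sum(!x$ratings$observed)))
  invisible(x)
}

#' Tidy a TrueSkill merge result
#'
#' @param x A `meal_trueskill` object.
#' @param ... Unused.
#' @return One row per item: `item_id`, `mu`, `sigma`, `observed`, `rank`.
#' @method tidy meal_trueskill
#' @export
tidy.meal_trueskill <- function(x, ...) {
  dplyr::left_join(x$ratings, x$ranking, by = "item_id")
}
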
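# Pivot-based N_c-way ranking sessions. An annotator is shown screens of N_c
# images (one pivot + up to N_c - 1 not-yet-placed candidates) and returns
# their order; candidates are partitioned quicksort-style into
# better-than / tied-with / worse-than the pivot, and the two strict
# partitions are ranked recursively. The result is a complete competition
# ranking of all items.

#' Run one ranking session
#'
#' @param item_ids Character vector of unique item ids (at least 1).
#' @param oracle Function `(item_ids) -> integer competition ranks` expressing
#'   the annotator's total preorder over any subset of up to `n_c` items;
#'   see [latent_oracle()].
#' @param n_c Images per screen including the pivot (at least 2); default 4.
#' @param seed Seed for the (uniform) pivot choices.
#' @param annotator_id Recorded in the session log.
#' @return A list of class `meal_session` with `ranking` (tibble `item_id`,
#'   `rank`; rank 1 = healthiest, competition ranking) and `log` (tibble of
#'   screens: `screen`, `pivot_id`, `candidate_ids`, `returned_ranks`).
#'
#' @details When the not-yet-placed set fits on one screen (at most `n_c`
#'   items) the oracle's full ordering of that screen is adopted directly;
#'   larger sets are pivot-partitioned and ranked recursively. The pivot of a
#'   subset is a uniform choice driven by a hash of `(seed, subset)`, so the
#'   recursion tree for a given item set and seed does not depend on `n_c`.
#' @examples
#' oracle <- latent_oracle(c(a = 0.1, b = 0.9, c = 0.5))
#' run_session(c("a", "b", "c"), oracle)$ranking
#' @export
run_session <- function(item_ids, oracle, n_c = 4L, seed = 1L,
                        annotator_id = "annotator1") {
  if (length(item_ids) < 1) abort("Need at least one item.")
  if (anyDuplicated(item_ids)) abort("item_ids must be unique.")
  if (n_c < 2) abort("n_c must be at least 2.")
  log_env <- new.env(parent = emptyenv())
  log_env$screens <- list()

  ask <- function(pivot, chunk) {
    ids <- c(pivot, chunk)
    ranks <- oracle(ids)
    if (!is.numeric(ranks) || length(ranks) != length(ids) || any(is.na(ranks))) {
      abort("Protocol error: oracle must return one rank per presented item.")
    }
    log_env$screens[[length(log_env$screens) + 1]] <-
      list(pivot_id = pivot, candidate_ids = chunk, returned_ranks = as.integer(ranks))
    ranks
  }

  # uniform pivot choice from a hash of (seed, subset): independent of n_c
  # and of the order the recursion visits subsets
  pick_pivot <- function(ids) {
    codes <- utf8ToInt(paste(sort(ids), collapse = "|"))
    h <- sum(codes * (seq_along(codes) %% 97 + 1)) + as.integer(seed) * 31
    ids[(h %% length(ids)) + 1]
  }

  rank_rec <- function(ids) {
    n <- length(ids)
    if (n == 0) return(tibble::tibble(item_id = character(), rank = integer()))
    if (n == 1) return(tibble::tibble(item_id = ids, rank = 1L))
    pivot <- pick_pivot(ids)
    rest <- setdiff(ids, pivot)
    if (n <= n_c) {  # everything fits one screen: adopt its full ordering
      ranks <- ask(pivot, rest)
      return(tibble::tibble(item_id = c(pivot, rest),
                            rank = as.integer(ranks)))
    }
    better <- tied <- worse <- character()
    for (chunk in split(rest, ceiling(seq_along(rest) / (n_c - 1)))) {
      ranks <- ask(pivot, chunk)
      pivot_rank <- ranks[1]
      cand_ranks <- ranks[-1]
      better <- c(better, chunk[cand_ranks < pivot_rank])
      tied <- c(tied, chunk[cand_ranks == pivot_rank])
      worse <- c(worse, chunk[cand_ranks > pivot_rank])
    }
    rb <- rank_rec(better)
    rw <- rank_rec(worse)
    pivot_rank <- length(better) + 1L
    dplyr::bind_rows(
      rb,
      tibble::tibble(item_id = c(pivot, tied), rank = pivot_rank),
      dplyr::mutate(rw, rank = .data$rank + pivot_rank + length(tied))
    )
  }

  ranking <- rank_rec(item_ids)
  ranking <- ranking[match(item_ids, ranking$item_id), ]
  log <- tibble::tibble(
    screen = seq_along(log_env$screens),
    pivot_id = vapply(log_env$screens, `[[`, character(1), "pivot_id"),
    candidate_ids = lapply(log_env$screens, `[[`, "candidate_ids"),
    returned_ranks = lapply(log_env$screens, `[[`, "returned_ranks")
  )
  structure(list(ranking = ranking, log = log, n_c = as.integer(n_c),
                 annotator_id = annotator_id),
            class = "meal_session")
}

#' @export
print.meal_session <- function(x, ...) {
  cat(sprintf("<meal_session> %d items ranked in %d screen(s) (n_c = %d)\n",
              nrow(x$ranking), nrow(x$log), x$n_c))
  invisible(x)
}

#' Extract strictly ordered training pairs from a ranking
#'
#' Every unordered pair of items with strictly different ranks yields one
#' oriented pair, healthier item first; tied pairs are never emitted. If more
#' than `max_pairs` strict pairs exist, a seeded uniform subsample is
#' returned.
#'
#' @param ranking Tibble with `item_id` and `rank` (or a `meal_session`).
#' @param max_pairs Upper bound on returned pairs (default unlimited).
#' @param seed Seed for the subsample.
#' @return A tibble with `healthier_id`, `less_healthy_id`.
#' @examples
#' r <- tibble::tibble(item_id = c("a", "b", "c"), rank = c(1L, 1L, 2L))
#' extract_pairs(r)
#' @export
extract_pairs <- function(ranking, max_pairs = Inf, seed = 1L) {
  if (inherits(ranking, "meal_session")) ranking <- ranking$ranking
  stopifnot(all(c("item_id", "rank") %in% names(ranking)))
  n <- nrow(ranking)
  if (n < 2) return(tibble::tibble(healthier_id = character(),
                                   less_healthy_id = character()))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ri <- ranking$rank[idx[, 1]]; rj <- ranking$rank[idx[, 2]]
  strict <- ri != rj
  i <- idx[strict, 1]; j <- idx[strict, 2]
  swap <- ranking$rank[i] > ranking$rank[j]
  healthier <- ifelse(swap, j, i)
  less <- ifelse(swap, i, j)
  pairs <- tibble::tibble(healthier_id = ranking$item_id[healthier],
                          less_healthy_id = ranking$item_id[less])
  if (is.finite(max_pairs) && nrow(pairs) > max_pairs) {
    keep <- withr::with_seed(as.integer(seed),
                             sort(sample.int(nrow(pairs), max_pairs)))
    pairs <- pairs[keep, ]
  }
  pairs
}

#' Item-level train/test split
#'
#' Items (not pairs) are split, so no training pair touches a test item and
#' no image leaks across the split. Training pairs are those whose both
#' members are training items.
#'
#' @param pairs Tibble of pairs from [extract_pairs()].
#' @param ranking Tibble with `item_id`, `rank` covering all items.
#' @param train_fraction Fraction of items used for training (default 0.9).
#' @param seed Seed for the item shuffle.
#' @return A list with `train_pairs` (tibble), `train_items`, `test_items`
#'   (character vectors).
#' @export
split_dataset <- function(pairs, ranking, train_fraction = 0.9, seed = 1L) {
  if (inherits(ranking, "meal_session")) ranking <- ranking$ranking
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be strictly between 0 and 1.")
  }
  ids <- ranking$item_id
  n_train <- round(length(ids) * train_fraction)
  if (length(ids) - n_train < 2) {
    abort("Split would leave fewer than 2 test items.")
  }
  shuffled <- withr::with_seed(as.integer(seed), sample(ids))
  train_items <- sort(shuffled[seq_len(n_train)])
  test_items <- sort(setdiff(ids, train_items))
  train_pairs <- pairs[pairs$healthier_id %in% train_items &
                         pairs$less_healthy_id %in% train_items, ]
  list(train_pairs = train_pairs, train_items = train_items,
       test_items = test_items)
}
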
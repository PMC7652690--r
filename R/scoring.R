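# Converting raw network outputs into the user-facing 0-100 healthiness
# deviation score, and screening meals against a threshold Th.

#' Deviation healthiness scores
#'
#' Standardizes raw network outputs against a reference population (mean 0,
#' unit variance, population SD) and maps them to the 0-100 deviation-score
#' convention \eqn{s = 50 + 10 z}, clipped to `[0, 100]`. With the default
#' self-reference, the input scores are their own reference population, so
#' the pre-clip mean is exactly 50 and the pre-clip SD exactly 10. A min-max
#' alternative (`transform = "minmax"`) maps the reference range onto 0-100.
#'
#' @param scores Tibble with `item_id` and `raw` (see [score_meals()]), or a
#'   bare numeric vector.
#' @param reference Numeric vector of raw reference scores, or `NULL` to use
#'   the inputs themselves. Must have length >= 2 and nonzero variance.
#' @param transform `"deviation"` (default) or `"minmax"`.
#' @return A tibble with `item_id`, `raw`, `z`, `s`.
#' @examples
#' deviation_scores(c(1, 2, 3))$s   # 37.75, 50, 62.25
#' @export
deviation_scores <- function(scores, reference = NULL,
                             transform = c("deviation", "minmax")) {
  transform <- match.arg(transform)
  if (is.numeric(scores)) {
    scores <- tibble::tibble(item_id = as.character(seq_along(scores)),
                             raw = as.numeric(scores))
  }
  stopifnot(all(c("item_id", "raw") %in% names(scores)))
  ref <- reference %||% scores$raw
  if (length(ref) < 2) abort("Reference set must contain at least 2 scores.")
  mu <- mean(ref)
  sigma <- sqrt(mean((ref - mu)^2))   # population SD: the reference IS the population
  if (sigma == 0) abort("Degenerate reference: zero variance.")
  z <- (scores$raw - mu) / sigma
  s <- if (transform == "deviation") {
    pmin(pmax(50 + 10 * z, 0), 100)
  } else {
    100 * (scores$raw - min(ref)) / (max(ref) - min(ref))
  }
  tibble::tibble(item_id = scores$item_id, raw = scores$raw, z = z, s = s)
}

#' Screen meals against a healthiness threshold
#'
#' A meal is flagged for dietitian intervention exactly when its deviation
#' score falls below the threshold (s < Th).
#'
#' @param scores Tibble with `item_id` and `s` (see [deviation_scores()]).
#' @param th Threshold on the 0-100 deviation scale.
#' @return A tibble of class `meal_screening` with `item_id`, `s`, `flagged`,
#'   `th`; the flagged count is attached as attribute `n_flagged`.
#' @examples
#' sc <- deviation_scores(c(1, 2, 3))
#' screen_meals(sc, th = 45)
#' @export
screen_meals <- function(scores, th) {
  stopifnot(all(c("item_id", "s") %in% names(scores)))
  out <- tibble::tibble(item_id = scores$item_id, s = scores$s,
                        flagged = scores$s < th, th = th)
  attr(out, "n_flagged") <- sum(out$flagged)
  class(out) <- c("meal_screening", class(out))
  out
}

#' Threshold flagging the lower k percent of a reference population
#'
#' Th is the k-th percentile (linear interpolation, quantile type 7) of the
#' reference deviation scores; screening at this Th flags approximately - and
#' because of the strict `s < Th` rule, at most - the worst k% of the
#' reference.
#'
#' @param reference Numeric vector of reference deviation scores, or a tibble
#'   with an `s` column.
#' @param k_percent Percent in (0, 100) defining "unhealthy" as the lower k%.
#' @return The threshold Th.
#' @examples
#' threshold_for_quantile(c(10, 20, 30, 40), 50)  # 25
#' @export
threshold_for_quantile <- function(reference, k_percent) {
  if (is.data.frame(reference)) reference <- reference$s
  if (!length(reference)) abort("Reference must be non-empty.")
  if (k_percent <= 0 || k_percent >= 100) {
    abort("k_percent must be strictly between 0 and 100.")
  }
  unname(quantile(reference, k_percent / 100, type = 7))
}

#' @export
print.meal_screening <- function(x, ...) {
  cat(sprintf("<meal_screening> %d of %d meals flagged (s < %.2f)\n",
              attr(x, "n_flagged"), nrow(x), x$th[1]))
  NextMethod()
}

#' Distribution plot of deviation scores with the screening threshold
#'
#' @param object A `meal_screening` from [screen_meals()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meal_screening
#' @export
autoplot.meal_screening <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s, fill = .data$flagged)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$th[1], linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "healthiness deviation score s", y = "meals",
                  fill = "flagged",
                  title = sprintf("Screening at Th = %.1f", object$th[1])) +
    ggplot2::theme_minimal()
}
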
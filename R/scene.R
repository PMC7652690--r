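# Synthetic meal scenes: parametric dishes on textured backgrounds, with
# pixel-accurate food masks and a known latent healthiness value. These stand
# in for real meal photographs so every downstream claim can be checked
# against ground truth.

# 8-bit color constants (kept on the 0..255 grid so PNG round-trips exactly)
.dish_palette <- list(
  vegetable = c(51L, 166L, 64L),
  fried     = c(204L, 153L, 38L),
  staple    = c(237L, 224L, 198L)
)

.bg_palette_neutral <- list(
  c(120L, 120L, 120L), c(150L, 130L, 110L), c(100L, 110L, 125L),
  c(135L, 125L, 140L), c(165L, 155L, 140L)
)

# graded red (1, least healthy) to green (5, healthiest); used when the
# generator deliberately confounds background hue with latent healthiness
.bg_palette_confounded <- list(
  c(185L, 85L, 70L), c(175L, 120L, 80L), c(150L, 140L, 90L),
  c(110L, 150L, 90L), c(80L, 165L, 85L)
)

#' Construct a dish
#'
#' A dish is a disc with a composition over three food classes rendered as
#' concentric color bands (vegetable at the center, then fried, then staple),
#' each band's area proportional to its fraction.
#'
#' @param center Numeric `(row, col)` of the disc center, in pixels.
#' @param radius Disc radius in pixels (at least 3).
#' @param vegetable,fried,staple Non-negative composition fractions summing
#'   to 1 (tolerance 1e-9).
#' @return A list of class `meal_dish`.
#' @examples
#' meal_dish(c(32, 32), 8, vegetable = 0.5, fried = 0, staple = 0.5)
#' @export
meal_dish <- function(center, radius, vegetable, fried, staple) {
  comp <- c(vegetable = vegetable, fried = fried, staple = staple)
  if (any(!is.finite(comp)) || any(comp < 0)) {
    abort("Dish composition fractions must be finite and non-negative.")
  }
  if (abs(sum(comp) - 1) > 1e-9) {
    abort(sprintf("Dish composition must sum to 1 (got %.12f).", sum(comp)))
  }
  if (!is.numeric(center) || length(center) != 2 || any(!is.finite(center))) {
    abort("Dish center must be a finite (row, col) pair.")
  }
  if (!is.numeric(radius) || length(radius) != 1 || radius < 3) {
    abort("Dish radius must be a single number >= 3 pixels.")
  }
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 composition = comp),
            class = "meal_dish")
}

#' Construct a meal scene
#'
#' @param dishes List of [meal_dish()] objects (1 to 6). Dish discs must lie
#'   fully inside the image and must not overlap.
#' @param background_id Integer background style index.
#' @param image_size Side length of the square image in pixels.
#' @return A list of class `meal_scene`.
#' @examples
#' sc <- meal_scene(list(meal_dish(c(16, 16), 6, 1, 0, 0)), image_size = 32)
#' @export
meal_scene <- function(dishes, background_id = 1L, image_size = 64L) {
  if (inherits(dishes, "meal_dish")) dishes <- list(dishes)
  scene <- structure(
    list(dishes = dishes, background_id = as.integer(background_id),
         image_size = as.integer(image_size)),
    class = "meal_scene"
  )
  validate_scene(scene)
  scene
}

#' @rdname meal_scene
#' @param scene A `meal_scene` to validate.
#' @export
validate_scene <- function(scene) {
  if (!inherits(scene, "meal_scene")) abort("Not a meal_scene.")
  nd <- length(scene$dishes)
  if (nd < 1 || nd > 6) abort("A scene must contain between 1 and 6 dishes.")
  s <- scene$image_size
  for (d in scene$dishes) {
    if (!inherits(d, "meal_dish")) abort("All scene elements must be meal_dish objects.")
    if (d$center[1] - d$radius < 1 || d$center[1] + d$radius > s ||
        d$center[2] - d$radius < 1 || d$center[2] + d$radius > s) {
      abort("Dish disc extends outside the image.")
    }
  }
  if (nd > 1) {
    for (a in seq_len(nd - 1)) for (b in (a + 1):nd) {
      da <- scene$dishes[[a]]; db <- scene$dishes[[b]]
      if (sqrt(sum((da$center - db$center)^2)) <= da$radius + db$radius) {
        abort("Dish discs overlap.")
      }
    }
  }
  invisible(scene)
}

#' Latent healthiness of a scene
#'
#' The deterministic ground-truth healthiness used by the synthetic world:
#' \deqn{h = 2.0 V - 1.5 F + 0.5 (D - 1)}
#' where `V` and `F` are the area-weighted vegetable and fried fractions over
#' all dishes (weights proportional to squared radius) and `D` is the number
#' of dishes. More vegetables and more dishes raise it; fried food lowers it.
#' Coefficients are configurable via `latent_coefs`.
#'
#' @param scene A [meal_scene()].
#' @param coefs Length-3 numeric: weights of the vegetable fraction, the fried
#'   fraction, and each dish beyond the first.
#' @return A single number.
#' @examples
#' sc <- meal_scene(list(meal_dish(c(16, 16), 6, 0.5, 0, 0.5)), image_size = 32)
#' latent_healthiness(sc)  # 2.0 * 0.5 = 1
#' @export
latent_healthiness <- function(scene, coefs = meal_config()$latent_coefs) {
  validate_scene(scene)
  w <- vapply(scene$dishes, function(d) d$radius^2, numeric(1))
  v <- vapply(scene$dishes, function(d) d$composition[["vegetable"]], numeric(1))
  f <- vapply(scene$dishes, function(d) d$composition[["fried"]], numeric(1))
  V <- sum(w * v) / sum(w)
  F <- sum(w * f) / sum(w)
  D <- length(scene$dishes)
  unname(coefs[1] * V + coefs[2] * F + coefs[3] * (D - 1))
}

# per-pixel class matrix for one dish: 0 outside the disc, else 1/2/3 by the
# concentric band the pixel's normalized squared distance falls in
.dish_classes <- function(dish, image_size) {
  s <- image_size
  rows <- matrix(seq_len(s), s, s)
  cols <- matrix(seq_len(s), s, s, byrow = TRUE)
  d2 <- (rows - dish$center[1])^2 + (cols - dish$center[2])^2
  u <- d2 / dish$radius^2
  cls <- matrix(0L, s, s)
  cum <- cumsum(dish$composition)
  cum[3] <- 1  # guard against 1e-9 shortfall: the outer band closes the disc
  inside <- u <= 1
  assigned <- matrix(FALSE, s, s)
  for (k in 1:3) {
    if (dish$composition[k] <= 0) next
    sel <- inside & !assigned & (u <= cum[k])
    cls[sel] <- k
    assigned <- assigned | sel
  }
  cls
}

#' Render a scene to image, mask, labels and latent value
#'
#' Deterministic for a fixed `(scene, seed)` pair. The background texture
#' depends on `background_id` and `seed` only; background pixels never enter
#' the mask, so two scenes differing only in background render to identical
#' masks and identical masked images.
#'
#' @param scene A [meal_scene()].
#' @param seed Integer seed for the background texture.
#' @param config A [meal_config()]; controls the background palette
#'   (`background_mode`) and texture amplitude.
#' @return A list with `image` (H x W x 3 array in `[0, 1]`), `mask`
#'   (H x W 0/1 integer matrix marking food pixels), `labels` (H x W integer
#'   matrix: 0 background, 1 vegetable, 2 fried, 3 staple) and `latent`.
#' @examples
#' sc <- meal_scene(list(meal_dish(c(16, 16), 6, 1, 0, 0)), image_size = 32)
#' r <- render_scene(sc, seed = 1)
#' sum(r$mask)
#' @export
render_scene <- function(scene, seed = 1L, config = meal_config()) {
  validate_scene(scene)
  s <- scene$image_size
  palette <- if (identical(config$background_mode, "confounded")) {
    .bg_palette_confounded
  } else {
    .bg_palette_neutral
  }
  base <- palette[[((scene$background_id - 1L) %% length(palette)) + 1L]]
  amp <- config$background_noise
  img8 <- withr::with_seed(as.integer(seed), {
    noise <- array(sample.int(2L * amp + 1L, s * s * 3L, replace = TRUE) - amp - 1L,
                   dim = c(s, s, 3))
    sweep(noise, 3, base, "+")
  })
  img8 <- pmin(pmax(img8, 0L), 255L)

  labels <- matrix(0L, s, s)
  for (d in scene$dishes) {
    cls <- .dish_classes(d, s)
    labels[cls > 0L] <- cls[cls > 0L]
  }
  for (k in 1:3) {
    sel <- labels == k
    if (!any(sel)) next
    col8 <- .dish_palette[[k]]
    for (ch in 1:3) {
      plane <- img8[, , ch]
      plane[sel] <- col8[ch]
      img8[, , ch] <- plane
    }
  }
  mask <- matrix(as.integer(labels > 0L), s, s)
  list(image = img8 / 255, mask = mask, labels = labels,
       latent = latent_healthiness(scene, config$latent_coefs))
}
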
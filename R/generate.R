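# Seeded generation of whole synthetic datasets: random scenes, their
# renderings, per-pixel segmentation labels, and the manifest tying them
# together. Everything is a pure function of (config, seed).

.sample_scene <- function(config) {
  s <- config$image_size
  dmin <- config$dish_count_range[1]; dmax <- config$dish_count_range[2]
  rmin <- config$dish_radius_range[1]; rmax <- config$dish_radius_range[2]
  n_d <- if (dmax > dmin) sample(dmin:dmax, 1) else dmin
  dishes <- list()
  for (k in seq_len(n_d)) {
    placed <- FALSE
    for (try in 1:300) {
      r <- runif(1, rmin, rmax)
      ctr <- runif(2, 1 + r, s - r)
      ok <- all(vapply(dishes, function(d) {
        sqrt(sum((d$center - ctr)^2)) > d$radius + r
      }, logical(1)))
      if (ok) {
        g <- rgamma(3, 1)            # flat Dirichlet over the 3 food classes
        comp <- g / sum(g)
        dishes[[length(dishes) + 1]] <-
          meal_dish(ctr, r, comp[1], comp[2], comp[3])
        placed <- TRUE
        break
      }
    }
    if (!placed) break  # crowded canvas: keep the dishes placed so far
  }
  dishes
}

# fixed latent breakpoints mapping healthiness to the 5 graded background
# styles in "confounded" mode (style 1 = reddest = least healthy)
.confound_breaks <- c(0.0, 0.6, 1.2, 1.8)

#' Generate a synthetic meal dataset
#'
#' Draws `n` random meal scenes (dish count, placement, composition and
#' background style all seeded), renders each, and returns one tibble with the
#' images, masks, per-pixel class labels and latent healthiness values. With
#' `background_mode = "confounded"` the background style is a deterministic
#' function of the latent value (red backgrounds behind unhealthy meals,
#' green behind healthy ones), creating the context/healthiness confound that
#' food-region masking is designed to defeat.
#'
#' @param n Number of meals (at least 1).
#' @param config A [meal_config()].
#' @param seed Integer seed; the whole dataset is a pure function of
#'   `(n, config, seed)`.
#' @return A tibble with columns `id`, `image` (list of H x W x 3 arrays),
#'   `mask` (list of 0/1 matrices), `labels` (list of integer matrices),
#'   `latent`, `background_id`. The config and seed are attached as
#'   attributes `config` and `seed`.
#' @examples
#' meals <- generate_meals(4, meal_config(image_size = 32,
#'                                        dish_radius_range = c(4, 6)), seed = 1)
#' meals$latent
#' @export
generate_meals <- function(n, config = meal_config(), seed = 1L) {
  if (!is.numeric(n) || n < 1) abort("n must be a positive integer.")
  n <- as.integer(n)
  confounded <- identical(config$background_mode, "confounded")
  rows <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      dishes <- .sample_scene(config)
      bg <- sample.int(config$n_backgrounds, 1)
      bg_seed <- sample.int(2^31 - 2, 1)
      scene <- meal_scene(dishes, background_id = bg,
                          image_size = config$image_size)
      if (confounded) {
        h <- latent_healthiness(scene, config$latent_coefs)
        scene$background_id <- findInterval(h, .confound_breaks) + 1L
      }
      r <- render_scene(scene, seed = bg_seed, config = config)
      list(id = sprintf("meal%04d", i), image = r$image, mask = r$mask,
           labels = r$labels, latent = r$latent,
           background_id = scene$background_id, bg_seed = bg_seed,
           scene = scene)
    })
  })
  out <- tibble::tibble(
    id = vapply(rows, `[[`, character(1), "id"),
    image = lapply(rows, `[[`, "image"),
    mask = lapply(rows, `[[`, "mask"),
    labels = lapply(rows, `[[`, "labels"),
    latent = vapply(rows, `[[`, numeric(1), "latent"),
    background_id = vapply(rows, `[[`, integer(1), "background_id")
  )
  attr(out, "scenes") <- lapply(rows, `[[`, "scene")
  attr(out, "bg_seeds") <- vapply(rows, `[[`, integer(1), "bg_seed")
  attr(out, "config") <- config
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Re-render a dataset with fresh random backgrounds
#'
#' Keeps every scene's dishes (hence mask, labels and latent) but redraws the
#' background style uniformly and re-textures it. Used to break any background
#' cue at evaluation time: a model that learned food content is unaffected,
#' one that learned the background collapses.
#'
#' @param meals A dataset from [generate_meals()].
#' @param seed Integer seed for the new backgrounds.
#' @return A tibble like `meals` with new `image` and `background_id`.
#' @export
shuffle_backgrounds <- function(meals, seed = 1L) {
  scenes <- attr(meals, "scenes")
  if (is.null(scenes)) abort("meals must carry scene metadata (from generate_meals()).")
  config <- attr(meals, "config")
  cfg_random <- config
  cfg_random$background_mode <- "random"
  out <- meals
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(nrow(meals))) {
      sc <- scenes[[i]]
      sc$background_id <- sample.int(config$n_backgrounds, 1)
      r <- render_scene(sc, seed = sample.int(2^31 - 2, 1), config = cfg_random)
      out$image[[i]] <- r$image
      out$background_id[i] <- sc$background_id
      scenes[[i]] <- sc
    }
  })
  attr(out, "scenes") <- scenes
  attr(out, "config") <- config
  out
}

#' Write a dataset to PNG files plus a CSV manifest
#'
#' Images are 8-bit RGB PNG; masks are 8-bit grayscale PNG (food = 255,
#' background = 0); labels are grayscale PNG with class k stored as 85 k. The
#' manifest lists `id, image_path, mask_path, labels_path, latent` with paths
#' relative to the manifest, and embeds provenance (config hash, seed) as a
#' comment line.
#'
#' @param meals A dataset from [generate_meals()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_meals <- function(meals, dir) {
  config <- attr(meals, "config") %||% meal_config()
  seed <- attr(meals, "seed") %||% NA_integer_
  for (sub in c("images", "masks", "labels")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  rel_img <- file.path("images", paste0(meals$id, ".png"))
  rel_msk <- file.path("masks", paste0(meals$id, ".png"))
  rel_lab <- file.path("labels", paste0(meals$id, ".png"))
  for (i in seq_len(nrow(meals))) {
    png::writePNG(meals$image[[i]], file.path(dir, rel_img[i]))
    png::writePNG(meals$mask[[i]] * 1.0, file.path(dir, rel_msk[i]))
    png::writePNG(meals$labels[[i]] * (85 / 255), file.path(dir, rel_lab[i]))
  }
  manifest <- tibble::tibble(id = meals$id, image_path = rel_img,
                             mask_path = rel_msk, labels_path = rel_lab,
                             latent = meals$latent)
  path <- file.path(dir, "manifest.csv")
  write_meal_csv(manifest, path, config = config, seed = seed)
  invisible(path)
}

#' Read a dataset back from a manifest
#'
#' Masks are re-binarized by thresholding the 8-bit grayscale at >= 128.
#'
#' @param manifest_path Path to a manifest written by [write_meals()].
#' @return A tibble with `id`, `image`, `mask`, `labels`, `latent`.
#' @export
read_meals <- function(manifest_path) {
  manifest <- read_meal_csv(manifest_path,
                            required = c("id", "image_path", "mask_path", "latent"))
  base <- dirname(manifest_path)
  n <- nrow(manifest)
  image <- mask <- labels <- vector("list", n)
  for (i in seq_len(n)) {
    for (col in c("image_path", "mask_path")) {
      p <- file.path(base, manifest[[col]][i])
      if (!file.exists(p)) {
        abort(sprintf("Manifest row %d: file not found: %s", i, p))
      }
    }
    image[[i]] <- png::readPNG(file.path(base, manifest$image_path[i]))
    m <- png::readPNG(file.path(base, manifest$mask_path[i]))
    mask[[i]] <- matrix(as.integer(round(m * 255) >= 128), nrow(m), ncol(m))
    if (!is.null(manifest$labels_path)) {
      l <- png::readPNG(file.path(base, manifest$labels_path[i]))
      labels[[i]] <- matrix(as.integer(round(l * 255 / 85)), nrow(l), ncol(l))
    }
  }
  out <- tibble::tibble(id = manifest$id, image = image, mask = mask,
                        labels = labels, latent = manifest$latent)
  attr(out, "config_hash") <- attr(manifest, "config_hash")
  out
}
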
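#' Default run configuration
#'
#' All tunable settings of the toolkit live in one flat list with defaults, so
#' that a whole pipeline run is reproducible from `(config, seed)` alone.
#' Unknown keys are rejected, which catches typos early.
#'
#' Key groups:
#' \describe{
#'   \item{scene generation}{`image_size` (pixels, square), `dish_count_range`,
#'     `dish_radius_range` (pixels), `latent_coefs` (vegetable, fried,
#'     per-extra-dish weights of the latent healthiness function),
#'     `n_backgrounds`, `background_mode` (`"random"` or `"confounded"`, the
#'     latter ties background hue to latent healthiness to emulate
#'     context/healthiness confounding).}
#'   \item{annotation}{`noise_sd` (SD of the simulated annotator's Gaussian
#'     judgment noise on the latent scale), `tie_tolerance` (minimum perceived
#'     latent difference), `n_c` (images per comparison screen, one of which is
#'     the pivot).}
#'   \item{training}{`train_fraction` (item-level train share), `max_pairs`,
#'     `conv_channels`, `fc_hidden`, `n_classes` (segmentation classes incl.
#'     background), `epochs`, `pretrain_epochs`, `batch_size` (pairs per
#'     minibatch), `learning_rate`, `loss` (`"logistic"` or `"hinge"`),
#'     `hinge_margin`, `mask_mode`, `pretrain_mode`, `augment_flips`.}
#'   \item{scoring/screening}{`score_transform` (`"deviation"` = 50 + 10 z,
#'     clipped to 0-100; `"minmax"` alternative), `screen_k` (percent defining
#'     "unhealthy" as the lower k% of the reference).}
#'   \item{rank merging}{`trueskill_mu0`, `trueskill_sigma0`,
#'     `trueskill_beta`, `trueskill_tau`, `trueskill_sweeps`.}
#' }
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `meal_config`.
#' @examples
#' cfg <- meal_config(image_size = 32, epochs = 5)
#' cfg$image_size
#' @export
meal_config <- function(...) {
  defaults <- list(
    # synthetic scenes
    image_size        = 64L,
    dish_count_range  = c(1L, 4L),
    dish_radius_range = c(7, 11),
    latent_coefs      = c(vegetable = 2.0, fried = -1.5, dish = 0.5),
    n_backgrounds     = 5L,
    background_mode   = "random",
    background_noise  = 12L,          # +- 8-bit counts of per-pixel texture
    # simulated annotator
    noise_sd          = 0,
    tie_tolerance     = 0,
    n_c               = 4L,
    # pairs / split
    train_fraction    = 0.9,
    max_pairs         = 2000L,
    # network
    conv_channels     = c(12L, 24L),
    fc_hidden         = 32L,
    n_classes         = 4L,
    epochs            = 30L,
    pretrain_epochs   = 20L,
    batch_size        = 16L,
    learning_rate     = 2e-3,
    pretrain_learning_rate = 1e-2,
    loss              = "logistic",
    hinge_margin      = 1,
    mask_mode         = TRUE,
    mask_pool         = FALSE,        # masked average pooling instead of input masking
    pretrain_mode     = TRUE,
    augment_flips     = FALSE,
    # scoring / screening
    score_transform   = "deviation",
    screen_k          = 50,
    # TrueSkill merge
    trueskill_mu0     = 25,
    trueskill_sigma0  = 25 / 3,
    trueskill_beta    = 25 / 6,
    trueskill_tau     = 25 / 300,
    trueskill_sweeps  = 10L
  )
  overrides <- list(...)
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == "")) {
      abort("All arguments to meal_config() must be named.")
    }
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown)) {
      abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
    }
    defaults[nm] <- overrides
  }
  structure(defaults, class = "meal_config")
}

#' @export
print.meal_config <- function(x, ...) {
  cat("<meal_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Derive a per-stage seed from one global seed
#'
#' Pipeline stages each get their own RNG seed derived deterministically from
#' the global seed and the stage name, so inserting a stage never shifts the
#' random stream of the stages after it.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' stage_seed(1, "generate")
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  v <- (abs(seed) %% 65521) * 69621 + h * 8191 + 1
  as.integer(v %% (2^31 - 2) + 1)
}

#' Hash a configuration for artifact provenance
#'
#' Canonical text dump of the config hashed with MD5. Every CSV the pipeline
#' writes embeds this hash so artifacts produced under different configs are
#' detected when mixed.
#'
#' @param config A `meal_config`.
#' @return A 32-character hex string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "meal_config"))
  dump <- vapply(names(config), function(nm) {
    paste0(nm, "=", paste(format(config[[nm]], digits = 17), collapse = ","))
  }, character(1))
  f <- tempfile(fileext = ".cfg")
  on.exit(unlink(f))
  writeLines(dump[order(names(config))], f)
  unname(tools::md5sum(f))
}
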
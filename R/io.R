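# CSV plumbing shared by every artifact the pipeline writes. One dialect:
# UTF-8, comma, header row, "." decimal, floats at 17 significant digits (so
# doubles round-trip bit-exactly), and a leading provenance comment line
# carrying the config hash and seed.

.provenance_line <- function(config = NULL, seed = NA, hash = NULL) {
  h <- hash %||% if (!is.null(config)) config_hash(config) else "none"
  sprintf("# mealrank %s config_hash=%s seed=%s",
          as.character(utils::packageVersion("mealrank")), h,
          ifelse(is.na(seed), "NA", format(seed)))
}

#' Write a tibble as a provenance-stamped CSV
#'
#' @param df A data frame.
#' @param path Output path.
#' @param config Optional [meal_config()] whose hash is embedded.
#' @param seed Optional seed recorded in the provenance line.
#' @param hash Pre-computed hash overriding `config`.
#' @return `path`, invisibly.
#' @export
write_meal_csv <- function(df, path, config = NULL, seed = NA, hash = NULL) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  con <- file(path, open = "wb")  # binary mode: LF on every platform
  on.exit(close(con))
  writeLines(.provenance_line(config, seed, hash), con)
  readr::write_csv(out, con, na = "")
  invisible(path)
}

#' Read a provenance-stamped CSV
#'
#' Validates required columns, converts the named numeric columns with
#' row-numbered errors for malformed values, and attaches the embedded config
#' hash as attribute `config_hash`.
#'
#' @param path Input path.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns to parse as numbers (defaults to those of
#'   `required` named `latent`, `rank`, `raw`, `z`, `s`, or `mu`/`sigma`).
#' @return A tibble.
#' @export
read_meal_csv <- function(path,
                          required = character(),
                          numeric_cols = intersect(required,
                            c("latent", "rank", "raw", "z", "s", "mu", "sigma", "Th"))) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  first <- readLines(path, n = 1)
  hash <- NA_character_
  skip <- 0
  if (startsWith(first, "#")) {
    skip <- 1
    m <- regmatches(first, regexec("config_hash=([0-9a-f]+|none)", first))[[1]]
    if (length(m) == 2) hash <- m[2]
  }
  df <- readr::read_csv(path, skip = skip, col_types = readr::cols(.default = "c"),
                        progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0(path, ": missing column(s): ", paste(missing, collapse = ", ")))
  }
  for (col in intersect(numeric_cols, names(df))) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad)) {
      abort(sprintf("%s: non-numeric value in column '%s' at data row %s",
                    path, col, paste(bad, collapse = ", ")))
    }
    df[[col]] <- parsed
  }
  id_col <- intersect(c("id", "item_id"), names(df))
  for (col in id_col) {
    dup <- unique(df[[col]][duplicated(df[[col]])])
    if (length(dup)) {
      abort(sprintf("%s: duplicate %s: %s", path, col, paste(dup, collapse = ", ")))
    }
  }
  attr(df, "config_hash") <- hash
  tibble::as_tibble(df)
}

#' @rdname meal_artifacts
#' @export
write_ranking <- function(ranking, path, config = NULL, seed = NA) {
  stopifnot(all(c("item_id", "rank") %in% names(ranking)))
  write_meal_csv(ranking[c("item_id", "rank")], path, config, seed)
}

#' Artifact readers and writers
#'
#' Rankings (`item_id, rank`), training pairs (`healthier_id,
#' less_healthy_id`), and score tables (`item_id, raw, z, s`) round-trip
#' through CSV with provenance. Loading validates structure and reports
#' malformed rows by number.
#'
#' @param ranking,pairs,scores Tibbles in the respective schema.
#' @param path File path.
#' @param config,seed Provenance (see [write_meal_csv()]).
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name meal_artifacts
#' @export
read_ranking <- function(path) {
  df <- read_meal_csv(path, required = c("item_id", "rank"))
  df$rank <- as.integer(df$rank)
  if (any(df$rank < 1)) abort(paste0(path, ": ranks must be >= 1"))
  df
}

#' @rdname meal_artifacts
#' @export
write_pairs <- function(pairs, path, config = NULL, seed = NA) {
  stopifnot(all(c("healthier_id", "less_healthy_id") %in% names(pairs)))
  write_meal_csv(pairs[c("healthier_id", "less_healthy_id")], path, config, seed)
}

#' @rdname meal_artifacts
#' @export
read_pairs <- function(path) {
  read_meal_csv(path, required = c("healthier_id", "less_healthy_id"))
}

#' @rdname meal_artifacts
#' @export
write_scores <- function(scores, path, config = NULL, seed = NA) {
  stopifnot(all(c("item_id", "raw") %in% names(scores)))
  write_meal_csv(scores, path, config, seed)
}

#' @rdname meal_artifacts
#' @export
read_scores <- function(path) {
  read_meal_csv(path, required = c("item_id", "raw"),
                numeric_cols = c("raw", "z", "s"))
}

# refuse to combine artifacts written under different configs
.check_hashes <- function(...) {
  hashes <- vapply(list(...), function(x) attr(x, "config_hash") %||% NA_character_,
                   character(1))
  known <- stats::na.omit(hashes[hashes != "none"])
  if (length(unique(known)) > 1) {
    abort(paste0("Artifacts were written under different configs: ",
                 paste(unique(known), collapse = " vs ")))
  }
  invisible(TRUE)
}
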
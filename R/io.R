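# CSV dialect throughout: comma-separated, UTF-8, mandatory header, '.'
# decimal separator, no quoting of numerics.  Numeric columns are written
# with 17 significant digits so write/read round-trips are exact.

fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1L))
}

#' Write a trial table to CSV
#'
#' Columns, in order: `participant_id`, `trial_index`, `category_id`,
#' `alpha`, `nonneutral_position`, `chosen_position`, `chose_nonneutral`,
#' `rt_ms`.  Numerics are written with full precision so
#' [read_trials()] recovers the table exactly.
#'
#' @param trials a trial table
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trials <- function(trials, path) {
  check_trial_schema(names(trials))
  out <- data.frame(participant_id = trials$participant_id,
                    trial_index = trials$trial_index,
                    category_id = trials$category_id,
                    alpha = fmt_num(trials$alpha),
                    nonneutral_position = trials$nonneutral_position,
                    chosen_position = trials$chosen_position,
                    chose_nonneutral = trials$chose_nonneutral,
                    rt_ms = fmt_num(trials$rt_ms),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

check_trial_schema <- function(cols) {
  missing <- setdiff(trial_columns, cols)
  extra <- setdiff(cols, trial_columns)
  if (length(missing) || length(extra))
    stop("trial table schema error",
         if (length(missing)) paste0("; missing column(s): ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected column(s): ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

#' Read a trial table from CSV
#'
#' Validates the exact column set before parsing and reports malformed
#' rows by number rather than coercing them.
#'
#' @param path CSV file written by [write_trials()] (or matching its
#'   schema)
#' @return a trial table data frame
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  check_trial_schema(names(d))
  d <- d[, trial_columns]
  num <- function(col) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !(d[[col]] %in% "NA"))
    if (length(bad))
      stop("malformed numeric in column '", col, "' at row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    v
  }
  d$trial_index <- as.integer(num("trial_index"))
  d$alpha <- num("alpha")
  d$rt_ms <- num("rt_ms")
  lg <- d$chose_nonneutral %in% c("TRUE", "FALSE")
  if (!all(lg))
    stop("malformed logical in column 'chose_nonneutral' at row(s): ",
         paste(utils::head(which(!lg), 10L), collapse = ", "), call. = FALSE)
  d$chose_nonneutral <- d$chose_nonneutral == "TRUE"
  pos_ok <- d$nonneutral_position %in% c("left", "right") &
    d$chosen_position %in% c("left", "right")
  if (!all(pos_ok))
    stop("malformed position at row(s): ",
         paste(utils::head(which(!pos_ok), 10L), collapse = ", "),
         call. = FALSE)
  d
}

#' Write an image sequence as PNG files
#'
#' One file per (category, alpha), named `<category>_a<signed-alpha>.png`.
#'
#' @param seq an `image_sequence`
#' @param dir output directory (created if missing)
#' @return character vector of file paths, invisibly
#' @export
write_sequence_png <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(seq$alpha_levels))
  for (i in seq_along(seq$alpha_levels)) {
    a <- seq$alpha_levels[i]
    paths[i] <- file.path(dir, sprintf("%s_a%+.4f.png", seq$category_id, a))
    png::writePNG(seq$images[[i]] / 255, paths[i])
  }
  invisible(paths)
}

#' Read an RGB image from PNG
#'
#' @param path PNG file
#' @return an `H x W x 3` array with values in `[0, 255]`
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Serialize / restore a generator configuration as JSON
#'
#' @param cfg a [generator_config()]
#' @param path JSON file
#' @return `write_generator_config`: `path` invisibly;
#'   `read_generator_config`: a `generator_config`
#' @export
write_generator_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$effect_sizes <- as.list(x$effect_sizes)  # keep the feature names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  generator_config(
    n_categories = j$n_categories,
    alpha_levels = j$alpha_levels,
    image_size = j$image_size,
    effect_sizes = unlist(j$effect_sizes),
    downturn_fraction = j$downturn_fraction,
    noise_sd = j$noise_sd,
    score_base = j$score_base,
    score_base_sd = j$score_base_sd,
    score_slope = j$score_slope,
    downturn_drop = j$downturn_drop,
    rt_median_ms = j$rt_median_ms,
    rt_sdlog = j$rt_sdlog,
    rng_seed = j$rng_seed)
}
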
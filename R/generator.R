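#' Configuration for the synthetic sequence generator
#'
#' Defines the study conditions the generator emulates: the number of
#' categories, the alpha grid (symmetric about zero, denser near zero),
#' image size, per-feature effect slopes, and the aesthetic-score model.
#' Defaults mirror a design with 489 categories, one seed each and 15
#' alpha levels in `[-0.25, 0.25]`.
#'
#' @param n_categories positive integer
#' @param alpha_levels strictly increasing reals in `[-0.25, 0.25]`,
#'   symmetric about 0 and containing 0
#' @param image_size pixels per side, at least 8
#' @param effect_sizes named vector of feature slopes; names must be a
#'   subset of the transformable features `brightness`, `contrast`,
#'   `saturation`, `colorfulness`, `sharpness`.  `brightness` is an
#'   additive intensity shift per unit alpha; the others are multiplicative
#'   gains per unit alpha.
#' @param downturn_fraction proportion in `[0, 1]` of categories whose
#'   aesthetic score dips at the top alpha level
#' @param noise_sd nonnegative SD of the aesthetic-score noise
#' @param score_base,score_base_sd,score_slope aesthetic-score model
#'   `score = base_cat + score_slope * alpha + noise` with per-category
#'   intercepts `base_cat ~ N(score_base, score_base_sd)`
#' @param downturn_drop amount by which a downturn category's top-alpha
#'   score falls below the second-highest level's score
#' @param rt_median_ms,rt_sdlog log-normal response-time model; only the
#'   median matters for the cleaning rules
#' @param rng_seed integer master seed
#' @return a `generator_config` list
#' @export
generator_config <- function(n_categories = 489L,
                             alpha_levels = default_alpha_levels(),
                             image_size = 64L,
                             effect_sizes = c(brightness = 60, contrast = 1.2,
                                              saturation = 0.8,
                                              colorfulness = 1.0,
                                              sharpness = 2.0),
                             downturn_fraction = 0.05,
                             noise_sd = 0.02,
                             score_base = 0.5,
                             score_base_sd = 0.05,
                             score_slope = 1.0,
                             downturn_drop = 0.05,
                             rt_median_ms = 800,
                             rt_sdlog = 0.35,
                             rng_seed = 1L) {
  cfg <- structure(list(n_categories = as.integer(n_categories),
                        alpha_levels = as.numeric(alpha_levels),
                        image_size = as.integer(image_size),
                        effect_sizes = effect_sizes,
                        downturn_fraction = downturn_fraction,
                        noise_sd = noise_sd,
                        score_base = score_base,
                        score_base_sd = score_base_sd,
                        score_slope = score_slope,
                        downturn_drop = downturn_drop,
                        rt_median_ms = rt_median_ms,
                        rt_sdlog = rt_sdlog,
                        rng_seed = as.integer(rng_seed)),
                   class = "generator_config")
  validate_generator_config(cfg)
}

#' @rdname generator_config
#' @export
default_alpha_levels <- function() {
  pos <- c(0.0025, 0.005, 0.01, 0.025, 0.05, 0.10, 0.25)
  sort(c(-pos, 0, pos))
}

validate_generator_config <- function(cfg) {
  a <- cfg$alpha_levels
  if (cfg$n_categories < 1L) stop("n_categories must be positive", call. = FALSE)
  if (is.unsorted(a, strictly = TRUE))
    stop("alpha_levels must be strictly increasing", call. = FALSE)
  if (!any(a == 0)) stop("alpha_levels must contain 0", call. = FALSE)
  if (max(abs(a + rev(a))) > 1e-12)
    stop("alpha_levels must be symmetric about 0", call. = FALSE)
  if (min(a) < -0.25 - 1e-12 || max(a) > 0.25 + 1e-12)
    stop("alpha_levels must lie in [-0.25, 0.25]", call. = FALSE)
  bad <- setdiff(names(cfg$effect_sizes),
                 c("brightness", "contrast", "saturation", "colorfulness",
                   "sharpness"))
  if (length(bad))
    stop("unknown effect_sizes entries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (cfg$downturn_fraction < 0 || cfg$downturn_fraction > 1)
    stop("downturn_fraction must be in [0, 1]", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  invisible(cfg)
}

category_ids <- function(n) sprintf("cat%04d", seq_len(n))

#' Broad content-group labels for categories
#'
#' Assigns each category one of eight broad semantic group labels
#' (animal, clothing, food, indoor, nature, outdoor, tool, vehicle) in
#' round-robin order.  The labels carry no visual meaning in the synthetic
#' generator; they exist to exercise confound analyses.
#'
#' @param ids character vector of category ids
#' @return character vector of group labels, same length as `ids`
#' @export
broad_category_labels <- function(ids) {
  .BROAD_GROUPS[(seq_along(ids) - 1L) %% length(.BROAD_GROUPS) + 1L]
}

#' Stimulus bookkeeping
#'
#' Computes the number of retained categories and total stimuli from a
#' starting category count, a manual exclusion count, seeds per category
#' and alpha levels per seed.
#'
#' @param n_initial starting number of categories
#' @param n_excluded number excluded
#' @param n_seeds seeds (base-image instances) per category
#' @param n_alpha alpha levels per seed
#' @return list with `n_categories` and `n_stimuli`
#' @export
#' @examples
#' stimulus_bookkeeping(1000, 511, 1, 15)  # 489 categories, 7335 stimuli
stimulus_bookkeeping <- function(n_initial, n_excluded, n_seeds, n_alpha) {
  stopifnot(n_excluded <= n_initial)
  n_cat <- as.integer(n_initial - n_excluded)
  list(n_categories = n_cat,
       n_stimuli = as.integer(n_cat * n_seeds * n_alpha))
}

#' Generate a procedural base image for one category
#'
#' Produces a deterministic RGB image from the category id and the
#' configuration seed: a smooth oriented gradient, a handful of elliptical
#' "object" blobs, and a faint sinusoidal texture.  The construction
#' guarantees spatial structure (several distinct region intensities) so
#' every feature operator has nonzero dynamic range.
#'
#' @param category_id character id
#' @param cfg a [generator_config()]
#' @return an `image_size x image_size x 3` array in `[0, 255]`
#' @export
generate_base_image <- function(category_id, cfg) {
  if (cfg$image_size < 8L)
    stop("configuration error: image_size must be at least 8", call. = FALSE)
  n <- cfg$image_size
  seed <- (hash_id(category_id) + 977 * (cfg$rng_seed %% 1000003L)) %% 2147483629
  withr::with_seed(as.integer(seed), {
    cx <- matrix(rep(seq(0, 1, length.out = n), each = n), n, n)  # column coord
    ry <- t(cx)                                                   # row coord
    theta <- stats::runif(1, 0, 2 * pi)
    g <- (cos(theta) * cx + sin(theta) * ry + 1) / 2
    base <- stats::runif(3, 40, 120)
    amp <- stats::runif(3, 50, 110)
    img <- array(0, c(n, n, 3L))
    for (k in 1:3) img[, , k] <- base[k] + amp[k] * g
    for (b in seq_len(sample(3:6, 1L))) {
      c0 <- stats::runif(2, 0.15, 0.85)
      ax <- stats::runif(2, 0.08, 0.30)
      rot <- stats::runif(1, 0, pi)
      col <- stats::runif(3, 10, 245)
      u <- (cx - c0[1L]) * cos(rot) + (ry - c0[2L]) * sin(rot)
      v <- -(cx - c0[1L]) * sin(rot) + (ry - c0[2L]) * cos(rot)
      mask <- (u / ax[1L])^2 + (v / ax[2L])^2 <= 1
      for (k in 1:3) {
        ch <- img[, , k]
        ch[mask] <- 0.15 * ch[mask] + 0.85 * col[k]
        img[, , k] <- ch
      }
    }
    tex <- 9 * sin(2 * pi * 7 * cx) * sin(2 * pi * 7 * ry)
    for (k in 1:3) img[, , k] <- img[, , k] + tex
    clip255(img)
  })
}

#' Apply the alpha transform to an image
#'
#' Steers the named features of `cfg$effect_sizes` along alpha with
#' elementary, auditable operators: an additive luma shift for brightness;
#' a multiplicative scaling of deviations about the mean luma for
#' contrast; a luma-preserving chroma gain for saturation and colorfulness
#' (both scale the opponent-colour components about the per-pixel luma, so
#' their gains compound); and an unsharp-mask blend with a 3x3 box-blurred
#' copy for sharpness (negative alpha blurs, positive alpha enhances).
#' Channels are clipped to `[0, 255]` at the end; `alpha = 0` returns the
#' input unchanged, exactly.
#'
#' @param img an RGB image array
#' @param alpha real in the range of `cfg$alpha_levels`
#' @param cfg a [generator_config()]
#' @return transformed image, same shape, values in `[0, 255]`
#' @export
apply_alpha_transform <- function(img, alpha, cfg) {
  assert_image(img)
  rng <- range(cfg$alpha_levels)
  if (alpha < rng[1L] - 1e-12 || alpha > rng[2L] + 1e-12)
    stop("alpha outside the configured range", call. = FALSE)
  if (alpha == 0) return(img)
  es <- cfg$effect_sizes
  out <- img
  if (!is.na(es["brightness"]))
    out <- out + es[["brightness"]] * alpha
  if (!is.na(es["contrast"])) {
    m <- mean(luma_matrix(out))
    out <- (out - m) * (1 + es[["contrast"]] * alpha) + m
  }
  chroma_gain <- 1
  if (!is.na(es["saturation"]))
    chroma_gain <- chroma_gain * (1 + es[["saturation"]] * alpha)
  if (!is.na(es["colorfulness"]))
    chroma_gain <- chroma_gain * (1 + es[["colorfulness"]] * alpha)
  if (chroma_gain != 1) {
    g <- luma_matrix(out)
    for (k in 1:3) out[, , k] <- g + (out[, , k] - g) * chroma_gain
  }
  if (!is.na(es["sharpness"])) {
    for (k in 1:3) {
      bl <- box_blur3(out[, , k])
      out[, , k] <- out[, , k] + es[["sharpness"]] * alpha * (out[, , k] - bl)
    }
  }
  clip255(out)
}

#' Generate one alpha-indexed image sequence
#'
#' Builds the base image for the category, applies the alpha transform at
#' every configured level, and attaches synthetic aesthetic scores
#' `score = base_cat + score_slope * alpha + N(0, noise_sd)`.  A downturn
#' category has its top-alpha score replaced by the second-highest level's
#' score minus `downturn_drop`, emulating sequences whose aesthetic
#' quality dips at the extreme despite still-increasing low-level
#' features.
#'
#' @param category_id character id
#' @param cfg a [generator_config()]
#' @param downturn `TRUE`, `FALSE`, or `NA` (default) to draw the downturn
#'   designation with probability `cfg$downturn_fraction` from the
#'   category's RNG stream
#' @return an `image_sequence` list with `category_id`, `alpha_levels`,
#'   `images` (list of arrays), `aesthetic_scores`, `downturn`
#' @export
generate_sequence <- function(category_id, cfg, downturn = NA) {
  base <- generate_base_image(category_id, cfg)
  images <- lapply(cfg$alpha_levels, function(a)
    apply_alpha_transform(base, a, cfg))
  seed <- (hash_id(category_id) + 977 * (cfg$rng_seed %% 1000003L) + 7L) %%
    2147483629
  scores <- withr::with_seed(as.integer(seed), {
    if (is.na(downturn)) downturn <- stats::runif(1) < cfg$downturn_fraction
    base_cat <- cfg$score_base + stats::rnorm(1, 0, cfg$score_base_sd)
    s <- base_cat + cfg$score_slope * cfg$alpha_levels +
      stats::rnorm(length(cfg$alpha_levels), 0, cfg$noise_sd)
    if (downturn) {
      n <- length(s)
      s[n] <- s[n - 1L] - cfg$downturn_drop
    }
    list(scores = s, downturn = downturn)
  })
  structure(list(category_id = category_id,
                 alpha_levels = cfg$alpha_levels,
                 images = images,
                 aesthetic_scores = scores$scores,
                 downturn = scores$downturn),
            class = "image_sequence")
}

#' Generate the full set of image sequences
#'
#' Generates one sequence per category.  Downturn categories are
#' designated globally: exactly `ceiling(downturn_fraction * n_categories)`
#' categories, sampled without replacement from the master seed, so the
#' realized downturn count matches the configured fraction rather than
#' fluctuating binomially.
#'
#' @param cfg a [generator_config()]
#' @return list of `image_sequence` objects, one per category
#' @export
generate_dataset <- function(cfg) {
  ids <- category_ids(cfg$n_categories)
  n_down <- ceiling(cfg$downturn_fraction * cfg$n_categories)
  down_ids <- withr::with_seed(cfg$rng_seed,
                               sample(ids, n_down))
  seqs <- lapply(ids, function(id)
    generate_sequence(id, cfg, downturn = id %in% down_ids))
  names(seqs) <- ids
  seqs
}

#' Simulate a feature table with a known linear score model
#'
#' Draws `n` rows of seven correlated standardized features (equicorrelated
#' multivariate normal) and a score `intercept + X beta + N(0, noise_sd)`.
#' Used for coefficient-recovery and coverage studies where the generating
#' truth must be known exactly.
#'
#' @param n number of rows
#' @param beta named numeric of length 7 (feature order of
#'   `extract_features`)
#' @param intercept scalar
#' @param rho pairwise feature correlation
#' @param noise_sd residual SD
#' @param seed integer seed
#' @return data frame with `category_id`, `alpha` (0), `aesthetic_score`
#'   and the seven feature columns
#' @export
simulate_feature_scores <- function(n, beta, intercept = 0, rho = 0.3,
                                    noise_sd = 0.5, seed = 1L) {
  stopifnot(length(beta) == 7L, abs(rho) < 1)
  sigma <- matrix(rho, 7L, 7L); diag(sigma) <- 1
  withr::with_seed(as.integer(seed), {
    x <- MASS::mvrnorm(n, mu = rep(0, 7L), Sigma = sigma)
    colnames(x) <- .FEATURE_NAMES
    y <- intercept + drop(x %*% beta) + stats::rnorm(n, 0, noise_sd)
    data.frame(category_id = sprintf("row%05d", seq_len(n)), alpha = 0,
               aesthetic_score = y, x, stringsAsFactors = FALSE)
  })
}
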
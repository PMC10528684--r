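#' RGB channel histograms for an image sequence
#'
#' Counts pixel intensities of each channel into 256 unit bins
#' (`[0,1), [1,2), ..., [254,255), [255,255]`) for every alpha level of a
#' sequence.  Counts per histogram always sum to the pixel count.
#'
#' @param seq an `image_sequence`
#' @return data frame with columns `alpha`, `channel` (`R`/`G`/`B`),
#'   `intensity` (0-255 bin lower edge), `count`
#' @export
rgb_histograms <- function(seq) {
  stopifnot(inherits(seq, "image_sequence"))
  chan <- c("R", "G", "B")
  out <- list()
  for (i in seq_along(seq$alpha_levels)) {
    img <- seq$images[[i]]
    for (k in 1:3) {
      bin <- pmin(floor(img[, , k]), 255)
      counts <- tabulate(bin + 1L, nbins = 256L)
      out[[length(out) + 1L]] <- data.frame(
        alpha = seq$alpha_levels[i], channel = chan[k],
        intensity = 0:255, count = counts)
    }
  }
  do.call(rbind, out)
}

screen_select <- function(stat, tail_fraction, decreasing) {
  # deterministic: order by the statistic, ties broken by category id
  ids <- names(stat)
  ord <- order(if (decreasing) -stat else stat, ids)
  k <- as.integer(ceiling(tail_fraction * length(stat)))
  sel <- ids[ord[seq_len(k)]]
  list(selected = sel,
       statistic_per_category = stat,
       cutoff = unname(stat[ord[k]]),
       n_selected = k)
}

#' Screen for sequences with the most stable low-level features
#'
#' For each category, sums the absolute change of the standardized
#' low-level features (brightness, contrast, sharpness, saturation by
#' default) between the lowest and highest alpha level, and selects the
#' `tail_fraction` of categories with the smallest sum.  Sequences whose
#' aesthetic score still rises despite stable low-level features point to
#' higher-level image properties at work.
#'
#' @param features a standardized feature table (z-scores; columns
#'   `category_id`, `alpha`, feature columns)
#' @param feature_set features entering the statistic (default the four
#'   low-level features)
#' @param tail_fraction selected tail (default 0.05)
#' @return a `screen_result` list: `selected` (ids),
#'   `statistic_per_category` (named), `cutoff`, `n_selected`
#' @export
stable_feature_sequences <- function(features,
                                     feature_set = .LOW_LEVEL_FEATURES,
                                     tail_fraction = 0.05) {
  stopifnot(all(c("category_id", "alpha", feature_set) %in% names(features)))
  a_min <- min(features$alpha); a_max <- max(features$alpha)
  ids <- sort(unique(features$category_id))
  stat <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (id in ids) {
    lo <- features[features$category_id == id & features$alpha == a_min, ]
    hi <- features[features$category_id == id & features$alpha == a_max, ]
    if (!nrow(lo) || !nrow(hi)) next
    stat[id] <- sum(abs(as.numeric(hi[1L, feature_set]) -
                          as.numeric(lo[1L, feature_set])))
  }
  if (anyNA(stat)) {
    warning(sum(is.na(stat)), " categor(ies) missing an extreme alpha ",
            "level; skipped", call. = FALSE)
    stat <- stat[!is.na(stat)]
  }
  structure(screen_select(stat, tail_fraction, decreasing = FALSE),
            class = "screen_result")
}

#' Screen for sequences whose aesthetic score dips at the top alpha
#'
#' For each sequence, computes `score(alpha_ref) - score(alpha_top)` and
#' selects the `tail_fraction` of categories with the largest value, i.e.
#' the strongest decrease in aesthetic quality between the reference and
#' the top alpha level despite still-increasing low-level features.
#'
#' @param sequences list of `image_sequence` objects
#' @param alpha_top top alpha level (default 0.25)
#' @param alpha_ref reference level (default 0.10)
#' @param tail_fraction selected tail (default 0.05)
#' @return a `screen_result` list as in [stable_feature_sequences()]
#' @export
aesthetic_downturn_sequences <- function(sequences, alpha_top = 0.25,
                                         alpha_ref = 0.10,
                                         tail_fraction = 0.05) {
  if (inherits(sequences, "image_sequence")) sequences <- list(sequences)
  stat <- numeric(); skipped <- 0L
  for (s in sequences) {
    i_top <- which(abs(s$alpha_levels - alpha_top) < 1e-9)
    i_ref <- which(abs(s$alpha_levels - alpha_ref) < 1e-9)
    if (!length(i_top) || !length(i_ref)) { skipped <- skipped + 1L; next }
    stat[s$category_id] <- s$aesthetic_scores[i_ref] -
      s$aesthetic_scores[i_top]
  }
  if (skipped)
    warning(skipped, " sequence(s) missing a required alpha level; skipped",
            call. = FALSE)
  if (!length(stat)) stop("no sequence has both alpha levels", call. = FALSE)
  structure(screen_select(stat, tail_fraction, decreasing = TRUE),
            class = "screen_result")
}

#' Gaussian summary of embedded images
#'
#' Embeds each image into a fixed-dimension vector (default: the seven
#' image features) and returns the mean vector and population covariance
#' of the embeddings.  This is the per-population summary entering the
#' Fréchet distance.
#'
#' @param images list of RGB image arrays (at least 2)
#' @param embedder function image -> numeric vector of fixed length;
#'   default [extract_features()]
#' @param params quadtree parameters for the default embedder
#' @return a `gaussian_summary` list with `mean` (length d) and `cov`
#'   (d x d, symmetric PSD up to tolerance), `n`
#' @export
embed_images <- function(images, embedder = NULL,
                         params = quadtree_params()) {
  if (length(images) < 2L)
    stop("need at least 2 images for a Gaussian summary", call. = FALSE)
  if (is.null(embedder)) embedder <- function(img) extract_features(img, params)
  e <- t(vapply(images, embedder, numeric(length(embedder(images[[1L]])))))
  gaussian_summary_of(e)
}

#' @rdname embed_images
#' @param x numeric matrix of embeddings, one row per image
#' @export
gaussian_summary_of <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 embeddings", call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sigma <- crossprod(xc) / n  # population covariance
  sigma <- (sigma + t(sigma)) / 2
  structure(list(mean = mu, cov = sigma, n = n),
            class = "gaussian_summary")
}

# symmetric PSD square root by eigendecomposition; eigenvalues in
# [-tol, 0) are clipped to 0, more negative ones raise an error
psd_sqrt <- function(m, tol = 1e-9) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < -tol)
    stop("matrix is not positive semidefinite; eigenvalues: ",
         paste(signif(e$values, 4L), collapse = ", "), call. = FALSE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Fréchet distance between two Gaussian summaries
#'
#' `||mu_a - mu_b||^2 + Tr(S_a + S_b - 2 (S_a S_b)^{1/2})`, the squared
#' 2-Wasserstein distance between the two Gaussians.  Symmetric,
#' nonnegative, and 0 iff the summaries coincide.  The matrix square root
#' uses a symmetric eigendecomposition of
#' `S_a^{1/2} S_b S_a^{1/2}`, with negative eigenvalues above `-1e-9`
#' clipped to zero.
#'
#' @param a,b `gaussian_summary` objects of matching dimension
#' @return nonnegative scalar
#' @export
#' @examples
#' a <- gaussian_summary_of(matrix(c(-1, 1), ncol = 1))  # mean 0, var 1
#' b <- gaussian_summary_of(matrix(c(0, 2), ncol = 1))   # mean 1, var 1
#' frechet_distance(a, b)  # 1
frechet_distance <- function(a, b) {
  if (length(a$mean) != length(b$mean))
    stop("dimension mismatch between summaries", call. = FALSE)
  sa <- psd_sqrt(a$cov)
  inner <- sa %*% b$cov %*% sa
  inner <- (inner + t(inner)) / 2
  ev <- eigen(inner, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9)
    stop("cross term is not positive semidefinite; eigenvalues: ",
         paste(signif(ev, 4L), collapse = ", "), call. = FALSE)
  tr_cross <- sum(sqrt(pmax(ev, 0)))
  d <- sum((a$mean - b$mean)^2) + sum(diag(a$cov)) + sum(diag(b$cov)) -
    2 * tr_cross
  max(d, 0)
}

#' Mean Fréchet distance profile across alpha levels
#'
#' Embeds all images at each alpha level and computes the Fréchet
#' distance between every level's Gaussian summary and the summary of a
#' reference level, mirroring a realism-versus-alpha curve (with a
#' pluggable embedding in place of a learned one).
#'
#' @param sequences list of `image_sequence` objects
#' @param reference_alpha level whose population is the reference
#'   (default the maximum level)
#' @param embedder,params passed to [embed_images()]
#' @return data frame with columns `alpha` and `frechet`
#' @export
frechet_profile <- function(sequences, reference_alpha = NULL,
                            embedder = NULL, params = quadtree_params()) {
  if (inherits(sequences, "image_sequence")) sequences <- list(sequences)
  levels <- sort(unique(unlist(lapply(sequences, `[[`, "alpha_levels"))))
  if (is.null(reference_alpha)) reference_alpha <- max(levels)
  pool <- function(al) {
    imgs <- list()
    for (s in sequences) {
      i <- which(abs(s$alpha_levels - al) < 1e-9)
      if (length(i)) imgs[[length(imgs) + 1L]] <- s$images[[i]]
    }
    imgs
  }
  ref <- embed_images(pool(reference_alpha), embedder, params)
  out <- data.frame(alpha = levels, frechet = NA_real_)
  for (i in seq_along(levels)) {
    out$frechet[i] <- frechet_distance(
      embed_images(pool(levels[i]), embedder, params), ref)
  }
  out
}
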
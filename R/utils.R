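#' @keywords internal
"_PACKAGE"

# ITU-R 601 luma weights; kept real-valued so operator examples are exact
.LUMA_W <- c(0.299, 0.587, 0.114)

.FEATURE_NAMES <- c("brightness", "contrast", "sharpness", "saturation",
                    "colorfulness", "complexity", "symmetry")
.LOW_LEVEL_FEATURES <- c("brightness", "contrast", "sharpness", "saturation")

.BROAD_GROUPS <- c("animal", "clothing", "food", "indoor",
                   "nature", "outdoor", "tool", "vehicle")

clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' Deterministic 32-bit hash of a string
#'
#' Polynomial rolling hash used to derive per-category RNG streams from a
#' single configuration seed.  Not cryptographic; collisions are irrelevant
#' at the scale of a few thousand category ids.
#' @param x character scalar
#' @return integer in `[0, 2147483628]`
#' @keywords internal
hash_id <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

# population standard deviation (divide by N) -- documented choice so that
# hand-derived operator values are exact
sd_pop <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

assert_image <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  d <- dim(img)
  if (d[1L] * d[2L] < 2L)
    stop(sprintf("`%s` must have at least 2 pixels", arg), call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(sprintf("`%s` must contain finite values in [0, 255]", arg),
         call. = FALSE)
  invisible(img)
}

luma_matrix <- function(img) {
  .LUMA_W[1L] * img[, , 1L] + .LUMA_W[2L] * img[, , 2L] + .LUMA_W[3L] * img[, , 3L]
}

# 3x3 box blur with replicated borders, applied per channel
box_blur3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- function(d) pmin(pmax(seq_len(nr) + d, 1L), nr)
  ci <- function(d) pmin(pmax(seq_len(nc) + d, 1L), nc)
  acc <- matrix(0, nr, nc)
  for (dr in -1:1)
    for (dc in -1:1)
      acc <- acc + m[ri(dr), ci(dc)]
  acc / 9
}
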
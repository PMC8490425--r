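#' Structural similarity index (SSIM)
#'
#' Windowed SSIM with Gaussian weights (11x11, sigma 1.5) and the usual two
#' stabilization constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` where `L` is
#' the dynamic range. The map is averaged over windows fully inside the
#' image, so no border padding enters the score. Symmetric in its two
#' arguments.
#'
#' @param a,b numeric matrices with equal dimensions.
#' @param window odd window size (default 11, shrunk if the image is small).
#' @param sigma Gaussian window sigma.
#' @param data_range dynamic range `L`; default spans both images jointly.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b, window = 11L, sigma = 1.5, data_range = NULL) {
  if (!all(dim(a) == dim(b))) stop("images must have equal dimensions")
  window <- min(window, min(dim(a)))
  if (window %% 2L == 0L) window <- window - 1L
  if (window < 3L) stop("image too small for an SSIM window")
  if (is.null(data_range)) {
    data_range <- max(max(a), max(b)) - min(min(a), min(b))
    if (data_range <= 0) data_range <- 1
  }
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  half <- (window - 1L) %/% 2L
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  mu_a <- sep_conv2(a, k); mu_b <- sep_conv2(b, k)
  s_aa <- sep_conv2(a * a, k) - mu_a^2
  s_bb <- sep_conv2(b * b, k) - mu_b^2
  s_ab <- sep_conv2(a * b, k) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * s_ab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (s_aa + s_bb + c2)
  mean((num / den)[!is.na(num / den)])
}

# separable 2-D convolution; NA outside fully-supported windows
sep_conv2 <- function(img, k) {
  cols <- apply(img, 2L, function(v) stats::filter(v, k, sides = 2))
  t(apply(cols, 1L, function(v) stats::filter(v, k, sides = 2)))
}

#' Mutual information of two images
#'
#' Shannon mutual information (in bits) of the joint histogram obtained by
#' binning each image over its own intensity range into `bins` equal-width
#' bins. `mutual_information(x, x)` equals the entropy of `x`'s binned
#' marginal.
#'
#' @param a,b numeric matrices with equal dimensions.
#' @param bins number of histogram bins per image.
#' @return non-negative scalar (bits).
#' @export
mutual_information <- function(a, b, bins = 64L) {
  if (!all(dim(a) == dim(b))) stop("images must have equal dimensions")
  ia <- bin_index(as.vector(a), bins)
  ib <- bin_index(as.vector(b), bins)
  joint <- tabulate((ia - 1L) * bins + ib, nbins = bins * bins)
  p <- joint / sum(joint)
  pm <- base::matrix(p, bins, bins)  # [ib, ia]
  pa <- colSums(pm); pb <- rowSums(pm)
  nz <- p > 0
  outer_p <- as.vector(pb %o% pa)
  sum(p[nz] * log2(p[nz] / outer_p[nz]))
}

bin_index <- function(v, bins) {
  rng <- range(v)
  if (rng[2] <= rng[1]) return(rep(1L, length(v)))
  i <- floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  pmin(i, bins)
}

#' Pearson correlation of two images
#'
#' Pearson correlation coefficient over flattened pixel intensities.
#'
#' @param a,b numeric matrices with equal dimensions; both non-constant.
#' @return scalar in `[-1, 1]`.
#' @export
pcc <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("images must have equal dimensions")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("PCC undefined for a constant image")
  stats::cor(as.vector(a), as.vector(b))
}

#' Interquartile range with linear-interpolation quartiles
#'
#' `Q3 - Q1` using type-7 (linear interpolation) quantiles, the rule used
#' when ranking transformation models by the spread of their similarity
#' scores. For `c(1, 2, 3, 4, 100)` the quartiles are 2 and 4, so the IQR
#' is 2.
#'
#' @param x numeric vector.
#' @return non-negative scalar.
#' @export
iqr_linear <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Paired Student's t test
#'
#' Thin wrapper around [stats::t.test()] for paired scores (one score per
#' image from each of two methods), returning the statistic, p-value and a
#' significance flag at the requested level.
#'
#' @param x,y paired numeric vectors.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param alpha significance level.
#' @return list with `statistic`, `p_value`, `significant`, `alternative`.
#' @export
paired_t_test <- function(x, y, alternative = "two.sided", alpha = 0.05) {
  d <- x - y
  if (length(d) < 2L)
    return(list(statistic = NA_real_, p_value = NA_real_,
                significant = FALSE, alternative = alternative))
  if (stats::sd(d) == 0) {
    # identical score vectors: no evidence of a difference
    return(list(statistic = 0, p_value = 1, significant = FALSE,
                alternative = alternative))
  }
  ht <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       significant = ht$p.value < alpha, alternative = alternative)
}
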
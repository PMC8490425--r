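#' Detect local features in an image
#'
#' Three detectors behind one interface, all returning subpixel keypoint
#' locations with patch descriptors:
#'
#' * `"blob"` (default): scale-covariant determinant-of-Hessian detector.
#'   The image is smoothed at several scales, the scale-normalized Hessian
#'   determinant magnitude is maximized over space, and keypoints are
#'   refined to subpixel accuracy by a quadratic fit. This fills the role
#'   fast Hessian-based detectors (SURF-style) play in multi-sensor
#'   registration.
#' * `"mser"`: simplified maximally-stable-extremal-regions detector — a
#'   threshold sweep over both polarities keeps connected components whose
#'   area is most stable across neighbouring thresholds and describes their
#'   centroids.
#' * `"harris"`: Harris corner detector with subpixel refinement.
#'
#' Descriptors are 64-dimensional normalized intensity patches (8x8 samples
#' at the keypoint's scale), robust to the small rotations and scale changes
#' of a near-perpendicular two-camera rig.
#'
#' @param img numeric matrix, at least 16x16.
#' @param detector `"blob"`, `"mser"` or `"harris"`.
#' @param max_keypoints keep at most this many strongest keypoints.
#' @param threshold_rel response threshold relative to the strongest
#'   response.
#' @return list of class `feature_set`: `points` (n x 2, `(x, y)`),
#'   `scales`, `responses`, `descriptors` (n x 64), `detector`.
#' @export
detect_features <- function(img, detector = c("blob", "mser", "harris"),
                            max_keypoints = 400L, threshold_rel = 0.02) {
  detector <- match.arg(detector)
  if (nrow(img) < 16L || ncol(img) < 16L) stop("image must be >= 16x16")
  rng <- range(img)
  if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  kp <- switch(detector,
    blob = detect_doh(img, threshold_rel),
    harris = detect_harris(img, threshold_rel),
    mser = detect_mser(img))
  if (nrow(kp) == 0L)
    return(structure(list(points = base::matrix(0, 0, 2), scales = numeric(0),
                          responses = numeric(0),
                          descriptors = base::matrix(0, 0, 64),
                          detector = detector),
                     class = "feature_set"))
  ord <- order(-kp[, "response"])
  kp <- kp[utils::head(ord, max_keypoints), , drop = FALSE]
  desc <- patch_descriptors(img, kp[, c("x", "y"), drop = FALSE],
                            kp[, "scale"])
  keep <- !is.na(desc[, 1])
  structure(list(points = kp[keep, c("x", "y"), drop = FALSE],
                 scales = kp[keep, "scale"],
                 responses = kp[keep, "response"],
                 descriptors = desc[keep, , drop = FALSE],
                 detector = detector),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set %s> %d keypoints\n", x$detector, nrow(x$points)))
  invisible(x)
}

# determinant-of-Hessian keypoints over a scale ladder
detect_doh <- function(img, threshold_rel) {
  sigmas <- c(1.2, 1.8, 2.7, 4.0)
  out <- NULL
  for (s in sigmas) {
    sm <- as.matrix(EBImage::gblur(img, sigma = s))
    resp <- s^4 * abs(hessian_det(sm))
    pk <- local_maxima(resp, threshold = threshold_rel * max(resp))
    if (nrow(pk)) out <- rbind(out, cbind(pk, scale = s))
  }
  dedupe_keypoints(out, radius = 2)
}

detect_harris <- function(img, threshold_rel, k = 0.04) {
  sm <- as.matrix(EBImage::gblur(img, sigma = 1))
  gx <- grad_x(sm); gy <- grad_y(sm)
  w <- 1.5
  a <- as.matrix(EBImage::gblur(gx * gx, sigma = w))
  b <- as.matrix(EBImage::gblur(gy * gy, sigma = w))
  cxy <- as.matrix(EBImage::gblur(gx * gy, sigma = w))
  resp <- a * b - cxy^2 - k * (a + b)^2
  pk <- local_maxima(resp, threshold = threshold_rel * max(resp))
  if (nrow(pk) == 0L) return(pk_empty())
  cbind(pk, scale = rep(2, nrow(pk)))
}

# threshold-sweep approximation of MSER: keep components whose area is
# stable across neighbouring thresholds, for both polarities
detect_mser <- function(img, levels = seq(0.1, 0.9, by = 0.025),
                        min_area = 20, max_area_frac = 0.25,
                        max_stability = 0.3) {
  npix <- length(img)
  cand <- NULL
  for (polarity in c(1, -1)) {
    src <- if (polarity > 0) img else 1 - img
    areas <- vector("list", length(levels))
    labs <- vector("list", length(levels))
    for (i in seq_along(levels)) {
      lab <- EBImage::bwlabel(src > levels[i])
      labs[[i]] <- lab
      areas[[i]] <- tabulate(lab[lab > 0])
    }
    for (i in seq_len(length(levels) - 1L)) {
      lab <- labs[[i]]
      a <- areas[[i]]
      ok <- which(a >= min_area & a <= max_area_frac * npix)
      for (id in ok) {
        idx <- which(lab == id)
        # one-sided stability: relative area change to the next (tighter)
        # threshold, tracked through a member pixel
        id_hi <- labs[[i + 1]][idx[1]]
        a_hi <- if (id_hi > 0) areas[[i + 1]][id_hi] else 0
        stab <- abs(a[id] - a_hi) / a[id]
        if (stab <= max_stability) {
          rr <- ((idx - 1) %% nrow(img)) + 1
          cc <- ((idx - 1) %/% nrow(img)) + 1
          cand <- rbind(cand, c(x = mean(cc), y = mean(rr),
                                response = 1 / (stab + 1e-3),
                                scale = max(2, sqrt(a[id] / pi) / 2)))
        }
      }
    }
  }
  if (is.null(cand)) return(pk_empty())
  colnames(cand) <- c("x", "y", "response", "scale")
  dedupe_keypoints(cand, radius = 3)
}

pk_empty <- function() {
  m <- base::matrix(numeric(0), 0, 4)
  colnames(m) <- c("x", "y", "response", "scale")
  m
}

# greedy non-max over a radius, strongest response wins
dedupe_keypoints <- function(kp, radius = 2) {
  if (is.null(kp) || nrow(kp) == 0L) return(pk_empty())
  kp <- kp[order(-kp[, "response"]), , drop = FALSE]
  keep <- logical(nrow(kp))
  for (i in seq_len(nrow(kp))) {
    if (i == 1L) { keep[1] <- TRUE; next }
    prev <- kp[keep, , drop = FALSE]
    d2 <- (prev[, "x"] - kp[i, "x"])^2 + (prev[, "y"] - kp[i, "y"])^2
    keep[i] <- min(d2) > radius^2
  }
  kp[keep, , drop = FALSE]
}

grad_x <- function(img) {
  nc <- ncol(img)
  (img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]) / 2
}
grad_y <- function(img) {
  nr <- nrow(img)
  (img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]) / 2
}

hessian_det <- function(img) {
  lxx <- grad_x(grad_x(img))
  lyy <- grad_y(grad_y(img))
  lxy <- grad_y(grad_x(img))
  lxx * lyy - lxy^2
}

# 3x3 non-max suppression + quadratic subpixel refinement
local_maxima <- function(resp, threshold, border = 4L) {
  nr <- nrow(resp); nc <- ncol(resp)
  out <- NULL
  interior_r <- (border + 1L):(nr - border)
  interior_c <- (border + 1L):(nc - border)
  sub <- resp[interior_r, interior_c]
  shift <- function(dr, dc) resp[interior_r + dr, interior_c + dc]
  is_max <- sub >= threshold &
    sub >= shift(-1, -1) & sub >= shift(-1, 0) & sub >= shift(-1, 1) &
    sub >= shift(0, -1) & sub > shift(0, 1) &
    sub > shift(1, -1) & sub > shift(1, 0) & sub > shift(1, 1)
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(pk_empty())
  rr <- idx[, 1] + border; cc <- idx[, 2] + border
  # quadratic fit along each axis: offset = (f(-1) - f(1)) / (2 (f(-1) - 2 f(0) + f(1)))
  f0 <- resp[cbind(rr, cc)]
  fxm <- resp[cbind(rr, cc - 1L)]; fxp <- resp[cbind(rr, cc + 1L)]
  fym <- resp[cbind(rr - 1L, cc)]; fyp <- resp[cbind(rr + 1L, cc)]
  dx <- (fxm - fxp) / (2 * (fxm - 2 * f0 + fxp))
  dy <- (fym - fyp) / (2 * (fym - 2 * f0 + fyp))
  dx[!is.finite(dx) | abs(dx) > 0.6] <- 0
  dy[!is.finite(dy) | abs(dy) > 0.6] <- 0
  m <- cbind(x = cc + dx, y = rr + dy, response = f0)
  m
}

# 8x8 intensity patches sampled proportionally to the keypoint scale,
# zero-mean unit-norm; the support spans several structure elements so
# repeated local patterns stay distinguishable
patch_descriptors <- function(img, pts, scales, grid_n = 8L) {
  n <- nrow(pts)
  desc <- base::matrix(NA_real_, n, grid_n * grid_n)
  offs <- seq(-(grid_n - 1) / 2, (grid_n - 1) / 2, length.out = grid_n)
  for (i in seq_len(n)) {
    step <- max(2.5, 2 * scales[i])
    gx <- pts[i, 1] + offs * step
    gy <- pts[i, 2] + offs * step
    vals <- bilinear_sample(img, rep(gx, each = grid_n),
                            rep(gy, times = grid_n), fill = NA_real_)
    if (anyNA(vals)) next
    vals <- vals - mean(vals)
    nv <- sqrt(sum(vals^2))
    if (nv < 1e-12) next
    desc[i, ] <- vals / nv
  }
  desc
}

#' Match feature descriptors between two images
#'
#' Nearest-neighbour matching with Lowe's distance-ratio test and optional
#' mutual-best filtering.
#'
#' @param fixed_feats,moving_feats `feature_set`s from [detect_features()].
#' @param ratio distance-ratio threshold (best/second-best); 0 rejects
#'   everything.
#' @param mutual require the match to be nearest in both directions.
#' @return list of class `match_set`: `fixed_points`, `moving_points`
#'   (n x 2), `distances`.
#' @export
match_features <- function(fixed_feats, moving_feats, ratio = 0.7,
                           mutual = TRUE) {
  da <- fixed_feats$descriptors; db <- moving_feats$descriptors
  if (nrow(da) == 0L || nrow(db) == 0L)
    stop("cannot match empty descriptor sets")
  # squared euclidean cross-distance
  d2 <- outer(rowSums(da^2), rowSums(db^2), "+") - 2 * da %*% t(db)
  d2[d2 < 0] <- 0
  nn1 <- apply(d2, 1L, which.min)
  d1 <- d2[cbind(seq_len(nrow(d2)), nn1)]
  d2nd <- apply(d2, 1L, function(r) sort(r, partial = 2)[2])
  pass <- sqrt(d1) <= ratio * sqrt(d2nd)
  pass[!is.finite(d2nd)] <- FALSE
  if (mutual) {
    back <- apply(d2, 2L, which.min)
    pass <- pass & back[nn1] == seq_len(nrow(d2))
  }
  idx <- which(pass)
  structure(list(fixed_points = fixed_feats$points[idx, , drop = FALSE],
                 moving_points = moving_feats$points[nn1[idx], , drop = FALSE],
                 distances = sqrt(d1[idx])),
            class = "match_set")
}

#' Construct a match set from explicit correspondences
#' @param fixed_points,moving_points n x 2 matrices of `(x, y)` points.
#' @param distances optional per-pair match distances.
#' @return `match_set`.
#' @export
match_set <- function(fixed_points, moving_points, distances = NULL) {
  fixed_points <- base::matrix(fixed_points, ncol = 2L)
  moving_points <- base::matrix(moving_points, ncol = 2L)
  if (nrow(fixed_points) != nrow(moving_points))
    stop("point sets differ in length")
  if (is.null(distances)) distances <- rep(0, nrow(fixed_points))
  structure(list(fixed_points = fixed_points, moving_points = moving_points,
                 distances = distances),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set> %d correspondences\n", nrow(x$fixed_points)))
  invisible(x)
}
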
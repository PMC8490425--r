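#' Intensity-based registration
#'
#' Estimates the transform aligning `moving` onto `fixed` by minimizing the
#' mean-squared intensity difference over the overlap, with a 3-level
#' multi-resolution pyramid and Nelder-Mead refinement at each level
#' (coarse levels capture large displacements, fine levels polish).
#'
#' @param fixed,moving numeric matrices (grayscale images).
#' @param kind `"translation"`, `"similarity"` or `"affine"`.
#' @param pyramid_levels number of pyramid levels.
#' @param maxit Nelder-Mead iteration budget per level.
#' @return `transform_model`; `provenance$converged` flags optimizer
#'   convergence at the finest level, `provenance$score` is the final SSIM.
#' @export
register_intensity <- function(fixed, moving,
                               kind = c("translation", "similarity",
                                        "affine"),
                               pyramid_levels = 3L, maxit = 300L) {
  kind <- match.arg(kind)
  pyr_f <- image_pyramid(fixed, pyramid_levels)
  pyr_m <- image_pyramid(moving, pyramid_levels)
  p <- init_params(kind)
  converged <- TRUE
  for (lev in rev(seq_len(pyramid_levels))) {
    f <- pyr_f[[lev]]; m <- pyr_m[[lev]]
    scale <- 2^(lev - 1)
    obj <- function(par) {
      mat <- params_to_matrix(par, kind, trans_scale = 1 / scale)
      w <- warp_image(m, transform_model(kind, mat), dim(f), fill = NA)
      ok <- w$mask
      if (mean(ok) < 0.25) return(1e6)
      mean((w$image[ok] - f[ok])^2)
    }
    fit <- stats::optim(p, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit,
                                       reltol = 1e-9,
                                       parscale = param_scales(kind)))
    p <- fit$par
    if (lev == 1L) converged <- fit$convergence == 0L
  }
  mat <- params_to_matrix(p, kind, trans_scale = 1)
  w <- warp_image(moving, mat, dim(fixed))
  transform_model(kind, mat,
                  provenance = list(technique = "intensity",
                                    converged = converged,
                                    score = ssim(fixed, w$image)))
}

image_pyramid <- function(img, levels) {
  out <- list(img)
  for (l in seq_len(levels - 1L)) {
    prev <- out[[l]]
    nr <- nrow(prev) %/% 2L; nc <- ncol(prev) %/% 2L
    if (nr < 16L || nc < 16L) break
    sub <- prev[seq_len(2L * nr), seq_len(2L * nc)]
    out[[l + 1L]] <- 0.25 * (sub[seq(1, 2 * nr, 2), seq(1, 2 * nc, 2)] +
                             sub[seq(2, 2 * nr, 2), seq(1, 2 * nc, 2)] +
                             sub[seq(1, 2 * nr, 2), seq(2, 2 * nc, 2)] +
                             sub[seq(2, 2 * nr, 2), seq(2, 2 * nc, 2)])
  }
  out
}

init_params <- function(kind) {
  switch(kind,
         translation = c(0, 0),
         similarity = c(0, 0, 0, 0),          # log-scale, angle, tx, ty
         affine = c(0, 0, 0, 0, 0, 0))        # da11 a12 a21 da22 tx ty
}

param_scales <- function(kind) {
  switch(kind,
         translation = c(1, 1),
         similarity = c(0.02, 0.02, 1, 1),
         affine = c(0.02, 0.02, 0.02, 0.02, 1, 1))
}

params_to_matrix <- function(p, kind, trans_scale = 1) {
  switch(kind,
    translation = rbind(c(1, 0, p[1] * trans_scale),
                        c(0, 1, p[2] * trans_scale),
                        c(0, 0, 1)),
    similarity = {
      s <- exp(p[1]); th <- p[2]
      rbind(c(s * cos(th), -s * sin(th), p[3] * trans_scale),
            c(s * sin(th),  s * cos(th), p[4] * trans_scale),
            c(0, 0, 1))
    },
    affine = rbind(c(1 + p[1], p[2], p[5] * trans_scale),
                   c(p[3], 1 + p[4], p[6] * trans_scale),
                   c(0, 0, 1)))
}

#' Feature-based registration
#'
#' Composition detect -> match -> MSAC: detects keypoints in both images,
#' matches descriptors with the ratio test, and robustly estimates the
#' moving-to-fixed transform.
#'
#' @param fixed,moving numeric matrices (grayscale images).
#' @param detector passed to [detect_features()].
#' @param kind transform kind (default projective).
#' @param seed MSAC seed.
#' @param ratio match ratio-test threshold.
#' @param trials MSAC trials.
#' @param inlier_tol_px MSAC inlier tolerance.
#' @param presmooth_sigma Gaussian blur applied to both images before
#'   detection (0 disables); suppresses sensor noise that otherwise
#'   degrades keypoint repeatability.
#' @return `transform_model` with filled provenance (detector, match count,
#'   SSIM score after warping).
#' @export
register_features <- function(fixed, moving, detector = "blob",
                              kind = "projective", seed = 1L, ratio = 0.7,
                              trials = 1000L, inlier_tol_px = 1.5,
                              presmooth_sigma = 1) {
  if (presmooth_sigma > 0) {
    fixed_s <- as.matrix(EBImage::gblur(fixed, sigma = presmooth_sigma))
    moving_s <- as.matrix(EBImage::gblur(moving, sigma = presmooth_sigma))
  } else {
    fixed_s <- fixed; moving_s <- moving
  }
  ff <- detect_features(fixed_s, detector)
  fm <- detect_features(moving_s, detector)
  matches <- match_features(ff, fm, ratio = ratio)
  need <- min_sample_size(kind)
  if (nrow(matches$fixed_points) < max(need, 4L))
    stop("too few matches (", nrow(matches$fixed_points),
         ") for feature-based registration")
  tm <- estimate_msac(matches, kind, seed = seed, trials = trials,
                      inlier_tol_px = inlier_tol_px)
  # model-guided subpixel refinement: re-localize each inlier in the moving
  # image by correlation around its model-predicted position, then refit
  inl <- tm$provenance$inliers
  if (length(inl) >= 2L * min_sample_size(kind)) {
    for (pass in 1:2) {
      # re-select inliers under the current model so true matches recovered
      # by refinement can join the fit
      r2 <- rowSums((apply_transform(tm$matrix, matches$moving_points) -
                       matches$fixed_points)^2)
      inl <- which(r2 < inlier_tol_px^2)
      if (length(inl) < min_sample_size(kind)) break
      fx <- matches$fixed_points[inl, , drop = FALSE]
      pred <- apply_transform(solve(tm$matrix), fx)
      ref <- refine_correspondences(fixed_s, moving_s, fx, pred,
                                    window = 13L, search = 1, step = 0.25)
      ok <- !is.na(ref[, 1])
      if (sum(ok) < min_sample_size(kind)) break
      refit <- tryCatch(fit_transform(fx[ok, , drop = FALSE],
                                      ref[ok, , drop = FALSE], kind),
                        error = function(e) NULL)
      if (is.null(refit)) break
      refit$provenance <- tm$provenance
      refit$provenance$refined <- sum(ok)
      tm <- refit
    }
  }
  w <- warp_image(moving, tm, dim(fixed))
  tm$provenance$technique <- "features"
  tm$provenance$detector <- detector
  tm$provenance$score <- ssim(fixed, w$image)
  tm
}

# re-localize predicted moving-frame positions by normalized cross
# correlation over a subpixel search grid, with parabolic peak refinement
refine_correspondences <- function(fixed_img, moving_img, fixed_pts,
                                   moving_pred, window = 9L, search = 1.5,
                                   step = 0.5) {
  half <- (window - 1) / 2
  offs <- -half:half
  px <- rep(offs, each = window); py <- rep(offs, times = window)
  n <- nrow(fixed_pts)
  steps <- seq(-search, search, by = step)
  ns <- length(steps)
  ncc <- array(NA_real_, c(n, ns, ns))
  tmpl <- base::matrix(NA_real_, n, window * window)
  for (i in seq_len(n))
    tmpl[i, ] <- bilinear_sample(fixed_img, fixed_pts[i, 1] + px,
                                 fixed_pts[i, 2] + py, fill = NA_real_)
  tmpl <- tmpl - rowMeans(tmpl)
  tn <- sqrt(rowSums(tmpl^2))
  for (a in seq_len(ns)) for (b in seq_len(ns)) {
    for (i in seq_len(n)) {
      if (is.na(tn[i]) || tn[i] < 1e-12) next
      patch <- bilinear_sample(moving_img,
                               moving_pred[i, 1] + steps[a] + px,
                               moving_pred[i, 2] + steps[b] + py,
                               fill = NA_real_)
      if (anyNA(patch)) next
      patch <- patch - mean(patch)
      pn <- sqrt(sum(patch^2))
      if (pn < 1e-12) next
      ncc[i, a, b] <- sum(tmpl[i, ] * patch) / (tn[i] * pn)
    }
  }
  out <- base::matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    sl <- ncc[i, , ]
    if (all(is.na(sl))) next
    peak <- which(sl == max(sl, na.rm = TRUE), arr.ind = TRUE)[1, ]
    dx <- steps[peak[1]]; dy <- steps[peak[2]]
    # parabolic sub-step refinement where the peak is interior
    if (peak[1] > 1 && peak[1] < ns && !anyNA(sl[peak[1] + c(-1, 1),
                                                 peak[2]])) {
      f0 <- sl[peak[1], peak[2]]
      fm1 <- sl[peak[1] - 1, peak[2]]; fp1 <- sl[peak[1] + 1, peak[2]]
      den <- fm1 - 2 * f0 + fp1
      if (den < 0) dx <- dx + step * (fm1 - fp1) / (2 * den)
    }
    if (peak[2] > 1 && peak[2] < ns && !anyNA(sl[peak[1],
                                                 peak[2] + c(-1, 1)])) {
      f0 <- sl[peak[1], peak[2]]
      fm1 <- sl[peak[1], peak[2] - 1]; fp1 <- sl[peak[1], peak[2] + 1]
      den <- fm1 - 2 * f0 + fp1
      if (den < 0) dy <- dy + step * (fm1 - fp1) / (2 * den)
    }
    out[i, ] <- c(moving_pred[i, 1] + dx, moving_pred[i, 2] + dy)
  }
  out
}

#' Grayscale rendering of a cube for registration
#'
#' Pseudo-RGB followed by luminance conversion, the representation used to
#' drive the registration metrics.
#'
#' @param cube `hs_cube`.
#' @param band optional single band index: min-max scaled band plane
#'   instead of the pseudo-RGB path.
#' @return numeric matrix in `[0, 1]`.
#' @export
gray_from_cube <- function(cube, band = NULL) {
  if (!is.null(band)) {
    plane <- cube$data[, , band]
    rng <- range(plane)
    return(if (rng[2] > rng[1]) (plane - rng[1]) / (rng[2] - rng[1])
           else plane * 0)
  }
  to_grayscale(pseudo_rgb(cube))
}

#' Coarse-to-fine search for the best registration band pair
#'
#' Stage 1 scans a coarse grid of (VNIR band, NIR band) combinations —
#' default steps of 7 and 3 bands respectively — registering the two
#' single-band grayscale images at each combination and scoring the result.
#' Stage 2 repeats at single-band steps inside the neighbourhood of the
#' best coarse pair. SSIM drives the final selection because it responds to
#' image structure rather than raw intensity; MI and PCC grids can be
#' computed for diagnostics.
#'
#' @param vnir,nir pre-processed `hs_cube`s on a common spatial grid.
#' @param coarse_steps `c(vnir_step, nir_step)`.
#' @param metric `"ssim"`, `"mi"` or `"pcc"` (SSIM recommended).
#' @param seed base seed; each band pair derives its own MSAC seed so a
#'   pair's score is reproducible in both stages.
#' @param registration `"features"` (register each pair before scoring) or
#'   `"none"` (score as-is; for already-registered cubes).
#' @param detector,kind,trials registration settings.
#' @return list of class `band_search_result`: `coarse` and `fine` stages
#'   (band index vectors + score grids), `best_pair` (VNIR, NIR band
#'   indices), `best_score`, `best_transform`, `metric`, `steps`.
#' @export
coarse_to_fine_band_search <- function(vnir, nir, coarse_steps = c(7L, 3L),
                                       metric = c("ssim", "mi", "pcc"),
                                       seed = 1L,
                                       registration = c("features", "none"),
                                       detector = "blob",
                                       kind = "projective",
                                       trials = 300L) {
  metric <- match.arg(metric)
  registration <- match.arg(registration)
  b1 <- n_bands(vnir); b2 <- n_bands(nir)
  vb <- seq(1L, b1, by = coarse_steps[1])
  nb <- seq(1L, b2, by = coarse_steps[2])
  score_pair <- function(i, j) {
    f <- gray_from_cube(vnir, band = i)
    m <- gray_from_cube(nir, band = j)
    if (registration == "features") {
      tm <- tryCatch(
        register_features(f, m, detector = detector, kind = kind,
                          seed = as.integer(seed + 1000L * i + j),
                          trials = trials),
        error = function(e) NULL)
      if (is.null(tm)) return(list(score = NA_real_, tm = NULL))
      m <- warp_image(m, tm, dim(f))$image
    } else tm <- NULL
    s <- tryCatch(switch(metric, ssim = ssim(f, m),
                         mi = mutual_information(f, m), pcc = pcc(f, m)),
                  error = function(e) NA_real_)
    list(score = s, tm = tm)
  }
  grid_scan <- function(vb, nb) {
    g <- base::matrix(NA_real_, length(vb), length(nb),
                      dimnames = list(vb, nb))
    tms <- list()
    for (ii in seq_along(vb)) for (jj in seq_along(nb)) {
      r <- score_pair(vb[ii], nb[jj])
      g[ii, jj] <- r$score
      tms[[paste(vb[ii], nb[jj])]] <- r$tm
    }
    list(grid = g, tms = tms)
  }
  coarse <- grid_scan(vb, nb)
  bc <- best_grid_cell(coarse$grid, vb, nb)
  if (is.null(bc)) stop("no band pair produced a valid registration score")
  fine_vb <- seq(max(1L, bc[1] - coarse_steps[1] + 1L),
                 min(b1, bc[1] + coarse_steps[1] - 1L))
  fine_nb <- seq(max(1L, bc[2] - coarse_steps[2] + 1L),
                 min(b2, bc[2] + coarse_steps[2] - 1L))
  fine <- grid_scan(fine_vb, fine_nb)
  bf <- best_grid_cell(fine$grid, fine_vb, fine_nb)
  best_tm <- fine$tms[[paste(bf[1], bf[2])]]
  structure(list(metric = metric, steps = coarse_steps,
                 coarse = list(vnir_bands = vb, nir_bands = nb,
                               grid = coarse$grid),
                 fine = list(vnir_bands = fine_vb, nir_bands = fine_nb,
                             grid = fine$grid),
                 best_pair = bf,
                 best_score = fine$grid[match(bf[1], fine_vb),
                                        match(bf[2], fine_nb)],
                 best_transform = best_tm),
            class = "band_search_result")
}

# argmax over a score grid; NAs excluded, ties broken by lowest index pair
best_grid_cell <- function(grid, vb, nb) {
  if (all(is.na(grid))) return(NULL)
  best <- max(grid, na.rm = TRUE)
  hits <- which(grid == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  c(vb[hits[1, 1]], nb[hits[1, 2]])
}

#' @export
print.band_search_result <- function(x, ...) {
  cat(sprintf(
    "<band_search_result %s> best pair VNIR band %d / NIR band %d (%.4f)\n",
    toupper(x$metric), x$best_pair[1], x$best_pair[2], x$best_score))
  invisible(x)
}

#' Write a band-search result as CSV grids plus a JSON summary
#' @param res `band_search_result`.
#' @param path base path; `_coarse.csv`, `_fine.csv`, `.json` appended.
#' @return `path`, invisibly.
#' @export
write_band_search <- function(res, path) {
  utils::write.csv(res$coarse$grid, paste0(path, "_coarse.csv"))
  utils::write.csv(res$fine$grid, paste0(path, "_fine.csv"))
  jsonlite::write_json(list(metric = res$metric, steps = res$steps,
                            best_pair = res$best_pair,
                            best_score = res$best_score),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Select a reusable transformation model across a dataset
#'
#' Applies every candidate transform to every image pair in the dataset
#' and scores each with SSIM (or MI/PCC). Candidates whose scores are
#' significantly below the highest-mean candidate (paired two-tailed t
#' test at `alpha`) are ruled out; among the statistically comparable
#' candidates the winner is the one with the lowest interquartile range of
#' scores — the most consistent model across scenes. The t test of the
#' winner against the highest-mean candidate is reported.
#'
#' @param candidates list of `transform_model`s.
#' @param dataset list of pairs; each element is a list with `fixed` and
#'   `moving` grayscale matrices (use [gray_from_cube()]).
#' @param metric `"ssim"`, `"mi"` or `"pcc"`.
#' @param alpha significance level for the t test.
#' @return list: `winner` (`transform_model`), `winner_index`, `scores`
#'   (pairs x candidates matrix), `iqr`, `means`, `t_test` (winner vs
#'   highest-mean candidate).
#' @export
select_transform_model <- function(candidates, dataset,
                                   metric = c("ssim", "mi", "pcc"),
                                   alpha = 0.05) {
  metric <- match.arg(metric)
  if (length(candidates) == 0L) stop("no candidates")
  metric_fn <- switch(metric, ssim = ssim, mi = mutual_information,
                      pcc = pcc)
  scores <- base::matrix(NA_real_, length(dataset), length(candidates))
  for (ci in seq_along(candidates)) {
    for (di in seq_along(dataset)) {
      pair <- dataset[[di]]
      w <- warp_image(pair$moving, candidates[[ci]], dim(pair$fixed))
      scores[di, ci] <- metric_fn(pair$fixed, w$image)
    }
  }
  if (length(candidates) == 1L)
    return(list(winner = candidates[[1]], winner_index = 1L,
                scores = scores, iqr = iqr_linear(scores[, 1]),
                means = mean(scores[, 1]), t_test = NULL))
  iqrs <- apply(scores, 2L, iqr_linear)
  means <- colMeans(scores)
  hm <- which.max(means)
  eligible <- vapply(seq_along(candidates), function(ci) {
    if (ci == hm) return(TRUE)
    tt <- paired_t_test(scores[, ci], scores[, hm], alpha = alpha)
    is.na(tt$p_value) || !tt$significant
  }, logical(1))
  wi <- which(eligible)[which.min(iqrs[eligible])]
  tt <- if (wi == hm) paired_t_test(scores[, wi], scores[, wi],
                                    alpha = alpha)
        else paired_t_test(scores[, wi], scores[, hm], alpha = alpha)
  list(winner = candidates[[wi]], winner_index = wi, scores = scores,
       iqr = iqrs, means = means, eligible = eligible, t_test = tt)
}
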
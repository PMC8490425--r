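#' MSAC robust transform estimation
#'
#' M-estimator Sample Consensus: random minimal samples of the
#' correspondences are fit exactly, every hypothesis is scored with the
#' truncated squared reprojection error `sum(min(r^2, tol^2))`, and the best
#' hypothesis is refit by least squares on its inlier set. Unlike plain
#' RANSAC, inlier residuals contribute their actual squared error to the
#' score, so among hypotheses with equal inlier counts the tighter fit wins.
#' Deterministic given `seed`.
#'
#' @param matches `match_set`.
#' @param kind transform kind (`"translation"`, `"similarity"`, `"affine"`,
#'   `"projective"`).
#' @param seed integer RNG seed (mandatory: the estimate is a random
#'   variable of the sampling).
#' @param trials number of random minimal samples.
#' @param inlier_tol_px inlier threshold on reprojection error (pixels).
#' @return `transform_model`; `provenance` holds `inliers` (indices into the
#'   match set), `cost`, `seed`, `trials`, `inlier_tol_px`.
#' @export
estimate_msac <- function(matches, kind, seed, trials = 1000L,
                          inlier_tol_px = 1.5) {
  kind <- match.arg(kind, c("translation", "similarity", "affine",
                            "projective"))
  if (missing(seed)) stop("`seed` is mandatory for MSAC")
  fx <- matches$fixed_points; mv <- matches$moving_points
  n <- nrow(fx)
  need <- min_sample_size(kind)
  if (n < need) stop("need at least ", need, " matches for kind = ", kind)
  tol2 <- inlier_tol_px^2
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed))
  best_cost <- Inf; best_m <- NULL
  for (i in seq_len(trials)) {
    s <- sample.int(n, need)
    m <- tryCatch(fit_transform(fx[s, , drop = FALSE],
                                mv[s, , drop = FALSE], kind)$matrix,
                  error = function(e) NULL)
    if (is.null(m)) next
    r2 <- rowSums((apply_transform(m, mv) - fx)^2)
    cost <- sum(pmin(r2, tol2))
    if (cost < best_cost) {
      best_cost <- cost
      best_m <- m
    }
  }
  if (is.null(best_m)) stop("MSAC found no valid hypothesis")
  r2 <- rowSums((apply_transform(best_m, mv) - fx)^2)
  inliers <- which(r2 < tol2)
  if (length(inliers) < need)
    stop("MSAC consensus too small (", length(inliers), " inliers)")
  refit <- fit_transform(fx[inliers, , drop = FALSE],
                         mv[inliers, , drop = FALSE], kind)
  r2_refit <- rowSums((apply_transform(refit$matrix, mv) - fx)^2)
  cost_refit <- sum(pmin(r2_refit, tol2))
  final <- if (cost_refit <= best_cost) refit$matrix else best_m
  final_cost <- min(cost_refit, best_cost)
  transform_model(kind, final,
                  provenance = list(technique = "msac",
                                    inliers = inliers,
                                    n_matches = n,
                                    cost = final_cost,
                                    seed = as.integer(seed),
                                    trials = trials,
                                    inlier_tol_px = inlier_tol_px))
}
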
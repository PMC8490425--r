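#' Unsupervised segmentation of a cube
#'
#' Clusters per-pixel spectra (Euclidean distance on the per-pixel
#' normalized cube) into `K` clusters with K-means, K-medoids or
#' hierarchical K-means. The hierarchical variant starts from one cluster
#' and repeatedly bisects the cluster with the largest within-cluster
#' inertia until `K` clusters exist. Deterministic given `seed` (cluster
#' initialization uses the same seed across runs and data types, so paired
#' comparisons share initial conditions).
#'
#' @param cube `hs_cube` (or the `cube` element of a `fused_cube`),
#'   normalized per pixel.
#' @param K number of clusters.
#' @param algorithm `"kmeans"`, `"kmedoids"` or `"hierarchical_kmeans"`.
#' @param seed integer seed.
#' @return integer matrix of cluster ids (rows x cols).
#' @export
segment_cube <- function(cube, K,
                         algorithm = c("kmeans", "kmedoids",
                                       "hierarchical_kmeans"),
                         seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (inherits(cube, "fused_cube")) cube <- cube$cube
  d <- dim(cube$data)
  flat <- base::matrix(cube$data, d[1] * d[2], d[3])
  if (K < 1L || K > nrow(flat)) stop("K out of range")
  if (K == 1L) return(base::matrix(1L, d[1], d[2]))
  cl <- with_seed(seed, switch(algorithm,
    kmeans = stats::kmeans(flat, K, iter.max = 100L, nstart = 1L)$cluster,
    kmedoids = {
      if (nrow(flat) <= 2500L)
        cluster::pam(flat, K, cluster.only = TRUE, pamonce = 5)
      else
        cluster::clara(flat, K, samples = 5,
                       sampsize = min(nrow(flat), 40 + 2 * K))$clustering
    },
    hierarchical_kmeans = hierarchical_kmeans(flat, K)))
  base::matrix(as.integer(cl), d[1], d[2])
}

# bisecting K-means: split the largest-inertia cluster until K clusters
hierarchical_kmeans <- function(flat, K) {
  assign_id <- rep(1L, nrow(flat))
  inertia <- function(idx) {
    if (length(idx) < 2L) return(0)
    sub <- flat[idx, , drop = FALSE]
    sum(sweep(sub, 2L, colMeans(sub))^2)
  }
  while (max(assign_id) < K) {
    ids <- seq_len(max(assign_id))
    wss <- vapply(ids, function(i) inertia(which(assign_id == i)),
                  numeric(1))
    target <- ids[which.max(wss)]
    idx <- which(assign_id == target)
    if (length(idx) < 2L || wss[target] == 0) break  # nothing left to split
    km <- stats::kmeans(flat[idx, , drop = FALSE], 2L, iter.max = 100L)
    assign_id[idx[km$cluster == 2L]] <- max(assign_id) + 1L
  }
  assign_id
}

#' Map clusters onto ground-truth classes by Jaccard overlap
#'
#' Each ground-truth class is assigned the cluster with the largest Jaccard
#' index against that class's labeled pixels. Conflicts (one cluster best
#' for several classes) are resolved greedily in descending Jaccard order,
#' each cluster used at most once; clusters left unassigned become
#' unlabeled. Invariant to any relabeling of cluster ids.
#'
#' @param clusters integer matrix of cluster ids.
#' @param gt `label_map` ground truth.
#' @return `label_map` of predicted classes.
#' @export
clusters_to_classes <- function(clusters, gt) {
  labels <- gt$labels
  if (!all(dim(clusters) == dim(labels))) stop("dimension mismatch")
  labeled <- labels > 0L
  if (!any(labeled)) stop("ground truth has no labeled pixels")
  classes <- sort(unique(labels[labeled]))
  cl_ids <- sort(unique(as.vector(clusters)))
  jac <- base::matrix(0, length(classes), length(cl_ids),
                      dimnames = list(classes, cl_ids))
  for (ci in seq_along(classes)) {
    in_class <- labels == classes[ci] & labeled
    for (ki in seq_along(cl_ids)) {
      in_cl <- clusters == cl_ids[ki] & labeled
      u <- sum(in_class | in_cl)
      jac[ci, ki] <- if (u > 0) sum(in_class & in_cl) / u else 0
    }
  }
  out <- base::matrix(0L, nrow(labels), ncol(labels))
  used_cl <- logical(length(cl_ids))
  used_class <- logical(length(classes))
  ord <- order(-as.vector(jac))
  for (o in ord) {
    ci <- ((o - 1L) %% length(classes)) + 1L
    ki <- ((o - 1L) %/% length(classes)) + 1L
    if (used_class[ci] || used_cl[ki] || jac[ci, ki] <= 0) next
    out[clusters == cl_ids[ki]] <- classes[ci]
    used_class[ci] <- TRUE
    used_cl[ki] <- TRUE
  }
  label_map(out, gt$class_names)
}

#' Jaccard index per class
#'
#' Intersection-over-union between each predicted and ground-truth class
#' mask: `|pred = c & gt = c| / |pred = c | gt = c|` over the full image,
#' so predictions spilling outside a class's true support count against
#' it. Classes absent from both maps are excluded as undefined.
#'
#' @param pred,gt `label_map`s with matching dimensions.
#' @return list: `per_class` (named numeric), `mean`.
#' @export
jaccard_index <- function(pred, gt) {
  p <- pred$labels; g <- gt$labels
  if (!all(dim(p) == dim(g))) stop("dimension mismatch")
  classes <- sort(unique(g[g > 0L]))
  scores <- vapply(classes, function(cl) {
    inter <- sum(p == cl & g == cl)
    uni <- sum(p == cl | g == cl)
    if (uni == 0L) NA_real_ else inter / uni
  }, numeric(1))
  names(scores) <- gt$class_names[classes]
  scores <- scores[!is.na(scores)]
  list(per_class = scores, mean = mean(scores))
}

#' Overall pixel accuracy
#'
#' Fraction of ground-truth-labeled pixels whose predicted class matches.
#'
#' @param pred,gt `label_map`s with matching dimensions.
#' @return scalar in `[0, 1]`.
#' @export
overall_accuracy <- function(pred, gt) {
  p <- pred$labels; g <- gt$labels
  if (!all(dim(p) == dim(g))) stop("dimension mismatch")
  labeled <- g > 0L
  if (!any(labeled)) stop("ground truth has no labeled pixels")
  mean(p[labeled] == g[labeled])
}

#' Classifier configuration
#'
#' Hyperparameter search spec for the supervised harness. SVM runs a
#' coarse log-grid over cost and gamma followed by a 3x3 fine refinement
#' around the coarse optimum; RF and KNN run a coarse grid only.
#'
#' @param kind `"svm"`, `"rf"` or `"knn"`.
#' @param seed integer seed.
#' @param svm_exp coarse exponent grid for cost and gamma (powers of 10).
#' @param rf_trees candidate forest sizes.
#' @param knn_k candidate neighbour counts.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(kind = c("svm", "rf", "knn"), seed = 1L,
                              svm_exp = -3:3,
                              rf_trees = c(50L, 100L, 200L, 300L, 500L),
                              knn_k = seq(1L, 25L, by = 2L)) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed), svm_exp = svm_exp,
                 rf_trees = rf_trees, knn_k = knn_k),
            class = "classifier_config")
}

#' Train and evaluate a pixel classifier
#'
#' Hyperparameters are chosen by validation accuracy over the configured
#' grid (with a fine refinement stage for SVM); the winning model is then
#' trained on the training set and evaluated once on the held-out test
#' set. Deterministic given `cfg$seed`.
#'
#' @param train,val,test lists with `x` (spectra matrix, pixels x bands)
#'   and `y` (factor of class labels); disjoint pixel sets.
#' @param cfg `classifier_config`.
#' @return list: `kind`, `best_params`, `val_accuracy`, `test_accuracy`.
#' @export
train_eval_classifier <- function(train, val, test, cfg) {
  if (nlevels(droplevels(train$y)) < 2L)
    stop("training set must contain at least 2 classes")
  if (!all(levels(factor(val$y)) %in% levels(factor(train$y))) ||
      !all(levels(factor(test$y)) %in% levels(factor(train$y))))
    stop("a class missing from the training set appears in val/test")
  acc <- function(pred, y) mean(pred == y)
  fit_score <- switch(cfg$kind,
    svm = function(p) {
      m <- with_seed(cfg$seed,
                     e1071::svm(train$x, train$y, cost = 10^p[1],
                                gamma = 10^p[2], kernel = "radial"))
      list(model = m, val = acc(stats::predict(m, val$x), val$y))
    },
    rf = function(p) {
      m <- with_seed(cfg$seed,
                     randomForest::randomForest(train$x, train$y,
                                                ntree = p[1]))
      list(model = m, val = acc(stats::predict(m, val$x), val$y))
    },
    knn = function(p) {
      pr <- with_seed(cfg$seed,
                      class::knn(train$x, val$x, train$y, k = p[1]))
      list(model = NULL, val = acc(pr, val$y))
    })
  grid <- switch(cfg$kind,
    svm = as.matrix(expand.grid(cost = cfg$svm_exp, gamma = cfg$svm_exp)),
    rf = base::matrix(cfg$rf_trees, ncol = 1,
                      dimnames = list(NULL, "ntree")),
    knn = base::matrix(cfg$knn_k, ncol = 1, dimnames = list(NULL, "k")))
  vals <- apply(grid, 1L, function(p) fit_score(p)$val)
  best <- grid[which.max(vals), , drop = TRUE]
  best_val <- max(vals)
  if (cfg$kind == "svm") {
    fine <- as.matrix(expand.grid(cost = best["cost"] + c(-0.5, 0, 0.5),
                                  gamma = best["gamma"] + c(-0.5, 0, 0.5)))
    fvals <- apply(fine, 1L, function(p) fit_score(p)$val)
    if (max(fvals) >= best_val) {
      best <- fine[which.max(fvals), , drop = TRUE]
      best_val <- max(fvals)
    }
  }
  test_acc <- switch(cfg$kind,
    svm = {
      m <- with_seed(cfg$seed,
                     e1071::svm(train$x, train$y, cost = 10^best["cost"],
                                gamma = 10^best["gamma"],
                                kernel = "radial"))
      acc(stats::predict(m, test$x), test$y)
    },
    rf = {
      m <- with_seed(cfg$seed,
                     randomForest::randomForest(train$x, train$y,
                                                ntree = best["ntree"]))
      acc(stats::predict(m, test$x), test$y)
    },
    knn = acc(with_seed(cfg$seed,
                        class::knn(train$x, test$x, train$y,
                                   k = best["k"])),
              test$y))
  list(kind = cfg$kind, best_params = as.list(best),
       val_accuracy = best_val, test_accuracy = test_acc)
}

#' Build the three modality data stacks from a plastic scene
#'
#' Prepares the per-pixel spectra each modality contributes on the common
#' VNIR grid: the band-trimmed normalized VNIR cube; the NIR cube warped
#' into the VNIR frame through the scene's true transform, trimmed and
#' normalized; and the fused cube. Band trimming uses the clean-band
#' truth recorded by the generator (equivalently, the cutoffs an RD
#' analysis of a matching reference panel recovers).
#'
#' @param scene plastic `scene_pair`.
#' @param k_bands fusion offset edge bands.
#' @return list with `VNIR`, `NIR`, `FUSED` pixel-by-band matrices.
#' @export
modality_stack <- function(scene, k_bands = 5L) {
  vd <- dim(scene$vnir$data)
  vcut <- scene$meta$vnir_cut_idx
  ncut <- scene$meta$nir_cut_idx
  nir_reg <- warp_cube(scene$nir, scene$true_transform, vd[1:2])$cube
  vnir_cutr <- fixed_cutoffs(scene$vnir$wavelengths,
                             scene$vnir$wavelengths[vcut[1]],
                             scene$vnir$wavelengths[vcut[2]])
  nir_cutr <- fixed_cutoffs(nir_reg$wavelengths,
                            nir_reg$wavelengths[ncut[1]],
                            nir_reg$wavelengths[ncut[2]])
  vtrim <- minmax_normalize_pixels(
    hs_cube(scene$vnir$data[, , vcut[1]:vcut[2], drop = FALSE],
            scene$vnir$wavelengths[vcut[1]:vcut[2]], "VNIR"))
  ntrim <- minmax_normalize_pixels(
    hs_cube(nir_reg$data[, , ncut[1]:ncut[2], drop = FALSE],
            nir_reg$wavelengths[ncut[1]:ncut[2]], "NIR"))
  fused <- fuse(scene$vnir, nir_reg, vnir_cutr, nir_cutr,
                k_bands = k_bands)
  npix <- vd[1] * vd[2]
  list(VNIR = base::matrix(vtrim$data, npix, n_bands(vtrim)),
       NIR = base::matrix(ntrim$data, npix, n_bands(ntrim)),
       FUSED = base::matrix(fused$cube$data, npix, n_bands(fused$cube)))
}

#' Compare VNIR, NIR and fused data across problems and scenes
#'
#' For every scene, builds the three modality stacks, splits the labeled
#' pixels of each requested problem into train/test, fits the classifier
#' and records test accuracy. Scores are aggregated across scenes and the
#' fused modality is compared with the best single modality by a paired
#' one-tailed t test at the requested level.
#'
#' @param scenes list of plastic `scene_pair`s.
#' @param problems subset of `"color"`, `"material"`, `"material_color"`.
#' @param classifier `"knn"`, `"svm"` or `"rf"`; KNN (fixed `k`) is the
#'   fast default for benchmark sweeps, the others run their full grids.
#' @param n_train_per_class training pixels sampled per class.
#' @param max_test cap on test pixels per scene.
#' @param knn_k neighbour count for the KNN default.
#' @param seed base seed (drives pixel sampling and classifier seeds).
#' @param alpha significance level.
#' @return list of class `eval_report`: per problem, `scores` (scenes x 3
#'   modalities), `means`, `sds`, and `t_fused_vs_best`.
#' @export
compare_modalities <- function(scenes,
                               problems = c("color", "material",
                                            "material_color"),
                               classifier = "knn",
                               n_train_per_class = 40L, max_test = 4000L,
                               knn_k = 5L, seed = 1L, alpha = 0.05) {
  problems <- match.arg(problems, several.ok = TRUE)
  gt_field <- c(color = "color_gt", material = "material_gt",
                material_color = "material_color_gt")
  mods <- c("VNIR", "NIR", "FUSED")
  out <- list()
  scores <- lapply(problems, function(p)
    base::matrix(NA_real_, length(scenes), 3L,
                 dimnames = list(NULL, mods)))
  names(scores) <- problems
  for (si in seq_along(scenes)) {
    scene <- scenes[[si]]
    stacks <- modality_stack(scene)
    for (p in problems) {
      gt <- scene[[gt_field[[p]]]]
      lab <- as.vector(gt$labels)
      labeled <- which(lab > 0L)
      split <- with_seed(seed + 131L * si, {
        tr <- unlist(lapply(split(labeled, lab[labeled]), function(idx)
          sample(idx, min(n_train_per_class, floor(length(idx) / 2)))))
        te <- setdiff(labeled, tr)
        if (length(te) > max_test) te <- sample(te, max_test)
        list(tr = tr, te = te)
      })
      y_tr <- factor(lab[split$tr])
      y_te <- factor(lab[split$te], levels = levels(y_tr))
      for (m in mods) {
        x_tr <- stacks[[m]][split$tr, , drop = FALSE]
        x_te <- stacks[[m]][split$te, , drop = FALSE]
        accv <- if (classifier == "knn") {
          pr <- with_seed(seed + si,
                          class::knn(x_tr, x_te, y_tr, k = knn_k))
          mean(pr == y_te)
        } else {
          cfg <- classifier_config(classifier, seed = seed + si)
          fit <- train_eval_classifier(list(x = x_tr, y = y_tr),
                                       list(x = x_te, y = y_te),
                                       list(x = x_te, y = y_te), cfg)
          fit$test_accuracy
        }
        scores[[p]][si, m] <- accv
      }
    }
  }
  for (p in problems) {
    sc <- scores[[p]]
    means <- colMeans(sc)
    best_single <- mods[which.max(means[1:2])]
    tt <- paired_t_test(sc[, "FUSED"], sc[, best_single],
                        alternative = "greater", alpha = alpha)
    out[[p]] <- list(scores = sc, means = means,
                     sds = apply(sc, 2L, stats::sd),
                     best_single = best_single, t_fused_vs_best = tt)
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  for (p in names(x)) {
    cat(sprintf("%s: VNIR %.3f  NIR %.3f  FUSED %.3f  (fused vs %s: p = %.3g%s)\n",
                p, x[[p]]$means["VNIR"], x[[p]]$means["NIR"],
                x[[p]]$means["FUSED"], x[[p]]$best_single,
                x[[p]]$t_fused_vs_best$p_value,
                if (x[[p]]$t_fused_vs_best$significant) " *" else ""))
  }
  invisible(x)
}

#' Write an evaluation report as CSV plus JSON summary
#' @param report `eval_report`.
#' @param path base path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  rows <- do.call(rbind, lapply(names(report), function(p) {
    sc <- report[[p]]$scores
    data.frame(problem = p, scene = seq_len(nrow(sc)), sc,
               check.names = FALSE)
  }))
  utils::write.csv(rows, paste0(path, ".csv"), row.names = FALSE)
  summ <- lapply(report, function(e)
    list(means = as.list(e$means), sds = as.list(e$sds),
         best_single = e$best_single,
         p_fused_vs_best = e$t_fused_vs_best$p_value))
  jsonlite::write_json(summ, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
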
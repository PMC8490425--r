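#' Geometric transform model
#'
#' A 2-D transform mapping moving-frame pixel coordinates `(x, y, 1)` (x =
#' column, y = row, pixel centers at integers starting from 1) to the fixed
#' frame via a 3x3 homogeneous matrix. `kind` constrains the free
#' parameters: translation (2), similarity (4: isotropic scale, rotation,
#' shift), affine (6), projective (8).
#'
#' @param kind one of `"translation"`, `"similarity"`, `"affine"`,
#'   `"projective"`.
#' @param matrix 3x3 homogeneous matrix; bottom row must be `(0, 0, 1)`
#'   unless `kind = "projective"`.
#' @param provenance named list (technique, detector, band pair, seed,
#'   score, ...).
#' @return An object of class `transform_model`.
#' @export
transform_model <- function(kind, matrix, provenance = list()) {
  kind <- match.arg(kind, c("translation", "similarity", "affine",
                            "projective"))
  matrix <- base::matrix(as.numeric(matrix), 3L, 3L)
  if (abs(det(matrix)) < 1e-12) stop("transform matrix is singular")
  if (kind != "projective" &&
      max(abs(matrix[3, ] - c(0, 0, 1))) > 1e-9)
    stop("bottom row must be (0, 0, 1) for kind = ", kind)
  if (kind == "projective" && abs(matrix[3, 3]) > 1e-12)
    matrix <- matrix / matrix[3, 3]
  structure(list(kind = kind, matrix = matrix, provenance = provenance),
            class = "transform_model")
}

#' @export
print.transform_model <- function(x, ...) {
  cat(sprintf("<transform_model %s>\n", x$kind))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Apply a transform to points
#' @param tm `transform_model` (or bare 3x3 matrix).
#' @param pts n x 2 matrix of `(x, y)` coordinates.
#' @return n x 2 matrix of mapped coordinates.
#' @export
apply_transform <- function(tm, pts) {
  m <- if (inherits(tm, "transform_model")) tm$matrix else tm
  pts <- base::matrix(pts, ncol = 2L)
  h <- m %*% rbind(t(pts), 1)
  t(h[1:2, , drop = FALSE] / rep(h[3, ], each = 2L))
}

#' Invert a transform
#' @param tm `transform_model`.
#' @return `transform_model` of the same kind.
#' @export
invert_transform <- function(tm) {
  transform_model(tm$kind, solve(tm$matrix), tm$provenance)
}

#' Least-squares transform fit from point correspondences
#'
#' Direct (non-robust) estimate of the transform mapping `moving` points
#' onto `fixed` points: closed-form least squares for translation,
#' similarity and affine; normalized direct linear transform (DLT) for
#' projective. This is the refit step used inside MSAC and the oracle that
#' MSAC must match on outlier-free data.
#'
#' @param fixed,moving n x 2 matrices of `(x, y)` coordinates.
#' @param kind transform kind.
#' @return `transform_model`.
#' @export
fit_transform <- function(fixed, moving, kind) {
  kind <- match.arg(kind, c("translation", "similarity", "affine",
                            "projective"))
  fixed <- base::matrix(fixed, ncol = 2L)
  moving <- base::matrix(moving, ncol = 2L)
  n <- nrow(fixed)
  if (nrow(moving) != n) stop("point sets differ in length")
  need <- min_sample_size(kind)
  if (n < need) stop(kind, " fit needs at least ", need, " correspondences")
  m <- switch(kind,
    translation = {
      t <- colMeans(fixed) - colMeans(moving)
      rbind(c(1, 0, t[1]), c(0, 1, t[2]), c(0, 0, 1))
    },
    similarity = {
      # [x'; y'] = [a -b; b a] [x; y] + [tx; ty]
      A <- rbind(cbind(moving[, 1], -moving[, 2], 1, 0),
                 cbind(moving[, 2],  moving[, 1], 0, 1))
      b <- c(fixed[, 1], fixed[, 2])
      p <- qr.solve(A, b)
      rbind(c(p[1], -p[2], p[3]), c(p[2], p[1], p[4]), c(0, 0, 1))
    },
    affine = {
      A <- cbind(moving, 1)
      px <- qr.solve(A, fixed[, 1])
      py <- qr.solve(A, fixed[, 2])
      rbind(px, py, c(0, 0, 1))
    },
    projective = fit_homography_dlt(fixed, moving))
  transform_model(kind, m)
}

min_sample_size <- function(kind) {
  switch(kind, translation = 1L, similarity = 2L, affine = 3L,
         projective = 4L)
}

# Hartley-normalized DLT homography estimate.
fit_homography_dlt <- function(fixed, moving) {
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
    list(T = T, p = t(T %*% rbind(t(p), 1))[, 1:2, drop = FALSE])
  }
  nf <- norm_pts(fixed); nm <- norm_pts(moving)
  x <- nm$p[, 1]; y <- nm$p[, 2]; u <- nf$p[, 1]; v <- nf$p[, 2]
  z <- rep(0, length(x)); o <- rep(1, length(x))
  A <- rbind(cbind(-x, -y, -o, z, z, z, u * x, u * y, u),
             cbind(z, z, z, -x, -y, -o, v * x, v * y, v))
  # null vector of A: eigenvector of the smallest eigenvalue of A'A
  # (works for the minimal 4-point case where A has only 8 rows)
  h <- eigen(crossprod(A), symmetric = TRUE)$vectors[, 9]
  H <- solve(nf$T) %*% base::matrix(h, 3, 3, byrow = TRUE) %*% nm$T
  H / H[3, 3]
}

#' Bilinear sampling of an image at fractional coordinates
#'
#' @param img numeric matrix (rows x cols).
#' @param x,y coordinate vectors (x = column, y = row, centers at integers).
#' @param fill value for coordinates outside the image.
#' @return numeric vector of sampled values.
#' @export
bilinear_sample <- function(img, x, y, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  valid <- x >= 1 & x <= nc & y >= 1 & y <= nr
  # clamp so index arithmetic stays in range; invalid results overwritten
  x0c <- pmin(pmax(x0, 1L), nc); y0c <- pmin(pmax(y0, 1L), nr)
  x1c <- pmin(x0c + 1L, nc); y1c <- pmin(y0c + 1L, nr)
  i00 <- (x0c - 1L) * nr + y0c
  i10 <- (x1c - 1L) * nr + y0c
  i01 <- (x0c - 1L) * nr + y1c
  i11 <- (x1c - 1L) * nr + y1c
  out <- (1 - fx) * (1 - fy) * img[i00] + fx * (1 - fy) * img[i10] +
         (1 - fx) * fy * img[i01] + fx * fy * img[i11]
  out[!valid] <- fill
  out
}

#' Warp an image into a fixed frame
#'
#' Inverse mapping with bilinear interpolation: each output pixel is sampled
#' from the moving image at `t^-1 (x, y)`.
#'
#' @param img moving image matrix.
#' @param tm `transform_model` mapping moving to fixed coordinates.
#' @param out_dims `c(rows, cols)` of the output; default `dim(img)`.
#' @param fill fill value outside the moving frame.
#' @return list with `image` (matrix) and `mask` (logical matrix, TRUE where
#'   the sample fell inside the moving frame).
#' @export
warp_image <- function(img, tm, out_dims = dim(img), fill = 0) {
  inv <- solve(if (inherits(tm, "transform_model")) tm$matrix else tm)
  nr <- out_dims[1]; nc <- out_dims[2]
  grid_x <- rep(seq_len(nc), each = nr)
  grid_y <- rep(seq_len(nr), times = nc)
  src <- apply_transform(inv, cbind(grid_x, grid_y))
  vals <- bilinear_sample(img, src[, 1], src[, 2], fill = NA_real_)
  mask <- base::matrix(!is.na(vals), nr, nc)
  vals[is.na(vals)] <- fill
  list(image = base::matrix(vals, nr, nc), mask = mask)
}

#' Warp a hyperspectral cube into a fixed frame
#'
#' Applies [warp_image()] band by band with shared sampling coordinates.
#'
#' @param cube moving `hs_cube`.
#' @param tm `transform_model` (moving to fixed).
#' @param out_dims `c(rows, cols)` of the output grid.
#' @param fill fill value outside the moving frame.
#' @return list with `cube` (warped `hs_cube`) and `mask` (logical matrix).
#' @export
warp_cube <- function(cube, tm, out_dims = dim(cube$data)[1:2], fill = 0) {
  inv <- solve(if (inherits(tm, "transform_model")) tm$matrix else tm)
  nr <- out_dims[1]; nc <- out_dims[2]
  grid_x <- rep(seq_len(nc), each = nr)
  grid_y <- rep(seq_len(nr), times = nc)
  src <- apply_transform(inv, cbind(grid_x, grid_y))
  nb <- n_bands(cube)
  out <- array(fill, c(nr, nc, nb))
  mask <- NULL
  for (b in seq_len(nb)) {
    vals <- bilinear_sample(cube$data[, , b], src[, 1], src[, 2],
                            fill = NA_real_)
    if (is.null(mask)) mask <- base::matrix(!is.na(vals), nr, nc)
    vals[is.na(vals)] <- fill
    out[, , b] <- vals
  }
  meta <- cube$meta
  meta$warped_by <- if (inherits(tm, "transform_model")) tm$kind else "matrix"
  list(cube = hs_cube(out, cube$wavelengths, cube$modality, meta),
       mask = mask)
}

#' Crop two co-registered cubes to their common region of interest
#'
#' Finds the largest axis-aligned rectangle fully inside the validity mask
#' produced by warping and crops both cubes to it, so downstream fusion only
#' sees pixels observed by both cameras.
#'
#' @param fixed,warped `hs_cube`s with equal spatial dims.
#' @param mask logical matrix (TRUE = valid), same dims.
#' @return list with cropped `fixed`, `warped` and `roi`
#'   (`c(row1, row2, col1, col2)`).
#' @export
crop_common_roi <- function(fixed, warped, mask) {
  df <- dim(fixed$data)[1:2]
  if (!all(df == dim(warped$data)[1:2]) || !all(df == dim(mask)))
    stop("fixed, warped and mask must share spatial dimensions")
  roi <- largest_true_rectangle(mask)
  if (is.null(roi)) stop("validity mask has no TRUE region")
  list(fixed = hs_cube(fixed$data[roi[1]:roi[2], roi[3]:roi[4], ,
                                  drop = FALSE],
                       fixed$wavelengths, fixed$modality, fixed$meta),
       warped = hs_cube(warped$data[roi[1]:roi[2], roi[3]:roi[4], ,
                                    drop = FALSE],
                        warped$wavelengths, warped$modality, warped$meta),
       roi = roi)
}

#' Largest all-TRUE axis-aligned rectangle in a logical matrix
#'
#' Stack-based maximal-rectangle-in-histogram scan, O(rows * cols).
#'
#' @param mask logical matrix.
#' @return `c(row1, row2, col1, col2)` or `NULL` if no TRUE cell.
#' @export
largest_true_rectangle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  heights <- integer(nc)
  best <- 0L; roi <- NULL
  for (r in seq_len(nr)) {
    heights <- ifelse(mask[r, ], heights + 1L, 0L)
    # largest rectangle in histogram `heights`
    stack_idx <- integer(0)
    h <- c(heights, 0L)
    for (j in seq_along(h)) {
      while (length(stack_idx) && h[stack_idx[length(stack_idx)]] > h[j]) {
        top <- stack_idx[length(stack_idx)]
        stack_idx <- stack_idx[-length(stack_idx)]
        left <- if (length(stack_idx)) stack_idx[length(stack_idx)] + 1L
                else 1L
        area <- h[top] * (j - left)
        if (area > best) {
          best <- area
          roi <- c(r - h[top] + 1L, r, left, j - 1L)
        }
      }
      stack_idx <- c(stack_idx, j)
    }
  }
  roi
}

#' Serialize a transform model to JSON
#' @param tm `transform_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(tm, path) {
  jsonlite::write_json(
    list(kind = tm$kind,
         matrix = as.vector(t(tm$matrix)),  # row-major
         provenance = tm$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transform model from JSON
#' @param path JSON path written by [write_transform()].
#' @return `transform_model`.
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  transform_model(x$kind, base::matrix(unlist(x$matrix), 3, 3, byrow = TRUE),
                  as.list(x$provenance))
}
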
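# Shared fixture builders: everything is generated in code at test time.

random_cube <- function(rows = 6, cols = 5, bands = 8, seed = 1,
                        modality = "VNIR") {
  set.seed(seed)
  hs_cube(array(runif(rows * cols * bands), c(rows, cols, bands)),
          seq(450, 450 + 10 * (bands - 1), by = 10), modality)
}

# values representable exactly in float32 so ENVI round trips bit-exactly
float32_cube <- function(rows = 4, cols = 3, bands = 5, seed = 2) {
  set.seed(seed)
  v <- round(runif(rows * cols * bands) * 1024) / 1024
  hs_cube(array(v, c(rows, cols, bands)),
          seq(435, 435 + 5 * (bands - 1), by = 5))
}

small_target_spec <- function(seed, dims = c(128L, 128L), base_sd = 0.01)
  scene_spec(vnir_dims = dims, seed = seed, base_sd = base_sd)

# rotation about the image center as a similarity transform
rotation_about_center <- function(theta_deg, dims) {
  th <- theta_deg * pi / 180
  cx <- (dims[2] + 1) / 2; cy <- (dims[1] + 1) / 2
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Tc <- rbind(c(1, 0, cx), c(0, 1, cy), c(0, 0, 1))
  Tm <- rbind(c(1, 0, -cx), c(0, 1, -cy), c(0, 0, 1))
  transform_model("similarity", Tc %*% R %*% Tm)
}

n_bands_of <- function(cube) dim(cube$data)[3]

# independent naive SSIM oracle: literal sliding-window loops with
# Gaussian weights computed from first principles
naive_ssim <- function(a, b, window = 11L, sigma = 1.5) {
  L <- max(a, b) - min(a, b)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  half <- (window - 1) / 2
  w1 <- exp(-((-half:half)^2) / (2 * sigma^2)); w1 <- w1 / sum(w1)
  w2 <- outer(w1, w1)
  vals <- c()
  for (r in (half + 1):(nrow(a) - half)) {
    for (cl in (half + 1):(ncol(a) - half)) {
      pa <- a[(r - half):(r + half), (cl - half):(cl + half)]
      pb <- b[(r - half):(r + half), (cl - half):(cl + half)]
      ma <- sum(w2 * pa); mb <- sum(w2 * pb)
      va <- sum(w2 * pa^2) - ma^2; vb <- sum(w2 * pb^2) - mb^2
      cab <- sum(w2 * pa * pb) - ma * mb
      vals <- c(vals, ((2 * ma * mb + c1) * (2 * cab + c2)) /
                  ((ma^2 + mb^2 + c1) * (va + vb + c2)))
    }
  }
  mean(vals)
}

frobenius_after_scale <- function(a, b) {
  na <- a / sqrt(sum(a^2)) * sign(a[3, 3])
  nb <- b / sqrt(sum(b^2)) * sign(b[3, 3])
  sqrt(sum((na - nb)^2))
}
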
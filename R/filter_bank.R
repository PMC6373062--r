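# Multi-scale filter bank feeding the pixel-level scene classifier.
# Families: noise reduction (Kuwahara, bilateral), edges (Sobel, Hessian
# eigenvalues, Gabor), and local rank/texture statistics (mean, variance,
# median, maximum, minimum, entropy) at several radii.

conv2 <- function(x, k) {
  pr <- max(0L, ceiling((nrow(k) - nrow(x)) / 2) + 1L) * (nrow(k) > nrow(x))
  pc <- max(0L, ceiling((ncol(k) - ncol(x)) / 2) + 1L) * (ncol(k) > ncol(x))
  if (pr > 0 || pc > 0) {
    ri <- pmin(pmax(seq_len(nrow(x) + 2L * pr) - pr, 1L), nrow(x))
    ci <- pmin(pmax(seq_len(ncol(x) + 2L * pc) - pc, 1L), ncol(x))
    out <- EBImage::filter2(x[ri, ci, drop = FALSE], k, boundary = "replicate")
    return(out[pr + seq_len(nrow(x)), pc + seq_len(ncol(x)), drop = FALSE])
  }
  EBImage::filter2(x, k, boundary = "replicate")
}

shift_mat <- function(x, dr, dc) {
  # shift with edge replication: out[i,j] = x[i+dr, j+dc]
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  x[ri, ci, drop = FALSE]
}

box_kernel <- function(r) {
  n <- 2L * r + 1L
  matrix(1 / (n * n), n, n)
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

sobel_magnitude <- function(x) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  sqrt(conv2(x, kx)^2 + conv2(x, t(kx))^2)
}

kuwahara_filter <- function(x, r = 2L) {
  # adaptive mean: of the four (r+1)x(r+1) corner sub-windows take the mean
  # of the one with lowest variance (edge preserving)
  k <- matrix(1 / (r + 1)^2, r + 1L, r + 1L)
  m <- conv2(x, k)
  s <- conv2(x^2, k)
  half <- ceiling(r / 2)
  offs <- list(c(-half, -half), c(-half, half), c(half, -half), c(half, half))
  means <- lapply(offs, function(o) shift_mat(m, o[1], o[2]))
  vars <- lapply(seq_along(offs), function(i) {
    sm <- shift_mat(s, offs[[i]][1], offs[[i]][2])
    pmax(sm - means[[i]]^2, 0)
  })
  best <- means[[1]]; bestv <- vars[[1]]
  for (i in 2:4) {
    take <- vars[[i]] < bestv
    best[take] <- means[[i]][take]
    bestv[take] <- vars[[i]][take]
  }
  best
}

bilateral_filter <- function(x, sigma_s = 2, sigma_r = 30, radius = 3L) {
  num <- matrix(0, nrow(x), ncol(x))
  den <- num
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      ws <- exp(-(dr^2 + dc^2) / (2 * sigma_s^2))
      xs <- shift_mat(x, dr, dc)
      w <- ws * exp(-(xs - x)^2 / (2 * sigma_r^2))
      num <- num + w * xs
      den <- den + w
    }
  }
  num / den
}

hessian_eigen <- function(x, sigma) {
  xs <- conv2(x, gauss_kernel(sigma))
  d2 <- matrix(c(1, -2, 1), 1, 3)
  ixx <- conv2(xs, matrix(c(1, -2, 1), 3, 1))
  iyy <- conv2(xs, d2)
  dxy <- matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3) / 4
  ixy <- conv2(xs, dxy)
  tr <- ixx + iyy
  disc <- sqrt(pmax((ixx - iyy)^2 + 4 * ixy^2, 0))
  list(hi = (tr + disc) / 2, lo = (tr - disc) / 2)
}

gabor_kernel <- function(wavelength, theta, sigma = 0.56 * wavelength,
                         gamma = 0.5) {
  r <- ceiling(2.5 * sigma)
  g <- expand.grid(y = -r:r, x = -r:r)
  xp <- g$x * cos(theta) + g$y * sin(theta)
  yp <- -g$x * sin(theta) + g$y * cos(theta)
  k <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) *
    cos(2 * pi * xp / wavelength)
  k <- k - mean(k)
  matrix(k, 2 * r + 1, 2 * r + 1)
}

local_entropy <- function(x, r, n_bins = 8L) {
  rng <- range(x)
  if (diff(rng) == 0) return(matrix(0, nrow(x), ncol(x)))
  b <- pmin(floor((x - rng[1]) / diff(rng) * n_bins), n_bins - 1L)
  k <- box_kernel(r)
  ent <- matrix(0, nrow(x), ncol(x))
  for (i in 0:(n_bins - 1L)) {
    p <- conv2((b == i) * 1, k)
    p <- pmin(pmax(p, 0), 1)
    nz <- p > 1e-12
    ent[nz] <- ent[nz] - p[nz] * log2(p[nz])
  }
  ent
}

#' Filter-bank configuration for pixel-level segmentation
#'
#' Defines the feature families computed per pixel: raw intensity, Kuwahara
#' and bilateral smoothing, Sobel gradient magnitude, Hessian eigenvalues at
#' several scales, a Gabor bank, and six rank/texture filters (mean,
#' variance, median, maximum, minimum, entropy) at several radii.
#'
#' @param rank_radii integer radii for the rank filters.
#' @param hessian_sigmas Gaussian scales for the Hessian.
#' @param gabor_orientations number of evenly spaced Gabor orientations.
#' @param gabor_wavelengths Gabor wavelengths in pixels.
#' @param kuwahara_radius radius of the Kuwahara sub-windows.
#' @param bilateral list with `sigma_s`, `sigma_r`, `radius`.
#' @return a `filter_bank` configuration list.
#' @export
filter_bank <- function(rank_radii = c(1L, 2L, 4L),
                        hessian_sigmas = c(1, 2),
                        gabor_orientations = 4L,
                        gabor_wavelengths = c(4, 8),
                        kuwahara_radius = 2L,
                        bilateral = list(sigma_s = 2, sigma_r = 30, radius = 3L)) {
  structure(list(rank_radii = as.integer(rank_radii),
                 hessian_sigmas = hessian_sigmas,
                 gabor_orientations = as.integer(gabor_orientations),
                 gabor_wavelengths = gabor_wavelengths,
                 kuwahara_radius = as.integer(kuwahara_radius),
                 bilateral = bilateral),
            class = "filter_bank")
}

#' Compute the per-pixel feature stack
#'
#' @param img numeric matrix (enhanced grayscale, `[0, 255]`).
#' @param bank a [filter_bank()] configuration.
#' @return `H x W x F` array with a `feature_names` attribute.
#' @export
build_pixel_features <- function(img, bank = filter_bank()) {
  stopifnot(is.matrix(img))
  if (nrow(img) < 1L || ncol(img) < 1L) stop("empty image", call. = FALSE)
  planes <- list(raw = img)
  planes$kuwahara <- kuwahara_filter(img, bank$kuwahara_radius)
  planes$bilateral <- bilateral_filter(img, bank$bilateral$sigma_s,
                                       bank$bilateral$sigma_r,
                                       bank$bilateral$radius)
  planes$sobel <- sobel_magnitude(img)
  for (s in bank$hessian_sigmas) {
    h <- hessian_eigen(img, s)
    planes[[sprintf("hessian_hi_s%g", s)]] <- h$hi
    planes[[sprintf("hessian_lo_s%g", s)]] <- h$lo
  }
  thetas <- pi * (seq_len(bank$gabor_orientations) - 1L) / bank$gabor_orientations
  for (w in bank$gabor_wavelengths) {
    for (i in seq_along(thetas)) {
      planes[[sprintf("gabor_w%g_t%d", w, i)]] <-
        conv2(img, gabor_kernel(w, thetas[i]))
    }
  }
  for (r in bank$rank_radii) {
    k <- box_kernel(r)
    m <- conv2(img, k)
    v <- pmax(conv2(img^2, k) - m^2, 0)
    planes[[sprintf("mean_r%d", r)]] <- m
    planes[[sprintf("var_r%d", r)]] <- v
    med <- EBImage::medianFilter(img / 255, r) * 255
    planes[[sprintf("median_r%d", r)]] <- matrix(as.numeric(med), nrow(img), ncol(img))
    br <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    planes[[sprintf("max_r%d", r)]] <-
      matrix(as.numeric(EBImage::dilate(img / 255, br)) * 255, nrow(img), ncol(img))
    planes[[sprintf("min_r%d", r)]] <-
      matrix(as.numeric(EBImage::erode(img / 255, br)) * 255, nrow(img), ncol(img))
    planes[[sprintf("entropy_r%d", r)]] <- local_entropy(img, r)
  }
  out <- array(unlist(planes, use.names = FALSE),
               dim = c(nrow(img), ncol(img), length(planes)))
  attr(out, "feature_names") <- names(planes)
  attr(out, "bank") <- bank
  out
}
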
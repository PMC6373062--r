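# Zernike-moment texture measure for the third debris gate. Moments A_nl of
# the m x m window centered at each object pixel are computed on the unit
# disk inscribed in the window; the texture score of an object is the mean
# of |A_nl| over its pixels and all (n, l) pairs with n <= n_max
# (n - |l| even; odd-parity pairs are identically zero and excluded).

zernike_radial <- function(n, l, r) {
  l <- abs(l)
  out <- numeric(length(r))
  for (s in 0:((n - l) / 2)) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + l) / 2 - s) * factorial((n - l) / 2 - s)) *
      r^(n - 2 * s)
  }
  out
}

#' Zernike basis for an m x m window
#'
#' Complex-conjugated Zernike polynomials sampled at the pixel centers of
#' an `m x m` window, restricted to the inscribed unit disk. Pairs run over
#' `n = 0..n_max`, `l = 0..n`, `n - l` even (negative repetitions carry the
#' same magnitudes).
#'
#' @param m odd window size in pixels.
#' @param n_max maximum order.
#' @return list with `conj_v` (complex matrix, disk pixels x pairs),
#'   `inside` (logical length `m*m`), `pairs` (tibble of n, l), and the
#'   normalisation factors `(n+1)/pi`.
#' @export
zernike_basis <- function(m, n_max = 9L) {
  stopifnot(m >= 2L)
  half <- (m - 1) / 2
  coord <- (seq_len(m) - 1 - half) / half
  g <- expand.grid(y = coord, x = coord)
  r <- sqrt(g$x^2 + g$y^2)
  inside <- r <= 1
  theta <- atan2(g$y[inside], g$x[inside])
  rr <- r[inside]
  pairs <- dplyr::filter(tidyr::expand_grid(n = 0:n_max, l = 0:n_max),
                         .data$l <= .data$n, (.data$n - .data$l) %% 2L == 0L)
  conj_v <- vapply(seq_len(nrow(pairs)), function(i) {
    R <- zernike_radial(pairs$n[i], pairs$l[i], rr)
    R * exp(complex(imaginary = -pairs$l[i] * theta))
  }, complex(sum(inside)))
  list(conj_v = conj_v, inside = inside, pairs = pairs,
       norm = (pairs$n + 1) / pi, m = m, n_max = n_max)
}

#' Zernike moments of a single square patch
#'
#' `A_nl = (n+1)/pi * sum_xy conj(v_nl)(r, theta) I(x, y)` over the
#' inscribed unit disk.
#'
#' @param patch `m x m` numeric matrix.
#' @param basis a [zernike_basis()] for the same `m`.
#' @return complex vector of moments, one per (n, l) pair in `basis$pairs`.
#' @export
zernike_moments <- function(patch, basis) {
  stopifnot(nrow(patch) == basis$m, ncol(patch) == basis$m)
  v <- as.vector(patch)[basis$inside]
  drop(t(basis$conj_v) %*% v) * basis$norm
}

reflect_pad <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  if (r >= nr || r >= nc) stop("window larger than image allows", call. = FALSE)
  ri <- c(rev(seq_len(r) + 1L), seq_len(nr), nr - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(nc), nc - seq_len(r))
  img[ri, ci, drop = FALSE]
}

#' Zernike texture score of an object
#'
#' For each pixel of the object mask, the moments of the window centered
#' there are computed (image reflected at borders) and their magnitudes
#' averaged over pixels and (n, l) pairs.
#'
#' @param img grayscale matrix (enhanced image).
#' @param obj a `cell_object`.
#' @param n_max maximum order (default 9).
#' @param window odd window size in pixels (default 25).
#' @param basis optional precomputed [zernike_basis()].
#' @return scalar texture score.
#' @export
zernike_texture <- function(img, obj, n_max = 9L, window = 25L, basis = NULL) {
  if (length(obj$nucleus_idx) == 0) stop("empty object mask", call. = FALSE)
  if (is.null(basis)) basis <- zernike_basis(window, n_max)
  if (basis$m %% 2L != 1L) stop("texture window size must be odd", call. = FALSE)
  r <- (basis$m - 1L) / 2L
  pad <- reflect_pad(img, r)
  nr <- nrow(img)
  idx <- c(obj$nucleus_idx, obj$cyto_idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  # gather windows as rows of a matrix: disk pixels only
  m <- basis$m
  off <- expand.grid(dr = 0:(m - 1L), dc = 0:(m - 1L))
  inside <- basis$inside
  off <- off[inside, , drop = FALSE]
  npr <- nrow(pad)
  base <- (rows) + (cols - 1L) * npr  # top-left of window in padded image
  win_idx <- outer(base, off$dr + off$dc * npr, "+")
  W <- matrix(pad[win_idx], nrow = length(idx))
  re <- W %*% Re(basis$conj_v)
  im <- W %*% Im(basis$conj_v)
  mags <- sqrt(re^2 + im^2) %*% diag(basis$norm, nrow = length(basis$norm))
  mean(mags)
}

otsu_threshold <- function(x) {
  # Otsu's criterion on a 256-bin histogram of the score vector
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  b <- pmin(floor((x - rng[1]) / diff(rng) * 256), 255)
  h <- tabulate(b + 1L, nbins = 256L)
  p <- h / sum(h)
  om <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mt <- mu[256]
  sb <- (mt * om - mu)^2 / (om * (1 - om))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb) - 1L
  rng[1] + (k + 0.5) / 256 * diff(rng)
}

#' Texture gate
#'
#' Applies the texture threshold to the survivors of the shape gate.
#' `"AUTO"` derives a threshold by an Otsu split of the batch's score
#' distribution, acted on only when the high-score group mean exceeds the
#' low-score group mean by `auto_ratio_min` (a homogeneous all-cell batch
#' is then left untouched). Objects above the threshold are rejected with
#' stage TEXTURE. With fewer than 2 scored objects under AUTO, all are
#' retained and a warning condition is signalled.
#'
#' @param objs list of `cell_object`s with `texture_score` populated.
#' @param cfg a [debris_config()].
#' @return the object list with updated rejection stages.
#' @export
texture_gate <- function(objs, cfg = debris_config()) {
  if (length(objs) == 0) return(objs)
  scores <- vapply(objs, function(o) o$texture_score, numeric(1))
  if (identical(cfg$texture_threshold, "AUTO")) {
    if (length(scores) < 2L) {
      warning("texture gate AUTO needs at least 2 objects; retaining all")
      return(objs)
    }
    med <- stats::median(scores)
    spread <- max(stats::mad(scores), 0.05 * med, 1e-12)
    thr <- med + cfg$auto_gap_min * spread
  } else {
    thr <- cfg$texture_threshold
  }
  for (i in seq_along(objs)) {
    if (!is.na(objs[[i]]$texture_score) && objs[[i]]$texture_score > thr) {
      objs[[i]]$rejection_stage <- "TEXTURE"
    }
  }
  objs
}

#' Three-phase debris rejection
#'
#' Applies the size, shape and texture gates strictly in that order; an
#' object reaches a later gate only if it passed all earlier ones. Returns
#' the retained objects and a per-stage rejection report.
#'
#' @param img enhanced grayscale matrix (for the texture measure).
#' @param labels a `label_map`.
#' @param cfg a [debris_config()].
#' @param candidate_classes passed to [label_objects()].
#' @return list with `retained` (cell objects), `rejected` (cell objects),
#'   `report` (tibble of per-stage counts) and `objects` (tidy tibble of
#'   every candidate with its stage and scores).
#' @export
reject_debris <- function(img, labels, cfg = debris_config(),
                          candidate_classes = "NUCLEUS") {
  objs <- label_objects(labels, area_factor = cfg$area_factor,
                        candidate_classes = candidate_classes)
  if (length(objs) == 0) {
    return(list(retained = list(), rejected = list(),
                report = tibble::tibble(stage = c("SIZE", "SHAPE", "TEXTURE"),
                                        rejected = c(0L, 0L, 0L)),
                objects = objects_tibble(objs)))
  }
  objs <- lapply(objs, size_gate, cfg = cfg)
  pass_size <- vapply(objs, function(o) o$rejection_stage == "NONE", logical(1))
  objs[pass_size] <- lapply(objs[pass_size], shape_gate, cfg = cfg)
  pass_shape <- vapply(objs, function(o) o$rejection_stage == "NONE", logical(1))
  if (any(pass_shape)) {
    basis <- zernike_basis(cfg$zernike_window, cfg$zernike_order)
    objs[pass_shape] <- lapply(objs[pass_shape], function(o) {
      o$texture_score <- zernike_texture(img, o, basis = basis)
      o
    })
    objs[pass_shape] <- texture_gate(objs[pass_shape], cfg)
  }
  stages <- vapply(objs, function(o) o$rejection_stage, character(1))
  list(
    retained = objs[stages == "NONE"],
    rejected = objs[stages != "NONE"],
    report = tibble::tibble(
      stage = c("SIZE", "SHAPE", "TEXTURE"),
      rejected = c(sum(stages == "SIZE"), sum(stages == "SHAPE"),
                   sum(stages == "TEXTURE"))
    ),
    objects = objects_tibble(objs)
  )
}
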
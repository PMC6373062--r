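# Shared fixtures, built once per test run on first use.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small rendered scene with one cell per mid-size class + debris
small_scene <- function() {
  fixture("small_scene", function() {
    counts <- c(SUPERFICIAL = 1, INTERMEDIATE = 1, COLUMNAR = 2, MILD = 2,
                MODERATE = 2, SEVERE = 2, CARCINOMA_IN_SITU = 2)
    sc <- render_scene(scene_recipe(cells_per_class = counts, n_speck = 2,
                                    n_fiber = 1, n_blob = 1, seed = 421))
    sc$enh <- enhance(sc$gray)
    sc
  })
}

# ground-truth scribbles sampled per class from a scene
scribbles_from_truth <- function(sc, n_per_class = 150, seed = 99) {
  gt <- sc$truth$labels
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_along(scene_classes), function(k) {
      idx <- which(gt == k)
      if (length(idx) == 0) return(NULL)
      idx <- sample(idx, min(n_per_class, length(idx)))
      annotations(((idx - 1L) %% nrow(gt)) + 1L,
                  ((idx - 1L) %/% nrow(gt)) + 1L, scene_classes[k])
    }))
  })
}

# scene + trained pixel classifier + feature stack (expensive; shared)
segmentation_fixture <- function() {
  fixture("segmentation_fixture", function() {
    sc <- small_scene()
    stack <- build_pixel_features(sc$enh)
    ann <- scribbles_from_truth(sc)
    clf <- train_pixel_classifier(stack, ann, seed = 7)
    list(scene = sc, stack = stack, clf = clf)
  })
}

# draw a filled disk / ellipse mask as a cell_object on a flat image
disk_object <- function(radius, dim = 2L * radius + 11L, intensity = 60,
                        bg = 200, ratio = 1, angle = 0) {
  ctr <- c(dim, dim) / 2
  a <- radius / sqrt(ratio); b <- radius * sqrt(ratio)
  idx <- papscreen:::ellipse_mask_idx(dim, dim, ctr, a, b, angle)
  img <- matrix(bg, dim, dim)
  img[idx] <- intensity
  lab <- matrix(3L, dim, dim)
  lab[idx] <- 1L
  list(img = img, labels = label_map(lab),
       obj = label_objects(label_map(lab))[[1]])
}

# independent brute-force Zernike moment oracle: explicit double sum with
# the factorial radial series, no shared code with the implementation
zernike_oracle <- function(patch, n, l) {
  m <- nrow(patch)
  half <- (m - 1) / 2
  acc <- 0 + 0i
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      y <- (i - 1 - half) / half
      x <- (j - 1 - half) / half
      r <- sqrt(x^2 + y^2)
      if (r > 1) next
      theta <- atan2(y, x)
      R <- 0
      for (s in 0:((n - abs(l)) / 2)) {
        R <- R + (-1)^s * factorial(n - s) /
          (factorial(s) * factorial((n + abs(l)) / 2 - s) *
             factorial((n - abs(l)) / 2 - s)) * r^(n - 2 * s)
      }
      v <- R * exp(1i * l * theta)
      acc <- acc + Conj(v) * patch[i, j]
    }
  }
  (n + 1) / pi * acc
}
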
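# Synthetic data: labelled feature tables drawn from the per-class
# morphometric statistics of the Herlev-style training material, and
# rendered slide scenes with ground-truth masks and debris, so every
# pipeline stage can be exercised without external image data.

#' Per-class morphometric statistics
#'
#' Mean and SD per cell class for nucleus area, cytoplasm area, N/C ratio,
#' nucleus/cytoplasm brightness and perimeters, in calibrated pixel-count
#' units (0.201 um/pixel acquisition). The carcinoma-in-situ cytoplasm
#' perimeter is carried as printed in the source material but flagged: it
#' is inconsistent with the class's cytoplasm area, and the scene renderer
#' derives perimeters from areas instead.
#'
#' @return tibble with `class`, `feature`, `mean`, `sd`, `flagged`.
#' @export
class_stats <- function() {
  feats <- c("nucleus_area", "cyto_area", "nc_ratio", "nucleus_brightness",
             "cyto_brightness", "nucleus_perimeter", "cyto_perimeter")
  m <- rbind(
    SUPERFICIAL       = c(631,  61487, 0.01, 66, 134, 88,  1034),
    INTERMEDIATE      = c(1315, 44961, 0.03, 67, 131, 130, 894),
    COLUMNAR          = c(1591, 3290,  0.35, 94, 138, 153, 323),
    MILD              = c(4690, 15459, 0.27, 98, 142, 257, 589),
    MODERATE          = c(3873, 7288,  0.38, 92, 135, 231, 443),
    SEVERE            = c(2949, 3415,  0.49, 94, 143, 208, 323),
    CARCINOMA_IN_SITU = c(2986, 2115,  0.60, 97, 142, 215, 28)
  )
  s <- rbind(
    SUPERFICIAL       = c(206,  23780, 0.01, 17, 23, 15, 221),
    INTERMEDIATE      = c(390,  15345, 0.01, 19, 22, 19, 166),
    COLUMNAR          = c(699,  1829,  0.10, 25, 36, 35, 103),
    MILD              = c(1901, 10539, 0.10, 17, 19, 55, 203),
    MODERATE          = c(1651, 5207,  0.12, 15, 18, 49, 141),
    SEVERE            = c(1474, 2276,  0.14, 22, 29, 52, 95),
    CARCINOMA_IN_SITU = c(1474, 1490,  0.13, 18, 22, 48, 67)
  )
  out <- tidyr::expand_grid(class = cell_classes, feature = feats)
  out$mean <- as.numeric(mapply(function(cl, f) m[cl, match(f, feats)], out$class, out$feature))
  out$sd <- as.numeric(mapply(function(cl, f) s[cl, match(f, feats)], out$class, out$feature))
  out$flagged <- out$class == "CARCINOMA_IN_SITU" & out$feature == "cyto_perimeter"
  out
}

stat_of <- function(stats, cl, feat) {
  row <- stats[stats$class == cl & stats$feature == feat, ]
  c(mean = unname(row$mean[1]), sd = unname(row$sd[1]))
}

#' Truncated-normal draws by rejection sampling
#'
#' @param n draws.
#' @param mean,sd normal parameters.
#' @param lower,upper truncation bounds.
#' @return numeric vector of `n` draws from the truncated distribution.
#' @export
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

physical_bounds <- function(feature) {
  switch(feature,
         nucleus_area = , cyto_area = , nucleus_perimeter = ,
         cyto_perimeter = c(1e-6, Inf),
         nc_ratio = c(0, 1),
         nucleus_brightness = , cyto_brightness = c(0, 255),
         c(-Inf, Inf))
}

#' Generate a labelled feature table from the class statistics
#'
#' The seven tabulated features are drawn as independent Gaussians
#' truncated at their physical bounds (areas and perimeters positive,
#' ratios in `[0, 1]`, brightness in `[0, 255]`). The remaining features of
#' the 29-column table are synthesized consistently with near-elliptical
#' geometry (diameters from areas through a jittered axis ratio, histogram
#' statistics from a Gaussian intensity model). An optional `correlation`
#' knob couples the nucleus-area and N/C-ratio draws for harder benchmarks.
#'
#' @param n_per_class cells per class (scalar or named vector over
#'   [cell_classes]).
#' @param seed integer seed (the table is a pure function of it).
#' @param stats statistics tibble (default [class_stats()]).
#' @param correlation correlation between nucleus area and N/C ratio
#'   (default 0, the independence assumption of the source marginals).
#' @return tibble with `label` plus the 29 [feature_names] columns.
#' @export
gen_feature_table <- function(n_per_class, seed = 1L, stats = class_stats(),
                              correlation = 0) {
  if (any(n_per_class < 1)) stop("n_per_class must be >= 1", call. = FALSE)
  if (length(n_per_class) == 1L) {
    n_per_class <- stats::setNames(rep(n_per_class, length(cell_classes)), cell_classes)
  }
  withr::with_seed(seed, {
    rows <- lapply(cell_classes, function(cl) {
      n <- n_per_class[[cl]]
      draw <- function(feat) {
        p <- stat_of(stats, cl, feat); b <- physical_bounds(feat)
        rnorm_trunc(n, p["mean"], p["sd"], b[1], b[2])
      }
      na <- draw("nucleus_area")
      nc <- if (correlation != 0) {
        p_na <- stat_of(stats, cl, "nucleus_area")
        p_nc <- stat_of(stats, cl, "nc_ratio")
        z_na <- (na - p_na["mean"]) / max(p_na["sd"], 1e-9)
        raw <- p_nc["mean"] + p_nc["sd"] *
          (correlation * z_na + sqrt(1 - correlation^2) * stats::rnorm(n))
        pmin(pmax(raw, 0), 1)
      } else draw("nc_ratio")
      ca <- draw("cyto_area")
      nb <- draw("nucleus_brightness")
      cb <- draw("cyto_brightness")
      np <- draw("nucleus_perimeter")
      cp <- draw("cyto_perimeter")
      rho_n <- stats::runif(n, 0.58, 0.72)   # nucleus axis ratio
      rho_c <- stats::runif(n, 0.58, 0.72)
      n_long <- 2 * sqrt(na / (pi * rho_n))
      c_long <- 2 * sqrt(ca / (pi * rho_c))
      sig <- abs(stats::rnorm(n, 8, 2)) + 0.5  # intensity spread model
      tibble::tibble(
        label = cl,
        nucleus_area = na, nucleus_gray_level = nb,
        nucleus_shortest_diameter = rho_n * n_long,
        nucleus_longest_diameter = n_long,
        nucleus_elongation = rho_n,
        nucleus_roundness = rho_n,
        nucleus_perimeter = np,
        nucleus_maxima = 1 + stats::rpois(n, 2),
        nucleus_minima = 1 + stats::rpois(n, 2),
        nc_ratio = nc,
        nucleus_solidity = stats::runif(n, 0.9, 0.99),
        nucleus_eccentricity = sqrt(1 - rho_n^2),
        nucleus_sd = sig,
        nucleus_variance = sig^2,
        nucleus_entropy = log2(sig * sqrt(2 * pi * exp(1))),
        cyto_area = ca, cyto_gray_level = cb,
        cyto_shortest_diameter = rho_c * c_long,
        cyto_longest_diameter = c_long,
        cyto_elongation = rho_c,
        cyto_roundness = rho_c,
        cyto_perimeter = cp,
        cyto_maxima = 1 + stats::rpois(n, 3),
        cyto_minima = 1 + stats::rpois(n, 3),
        nucleus_relative_position = pmin(abs(stats::rnorm(n, 0, 0.08)), 1),
        nucleus_compactness = pmin(4 * pi * na / np^2, 1),
        nucleus_mean = nb,
        nucleus_smoothness = 1 - 1 / (1 + (sig / 255)^2),
        nucleus_energy = pmin(1 / (2 * sig * sqrt(pi)), 1)
      )
    })
    out <- dplyr::bind_rows(rows)
    out$label <- factor(out$label, levels = cell_classes)
    out
  })
}

#' Scene recipe for the slide renderer
#'
#' @param cells_per_class cells per class (scalar or named vector).
#' @param n_speck,n_fiber,n_blob debris counts by type: sub-size specks,
#'   elongated fibers (circularity below the shape band), and
#'   speckled blobs with outlying texture scores.
#' @param dim image height/width in pixels (`NULL`: sized automatically).
#' @param scale linear rendering scale relative to the calibrated unit
#'   system (default 0.25; areas in units = pixel count / scale^2).
#' @param bg_mean,noise_sd background level and additive Gaussian noise SD.
#' @param seed integer seed; fixes the scene exactly.
#' @param max_retries placement attempts per object before a placement
#'   error is raised.
#' @export
scene_recipe <- function(cells_per_class = 2L, n_speck = 0L, n_fiber = 0L,
                         n_blob = 0L, dim = NULL, scale = 0.25,
                         bg_mean = 200, noise_sd = 4, seed = 1L,
                         max_retries = 400L) {
  if (length(cells_per_class) == 1L) {
    cells_per_class <- stats::setNames(rep(cells_per_class, length(cell_classes)),
                                       cell_classes)
  }
  structure(list(cells_per_class = cells_per_class, n_speck = as.integer(n_speck),
                 n_fiber = as.integer(n_fiber), n_blob = as.integer(n_blob),
                 dim = dim, scale = scale, bg_mean = bg_mean,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 max_retries = as.integer(max_retries)),
            class = "scene_recipe")
}

ellipse_mask_idx <- function(nr, nc, center, a, b, phi) {
  r0 <- max(1L, floor(center[1] - a)); r1 <- min(nr, ceiling(center[1] + a))
  c0 <- max(1L, floor(center[2] - a)); c1 <- min(nc, ceiling(center[2] + a))
  g <- expand.grid(r = r0:r1, c = c0:c1)
  dy <- g$r - center[1]; dx <- g$c - center[2]
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  v <- (-dx * sin(phi) + dy * cos(phi)) / b
  keep <- u^2 + v^2 <= 1
  g$r[keep] + (g$c[keep] - 1L) * nr
}

#' Render a synthetic slide scene with ground truth
#'
#' Cells are elliptical cytoplasm regions with interior elliptical nuclei,
#' sized and shaded per class statistics; debris types are constructed to
#' trip specific gates (specks below the lower area bound, fibers below the
#' circularity band, speckled blobs with outlying Zernike texture). Returns
#' the image, the ground-truth label map, an object index map and a
#' manifest of every rendered object.
#'
#' @param recipe a [scene_recipe()].
#' @param stats class statistics (default [class_stats()]).
#' @return list: `image` (H x W x 3 RGB array), `gray` (matrix), `truth`
#'   (`label_map`), `object_map` (H x W integer), `manifest` (tibble),
#'   `area_factor` (units per pixel, `1/scale^2`).
#' @export
render_scene <- function(recipe = scene_recipe(), stats = class_stats()) {
  withr::with_seed(recipe$seed, {
    s <- recipe$scale
    af <- 1 / s^2
    specs <- list()
    for (cl in cell_classes) {
      n <- recipe$cells_per_class[[cl]]
      if (n < 1) next
      p_na <- stat_of(stats, cl, "nucleus_area")
      p_ca <- stat_of(stats, cl, "cyto_area")
      p_nb <- stat_of(stats, cl, "nucleus_brightness")
      p_cb <- stat_of(stats, cl, "cyto_brightness")
      for (i in seq_len(n)) {
        na <- rnorm_trunc(1, p_na["mean"], p_na["sd"], 250, Inf)
        # cytoplasm area: for the compact classes it is derived through the
        # drawn N/C ratio (the printed area and ratio marginals are mutually
        # consistent only if the two areas are correlated, and the ratio is
        # the tighter, more diagnostic marginal); for the large superficial
        # and intermediate classes the independent area draw already
        # reproduces the printed ratio marginal without the heavy 1/ratio
        # tail
        if (cl %in% c("SUPERFICIAL", "INTERMEDIATE")) {
          ca <- rnorm_trunc(1, p_ca["mean"], p_ca["sd"], max(0.6 * na, 1600 - na), Inf)
        } else {
          p_nc <- stat_of(stats, cl, "nc_ratio")
          nc_draw <- rnorm_trunc(1, p_nc["mean"], p_nc["sd"],
                                 max(0.01, p_nc["mean"] - 2.5 * p_nc["sd"]),
                                 min(0.95, p_nc["mean"] + 2.5 * p_nc["sd"]))
          ca <- max(min(na * (1 - nc_draw) / nc_draw,
                        p_ca["mean"] + 2.5 * p_ca["sd"]),
                    0.6 * na, 1600 - na)
        }
        cb <- rnorm_trunc(1, p_cb["mean"], p_cb["sd"], 115, 180)
        # hematoxylin: nuclei are darker than any cytoplasm; grayscale
        # rendering has no hue channel, so the intensity envelopes are kept
        # disjoint for the scene to be resolvable by local pixel features
        nb <- rnorm_trunc(1, p_nb["mean"], p_nb["sd"], 20, min(110, cb - 25))
        specs[[length(specs) + 1L]] <- list(
          kind = cl, is_cell = TRUE,
          nucleus_area = na, cyto_area = ca,
          nucleus_brightness = nb, cyto_brightness = cb)
      }
    }
    for (i in seq_len(recipe$n_speck)) {
      specs[[length(specs) + 1L]] <- list(kind = "speck", is_cell = FALSE,
                                          area_units = stats::runif(1, 120, 480))
    }
    for (i in seq_len(recipe$n_fiber)) {
      specs[[length(specs) + 1L]] <- list(kind = "fiber", is_cell = FALSE,
                                          len_px = stats::runif(1, 60, 85))
    }
    for (i in seq_len(recipe$n_blob)) {
      specs[[length(specs) + 1L]] <- list(kind = "noisy_blob", is_cell = FALSE,
                                          area_units = stats::runif(1, 2500, 6000))
    }
    # bounding radius per object in px
    radius_of <- function(sp) {
      if (sp$is_cell) sqrt((sp$nucleus_area + sp$cyto_area) * s^2 / (pi * 0.45))
      else if (sp$kind == "speck") sqrt(sp$area_units * s^2 / pi) + 1
      else if (sp$kind == "fiber") sp$len_px / 2 + 2
      else sqrt(sp$area_units * s^2 / (pi * 0.5)) + 1
    }
    radii <- vapply(specs, radius_of, numeric(1))
    if (is.null(recipe$dim)) {
      side <- ceiling(sqrt(3.2 * sum(pi * radii^2)) + 2 * max(radii, 0))
      dims <- c(side, side)
    } else dims <- recipe$dim
    nr <- dims[1]; nc <- dims[2]
    img <- matrix(recipe$bg_mean, nr, nc)
    lab <- matrix(match("BACKGROUND", scene_classes), nr, nc)
    omap <- matrix(0L, nr, nc)
    placed <- matrix(numeric(0), ncol = 3)
    rows <- list()
    order_idx <- order(radii, decreasing = TRUE)  # large first packs better
    for (oi in order_idx) {
      sp <- specs[[oi]]
      rad <- radii[oi]
      ok <- FALSE
      for (try in seq_len(recipe$max_retries)) {
        ctr <- c(stats::runif(1, rad + 2, nr - rad - 1),
                 stats::runif(1, rad + 2, nc - rad - 1))
        if (nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - ctr[1])^2 + (placed[, 2] - ctr[2])^2) >
                placed[, 3] + rad + 8)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place object on canvas (placement error)", call. = FALSE)
      placed <- rbind(placed, c(ctr, rad))
      id <- length(rows) + 1L
      phi <- stats::runif(1, 0, pi)
      if (sp$is_cell) {
        cell_px <- (sp$nucleus_area + sp$cyto_area) * s^2
        nuc_px <- sp$nucleus_area * s^2
        rho_c <- stats::runif(1, 0.45, 0.58)  # discrete circularity stays inside the shape band
        rho_n <- stats::runif(1, 0.45, 0.58)
        a_c <- sqrt(cell_px / (pi * rho_c)); b_c <- rho_c * a_c
        a_n <- sqrt(nuc_px / (pi * rho_n)); b_n <- rho_n * a_n
        off_max <- max(b_c - a_n - 1, 0) * 0.3
        off <- stats::runif(2, -off_max / 2, off_max / 2)
        cell_idx <- ellipse_mask_idx(nr, nc, ctr, a_c, b_c, phi)
        nuc_idx <- ellipse_mask_idx(nr, nc, ctr + off, a_n, b_n,
                                    phi + stats::runif(1, -0.4, 0.4))
        nuc_idx <- intersect(nuc_idx, cell_idx)
        cyto_idx <- setdiff(cell_idx, nuc_idx)
        img[cyto_idx] <- sp$cyto_brightness
        # chromatin mottling: coarse granular texture inside the nucleus,
        # the cue that distinguishes nuclei from uniformly dark cytoplasm
        nrows_i <- ((nuc_idx - 1L) %% nr) + 1L
        ncols_i <- ((nuc_idx - 1L) %/% nr) + 1L
        key <- (nrows_i %/% 2L) * 7919L + (ncols_i %/% 2L)
        uk <- unique(key)
        lev <- stats::rnorm(length(uk), 0, 9)
        img[nuc_idx] <- pmax(sp$nucleus_brightness + lev[match(key, uk)], 5)
        lab[cyto_idx] <- match("CYTOPLASM", scene_classes)
        lab[nuc_idx] <- match("NUCLEUS", scene_classes)
        omap[cell_idx] <- id
        rows[[id]] <- tibble::tibble(
          id = id, kind = sp$kind, is_cell = TRUE,
          binary = as.character(binary_label(sp$kind)),
          row = ctr[1] + off[1], col = ctr[2] + off[2],
          nucleus_area = length(nuc_idx) * af,
          cyto_area = length(cyto_idx) * af,
          area_units = length(cell_idx) * af,
          nucleus_brightness = sp$nucleus_brightness,
          cyto_brightness = sp$cyto_brightness)
      } else {
        if (sp$kind == "speck") {
          r_px <- sqrt(sp$area_units * s^2 / pi)
          idx <- ellipse_mask_idx(nr, nc, ctr, r_px, r_px * 0.85, phi)
          img[idx] <- 60
        } else if (sp$kind == "fiber") {
          half <- sp$len_px / 2
          g <- expand.grid(r = max(1, floor(ctr[1] - half - 2)):min(nr, ceiling(ctr[1] + half + 2)),
                           c = max(1, floor(ctr[2] - half - 2)):min(nc, ceiling(ctr[2] + half + 2)))
          dy <- g$r - ctr[1]; dx <- g$c - ctr[2]
          u <- dx * cos(phi) + dy * sin(phi)
          v <- -dx * sin(phi) + dy * cos(phi)
          keep <- abs(u) <= half & abs(v) <= 1
          idx <- g$r[keep] + (g$c[keep] - 1L) * nr
          img[idx] <- 90
        } else {
          rho <- 0.5
          a <- sqrt(sp$area_units * s^2 / (pi * rho)); b <- rho * a
          idx <- ellipse_mask_idx(nr, nc, ctr, a, b, phi)
          # coarse blockwise speckle: variation at the texture-window scale
          blk <- 5L
          rows_i <- ((idx - 1L) %% nr) + 1L
          cols_i <- ((idx - 1L) %/% nr) + 1L
          key <- (rows_i %/% blk) * 7919L + (cols_i %/% blk)
          uk <- unique(key)
          lev <- sample(c(15, 240), length(uk), replace = TRUE)
          img[idx] <- lev[match(key, uk)]
        }
        lab[idx] <- match("DEBRIS", scene_classes)
        omap[idx] <- id
        rows[[id]] <- tibble::tibble(
          id = id, kind = sp$kind, is_cell = FALSE, binary = NA_character_,
          row = ctr[1], col = ctr[2],
          nucleus_area = NA_real_, cyto_area = NA_real_,
          area_units = length(idx) * af,
          nucleus_brightness = NA_real_, cyto_brightness = NA_real_)
      }
    }
    img <- img + stats::rnorm(length(img), 0, recipe$noise_sd)
    img <- pmin(pmax(img, 0), 255)
    rgb <- array(img, dim = c(nr, nc, 3))
    attr(rgb, "pixel_size_um") <- 0.201 / s
    list(image = rgb, gray = img, truth = label_map(lab),
         object_map = omap, manifest = dplyr::bind_rows(rows),
         area_factor = af, scale = s)
  })
}

#' Match retained objects to manifest cells
#'
#' Greedy one-to-one assignment by centroid distance (closest pairs first)
#' between extracted objects and the manifest's cells, used to score
#' end-to-end runs against the rendered ground truth.
#'
#' @param objs list of `cell_object`s (e.g. `reject_debris()$retained`).
#' @param manifest manifest tibble from [render_scene()].
#' @param max_dist maximum centroid distance in pixels for a match.
#' @return integer vector over `objs`: matched manifest `id` or `NA`.
#' @export
match_manifest <- function(objs, manifest, max_dist = 25) {
  cells <- manifest[manifest$is_cell, ]
  if (length(objs) == 0 || nrow(cells) == 0) {
    return(rep(NA_integer_, length(objs)))
  }
  d <- outer(seq_along(objs), seq_len(nrow(cells)), function(i, j) {
    oi <- vapply(objs[i], function(o) o$centroid[1], numeric(1))
    oj <- vapply(objs[i], function(o) o$centroid[2], numeric(1))
    sqrt((oi - cells$row[j])^2 + (oj - cells$col[j])^2)
  })
  out <- rep(NA_integer_, length(objs))
  taken <- rep(FALSE, nrow(cells))
  ord <- order(d)
  for (k in ord) {
    if (d[k] > max_dist) break
    i <- ((k - 1L) %% length(objs)) + 1L
    j <- ((k - 1L) %/% length(objs)) + 1L
    if (is.na(out[i]) && !taken[j]) {
      out[i] <- cells$id[j]
      taken[j] <- TRUE
    }
  }
  out
}
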
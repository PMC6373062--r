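# Per-cell morphometry: the 29 nucleus/cytoplasm features used by the
# classifier. Geometry is measured on the object masks, intensity features
# on the enhanced grayscale image; areas and lengths are reported in the
# calibrated unit system of the training statistics.

#' The seven cervical-cell classes
#'
#' First three are normal epithelial classes, last four graded
#' abnormalities. Declaration order fixes tie-breaking.
#' @export
cell_classes <- c("SUPERFICIAL", "INTERMEDIATE", "COLUMNAR",
                  "MILD", "MODERATE", "SEVERE", "CARCINOMA_IN_SITU")

#' Map a cell class to the binary diagnosis
#'
#' @param class character vector of [cell_classes] values.
#' @return factor with levels NORMAL, ABNORMAL.
#' @export
binary_label <- function(class) {
  class <- as.character(class)
  if (!all(class %in% cell_classes)) stop("unknown cell class", call. = FALSE)
  factor(ifelse(class %in% cell_classes[1:3], "NORMAL", "ABNORMAL"),
         levels = c("NORMAL", "ABNORMAL"))
}

#' Canonical order of the 29 per-cell features
#' @export
feature_names <- c(
  "nucleus_area", "nucleus_gray_level", "nucleus_shortest_diameter",
  "nucleus_longest_diameter", "nucleus_elongation", "nucleus_roundness",
  "nucleus_perimeter", "nucleus_maxima", "nucleus_minima",
  "nc_ratio", "nucleus_solidity", "nucleus_eccentricity",
  "nucleus_sd", "nucleus_variance", "nucleus_entropy",
  "cyto_area", "cyto_gray_level", "cyto_shortest_diameter",
  "cyto_longest_diameter", "cyto_elongation", "cyto_roundness",
  "cyto_perimeter", "cyto_maxima", "cyto_minima",
  "nucleus_relative_position", "nucleus_compactness",
  "nucleus_mean", "nucleus_smoothness", "nucleus_energy"
)

min_enclosing_circle <- function(pts) {
  # exact minimal enclosing circle over the convex hull (small point sets)
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  n <- nrow(hull)
  if (n == 1L) return(list(center = hull[1, ], radius = 0))
  circ2 <- function(a, b) list(center = (a + b) / 2, radius = sqrt(sum((a - b)^2)) / 2)
  circ3 <- function(a, b, c) {
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) return(NULL)
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) + sum(c^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) + sum(c^2) * (b[1] - a[1])) / d
    ctr <- c(ux, uy)
    list(center = ctr, radius = sqrt(sum((ctr - a)^2)))
  }
  covers <- function(circ) all(sqrt((hull[, 1] - circ$center[1])^2 +
                                    (hull[, 2] - circ$center[2])^2) <= circ$radius + 1e-9)
  best <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cc <- circ2(hull[i, ], hull[j, ])
    if (covers(cc) && (is.null(best) || cc$radius < best$radius)) best <- cc
  }
  if (!is.null(best)) return(best)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- circ3(hull[i, ], hull[j, ], hull[k, ])
    if (!is.null(cc) && covers(cc) && (is.null(best) || cc$radius < best$radius)) best <- cc
  }
  best
}

region_geometry <- function(idx, nr, nc, lf) {
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  mask <- matrix(FALSE, nr, nc); mask[idx] <- TRUE
  # crop with 1-px border for the distance transform
  r0 <- max(min(rows) - 1L, 1L); r1 <- min(max(rows) + 1L, nr)
  c0 <- max(min(cols) - 1L, 1L); c1 <- min(max(cols) + 1L, nc)
  crop <- mask[r0:r1, c0:c1, drop = FALSE]
  crop_p <- rbind(FALSE, cbind(FALSE, crop, FALSE), FALSE)
  dm <- EBImage::distmap(crop_p * 1)
  shortest <- 2 * max(dm)
  pts <- cbind(rows, cols)
  mec <- min_enclosing_circle(pts)
  longest <- 2 * mec$radius
  if (longest == 0) longest <- 1  # single pixel: unit-size convention
  if (shortest == 0) shortest <- 1
  per_px <- contour_perimeter(mask)
  area_px <- length(idx)
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hull_pts <- pts[hull, , drop = FALSE]
  hull_area <- if (nrow(hull_pts) >= 3) {
    x <- hull_pts[, 2]; y <- hull_pts[, 1]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2 + per_px / 2 + 1
  } else area_px
  hull_area <- max(hull_area, area_px)
  mu_r <- mean(rows); mu_c <- mean(cols)
  m20 <- mean((rows - mu_r)^2); m02 <- mean((cols - mu_c)^2)
  m11 <- mean((rows - mu_r) * (cols - mu_c))
  common <- sqrt(pmax((m20 - m02)^2 + 4 * m11^2, 0))
  l1 <- (m20 + m02 + common) / 2
  l2 <- (m20 + m02 - common) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(pmax(1 - l2 / l1, 0))
  ecc <- min(ecc, 1 - 1e-12)
  list(
    area_px = area_px,
    shortest = min(shortest, longest) * lf,
    longest = longest * lf,
    perimeter = per_px * lf,
    roundness = min(area_px / (pi * (longest / 2)^2), 1),
    solidity = min(area_px / hull_area, 1),
    eccentricity = ecc,
    centroid = c(mu_r, mu_c),
    compactness_val = if (per_px > 0) circularity(area_px, per_px) else NA_real_
  )
}

count_regional_extrema <- function(img_crop, mask_crop, radius = 3L, maxima = TRUE) {
  br <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  x <- img_crop / 255
  ref <- if (maxima) EBImage::dilate(x, br) else EBImage::erode(x, br)
  flat <- abs(matrix(as.numeric(ref), nrow(x), ncol(x)) - x) < 1e-9
  flat <- flat & mask_crop
  if (!any(flat)) return(0L)
  max(label_components_8(flat))
}

hist_features <- function(vals) {
  v <- pmin(pmax(round(vals), 0), 255)
  p <- tabulate(v + 1L, nbins = 256L) / length(v)
  nz <- p > 0
  sigma01 <- stats::sd(vals / 255)
  if (is.na(sigma01)) sigma01 <- 0
  list(
    mean = mean(vals),
    sd = if (length(vals) > 1) stats::sd(vals) else 0,
    variance = if (length(vals) > 1) stats::var(vals) else 0,
    entropy = -sum(p[nz] * log2(p[nz])),
    energy = sum(p^2),
    smoothness = 1 - 1 / (1 + sigma01^2)
  )
}

#' Extract the 29 per-cell features
#'
#' Intensity features (gray levels, mean, SD, variance, entropy, energy,
#' smoothness, regional extrema) are measured on the plain grayscale image
#' (the weighted-luminance conversion), not on the locally equalized one:
#' adaptive equalization is a segmentation aid, and densitometry on its
#' output loses the absolute staining scale that separates the cell
#' classes.
#'
#' @param img grayscale matrix in `[0, 255]` (unenhanced luminance).
#' @param obj a `cell_object` (non-empty nucleus mask; cytoplasm optional —
#'   with no cytoplasm the cytoplasm features are `NA` and the
#'   nucleus-to-cytoplasm ratio is 1).
#' @param area_factor calibrated area units per pixel.
#' @return one-row tibble with the [feature_names] columns.
#' @export
extract_features <- function(img, obj, area_factor = 1) {
  if (length(obj$nucleus_idx) == 0) stop("empty nucleus mask", call. = FALSE)
  nr <- obj$dim[1]; nc <- obj$dim[2]
  lf <- sqrt(area_factor)
  ng <- region_geometry(obj$nucleus_idx, nr, nc, lf)
  nh <- hist_features(img[obj$nucleus_idx])
  rows <- ((obj$nucleus_idx - 1L) %% nr) + 1L
  cols <- ((obj$nucleus_idx - 1L) %/% nr) + 1L
  r0 <- max(min(rows) - 3L, 1L); r1 <- min(max(rows) + 3L, nr)
  c0 <- max(min(cols) - 3L, 1L); c1 <- min(max(cols) + 3L, nc)
  nmask <- matrix(FALSE, nr, nc); nmask[obj$nucleus_idx] <- TRUE
  nmax <- count_regional_extrema(img[r0:r1, c0:c1], nmask[r0:r1, c0:c1], maxima = TRUE)
  nmin <- count_regional_extrema(img[r0:r1, c0:c1], nmask[r0:r1, c0:c1], maxima = FALSE)

  has_cyto <- length(obj$cyto_idx) > 0
  if (has_cyto) {
    cg <- region_geometry(obj$cyto_idx, nr, nc, lf)
    crows <- ((obj$cyto_idx - 1L) %% nr) + 1L
    ccols <- ((obj$cyto_idx - 1L) %/% nr) + 1L
    cr0 <- max(min(crows) - 3L, 1L); cr1 <- min(max(crows) + 3L, nr)
    cc0 <- max(min(ccols) - 3L, 1L); cc1 <- min(max(ccols) + 3L, nc)
    cmask <- matrix(FALSE, nr, nc); cmask[obj$cyto_idx] <- TRUE
    cmax <- count_regional_extrema(img[cr0:cr1, cc0:cc1], cmask[cr0:cr1, cc0:cc1], maxima = TRUE)
    cmin <- count_regional_extrema(img[cr0:cr1, cc0:cc1], cmask[cr0:cr1, cc0:cc1], maxima = FALSE)
    cyto_gray <- mean(img[obj$cyto_idx])
    # relative position: centroid offset over the cell's longest radius,
    # measured on the whole cell (nucleus + cytoplasm)
    cell_g <- region_geometry(c(obj$nucleus_idx, obj$cyto_idx), nr, nc, lf)
    relpos <- sqrt(sum((ng$centroid - cell_g$centroid)^2)) * lf / (cell_g$longest / 2)
    na <- ng$area_px * area_factor
    ca <- cg$area_px * area_factor
    nc_ratio <- na / (na + ca)
  } else {
    cg <- NULL; cmax <- NA_integer_; cmin <- NA_integer_
    cyto_gray <- NA_real_; relpos <- NA_real_
    na <- ng$area_px * area_factor
    nc_ratio <- 1
  }
  tibble::tibble(
    nucleus_area = ng$area_px * area_factor,
    nucleus_gray_level = nh$mean,
    nucleus_shortest_diameter = ng$shortest,
    nucleus_longest_diameter = ng$longest,
    nucleus_elongation = ng$shortest / ng$longest,
    nucleus_roundness = ng$roundness,
    nucleus_perimeter = ng$perimeter,
    nucleus_maxima = as.numeric(nmax),
    nucleus_minima = as.numeric(nmin),
    nc_ratio = nc_ratio,
    nucleus_solidity = ng$solidity,
    nucleus_eccentricity = ng$eccentricity,
    nucleus_sd = nh$sd,
    nucleus_variance = nh$variance,
    nucleus_entropy = nh$entropy,
    cyto_area = if (has_cyto) cg$area_px * area_factor else NA_real_,
    cyto_gray_level = cyto_gray,
    cyto_shortest_diameter = if (has_cyto) cg$shortest else NA_real_,
    cyto_longest_diameter = if (has_cyto) cg$longest else NA_real_,
    cyto_elongation = if (has_cyto) cg$shortest / cg$longest else NA_real_,
    cyto_roundness = if (has_cyto) cg$roundness else NA_real_,
    cyto_perimeter = if (has_cyto) cg$perimeter else NA_real_,
    cyto_maxima = as.numeric(cmax),
    cyto_minima = as.numeric(cmin),
    nucleus_relative_position = relpos,
    nucleus_compactness = ng$compactness_val,
    nucleus_mean = nh$mean,
    nucleus_smoothness = nh$smoothness,
    nucleus_energy = nh$energy
  )
}

#' Extract features for a list of retained objects
#'
#' @param img grayscale matrix (unenhanced luminance; see
#'   [extract_features()]).
#' @param objs list of `cell_object`s.
#' @param area_factor calibrated area units per pixel.
#' @return tibble, one row per object, with an `id` column plus the 29
#'   [feature_names].
#' @export
extract_features_all <- function(img, objs, area_factor = 1) {
  if (length(objs) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      as.list(rep(NA_real_, length(feature_names))), feature_names))[0, ]
    return(dplyr::bind_cols(tibble::tibble(id = integer()), out))
  }
  dplyr::bind_rows(lapply(objs, function(o) {
    dplyr::bind_cols(tibble::tibble(id = o$id),
                     extract_features(img, o, area_factor))
  }))
}

#' Write / read a feature table as CSV
#'
#' The header is the fixed 29-column [feature_names] order (plus `id` and
#' `label` when present) and is validated exactly on read.
#' @param tbl feature tibble.
#' @param path CSV path.
#' @export
write_feature_table <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  want <- setdiff(names(tbl), c("id", "label"))
  if (!identical(sort(want), sort(feature_names))) {
    stop("feature table header does not match the 29 canonical feature names",
         call. = FALSE)
  }
  if ("label" %in% names(tbl)) tbl$label <- factor(tbl$label, levels = cell_classes)
  tbl
}
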
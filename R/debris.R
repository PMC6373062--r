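# Three-phase sequential debris elimination: a size gate on calibrated
# area, a shape gate on normalized circularity, and a texture gate on
# averaged Zernike-moment magnitudes. Objects are tested by a later gate
# only if they pass all earlier ones.

#' Debris-rejection configuration
#'
#' Area bounds are in the same calibrated unit system as the training-class
#' statistics (pixel counts times `area_factor`). The circularity band is on
#' normalized circularity `4*pi*A/p^2` (1 for a circle): objects more
#' circular than `compactness_high` or more elongated than
#' `compactness_low` are debris.
#'
#' @param area_min,area_max inclusive area band (defaults 625 and 85267).
#' @param compactness_low,compactness_high circularity band (defaults 0.15,
#'   0.97).
#' @param zernike_order maximum Zernike order `n_max` (default 9).
#' @param zernike_window odd window size in pixels for the texture measure.
#' @param texture_threshold numeric fixed threshold, or `"AUTO"` to flag
#'   outlying scores relative to the batch (median + `auto_gap_min` MADs).
#' @param auto_gap_min robust spreads above the batch median at which an
#'   AUTO score is called outlying.
#' @param area_factor calibrated area units per pixel (default 1).
#' @return a `debris_config` list.
#' @export
debris_config <- function(area_min = 625, area_max = 85267,
                          compactness_low = 0.15, compactness_high = 0.97,
                          zernike_order = 9L, zernike_window = 25L,
                          texture_threshold = "AUTO", auto_gap_min = 3.5,
                          area_factor = 1) {
  stopifnot(area_min > 0, area_min < area_max,
            compactness_low >= 0, compactness_low < compactness_high)
  structure(list(area_min = area_min, area_max = area_max,
                 compactness_low = compactness_low,
                 compactness_high = compactness_high,
                 zernike_order = as.integer(zernike_order),
                 zernike_window = as.integer(zernike_window),
                 texture_threshold = texture_threshold,
                 auto_gap_min = auto_gap_min,
                 area_factor = area_factor),
            class = "debris_config")
}

label_components_8 <- function(mask) {
  # 8-connected components: EBImage::bwlabel is 4-connected; merge labels
  # that touch diagonally with a small union-find pass
  lab <- matrix(as.integer(EBImage::bwlabel(mask * 1)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[1:(nr - 1L), if (off[2] == 1L) 2:nc else 1:(nc - 1L), drop = FALSE]
    b <- lab[2:nr, if (off[2] == 1L) 1:(nc - 1L) else 2:nc, drop = FALSE]
    hit <- which(a > 0L & b > 0L & a != b)
    if (length(hit)) {
      pairs <- unique(cbind(a[hit], b[hit]))
      for (i in seq_len(nrow(pairs))) union(pairs[i, 1], pairs[i, 2])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

contour_perimeter <- function(mask) {
  # polygon length of the outer contour traced through pixel centers
  # (8-connected); diagonal steps count sqrt(2)
  if (sum(mask) == 1L) return(0)
  oc <- EBImage::ocontour(mask * 1)
  if (length(oc) == 0) return(0)
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  if (is.null(pts) || nrow(pts) < 2L) return(0)
  d <- pts - pts[c(2:nrow(pts), 1L), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Normalized circularity from area and perimeter
#'
#' `4*pi*A/p^2`: exactly 1 for a continuous circle, `pi/4` for a square.
#' @param area,perimeter positive reals in consistent units.
#' @return circularity value.
#' @export
circularity <- function(area, perimeter) 4 * pi * area / perimeter^2

#' Extract candidate cell objects from a label map
#'
#' 8-connected components of NUCLEUS-labelled pixels become candidates; the
#' surrounding CYTOPLASM component is attached when it touches the nucleus.
#' Area is pixel count times `area_factor`; perimeter is the outer-contour
#' polygon length times `sqrt(area_factor)`, so both are in the calibrated
#' unit system of the training statistics.
#'
#' @param labels a `label_map`.
#' @param area_factor calibrated area units per pixel.
#' @param candidate_classes scene classes whose components become
#'   candidates (default `"NUCLEUS"`; add `"DEBRIS"` to route ground-truth
#'   debris components through the gates).
#' @param close_radius radius of the morphological closing applied to the
#'   candidate mask before labelling (0 to disable). Pixel classifiers
#'   leave speckle that can split one nucleus into fragments; closing
#'   reconnects them.
#' @return list of `cell_object`s (possibly empty). Nucleus components
#'   attached to the same cytoplasm component are merged into one object
#'   (a cell has one cytoplasm; fragments of its nucleus are not separate
#'   candidates).
#' @export
label_objects <- function(labels, area_factor = 1,
                          candidate_classes = "NUCLEUS",
                          close_radius = 2L) {
  stopifnot(inherits(labels, "label_map"))
  lmat <- labels$labels
  cand_idx <- match(candidate_classes, scene_classes)
  nuc_mask <- matrix(lmat %in% cand_idx, nrow(lmat), ncol(lmat))
  if (!any(nuc_mask)) return(list())
  if (close_radius > 0) {
    br <- EBImage::makeBrush(2L * close_radius + 1L, shape = "disc")
    closed <- EBImage::erode(EBImage::dilate(nuc_mask * 1, br), br)
    nuc_mask <- matrix(as.numeric(closed) > 0.5, nrow(lmat), ncol(lmat))
  }
  comp <- label_components_8(nuc_mask)
  cyto_mask <- lmat == match("CYTOPLASM", scene_classes)
  cyto_comp <- if (any(cyto_mask)) label_components_8(cyto_mask) else NULL
  nr <- nrow(lmat); nc <- ncol(lmat)
  n_comp <- max(comp)
  # cytoplasm components touching each nucleus component (8-neighbourhood)
  touching <- vector("list", n_comp)
  if (!is.null(cyto_comp)) {
    for (i in seq_len(n_comp)) {
      idx <- which(comp == i)
      rows <- ((idx - 1L) %% nr) + 1L
      cols <- ((idx - 1L) %/% nr) + 1L
      rr <- pmin(pmax(rep(rows, 8) + rep(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L), each = length(rows)), 1L), nr)
      cc <- pmin(pmax(rep(cols, 8) + rep(c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L), each = length(cols)), 1L), nc)
      touch <- unique(cyto_comp[cbind(rr, cc)])
      touching[[i]] <- touch[touch > 0L]
    }
    # merge nucleus components sharing any cytoplasm component
    group <- seq_len(n_comp)
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(n_comp)) {
      for (ct in touching[[i]]) {
        key <- as.character(ct)
        if (is.null(seen[[key]])) seen[[key]] <- i
        else {
          g <- group[seen[[key]]]
          group[group == group[i]] <- g
        }
      }
    }
  } else {
    group <- seq_len(n_comp)
  }
  lf <- sqrt(area_factor)
  objs <- list()
  for (g in unique(group)) {
    members <- which(group == g)
    idx <- which(comp %in% members)
    cyto_ids <- unique(unlist(touching[members]))
    cyto_idx <- if (length(cyto_ids)) which(cyto_comp %in% cyto_ids) else integer(0)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    all_idx <- c(idx, cyto_idx)
    obj_mask <- matrix(FALSE, nr, nc)
    obj_mask[all_idx] <- TRUE
    per_px <- contour_perimeter(obj_mask)
    objs[[length(objs) + 1L]] <- structure(list(
      id = length(objs) + 1L, dim = c(nr, nc),
      nucleus_idx = idx, cyto_idx = cyto_idx,
      area = length(all_idx) * area_factor,
      perimeter = per_px * lf,
      centroid = c(mean(rows), mean(cols)),
      compactness = if (per_px > 0) circularity(length(all_idx), per_px) else NA_real_,
      raw_p2a = if (per_px > 0) per_px^2 / length(all_idx) else NA_real_,
      texture_score = NA_real_,
      rejection_stage = "NONE"
    ), class = "cell_object")
  }
  objs
}

object_mask <- function(obj, which = c("all", "nucleus", "cyto")) {
  which <- match.arg(which)
  idx <- switch(which, all = c(obj$nucleus_idx, obj$cyto_idx),
                nucleus = obj$nucleus_idx, cyto = obj$cyto_idx)
  m <- matrix(FALSE, obj$dim[1], obj$dim[2])
  m[idx] <- TRUE
  m
}

#' @method tidy cell_object
#' @export
tidy.cell_object <- function(x, ...) {
  tibble::tibble(id = x$id, area = x$area, perimeter = x$perimeter,
                 row = x$centroid[1], col = x$centroid[2],
                 compactness = x$compactness, raw_p2a = x$raw_p2a,
                 texture_score = x$texture_score,
                 rejection_stage = x$rejection_stage,
                 n_nucleus_px = length(x$nucleus_idx),
                 n_cyto_px = length(x$cyto_idx))
}

objects_tibble <- function(objs) {
  if (length(objs) == 0) {
    return(tibble::tibble(id = integer(), area = numeric(), perimeter = numeric(),
                          row = numeric(), col = numeric(), compactness = numeric(),
                          raw_p2a = numeric(), texture_score = numeric(),
                          rejection_stage = character(), n_nucleus_px = integer(),
                          n_cyto_px = integer()))
  }
  dplyr::bind_rows(lapply(objs, tidy.cell_object))
}

#' Size gate
#'
#' Retains an object iff `area_min <= area <= area_max` (bounds inclusive).
#' @param obj a `cell_object` with calibrated area.
#' @param cfg a [debris_config()].
#' @return the object, with `rejection_stage = "SIZE"` when rejected.
#' @export
size_gate <- function(obj, cfg = debris_config()) {
  if (obj$area < cfg$area_min || obj$area > cfg$area_max) {
    obj$rejection_stage <- "SIZE"
  }
  obj
}

#' Shape compactness of an object
#'
#' Normalized circularity `4*pi*A/p^2` of the object mask; the raw
#' perimeter-squared-over-area descriptor is kept in `obj$raw_p2a`.
#' @param obj a `cell_object`.
#' @return circularity value.
#' @export
compactness <- function(obj) {
  if (is.na(obj$compactness) || obj$perimeter <= 0) {
    stop("degenerate object: perimeter is zero", call. = FALSE)
  }
  obj$compactness
}

#' Shape gate
#'
#' Rejects (stage SHAPE) when circularity exceeds `compactness_high` or
#' falls below `compactness_low`.
#' @inheritParams size_gate
#' @export
shape_gate <- function(obj, cfg = debris_config()) {
  c <- compactness(obj)
  if (c > cfg$compactness_high || c < cfg$compactness_low) {
    obj$rejection_stage <- "SHAPE"
  }
  obj
}
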
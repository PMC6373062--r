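# Trainable pixel-level scene segmentation: nucleus / cytoplasm /
# background / debris, learned from scribble annotations over the filter
# bank and applied per pixel by a seeded random forest.

#' Scene classes recognised by the pixel classifier
#'
#' Declaration order fixes argmax tie-breaking (NUCLEUS first).
#' @export
scene_classes <- c("NUCLEUS", "CYTOPLASM", "BACKGROUND", "DEBRIS")

#' Build a scribble annotation set
#'
#' @param rows,cols integer pixel coordinates (1-based).
#' @param class scene class per pixel (recycled), one of [scene_classes].
#' @return tibble with columns `row`, `col`, `class`.
#' @export
annotations <- function(rows, cols, class) {
  class <- as.character(class)
  if (!all(class %in% scene_classes)) {
    stop("unknown scene class; must be one of ", paste(scene_classes, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(row = as.integer(rows), col = as.integer(cols),
                 class = rep_len(class, length(rows)))
}

stack_to_df <- function(stack, idx = NULL) {
  f <- dim(stack)[3]
  n <- prod(dim(stack)[1:2])
  m <- matrix(stack, n, f)
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  df <- as.data.frame(m)
  names(df) <- attr(stack, "feature_names")
  df
}

#' Train the pixel-level scene classifier
#'
#' Fits a probability random forest on (feature-vector, class) pairs taken
#' at the annotated pixels only. Deterministic for a fixed seed.
#'
#' @param stacks list of feature stacks from [build_pixel_features()] (or a
#'   single stack).
#' @param annotation_sets list of tibbles from [annotations()], parallel to
#'   `stacks`; every pixel coordinate must lie inside its image.
#' @param seed integer RNG seed.
#' @param num_trees forest size (default 200).
#' @param max_per_class cap on annotated pixels used per class; beyond it a
#'   seeded subsample is taken.
#' @return a `pixel_classifier` object.
#' @export
train_pixel_classifier <- function(stacks, annotation_sets, seed = 1L,
                                   num_trees = 200L, max_per_class = 5000L) {
  if (!is.list(stacks) || is.array(stacks)) stacks <- list(stacks)
  if (inherits(annotation_sets, "data.frame")) annotation_sets <- list(annotation_sets)
  stopifnot(length(stacks) == length(annotation_sets))
  parts <- purrr::map2(stacks, annotation_sets, function(st, ann) {
    h <- dim(st)[1]; w <- dim(st)[2]
    if (any(ann$row < 1L | ann$row > h | ann$col < 1L | ann$col > w)) {
      stop("annotation coordinates outside image bounds", call. = FALSE)
    }
    idx <- ann$row + (ann$col - 1L) * h
    df <- stack_to_df(st, idx)
    df$.class <- ann$class
    df
  })
  train <- dplyr::bind_rows(parts)
  missing <- setdiff(scene_classes, unique(train$.class))
  if (length(missing) > 0) {
    stop("no annotated pixels for class(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  train <- withr::with_seed(seed, {
    dplyr::slice_sample(dplyr::group_by(train, .data$.class),
                        n = max_per_class, replace = FALSE) |> dplyr::ungroup()
  })
  y <- factor(train$.class, levels = scene_classes)
  x <- dplyr::select(train, -".class")
  fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                        probability = TRUE, seed = seed, num.threads = 1L)
  structure(list(forest = fit, classes = scene_classes,
                 bank = attr(stacks[[1]], "bank"),
                 feature_names = attr(stacks[[1]], "feature_names"),
                 seed = seed, num_trees = num_trees),
            class = "pixel_classifier")
}

#' Segment a scene into per-pixel class labels and probabilities
#'
#' @param img enhanced grayscale matrix.
#' @param clf a [train_pixel_classifier()] model.
#' @param stack optional precomputed feature stack; must match the
#'   classifier's filter-bank configuration.
#' @param chunk pixels scored per prediction block (memory control).
#' @param smooth_radius optional spatial regularisation: the per-class
#'   probability maps are box-smoothed with this radius before the argmax
#'   (0, the default, disables it; object extraction already repairs label
#'   speckle by morphological closing, and smoothing blurs the nucleus
#'   boundary of small cells).
#' @return a `label_map`: list with `labels` (H x W integer matrix, levels =
#'   [scene_classes]) and `probs` (H x W x 4 array summing to 1 per pixel);
#'   labels are the per-pixel argmax of `probs` (ties to the first class).
#' @export
segment_scene <- function(img, clf, stack = NULL, chunk = 250000L,
                          smooth_radius = 0L) {
  stopifnot(inherits(clf, "pixel_classifier"))
  if (is.null(stack)) {
    stack <- build_pixel_features(img, clf$bank)
  } else if (!identical(attr(stack, "bank"), clf$bank)) {
    stop("feature stack filter-bank configuration does not match the classifier",
         call. = FALSE)
  }
  h <- dim(stack)[1]; w <- dim(stack)[2]
  df <- stack_to_df(stack)
  n <- nrow(df)
  probs <- matrix(NA_real_, n, length(clf$classes))
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, n)
    pr <- predict(clf$forest, df[s:e, , drop = FALSE], num.threads = 1L)$predictions
    probs[s:e, ] <- pr[, clf$classes, drop = FALSE]
  }
  if (smooth_radius > 0 && h > 2L * smooth_radius + 1L && w > 2L * smooth_radius + 1L) {
    k <- box_kernel(smooth_radius)
    for (j in seq_len(ncol(probs))) {
      probs[, j] <- as.vector(conv2(matrix(probs[, j], h, w), k))
    }
    probs <- pmin(pmax(probs, 0), 1)
  }
  probs <- probs / rowSums(probs)
  lab <- max.col(probs, ties.method = "first")
  structure(list(labels = matrix(lab, h, w),
                 probs = array(probs, c(h, w, length(clf$classes))),
                 classes = clf$classes),
            class = "label_map")
}

#' Build a label map directly from an integer matrix
#'
#' Used for ground-truth maps; probabilities are one-hot.
#' @param labels H x W integer matrix with values in `1:4` indexing
#'   [scene_classes].
#' @return a `label_map`.
#' @export
label_map <- function(labels) {
  stopifnot(is.matrix(labels), all(labels %in% seq_along(scene_classes)))
  probs <- array(0, c(nrow(labels), ncol(labels), length(scene_classes)))
  for (k in seq_along(scene_classes)) probs[, , k] <- (labels == k) * 1
  structure(list(labels = labels, probs = probs, classes = scene_classes),
            class = "label_map")
}

#' @method tidy label_map
#' @export
tidy.label_map <- function(x, ...) {
  tibble::tibble(
    row = rep(seq_len(nrow(x$labels)), times = ncol(x$labels)),
    col = rep(seq_len(ncol(x$labels)), each = nrow(x$labels)),
    class = scene_classes[as.vector(x$labels)]
  )
}

#' Zijdenbos similarity index between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 for identical non-empty masks, 0 for
#' disjoint masks. Undefined (error) when both masks are empty.
#'
#' @param mask_a,mask_b logical matrices of identical shape.
#' @return similarity in `[0, 1]`.
#' @export
zsi <- function(mask_a, mask_b) {
  stopifnot(identical(dim(mask_a), dim(mask_b)))
  a <- sum(mask_a); b <- sum(mask_b)
  if (a + b == 0) stop("ZSI undefined: both masks are empty", call. = FALSE)
  2 * sum(mask_a & mask_b) / (a + b)
}
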
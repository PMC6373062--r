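# Self-contained synthetic benchmark: renders training and test slides,
# trains the pixel classifier from ground-truth scribbles, runs the full
# screening pipeline on the test slide and scores it against the manifest.

#' Run the full pipeline on rendered scenes and score against ground truth
#'
#' Renders one (or more) training scene and a test scene from the class
#' statistics, trains the pixel-level segmenter on seeded ground-truth
#' scribbles, trains the fuzzy C-means classifier on features extracted
#' from the training scenes, then segments, debris-rejects, extracts and
#' classifies the test scene. Every stochastic step derives its seed from
#' `seed`, so the whole benchmark is reproducible.
#'
#' @param seed master seed.
#' @param train_cells_per_class,test_cells_per_class cells per class in the
#'   rendered scenes (scalar or named vector).
#' @param n_train_scenes training scenes rendered (default 2).
#' @param features classifier feature subset (default: the seven
#'   class-statistics features, the discriminative core of the table).
#' @param c,q fuzzy C-means parameters.
#' @param restarts FCM restarts.
#' @param scribbles_per_class annotated pixels per scene class.
#' @param debris_counts named list with `n_speck`, `n_fiber`, `n_blob` for
#'   the test scene.
#' @return list: `binary_accuracy` (manifest binary label recovered, all
#'   rendered cells in the denominator), `class_accuracy` (7-class, matched
#'   cells), `segmentation_accuracy` (test-scene pixel accuracy vs ground
#'   truth), `n_cells`, `n_matched`, per-stage debris `report`, and the
#'   per-cell `cells` tibble.
#' @export
synthetic_benchmark <- function(seed = 1L,
                                train_cells_per_class = 15L,
                                test_cells_per_class = 20L,
                                n_train_scenes = 2L,
                                features = stats_features,
                                c = 25L, q = 1.0930, restarts = 3L,
                                scribbles_per_class = 400L,
                                debris_counts = list(n_speck = 3L,
                                                     n_fiber = 2L,
                                                     n_blob = 2L)) {
  train_scenes <- lapply(seq_len(n_train_scenes), function(i) {
    render_scene(scene_recipe(cells_per_class = train_cells_per_class,
                              n_speck = 3L, n_fiber = 1L, n_blob = 1L,
                              seed = seed * 1000L + i))
  })
  test_sc <- render_scene(scene_recipe(
    cells_per_class = test_cells_per_class,
    n_speck = debris_counts$n_speck, n_fiber = debris_counts$n_fiber,
    n_blob = debris_counts$n_blob, seed = seed * 1000L + 500L))
  af <- test_sc$area_factor
  cfg <- debris_config(area_factor = af)

  # pixel classifier from seeded ground-truth scribbles of the first scene
  sc1 <- train_scenes[[1]]
  enh1 <- enhance(sc1$gray)
  stack1 <- build_pixel_features(enh1)
  gt <- sc1$truth$labels
  ann <- withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_along(scene_classes), function(k) {
      idx <- which(gt == k)
      if (length(idx) == 0) return(NULL)
      idx <- sample(idx, min(scribbles_per_class, length(idx)))
      annotations(((idx - 1L) %% nrow(gt)) + 1L,
                  ((idx - 1L) %/% nrow(gt)) + 1L, scene_classes[k])
    }))
  })
  pclf <- train_pixel_classifier(stack1, ann, seed = seed)

  run_scene <- function(sc, stack = NULL) {
    enh <- enhance(sc$gray)
    lm <- segment_scene(enh, pclf, stack = stack)
    dr <- reject_debris(enh, lm, cfg)
    ft <- extract_features_all(sc$gray, dr$retained, af)
    mi <- match_manifest(dr$retained, sc$manifest)
    list(ft = ft, mi = mi, lm = lm, dr = dr)
  }

  train_parts <- vector("list", n_train_scenes)
  train_parts[[1]] <- run_scene(sc1, stack1)
  rm(stack1)
  if (n_train_scenes > 1) {
    for (i in 2:n_train_scenes) train_parts[[i]] <- run_scene(train_scenes[[i]])
  }
  train_tbl <- dplyr::bind_rows(lapply(seq_len(n_train_scenes), function(i) {
    p <- train_parts[[i]]
    man <- train_scenes[[i]]$manifest
    tbl <- p$ft
    tbl$label <- factor(man$kind[match(p$mi, man$id)], levels = cell_classes)
    tbl[!is.na(p$mi), , drop = FALSE]
  }))
  cclf <- fit_cell_classifier(train_tbl, features = features, c = c, q = q,
                              seed = seed, restarts = restarts)

  te <- run_scene(test_sc)
  pred <- predict(cclf, te$ft)
  man <- test_sc$manifest
  n_cells <- sum(man$is_cell)
  ok <- !is.na(te$mi) & !is.na(pred$class)
  truth_bin <- man$binary[match(te$mi, man$id)]
  truth_cls <- man$kind[match(te$mi, man$id)]
  binary_accuracy <- sum(as.character(pred$binary)[ok] == truth_bin[ok]) / n_cells
  class_accuracy <- mean(as.character(pred$class)[ok] == truth_cls[ok])
  list(
    binary_accuracy = binary_accuracy,
    class_accuracy = class_accuracy,
    segmentation_accuracy = mean(te$lm$labels == test_sc$truth$labels),
    n_cells = n_cells,
    n_matched = sum(ok),
    report = te$dr$report,
    cells = dplyr::bind_cols(
      tibble::tibble(manifest_id = te$mi, truth_binary = truth_bin,
                     truth_class = truth_cls),
      pred),
    pixel_classifier = pclf,
    cell_classifier = cclf
  )
}

#' The seven class-statistics features
#'
#' The features tabulated per class in [class_stats()] — the
#' discriminative core used as the default classifier subset for synthetic
#' benchmarks.
#' @export
stats_features <- c("nucleus_area", "cyto_area", "nc_ratio",
                    "nucleus_gray_level", "cyto_gray_level",
                    "nucleus_perimeter", "cyto_perimeter")
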
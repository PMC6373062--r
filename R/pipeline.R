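# End-to-end orchestration: enhance -> segment -> debris-reject ->
# extract -> classify -> screen, with one config object covering every
# stage and a YAML round-trip for reproducible runs.

#' Pipeline configuration
#'
#' Collects the per-stage settings; every stochastic stage carries a seed.
#'
#' @param pixel_size_um physical pixel size of the input images.
#' @param clip_limit,tile_grid enhancement settings (see [enhance()]).
#' @param bank a [filter_bank()].
#' @param debris a [debris_config()].
#' @param features classifier feature subset (default [reference_subset]).
#' @param c,q FCM parameters.
#' @param restarts FCM restarts.
#' @param min_abnormal slide-positivity threshold (see [screen_slide()]).
#' @param seed master seed.
#' @export
pipeline_config <- function(pixel_size_um = 0.201, clip_limit = 2,
                            tile_grid = c(8, 8), bank = filter_bank(),
                            debris = debris_config(),
                            features = reference_subset, c = 25L,
                            q = 1.0930, restarts = 1L, min_abnormal = 1L,
                            seed = 1L) {
  structure(list(pixel_size_um = pixel_size_um, clip_limit = clip_limit,
                 tile_grid = tile_grid, bank = bank, debris = debris,
                 features = features, c = as.integer(c), q = q,
                 restarts = as.integer(restarts),
                 min_abnormal = as.integer(min_abnormal),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(x) if (is.list(x)) unclass(x) else x),
                   path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in intersect(names(raw), names(cfg))) {
    cur <- cfg[[nm]]
    cfg[[nm]] <- if (inherits(cur, "filter_bank")) do.call(filter_bank, raw[[nm]])
    else if (inherits(cur, "debris_config")) do.call(debris_config, raw[[nm]])
    else raw[[nm]]
  }
  cfg
}

#' Screen one or more slide images
#'
#' Runs the full pipeline on each image with trained segmentation and cell
#' classifiers: enhancement, pixel-level segmentation, three-phase debris
#' rejection, feature extraction, fuzzy C-means classification and the
#' slide-level diagnosis. Deterministic given the models, inputs and seeds.
#'
#' @param images list of RGB arrays/gray matrices, or file paths.
#' @param seg a [train_pixel_classifier()] model.
#' @param clf a [fit_cell_classifier()] model.
#' @param cfg a [pipeline_config()].
#' @return list with `slides` (one diagnosis row per image), `cells`
#'   (per-cell features, posteriors and classes) and `log` (per-stage
#'   object counts per image).
#' @export
run_screen <- function(images, seg, clf, cfg = pipeline_config()) {
  if (is.null(seg) || !inherits(seg, "pixel_classifier")) {
    stop("missing or invalid segmentation model; train one with train_pixel_classifier()",
         call. = FALSE)
  }
  if (is.null(clf) || !inherits(clf, "cell_classifier")) {
    stop("missing or invalid cell classifier; train one with fit_cell_classifier()",
         call. = FALSE)
  }
  if (!is.list(images)) images <- list(images)
  slides <- list(); cells <- list(); logs <- list()
  for (i in seq_along(images)) {
    im <- images[[i]]
    if (is.character(im)) im <- read_image(im, cfg$pixel_size_um)
    gray <- if (is.matrix(im)) im else rgb_to_gray(im)
    enh <- enhance(gray, cfg$clip_limit, cfg$tile_grid)
    labels <- segment_scene(enh, seg)
    dr <- reject_debris(enh, labels, cfg$debris)
    feats <- extract_features_all(gray, dr$retained, cfg$debris$area_factor)
    if (nrow(feats) > 0) {
      pred <- predict(clf, feats)
      cell_tbl <- dplyr::bind_cols(tibble::tibble(slide = i), feats, pred)
    } else {
      pred <- tibble::tibble(binary = factor(character(), levels = c("NORMAL", "ABNORMAL")))
      cell_tbl <- tibble::tibble(slide = integer())
    }
    slides[[i]] <- dplyr::bind_cols(tibble::tibble(slide = i),
                                    screen_slide(pred, cfg$min_abnormal))
    cells[[i]] <- cell_tbl
    logs[[i]] <- tibble::tibble(
      slide = i, stage = c("candidates", "size_rejected", "shape_rejected",
                           "texture_rejected", "retained"),
      count = c(nrow(dr$objects), dr$report$rejected[1], dr$report$rejected[2],
                dr$report$rejected[3], length(dr$retained)))
  }
  list(slides = dplyr::bind_rows(slides), cells = dplyr::bind_rows(cells),
       log = dplyr::bind_rows(logs))
}
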
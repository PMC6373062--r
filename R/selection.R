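# Wrapper feature selection: subsets are scored by the stratified k-fold
# cross-validated misclassification rate of the fuzzy C-means classifier,
# and searched by simulated annealing with geometric cooling.

#' Reference default feature subset
#'
#' The 18 predominantly nucleus-constrained features used as the shipped
#' default classifier subset (selection on new data is data- and
#' seed-dependent).
#' @export
reference_subset <- c(
  "nucleus_area", "nucleus_gray_level", "nucleus_shortest_diameter",
  "nucleus_longest_diameter", "nucleus_perimeter", "nucleus_maxima",
  "nucleus_minima", "cyto_area", "cyto_gray_level", "cyto_perimeter",
  "nc_ratio", "nucleus_eccentricity", "nucleus_sd", "nucleus_variance",
  "nucleus_entropy", "nucleus_relative_position", "nucleus_mean",
  "nucleus_energy"
)

stratified_folds <- function(labels, k) {
  labels <- as.factor(labels)
  if (any(table(labels) < k)) {
    stop("every class needs at least k members for stratified folds", call. = FALSE)
  }
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated wrapper fitness of a feature subset
#'
#' Stratified k-fold: per fold the fuzzy C-means classifier is fitted on
#' the training split restricted to the subset and evaluated on the held
#' out split; the mean misclassification fraction over folds is returned.
#' Deterministic for fixed `seed`, so the fitness is a pure function of the
#' subset.
#'
#' @param table labelled feature tibble.
#' @param features character vector (or logical bitmask over
#'   [feature_names]) selecting the subset.
#' @param k folds (default 10).
#' @param c clusters for the wrapped classifier.
#' @param q fuzzifier.
#' @param seed integer seed (folds and classifier initialisation).
#' @param restarts FCM restarts inside the wrapper.
#' @return mean misclassification rate in `[0, 1]`.
#' @export
wrapper_fitness <- function(table, features, k = 10L, c = 25L, q = 1.0930,
                            seed = 1L, restarts = 1L) {
  if (is.logical(features)) features <- feature_names[features]
  if (length(features) == 0) stop("empty feature subset", call. = FALSE)
  stopifnot("label" %in% names(table))
  tbl <- tidyr::drop_na(table, dplyr::all_of(features))
  fold <- withr::with_seed(seed, stratified_folds(tbl$label, k))
  errs <- vapply(seq_len(k), function(f) {
    train <- tbl[fold != f, , drop = FALSE]
    test <- tbl[fold == f, , drop = FALSE]
    clf <- fit_cell_classifier(train, features = features, c = c, q = q,
                               seed = seed, restarts = restarts)
    pred <- predict(clf, test)
    mean(as.character(pred$class) != as.character(test$label))
  }, numeric(1))
  mean(errs)
}

#' Simulated-annealing configuration
#'
#' @param t_initial starting temperature.
#' @param alpha geometric cooling factor in (0, 1).
#' @param moves_per_temp proposals per temperature block.
#' @param t_min stopping temperature.
#' @param k cross-validation folds for the wrapper.
#' @param c,q wrapped-classifier parameters.
#' @param restarts FCM restarts inside the wrapper.
#' @param reruns independent SA reruns for the optional stability report.
#' @param seed integer seed.
#' @export
sa_config <- function(t_initial = 1, alpha = 0.95, moves_per_temp = 20L,
                      t_min = 1e-3, k = 10L, c = 25L, q = 1.0930,
                      restarts = 1L, reruns = 60L, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, k >= 2)
  structure(list(t_initial = t_initial, alpha = alpha,
                 moves_per_temp = as.integer(moves_per_temp), t_min = t_min,
                 k = as.integer(k), c = as.integer(c), q = q,
                 restarts = as.integer(restarts), reruns = as.integer(reruns),
                 seed = as.integer(seed)),
            class = "sa_config")
}

#' Select a feature subset by simulated annealing
#'
#' Single-bit neighbour moves (redrawn if a move would empty the subset);
#' a move is accepted when its error does not increase, otherwise with
#' probability `exp(-delta/T)`; temperature cools geometrically per block.
#' Fitness values are memoised, so revisited subsets cost nothing. Returns
#' the best state ever visited and the full trace.
#'
#' @param table labelled feature tibble.
#' @param cfg an [sa_config()].
#' @param features candidate feature pool (default all 29).
#' @return list with `subset` (names), `error`, and `trace` tibble
#'   (iteration, temperature, error, accepted, best_error, n_features).
#' @export
sa_select <- function(table, cfg = sa_config(), features = feature_names) {
  stopifnot(nlevels(droplevels(as.factor(table$label))) >= 2)
  p <- length(features)
  cache <- new.env(parent = emptyenv())
  fit_of <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- wrapper_fitness(table, features[mask], k = cfg$k, c = cfg$c,
                         q = cfg$q, seed = cfg$seed, restarts = cfg$restarts)
    cache[[key]] <- v
    v
  }
  withr::with_seed(cfg$seed + 1L, {
    state <- rep(TRUE, p)
    err <- fit_of(state)
    best_state <- state; best_err <- err
    temp <- cfg$t_initial
    rows <- list()
    it <- 0L
    while (temp >= cfg$t_min) {
      for (m in seq_len(cfg$moves_per_temp)) {
        it <- it + 1L
        repeat {
          flip <- sample.int(p, 1L)
          cand <- state
          cand[flip] <- !cand[flip]
          if (any(cand)) break
        }
        cand_err <- fit_of(cand)
        delta <- cand_err - err
        accept <- delta <= 0 || stats::runif(1) < exp(-delta / temp)
        if (accept) {
          state <- cand; err <- cand_err
          if (err < best_err) { best_err <- err; best_state <- state }
        }
        rows[[it]] <- tibble::tibble(iteration = it, temperature = temp,
                                     error = cand_err, accepted = accept,
                                     best_error = best_err,
                                     n_features = sum(if (accept) state else state))
      }
      temp <- temp * cfg$alpha
    }
    list(subset = features[best_state], error = best_err,
         trace = dplyr::bind_rows(rows))
  })
}

#' Per-feature selection frequency across SA reruns
#'
#' Stability report: runs [sa_select()] `reruns` times with derived seeds
#' and reports how often each feature appears in the selected subset.
#'
#' @param table labelled feature tibble.
#' @param cfg an [sa_config()]; `cfg$reruns` controls the number of runs.
#' @param features candidate pool.
#' @return tibble (`feature`, `frequency`).
#' @export
sa_stability <- function(table, cfg = sa_config(), features = feature_names) {
  picks <- lapply(seq_len(cfg$reruns), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    sa_select(table, cfg_r, features)$subset
  })
  tibble::tibble(
    feature = features,
    frequency = vapply(features, function(f)
      mean(vapply(picks, function(s) f %in% s, logical(1))), numeric(1))
  )
}
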
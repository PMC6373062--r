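# Fuzzy C-means clustering with Bayesian defuzzification. Memberships
# follow m_ik = 1 / sum_j (d_ik/d_jk)^(2/(q-1)); the crisp class decision
# comes from a cluster-to-class probabilistic model: P(class|cluster) is the
# normalized Bayes posterior of smoothed cluster-conditional likelihoods
# and mass-proportional class priors, and a point's class posterior is its
# membership-weighted mixture of cluster posteriors.

fcm_memberships <- function(D, q) {
  # D: c x n distances; stable evaluation through logs since the exponent
  # 2/(q-1) is large for q near 1
  e <- -2 / (q - 1)
  U <- matrix(0, nrow(D), ncol(D))
  zero <- D < 1e-12
  any_zero <- colSums(zero) > 0
  if (any(any_zero)) {
    for (k in which(any_zero)) {
      z <- which(zero[, k])
      U[z[1], k] <- 1  # coincident with a center: full membership (first on ties)
    }
  }
  ok <- which(!any_zero)
  if (length(ok)) {
    L <- e * log(D[, ok, drop = FALSE])
    L <- sweep(L, 2, apply(L, 2, max))
    W <- exp(L)
    U[, ok] <- sweep(W, 2, colSums(W), "/")
  }
  U
}

dist_to_centers <- function(X, centers) {
  # c x n Euclidean distances
  cn <- rowSums(centers^2)
  xn <- rowSums(X^2)
  d2 <- outer(cn, xn, "+") - 2 * centers %*% t(X)
  sqrt(pmax(d2, 0))
}

farthest_point_init <- function(X, c) {
  n <- nrow(X)
  centers <- matrix(NA_real_, c, ncol(X))
  i <- sample.int(n, 1L)
  centers[1, ] <- X[i, ]
  d <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in 2:c) {
    p <- d / sum(d)
    if (!all(is.finite(p)) || sum(d) <= 0) p <- rep(1 / n, n)
    i <- sample.int(n, 1L, prob = p)
    centers[j, ] <- X[i, ]
    d <- pmin(d, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

#' Fit a fuzzy C-means model
#'
#' Alternates membership updates and membership^q-weighted center updates
#' until the maximum center shift falls below `tol`. Centers are seeded by
#' farthest-point (k-means++-style) sampling; with `restarts > 1` the run
#' with the lowest final objective is kept. Deterministic under `seed`.
#'
#' @param X numeric matrix (points x features), already standardized.
#' @param c number of clusters (default 25).
#' @param q fuzzifier > 1 (default 1.0930).
#' @param tol convergence tolerance on the center shift.
#' @param max_iter iteration cap.
#' @param seed integer seed.
#' @param restarts independent seeded restarts.
#' @return an `fcm_model`: centers, memberships `u` (clusters x points),
#'   objective trace, and fit metadata.
#' @export
fcm_fit <- function(X, c = 25L, q = 1.0930, tol = 1e-5, max_iter = 300L,
                    seed = 1L, restarts = 1L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in input", call. = FALSE)
  if (c < 2L) stop("`c` must be at least 2", call. = FALSE)
  if (q <= 1) stop("`q` must exceed 1", call. = FALSE)
  if (nrow(X) <= c) stop("need more points than clusters", call. = FALSE)
  run_one <- function(rs) {
    centers <- farthest_point_init(X, c)
    obj <- numeric(0)
    for (it in seq_len(max_iter)) {
      D <- dist_to_centers(X, centers)
      U <- fcm_memberships(D, q)
      Uq <- U^q
      new_centers <- (Uq %*% X) / rowSums(Uq)
      empty <- !is.finite(rowSums(new_centers))
      new_centers[empty, ] <- centers[empty, ]
      obj <- c(obj, sum(Uq * D^2))
      shift <- max(abs(new_centers - centers))
      centers <- new_centers
      if (shift < tol) break
    }
    D <- dist_to_centers(X, centers)
    U <- fcm_memberships(D, q)
    list(centers = centers, u = U, objective = sum(U^q * D^2),
         objective_trace = obj, iterations = length(obj))
  }
  fits <- withr::with_seed(seed, lapply(seq_len(restarts), run_one))
  best <- fits[[which.min(vapply(fits, function(f) f$objective, numeric(1)))]]
  structure(c(best, list(q = q, c = c, tol = tol, seed = seed,
                         restarts = restarts, dim = ncol(X))),
            class = "fcm_model")
}

#' Membership vector of a point (or rows of a matrix) in a fitted model
#'
#' @param x numeric vector (or points x features matrix) in the model's
#'   standardized feature space.
#' @param model an [fcm_fit()] model.
#' @return memberships: vector of length `c` (or clusters x points matrix),
#'   each column summing to 1.
#' @export
membership <- function(x, model) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$dim) stop("feature dimension mismatch", call. = FALSE)
  U <- fcm_memberships(dist_to_centers(x, model$centers), model$q)
  if (ncol(U) == 1L) drop(U) else U
}

#' @method glance fcm_model
#' @export
glance.fcm_model <- function(x, ...) {
  tibble::tibble(clusters = x$c, fuzzifier = x$q, objective = x$objective,
                 iterations = x$iterations, restarts = x$restarts)
}

#' @method tidy fcm_model
#' @export
tidy.fcm_model <- function(x, ...) {
  ctr <- tibble::as_tibble(x$centers, .name_repair = "minimal")
  names(ctr) <- paste0("dim", seq_len(ncol(ctr)))
  dplyr::bind_cols(tibble::tibble(cluster = seq_len(nrow(ctr))), ctr)
}

#' Fit the Bayesian cluster-to-class defuzzification model
#'
#' Each training point is hard-assigned to its maximum-membership cluster;
#' the cluster-conditional likelihoods are Laplace-smoothed class-wise
#' cluster occupancy fractions, priors are proportional to class mass, and
#' the posterior P(class | cluster) is the normalized Bayes product.
#'
#' @param model an [fcm_fit()] model.
#' @param labels factor of training labels aligned with the fitted points.
#' @param alpha Laplace smoothing constant (default 1).
#' @return a `defuzz_model` with `likelihood` (classes x clusters),
#'   `priors`, and `posterior` (classes x clusters, columns sum to 1).
#' @export
defuzz_fit <- function(model, labels, alpha = 1) {
  labels <- as.factor(labels)
  n <- ncol(model$u)
  if (length(labels) != n) stop("labels must align with the fitted points", call. = FALSE)
  if (any(table(labels) == 0)) stop("a class has zero training points", call. = FALSE)
  assign <- apply(model$u, 2, which.max)
  counts <- matrix(0, nlevels(labels), model$c,
                   dimnames = list(levels(labels), NULL))
  for (k in seq_len(n)) counts[labels[k], assign[k]] <- counts[labels[k], assign[k]] + 1
  class_tot <- rowSums(counts)
  lik <- (counts + alpha) / (class_tot + alpha * model$c)
  priors <- class_tot / sum(class_tot)
  post <- lik * priors
  colsum <- colSums(post)
  colsum[colsum == 0] <- 1
  post <- sweep(post, 2, colsum, "/")
  structure(list(likelihood = lik, priors = priors, posterior = post,
                 classes = levels(labels), alpha = alpha),
            class = "defuzz_model")
}

#' Predict cell classes from memberships and the defuzzification model
#'
#' A point's class posterior is the membership-weighted mixture of the
#' per-cluster class posteriors, normalized; the class is its argmax (ties
#' broken by class declaration order) and the binary diagnosis follows
#' [binary_label()] when the classes are the seven cell classes.
#'
#' @param X points x features matrix in the model's standardized space.
#' @param model an [fcm_fit()] model.
#' @param defuzz a [defuzz_fit()] model.
#' @return tibble with `class`, one posterior column per class
#'   (`post_<class>`), and `binary` when applicable.
#' @export
fcm_predict <- function(X, model, defuzz) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  U <- membership(X, model)
  if (is.vector(U)) U <- matrix(U, ncol = 1)
  P <- defuzz$posterior %*% U  # classes x points
  P <- sweep(P, 2, colSums(P), "/")
  cls <- defuzz$classes[apply(P, 2, which.max)]
  out <- tibble::tibble(class = factor(cls, levels = defuzz$classes))
  post <- tibble::as_tibble(t(P), .name_repair = "minimal")
  names(post) <- paste0("post_", defuzz$classes)
  out <- dplyr::bind_cols(out, post)
  if (all(defuzz$classes %in% cell_classes)) {
    out$binary <- binary_label(as.character(out$class))
    abn <- defuzz$classes %in% cell_classes[4:7]
    out$abnormal_posterior <- colSums(P[abn, , drop = FALSE])
  }
  out
}

#' Train a complete cell classifier on a labelled feature table
#'
#' Standardizes the selected features (z-scores with training statistics;
#' constant features get unit scale), fits fuzzy C-means and the Bayesian
#' defuzzification, and returns a predictor for new feature tables. Rows
#' with missing values in the selected features are dropped from training.
#'
#' @param table feature tibble with a `label` column.
#' @param features character vector of feature columns (default: all 29).
#' @param c,q,tol,max_iter,seed,restarts passed to [fcm_fit()].
#' @param alpha defuzzification smoothing.
#' @return a `cell_classifier`.
#' @export
fit_cell_classifier <- function(table, features = feature_names, c = 25L,
                                q = 1.0930, tol = 1e-5, max_iter = 300L,
                                seed = 1L, restarts = 1L, alpha = 1) {
  if (length(features) == 0) stop("empty feature subset", call. = FALSE)
  stopifnot("label" %in% names(table))
  tbl <- tidyr::drop_na(table, dplyr::all_of(features))
  tbl$label <- droplevels(as.factor(tbl$label))
  X <- as.matrix(tbl[, features, drop = FALSE])
  mu <- colMeans(X)
  sigma <- apply(X, 2, stats::sd)
  sigma[!is.finite(sigma) | sigma == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sigma, "/")
  model <- fcm_fit(Z, c = c, q = q, tol = tol, max_iter = max_iter,
                   seed = seed, restarts = restarts)
  defuzz <- defuzz_fit(model, tbl$label, alpha = alpha)
  structure(list(model = model, defuzz = defuzz, features = features,
                 center = mu, scale = sigma),
            class = "cell_classifier")
}

#' @export
predict.cell_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  ok <- stats::complete.cases(X)
  Z <- sweep(sweep(X[ok, , drop = FALSE], 2, object$center), 2, object$scale, "/")
  pred <- fcm_predict(Z, object$model, object$defuzz)
  if (all(ok)) return(pred)
  # rows with missing selected features get NA predictions
  out <- pred[rep(NA_integer_, nrow(X)), ]
  out[ok, ] <- pred
  out
}

#' @method glance cell_classifier
#' @export
glance.cell_classifier <- function(x, ...) {
  dplyr::bind_cols(glance.fcm_model(x$model),
                   tibble::tibble(n_features = length(x$features),
                                  n_classes = length(x$defuzz$classes)))
}

#' Cluster-count selection by cross-validated wrapper error
#'
#' @param table labelled feature tibble.
#' @param candidates integer cluster counts to try.
#' @param features feature subset used by the wrapper.
#' @param k folds.
#' @param seed integer seed.
#' @param ... passed to [wrapper_fitness()].
#' @return a `cluster_count_report` tibble (`clusters`, `cv_error`) with the
#'   chosen count (smallest argmin) in attribute `chosen`.
#' @export
choose_cluster_count <- function(table, candidates, features = feature_names,
                                 k = 10L, seed = 1L, ...) {
  errs <- vapply(candidates, function(cc) {
    wrapper_fitness(table, features, k = k, c = cc, seed = seed, ...)
  }, numeric(1))
  rep <- tibble::tibble(clusters = as.integer(candidates), cv_error = errs)
  attr(rep, "chosen") <- rep$clusters[which.min(rep$cv_error)]
  class(rep) <- c("cluster_count_report", class(rep))
  rep
}

#' Slide-level diagnosis from per-cell predictions
#'
#' @param cells tibble with a `binary` column (from the classifier).
#' @param min_abnormal abnormal-cell count at or above which the slide is
#'   called POSITIVE (default 1).
#' @return one-row tibble with per-class counts and the `diagnosis`.
#' @export
screen_slide <- function(cells, min_abnormal = 1L) {
  n_abn <- sum(cells$binary == "ABNORMAL", na.rm = TRUE)
  out <- tibble::tibble(n_cells = nrow(cells), n_abnormal = n_abn,
                        diagnosis = if (n_abn >= min_abnormal) "POSITIVE" else "NEGATIVE")
  if ("class" %in% names(cells)) {
    counts <- tibble::as_tibble(as.list(table(factor(cells$class, levels = cell_classes))))
    out <- dplyr::bind_cols(out, counts)
  }
  out
}
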
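## AdaBoost.M1 over shallow decision trees, mapping a feature vector to
## AFib / non-AFib. The boosting loop, the weak learner, prediction,
## feature importance, and a portable JSON serialization are all authored
## here: determinism is part of the contract (split search scans features
## in schema order, thresholds at sorted midpoints, ties broken by the
## first strictly better candidate), so a seed plus inputs fixes the model
## byte for byte.

POSITIVE_CLASS <- "AFIB"
NEGATIVE_CLASS <- "NON_AFIB"
MODEL_FORMAT_VERSION <- "afib-adaboost/1"
MAX_VOTE_WEIGHT <- log(1e6)

## Weighted Gini impurity of a (w1, w0) split pair, summed over children.
## y is 0/1 (1 = positive class), w nonnegative weights.

## Find the best single split of rows `idx` over columns of X.
## Returns NULL when no split improves impurity (e.g. pure node or all
## feature values tied). `ord` is the list of full-length sort orders per
## feature, computed once per training set.
best_split <- function(X, y, w, idx, ord) {
  n_all <- nrow(X)
  member <- logical(n_all)
  member[idx] <- TRUE
  wtot <- sum(w[idx])
  w1tot <- sum(w[idx] * y[idx])
  p <- w1tot / wtot
  parent_gini <- wtot * 2 * p * (1 - p)
  if (parent_gini <= 0) return(NULL)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    oj <- ord[[j]][member[ord[[j]]]]
    xs <- X[oj, j]
    m <- length(xs)
    if (xs[1] == xs[m]) next
    ws <- w[oj]
    cw <- cumsum(ws)
    cw1 <- cumsum(ws * y[oj])
    cut_ok <- which(xs[-m] < xs[-1])        # only between distinct values
    wL <- cw[cut_ok]; w1L <- cw1[cut_ok]
    wR <- wtot - wL;  w1R <- w1tot - w1L
    pL <- ifelse(wL > 0, w1L / wL, 0)
    pR <- ifelse(wR > 0, w1R / wR, 0)
    child <- wL * 2 * pL * (1 - pL) + wR * 2 * pR * (1 - pR)
    k <- which.min(child)                   # first minimum: deterministic
    ## zero-gain splits on an impure node are accepted (a deeper split may
    ## still separate, e.g. XOR-like interactions); ties keep first-found
    if (is.null(best) || child[k] < best$child_gini - 1e-15) {
      cut <- cut_ok[k]
      best <- list(feature = j,
                   threshold = (xs[cut] + xs[cut + 1L]) / 2,
                   child_gini = child[k],
                   decrease = parent_gini - child[k])
    }
  }
  best
}

leaf_class <- function(y, w, idx) {
  w1 <- sum(w[idx] * y[idx])
  w0 <- sum(w[idx]) - w1
  ## exact tie -> negative class (a screening tool prefers specificity)
  if (w1 > w0) POSITIVE_CLASS else NEGATIVE_CLASS
}

grow_tree <- function(X, y, w, idx, depth, max_depth, ord, splits_log) {
  sp <- if (depth < max_depth) best_split(X, y, w, idx, ord) else NULL
  if (is.null(sp)) {
    return(list(node = list(leaf = leaf_class(y, w, idx)),
                splits = splits_log))
  }
  splits_log[[length(splits_log) + 1L]] <-
    c(feature = sp$feature, decrease = sp$decrease)
  go_left <- X[idx, sp$feature] <= sp$threshold
  left <- grow_tree(X, y, w, idx[go_left], depth + 1L, max_depth, ord,
                    splits_log)
  right <- grow_tree(X, y, w, idx[!go_left], depth + 1L, max_depth, ord,
                     left$splits)
  list(node = list(feature = colnames(X)[sp$feature],
                   threshold = sp$threshold,
                   left = left$node, right = right$node),
       splits = right$splits)
}

predict_tree <- function(node, X) {
  if (!is.null(node$leaf)) return(rep(node$leaf, nrow(X)))
  out <- character(nrow(X))
  go_left <- X[, node$feature] <= node$threshold
  if (any(go_left)) out[go_left] <-
      predict_tree(node$left, X[go_left, , drop = FALSE])
  if (any(!go_left)) out[!go_left] <-
      predict_tree(node$right, X[!go_left, , drop = FALSE])
  out
}

tree_depth <- function(node) {
  if (!is.null(node$leaf)) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

#' Fit one weak learner (depth-limited decision tree)
#'
#' Weighted CART-style tree with Gini impurity, exhaustive midpoint
#' threshold search, features scanned in schema order and ties broken by
#' the first strictly better split — fully deterministic. Exposed mainly
#' so independent boosting implementations can share the identical weak
#' learner in cross-checks.
#'
#' @param X Numeric feature matrix (rows = measurements).
#' @param y Character labels (`"AFIB"` / `"NON_AFIB"`).
#' @param w Nonnegative case weights.
#' @param max_depth Maximum tree depth (default 2).
#' @return List with the `tree` (nested nodes) and per-split impurity
#'   `decreases` used for feature importance.
#' @export
fit_weak_learner <- function(X, y, w = rep(1 / nrow(X), nrow(X)),
                             max_depth = 2) {
  y01 <- as.numeric(y == POSITIVE_CLASS)
  ord <- lapply(seq_len(ncol(X)), function(j) order(X[, j]))
  res <- grow_tree(X, y01, w, seq_len(nrow(X)), 0L, max_depth, ord, list())
  list(tree = res$node, splits = res$splits)
}

binarize_labels <- function(labels) {
  ifelse(labels == POSITIVE_CLASS, POSITIVE_CLASS, NEGATIVE_CLASS)
}

#' Train an AdaBoost.M1 ensemble
#'
#' AdaBoost.M1 over depth-limited decision trees: weights start uniform;
#' round `t` fits a weak learner to the weighted data and computes its
#' weighted error `eps_t`. Boosting stops when `eps_t >= 0.5`. Otherwise
#' `beta_t = eps_t / (1 - eps_t)`, correctly classified rows are
#' down-weighted by `beta_t`, weights renormalize, and the learner's vote
#' weight is `ln(1/beta_t)`. A perfect learner (`eps_t = 0`) receives a
#' capped vote weight `ln(1e6)` and stops the loop.
#'
#' @param features Feature table from [feature_table()] (columns
#'   `measurement_id`, `label`, then [FEATURE_SCHEMA]) or a plain numeric
#'   data.frame/matrix of features.
#' @param labels Optional label vector; defaults to the table's `label`
#'   column. Any label other than `"AFIB"` is treated as the negative
#'   class.
#' @param rounds Maximum boosting rounds (default 50).
#' @param max_depth Weak-learner depth (default 2).
#' @param seed Integer seed recorded in the metadata (training itself is
#'   deterministic given the input order).
#' @return An object of class `afib_ensemble`.
#' @export
train_adaboost <- function(features, labels = NULL, rounds = 50,
                           max_depth = 2, seed = 0L) {
  rounds <- check_count(rounds, "rounds")
  max_depth <- check_count(max_depth, "max_depth")
  check_seed(seed)
  if (is.data.frame(features) && is.null(labels) &&
      "label" %in% names(features)) {
    labels <- features$label
  }
  feat_cols <- intersect(FEATURE_SCHEMA, colnames(features))
  if (length(feat_cols) == 0L) {
    afib_error("`features` contains no schema feature columns",
               "afib_schema_mismatch")
  }
  X <- as.matrix(as.data.frame(features)[, feat_cols, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) {
    afib_error("features contain non-finite values",
               "afib_invalid_parameter")
  }
  if (is.null(labels) || length(labels) != nrow(X)) {
    afib_error("`labels` must align with the feature rows",
               "afib_invalid_parameter")
  }
  y <- binarize_labels(labels)
  if (length(unique(y)) < 2L) {
    afib_error("training data must contain both classes",
               "afib_invalid_parameter")
  }
  n <- nrow(X)
  w <- rep(1 / n, n)
  learners <- list()
  eps_hist <- numeric(0)
  for (t in seq_len(rounds)) {
    wl <- fit_weak_learner(X, y, w, max_depth)
    pred <- predict_tree(wl$tree, X)
    wrong <- pred != y
    eps <- sum(w[wrong])
    if (eps >= 0.5) break
    if (eps == 0) {
      learners[[length(learners) + 1L]] <-
        list(tree = wl$tree, vote_weight = MAX_VOTE_WEIGHT,
             splits = wl$splits)
      eps_hist <- c(eps_hist, eps)
      break
    }
    beta <- eps / (1 - eps)
    learners[[length(learners) + 1L]] <-
      list(tree = wl$tree, vote_weight = log(1 / beta), splits = wl$splits)
    eps_hist <- c(eps_hist, eps)
    w[!wrong] <- w[!wrong] * beta
    w <- w / sum(w)
  }
  if (length(learners) == 0L) {
    afib_error("no weak learner achieved weighted error below 0.5",
               "afib_training_failed")
  }
  structure(list(
    learners = lapply(learners, function(l) l[c("tree", "vote_weight")]),
    splits = lapply(learners, function(l) l$splits),
    feature_names = feat_cols,
    feature_schema_version = FEATURE_SCHEMA_VERSION,
    metadata = list(rounds_requested = rounds,
                    rounds_used = length(learners),
                    max_depth = max_depth, seed = seed,
                    n_train = n, class_counts = as.list(table(y)),
                    weighted_errors = eps_hist)
  ), class = "afib_ensemble")
}

#' @export
print.afib_ensemble <- function(x, ...) {
  cat(sprintf("<afib_ensemble: %d weak learners (depth <= %d), %d features>\n",
              length(x$learners), x$metadata$max_depth,
              length(x$feature_names)))
  invisible(x)
}

fv_to_matrix <- function(ensemble, fv) {
  if (is.numeric(fv) && !is.matrix(fv)) fv <- t(as.matrix(fv))
  fv <- as.matrix(as.data.frame(fv)[, , drop = FALSE])
  missing <- setdiff(ensemble$feature_names, colnames(fv))
  if (length(missing) > 0L) {
    afib_error(paste0("feature vector is missing: ",
                      paste(missing, collapse = ", ")),
               "afib_schema_mismatch")
  }
  X <- fv[, ensemble$feature_names, drop = FALSE]
  storage.mode(X) <- "double"
  X
}

ensemble_margin <- function(ensemble, X) {
  total <- sum(vapply(ensemble$learners, function(l) l$vote_weight, 0.0))
  score <- numeric(nrow(X))
  for (l in ensemble$learners) {
    vote <- ifelse(predict_tree(l$tree, X) == POSITIVE_CLASS, 1, -1)
    score <- score + l$vote_weight * vote
  }
  pmin(1, pmax(-1, score / total))   # guard the [-1, 1] contract at 1 ulp
}

#' Classify feature vectors
#'
#' Weighted vote of the ensemble. The margin is (sum of vote weights for
#' AFib minus sum against) / (total vote weight), in \[-1, 1\]; the label
#' is `"AFIB"` iff the margin is strictly positive — an exact tie is
#' called `"NON_AFIB"`, since a screening tool prefers specificity on
#' ties.
#'
#' @param object An `afib_ensemble`.
#' @param fv A named feature vector from [compute_features()], a feature
#'   table, or a numeric matrix with schema column names.
#' @param ... Unused.
#' @return data.frame with columns `label` and `margin` (one row per
#'   input measurement).
#' @export
predict.afib_ensemble <- function(object, fv, ...) {
  X <- fv_to_matrix(object, fv)
  margin <- ensemble_margin(object, X)
  data.frame(label = ifelse(margin > 0, POSITIVE_CLASS, NEGATIVE_CLASS),
             margin = margin, stringsAsFactors = FALSE)
}

#' Feature importance of a trained ensemble
#'
#' Sum of vote-weighted Gini impurity decreases over every split using a
#' feature, normalized to sum to 1. The clustered-SD-derived features are
#' expected to dominate on rhythm data — the discrimination mechanism the
#' ensemble is built around.
#'
#' @param ensemble An `afib_ensemble`.
#' @return Named numeric vector over the ensemble's features, nonnegative,
#'   summing to 1.
#' @export
feature_importance <- function(ensemble) {
  stopifnot(inherits(ensemble, "afib_ensemble"))
  imp <- stats::setNames(numeric(length(ensemble$feature_names)),
                         ensemble$feature_names)
  for (t in seq_along(ensemble$learners)) {
    vw <- ensemble$learners[[t]]$vote_weight
    for (sp in ensemble$splits[[t]]) {
      f <- ensemble$feature_names[sp[["feature"]]]
      imp[f] <- imp[f] + vw * sp[["decrease"]]
    }
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp
}

#' Serialize / restore a trained ensemble
#'
#' Structural JSON (no opaque binary): format version, feature schema
#' version, learners as nested `(tree, vote_weight)` objects at full
#' floating-point precision, and training metadata. `load_model()`
#' verifies both versions and refuses mismatches; a reloaded model yields
#' identical margins.
#'
#' @param ensemble An `afib_ensemble`.
#' @param path File path of the model JSON.
#' @return `save_model()` the path invisibly; `load_model()` the
#'   `afib_ensemble`.
#' @export
save_model <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "afib_ensemble"))
  obj <- list(format_version = MODEL_FORMAT_VERSION,
              feature_schema_version = ensemble$feature_schema_version,
              feature_names = ensemble$feature_names,
              learners = lapply(ensemble$learners, function(l)
                list(tree = l$tree, vote_weight = l$vote_weight)),
              splits = ensemble$splits,
              metadata = ensemble$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

relist_tree <- function(node) {
  if (!is.null(node$leaf)) return(list(leaf = node$leaf))
  list(feature = node$feature, threshold = node$threshold,
       left = relist_tree(node$left), right = relist_tree(node$right))
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    afib_error(paste0("cannot parse model file: ",
                                      conditionMessage(e)),
                               "afib_model_parse")
                  })
  if (is.null(obj$format_version) ||
      !identical(obj$format_version, MODEL_FORMAT_VERSION)) {
    afib_error(sprintf("model format version mismatch (got %s, need %s)",
                       obj$format_version %||% "<none>",
                       MODEL_FORMAT_VERSION),
               "afib_version_mismatch")
  }
  if (!identical(obj$feature_schema_version, FEATURE_SCHEMA_VERSION)) {
    afib_error("feature schema version mismatch", "afib_version_mismatch")
  }
  splits <- lapply(obj$splits, function(round_splits)
    lapply(round_splits, function(sp)
      c(feature = as.numeric(sp$feature %||% sp[[1]]),
        decrease = as.numeric(sp$decrease %||% sp[[2]]))))
  structure(list(
    learners = lapply(obj$learners, function(l)
      list(tree = relist_tree(l$tree),
           vote_weight = as.numeric(l$vote_weight))),
    splits = splits,
    feature_names = unlist(obj$feature_names),
    feature_schema_version = obj$feature_schema_version,
    metadata = obj$metadata
  ), class = "afib_ensemble")
}
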
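# Multiclass gradient-boosted decision trees with native missing-value
# routing: one regression tree per class per boosting round, additive
# prediction scores per class, softmax class probabilities, and second-order
# greedy split search with gamma/lambda/alpha regularisation (C++ core in
# src/gbt.cpp).

stop_config <- function(fmt, ...) {
  stop(structure(class = c("ConfigError", "semloc_error", "error",
                           "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

stop_degenerate_labels <- function(msg) {
  stop(structure(class = c("DegenerateLabels", "semloc_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

#' Training configuration for the boosted-tree classifier
#'
#' Defaults follow the tuned sensor-only configuration: learning rate 0.025,
#' maximum tree depth 4, per-node complexity charge \code{gamma} 0.4, L2
#' weight \code{lambda} 1, L1 weight \code{alpha} 0, row subsampling 0.2 per
#' tree, feature subsampling 0.5 per node, and 200 boosting rounds.  For
#' sensor+venue feature sets the tuned values are 300 rounds, subsample 0.25
#' and colsample 0.2 (see \code{\link{train_config_venue}}).  Setting
#' \code{es_folds > 0} enables internal cross-validated early stopping:
#' training stops adding trees when the held-in CV loss stops improving for
#' \code{es_patience} rounds.
#'
#' @param learning_rate shrinkage applied to every leaf score.
#' @param max_depth maximum tree depth.
#' @param gamma minimum loss reduction (per split complexity charge).
#' @param lambda,alpha L2 / L1 penalties on leaf scores.
#' @param subsample fraction of training rows seen by each tree (in (0, 1]).
#' @param colsample fraction of features considered at each node (in (0, 1]).
#' @param max_rounds boosting round budget.
#' @param es_folds internal CV folds for early stopping (0 disables).
#' @param es_patience rounds without CV improvement before stopping.
#' @param seed RNG seed controlling row and feature subsampling.
#' @return list of class \code{semloc_train_config}.
#' @export
train_config <- function(learning_rate = 0.025, max_depth = 4, gamma = 0.4,
                         lambda = 1, alpha = 0, subsample = 0.2,
                         colsample = 0.5, max_rounds = 200, es_folds = 0,
                         es_patience = 10, seed = 1) {
  cfg <- list(learning_rate = learning_rate, max_depth = max_depth,
              gamma = gamma, lambda = lambda, alpha = alpha,
              subsample = subsample, colsample = colsample,
              max_rounds = max_rounds, es_folds = es_folds,
              es_patience = es_patience, seed = seed)
  if (subsample <= 0 || subsample > 1 || colsample <= 0 || colsample > 1)
    stop_config("subsample and colsample must lie in (0, 1]")
  if (learning_rate <= 0 || max_depth < 1 || max_rounds < 1 ||
      lambda < 0 || alpha < 0 || gamma < 0)
    stop_config("invalid training configuration")
  structure(cfg, class = "semloc_train_config")
}

#' @rdname train_config
#' @export
train_config_venue <- function(...) {
  defaults <- list(max_rounds = 300, subsample = 0.25, colsample = 0.2)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

#' Softmax class probabilities
#'
#' Converts per-class ensemble prediction scores to class probabilities,
#' \eqn{p_m = \exp(y_m) / \sum_j \exp(y_j)}, computed overflow-safely by
#' subtracting the row maximum first (the softmax is invariant to uniform
#' score shifts).
#'
#' @param scores numeric vector of M scores, or an n x M matrix.
#' @return probabilities of the same shape, each (row) summing to 1.
#' @export
class_probabilities <- function(scores) {
  if (is.matrix(scores)) {
    z <- exp(scores - apply(scores, 1, max))
    return(z / rowSums(z))
  }
  z <- exp(scores - max(scores))
  z / sum(z)
}

mlogloss <- function(prob, yidx) {
  p <- pmax(prob[cbind(seq_along(yidx), yidx)], 1e-15)
  -mean(log(p))
}

#' Route a feature vector through a decision tree
#'
#' Deterministic descent of a hand-built tree: at each internal node the
#' split feature is compared with the threshold (strictly-less goes left);
#' a missing split feature takes the node's designated missing branch.
#' Internal nodes are lists with \code{feature} (name or index),
#' \code{threshold}, \code{missing} (\code{"left"} or \code{"right"}),
#' \code{left} and \code{right}; leaves are lists with \code{score}.
#'
#' @param tree nested-list tree.
#' @param x named numeric feature vector (NA = missing).
#' @return the reached leaf score.
#' @export
route <- function(tree, x) {
  node <- tree
  while (is.null(node$score)) {
    v <- x[[node$feature]]
    go_left <- if (is.na(v)) identical(node$missing, "left")
               else v < node$threshold
    node <- if (go_left) node$left else node$right
  }
  node$score
}

# Route rows of X through one flat (vector-form) tree.
predict_flat_tree <- function(tree, X) {
  gbt_predict_tree_cpp(X, as.integer(tree$feature), tree$threshold,
                       tree$missing_left, as.integer(tree$left),
                       as.integer(tree$right), tree$value)
}

#' Per-class ensemble prediction scores
#'
#' The ensemble's score for class m is the sum of the leaf scores of all of
#' class m's trees, \eqn{y_m = \sum_k g_{k,m}(x)}.  An empty ensemble scores
#' 0 for every class.
#'
#' @param model a fitted \code{semloc_gbt} model.
#' @param X numeric feature matrix (columns in \code{model$feature_names}
#'   order; NA = missing).
#' @return n x M matrix of prediction scores.
#' @export
predict_scores <- function(model, X) {
  X <- as.matrix(X)
  M <- length(model$classes)
  scores <- matrix(0, nrow(X), M, dimnames = list(NULL, model$classes))
  for (m in seq_len(M))
    for (tr in model$trees[[m]])
      scores[, m] <- scores[, m] + predict_flat_tree(tr, X)
  scores
}

#' @export
predict.semloc_gbt <- function(object, newdata,
                               type = c("prob", "score", "class"), ...) {
  type <- match.arg(type)
  sc <- predict_scores(object, newdata)
  if (type == "score") return(sc)
  pr <- class_probabilities(sc)
  if (type == "prob") return(pr)
  object$classes[max.col(pr, ties.method = "first")]
}

# One boosting run.  yidx: 1..M class index per row.  If `val` rows are
# given, tracks validation multiclass logloss per round.
gbt_boost <- function(X, yidx, M, cfg, rounds, train_rows = seq_len(nrow(X)),
                      val_rows = integer(0)) {
  Xtr <- X[train_rows, , drop = FALSE]
  ytr <- yidx[train_rows]
  n <- nrow(Xtr)
  scores <- matrix(0, n, M)
  has_val <- length(val_rows) > 0
  if (has_val) {
    Xval <- X[val_rows, , drop = FALSE]
    yval <- yidx[val_rows]
    val_scores <- matrix(0, nrow(Xval), M)
    val_loss <- numeric(rounds)
  }
  train_loss <- numeric(rounds)
  trees <- replicate(M, list(), simplify = FALSE)
  n_sub <- max(1L, as.integer(ceiling(cfg$subsample * n)))
  for (t in seq_len(rounds)) {
    P <- class_probabilities(scores)
    for (m in seq_len(M)) {
      g <- P[, m] - as.numeric(ytr == m)
      h <- pmax(P[, m] * (1 - P[, m]), 1e-6)
      ridx <- sort(sample.int(n, n_sub)) - 1L
      tr <- gbt_build_tree_cpp(Xtr, g, h, ridx, cfg$lambda, cfg$alpha,
                               cfg$gamma, cfg$max_depth, cfg$colsample,
                               sample.int(.Machine$integer.max, 1))
      tr$value <- tr$value * cfg$learning_rate
      scores[, m] <- scores[, m] + predict_flat_tree(tr, Xtr)
      trees[[m]][[t]] <- tr
      if (has_val)
        val_scores[, m] <- val_scores[, m] + predict_flat_tree(tr, Xval)
    }
    train_loss[t] <- mlogloss(class_probabilities(scores), ytr)
    if (has_val) val_loss[t] <- mlogloss(class_probabilities(val_scores),
                                         yval)
  }
  list(trees = trees, train_loss = train_loss,
       val_loss = if (has_val) val_loss else NULL)
}

#' Fit the boosted-tree semantic-location classifier
#'
#' Stage-wise training: each round adds one tree per class, fit by exact
#' greedy split search to the first- and second-order residuals of the
#' softmax logistic loss under the configured regularisation, with row
#' subsampling per tree and feature subsampling per node.  With
#' \code{es_folds > 0} the round budget is first chosen by internal
#' cross-validation (training stops when the CV loss stops decreasing), then
#' the final ensemble is refit on all rows for that many rounds.
#'
#' @param X numeric feature matrix (NA = missing values, routed through the
#'   trees' missing branches).
#' @param y class labels (character or factor), one per row of \code{X}.
#' @param cfg a \code{\link{train_config}}.
#' @param classes optional fixed class ordering (defaults to the eleven
#'   classifiable place categories when \code{y} is drawn from them, else
#'   the sorted unique labels).
#' @return object of class \code{semloc_gbt}.
#' @export
gbt_fit <- function(X, y, cfg = train_config(), classes = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2)
    stop_degenerate_labels("training labels contain a single class")
  if (is.null(classes)) {
    classes <- if (all(y %in% classifiable_categories()))
      classifiable_categories() else sort(unique(y))
  }
  if (!all(y %in% classes)) stop_config("labels outside the class set")
  yidx <- match(y, classes)
  M <- length(classes)
  with_seed(cfg$seed, {
    rounds <- cfg$max_rounds
    cv_curve <- NULL
    if (cfg$es_folds > 0) {
      n <- nrow(X)
      fold <- sample(rep_len(seq_len(cfg$es_folds), n))
      losses <- sapply(seq_len(cfg$es_folds), function(k) {
        fit <- gbt_boost(X, yidx, M, cfg, cfg$max_rounds,
                         train_rows = which(fold != k),
                         val_rows = which(fold == k))
        fit$val_loss
      })
      cv_curve <- rowMeans(losses)
      best <- Inf; best_t <- 1L; wait <- 0L
      for (t in seq_along(cv_curve)) {
        if (cv_curve[t] < best - 1e-9) {
          best <- cv_curve[t]; best_t <- t; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$es_patience) break
        }
      }
      rounds <- best_t
    }
    fit <- gbt_boost(X, yidx, M, cfg, rounds)
    structure(list(classes = classes,
                   feature_names = colnames(X),
                   trees = fit$trees,
                   train_loss = fit$train_loss,
                   cv_curve = cv_curve,
                   n_rounds = rounds,
                   cfg = cfg),
              class = "semloc_gbt")
  })
}

#' @export
print.semloc_gbt <- function(x, ...) {
  cat(sprintf("<semloc_gbt %d classes x %d rounds, depth<=%d, lr %.3g>\n",
              length(x$classes), x$n_rounds, x$cfg$max_depth,
              x$cfg$learning_rate))
  invisible(x)
}

#' Save / load a fitted model
#'
#' Versioned JSON serialisation of the full ensemble (per-node feature name,
#' threshold, missing direction, children, leaf scores) for exact reload:
#' predictions from a reloaded model are identical.
#'
#' @param model a \code{semloc_gbt}.
#' @param path JSON file path.
#' @return \code{read_gbt} returns the model; \code{write_gbt} returns
#'   \code{path} invisibly.
#' @export
write_gbt <- function(model, path) {
  obj <- list(format_version = 1L,
              classes = model$classes,
              feature_names = model$feature_names,
              n_rounds = model$n_rounds,
              cfg = unclass(model$cfg),
              trees = model$trees)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_gbt
#' @export
read_gbt <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  # scalar JSON nulls (single-leaf trees) read back as NULL, not NA
  jvec <- function(x, as) {
    if (is.null(x)) return(as(NA))
    if (is.list(x))
      x <- unlist(lapply(x, function(e) if (is.null(e)) NA else e))
    as(x)
  }
  trees <- lapply(obj$trees, function(cls)
    lapply(cls, function(tr) {
      list(feature = jvec(tr$feature, as.integer),
           threshold = jvec(tr$threshold, as.numeric),
           missing_left = jvec(tr$missing_left, as.logical),
           left = jvec(tr$left, as.integer),
           right = jvec(tr$right, as.integer),
           value = jvec(tr$value, as.numeric))
    }))
  structure(list(classes = obj$classes, feature_names = obj$feature_names,
                 trees = trees, train_loss = NULL, cv_curve = NULL,
                 n_rounds = obj$n_rounds,
                 cfg = do.call(train_config, obj$cfg)),
            class = "semloc_gbt")
}

#' Hyperparameter grid search
#'
#' Evaluates every configuration on a participant subset by subject-wise
#' k-fold cross-validation (default 10 folds) of the macro one-vs-rest AUC,
#' and returns the configuration with the highest mean CV AUC (ties go to
#' the first grid entry).  Following the study design, tuning uses a small
#' seeded fraction of participants (see \code{\link{tuning_subset}}) so the
#' evaluation data stay untouched.
#'
#' @param X,y feature matrix and labels of the tuning subset.
#' @param subject participant id per row (folds never split a participant).
#' @param grid list of \code{\link{train_config}} objects.
#' @param k_folds number of CV folds.
#' @param seed RNG seed for fold assignment.
#' @return list with \code{best} (the winning config), \code{auc} (mean CV
#'   AUC per grid point).
#' @export
grid_search <- function(X, y, subject, grid, k_folds = 10, seed = 1) {
  if (!length(grid)) stop_config("empty grid")
  X <- as.matrix(X)
  ids <- unique(subject)
  k_folds <- min(k_folds, length(ids))
  fold_of <- with_seed(seed,
                       setNames(sample(rep_len(seq_len(k_folds),
                                               length(ids))), ids))
  aucs <- vapply(grid, function(cfg) {
    fold_auc <- vapply(seq_len(k_folds), function(k) {
      te <- fold_of[subject] == k
      if (length(unique(y[!te])) < 2 || !any(te)) return(NA_real_)
      fit <- gbt_fit(X[!te, , drop = FALSE], y[!te], cfg)
      pr <- predict(fit, X[te, , drop = FALSE], type = "prob")
      macro_ovr_auc(pr, y[te], fit$classes)
    }, 0)
    mean(fold_auc, na.rm = TRUE)
  }, 0)
  list(best = grid[[which.max(aucs)]], auc = aucs)
}

#' @rdname grid_search
#' @param ids all participant ids.
#' @param frac fraction of participants reserved for tuning (default 10\%).
#' @export
tuning_subset <- function(ids, frac = 0.1, seed = 1) {
  ids <- unique(ids)
  n <- max(1L, as.integer(round(frac * length(ids))))
  with_seed(seed, sort(sample(ids, n)))
}
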
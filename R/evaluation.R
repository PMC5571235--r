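# Subject-wise cross-validated evaluation: repeated 70/30 participant
# splits, per-category one-vs-rest AUC from the softmax probabilities,
# the venue-only baseline, and ablation feature importance.

stop_undefined_auc <- function(msg) {
  stop(structure(class = c("UndefinedAUC", "semloc_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

#' Split participants into train and test sets
#'
#' Random participant-level split: no visit of one participant can appear on
#' both sides, so evaluation estimates generalisation to unseen people.
#'
#' @param ids participant identifiers (duplicates allowed; split is on the
#'   unique set).
#' @param train_frac fraction of participants assigned to training
#'   (default 0.7).
#' @param seed RNG seed.
#' @return list with \code{train} and \code{test} id vectors (disjoint,
#'   exhaustive).
#' @export
subject_split <- function(ids, train_frac = 0.7, seed = 1) {
  ids <- unique(ids)
  if (length(ids) < 2) stop_config("need at least 2 participants to split")
  n_train <- max(1L, min(length(ids) - 1L,
                         as.integer(round(train_frac * length(ids)))))
  tr <- with_seed(seed, sample(ids, n_train))
  list(train = sort(tr), test = sort(setdiff(ids, tr)))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive outscores a random negative, with ties counted half,
#' \eqn{P(s^+ > s^-) + P(s^+ = s^-)/2}.  Implemented via average ranks, so
#' it matches the all-pairs construction exactly.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (logical, or 0/1).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop_undefined_auc("AUC undefined: one class absent")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Macro one-vs-rest AUC of a probability matrix; categories missing a class
# in `y` contribute nothing.
macro_ovr_auc <- function(prob, y, classes) {
  a <- vapply(classes, function(cl) {
    pos <- y == cl
    if (!any(pos) || all(pos)) return(NA_real_)
    roc_auc(prob[, cl], pos)
  }, 0)
  mean(a, na.rm = TRUE)
}

#' Assemble the supervised per-visit dataset for a cohort
#'
#' Runs stay detection on every participant, labels each detected visit with
#' the nearest same-day diary report (within 100 m), keeps visits labeled
#' with one of the eleven classifiable categories, and extracts the feature
#' matrix.  In \code{"sensor+venue"} mode the nearest-venue one-hot and
#' distance slots are appended.
#'
#' @param participants list of \code{\link{participant}} objects.
#' @param mode \code{"sensor"} (38 features) or \code{"sensor+venue"}
#'   (48 features).
#' @param venue_db,hierarchy venue database and category mapping (required
#'   in \code{"sensor+venue"} mode).
#' @param visits optional precomputed list of labeled visits per participant
#'   (as returned in this function's \code{visits} field) to skip
#'   re-detection.
#' @param base optional sensor-mode dataset from a previous call; in
#'   \code{"sensor+venue"} mode its feature matrix is reused and only the
#'   10 venue slots are computed.
#' @return list with \code{X} (feature matrix), \code{y} (labels),
#'   \code{subject} (participant id per row) and \code{visits}.
#' @export
cohort_dataset <- function(participants, mode = c("sensor", "sensor+venue"),
                           venue_db = NULL, hierarchy = NULL,
                           visits = NULL, base = NULL) {
  mode <- match.arg(mode)
  use_venue <- mode == "sensor+venue"
  if (use_venue && (is.null(venue_db) || is.null(hierarchy)))
    stop_config("sensor+venue mode needs venue_db and hierarchy")
  if (!is.null(base)) {
    stopifnot(use_venue, identical(base$mode, "sensor"))
    vrows <- list(); i <- 0
    for (p in participants) {
      for (v in base$visits[[p$id]]) {
        if (is.na(v$label) || !v$label %in% classifiable_categories()) next
        nv <- nearest_venue(v$center_lat, v$center_lon, venue_db)
        vrows[[i <- i + 1]] <- venue_features(nv$venue, nv$distance_m[1],
                                              hierarchy)
      }
    }
    stopifnot(i == nrow(base$X))
    return(list(X = cbind(base$X, do.call(rbind, vrows)), y = base$y,
                subject = base$subject, visits = base$visits,
                mode = mode))
  }
  rows <- list(); y <- character(0); subject <- character(0)
  all_visits <- list()
  for (p in participants) {
    vs <- if (!is.null(visits)) visits[[p$id]] else {
      det <- detect_visits_study(p)
      for (i in seq_along(det))
        det[[i]]$label <- match_visit_to_report(det[[i]], p$ema)
      det
    }
    all_visits[[p$id]] <- vs
    for (v in vs) {
      if (is.na(v$label) || !v$label %in% classifiable_categories()) next
      vf <- NULL
      if (use_venue) {
        nv <- nearest_venue(v$center_lat, v$center_lon, venue_db)
        vf <- venue_features(nv$venue, nv$distance_m[1], hierarchy)
      }
      rows[[length(rows) + 1]] <- build_feature_vector(v, p, venue = vf)
      y <- c(y, v$label)
      subject <- c(subject, p$id)
    }
  }
  X <- do.call(rbind, rows)
  list(X = X, y = y, subject = subject, visits = all_visits, mode = mode)
}

#' Repeated subject-wise evaluation of a featurised dataset
#'
#' Same procedure as \code{\link{evaluate_pipeline}} but starting from an
#' already-featurised dataset (\code{\link{cohort_dataset}}), so the two
#' feature modes can share one stay-detection pass.
#'
#' @param ds dataset from \code{\link{cohort_dataset}}.
#' @param cfg a \code{\link{train_config}}.
#' @param n_repeats,train_frac,seed see \code{\link{evaluate_pipeline}}.
#' @param classes class set evaluated.
#' @return a \code{semloc_eval} object.
#' @export
evaluate_dataset <- function(ds, cfg = train_config(), n_repeats = 100,
                             train_frac = 0.7, seed = 1, classes = NULL) {
  if (is.null(classes))
    classes <- if (all(ds$y %in% classifiable_categories()))
      classifiable_categories() else sort(unique(ds$y))
  aucs <- matrix(NA_real_, n_repeats, length(classes),
                 dimnames = list(NULL, classes))
  for (rep in seq_len(n_repeats)) {
    sp <- subject_split(ds$subject, train_frac,
                        seed = child_seed(seed, "split", rep))
    tr <- ds$subject %in% sp$train
    stopifnot(length(intersect(ds$subject[tr], ds$subject[!tr])) == 0)
    if (length(unique(ds$y[tr])) < 2) next
    cfg_rep <- cfg; cfg_rep$seed <- child_seed(seed, "fit", rep)
    fit <- gbt_fit(ds$X[tr, , drop = FALSE], ds$y[tr], cfg_rep,
                   classes = classes)
    prob <- predict(fit, ds$X[!tr, , drop = FALSE], type = "prob")
    yte <- ds$y[!tr]
    for (cl in classes) {
      pos <- yte == cl
      if (!any(pos) || all(pos)) next   # category absent from this fold
      aucs[rep, cl] <- roc_auc(prob[, cl], pos)
    }
  }
  summarise_aucs(aucs)
}

summarise_aucs <- function(aucs) {
  per_cat <- data.frame(
    category = colnames(aucs),
    mean_auc = colMeans(aucs, na.rm = TRUE),
    ci_lo = apply(aucs, 2, quantile, 0.025, na.rm = TRUE),
    ci_hi = apply(aucs, 2, quantile, 0.975, na.rm = TRUE),
    n_repeats = colSums(!is.na(aucs)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_category = per_cat,
                 macro_auc = mean(per_cat$mean_auc, na.rm = TRUE),
                 aucs = aucs),
            class = "semloc_eval")
}

#' @export
print.semloc_eval <- function(x, ...) {
  cat("Subject-wise cross-validated AUC\n")
  df <- x$per_category
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-30s %.3f (%.3f-%.3f) [n=%d]\n", df$category[i],
                df$mean_auc[i], df$ci_lo[i], df$ci_hi[i], df$n_repeats[i]))
  cat(sprintf("  %-30s %.3f\n", "Macro mean AUC", x$macro_auc))
  invisible(x)
}

#' Evaluate the semantic-location classifier on a cohort
#'
#' Repeats \code{n_repeats} times: split participants 70/30, fit the
#' boosted-tree classifier on the training participants' visits, and compute
#' the one-vs-rest AUC per category on the held-out participants' visits
#' from the softmax probabilities.  Reports the per-category mean AUC with
#' 2.5/97.5 percentile intervals over the repetitions, and the macro mean
#' (the unweighted mean of the per-category means).
#'
#' @inheritParams cohort_dataset
#' @param cfg a \code{\link{train_config}}.
#' @param n_repeats number of repeated splits (the study design uses 100).
#' @param train_frac fraction of participants used for training.
#' @param seed RNG seed for splits and fits.
#' @return object of class \code{semloc_eval}: \code{per_category}
#'   data.frame, \code{macro_auc}, and the raw \code{aucs} matrix
#'   (repetitions x categories).
#' @export
evaluate_pipeline <- function(participants, cfg = train_config(),
                              n_repeats = 100,
                              mode = c("sensor", "sensor+venue"),
                              venue_db = NULL, hierarchy = NULL,
                              train_frac = 0.7, seed = 1) {
  mode <- match.arg(mode)
  ds <- cohort_dataset(participants, mode, venue_db, hierarchy)
  evaluate_dataset(ds, cfg, n_repeats, train_frac, seed)
}

#' Venue-only baseline evaluation
#'
#' Scores every eligible labeled visit with the hard venue-database guess
#' (\code{\link{baseline_predict}}) and computes the per-category one-vs-rest
#' AUC, using score 1 for the predicted category and 0 otherwise.  Visits
#' labeled Work, Another's Home or Spiritual are excluded, since the venue
#' vocabulary has no counterpart for them; diary labels are translated to
#' venue categories via the fixed mapping before comparison.
#'
#' @param participants list of participants.
#' @param venue_db,hierarchy venue database and category mapping.
#' @param visits optional precomputed labeled visits (per participant).
#' @return data.frame with one row per eligible diary category:
#'   \code{category}, \code{auc}, \code{n_pos}, plus a macro mean row.
#' @export
foursquare_baseline_eval <- function(participants, venue_db, hierarchy,
                                     visits = NULL) {
  labels <- character(0); predicted <- character(0)
  for (p in participants) {
    vs <- if (!is.null(visits)) visits[[p$id]] else {
      det <- detect_visits_study(p)
      for (i in seq_along(det))
        det[[i]]$label <- match_visit_to_report(det[[i]], p$ema)
      det
    }
    for (v in vs) {
      if (is.na(v$label) || !v$label %in% classifiable_categories()) next
      if (v$label %in% baseline_skipped_categories()) next
      labels <- c(labels, v$label)
      predicted <- c(predicted, baseline_predict(v, venue_db, hierarchy))
    }
  }
  map <- ema_to_venue_category()
  cats <- setdiff(classifiable_categories(), baseline_skipped_categories())
  rows <- lapply(cats, function(cl) {
    pos <- labels == cl
    if (!any(pos) || all(pos))
      return(data.frame(category = cl, auc = NA_real_, n_pos = sum(pos)))
    score <- as.numeric(predicted == map[[cl]])
    data.frame(category = cl, auc = roc_auc(score, pos), n_pos = sum(pos))
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(category = "Macro mean",
                        auc = mean(out$auc, na.rm = TRUE),
                        n_pos = sum(out$n_pos)))
}

#' Ablation feature importance
#'
#' For each feature, reruns the repeated subject-wise evaluation with that
#' feature removed from the training data; importance is the baseline macro
#' mean AUC minus the ablated macro mean AUC (positive = removing the
#' feature hurts).  The same split seeds are reused, so the differences are
#' paired across repetitions and the reported standard error is that of the
#' paired per-repetition differences.
#'
#' @param ds a dataset from \code{\link{cohort_dataset}}.
#' @param cfg a \code{\link{train_config}}.
#' @param features features to ablate (default: all columns).
#' @param n_repeats repeated splits per evaluation (ablation sweeps usually
#'   use a reduced budget).
#' @param seed RNG seed.
#' @return data.frame with \code{feature}, \code{importance} (delta macro
#'   AUC) and \code{se}, sorted by decreasing importance.
#' @export
feature_importance <- function(ds, cfg = train_config(),
                               features = colnames(ds$X), n_repeats = 10,
                               seed = 1) {
  base <- evaluate_dataset(ds, cfg, n_repeats, seed = seed)
  base_rep <- rowMeans(base$aucs, na.rm = TRUE)
  rows <- lapply(features, function(f) {
    ds_f <- ds
    ds_f$X <- ds$X[, setdiff(colnames(ds$X), f), drop = FALSE]
    abl <- evaluate_dataset(ds_f, cfg, n_repeats, seed = seed)
    d <- base_rep - rowMeans(abl$aucs, na.rm = TRUE)
    data.frame(feature = f, importance = base$macro_auc - abl$macro_auc,
               se = sd(d) / sqrt(length(d)))
  })
  out <- do.call(rbind, rows)
  out[order(-out$importance), , drop = FALSE]
}
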
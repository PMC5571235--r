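# Association analyses: time spent per place category vs three-wave PHQ-9 /
# GAD-7 scores -- bootstrap Pearson correlations, consistent-threshold group
# construction, and relative-time group comparisons.

stop_undefined_correlation <- function(msg) {
  stop(structure(class = c("UndefinedCorrelation", "semloc_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

stop_degenerate_group <- function(msg) {
  stop(structure(class = c("DegenerateGroup", "semloc_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

#' Hours spent per place category
#'
#' Sums labeled visit durations by category for each participant.  Unvisited
#' categories get zero.  \code{budget_from_ema} instead sums the
#' self-reported diary intervals directly, mirroring the self-report
#' pathway.
#'
#' @param visits list of labeled \code{semloc_visit} (e.g. the
#'   \code{visits} field of \code{\link{cohort_dataset}}, flattened).
#' @param ids participant ids to include (defaults to those present).
#' @return data.frame, participants x 11 categories, in hours.
#' @export
time_per_category <- function(visits, ids = NULL) {
  cats <- classifiable_categories()
  vid <- vapply(visits, `[[`, "", "id")
  if (is.null(ids)) ids <- sort(unique(vid))
  out <- matrix(0, length(ids), length(cats), dimnames = list(ids, cats))
  for (v in visits) {
    if (is.na(v$label) || !v$label %in% cats || !v$id %in% ids) next
    out[v$id, v$label] <- out[v$id, v$label] + v$duration_s / 3600
  }
  as.data.frame(out)
}

#' @rdname time_per_category
#' @param participants list of \code{\link{participant}} objects.
#' @export
budget_from_ema <- function(participants) {
  cats <- classifiable_categories()
  ids <- vapply(participants, `[[`, "", "id")
  out <- matrix(0, length(ids), length(cats), dimnames = list(ids, cats))
  for (p in participants) {
    if (is.null(p$ema)) next
    for (i in seq_len(nrow(p$ema))) {
      cc <- p$ema$category[i]
      if (!cc %in% cats) next
      iv <- p$ema$intervals[[i]]
      out[p$id, cc] <- out[p$id, cc] + sum(iv[, 2] - iv[, 1]) / 3600
    }
  }
  as.data.frame(out)
}

#' Bootstrap Pearson correlation
#'
#' The reported coefficient is the median of \code{n_boot} Pearson
#' correlations over paired resamples; the p-value is the two-sided
#' t-distribution significance of the plain-sample correlation (the
#' bootstrap gives the point estimate its robustness, the test is on the
#' observed r).
#'
#' @param x,y paired numeric vectors (n >= 3, finite, non-degenerate).
#' @param n_boot bootstrap resamples (1000 in the study design).
#' @param seed RNG seed.
#' @return list with \code{r_median}, \code{r} (plain-sample), \code{p}.
#' @export
bootstrap_correlation <- function(x, y, n_boot = 1000, seed = 1) {
  if (length(x) != length(y) || length(x) < 3 ||
      any(!is.finite(x)) || any(!is.finite(y)))
    stop_undefined_correlation("need >= 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop_undefined_correlation("zero variance in x or y")
  n <- length(x)
  r_boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    if (sd(x[i]) == 0 || sd(y[i]) == 0) return(NA_real_)
    cor(x[i], y[i])
  }, 0))
  list(r_median = median(r_boot, na.rm = TRUE), r = cor(x, y),
       p = cor.test(x, y)$p.value)
}

#' Consistent-threshold group assignment
#'
#' Participants whose three scores all fall below the screening threshold
#' form the \code{"below"} group and those all above form \code{"above"};
#' anyone who crosses the threshold between assessments -- including scores
#' exactly at the threshold, which the strict below/above definitions leave
#' unassignable -- is \code{"excluded"}.
#'
#' @param scores n x 3 matrix (waves 0/3/6) or a length-3 vector.
#' @param threshold screening cut-off (10 for both PHQ-9 and GAD-7).
#' @return character vector of \code{"below"}, \code{"above"},
#'   \code{"excluded"}.
#' @export
assign_groups <- function(scores, threshold = 10) {
  if (is.null(dim(scores))) scores <- matrix(scores, 1)
  stopifnot(ncol(scores) == 3)
  below <- rowSums(scores < threshold) == 3
  above <- rowSums(scores > threshold) == 3
  ifelse(below, "below", ifelse(above, "above", "excluded"))
}

#' Group comparison of time spent per category
#'
#' For every place category, computes each group's share of the cohort's
#' total time there (group sum divided by the all-participant total, so
#' below + above + excluded shares sum to 1) with a 95 percent bootstrap
#' percentile CI (resampling group members, denominator fixed), and a
#' Welch two-sample t-test on the raw
#' per-participant hours with a significance flag at p < .05.  With as many
#' categories and instruments as are compared here, flags that survive no
#' multiplicity adjustment should be read as exploratory; the returned
#' table carries that note as an attribute.
#'
#' @param budgets data.frame from \code{\link{time_per_category}}.
#' @param groups character vector ("below"/"above"/"excluded"), one per
#'   budget row.
#' @param n_boot bootstrap iterations.
#' @param seed RNG seed.
#' @return data.frame, one row per category: group shares with CIs,
#'   Welch \code{t}, \code{df}, \code{p}, \code{significant}.
#' @export
group_difference <- function(budgets, groups, n_boot = 1000, seed = 1) {
  stopifnot(nrow(budgets) == length(groups))
  ib <- which(groups == "below"); ia <- which(groups == "above")
  if (length(ib) < 2 || length(ia) < 2)
    stop_degenerate_group("each group needs at least 2 participants")
  rows <- lapply(names(budgets), function(cc) {
    x <- budgets[[cc]]
    total <- sum(x)
    share <- function(idx, bseed) {
      if (total == 0) return(c(NA_real_, NA_real_, NA_real_))
      bs <- with_seed(bseed, vapply(seq_len(n_boot), function(b)
        sum(sample(x[idx], length(idx), replace = TRUE)) / total, 0))
      c(sum(x[idx]) / total, quantile(bs, c(0.025, 0.975)))
    }
    sb <- share(ib, child_seed(seed, cc, "below"))
    sa <- share(ia, child_seed(seed, cc, "above"))
    tt <- tryCatch(t.test(x[ia], x[ib]),   # Welch by default
                   error = function(e) NULL)
    data.frame(category = cc,
               share_below = sb[1], ci_lo_below = sb[2], ci_hi_below = sb[3],
               share_above = sa[1], ci_lo_above = sa[2], ci_hi_above = sa[3],
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < 0.05
  attr(out, "note") <- paste(
    "Significance flags are unadjusted for multiple comparisons;",
    "adjusted, these differences are nonsignificant.")
  out
}

#' Correlation table: time per category vs three-wave scores
#'
#' Bootstrap-median Pearson correlations between the hours spent in each
#' category and each of the six score columns (PHQ-9 and GAD-7 at weeks
#' 0/3/6), with unadjusted two-sided p-values.  Participants who cross the
#' screening threshold are retained here (the correlation analysis uses all
#' participants); categories with zero variance are reported as NA.
#'
#' @param budgets data.frame from \code{\link{time_per_category}}.
#' @param phq9,gad7 n x 3 integer score matrices.
#' @param n_boot bootstrap resamples per cell.
#' @param seed RNG seed.
#' @return list with matrices \code{r} and \code{p}
#'   (11 categories x 6 score columns).
#' @export
correlation_table <- function(budgets, phq9, gad7, n_boot = 1000, seed = 1) {
  scores <- cbind(phq9, gad7)
  colnames(scores) <- c(paste("PHQ-9 Week", c(0, 3, 6)),
                        paste("GAD-7 Week", c(0, 3, 6)))
  r <- p <- matrix(NA_real_, ncol(budgets), ncol(scores),
                   dimnames = list(names(budgets), colnames(scores)))
  for (cc in names(budgets))
    for (sc in colnames(scores)) {
      res <- tryCatch(
        bootstrap_correlation(budgets[[cc]], scores[, sc], n_boot,
                              seed = child_seed(seed, cc, sc)),
        UndefinedCorrelation = function(e) NULL)
      if (!is.null(res)) { r[cc, sc] <- res$r_median; p[cc, sc] <- res$p }
    }
  note <- paste("With 66 unadjusted comparisons, isolated significant",
                "cells can arise by chance; conservative corrections may",
                "be inappropriate given the dependence between cells.")
  structure(list(r = r, p = p), note = note)
}
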
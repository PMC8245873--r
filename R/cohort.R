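#' Geometric mean and geometric SD
#'
#' `geometric_mean(x)` is `exp(mean(log(x)))`; `geometric_sd(x)` is
#' `exp(sd(log(x)))` (dimensionless multiplicative spread). Both require
#' strictly positive input.
#'
#' @param x vector of positive numbers.
#' @return a single number.
#' @export
#' @examples
#' geometric_mean(c(1, 4))  # 2
geometric_mean <- function(x) {
  if (length(x) == 0L || any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric mean requires positive finite values", call. = FALSE)
  }
  exp(mean(log(x)))
}

#' @rdname geometric_mean
#' @export
geometric_sd <- function(x) {
  if (length(x) < 2L || any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric SD requires >= 2 positive finite values",
         call. = FALSE)
  }
  exp(stats::sd(log(x)))
}

#' Per-day cohort summary of the composite coefficient FaS
#'
#' For each requested day, the geometric mean of `FaS` across subjects,
#' a dispersion (SD), and the coefficient of variation in percent. The
#' default convention pairs the geometric mean with the arithmetic SD and
#' `CV% = 100 * SD / arithmetic mean`; set `cv = "geometric"` for the
#' log-scale convention (`SD = geometric SD` as a factor and
#' `CV% = 100 * sqrt(exp(sdlog^2) - 1)`).
#'
#' @param rid_df long cohort table from [cohort_rid()] (one group).
#' @param days days to summarize (must be present with defined `FaS` for
#'   every subject).
#' @param cv `"arithmetic"` (default) or `"geometric"`.
#' @return data frame with columns `day`, `gm_fas`, `sd_fas`, `cv_pct`.
#' @export
summarize_fas <- function(rid_df, days = 1:30,
                          cv = c("arithmetic", "geometric")) {
  cv <- match.arg(cv)
  if (length(unique(rid_df$subject_id)) < 2L) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  out <- lapply(days, function(d) {
    fas <- rid_df$FaS[rid_df$day == d]
    if (length(fas) == 0L) {
      stop("no FaS values at day ", d, call. = FALSE)
    }
    if (any(is.na(fas))) {
      stop("FaS undefined for some subjects at day ", d,
           " (tracer has not reached stores)", call. = FALSE)
    }
    if (cv == "arithmetic") {
      sd_fas <- stats::sd(fas)
      cv_pct <- 100 * sd_fas / mean(fas)
    } else {
      sdlog <- stats::sd(log(fas))
      sd_fas <- exp(sdlog)
      cv_pct <- 100 * sqrt(exp(sdlog^2) - 1)
    }
    data.frame(day = d, gm_fas = geometric_mean(fas),
               sd_fas = sd_fas, cv_pct = cv_pct)
  })
  do.call(rbind, out)
}

#' Evaluate RID prediction accuracy over candidate sampling days
#'
#' The study's central computation: for each day, total body stores are
#' predicted for every subject from the cohort geometric-mean `FaS` at
#' that day combined with the subject's own plasma specific activity
#' (`predicted = gm_fas / SAp`), mimicking a field study in which
#' individual `FaS` values are unknown. Predictions are compared with the
#' assigned TBS by
#' \itemize{
#'   \item ordinary least-squares regression of predicted (y) on assigned
#'     (x), with `r_squared` the squared Pearson correlation and `p` the
#'     two-sided test of zero slope;
#'   \item the squared Pearson correlation of the rank vectors
#'     (`rank_r_squared`, ties by average rank);
#'   \item the percentage of subjects whose prediction falls within each
#'     relative threshold of the assigned value
#'     (`|pred - assigned| / assigned <= threshold`);
#'   \item for the selected days, the frequency with which each day gives
#'     a subject's most accurate prediction (ties to the earliest day,
#'     tie events recorded in the report).
#' }
#'
#' @param rid_df long cohort table from [cohort_rid()] (one group).
#' @param assigned data frame with `subject_id` and `assigned_tbs`
#'   columns; defaults to the `assigned` attribute of `rid_df`.
#' @param days days to evaluate (default 1 to 30).
#' @param thresholds relative accuracy thresholds, percent.
#' @param selected_days days entering the best-day frequency analysis.
#' @param cv convention passed to [summarize_fas()].
#' @return An `accuracy_report`: list with `predictions` (long data
#'   frame), `regressions`, `pct_within`, `best_day_frequency`,
#'   `fas_summary`, `tbs_summary` (per-day GMean/Min/Max of predictions
#'   plus the assigned row) and `ties`.
#' @export
evaluate_sampling_days <- function(rid_df, assigned = NULL, days = 1:30,
                                   thresholds = c(10, 25, 50),
                                   selected_days = c(4, 7, 10, 14, 21, 28),
                                   cv = c("arithmetic", "geometric")) {
  cv <- match.arg(cv)
  if (is.null(assigned)) assigned <- attr(rid_df, "assigned")
  if (is.null(assigned)) {
    stop("`assigned` TBS table is required", call. = FALSE)
  }
  ids <- unique(rid_df$subject_id)
  if (length(ids) < 3L) {
    stop("need at least 3 subjects for the regression analysis",
         call. = FALSE)
  }
  if (!all(ids %in% assigned$subject_id)) {
    stop("assigned TBS missing for some subjects", call. = FALSE)
  }
  days <- sort(unique(as.integer(days)))
  selected_days <- sort(unique(as.integer(selected_days)))
  if (!all(selected_days %in% days)) {
    stop("`selected_days` must be a subset of `days`", call. = FALSE)
  }
  thresholds <- sort(thresholds)

  fas_summary <- summarize_fas(rid_df, days = days, cv = cv)
  truth <- stats::setNames(assigned$assigned_tbs, assigned$subject_id)

  pred_rows <- list()
  reg_rows <- list()
  pct_rows <- list()
  for (d in days) {
    sub <- rid_df[rid_df$day == d, , drop = FALSE]
    sub <- sub[match(ids, sub$subject_id), , drop = FALSE]
    gm <- fas_summary$gm_fas[fas_summary$day == d]
    pred <- predict_tbs(gm, sub$SAp)
    asg <- truth[ids]
    rel_err <- (pred - asg) / asg
    pred_rows[[length(pred_rows) + 1L]] <- data.frame(
      day = d, subject_id = ids, predicted_tbs = pred,
      assigned_tbs = unname(asg), rel_err = unname(rel_err))

    fit <- stats::lm(pred ~ asg)
    sm <- suppressWarnings(summary(fit))  # "perfect fit" note on exact data
    reg_rows[[length(reg_rows) + 1L]] <- data.frame(
      day = d,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = stats::cor(asg, pred)^2,
      p = sm$coefficients[2, 4],
      rank_r_squared = stats::cor(rank(asg), rank(pred))^2)

    pct_rows[[length(pct_rows) + 1L]] <- data.frame(
      day = d, threshold = thresholds,
      pct_within = vapply(thresholds, function(th) {
        100 * mean(abs(rel_err) <= th / 100)
      }, numeric(1)))
  }
  predictions <- do.call(rbind, pred_rows)
  regressions <- do.call(rbind, reg_rows)
  pct_within <- do.call(rbind, pct_rows)

  # best day per subject among the selected days; earliest wins ties
  sel <- predictions[predictions$day %in% selected_days, , drop = FALSE]
  ties <- character(0)
  best <- vapply(ids, function(id) {
    e <- sel[sel$subject_id == id, , drop = FALSE]
    e <- e[order(e$day), , drop = FALSE]
    ae <- abs(e$rel_err)
    winners <- e$day[ae == min(ae)]
    if (length(winners) > 1L) {
      ties <<- c(ties, sprintf("subject %s: tie among days %s", id,
                               paste(winners, collapse = ", ")))
    }
    winners[1]
  }, numeric(1))
  best_day_frequency <- data.frame(
    day = selected_days,
    count = vapply(selected_days, function(d) sum(best == d), numeric(1)))

  tbs_summary <- do.call(rbind, lapply(days, function(d) {
    p <- predictions$predicted_tbs[predictions$day == d]
    data.frame(day = d, gmean = geometric_mean(p),
               min = min(p), max = max(p))
  }))
  assigned_row <- data.frame(
    day = NA_integer_, gmean = geometric_mean(truth[ids]),
    min = min(truth[ids]), max = max(truth[ids]))

  structure(
    list(predictions = predictions, regressions = regressions,
         pct_within = pct_within, best_day_frequency = best_day_frequency,
         fas_summary = fas_summary,
         tbs_summary = rbind(cbind(series = "assigned", assigned_row),
                             cbind(series = "predicted", tbs_summary)),
         ties = ties, days = days, selected_days = selected_days,
         thresholds = thresholds, n_subjects = length(ids)),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report: %d subjects, days %d-%d>\n",
              x$n_subjects, min(x$days), max(x$days)))
  cat("  r_squared by selected day:\n")
  r <- x$regressions[x$regressions$day %in% x$selected_days, ]
  cat(sprintf("    day %2d: %.3f\n", r$day, r$r_squared), sep = "")
  if (length(x$ties)) {
    cat(sprintf("  %d best-day tie(s) recorded\n", length(x$ties)))
  }
  invisible(x)
}
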
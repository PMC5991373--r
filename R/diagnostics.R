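#' Round half away from zero
#'
#' Rounding convention used when matching printed tables: ties go away from
#' zero (the convention of the statistical software family the published
#' tables came from), unlike base R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(0.25, 1)  # 0.3, where round() gives 0.2
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Confusion matrix of a screening algorithm against the gold standard
#'
#' Excluded respondents contribute to no cell. Gold-positive is alopecia
#' areata (totalis/universalis or patchy); gold-negative is other hair loss.
#'
#' @param labels Named character vector from [classify_cohort()] (values
#'   `positive`/`negative`/`excluded`, names = respondent ids).
#' @param gold Named character vector of diagnosis class tokens, or a
#'   validated cohort data frame (its `id` and `diagnosis` columns are used).
#' @return Object of class `confusion_matrix`: list with integer `tp`,
#'   `fp`, `tn`, `fn` and `n_excluded`.
#' @export
confusion_matrix <- function(labels, gold) {
  if (is.data.frame(gold)) gold <- stats::setNames(gold$diagnosis, gold$id)
  missing_ids <- setdiff(names(labels), names(gold))
  if (length(missing_ids) > 0) {
    stop("ids present in labels but absent from gold standard: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  stopifnot(all(labels %in% c("positive", "negative", "excluded", "indeterminate")))
  g <- is_aa(gold[names(labels)])
  keep <- labels %in% c("positive", "negative")
  pos <- labels == "positive"
  structure(list(
    tp = sum(keep & pos & g), fp = sum(keep & pos & !g),
    tn = sum(keep & !pos & !g), fn = sum(keep & !pos & g),
    n_excluded = sum(!keep)
  ), class = "confusion_matrix")
}

#' Build a confusion matrix from cell counts
#'
#' @param tp,fp,tn,fn Non-negative integer cell counts.
#' @return `confusion_matrix` object.
#' @export
confusion_cells <- function(tp, fp, tn, fn) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(cells >= 0), all(cells == as.integer(cells)))
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn),
                 n_excluded = 0L),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d tn=%d fn=%d (excluded %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n_excluded))
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval obtained by inverting binomial tail probabilities,
#' in its beta-quantile form: lower bound `qbeta(alpha/2, k, n-k+1)` (0 when
#' `k = 0`), upper bound `qbeta(1-alpha/2, k+1, n-k)` (1 when `k = n`).
#' Coverage is conservative (at least the nominal level).
#'
#' @param k Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param alpha Significance level in (0,1); default 0.05 for a 95% CI.
#' @return Object of class `proportion_ci`: list with `point`, `lower`,
#'   `upper`, `numerator`, `denominator`, `alpha`.
#' @export
#' @examples
#' ci <- clopper_pearson(53, 59)
#' round(100 * c(ci$lower, ci$upper), 1)  # 79.2 96.2
clopper_pearson <- function(k, n, alpha = 0.05) {
  stopifnot(length(k) == 1, length(n) == 1, length(alpha) == 1,
            n >= 1, k >= 0, k <= n, k == as.integer(k), n == as.integer(n),
            alpha > 0, alpha < 1)
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  structure(list(point = k / n, lower = lower, upper = upper,
                 numerator = as.integer(k), denominator = as.integer(n),
                 alpha = alpha),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%.1f, %.1f) [%d%% CI]\n",
              x$numerator, x$denominator, 100 * x$point,
              100 * x$lower, 100 * x$upper, round(100 * (1 - x$alpha))))
  invisible(x)
}

#' Format a proportion CI as printed in the published tables
#'
#' `point (lower, upper)` in percent, one decimal, half-away-from-zero.
#'
#' @param ci A `proportion_ci`, or `NULL` (returns `"-"`).
#' @return Character scalar.
#' @export
format_pct_ci <- function(ci) {
  if (is.null(ci)) return("-")
  sprintf("%.1f (%.1f, %.1f)",
          round_half_away(100 * ci$point),
          round_half_away(100 * ci$lower),
          round_half_away(100 * ci$upper))
}

#' Diagnostic-accuracy summary of a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)`, each with a Clopper-Pearson interval. PPV/NPV are
#' `NULL` (flagged undefined) when their denominator is zero.
#'
#' @param cm A `confusion_matrix`.
#' @param alpha Significance level for the intervals.
#' @param algorithm_id Optional integer id carried into the summary.
#' @return Object of class `diagnostic_summary`: list with `algorithm_id`,
#'   `n_positive`, `n_evaluable`, and `proportion_ci` fields `sensitivity`,
#'   `specificity`, `ppv`, `npv`.
#' @export
summarize_diagnostics <- function(cm, alpha = 0.05, algorithm_id = NA_integer_) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn < 1) stop("no gold-positive evaluable respondents")
  if (cm$fp + cm$tn < 1) stop("no gold-negative evaluable respondents")
  ci_or_null <- function(k, n) if (n == 0) NULL else clopper_pearson(k, n, alpha)
  structure(list(
    algorithm_id = algorithm_id,
    n_positive = cm$tp + cm$fp,
    n_evaluable = cm$tp + cm$fp + cm$tn + cm$fn,
    n_excluded = cm$n_excluded,
    sensitivity = clopper_pearson(cm$tp, cm$tp + cm$fn, alpha),
    specificity = clopper_pearson(cm$tn, cm$fp + cm$tn, alpha),
    ppv = ci_or_null(cm$tp, cm$tp + cm$fp),
    npv = ci_or_null(cm$tn, cm$tn + cm$fn)
  ), class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("<diagnostic_summary%s> n_positive=%d\n",
              if (is.na(x$algorithm_id)) "" else paste0(" alg ", x$algorithm_id),
              x$n_positive))
  cat("  sensitivity ", format_pct_ci(x$sensitivity), "\n", sep = "")
  cat("  specificity ", format_pct_ci(x$specificity), "\n", sep = "")
  cat("  ppv         ", format_pct_ci(x$ppv), "\n", sep = "")
  cat("  npv         ", format_pct_ci(x$npv), "\n", sep = "")
  invisible(x)
}

#' Reconstruct integer confusion matrices from rounded printed summaries
#'
#' Published diagnostic tables print sensitivity and specificity rounded to
#' one decimal percent. Given those rounded values and the gold-standard
#' group sizes, an exhaustive search over `tp` in `0..n_case` and `tn` in
#' `0..n_control` recovers every integer confusion matrix consistent with
#' the printed numbers, allowing the table's n-positive, PPV and NPV to be
#' verified (or refuted) without respondent-level data.
#'
#' @param sens_pct,spec_pct Printed sensitivity/specificity in percent,
#'   one decimal.
#' @param n_case Number of gold-positive respondents.
#' @param n_control Number of gold-negative respondents.
#' @return List (possibly empty, signalling inconsistent inputs) of
#'   `confusion_matrix` objects, ordered by `tp` then `tn`.
#' @export
#' @examples
#' reconstruct_confusion(89.8, 82.8, 59, 180)  # unique: tp=53 fn=6 tn=149 fp=31
reconstruct_confusion <- function(sens_pct, spec_pct, n_case, n_control) {
  stopifnot(n_case >= 1, n_control >= 1,
            sens_pct >= 0, sens_pct <= 100, spec_pct >= 0, spec_pct <= 100)
  tp_ok <- which(round_half_away(100 * (0:n_case) / n_case) == sens_pct) - 1L
  tn_ok <- which(round_half_away(100 * (0:n_control) / n_control) == spec_pct) - 1L
  out <- list()
  for (tp in tp_ok) {
    for (tn in tn_ok) {
      out[[length(out) + 1L]] <-
        confusion_cells(tp = tp, fp = n_control - tn, tn = tn,
                        fn = n_case - tp)
    }
  }
  out
}

#' Classification-statistics table for a cohort
#'
#' One row per algorithm: screen-positive count, sensitivity, specificity,
#' PPV and NPV as `point (lower, upper)` percents, plus the underlying
#' integer cells and the per-algorithm excluded count. Algorithms without
#' a transcribed rule are skipped with a message.
#'
#' @param cohort Validated cohort data frame.
#' @param algos List of algorithm definitions ([alto_algorithms()]).
#' @param policy Unsure-handling policy, see [evaluate_rule()].
#' @param alpha Significance level for the intervals.
#' @param exclusion_mode `"per_algorithm"` (default): a respondent is
#'   excluded only from algorithms whose questions they left unanswered;
#'   `"global"`: respondents missing any question used by any defined
#'   algorithm are excluded from every row.
#' @return Data frame with one row per defined algorithm.
#' @export
table3_report <- function(cohort, algos, policy = "unsure_as_not_yes",
                          alpha = 0.05,
                          exclusion_mode = c("per_algorithm", "global")) {
  exclusion_mode <- match.arg(exclusion_mode)
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1, length(algos) >= 1)
  defined <- Filter(function(a) !is.null(a$rule), algos)
  if (length(defined) == 0) stop("no algorithm has a transcribed rule")
  if (length(defined) < length(algos)) {
    message("skipping ", length(algos) - length(defined),
            " algorithm(s) without a transcribed rule")
  }
  global_req <- NULL
  if (exclusion_mode == "global") {
    global_req <- Reduce(union, lapply(defined, function(a) {
      required_questions(a$rule)
    }))
  }
  rows <- lapply(defined, function(a) {
    labels <- classify_cohort(a, cohort, policy, required = global_req)
    cm <- confusion_matrix(labels, cohort)
    s <- summarize_diagnostics(cm, alpha, algorithm_id = a$id)
    data.frame(
      algorithm = a$id,
      n_positive = s$n_positive,
      n_excluded = cm$n_excluded,
      tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
      sensitivity = format_pct_ci(s$sensitivity),
      specificity = format_pct_ci(s$specificity),
      ppv = format_pct_ci(s$ppv),
      npv = format_pct_ci(s$npv),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
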
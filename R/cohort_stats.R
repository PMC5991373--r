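#' Fisher's exact test for an r x c contingency table
#'
#' The Freeman-Halton generalisation: the p-value is the total probability,
#' under the hypergeometric distribution with fixed margins, of every table
#' whose probability does not exceed that of the observed table
#' ("probability ordering" of extremeness). Computation is delegated to the
#' network algorithm in [stats::fisher.test()]; tables with a grand total
#' above the enumeration bound must opt in to Monte-Carlo estimation.
#'
#' @param counts Integer matrix (r x c, r and c >= 2) of non-negative counts.
#' @param monte_carlo Use Monte-Carlo p-value estimation for large tables.
#' @param B Number of Monte-Carlo replicates (when `monte_carlo = TRUE`).
#' @param total_limit Grand-total bound above which exact enumeration is
#'   refused (default 500).
#' @return The p-value.
#' @export
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2))  # 2/252
fisher_exact <- function(counts, monte_carlo = FALSE, B = 1e5,
                         total_limit = 500) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) >= 2, ncol(counts) >= 2,
            all(counts >= 0), all(counts == round(counts)), sum(counts) >= 1)
  if (sum(counts) > total_limit && !monte_carlo) {
    stop("grand total ", sum(counts), " exceeds the enumeration bound (",
         total_limit, "); use monte_carlo = TRUE")
  }
  if (monte_carlo && sum(counts) > total_limit) {
    return(stats::fisher.test(counts, simulate.p.value = TRUE, B = B)$p.value)
  }
  stats::fisher.test(counts, workspace = 2e7)$p.value
}

#' One-way analysis of variance
#'
#' Classical fixed-effects between/within decomposition with the F test
#' (equal variances assumed, as in standard ANOVA tables).
#'
#' @param samples Named list of numeric vectors, one per group. `NA`
#'   observations are dropped.
#' @return List with `F`, `p`, `df_between`, `df_within`, and the group
#'   means.
#' @export
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))$F  # 3
one_way_anova <- function(samples) {
  samples <- lapply(samples, function(x) x[!is.na(x)])
  samples <- Filter(function(x) length(x) > 0, samples)
  stopifnot(length(samples) >= 2)
  if (any(vapply(samples, length, integer(1)) < 2)) {
    stop("every group needs >= 2 non-missing observations for ANOVA")
  }
  y <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), vapply(samples, length, integer(1))))
  if (stats::var(y) == 0) stop("total variance is zero; F is degenerate")
  wss <- sum(vapply(samples, function(x) sum((x - mean(x))^2), numeric(1)))
  if (wss == 0) stop("zero within-group variance; p-value is degenerate")
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = fit$p.value,
       df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]),
       means = vapply(samples, mean, numeric(1)))
}

#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, capped at 1: the exact familywise correction
#' for `m` independent comparisons, slightly less conservative than
#' Bonferroni.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`; `NA` entries (e.g.
#'   from a degenerate pairwise test) pass through unadjusted.
#' @param m Number of comparisons; must be at least `length(p)`.
#' @return Adjusted p-values.
#' @export
#' @examples
#' sidak_adjust(0.01, 3)  # 0.029701
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)),
            m >= length(p), m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

#' Participant-characteristics table with group comparisons
#'
#' Reproduces the structure of the pilot study's demographics table:
#' per-diagnosis-class n, age mean (SD) with a one-way ANOVA across
#' classes and Sidak-adjusted pairwise contrasts (Welch t tests, m = 3),
#' and sex/race counts with column percents over known values and
#' Fisher's exact test p-values. Unknown demographics never exclude a
#' respondent from anything except the cell they are unknown for.
#'
#' @param cohort Validated cohort data frame.
#' @param pairwise_test `"welch"` (default) or `"student"` two-sample t
#'   test for the pairwise age contrasts.
#' @return List of class `table1_report` with components `n`, `age`
#'   (per-class mean/sd, ANOVA results, pairwise adjusted p-values),
#'   `sex` and `race` (count tables, percents, Fisher p).
#' @export
table1_report <- function(cohort, pairwise_test = c("welch", "student")) {
  pairwise_test <- match.arg(pairwise_test)
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1)
  classes <- .diag_tokens
  cls <- factor(cohort$diagnosis, levels = classes)
  n <- table(cls)

  # age: drop unknowns; ANOVA needs >= 2 per class and non-degenerate spread
  age_by <- split(cohort$age, cls)
  age_by <- lapply(age_by, function(x) x[!is.na(x)])
  age_tab <- data.frame(
    class = classes,
    n = vapply(age_by, length, integer(1)),
    mean = vapply(age_by, function(x) if (length(x)) mean(x) else NA_real_,
                  numeric(1)),
    sd = vapply(age_by, function(x) if (length(x) > 1) stats::sd(x) else NA_real_,
                numeric(1)),
    stringsAsFactors = FALSE
  )
  testable <- Filter(function(x) length(x) >= 2, age_by)
  anova_res <- tryCatch(one_way_anova(testable),
                        error = function(e) list(F = NA_real_, p = NA_real_,
                                                 degenerate = conditionMessage(e)))
  pair_p <- NULL
  if (length(testable) >= 2) {
    prs <- utils::combn(names(testable), 2, simplify = FALSE)
    raw <- vapply(prs, function(pr) {
      a <- testable[[pr[1]]]; b <- testable[[pr[2]]]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) return(NA_real_)
      stats::t.test(a, b, var.equal = (pairwise_test == "student"))$p.value
    }, numeric(1))
    pair_p <- data.frame(
      group1 = vapply(prs, `[`, "", 1), group2 = vapply(prs, `[`, "", 2),
      p_raw = raw, p_sidak = sidak_adjust(raw, m = 3),
      stringsAsFactors = FALSE
    )
  }

  cat_block <- function(value, known_tokens) {
    keep <- value %in% known_tokens
    tab <- table(factor(value[keep], levels = known_tokens), cls[keep])
    pct <- sweep(tab, 2, pmax(colSums(tab), 1), "/") * 100
    nonzero <- tab[, colSums(tab) > 0, drop = FALSE]
    p <- if (ncol(nonzero) >= 2 && nrow(nonzero) >= 2 && sum(nonzero) >= 1) {
      fisher_exact(unclass(nonzero), monte_carlo = sum(nonzero) > 500)
    } else NA_real_
    list(counts = tab, percent = pct, p = p, n_unknown = sum(!keep))
  }

  structure(list(
    n = n,
    age = list(by_class = age_tab, anova = anova_res, pairwise = pair_p,
               n_unknown = sum(is.na(cohort$age))),
    sex = cat_block(cohort$sex, c("female", "male")),
    race = cat_block(cohort$race,
                     c("white", "african_american", "hispanic", "asian", "other"))
  ), class = "table1_report")
}

#' @export
print.table1_report <- function(x, ...) {
  cat("Participant characteristics\n")
  cat("  n per class: ", paste(names(x$n), x$n, sep = "=", collapse = ", "),
      "\n", sep = "")
  a <- x$age$by_class
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  age %-20s %.1f (%.1f), n=%d\n",
                a$class[i], a$mean[i], a$sd[i], a$n[i]))
  }
  cat(sprintf("  age ANOVA p = %s\n", format.pval(x$age$anova$p, digits = 3)))
  cat(sprintf("  sex Fisher p = %s; race Fisher p = %s\n",
              format.pval(x$sex$p, digits = 3),
              format.pval(x$race$p, digits = 3)))
  invisible(x)
}

#' Item-response breakdown by diagnosis class
#'
#' For every questionnaire item: the count and percent answering "yes"
#' (pictures: selecting each photograph or the explicit none-of-these
#' choice) per diagnosis class, with the denominator equal to the number
#' of respondents who answered the item (conditional items: among those it
#' was administered to). Includes a configurable "yes to at least one of"
#' aggregate row.
#'
#' @param cohort Validated cohort data frame.
#' @param any_of Question identifiers aggregated by the "yes to one of the
#'   above" row; default the five unconditional yes/no items Q1-Q5
#'   (aggregate denominator = class size, as in the published table).
#' @return Data frame with columns `item`, `class`, `n_yes`, `n_answered`,
#'   `pct`.
#' @export
table2_report <- function(cohort, any_of = c("Q1", "Q2", "Q3", "Q4", "Q5")) {
  stopifnot(all(any_of %in% question_ids()))
  classes <- .diag_tokens
  cls <- factor(cohort$diagnosis, levels = classes)
  rows <- list()
  add <- function(item, class, n_yes, n_answered) {
    rows[[length(rows) + 1L]] <<- data.frame(
      item = item, class = class, n_yes = n_yes, n_answered = n_answered,
      pct = ifelse(n_answered > 0,
                   round_half_away(100 * n_yes / n_answered), NA_real_),
      stringsAsFactors = FALSE
    )
  }
  for (q in c("Q1", "Q2", "Q3", "Q3A", "Q3B", "Q4", "Q5")) {
    col <- cohort[[tolower(q)]]
    administered <- if (q %in% c("Q3A", "Q3B")) cohort$q3 == "yes"
                    else rep(TRUE, nrow(cohort))
    for (cl in classes) {
      sel <- cls == cl & administered
      add(q, cl, sum(col[sel] == "yes", na.rm = TRUE),
          sum(col[sel] != "missing", na.rm = TRUE))
    }
  }
  for (cl in classes) {
    sel <- cls == cl
    any_yes <- Reduce(`|`, lapply(any_of, function(q) {
      cohort[[tolower(q)]][sel] == "yes"
    }))
    add("any_yes", cl, sum(any_yes), sum(sel))
  }
  answered <- !q6_missing(cohort$q6)
  for (p in c("A", "B", "C", "D", "E")) {
    chosen <- picture_selected(cohort$q6, p)
    for (cl in classes) {
      sel <- cls == cl
      add(paste0("pic_", p), cl, sum(chosen[sel & answered]),
          sum(sel & answered))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
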
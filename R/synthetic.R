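#' @title Synthetic ALTO pilot cohorts
#' @description
#' The pilot study's respondent-level data are not deposited; the published
#' report prints only class sizes, per-class item-response marginals and
#' item-level missingness. The generator here draws seeded synthetic
#' cohorts with exactly that structure - three diagnosis classes
#' (totalis/universalis n=13, patchy n=46, other hair loss n=180),
#' per-class yes-probabilities for each item, conditional administration of
#' the Q3A/Q3B follow-ups, multi-select picture responses, and
#' missing-completely-at-random item blanks - so every downstream stage of
#' the pipeline can be exercised without patient data. Within a class,
#' items are conditionally independent apart from the skip-logic and
#' "universal body hair loss implies complete scalp loss" (Q5 => Q4)
#' constraints; dependence between the prior-diagnosis items (Q1/Q2) and
#' Q3 can be introduced via a per-class copula weight, which is what
#' [calibrate_spec()] tunes.
#' @name synthetic-cohort
NULL

class_profile <- function(class, n, age_mean, age_sd, p_female, race_probs,
                          p_yes, pic_probs, p_pic_none, missing,
                          p_not_sure = NULL, p_age_unknown = 0,
                          p_sex_unknown = 0, p_race_unknown = 0, rho = 0) {
  qs <- c("Q1", "Q2", "Q3", "Q3A", "Q3B", "Q4", "Q5")
  if (is.null(p_not_sure)) p_not_sure <- stats::setNames(rep(0, 7), qs)
  stopifnot(
    class %in% .diag_tokens, n >= 1,
    setequal(names(p_yes), qs), all(p_yes >= 0 & p_yes <= 1),
    all(p_not_sure >= 0), all(p_yes[qs] + p_not_sure[qs] <= 1),
    setequal(names(pic_probs), c("A", "B", "C", "D")),
    p_pic_none >= 0, p_pic_none < 1,
    all(pic_probs >= 0), all(pic_probs / (1 - p_pic_none) <= 1),
    setequal(names(missing), c(qs, "Q6")), all(missing >= 0 & missing < 1),
    rho >= 0, rho <= 1,
    abs(sum(race_probs) - 1) < 1e-9
  )
  if (p_yes[["Q4"]] < p_yes[["Q5"]]) {
    stop("p_yes[Q4] must be >= p_yes[Q5] (complete body hair loss implies ",
         "complete scalp hair loss)")
  }
  list(class = class, n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
       p_female = p_female, race_probs = race_probs, p_yes = p_yes,
       p_not_sure = p_not_sure, pic_probs = pic_probs, p_pic_none = p_pic_none,
       missing = missing, p_age_unknown = p_age_unknown,
       p_sex_unknown = p_sex_unknown, p_race_unknown = p_race_unknown,
       rho = rho)
}

#' Default synthetic-cohort specification
#'
#' Generative parameters taken from the pilot study's printed summaries:
#' class sizes 13/46/180, per-class item yes-fractions with the
#' denominators the printed percentages imply (conditional items as rates
#' among those administered and answering), picture-selection inclusion
#' fractions among respondents who completed the picture item, per-item
#' missingness rates mirroring the printed denominators, and demographic
#' distributions (truncated-normal ages, sex, race) from the
#' participant-characteristics table.
#'
#' @param seed Default seed stored in the spec (an integer).
#' @return Object of class `cohort_spec`: list with `profiles` (one per
#'   diagnosis class) and `seed`.
#' @export
#' @examples
#' spec <- default_cohort_spec()
#' vapply(spec$profiles, `[[`, integer(1), "n")  # 13 46 180
default_cohort_spec <- function(seed = 20180606) {
  qs <- c("Q1", "Q2", "Q3", "Q3A", "Q3B", "Q4", "Q5")
  p <- function(...) stats::setNames(c(...), qs)
  m <- function(...) stats::setNames(c(...), c(qs, "Q6"))
  races <- c("white", "african_american", "hispanic", "asian", "other")
  profiles <- list(
    class_profile(
      class = "totalis_universalis", n = 13,
      age_mean = 55.3, age_sd = 12.8, p_female = 9 / 13,
      race_probs = stats::setNames(c(8, 2, 0, 1, 0) / 11, races),
      p_race_unknown = 2 / 13,
      p_yes = p(13 / 13, 5 / 12, 13 / 13, 8 / 13, 10 / 11, 12 / 13, 11 / 13),
      pic_probs = c(A = 4 / 13, B = 1 / 13, C = 11 / 13, D = 3 / 13),
      p_pic_none = 0,
      missing = m(0, 1 / 13, 0, 0, 2 / 13, 0, 0, 0)
    ),
    class_profile(
      class = "patchy", n = 46,
      age_mean = 39.8, age_sd = 14.4, p_female = 37 / 46,
      race_probs = stats::setNames(c(25, 8, 7, 2, 0) / 42, races),
      p_race_unknown = 4 / 46,
      p_yes = p(44 / 46, 19 / 45, 42 / 46, 38 / 42, 26 / 40, 2 / 45, 1 / 45),
      pic_probs = c(A = 27 / 46, B = 8 / 46, C = 3 / 46, D = 35 / 46),
      p_pic_none = 1 / 46,
      missing = m(0, 1 / 46, 0, 0, 2 / 42, 1 / 46, 1 / 46, 0)
    ),
    class_profile(
      class = "other_hair_loss", n = 180,
      age_mean = 49.5, age_sd = 15.2, p_female = 167 / 179,
      p_age_unknown = 1 / 180, p_sex_unknown = 1 / 180,
      race_probs = stats::setNames(c(123, 31, 8, 9, 2) / 173, races),
      p_race_unknown = 7 / 180,
      p_yes = p(29 / 179, 7 / 175, 58 / 178, 21 / 55, 40 / 50, 7 / 180, 6 / 177),
      pic_probs = c(A = 8 / 74, B = 4 / 74, C = 0, D = 30 / 74),
      p_pic_none = 27 / 74,
      missing = m(1 / 180, 5 / 180, 2 / 180, 3 / 58, 8 / 58, 0, 3 / 180,
                  106 / 180)
    )
  )
  structure(list(profiles = profiles, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  sizes <- vapply(x$profiles, `[[`, integer(1), "n")
  cat("<cohort_spec> classes: ",
      paste(vapply(x$profiles, `[[`, "", "class"), sizes,
            sep = "=", collapse = ", "),
      " (total ", sum(sizes), "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# draw yes/not_sure/no from a single uniform
answer_from_u <- function(u, p_yes, p_ns) {
  ifelse(u < p_yes, "yes", ifelse(u < p_yes + p_ns, "not_sure", "no"))
}

generate_class <- function(profile, prefix) {
  n <- profile$n
  py <- profile$p_yes
  pns <- profile$p_not_sure
  rho <- profile$rho

  # Q1/Q2 optionally share Q3's latent uniform (comonotone coupling with
  # probability rho), preserving all marginals
  u3 <- stats::runif(n)
  coupled <- stats::runif(n) < rho
  u1 <- ifelse(coupled, u3, stats::runif(n))
  u2 <- ifelse(coupled, u3, stats::runif(n))
  q3 <- answer_from_u(u3, py[["Q3"]], pns[["Q3"]])
  q1 <- answer_from_u(u1, py[["Q1"]], pns[["Q1"]])
  q2 <- answer_from_u(u2, py[["Q2"]], pns[["Q2"]])

  # Q5 = yes forces Q4 = yes; Q4 among the rest uses the residual
  # probability so the Q4 marginal still equals p_yes[Q4]
  q5 <- answer_from_u(stats::runif(n), py[["Q5"]], pns[["Q5"]])
  p4_resid <- (py[["Q4"]] - py[["Q5"]]) / (1 - py[["Q5"]])
  pns4_resid <- min(pns[["Q4"]] / (1 - py[["Q5"]]), 1 - p4_resid)
  q4 <- ifelse(q5 == "yes", "yes",
               answer_from_u(stats::runif(n), p4_resid, pns4_resid))

  # conditional follow-ups, administered only after an affirmative Q3
  administered <- q3 == "yes"
  q3a <- rep("missing", n)
  q3b <- rep("missing", n)
  q3a[administered] <- answer_from_u(stats::runif(sum(administered)),
                                     py[["Q3A"]], pns[["Q3A"]])
  q3b[administered] <- answer_from_u(stats::runif(sum(administered)),
                                     py[["Q3B"]], pns[["Q3B"]])

  # picture item: blank (missing), else the explicit E choice, else
  # independent photo inclusions scaled so the marginal among answered
  # respondents equals the target; a draw with no photo and no E is an
  # answered-but-empty selection, a state the published denominators imply
  # (non-E selections sum to fewer than the non-E answerers)
  q6 <- rep("missing", n)
  pic_answered <- stats::runif(n) >= profile$missing[["Q6"]]
  is_e <- pic_answered & (stats::runif(n) < profile$p_pic_none)
  q6[is_e] <- "E"
  need <- which(pic_answered & !is_e)
  if (length(need) > 0) {
    q_incl <- profile$pic_probs / (1 - profile$p_pic_none)
    draws <- matrix(stats::runif(4 * length(need)), ncol = 4)
    q6[need] <- vapply(seq_along(need), function(j) {
      sel <- c("A", "B", "C", "D")[draws[j, ] < q_incl]
      if (length(sel) == 0) "none" else paste(sel, collapse = ";")
    }, character(1))
  }

  # item-level MCAR missingness (Q3A/Q3B rates are conditional on
  # administration); a masked Q3 takes its follow-ups with it (skip logic)
  mask <- function(ans, rate, eligible = rep(TRUE, n)) {
    hit <- eligible & (stats::runif(n) < rate)
    ans[hit] <- "missing"
    ans
  }
  q1 <- mask(q1, profile$missing[["Q1"]])
  q2 <- mask(q2, profile$missing[["Q2"]])
  q3 <- mask(q3, profile$missing[["Q3"]])
  q4 <- mask(q4, profile$missing[["Q4"]])
  q5 <- mask(q5, profile$missing[["Q5"]])
  q3a <- mask(q3a, profile$missing[["Q3A"]], administered)
  q3b <- mask(q3b, profile$missing[["Q3B"]], administered)
  lost <- administered & q3 != "yes"
  q3a[lost] <- "missing"
  q3b[lost] <- "missing"

  # demographics: truncated-normal age (study eligibility: 18 and older)
  age <- numeric(n)
  todo <- rep(TRUE, n)
  while (any(todo)) {
    age[todo] <- stats::rnorm(sum(todo), profile$age_mean, profile$age_sd)
    todo <- age < 18
  }
  age <- as.integer(round(age))
  age[stats::runif(n) < profile$p_age_unknown] <- NA_integer_
  sex <- ifelse(stats::runif(n) < profile$p_female, "female", "male")
  sex[stats::runif(n) < profile$p_sex_unknown] <- "unknown"
  race <- sample(names(profile$race_probs), n, replace = TRUE,
                 prob = profile$race_probs)
  race[stats::runif(n) < profile$p_race_unknown] <- "unknown"

  data.frame(
    id = sprintf("%s-%03d", prefix, seq_len(n)),
    age = age, sex = sex, race = race,
    diagnosis = profile$class, diagnosis_label = NA_character_,
    q1 = q1, q2 = q2, q3 = q3, q3a = q3a, q3b = q3b, q4 = q4, q5 = q5,
    q6 = q6, stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort
#'
#' Draws one cohort from a [default_cohort_spec()]-style specification.
#' Fully reproducible: the same spec and seed give byte-identical cohorts.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed overriding `spec$seed`.
#' @return Validated cohort data frame with `sum(n)` rows, classes in spec
#'   order.
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(), seed = 1)
#' table(cohort$diagnosis)
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  prefixes <- c(totalis_universalis = "tu", patchy = "pa",
                other_hair_loss = "oh")
  out <- do.call(rbind, lapply(spec$profiles, function(pr) {
    generate_class(pr, prefixes[[pr$class]])
  }))
  rownames(out) <- NULL
  out
}

#' Mean simulated operating points of scoring algorithms
#'
#' Generates `replicates` cohorts and averages each algorithm's observed
#' sensitivity and specificity (percent scale).
#'
#' @param spec A `cohort_spec`.
#' @param algos Algorithm definitions; placeholder (untranscribed) entries
#'   are skipped.
#' @param replicates Number of simulated cohorts.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param policy Unsure-handling policy.
#' @return Data frame: `algorithm`, `sensitivity`, `specificity`,
#'   `n_positive` (means over replicates, percents to full precision).
#' @export
simulated_operating_points <- function(spec, algos, replicates = 50,
                                       seed = spec$seed,
                                       policy = "unsure_as_not_yes") {
  defined <- Filter(function(a) !is.null(a$rule), algos)
  stopifnot(length(defined) >= 1, replicates >= 1)
  acc <- array(0, dim = c(length(defined), 3))
  for (r in seq_len(replicates)) {
    cohort <- generate_cohort(spec, seed = as.integer(seed) + r)
    for (j in seq_along(defined)) {
      labels <- classify_cohort(defined[[j]], cohort, policy)
      cm <- confusion_matrix(labels, cohort)
      acc[j, ] <- acc[j, ] + c(100 * cm$tp / (cm$tp + cm$fn),
                               100 * cm$tn / (cm$fp + cm$tn),
                               cm$tp + cm$fp)
    }
  }
  acc <- acc / replicates
  data.frame(
    algorithm = vapply(defined, `[[`, integer(1), "id"),
    sensitivity = acc[, 1], specificity = acc[, 2], n_positive = acc[, 3]
  )
}

#' Calibrate within-class dependence toward target operating points
#'
#' The joint item-response distribution is unidentified from published
#' marginals; this stochastic search tunes the per-class copula weight
#' coupling Q1/Q2 with Q3 (the only dependence parameter the generator
#' exposes) so that simulated mean sensitivity/specificity of the target
#' algorithms move closer to the supplied targets. Hill-climbing with
#' common random numbers: a proposal is accepted only if it improves the
#' mean absolute deviation, so the returned spec is never worse than the
#' input under the same evaluation seeds. Class sizes and all marginal
#' probabilities are never altered. No optimality is claimed.
#'
#' @param spec Starting `cohort_spec`.
#' @param targets Data frame with columns `algorithm`, `sensitivity`,
#'   `specificity` (percent scale).
#' @param algos Algorithm definitions.
#' @param iterations Number of proposals (0 returns `spec` unchanged).
#' @param seed Integer seed for the search and its simulations.
#' @param replicates Simulated cohorts per objective evaluation.
#' @return A `cohort_spec` with (possibly) updated per-class `rho`, and
#'   attributes `objective_start` / `objective_final`.
#' @export
calibrate_spec <- function(spec, targets, algos, iterations = 40,
                           seed = spec$seed, replicates = 12) {
  stopifnot(inherits(spec, "cohort_spec"),
            all(c("algorithm", "sensitivity", "specificity") %in% names(targets)),
            iterations >= 0)
  defined_ids <- vapply(Filter(function(a) !is.null(a$rule), algos),
                        `[[`, integer(1), "id")
  use <- targets$algorithm %in% defined_ids
  if (!any(use)) stop("no target references an algorithm with a defined rule")
  targets <- targets[use, , drop = FALSE]
  target_algos <- Filter(function(a) a$id %in% targets$algorithm, algos)
  if (iterations == 0) return(spec)

  objective <- function(s, eval_seed) {
    sim <- simulated_operating_points(s, target_algos, replicates = replicates,
                                      seed = eval_seed)
    sim <- sim[match(targets$algorithm, sim$algorithm), ]
    mean(abs(sim$sensitivity - targets$sensitivity) +
           abs(sim$specificity - targets$specificity))
  }
  with_rho <- function(s, rho) {
    for (i in seq_along(s$profiles)) s$profiles[[i]]$rho <- rho[i]
    s
  }

  eval_seed <- as.integer(seed) %% 100000L + 1L
  rho <- vapply(spec$profiles, `[[`, numeric(1), "rho")
  best <- objective(spec, eval_seed)
  start <- best
  set.seed(as.integer(seed))
  prop_noise <- stats::rnorm(iterations * length(rho), 0, 0.15)
  for (it in seq_len(iterations)) {
    delta <- prop_noise[((it - 1) * length(rho) + 1):(it * length(rho))]
    cand_rho <- pmin(1, pmax(0, rho + delta))
    cand <- objective(with_rho(spec, cand_rho), eval_seed)
    if (cand < best) {
      best <- cand
      rho <- cand_rho
    }
  }
  out <- with_rho(spec, rho)
  attr(out, "objective_start") <- start
  attr(out, "objective_final") <- best
  out
}
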
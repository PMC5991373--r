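# Builders and independent oracles used across the suite.

# One-row validated cohort data frame with given answers; defaults are a
# fully "no" respondent with an answered-but-empty picture item.
make_resp <- function(id = "r1", diagnosis = "patchy", age = 40L,
                      sex = "female", race = "white",
                      q1 = "no", q2 = "no", q3 = "no", q3a = "missing",
                      q3b = "missing", q4 = "no", q5 = "no", q6 = "none") {
  data.frame(id = id, age = age, sex = sex, race = race,
             diagnosis = diagnosis, diagnosis_label = NA_character_,
             q1 = q1, q2 = q2, q3 = q3, q3a = q3a, q3b = q3b,
             q4 = q4, q5 = q5, q6 = q6, stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Random respondent with arbitrary (possibly skip-logic-violating) raw fields,
# for property tests through validate_respondent().
random_raw_record <- function(id) {
  tok <- c("yes", "no", "not_sure", "", "maybe")
  pics <- c("", "E", "A", "C;D", "A;B;C;D", "none", "bogus")
  list(id = id,
       age = sample(c(18:90, NA), 1),
       sex = sample(c("female", "male", "unknown", "x"), 1),
       race = sample(c("white", "asian", "unknown", ""), 1),
       diagnosis = sample(c("totalis_universalis", "patchy", "other_hair_loss"), 1),
       q1 = sample(tok, 1), q2 = sample(tok, 1), q3 = sample(tok, 1),
       q3a = sample(tok, 1), q3b = sample(tok, 1),
       q4 = sample(tok, 1), q5 = sample(tok, 1),
       q6 = sample(pics, 1))
}

# Random validated respondent (direct construction, already skip-consistent
# unless violate = TRUE).
random_resp <- function(id, p_missing = 0.15) {
  tok <- function() sample(c("yes", "no", "not_sure", "missing"), 1,
                           prob = c(0.4, 0.3, 0.15, p_missing))
  q3 <- tok()
  adm <- identical(q3, "yes")
  make_resp(id = id,
            diagnosis = sample(c("totalis_universalis", "patchy",
                                 "other_hair_loss"), 1),
            q1 = tok(), q2 = tok(), q3 = q3,
            q3a = if (adm) tok() else "missing",
            q3b = if (adm) tok() else "missing",
            q4 = tok(), q5 = tok(),
            q6 = sample(c("missing", "E", "none", "A", "B", "C", "D",
                          "A;C", "B;D", "A;B;C;D"), 1))
}

# --- Independent rule-evaluation oracle ------------------------------------
# Translates the rule DSL text into a plain R logical expression and eval()s
# it against atom truth values; R's native & and | implement Kleene
# three-valued logic over NA, so this shares no code with the package's
# recursive tree evaluator.
oracle_evaluate <- function(rule_text, resp, policy = "unsure_as_not_yes") {
  atom_val <- function(q) {
    ans <- resp[[tolower(q)]]
    if (policy == "unsure_as_not_yes") return(ans == "yes")
    if (ans == "yes") TRUE else if (ans == "no") FALSE else NA
  }
  pic_val <- function(sel) {
    if (policy == "unsure_as_missing" && altoscreen::q6_missing(resp$q6)) {
      return(NA)
    }
    altoscreen::picture_selected(resp$q6, sel)
  }
  e <- rule_text
  e <- gsub("any\\(", "(", e)
  e <- gsub(",", "|", e)
  e <- gsub("pic\\(\\s*([A-Ea-e])\\s*\\)", "pic_val('\\1')", e)
  e <- gsub("(Q3A|Q3B|Q[1-5])", "atom_val('\\1')", e, ignore.case = TRUE)
  v <- eval(parse(text = e))
  if (is.na(v)) "indeterminate" else if (v) "positive" else "negative"
}

# --- Independent Clopper-Pearson oracle ------------------------------------
# Inverts the binomial tail sums by bisection: the lower bound is the p with
# P(X >= k | p) = alpha/2, the upper the p with P(X <= k | p) = alpha/2.
oracle_cp <- function(k, n, alpha = 0.05, tol = 1e-12) {
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else {
    bisect(function(p) sum(stats::dbinom(k:n, n, p)) - alpha / 2, 0, 1)
  }
  upper <- if (k == n) 1 else {
    bisect(function(p) alpha / 2 - sum(stats::dbinom(0:k, n, p)), 0, 1)
  }
  c(lower = lower, upper = upper)
}

# --- Independent Fisher-exact oracle ---------------------------------------
# Full enumeration of all tables with the observed margins; p = total
# hypergeometric probability of tables no more probable than the observed
# one (Freeman-Halton probability ordering). Handles r x c via recursive
# cell filling.
oracle_fisher <- function(counts) {
  counts <- as.matrix(counts)
  rs <- rowSums(counts)
  cs <- colSums(counts)
  n <- sum(counts)
  log_p <- function(tab) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
      sum(lgamma(tab + 1))
  }
  r <- nrow(counts); cc <- ncol(counts)
  obs <- log_p(counts)
  total <- 0
  fill <- function(tab, i, j, row_left, col_left) {
    if (i == r && j == cc) {
      tab[i, j] <- row_left[i]
      if (row_left[i] != col_left[j]) return()
      lp <- log_p(tab)
      if (lp <= obs + 1e-7) total <<- total + exp(lp)
      return()
    }
    if (j == cc) {                       # last column forced by row margin
      v <- row_left[i]
      if (v > col_left[j]) return()
      tab[i, j] <- v
      col_left[j] <- col_left[j] - v
      row_left[i] <- 0
      fill(tab, i + 1, 1, row_left, col_left)
      return()
    }
    if (i == r) {                        # last row forced by column margin
      v <- col_left[j]
      if (v > row_left[i]) return()
      tab[i, j] <- v
      row_left[i] <- row_left[i] - v
      col_left[j] <- 0
      fill(tab, i, j + 1, row_left, col_left)
      return()
    }
    for (v in 0:min(row_left[i], col_left[j])) {
      tab[i, j] <- v
      rl <- row_left; rl[i] <- rl[i] - v
      cl <- col_left; cl[j] <- cl[j] - v
      fill(tab, i, j + 1, rl, cl)
    }
  }
  fill(matrix(0L, r, cc), 1, 1, rs, cs)
  min(1, total)
}

# --- Independent one-way ANOVA oracle --------------------------------------
oracle_anova <- function(samples) {
  y <- unlist(samples)
  k <- length(samples)
  grand <- mean(y)
  ssb <- sum(vapply(samples, function(x) length(x) * (mean(x) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(samples, function(x) sum((x - mean(x))^2), numeric(1)))
  df1 <- k - 1
  df2 <- length(y) - k
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df_between = df1, df_within = df2)
}
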
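#' @title Boolean scoring rules for the ALTO
#' @description
#' Each ALTO scoring algorithm is a monotone boolean expression over
#' questionnaire atoms: an atom `Qx` is true iff the respondent answered
#' "yes" to item Qx, and `pic(X)` is true iff photograph X was selected in
#' Q6 (`pic(E)`: the explicit "no representative photographs" choice).
#' Rules are written in a small DSL with operators `&`, `|`, the n-ary
#' `any(...)` (semantically an OR, kept for readability of the published
#' algorithm descriptions), and parentheses.
#' @name rule-dsl
NULL

.atom_names <- c("Q1", "Q2", "Q3", "Q3A", "Q3B", "Q4", "Q5")
.pic_names <- c("A", "B", "C", "D", "E")

## Parser --------------------------------------------------------------------

tokenize_rule <- function(text) {
  pat <- "\\s*(any|pic\\(\\s*[A-Ea-e]\\s*\\)|Q3A|Q3B|Q[1-5]|[&|(),])"
  toks <- list()
  pos <- 1L
  s <- text
  while (nchar(trimws(s)) > 0) {
    m <- regexpr(pat, s, ignore.case = TRUE)
    if (m != 1L) {
      stop("rule syntax error at position ", pos + attr(m, "match.length"),
           ": cannot tokenize ", deparse(trimws(s)))
    }
    len <- attr(m, "match.length")
    tok <- trimws(substr(s, 1, len))
    toks[[length(toks) + 1L]] <- list(text = tok, pos = pos)
    pos <- pos + len
    s <- substr(s, len + 1L, nchar(s))
  }
  toks
}

#' Parse a rule expression
#'
#' Grammar: `expr := term ('|' term)*`; `term := factor ('&' factor)*`;
#' `factor := atom | pic(X) | any(atom, ...) | '(' expr ')'`.
#'
#' @param text Rule string, e.g. `"(Q1|Q2)&Q3&any(Q3A,Q3B,Q4,Q5)"`.
#' @return An object of class `alto_rule`: a nested list of nodes with
#'   `kind` in `atom`, `atom_pic`, `and`, `or`, `any`.
#' @export
#' @examples
#' r <- parse_rule("Q3 & any(Q3A, Q3B, Q4, Q5)")
#' format(r)
parse_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1, nzchar(trimws(text)))
  toks <- tokenize_rule(text)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]]$text else NULL
  advance <- function() {
    t <- toks[[i]]
    i <<- i + 1L
    t
  }
  expect <- function(what) {
    t <- peek()
    if (is.null(t) || t != what) {
      at <- if (i <= length(toks)) toks[[i]]$pos else nchar(text) + 1L
      stop("rule syntax error at position ", at, ": expected '", what, "'")
    }
    advance()
  }
  parse_atom <- function() {
    t <- peek()
    if (is.null(t)) stop("rule syntax error: unexpected end of input")
    up <- toupper(t)
    if (up %in% .atom_names) {
      advance()
      return(rule_atom(up))
    }
    if (grepl("^PIC\\(", up)) {
      advance()
      sel <- toupper(gsub("[^A-Ea-e]", "", sub("^pic", "", t, ignore.case = TRUE)))
      if (!(sel %in% .pic_names)) {
        stop("unknown picture atom: ", t)
      }
      return(rule_pic(sel))
    }
    stop("rule syntax error at position ", toks[[i]]$pos,
         ": unknown atom ", deparse(t))
  }
  parse_factor <- function() {
    t <- peek()
    if (identical(t, "(")) {
      advance()
      node <- parse_expr()
      expect(")")
      return(node)
    }
    if (!is.null(t) && tolower(t) == "any") {
      advance()
      expect("(")
      children <- list(parse_atom())
      while (identical(peek(), ",")) {
        advance()
        children[[length(children) + 1L]] <- parse_atom()
      }
      expect(")")
      return(structure(list(kind = "any", children = children),
                       class = "alto_rule"))
    }
    parse_atom()
  }
  parse_term <- function() {
    children <- list(parse_factor())
    while (identical(peek(), "&")) {
      advance()
      children[[length(children) + 1L]] <- parse_factor()
    }
    if (length(children) == 1L) children[[1L]]
    else structure(list(kind = "and", children = children), class = "alto_rule")
  }
  parse_expr <- function() {
    children <- list(parse_term())
    while (identical(peek(), "|")) {
      advance()
      children[[length(children) + 1L]] <- parse_term()
    }
    if (length(children) == 1L) children[[1L]]
    else structure(list(kind = "or", children = children), class = "alto_rule")
  }
  node <- parse_expr()
  if (i <= length(toks)) {
    stop("rule syntax error at position ", toks[[i]]$pos,
         ": unexpected ", deparse(toks[[i]]$text))
  }
  node
}

rule_atom <- function(q) {
  structure(list(kind = "atom", question = q), class = "alto_rule")
}
rule_pic <- function(sel) {
  structure(list(kind = "atom_pic", selection = sel), class = "alto_rule")
}

#' @export
format.alto_rule <- function(x, ...) {
  switch(x$kind,
    atom = x$question,
    atom_pic = paste0("pic(", x$selection, ")"),
    any = paste0("any(", paste(vapply(x$children, format, ""), collapse = ", "), ")"),
    and = paste0("(", paste(vapply(x$children, format, ""), collapse = " & "), ")"),
    or = paste0("(", paste(vapply(x$children, format, ""), collapse = " | "), ")"),
    stop("unknown node kind: ", x$kind)
  )
}

#' @export
print.alto_rule <- function(x, ...) {
  cat("<alto_rule> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Questions referenced by a rule
#'
#' Picture atoms map to Q6 (the picture item as a whole must be answered
#' for any `pic()` atom to be assessable).
#'
#' @param rule An `alto_rule`.
#' @return Character vector of question identifiers, in instrument order.
#' @export
required_questions <- function(rule) {
  collect <- function(node) {
    switch(node$kind,
      atom = node$question,
      atom_pic = "Q6",
      unlist(lapply(node$children, collect))
    )
  }
  ids <- question_ids()
  ids[ids %in% unique(collect(rule))]
}

## Evaluation ----------------------------------------------------------------

.unsure_policies <- c("unsure_as_not_yes", "unsure_as_missing")

# atom truth value for one respondent row; three-valued under unsure_as_missing
atom_value <- function(node, resp, policy) {
  if (node$kind == "atom_pic") {
    if (policy == "unsure_as_missing" && q6_missing(resp$q6)) return(NA)
    return(picture_selected(resp$q6, node$selection))
  }
  ans <- resp[[tolower(node$question)]]
  if (policy == "unsure_as_not_yes") return(ans == "yes")
  if (ans == "yes") TRUE else if (ans == "no") FALSE else NA
}

eval_node <- function(node, resp, policy) {
  switch(node$kind,
    atom = ,
    atom_pic = atom_value(node, resp, policy),
    and = {
      vals <- vapply(node$children, function(ch) {
        v <- eval_node(ch, resp, policy)
        if (is.na(v)) NA else v
      }, logical(1))
      Reduce(`&`, vals)  # Kleene: FALSE dominates NA
    },
    or = ,
    any = {
      vals <- vapply(node$children, function(ch) {
        v <- eval_node(ch, resp, policy)
        if (is.na(v)) NA else v
      }, logical(1))
      Reduce(`|`, vals)  # Kleene: TRUE dominates NA
    },
    stop("unknown node kind: ", node$kind)
  )
}

#' Evaluate a rule for one respondent
#'
#' Under the default `unsure_as_not_yes` policy, anything that is not an
#' affirmative "yes" (including "not sure", a missing answer, and a
#' non-administered conditional item) makes the atom false, so the verdict
#' is always `positive` or `negative`. Under `unsure_as_missing`, "not
#' sure" and missing answers enter as unknowns in Kleene three-valued
#' logic, and the verdict is `indeterminate` when an unknown is decisive.
#'
#' @param rule An `alto_rule`.
#' @param resp One-row validated cohort data frame.
#' @param policy `"unsure_as_not_yes"` (default) or `"unsure_as_missing"`.
#' @return `"positive"`, `"negative"`, or `"indeterminate"`.
#' @export
evaluate_rule <- function(rule, resp, policy = c("unsure_as_not_yes",
                                                 "unsure_as_missing")) {
  policy <- match.arg(policy)
  stopifnot(inherits(rule, "alto_rule"), nrow(resp) == 1)
  v <- eval_node(rule, resp, policy)
  if (is.na(v)) "indeterminate" else if (v) "positive" else "negative"
}

#' Classify a cohort with one scoring algorithm
#'
#' Respondents who did not answer every question the algorithm uses (among
#' those applicable to them under skip logic) are `excluded`, mirroring the
#' study's missing-data rule; the rest are screened `positive` or
#' `negative`.
#'
#' @param algo An algorithm definition from [alto_algorithms()], or a bare
#'   `alto_rule`.
#' @param cohort Validated cohort data frame.
#' @param policy Unsure-handling policy, see [evaluate_rule()].
#' @param required Question set that must be answered; defaults to
#'   [required_questions()] of the rule. Pass a union over several
#'   algorithms to apply a single global exclusion rule instead of the
#'   default per-algorithm one.
#' @return Named character vector (names = respondent ids) with values in
#'   `positive`, `negative`, `excluded`.
#' @export
classify_cohort <- function(algo, cohort, policy = "unsure_as_not_yes",
                            required = NULL) {
  rule <- if (inherits(algo, "alto_rule")) algo else algo$rule
  if (is.null(rule)) {
    stop("algorithm ", if (!inherits(algo, "alto_rule")) algo$id else "",
         " has no transcribed rule; it cannot classify respondents")
  }
  stopifnot(inherits(rule, "alto_rule"), is.data.frame(cohort),
            nrow(cohort) >= 1)
  if (is.null(required)) required <- required_questions(rule)
  if (length(required) == 0) stop("rule references no questions")
  out <- vapply(seq_len(nrow(cohort)), function(i) {
    resp <- cohort[i, , drop = FALSE]
    if (!is_evaluable(resp, required)) "excluded"
    else evaluate_rule(rule, resp, policy)
  }, character(1))
  names(out) <- cohort$id
  out
}

## Shipped algorithm definitions ---------------------------------------------

# The three algorithms stated in the running text of the study report.
# Loading refuses definition files in which these have been edited.
.text_verified_rules <- c(
  "1" = "(Q1 | Q2) & Q3 & any(Q3A, Q3B, Q4, Q5)",
  "3" = "(Q1 | Q2) & Q3 & Q3A & any(Q3B, Q4, Q5)",
  "5" = "Q3 & any(Q3A, Q3B, Q4, Q5)"
)

#' Load the nine ALTO scoring-algorithm definitions
#'
#' Definitions are read from a JSON array of
#' `{"id", "rule", "description", "source_confidence"}` records. Algorithms
#' 1, 3 and 5 are stated in the running text of the study report and must
#' match the package's hard-coded rules structurally; loading fails
#' otherwise. The remaining algorithms were published only as a figure and
#' ship as placeholders (`rule = NULL`, `source_confidence =
#' "figure_transcribed"`) that raise an error if used to classify, rather
#' than silently guessing a rule.
#'
#' @param file Path to a definitions JSON file; default is the file shipped
#'   with the package.
#' @return List of nine algorithm definitions (class `alto_algorithm`),
#'   each with `id`, `rule` (an `alto_rule` or `NULL`), `description`,
#'   `source_confidence`.
#' @export
#' @examples
#' algos <- alto_algorithms()
#' format(algos[[1]]$rule)
alto_algorithms <- function(file = system.file("extdata", "algorithms.json",
                                               package = "altoscreen")) {
  defs <- jsonlite::fromJSON(file, simplifyDataFrame = FALSE)
  if (length(defs) != 9) {
    stop("expected 9 algorithm definitions, got ", length(defs))
  }
  ids <- vapply(defs, function(d) as.integer(d$id), integer(1))
  if (anyDuplicated(ids) || !setequal(ids, 1:9)) {
    stop("algorithm ids must be exactly 1..9; got ",
         paste(sort(ids), collapse = ", "))
  }
  out <- lapply(defs, function(d) {
    id <- as.integer(d$id)
    rule <- if (is.null(d$rule)) NULL else parse_rule(d$rule)
    key <- as.character(id)
    if (key %in% names(.text_verified_rules)) {
      ref <- parse_rule(.text_verified_rules[[key]])
      if (is.null(rule) || !identical(unclass_rule(rule), unclass_rule(ref))) {
        stop("algorithm ", id, " is text-verified and its rule was edited; ",
             "expected ", format(ref))
      }
      conf <- "text_verified"
    } else {
      conf <- "figure_transcribed"
    }
    if (!is.null(d$source_confidence) && d$source_confidence != conf) {
      stop("algorithm ", id, " has source_confidence '", d$source_confidence,
           "' but must be '", conf, "'")
    }
    structure(list(id = id, rule = rule,
                   description = d$description %||% "",
                   source_confidence = conf),
              class = "alto_algorithm")
  })
  out[order(ids)]
}

# strip classes recursively so identical() compares structure only
unclass_rule <- function(node) {
  node <- unclass(node)
  if (!is.null(node$children)) node$children <- lapply(node$children, unclass_rule)
  node
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.alto_algorithm <- function(x, ...) {
  cat("<alto_algorithm ", x$id, "> [", x$source_confidence, "] ",
      if (is.null(x$rule)) "(rule not transcribed)" else format(x$rule),
      "\n", sep = "")
  invisible(x)
}
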
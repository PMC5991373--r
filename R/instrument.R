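#' ALTO questionnaire schema
#'
#' The ALTO instrument has eight closed-ended items. Q1/Q2 ask about a prior
#' diagnosis of alopecia areata (by a dermatologist / by another healthcare
#' professional), Q3 about round areas of hair loss on the face or scalp,
#' Q3A (hair grew back) and Q3B (hair loss lasted longer than 6 months) are
#' follow-ups administered only when Q3 is answered "yes", Q4 asks about
#' complete scalp hair loss, Q5 about complete hair loss on head and body,
#' and Q6 is a picture-selection item (photographs A-D plus an explicit
#' "no representative photographs" choice, E).
#'
#' @return An object of class `alto_schema`: a list with `items` (ordered
#'   question identifiers with display prompts) and `conditional_on`
#'   (named character vector mapping a conditional child to its parent item).
#' @export
#' @examples
#' sch <- alto_schema()
#' sch$conditional_on
alto_schema <- function() {
  items <- data.frame(
    id = c("Q1", "Q2", "Q3", "Q3A", "Q3B", "Q4", "Q5", "Q6"),
    prompt = c(
      "Diagnosed with alopecia areata by a dermatologist",
      "Diagnosed with alopecia areata by a non-dermatologist healthcare professional",
      "Round areas of hair loss on face or scalp",
      "Hair grew back",
      "Hair loss lasted longer than 6 months",
      "Complete hair loss on scalp",
      "Complete hair loss on head and body",
      "Picture selection (A-D, or E: no representative photographs)"
    ),
    stringsAsFactors = FALSE
  )
  structure(
    list(items = items, conditional_on = c(Q3A = "Q3", Q3B = "Q3")),
    class = "alto_schema"
  )
}

#' Question identifiers of the ALTO instrument
#'
#' @return Character vector of the eight item identifiers, in display order.
#' @export
question_ids <- function() {
  c("Q1", "Q2", "Q3", "Q3A", "Q3B", "Q4", "Q5", "Q6")
}

# item-answer tokens for the seven non-picture questions
.item_tokens <- c("yes", "no", "not_sure", "missing")
.diag_tokens <- c("totalis_universalis", "patchy", "other_hair_loss")
.sex_tokens <- c("female", "male", "unknown")
.race_tokens <- c("white", "african_american", "hispanic", "asian", "other",
                  "unknown")

# columns of a validated cohort data frame
.cohort_cols <- c("id", "age", "sex", "race", "diagnosis", "diagnosis_label",
                  "q1", "q2", "q3", "q3a", "q3b", "q4", "q5", "q6")

.item_cols <- c("q1", "q2", "q3", "q3a", "q3b", "q4", "q5")

#' Gold-standard positive classes
#'
#' Alopecia areata (the screen's target condition) comprises the
#' totalis/universalis and patchy phenotypes; "other hair loss" is the
#' gold-negative class.
#'
#' @param diagnosis Character vector of diagnosis class tokens.
#' @return Logical vector: `TRUE` where the diagnosis is alopecia areata.
#' @export
is_aa <- function(diagnosis) {
  stopifnot(all(diagnosis %in% .diag_tokens))
  diagnosis %in% c("totalis_universalis", "patchy")
}

## Q6 helpers ----------------------------------------------------------------

# Parse a q6 cell into list(selections, none, missing, empty). Three
# answered states exist: one or more photographs selected; the explicit
# "no representative photographs" choice (E); and an answered-but-empty
# form (token "none"), which the published per-class denominators imply
# occurred (photo selections sum to fewer than the non-E answerers).
parse_q6 <- function(x) {
  x <- trimws(as.character(x))
  if (is.na(x) || x == "" || x == "missing") {
    return(list(selections = character(0), none = FALSE, missing = TRUE))
  }
  if (tolower(x) == "none") {
    return(list(selections = character(0), none = FALSE, missing = FALSE))
  }
  if (toupper(x) == "E") {
    return(list(selections = character(0), none = TRUE, missing = FALSE))
  }
  sel <- toupper(trimws(strsplit(x, ";", fixed = TRUE)[[1]]))
  sel <- sel[sel != ""]
  if (length(sel) == 0 || !all(sel %in% c("A", "B", "C", "D"))) {
    return(list(selections = character(0), none = FALSE, missing = TRUE))
  }
  list(selections = sort(unique(sel)), none = FALSE, missing = FALSE)
}

#' Was a given photograph selected in Q6?
#'
#' @param q6 Character vector of Q6 cells in the cohort dialect
#'   (semicolon-joined subsets of A-D, the literal `"E"`, or
#'   `""`/`"missing"` for a blank item).
#' @param selection One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`. `"E"` is true
#'   when the respondent explicitly chose "no representative photographs".
#' @return Logical vector (never `NA`; a blank Q6 selects nothing).
#' @export
picture_selected <- function(q6, selection) {
  selection <- match.arg(toupper(selection), c("A", "B", "C", "D", "E"))
  vapply(q6, function(x) {
    p <- parse_q6(x)
    if (selection == "E") p$none else selection %in% p$selections
  }, logical(1), USE.NAMES = FALSE)
}

#' Is the Q6 item missing?
#'
#' @param q6 Character vector of Q6 cells.
#' @return Logical vector.
#' @export
q6_missing <- function(q6) {
  vapply(q6, function(x) parse_q6(x)$missing, logical(1), USE.NAMES = FALSE)
}

## Validation ----------------------------------------------------------------

normalize_item <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- "missing"
  x[x %in% c("not sure", "notsure", "unsure", "not_sure")] <- "not_sure"
  x[!(x %in% .item_tokens)] <- "missing"
  x
}

normalize_q6 <- function(x) {
  vapply(x, function(v) {
    p <- parse_q6(v)
    if (p$missing) "missing"
    else if (p$none) "E"
    else if (length(p$selections) == 0) "none"
    else paste(p$selections, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Validate a single raw respondent record
#'
#' Coerces a raw record (named list or one-row data frame of strings) into
#' the validated cohort representation. Unparseable item answers become
#' `"missing"`. The skip-logic invariant is enforced: when Q3 is not an
#' affirmative answer, the conditional follow-ups Q3A/Q3B are coerced to
#' `"missing"` with a warning (the items were not administered).
#'
#' @param record Named list or one-row data frame. Must contain `id`;
#'   recognised fields are `id, age, sex, race, diagnosis, diagnosis_label,
#'   q1, q2, q3, q3a, q3b, q4, q5, q6`.
#' @param schema An [alto_schema()].
#' @return A one-row data frame in the validated cohort layout.
#' @export
#' @examples
#' validate_respondent(list(id = "r1", diagnosis = "patchy",
#'                          q3 = "yes", q3a = "yes"))
validate_respondent <- function(record, schema = alto_schema()) {
  record <- as.list(record)
  nm <- tolower(names(record))
  if (anyDuplicated(nm)) {
    stop("duplicate fields in record: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(record) <- nm
  if (is.null(record$id) || is.na(record$id) || !nzchar(as.character(record$id))) {
    stop("record has no id field")
  }
  get <- function(f, default = NA_character_) {
    v <- record[[f]]
    if (is.null(v)) default else as.character(v)
  }

  diag <- tolower(trimws(get("diagnosis")))
  if (is.na(diag) || !(diag %in% .diag_tokens)) {
    stop("unknown diagnosis class: ", deparse(get("diagnosis")),
         " (expected one of ", paste(.diag_tokens, collapse = ", "), ")")
  }

  age <- suppressWarnings(as.integer(get("age")))
  sex <- tolower(trimws(get("sex")))
  if (is.na(sex) || !(sex %in% .sex_tokens)) sex <- "unknown"
  race <- tolower(trimws(get("race")))
  if (is.na(race) || !(race %in% .race_tokens)) race <- "unknown"

  label <- get("diagnosis_label", NA_character_)
  if (!is.na(label) && !nzchar(trimws(label))) label <- NA_character_
  out <- data.frame(
    id = as.character(record$id),
    age = age, sex = sex, race = race,
    diagnosis = diag,
    diagnosis_label = label,
    q1 = normalize_item(get("q1")), q2 = normalize_item(get("q2")),
    q3 = normalize_item(get("q3")), q3a = normalize_item(get("q3a")),
    q3b = normalize_item(get("q3b")), q4 = normalize_item(get("q4")),
    q5 = normalize_item(get("q5")), q6 = normalize_q6(get("q6")),
    stringsAsFactors = FALSE
  )

  # skip logic: Q3A/Q3B only administered after an affirmative Q3
  if (out$q3 != "yes" && (out$q3a != "missing" || out$q3b != "missing")) {
    warning("respondent ", out$id,
            ": Q3A/Q3B answered but Q3 != yes; coerced to missing")
    out$q3a <- "missing"
    out$q3b <- "missing"
  }
  out
}

#' Validate a raw cohort data frame
#'
#' Applies [validate_respondent()] row-wise and checks id uniqueness.
#'
#' @param raw Data frame of raw records (e.g. from [read_cohort()]).
#' @param schema An [alto_schema()].
#' @return Validated cohort data frame, one row per respondent.
#' @export
validate_cohort <- function(raw, schema = alto_schema()) {
  stopifnot(is.data.frame(raw), nrow(raw) >= 1)
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    validate_respondent(as.list(raw[i, , drop = FALSE]), schema)
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$id)) {
    stop("duplicate respondent ids: ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Questions applicable to a respondent
#'
#' All eight items, minus conditional follow-ups whose parent was not
#' answered "yes" (a "not sure" or missing Q3 also suppresses Q3A/Q3B:
#' the form presents them as follow-ups to an affirmative Q3).
#'
#' @param resp One-row validated cohort data frame.
#' @param schema An [alto_schema()].
#' @return Character vector of applicable question identifiers.
#' @export
applicable_questions <- function(resp, schema = alto_schema()) {
  stopifnot(nrow(resp) == 1)
  ids <- schema$items$id
  drop <- character(0)
  for (child in names(schema$conditional_on)) {
    parent <- schema$conditional_on[[child]]
    if (resp[[tolower(parent)]] != "yes") drop <- c(drop, child)
  }
  setdiff(ids, drop)
}

#' Is a respondent evaluable for a required question set?
#'
#' Mirrors the study's exclusion rule: a respondent is analysable for an
#' algorithm when every question the algorithm uses, among those actually
#' applicable to the respondent (skip logic), has a non-missing answer.
#' "Not sure" counts as answered.
#'
#' @param resp One-row validated cohort data frame.
#' @param required Character vector of question identifiers.
#' @param schema An [alto_schema()].
#' @return `TRUE` or `FALSE`.
#' @export
is_evaluable <- function(resp, required, schema = alto_schema()) {
  stopifnot(all(required %in% question_ids()))
  need <- intersect(required, applicable_questions(resp, schema))
  for (q in need) {
    ans <- if (q == "Q6") resp$q6 else resp[[tolower(q)]]
    if (ans == "missing") return(FALSE)
  }
  TRUE
}

## Cohort CSV dialect --------------------------------------------------------

#' Read a cohort CSV
#'
#' Expects the cohort dialect: header
#' `id,age,sex,race,diagnosis,diagnosis_label,q1,q2,q3,q3a,q3b,q4,q5,q6`;
#' item cells in `yes,no,not_sure` or empty for missing; `q6` a
#' semicolon-joined subset of A-D, the literal `E` ("no representative
#' photographs"), the literal `none` (form returned with the picture item
#' answered but nothing ticked), or empty for missing.
#'
#' @param path File path.
#' @param validate Validate records on read (default `TRUE`).
#' @return Cohort data frame.
#' @export
read_cohort <- function(path, validate = TRUE) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(0))
  missing_cols <- setdiff(.cohort_cols, tolower(names(raw)))
  if (length(missing_cols) > 0) {
    stop("cohort CSV is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  names(raw) <- tolower(names(raw))
  if (validate) validate_cohort(raw) else raw
}

#' Write a cohort CSV
#'
#' @param cohort Validated cohort data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[, .cohort_cols]
  for (col in .item_cols) out[[col]][out[[col]] == "missing"] <- ""
  out$q6[out$q6 == "missing"] <- ""
  out$age[is.na(out$age)] <- ""
  out$diagnosis_label[is.na(out$diagnosis_label)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
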
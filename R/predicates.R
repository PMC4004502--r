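# Declarative predicate trees and their three-valued evaluation.
#
# Indicator criteria are trees of leaves (comparisons against data items) and
# the combinators and/or/not, evaluated under Kleene logic: a leaf whose item
# is absent, unknown or unstructured evaluates to "undetermined"; AND
# short-circuits on not_satisfied, OR on satisfied. Internally the three
# states are encoded numerically (not_satisfied = 0, undetermined = 0.5,
# satisfied = 1) so AND is pmin, OR is pmax and NOT is 1 - x, and whole
# cohorts are evaluated vectorised.

TRI_NOT <- 0; TRI_UND <- 0.5; TRI_SAT <- 1

tri_label <- function(x) {
  c("not_satisfied", "undetermined", "satisfied")[match(x, c(0, 0.5, 1))]
}

#' Predicate constructors
#'
#' Build predicate trees for indicator definitions. `p_cmp()` compares a
#' scalar item (or a field of a composite item) against a constant with one of
#' `eq, ne, lt, le, gt, ge, in`; `p_flag()` tests a logical field for `TRUE`;
#' `p_date_before()` tests an item date strictly before the operation date
#' (same-day counts as not-before); `p_diagnosis()` matches the primary
#' location class and enforces the diagnosis–procedure linkage constraint
#' (diagnosis date, when recorded, must not fall after the operation date);
#' `p_procedure()` tests for any procedure code in the given classes;
#' `p_elective()` tests the harmonised operation urgency; `p_age()` compares
#' age at operation (operation-date year minus year of birth); `p_exclusion()`
#' tests an optional boolean exclusion item (absent means not-excluded in the
#' default lenient mode, undetermined in strict mode); `p_and()`, `p_or()` and
#' `p_not()` combine.
#'
#' @param item item name.
#' @param op comparison operator.
#' @param value constant to compare against (vector for `op = "in"`).
#' @param field optional field suffix for composite items (e.g. `"date"`).
#' @param locations diagnosis location classes (subset of
#'   `colon`, `rectosigmoid`, `rectum`).
#' @param classes procedure classes (e.g. `colectomy`, `rectum_resection`).
#' @param years age threshold in whole years.
#' @param ... subtrees.
#' @param x subtree.
#' @return a predicate tree (nested list).
#' @name predicates
NULL

#' @rdname predicates
#' @export
p_cmp <- function(item, op, value, field = NULL)
  list(type = "cmp", item = item, op = op, value = value, field = field)

#' @rdname predicates
#' @export
p_flag <- function(item, field = NULL)
  list(type = "cmp", item = item, op = "eq", value = TRUE, field = field)

#' @rdname predicates
#' @export
p_date_before <- function(item, field = NULL)
  list(type = "date_before", item = item, field = field)

#' @rdname predicates
#' @export
p_diagnosis <- function(locations)
  list(type = "diagnosis", locations = as.character(locations))

#' @rdname predicates
#' @export
p_procedure <- function(classes)
  list(type = "procedure", classes = as.character(classes))

#' @rdname predicates
#' @export
p_elective <- function() list(type = "elective")

#' @rdname predicates
#' @export
p_age <- function(op, years) list(type = "age", op = op, value = years)

#' @rdname predicates
#' @export
p_exclusion <- function(item) list(type = "exclusion", item = item)

#' @rdname predicates
#' @export
p_and <- function(...) list(type = "and", args = list(...))

#' @rdname predicates
#' @export
p_or <- function(...) list(type = "or", args = list(...))

#' @rdname predicates
#' @export
p_not <- function(x) list(type = "not", args = list(x))

# Default harmonisation of EMR operation-urgency categories onto the four
# registry categories. The EMR's scheme is finer (8 categories) and not
# unambiguously documented; "extra" has no defined meaning and is left
# unmapped on purpose (a standardisation problem, logged at evaluation).
#' Default operation-urgency harmonisation table
#' @return named character vector: EMR category -> registry category.
#' @export
default_urgency_map <- function() {
  c(scheduled = "elective", planned = "elective", waiting_list = "elective",
    semi_urgent = "urgent", urgent = "urgent", emergency = "emergency",
    immediate = "emergency", extra = NA_character_,
    # registry categories map to themselves
    elective = "elective", urgent = "urgent", emergency = "emergency",
    acute = "acute")
}

# Evaluation context: urgency harmonisation map, strict exclusion mode, and a
# collector environment for data-problem notes.
eval_context <- function(urgency_map = default_urgency_map(),
                         strict_exclusions = FALSE, notes = NULL) {
  list(urgency_map = urgency_map, strict_exclusions = strict_exclusions,
       notes = notes)
}

note_problem <- function(ctx, category, detail, n = 1L) {
  if (!is.null(ctx$notes) && n > 0)
    ctx$notes$log[[length(ctx$notes$log) + 1L]] <-
      list(category = category, detail = detail, n = as.integer(n))
  invisible(NULL)
}

# status vector -> logical "usable" mask; non-present statuses force the
# undetermined state.
item_present <- function(cohort, item) {
  cohort[[item_status_column(item)]] == "present"
}

# Vectorised evaluation of a predicate tree over a whole cohort.
# Returns a numeric vector in {0, 0.5, 1}.
eval_tri <- function(cohort, pred, ctx = eval_context()) {
  n <- nrow(cohort)
  if (n == 0) return(numeric(0))
  und <- function(ok, val) ifelse(ok, val, TRI_UND)
  num <- function(b) ifelse(is.na(b), TRI_UND, as.numeric(b))
  switch(pred$type,
    "and" = Reduce(pmin, lapply(pred$args, eval_tri, cohort = cohort, ctx = ctx)),
    "or"  = Reduce(pmax, lapply(pred$args, eval_tri, cohort = cohort, ctx = ctx)),
    "not" = TRI_SAT - eval_tri(cohort, pred$args[[1]], ctx),
    "cmp" = {
      cols <- item_value_columns(pred$item)
      col <- if (is.null(pred$field)) cols[1] else {
        hit <- cols[endsWith(cols, pred$field)]
        if (length(hit) != 1)
          stop_crcqi(paste("unknown field", pred$field, "for item", pred$item),
                     "crcqi_definition_error")
        hit
      }
      if (is.null(cohort[[col]]))
        stop_crcqi(paste("unknown item", pred$item), "crcqi_definition_error")
      v <- cohort[[col]]
      ok <- item_present(cohort, pred$item) & !is.na(v)
      r <- switch(pred$op,
        eq = v == pred$value, ne = v != pred$value,
        lt = v <  pred$value, le = v <= pred$value,
        gt = v >  pred$value, ge = v >= pred$value,
        "in" = v %in% pred$value,
        stop_crcqi(paste("unknown operator", pred$op), "crcqi_definition_error"))
      und(ok, num(r))
    },
    "date_before" = {
      cols <- item_value_columns(pred$item)
      col <- if (is.null(pred$field)) cols[1] else cols[endsWith(cols, pred$field)]
      v <- cohort[[col]]
      op <- cohort$operation_date
      ok <- item_present(cohort, pred$item) & !is.na(v) &
        item_present(cohort, "operation_date") & !is.na(op)
      und(ok, num(v < op))
    },
    "diagnosis" = {
      ok <- item_present(cohort, "diagnosis") & !is.na(cohort$diagnosis_location)
      loc <- cohort$diagnosis_location %in% pred$locations
      # lack-of-detail generalisation: an absent primary flag does not block
      # selection (codes too coarse to distinguish primary from recurrent);
      # an explicit FALSE does.
      prim <- is.na(cohort$diagnosis_primary) | cohort$diagnosis_primary
      # linkage constraint: a diagnosis established after the operation cannot
      # be its indication.
      linked <- is.na(cohort$diagnosis_date) | is.na(cohort$operation_date) |
        cohort$diagnosis_date <= cohort$operation_date
      after <- ok & !linked
      note_problem(ctx, "lack_of_relations",
                   "diagnosis date after operation date; relation not assumed",
                   sum(after))
      note_problem(ctx, "lack_of_detail",
                   "diagnosis primary/recurrent flag not recorded",
                   sum(ok & is.na(cohort$diagnosis_primary)))
      und(ok, num(loc & prim & linked))
    },
    "procedure" = {
      ok <- item_present(cohort, "procedure") & !is.na(cohort$procedure)
      hit <- vapply(strsplit(ifelse(is.na(cohort$procedure), "", cohort$procedure), ";",
                             fixed = TRUE),
                    function(s) any(s %in% pred$classes), logical(1))
      und(ok, num(hit))
    },
    "elective" = {
      ok <- item_present(cohort, "operation_urgency") &
        !is.na(cohort$operation_urgency)
      mapped <- unname(ctx$urgency_map[cohort$operation_urgency])
      unmapped <- ok & is.na(mapped)
      note_problem(ctx, "lack_of_standardisation",
                   "operation-urgency category without harmonisation mapping",
                   sum(unmapped))
      und(ok & !is.na(mapped), num(mapped == "elective"))
    },
    "age" = {
      ok <- item_present(cohort, "year_of_birth") & !is.na(cohort$year_of_birth) &
        item_present(cohort, "operation_date") & !is.na(cohort$operation_date)
      age <- as.integer(format(cohort$operation_date, "%Y")) - cohort$year_of_birth
      r <- switch(pred$op, lt = age < pred$value, ge = age >= pred$value,
                  le = age <= pred$value, gt = age > pred$value)
      und(ok, num(r))
    },
    "exclusion" = {
      st <- cohort[[item_status_column(pred$item)]]
      v <- cohort[[item_value_columns(pred$item)[1]]]
      out <- ifelse(st == "present" & !is.na(v), num(v),
                    if (isTRUE(ctx$strict_exclusions)) TRI_UND else TRI_NOT)
      out
    },
    stop_crcqi(paste("unknown predicate type", pred$type),
               "crcqi_definition_error")
  )
}

#' Evaluate a predicate on a single patient record
#'
#' Three-valued semantics: the result is `"undetermined"` iff a referenced
#' item is absent, unknown or unstructured and the outcome cannot be decided
#' from the present items (AND short-circuits on `not_satisfied`, OR on
#' `satisfied`).
#'
#' @param record a one-row cohort data.frame.
#' @param predicate a predicate tree (see [p_cmp()]).
#' @param ctx evaluation context from `eval_context()`; controls the urgency
#'   harmonisation map and strict exclusion mode.
#' @return one of `"satisfied"`, `"not_satisfied"`, `"undetermined"`.
#' @export
evaluate_predicate <- function(record, predicate, ctx = eval_context()) {
  stopifnot(nrow(record) == 1)
  tri_label(eval_tri(record, predicate, ctx))
}

# Item names referenced by a predicate tree (exclusion items are optional and
# not counted towards computability requirements).
predicate_items <- function(pred) {
  switch(pred$type,
    "and" = , "or" = , "not" =
      unique(unlist(lapply(pred$args, predicate_items))),
    "cmp" = pred$item,
    "date_before" = c(pred$item, "operation_date"),
    "diagnosis" = c("diagnosis", "operation_date"),
    "procedure" = "procedure",
    "elective" = "operation_urgency",
    "age" = c("year_of_birth", "operation_date"),
    "exclusion" = character(0),
    character(0)
  )
}
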
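# Indicator definitions and their evaluation.
#
# The indicator set ships as a declarative JSON document
# (inst/extdata/indicators.json): one object per indicator with numerator /
# denominator / exclusion predicate trees. Two indicators measure submission
# to the national audit itself; their numerators cannot exist in an EMR and
# are excluded from computation (denominators are kept). One indicator is a
# bare volume count with no percentage.

normalise_pred <- function(x) {
  if (is.null(x)) return(NULL)
  unbox1 <- function(v) if (is.list(v) && length(v) == 1 && !is.list(v[[1]])) v[[1]] else v
  x$type <- unbox1(x$type)
  if (x$type %in% c("and", "or", "not")) {
    x$args <- lapply(x$args, normalise_pred)
  } else {
    for (f in c("item", "op", "field"))
      if (!is.null(x[[f]])) x[[f]] <- unbox1(x[[f]])
    for (f in c("value", "locations", "classes"))
      if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]], use.names = FALSE)
  }
  x
}

#' Load the indicator definition set
#'
#' Parses the shipped (or a user-supplied) JSON definition document into a
#' named list of indicator definitions with predicate trees and the derived
#' per-element required-item sets.
#'
#' @param path path to a definitions JSON document; default the copy shipped
#'   with the package.
#' @param require_resection_for_7 the inclusion rule of the preoperative
#'   radiotherapy indicator is not stated; when `TRUE` its population is
#'   additionally restricted to patients with a rectum resection.
#' @return named list of `qi_definition` objects.
#' @export
indicator_definitions <- function(path = NULL, require_resection_for_7 = FALSE) {
  path <- path %||% system.file("extdata", "indicators.json", package = "crcqi")
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  defs <- lapply(doc$indicators, function(d) {
    def <- list(
      id = d[["id"]],
      title = d[["title"]],
      kind = d[["kind"]],
      numerator_excluded = isTRUE(d[["numerator_excluded"]]),
      count_only = isTRUE(d[["count_only"]]),
      numerator = normalise_pred(d[["numerator"]]),
      denominator = normalise_pred(d[["denominator"]]),
      exclusion = normalise_pred(d[["exclusion"]])
    )
    class(def) <- "qi_definition"
    def
  })
  names(defs) <- vapply(defs, `[[`, character(1), "id")
  if (require_resection_for_7 && "7" %in% names(defs)) {
    add <- p_procedure("rectum_resection")
    defs[["7"]]$denominator <- p_and(defs[["7"]]$denominator, add)
    defs[["7"]]$numerator <- p_and(defs[["7"]]$numerator, add)
  }
  for (nm in names(defs)) defs[[nm]]$required_items <- required_items(defs[[nm]])
  defs
}

#' Items required by each element of an indicator
#'
#' The union of item names referenced by the element's predicates (optional
#' exclusion-flag items are not required: an absent exclusion flag does not
#' block computability).
#'
#' @param definition a `qi_definition`.
#' @return list with character vectors `numerator` and `denominator`.
#' @export
required_items <- function(definition) {
  den <- sort(unique(predicate_items(definition$denominator)))
  num <- if (is.null(definition$numerator)) character(0) else
    sort(unique(c(den, predicate_items(definition$numerator))))
  list(numerator = num, denominator = den)
}

element_computable <- function(dataset, definition, element) {
  req <- definition$required_items[[element]]
  all(vapply(req, function(it) available_structured(dataset, it), logical(1)))
}

#' Select the patients of an indicator element
#'
#' A patient is selected iff the element's predicate is `satisfied` and the
#' exclusion predicate is not `satisfied` (in strict exclusion mode an
#' undetermined exclusion also removes the patient). Undetermined element
#' predicates never select.
#'
#' @param dataset a cohort data.frame.
#' @param definition a `qi_definition`.
#' @param element `"numerator"` or `"denominator"`.
#' @param ctx evaluation context (see `eval_context()`).
#' @return character vector of selected patient ids (sorted).
#' @export
select_patients <- function(dataset, definition, element = c("denominator", "numerator"),
                            ctx = eval_context()) {
  element <- match.arg(element)
  pred <- definition[[element]]
  if (is.null(pred))
    stop_crcqi(paste("indicator", definition$id, "has no", element),
               "crcqi_definition_error")
  if (nrow(dataset) == 0) return(character(0))
  sel <- eval_tri(dataset, pred, ctx) == TRI_SAT
  if (element == "numerator") # numerator membership presupposes denominator
    sel <- sel & eval_tri(dataset, definition$denominator, ctx) == TRI_SAT
  if (!is.null(definition$exclusion)) {
    ex <- eval_tri(dataset, definition$exclusion, ctx)
    keep <- if (isTRUE(ctx$strict_exclusions)) ex == TRI_NOT else ex != TRI_SAT
    sel <- sel & keep
  }
  sort(dataset$patient_id[sel])
}

#' Compute one indicator on one dataset
#'
#' Evaluates computability (every required item available in a structured
#' format somewhere in the dataset), the numerator and denominator selections
#' and the resulting percentage. Elements that are not computable, excluded by
#' design, or have a zero denominator report an undefined (`NA`) percentage.
#'
#' @inheritParams select_patients
#' @return a `qi_result` list: `id`, per-element `computable`, `selected` id
#'   sets and `count`s, `percentage` (raw) and `percentage_rounded` (half-up
#'   to integer percent, the reporting convention).
#' @export
compute_indicator <- function(dataset, definition, ctx = eval_context()) {
  elements <- c("denominator", if (!is.null(definition$numerator)) "numerator")
  res <- list(id = definition$id, kind = definition$kind,
              count_only = isTRUE(definition$count_only),
              numerator_excluded = isTRUE(definition$numerator_excluded),
              computable = list(), selected = list(), count = list())
  for (el in elements) {
    comp <- element_computable(dataset, definition, el)
    res$computable[[el]] <- comp
    if (comp) {
      ids <- select_patients(dataset, definition, el, ctx)
      res$selected[[el]] <- ids
      res$count[[el]] <- length(ids)
    } else {
      res$selected[[el]] <- character(0)
      res$count[[el]] <- NA_integer_
    }
  }
  if (res$numerator_excluded || res$count_only || is.null(definition$numerator)) {
    res$percentage <- NA_real_
  } else if (isTRUE(res$computable$numerator) && isTRUE(res$computable$denominator) &&
             !is.na(res$count$denominator) && res$count$denominator > 0) {
    res$percentage <- pct_of(res$count$numerator, res$count$denominator)
  } else {
    res$percentage <- NA_real_
  }
  res$percentage_rounded <- if (is.na(res$percentage)) NA_real_ else
    round_half_up(res$percentage)
  class(res) <- "qi_result"
  res
}

#' Compute the full indicator set on one dataset
#'
#' @param dataset a cohort data.frame.
#' @param definitions list from [indicator_definitions()].
#' @param ctx evaluation context.
#' @return named list of `qi_result` objects.
#' @export
compute_indicators <- function(dataset, definitions = indicator_definitions(),
                               ctx = eval_context()) {
  lapply(definitions, compute_indicator, dataset = dataset, ctx = ctx)
}

#' Tabulate indicator results for one or two sources
#'
#' @param registry_results,emr_results named lists from [compute_indicators()]
#'   (the second may be `NULL` for a single-source table).
#' @return data.frame with one row per indicator: counts, percentages and
#'   computability flags per source; undefined values are `NA` (rendered `-`
#'   when written).
#' @export
indicator_table <- function(registry_results, emr_results = NULL) {
  fmt_side <- function(res, prefix) {
    num <- vapply(res, function(r) r$count$numerator %||% NA_integer_, numeric(1))
    den <- vapply(res, function(r) r$count$denominator %||% NA_integer_, numeric(1))
    out <- data.frame(
      numerator = num, denominator = den,
      percentage = vapply(res, function(r) r$percentage, numeric(1)),
      percentage_rounded = vapply(res, function(r) r$percentage_rounded, numeric(1)),
      numerator_computable = vapply(res, function(r)
        r$computable$numerator %||% NA, logical(1)),
      denominator_computable = vapply(res, function(r)
        r$computable$denominator %||% NA, logical(1))
    )
    names(out) <- paste(prefix, names(out), sep = "_")
    out
  }
  out <- cbind(data.frame(indicator = names(registry_results),
                          kind = vapply(registry_results, `[[`, character(1), "kind")),
               fmt_side(registry_results, "registry"))
  if (!is.null(emr_results)) out <- cbind(out, fmt_side(emr_results, "emr"))
  rownames(out) <- NULL
  out
}
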
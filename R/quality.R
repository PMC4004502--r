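# Data quality: per-item structured availability, completeness and
# cross-source correctness, plus applicability-aware averages.
#
# Completeness is the share of applicable records in which an item is
# actually recorded; values explicitly recorded as 'unknown' count as absent,
# as does free-text-only ("unstructured") storage. Correctness is not byte
# equality but effect-equivalence: two recorded values are consistent when
# they drive the indicators the same way (e.g. both meeting dates on the same
# side of the operation date).

#' Per-item completeness
#'
#' @param dataset a cohort data.frame.
#' @param item item name.
#' @param applicable optional logical vector (length `nrow(dataset)`)
#'   flagging the records to which the item applies; default all records.
#' @return list `percent` (raw, `NA` when no record is applicable),
#'   `percent_rounded` (half-up integer), `n_present`, `n_applicable`.
#' @export
completeness <- function(dataset, item, applicable = NULL) {
  if (!item %in% c(qi_items(), qi_exclusion_items()))
    stop_crcqi(paste("unknown item", item), "crcqi_definition_error")
  st <- dataset[[item_status_column(item)]]
  if (is.null(applicable)) applicable <- rep(TRUE, nrow(dataset))
  st <- st[applicable]
  n_app <- length(st)
  n_pres <- sum(st == "present")
  p <- if (n_app > 0) 100 * n_pres / n_app else NA_real_
  list(percent = p,
       percent_rounded = if (is.na(p)) NA_real_ else round_half_up(p),
       n_present = n_pres, n_applicable = n_app)
}

#' Default effect-consistency rules
#'
#' One rule per item, each a function of the paired registry and EMR rows
#' returning a logical vector (`NA` = pair not evaluable under the rule, e.g.
#' an unmappable urgency category). Dates are compared by their side of the
#' operation date; procedure by resection class; urgency by the harmonised
#' elective/non-elective determination; diagnosis by location class
#' (colon-side vs rectum); stage items by their indicator-threshold side.
#'
#' @param urgency_map urgency harmonisation table (see
#'   [default_urgency_map()]).
#' @return named list of rule functions.
#' @export
default_consistency_rules <- function(urgency_map = default_urgency_map()) {
  side_of_op <- function(d, op) d < op
  date_rule <- function(col) function(r, e)
    side_of_op(r[[col]], r$operation_date) == side_of_op(e[[col]], e$operation_date)
  arm <- function(loc) ifelse(loc %in% c("colon", "rectosigmoid"), "colon_side",
                              ifelse(loc == "rectum", "rectum", NA))
  resection_class <- function(p) {
    cls <- lapply(strsplit(ifelse(is.na(p), "", p), ";", fixed = TRUE),
                  intersect, y = c("colectomy", "rectum_resection"))
    vapply(cls, function(s) paste(sort(s), collapse = "+"), character(1))
  }
  list(
    operation_date = function(r, e) r$operation_date == e$operation_date,
    year_of_birth = function(r, e) r$year_of_birth == e$year_of_birth,
    procedure = function(r, e)
      resection_class(r$procedure) == resection_class(e$procedure),
    operation_urgency = function(r, e) {
      mr <- unname(urgency_map[r$operation_urgency])
      me <- unname(urgency_map[e$operation_urgency])
      (mr == "elective") == (me == "elective")
    },
    diagnosis = function(r, e)
      arm(r$diagnosis_location) == arm(e$diagnosis_location),
    ct = function(r, e) (r$ct %in% c("T3", "T4")) == (e$ct %in% c("T3", "T4")),
    pn = function(r, e) (r$pn %in% c("N1", "N2")) == (e$pn %in% c("N1", "N2")),
    pm = function(r, e) (r$pm == "M0") == (e$pm == "M0"),
    examined_lymph_nodes = function(r, e)
      (r$examined_lymph_nodes >= 10) == (e$examined_lymph_nodes >= 10),
    circumferential_margin = function(r, e)
      (r$circumferential_margin <= 1) == (e$circumferential_margin <= 1),
    colonoscopy = function(r, e) {
      det <- function(d) !is.na(d$colonoscopy_performed) & d$colonoscopy_performed &
        !is.na(d$colonoscopy_complete) & d$colonoscopy_complete &
        !is.na(d$colonoscopy_date) & d$colonoscopy_date < d$operation_date
      det(r) == det(e)
    },
    chemotherapy = function(r, e) r$chemotherapy == e$chemotherapy,
    meeting_date = date_rule("meeting_date"),
    radiotherapy_start_date = date_rule("radiotherapy_start_date")
  )
}

#' Per-item correctness across matched pairs
#'
#' Evaluated only over matched pairs in which both sources record the item
#' (status `present`); a pair is correct iff the item's effect-equivalence
#' rule holds. Rules are symmetric in the two sources.
#'
#' @param registry_dataset,emr_dataset cohort data.frames.
#' @param matches a `qi_match` from [match_patients()].
#' @param item item name.
#' @param rule consistency rule; default the shipped rule for `item`.
#' @return list `percent` (raw, `NA` when no pair is evaluable),
#'   `percent_rounded`, `n_correct`, `n_evaluable`.
#' @export
correctness <- function(registry_dataset, emr_dataset, matches, item,
                        rule = NULL) {
  rules <- default_consistency_rules()
  rule <- rule %||% rules[[item]]
  if (is.null(rule))
    stop_crcqi(paste("no consistency rule for item", item),
               "crcqi_definition_error")
  ri <- match(matches$pairs$registry_id, registry_dataset$patient_id)
  ei <- match(matches$pairs$emr_id, emr_dataset$patient_id)
  r <- registry_dataset[ri, , drop = FALSE]
  e <- emr_dataset[ei, , drop = FALSE]
  stc <- item_status_column(item)
  both <- r[[stc]] == "present" & e[[stc]] == "present"
  r <- r[both, , drop = FALSE]; e <- e[both, , drop = FALSE]
  okv <- if (nrow(r)) rule(r, e) else logical(0)
  okv <- okv[!is.na(okv)]
  n_eval <- length(okv); n_corr <- sum(okv)
  p <- if (n_eval > 0) 100 * n_corr / n_eval else NA_real_
  list(percent = p,
       percent_rounded = if (is.na(p)) NA_real_ else round_half_up(p),
       n_correct = n_corr, n_evaluable = n_eval)
}

#' Full data-quality report
#'
#' One row per item: structured availability per source, completeness per
#' source, correctness across matched pairs, and whether the item is
#' universally applicable (non-universal items — colonoscopy,
#' chemotherapy/medication, meeting date, radiotherapy start date — are kept
#' in the table, bracketed, but excluded from the completeness average).
#' Completeness is computed over the matched cohort of each source so the two
#' columns describe the same patients.
#'
#' @inheritParams correctness
#' @param restrict_to_matched compute completeness over matched records only
#'   (default) or over each full dataset.
#' @return a `qi_quality` data.frame.
#' @export
data_quality_report <- function(registry_dataset, emr_dataset, matches,
                                restrict_to_matched = TRUE) {
  if (restrict_to_matched) {
    reg <- registry_dataset[registry_dataset$patient_id %in%
                              matches$pairs$registry_id, , drop = FALSE]
    emr <- emr_dataset[emr_dataset$patient_id %in%
                         matches$pairs$emr_id, , drop = FALSE]
  } else {
    reg <- registry_dataset; emr <- emr_dataset
  }
  rows <- lapply(qi_items(), function(it) {
    cr <- completeness(reg, it)
    ce <- completeness(emr, it)
    co <- correctness(registry_dataset, emr_dataset, matches, it)
    data.frame(
      item = it,
      universal = !(it %in% qi_bracketed_items()),
      available_registry = available_structured(reg, it),
      available_emr = available_structured(emr, it),
      completeness_registry = cr$percent,
      completeness_registry_n = cr$n_present,
      completeness_registry_of = cr$n_applicable,
      completeness_emr = ce$percent,
      completeness_emr_n = ce$n_present,
      completeness_emr_of = ce$n_applicable,
      correctness = co$percent,
      correctness_n = co$n_correct,
      correctness_of = co$n_evaluable
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qi_quality", "data.frame")
  out
}

#' Applicability-aware quality averages
#'
#' Unweighted means: completeness per source over the universally-applicable
#' items only; correctness over every item with at least one evaluable pair.
#' An item stored only unstructured contributes 0% completeness (it is
#' unavailable to automated computation), matching the reporting convention.
#'
#' @param report a `qi_quality` data.frame from [data_quality_report()].
#' @return list with raw and half-up-rounded averages:
#'   `completeness_registry`, `completeness_emr`, `correctness`.
#' @export
aggregate_quality <- function(report) {
  uni <- report[report$universal, , drop = FALSE]
  if (nrow(uni) == 0)
    stop_crcqi("no universally-applicable items", "crcqi_definition_error")
  comp <- function(p, avail) mean(ifelse(avail, p, 0))
  cr <- comp(uni$completeness_registry, uni$available_registry)
  ce <- comp(uni$completeness_emr, uni$available_emr)
  co <- mean(report$correctness, na.rm = TRUE)
  list(completeness_registry = cr,
       completeness_registry_rounded = round_half_up(cr),
       completeness_emr = ce,
       completeness_emr_rounded = round_half_up(ce),
       correctness = co,
       correctness_rounded = round_half_up(co))
}
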
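# Deterministic fixture construction: minimal paired datasets whose
# cross-classification for a named indicator element reproduces a requested
# TP / reference-only / test-only / TN count vector exactly. Used to rebuild
# published cross-tabulations at desk scale and for round-trip property
# tests. No randomness: patient i gets a unique operation date as matching
# key, identical on both sides of a matched pair.

fixture_states <- function() c("pos", "neg", "out")

# One patient record in a given element state.
#   numerator element:  pos = numerator, neg = denominator only, out = neither
#   denominator element: pos = denominator, neg/out = not in it
fixture_patient <- function(cohort, i, indicator, element, state, key = i) {
  op <- as.Date("2011-01-01") + key
  co <- set_item(cohort, i, "operation_date", op)
  co$gender[i] <- "female"
  co <- set_item(co, i, "year_of_birth", 1950L)
  colonic <- function(co) {
    co <- set_item(co, i, "diagnosis", location = "colon", primary = TRUE,
                   date = op - 40)
    set_item(co, i, "procedure", "colectomy")
  }
  rectal <- function(co) {
    co <- set_item(co, i, "diagnosis", location = "rectum", primary = TRUE,
                   date = op - 40)
    set_item(co, i, "procedure", "rectum_resection")
  }
  not_primary <- function(co) {
    co <- set_item(co, i, "diagnosis", location = "colon", primary = FALSE,
                   date = op - 40)
    set_item(co, i, "procedure", "colectomy")
  }
  co <- set_item(co, i, "operation_urgency", "elective")
  co <- set_item(co, i, "meeting_date", op - 7)
  co <- set_item(co, i, "colonoscopy", performed = TRUE, complete = TRUE,
                 date = op - 30)
  co <- set_item(co, i, "chemotherapy", TRUE)
  co <- set_item(co, i, "examined_lymph_nodes", 14L)
  co <- set_item(co, i, "circumferential_margin", 5)
  co <- set_item(co, i, "ct", "T3")
  co <- set_item(co, i, "pn", "N0")
  co <- set_item(co, i, "pm", "M0")
  co <- set_item(co, i, "radiotherapy_start_date", op - 30)

  den_out <- switch(indicator,
    "1" = , "8b" = , "2" = , "4" = , "5a" = , "5b" = not_primary,
    "3" = , "6a" = , "6b" = colonic,
    "7" = function(co) { co <- rectal(co); set_item(co, i, "ct", "T1") })
  den_in <- switch(indicator,
    "1" = , "8b" = , "2" = colonic,
    "3" = , "6a" = , "6b" = rectal,
    "4" = colonic,
    "5a" = function(co) {
      co <- colonic(co); co <- set_item(co, i, "pn", "N1")
      set_item(co, i, "year_of_birth", 1960L) },
    "5b" = function(co) {
      co <- colonic(co); co <- set_item(co, i, "pn", "N1")
      set_item(co, i, "year_of_birth", 1930L) },
    "7" = rectal)
  if (element == "denominator") {
    co <- if (state == "pos") den_in(co) else den_out(co)
    return(co)
  }
  # numerator element
  co <- if (state == "out") den_out(co) else den_in(co)
  if (state == "neg") {
    co <- switch(indicator,
      "2" = set_item(co, i, "examined_lymph_nodes", 4L),
      "3" = set_item(co, i, "meeting_date", op + 7),
      "4" = set_item(co, i, "colonoscopy", performed = TRUE, complete = FALSE,
                     date = op - 30),
      "5a" = , "5b" = set_item(co, i, "chemotherapy", FALSE),
      "6b" = co,  # margin 5 mm is already numerator-negative
      "7" = set_item(co, i, "radiotherapy_start_date", op + 10),
      stop_crcqi(paste("no numerator for indicator", indicator),
                 "crcqi_definition_error"))
  } else if (state == "pos" && indicator == "6b") {
    co <- set_item(co, i, "circumferential_margin", 0.5)
  }
  co
}

parse_element_id <- function(element_id) {
  parts <- strsplit(element_id, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop_crcqi("element_id must look like '3.numerator'", "crcqi_definition_error")
  ind <- parts[1]
  el <- if (parts[2] == "count") "denominator" else parts[2]
  defs <- indicator_definitions()
  if (!ind %in% names(defs))
    stop_crcqi(paste("unknown indicator", ind), "crcqi_definition_error")
  if (!el %in% c("numerator", "denominator"))
    stop_crcqi(paste("unknown element", parts[2]), "crcqi_definition_error")
  if (el == "numerator" &&
      (is.null(defs[[ind]]$numerator) || isTRUE(defs[[ind]]$numerator_excluded)))
    stop_crcqi(paste("indicator", ind, "has no computable numerator"),
               "crcqi_definition_error")
  list(indicator = ind, element = el, definition = defs[[ind]])
}

#' Build a paired fixture reproducing a requested cross-classification
#'
#' Constructs minimal registry/EMR datasets such that evaluating the named
#' indicator element on each source, matching, and cross-classifying yields
#' exactly the requested counts. For a numerator element the accompanying
#' universe is the denominator selection; the `*_in_*_universe` and
#' `*_universe_extra` arguments shape those universes (and hence the
#' negatives used by specificity and NPV) without touching the four core
#' cells.
#'
#' @param element_id `"<indicator>.<numerator|denominator|count>"`, e.g.
#'   `"3.numerator"`.
#' @param tp matched pairs selected on both sides.
#' @param ref_only patients selected only in the registry.
#' @param test_only patients selected only in the EMR.
#' @param tn matched pairs in both universes selected by neither.
#' @param extra_unmatched_ref,extra_unmatched_test selected patients with no
#'   record at all on the other side.
#' @param ref_only_in_test_universe of the `ref_only` pairs, how many have an
#'   EMR record inside the test universe (denominator) rather than outside.
#' @param test_only_in_ref_universe symmetric.
#' @param ref_universe_extra,test_universe_extra additional matched pairs in
#'   one universe only, selected by neither side.
#' @return list `registry`, `emr` (cohort data.frames).
#' @export
build_fixture_from_crosstab <- function(element_id, tp, ref_only, test_only,
                                        tn, extra_unmatched_ref = 0,
                                        extra_unmatched_test = 0,
                                        ref_only_in_test_universe = 0,
                                        test_only_in_ref_universe = 0,
                                        ref_universe_extra = 0,
                                        test_universe_extra = 0) {
  counts <- c(tp, ref_only, test_only, tn, extra_unmatched_ref,
              extra_unmatched_test, ref_only_in_test_universe,
              test_only_in_ref_universe, ref_universe_extra,
              test_universe_extra)
  if (any(counts < 0) || ref_only_in_test_universe > ref_only ||
      test_only_in_ref_universe > test_only)
    stop_crcqi("fixture counts must be consistent and non-negative",
               "crcqi_config_error")
  el <- parse_element_id(element_id)
  # per-patient (registry state, emr state); NA = record missing on that side
  plan <- rbind(
    if (tp) cbind("pos", "pos")[rep(1, tp), , drop = FALSE],
    if (ref_only) cbind("pos", rep(c("neg", "out"),
      c(ref_only_in_test_universe, ref_only - ref_only_in_test_universe))),
    if (test_only) cbind(rep(c("neg", "out"),
      c(test_only_in_ref_universe, test_only - test_only_in_ref_universe)), "pos"),
    if (tn) cbind("neg", "neg")[rep(1, tn), , drop = FALSE],
    if (ref_universe_extra) cbind("neg", "out")[rep(1, ref_universe_extra), , drop = FALSE],
    if (test_universe_extra) cbind("out", "neg")[rep(1, test_universe_extra), , drop = FALSE],
    if (extra_unmatched_ref) cbind("pos", NA)[rep(1, extra_unmatched_ref), , drop = FALSE],
    if (extra_unmatched_test) cbind(NA, "pos")[rep(1, extra_unmatched_test), , drop = FALSE]
  )
  n <- if (is.null(plan)) 0L else nrow(plan)
  reg_rows <- which(!is.na(plan[, 1]))
  emr_rows <- which(!is.na(plan[, 2]))
  build <- function(rows, side, states) {
    co <- new_cohort(length(rows), source = side,
                     ids = sprintf("%s%04d", toupper(substr(side, 1, 1)), rows))
    # the global row index keys the operation date, so matched pairs share it
    for (k in seq_along(rows))
      co <- fixture_patient(co, k, el$indicator, el$element, states[k],
                            key = rows[k])
    co
  }
  list(registry = build(reg_rows, "registry", plan[reg_rows, 1]),
       emr = build(emr_rows, "emr", plan[emr_rows, 2]))
}

#' Evaluate and cross-classify one element of a paired fixture
#'
#' Convenience wrapper: computes the element's selection on both sides, the
#' matching, the appropriate universes (denominator selections for a
#' numerator element, all patients otherwise) and the cross-classification.
#'
#' @inheritParams build_fixture_from_crosstab
#' @param fixture list with `registry` and `emr` cohorts.
#' @param ctx evaluation context.
#' @return a `qi_crosstab`.
#' @export
cross_classify_element <- function(fixture, element_id, ctx = eval_context()) {
  el <- parse_element_id(element_id)
  def <- el$definition
  m <- match_patients(fixture$registry, fixture$emr)
  sel_r <- select_patients(fixture$registry, def, el$element, ctx)
  sel_e <- select_patients(fixture$emr, def, el$element, ctx)
  if (el$element == "numerator") {
    uni_r <- select_patients(fixture$registry, def, "denominator", ctx)
    uni_e <- select_patients(fixture$emr, def, "denominator", ctx)
  } else {
    uni_r <- fixture$registry$patient_id
    uni_e <- fixture$emr$patient_id
  }
  cross_classify(sel_r, sel_e, uni_r, uni_e, m, element = element_id)
}
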
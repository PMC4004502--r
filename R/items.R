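# Patient-level data model.
#
# A cohort is a plain data.frame with one row per patient and, for each of the
# 14 indicator data items, one or more value columns plus a single
# `<item>_status` column. This mirrors the on-disk CSV layout, keeps the whole
# dataset inspectable with ordinary data-frame tools, and makes per-item
# degradation (missingness, unstructured storage, value errors) explicit
# rather than encoded as bare NAs.

#' Names of the 14 indicator data items
#'
#' The items jointly required to compute the indicator set: operation date,
#' year of birth, procedure, operation urgency, primary location/diagnosis,
#' cT score, pN stage, pM stage, examined lymph nodes, circumferential margin,
#' colonoscopy, chemotherapy/medication, meeting date and radiotherapy start
#' date.
#'
#' @return character vector of item names.
#' @export
qi_items <- function() {
  c("operation_date", "year_of_birth", "procedure", "operation_urgency",
    "diagnosis", "ct", "pn", "pm", "examined_lymph_nodes",
    "circumferential_margin", "colonoscopy", "chemotherapy",
    "meeting_date", "radiotherapy_start_date")
}

# Optional boolean exclusion-criterion items. No structured representation
# exists for these in either source system; they default to status "absent"
# and evaluation treats an absent exclusion as not-excluded (lenient mode).
qi_exclusion_items <- function() {
  c("recurrent_carcinoma", "tem_resection", "colonoscopy_resection",
    "previous_radiotherapy")
}

# Items that do not apply to every operated patient (treatment/event dependent);
# excluded from the completeness average. Rendered bracketed in reports.
qi_bracketed_items <- function() {
  c("colonoscopy", "chemotherapy", "meeting_date", "radiotherapy_start_date")
}

qi_statuses <- function() c("present", "absent", "unknown", "unstructured")

# value columns backing each item
item_value_columns <- function(item) {
  switch(item,
    diagnosis   = c("diagnosis_location", "diagnosis_primary", "diagnosis_date"),
    colonoscopy = c("colonoscopy_performed", "colonoscopy_complete",
                    "colonoscopy_date"),
    item
  )
}

item_status_column <- function(item) paste0(item, "_status")

cohort_date_columns <- function() {
  c("operation_date", "diagnosis_date", "colonoscopy_date", "meeting_date",
    "radiotherapy_start_date")
}

# column template: name -> prototype vector (class carrier)
cohort_prototype <- function() {
  d <- as.Date(character())
  list(
    patient_id = character(), source = character(), gender = character(),
    year_of_birth = integer(), year_of_birth_status = character(),
    operation_date = d, operation_date_status = character(),
    procedure = character(), procedure_status = character(),
    operation_urgency = character(), operation_urgency_status = character(),
    diagnosis_location = character(), diagnosis_primary = logical(),
    diagnosis_date = d, diagnosis_status = character(),
    ct = character(), ct_status = character(),
    pn = character(), pn_status = character(),
    pm = character(), pm_status = character(),
    examined_lymph_nodes = integer(), examined_lymph_nodes_status = character(),
    circumferential_margin = numeric(), circumferential_margin_status = character(),
    colonoscopy_performed = logical(), colonoscopy_complete = logical(),
    colonoscopy_date = d, colonoscopy_status = character(),
    chemotherapy = logical(), chemotherapy_status = character(),
    meeting_date = d, meeting_date_status = character(),
    radiotherapy_start_date = d, radiotherapy_start_date_status = character(),
    recurrent_carcinoma = logical(), recurrent_carcinoma_status = character(),
    tem_resection = logical(), tem_resection_status = character(),
    colonoscopy_resection = logical(), colonoscopy_resection_status = character(),
    previous_radiotherapy = logical(), previous_radiotherapy_status = character()
  )
}

#' Create an empty patient cohort
#'
#' Returns a data.frame with `n` skeleton rows: every data item carries status
#' `"absent"` and an empty value, exclusion items included. Fill values with
#' [set_item()] or ordinary data-frame assignment.
#'
#' @param n number of patients.
#' @param source dataset side, `"registry"` or `"emr"` (or `"truth"`).
#' @param ids optional character patient identifiers; generated when `NULL`.
#' @return a cohort data.frame.
#' @export
new_cohort <- function(n = 0, source = "registry", ids = NULL) {
  proto <- cohort_prototype()
  out <- lapply(proto, function(p) c(p, rep(p[NA_integer_], n)))
  out <- data.frame(out, stringsAsFactors = FALSE)
  if (n > 0) {
    out$patient_id <- ids %||% sprintf("%s%04d", toupper(substr(source, 1, 1)), seq_len(n))
    out$source <- source
    for (it in c(qi_items(), qi_exclusion_items()))
      out[[item_status_column(it)]] <- "absent"
  }
  class(out) <- c("qi_cohort", "data.frame")
  out
}

#' Set a data item's value (and mark it present)
#'
#' @param cohort a cohort data.frame.
#' @param i row index or logical vector.
#' @param item item name (one of [qi_items()] or an exclusion item).
#' @param ... named value columns for composite items (e.g. `location=`,
#'   `primary=`, `date=` for `diagnosis`), or a single unnamed value for
#'   scalar items.
#' @param status new status, default `"present"`.
#' @return the modified cohort.
#' @export
set_item <- function(cohort, i, item, ..., status = "present") {
  vals <- list(...)
  cols <- item_value_columns(item)
  if (length(vals) == 1 && is.null(names(vals))) {
    stopifnot(length(cols) == 1)
    names(vals) <- cols
  } else if (length(vals)) {
    # composite fields addressed by suffix: location/primary/date, performed/...
    names(vals) <- vapply(names(vals), function(nm) {
      hit <- cols[endsWith(cols, nm)]
      if (length(hit) != 1) stop("unknown field '", nm, "' for item ", item)
      hit
    }, character(1))
  }
  for (nm in names(vals)) cohort[[nm]][i] <- vals[[nm]]
  cohort[[item_status_column(item)]][i] <- status
  if (status != "present") {
    for (nm in cols) cohort[[nm]][i] <- cohort[[nm]][NA_integer_]
  }
  cohort
}

#' Validate a cohort data.frame
#'
#' Checks the structural invariants: all expected columns exist, every status
#' is one of present/absent/unknown/unstructured, `status == "present"` rows
#' carry a value (and conversely non-present rows carry none for scalar
#' items), dates are valid, and counts/lengths are non-negative.
#'
#' @param cohort a cohort data.frame.
#' @return `cohort`, invisibly; signals a classed error on violation.
#' @export
validate_cohort <- function(cohort) {
  need <- names(cohort_prototype())
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop_crcqi(paste("cohort lacks columns:", paste(miss, collapse = ", ")),
               "crcqi_schema_error")
  if (anyDuplicated(cohort$patient_id))
    stop_crcqi("duplicated patient_id", "crcqi_schema_error")
  for (it in c(qi_items(), qi_exclusion_items())) {
    st <- cohort[[item_status_column(it)]]
    if (any(!st %in% qi_statuses()))
      stop_crcqi(paste("invalid status for item", it), "crcqi_schema_error")
    main <- item_value_columns(it)[1]
    v <- cohort[[main]]
    if (any(st == "present" & is.na(v)))
      stop_crcqi(paste("status 'present' without a value:", it),
                 "crcqi_schema_error")
  }
  if (any(!is.na(cohort$examined_lymph_nodes) & cohort$examined_lymph_nodes < 0))
    stop_crcqi("negative examined_lymph_nodes", "crcqi_schema_error")
  if (any(!is.na(cohort$circumferential_margin) & cohort$circumferential_margin < 0))
    stop_crcqi("negative circumferential_margin", "crcqi_schema_error")
  invisible(cohort)
}

#' Read / write cohorts as CSV
#'
#' One row per patient, one column per value plus a `_status` column per item;
#' dates ISO-8601 (`YYYY-MM-DD`); procedure code sets serialised as
#' `;`-separated strings.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @return `read_cohort_csv()` returns a validated cohort;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (dc in cohort_date_columns()) out[[dc]] <- format(out[[dc]], "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  proto <- cohort_prototype()
  out <- new_cohort(0)
  out <- out[0, , drop = FALSE]
  n <- nrow(raw)
  res <- lapply(names(proto), function(nm) {
    col <- if (nm %in% names(raw)) raw[[nm]] else rep(NA_character_, n)
    p <- proto[[nm]]
    if (inherits(p, "Date")) as.Date(col)
    else if (is.integer(p)) as.integer(col)
    else if (is.numeric(p)) as.numeric(col)
    else if (is.logical(p)) as.logical(col)
    else col
  })
  names(res) <- names(proto)
  out <- data.frame(res, stringsAsFactors = FALSE)
  class(out) <- c("qi_cohort", "data.frame")
  validate_cohort(out)
  out
}

#' @rdname write_cohort_csv
#' @export
write_cohort_json <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (dc in cohort_date_columns()) out[[dc]] <- format(out[[dc]], "%Y-%m-%d")
  jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Is an item available in a structured format anywhere in the dataset?
# An item stored only as free text (status "unstructured" on every record)
# cannot feed automated computation.
available_structured <- function(cohort, item) {
  st <- cohort[[item_status_column(item)]]
  nrow(cohort) == 0 || any(st != "unstructured")
}
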
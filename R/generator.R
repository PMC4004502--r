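# Synthetic paired-cohort generator.
#
# The generator states a world: a single surgical year of ~75-79 colorectal
# resection patients whose care is recorded once in the hospital EMR (the
# source system, so every patient gets an EMR record) and abstracted into the
# audit registry with a configurable coverage. Degradation is applied per
# item and per source: structured availability (free-text-only items),
# completeness (absent or explicit 'unknown'), effect-visible value errors,
# and the EMR extraction anomalies (missing diagnosis, diagnosis dated after
# the operation, imprecise diagnosis codes, wrong procedure class). True
# values and memberships are kept in a truth ledger for parameter-recovery
# tests.

#' Generator configuration
#'
#' Default rates emulate the per-item completeness and correctness profile of
#' a registry/EMR pair in which pathology-derived items (cT, pN, pM, examined
#' lymph nodes, circumferential margin) live only in free text on the EMR
#' side. Completeness probabilities are per item and source, interpreted as
#' the probability that an applicable value is recorded; error probabilities
#' are the chance that the EMR value is effect-inconsistent with the true
#' (and registry-recorded) value.
#'
#' @param n_patients number of true patients (>= 1).
#' @param registry_coverage probability a patient is abstracted into the
#'   registry.
#' @param emr_extract_noise named probabilities `missing_diagnosis`,
#'   `diagnosis_after_operation`, `imprecise_code`, `wrong_procedure_class`.
#' @param per_item_completeness list with named numeric vectors `registry`
#'   and `emr` (item -> probability of being recorded).
#' @param per_item_error named numeric vector, item -> probability of an
#'   effect-inconsistent EMR value.
#' @param unstructured_items EMR items stored only as free text.
#' @param unknown_fraction share of the missingness mass recorded as an
#'   explicit `'unknown'` rather than plainly absent.
#' @param registry_error named numeric vector of registry-side error rates;
#'   default zero everywhere (the registry is degraded only by missingness
#'   unless stated otherwise).
#' @param seed integer random seed.
#' @return validated `qi_generator_config` list.
#' @export
generator_config <- function(
    n_patients = 79,
    registry_coverage = 75 / 79,
    emr_extract_noise = c(missing_diagnosis = 0.05,
                          diagnosis_after_operation = 0.09,
                          imprecise_code = 0.05,
                          wrong_procedure_class = 0.015),
    per_item_completeness = NULL,
    per_item_error = NULL,
    unstructured_items = c("ct", "pn", "pm", "examined_lymph_nodes",
                           "circumferential_margin"),
    unknown_fraction = 0.2,
    registry_error = NULL,
    seed = 1L) {
  items <- qi_items()
  full <- stats::setNames(rep(1, length(items)), items)
  def_reg <- full
  def_reg[c("ct", "circumferential_margin", "examined_lymph_nodes",
            "chemotherapy", "meeting_date")] <- c(0.39, 0.24, 0.99, 0.99, 0.85)
  def_emr <- full
  def_emr[c("colonoscopy", "chemotherapy", "meeting_date",
            "radiotherapy_start_date")] <- c(0.80, 0.97, 0.79, 0.72)
  comp <- per_item_completeness %||% list(registry = def_reg, emr = def_emr)
  for (side in c("registry", "emr")) {
    v <- full; v[names(comp[[side]])] <- comp[[side]]; comp[[side]] <- v
  }
  err0 <- stats::setNames(rep(0, length(items)), items)
  def_err <- err0
  def_err[c("procedure", "operation_urgency", "diagnosis", "colonoscopy",
            "chemotherapy", "meeting_date")] <- c(0.03, 0.05, 0.09, 0.17,
                                                  0.79, 0.02)
  err <- err0; err[names(per_item_error %||% def_err)] <- per_item_error %||% def_err
  rerr <- err0; rerr[names(registry_error %||% err0)] <- registry_error %||% err0
  cfg <- list(n_patients = as.integer(n_patients),
              registry_coverage = registry_coverage,
              emr_extract_noise = emr_extract_noise,
              per_item_completeness = comp,
              per_item_error = err,
              registry_error = rerr,
              unstructured_items = unstructured_items,
              unknown_fraction = unknown_fraction,
              seed = as.integer(seed))
  class(cfg) <- "qi_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 1)
    stop_crcqi("n_patients must be >= 1", "crcqi_empty_cohort")
  probs <- c(cfg$registry_coverage, cfg$emr_extract_noise, cfg$unknown_fraction,
             cfg$per_item_completeness$registry, cfg$per_item_completeness$emr,
             cfg$per_item_error, cfg$registry_error)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop_crcqi("all probabilities must lie in [0, 1]", "crcqi_config_error")
  bad <- setdiff(cfg$unstructured_items, qi_items())
  if (length(bad))
    stop_crcqi(paste("unknown unstructured item:", paste(bad, collapse = ", ")),
               "crcqi_config_error")
  invisible(cfg)
}

#' Read a generator configuration from JSON
#' @param path JSON file with fields of [generator_config()].
#' @return validated `qi_generator_config`.
#' @export
read_generator_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- doc[intersect(names(doc), names(formals(generator_config)))]
  if (!is.null(args$per_item_completeness))
    args$per_item_completeness <- lapply(args$per_item_completeness, unlist)
  for (f in c("emr_extract_noise", "per_item_error", "registry_error"))
    if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
  do.call(generator_config, args)
}

# --- truth simulation --------------------------------------------------------

simulate_truth <- function(n) {
  co <- new_cohort(n, source = "truth", ids = sprintf("T%04d", seq_len(n)))
  co$gender <- sample(c("male", "female"), n, TRUE, prob = c(0.55, 0.45))
  op <- as.Date("2011-01-01") + sample(0:364, n, TRUE)
  yob <- sample(1925:1990, n, TRUE)
  loc <- sample(c("colon", "rectosigmoid", "rectum"), n, TRUE,
                prob = c(0.52, 0.08, 0.40))
  primary <- stats::runif(n) < 0.96
  ddate <- op - sample(14:120, n, TRUE)
  proc <- ifelse(loc == "rectum", "rectum_resection", "colectomy")
  extra <- stats::runif(n) < 0.3
  proc[extra] <- paste0(proc[extra], ";stoma_formation")
  urg <- sample(c("elective", "urgent", "emergency", "acute"), n, TRUE,
                prob = c(0.55, 0.20, 0.15, 0.10))
  ct <- sample(c("T1", "T2", "T3", "T4"), n, TRUE, prob = c(0.10, 0.20, 0.55, 0.15))
  pn <- sample(c("N0", "N1", "N2"), n, TRUE, prob = c(0.60, 0.27, 0.13))
  pm <- sample(c("M0", "M1"), n, TRUE, prob = c(0.92, 0.08))
  nodes <- stats::rpois(n, 14)
  crm <- round(stats::rexp(n, rate = 0.15), 1)
  scope_perf <- stats::runif(n) < 0.92
  scope_comp <- scope_perf & stats::runif(n) < 0.85
  scope_date <- op - sample(10:90, n, TRUE)
  age <- 2011L - yob
  stage3 <- pn %in% c("N1", "N2") & pm == "M0"
  p_chemo <- ifelse(stage3 & age < 75, 0.80, ifelse(stage3, 0.20, 0.25))
  chemo <- stats::runif(n) < p_chemo
  meet_before <- stats::runif(n) < 0.97
  meet <- ifelse(meet_before, op - sample(3:30, n, TRUE), op + sample(1:14, n, TRUE))
  rt_candidate <- loc == "rectum" & ct %in% c("T3", "T4")
  rt <- stats::runif(n) < ifelse(rt_candidate, 0.90, 0.05)
  rt_date <- op - sample(20:60, n, TRUE)

  co$year_of_birth <- yob
  co$operation_date <- op
  co$procedure <- proc
  co$operation_urgency <- urg
  co$diagnosis_location <- loc
  co$diagnosis_primary <- primary
  co$diagnosis_date <- ddate
  co$ct <- ct; co$pn <- pn; co$pm <- pm
  co$examined_lymph_nodes <- as.integer(nodes)
  co$circumferential_margin <- crm
  co$colonoscopy_performed <- scope_perf
  co$colonoscopy_complete <- scope_comp
  co$colonoscopy_date <- as.Date(scope_date, origin = "1970-01-01")
  co$chemotherapy <- chemo
  co$meeting_date <- as.Date(meet, origin = "1970-01-01")
  rt_d <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  rt_d[rt] <- rt_date[rt]
  co$radiotherapy_start_date <- rt_d
  for (it in qi_items()) co[[item_status_column(it)]] <- "present"
  co$radiotherapy_start_date_status[!rt] <- "absent"
  # exclusion criteria exist in the world but are not recorded in either source
  co$recurrent_carcinoma <- !primary
  co$recurrent_carcinoma_status <- "present"
  co
}

# effect-inconsistent replacement, item specific: errors must be visible to
# the indicator logic, so each replacement crosses the item's decision
# boundary (a date moves across the operation date, a stage flips its class,
# a count crosses the 10-node threshold, ...).
inject_error <- function(co, i, item) {
  op <- co$operation_date[i]
  flip_date <- function(d) as.Date(ifelse(is.na(d), NA,
    ifelse(d < op, op + 7L, op - 7L)), origin = "1970-01-01")
  switch(item,
    meeting_date = { co$meeting_date[i] <- flip_date(co$meeting_date[i]) },
    radiotherapy_start_date = {
      co$radiotherapy_start_date[i] <- flip_date(co$radiotherapy_start_date[i]) },
    colonoscopy = { co$colonoscopy_complete[i] <- !co$colonoscopy_complete[i] },
    chemotherapy = { co$chemotherapy[i] <- !co$chemotherapy[i] },
    procedure = {
      co$procedure[i] <- if (grepl("rectum_resection", co$procedure[i]))
        "colectomy" else "rectum_resection" },
    operation_urgency = {
      co$operation_urgency[i] <- if (co$operation_urgency[i] == "elective")
        "emergency" else "elective" },
    diagnosis = {
      co$diagnosis_location[i] <- if (co$diagnosis_location[i] == "rectum")
        "colon" else "rectum" },
    ct = { co$ct[i] <- if (co$ct[i] %in% c("T3", "T4")) "T2" else "T3" },
    pn = { co$pn[i] <- if (co$pn[i] %in% c("N1", "N2")) "N0" else "N1" },
    pm = { co$pm[i] <- if (co$pm[i] == "M0") "M1" else "M0" },
    operation_date = { co$operation_date[i] <- co$operation_date[i] + 1L },
    year_of_birth = { co$year_of_birth[i] <- co$year_of_birth[i] + 1L },
    examined_lymph_nodes = {
      co$examined_lymph_nodes[i] <-
        if (co$examined_lymph_nodes[i] >= 10) 5L else 12L },
    circumferential_margin = {
      co$circumferential_margin[i] <-
        if (co$circumferential_margin[i] <= 1) 5 else 0.5 }
  )
  co
}

degrade_side <- function(truth, side, cfg) {
  n <- nrow(truth)
  co <- truth
  co$source <- side
  # value errors first (on true values), then completeness/unstructured masks
  err <- if (side == "emr") cfg$per_item_error else cfg$registry_error
  for (it in qi_items()) {
    if (err[[it]] <= 0) next
    hit <- which(stats::runif(n) < err[[it]])
    for (i in hit) co <- inject_error(co, i, it)
  }
  if (side == "emr") {
    noise <- cfg$emr_extract_noise
    a <- stats::runif(n) < noise[["missing_diagnosis"]]
    b <- stats::runif(n) < noise[["diagnosis_after_operation"]]
    c_ <- stats::runif(n) < noise[["imprecise_code"]]
    d <- stats::runif(n) < noise[["wrong_procedure_class"]]
    if (any(b)) co$diagnosis_date[b] <- co$operation_date[b] + sample(1:30, sum(b), TRUE)
    if (any(c_)) co$diagnosis_primary[c_] <- NA  # code too coarse to tell
    for (i in which(d)) co <- inject_error(co, i, "procedure")
    if (any(a)) co <- set_item(co, a, "diagnosis", status = "absent")
    # the EMR stores recurrent/primary only through the (imprecise) code
  }
  comp <- cfg$per_item_completeness[[side]]
  for (it in qi_items()) {
    applicable <- co[[item_status_column(it)]] == "present"
    drop <- applicable & stats::runif(n) >= comp[[it]]
    if (any(drop)) {
      unk <- drop & stats::runif(n) < cfg$unknown_fraction
      if (any(unk)) co <- set_item(co, unk, it, status = "unknown")
      if (any(drop & !unk)) co <- set_item(co, drop & !unk, it, status = "absent")
    }
  }
  if (side == "emr") {
    for (it in cfg$unstructured_items)
      co <- set_item(co, rep(TRUE, n), it, status = "unstructured")
  }
  # neither source records the exclusion criteria in a structured way
  for (it in qi_exclusion_items())
    co <- set_item(co, rep(TRUE, n), it, status = "absent")
  co
}

#' Generate a paired registry/EMR cohort with a truth ledger
#'
#' Every true patient yields an EMR record (the EMR is the source system) and
#' a registry record with probability `registry_coverage`. Identical
#' configuration and seed give byte-identical output.
#'
#' @param config a `qi_generator_config` from [generator_config()].
#' @return list `registry`, `emr` (cohort data.frames) and `truth` (a
#'   `qi_truth_ledger`: `truth` cohort, `identity` map, `memberships` of true
#'   indicator elements).
#' @export
generate_paired_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  with_seed(config$seed, {
    n <- config$n_patients
    truth <- simulate_truth(n)
    emr <- degrade_side(truth, "emr", config)
    reg_full <- degrade_side(truth, "registry", config)
    in_reg <- stats::runif(n) < config$registry_coverage
    # registry numbering follows abstraction order; EMR extraction order is
    # independent of it, so shuffle
    reg <- reg_full[in_reg, , drop = FALSE]
    reg$patient_id <- sprintf("R%04d", seq_len(nrow(reg)))
    perm <- sample.int(n)
    emr <- emr[perm, , drop = FALSE]
    emr$patient_id <- sprintf("E%04d", seq_len(n))
    identity <- data.frame(
      truth_id = truth$patient_id,
      registry_id = NA_character_,
      emr_id = NA_character_)
    identity$registry_id[in_reg] <- reg$patient_id
    identity$emr_id[perm] <- emr$patient_id
    defs <- indicator_definitions()
    memberships <- do.call(rbind, lapply(defs, function(d) {
      els <- c("denominator", if (!is.null(d$numerator)) "numerator")
      do.call(rbind, lapply(els, function(el) {
        ids <- select_patients(truth, d, el)
        data.frame(indicator = rep(d$id, length(ids)),
                   element = rep(el, length(ids)), truth_id = ids)
      }))
    }))
    rownames(memberships) <- NULL
    ledger <- structure(list(truth = truth, identity = identity,
                             memberships = memberships),
                        class = "qi_truth_ledger")
    rownames(reg) <- rownames(emr) <- NULL
    list(registry = reg, emr = emr, truth = ledger)
  })
}
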
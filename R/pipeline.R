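# End-to-end orchestration: load or generate the paired cohorts, compute the
# indicator set on both sources, match patients, cross-classify every
# computable element, run the accuracy and overlap statistics, the data
# quality analysis, and emit the report bundle as CSV/JSON.

PROBLEM_CATEGORIES <- c("not_structured", "incorrect_data",
                        "incomplete_history", "lack_of_relations",
                        "lack_of_detail", "lack_of_standardisation")

#' Pipeline configuration
#'
#' @param registry_path,emr_path cohort CSV paths; supply either both paths
#'   or `generator`, never both.
#' @param generator a `qi_generator_config` (or path to its JSON).
#' @param definitions_path optional indicator-definition JSON.
#' @param out_dir output directory for the report bundle (`NULL` = don't
#'   write).
#' @param alpha significance level for the overlap test, in (0, 1).
#' @param strict_exclusions treat absent exclusion flags as undetermined
#'   instead of not-excluded.
#' @param locale `"point"` or `"comma"` decimal rendering for formatted
#'   ratio columns.
#' @param seed integer seed (forwarded to the generator when used).
#' @return validated `qi_pipeline_config` list.
#' @export
pipeline_config <- function(registry_path = NULL, emr_path = NULL,
                            generator = NULL, definitions_path = NULL,
                            out_dir = NULL, alpha = 0.05,
                            strict_exclusions = FALSE, locale = "point",
                            seed = 1L) {
  have_paths <- !is.null(registry_path) && !is.null(emr_path)
  if (identical(have_paths, !is.null(generator)))
    stop_crcqi("supply exactly one of {registry_path+emr_path, generator}",
               "crcqi_config_error")
  if (!(alpha > 0 && alpha < 1))
    stop_crcqi("alpha must lie in (0, 1)", "crcqi_config_error")
  if (is.character(generator)) generator <- read_generator_config(generator)
  if (!is.null(generator)) generator$seed <- as.integer(seed)
  structure(list(registry_path = registry_path, emr_path = emr_path,
                 generator = generator, definitions_path = definitions_path,
                 out_dir = out_dir, alpha = alpha,
                 strict_exclusions = strict_exclusions, locale = locale,
                 seed = as.integer(seed)),
            class = "qi_pipeline_config")
}

collect_problems <- function(notes, registry, emr, match) {
  log <- notes$log
  add <- function(cat, detail, n) {
    if (n > 0) log[[length(log) + 1L]] <<-
        list(category = cat, detail = detail, n = as.integer(n))
  }
  for (nm in c("registry", "emr")) {
    d <- if (nm == "registry") registry else emr
    for (it in qi_items())
      add("not_structured",
          sprintf("item '%s' stored only as free text in %s", it, nm),
          as.integer(!available_structured(d, it)))
  }
  add("incorrect_data", "records in ambiguous matching groups",
      length(unlist(lapply(match$ambiguous, `[[`, "emr_ids"))))
  add("incomplete_history", "records unmatched across sources",
      nrow(match$unmatched_registry) + nrow(match$unmatched_emr))
  if (length(log) == 0)
    return(data.frame(category = character(), detail = character(),
                      n = integer()))
  df <- do.call(rbind, lapply(log, as.data.frame))
  # the same leaf is re-evaluated once per indicator element; the maximum
  # over evaluations is the number of distinct records affected
  stats::aggregate(n ~ category + detail, df, max)
}

write_undef <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- ifelse(is.na(out[[j]]), "-", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, na = "-")
  invisible(path)
}

#' Run the full comparison pipeline
#'
#' Loads (or generates) the paired cohorts, computes every indicator on both
#' sources with computability flags, matches patients, cross-classifies each
#' computable element, derives accuracy statistics and the
#' overlapping-samples proportion test for indicators with computable
#' numerators on both sides, and measures data quality. When `out_dir` is
#' set, writes `indicator_results.csv`, `crosstabs.csv`, `accuracy.csv`,
#' `data_quality.csv`, `matching_flow.csv`, `problems.csv` and a
#' `manifest.json` recording config, seed and package version.
#'
#' @param config a `qi_pipeline_config`.
#' @return the report bundle (list), invisibly when written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qi_pipeline_config"))
  if (!is.null(config$generator)) {
    gen <- generate_paired_cohort(config$generator)
    registry <- gen$registry; emr <- gen$emr; truth <- gen$truth
  } else {
    registry <- read_cohort_csv(config$registry_path)
    emr <- read_cohort_csv(config$emr_path)
    truth <- NULL
  }
  validate_cohort(registry); validate_cohort(emr)
  notes <- new.env(); notes$log <- list()
  ctx <- eval_context(strict_exclusions = config$strict_exclusions,
                      notes = notes)
  defs <- indicator_definitions(config$definitions_path)

  res_r <- compute_indicators(registry, defs, ctx)
  res_e <- compute_indicators(emr, defs, ctx)
  m <- match_patients(registry, emr)

  crosstabs <- list(); acc_rows <- list()
  for (id in names(defs)) {
    def <- defs[[id]]
    els <- c("denominator",
             if (!is.null(def$numerator) && !def$numerator_excluded) "numerator")
    for (el in els) {
      if (!isTRUE(res_r[[id]]$computable[[el]]) ||
          !isTRUE(res_e[[id]]$computable[[el]])) next
      if (el == "numerator") {
        uni_r <- res_r[[id]]$selected$denominator
        uni_e <- res_e[[id]]$selected$denominator
      } else {
        uni_r <- registry$patient_id; uni_e <- emr$patient_id
      }
      ct <- cross_classify(res_r[[id]]$selected[[el]], res_e[[id]]$selected[[el]],
                           uni_r, uni_e, m, element = paste(id, el, sep = "."))
      crosstabs[[ct$element]] <- ct
      if (el == "numerator") {
        ov <- overlap_outcomes(res_r[[id]], res_e[[id]], m)
        test <- if (!is.na(res_r[[id]]$percentage) &&
                    !is.na(res_e[[id]]$percentage)) {
          suppressWarnings(overlapping_proportions_test(
            res_r[[id]]$count$numerator, res_r[[id]]$count$denominator,
            res_e[[id]]$count$numerator, res_e[[id]]$count$denominator,
            ov))
        } else NULL
        acc_rows[[id]] <- list(indicator = id, registry = res_r[[id]],
                               emr = res_e[[id]], accuracy = accuracy_stats(ct),
                               test = test)
      }
    }
  }

  quality <- data_quality_report(registry, emr, m)
  averages <- aggregate_quality(quality)
  emr_sel <- res_e[["1"]]$selected$denominator
  flow <- match_flow_summary(m, registry, emr, emr_sel)
  problems <- collect_problems(notes, registry, emr, m)

  bundle <- list(
    registry = registry, emr = emr, truth = truth,
    results = list(registry = res_r, emr = res_e),
    indicator_table = indicator_table(res_r, res_e),
    match = m, flow = flow,
    crosstabs = crosstabs,
    crosstab_table = crosstab_table(crosstabs),
    accuracy_table = if (length(acc_rows))
      accuracy_table(acc_rows, config$locale) else NULL,
    quality = quality, quality_averages = averages,
    problems = problems,
    config = config)
  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config$out_dir)
    return(invisible(bundle))
  }
  bundle
}

overlap_outcomes <- function(res_ref, res_test, match) {
  # paired numerator outcomes for subjects in both denominators
  pr <- match$pairs$registry_id; pe <- match$pairs$emr_id
  shared <- pr %in% res_ref$selected$denominator &
    pe %in% res_test$selected$denominator
  cbind(pr[shared] %in% res_ref$selected$numerator,
        pe[shared] %in% res_test$selected$numerator)
}

crosstab_table <- function(crosstabs) {
  if (length(crosstabs) == 0)
    return(data.frame(element = character(), tp = integer(),
                      ref_only = integer(), test_only = integer(),
                      tn = integer(), n_ref = integer(), n_test = integer()))
  out <- do.call(rbind, lapply(crosstabs, function(ct)
    data.frame(element = ct$element, tp = ct$tp, ref_only = ct$ref_only,
               test_only = ct$test_only, tn = ct$tn,
               n_ref = ct$n_ref, n_test = ct$n_test)))
  rownames(out) <- NULL
  out
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_undef(bundle$indicator_table, p("indicator_results.csv"))
  write_undef(bundle$crosstab_table, p("crosstabs.csv"))
  if (!is.null(bundle$accuracy_table))
    write_undef(bundle$accuracy_table, p("accuracy.csv"))
  write_undef(bundle$quality, p("data_quality.csv"))
  write_undef(bundle$flow, p("matching_flow.csv"))
  write_undef(bundle$problems, p("problems.csv"))
  jsonlite::write_json(
    list(package = "crcqi",
         version = as.character(utils::packageVersion("crcqi")),
         seed = bundle$config$seed,
         alpha = bundle$config$alpha,
         strict_exclusions = bundle$config$strict_exclusions,
         locale = bundle$config$locale,
         generated = !is.null(bundle$config$generator),
         quality_averages = bundle$quality_averages),
    p("manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
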
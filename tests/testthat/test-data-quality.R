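# Completeness, correctness, quality averages.

pairwise_match <- function(reg, emr) {
  structure(list(pairs = data.frame(registry_id = reg$patient_id,
                                    emr_id = emr$patient_id, similarity = 1),
                 unmatched_registry = data.frame(id = character(),
                                                 reason = character()),
                 unmatched_emr = data.frame(id = character(),
                                            reason = character()),
                 ambiguous = list()),
            class = "qi_match")
}

test_that("completeness counts present over applicable, unknown as absent", {
  co <- new_cohort(75)
  co <- set_item(co, 1:29, "ct", "T3")
  c1 <- completeness(co, "ct")
  expect_equal(c1$n_present, 29)
  expect_equal(c1$n_applicable, 75)
  expect_equal(c1$percent, 100 * 29 / 75, tolerance = 1e-12)
  expect_equal(c1$percent_rounded, 39)
  # explicit 'unknown' diminishes completeness just like absence
  co2 <- set_item(new_cohort(10), 1:10, "pm", status = "unknown")
  expect_equal(completeness(co2, "pm")$percent, 0)
  # unstructured storage also counts as unavailable
  co3 <- set_item(new_cohort(10), 1:10, "pn", status = "unstructured")
  expect_equal(completeness(co3, "pn")$percent, 0)
  # applicability restriction
  c4 <- completeness(co, "ct", applicable = seq_len(75) <= 29)
  expect_equal(c4$percent, 100)
  expect_error(completeness(co, "bogus"), class = "crcqi_error")
})

test_that("meeting-date correctness is the share of same-side pairs", {
  n <- 60
  op <- as.Date("2011-06-01") + seq_len(n)
  reg <- new_cohort(n, "registry")
  emr <- new_cohort(n, "emr")
  reg$operation_date <- emr$operation_date <- op
  reg$operation_date_status <- emr$operation_date_status <- "present"
  reg <- set_item(reg, 1:n, "meeting_date", op - 7)
  # EMR dates differ by value but agree in effect, except one crossing the
  # operation date; two pairs not evaluable (absent on the EMR side)
  emr <- set_item(emr, 1:n, "meeting_date", op - 3)
  emr <- set_item(emr, 1, "meeting_date", op[1] + 5)
  emr <- set_item(emr, 59:60, "meeting_date", status = "absent")
  m <- pairwise_match(reg, emr)
  co <- correctness(reg, emr, m, "meeting_date")
  expect_equal(co$n_evaluable, 58)
  expect_equal(co$n_correct, 57)
  expect_equal(co$percent_rounded, 98)
})

test_that("correctness rules compare effect, not bytes, and are symmetric", {
  n <- 20
  op <- as.Date("2011-06-01") + seq_len(n)
  reg <- new_cohort(n, "registry"); emr <- new_cohort(n, "emr")
  reg$operation_date <- emr$operation_date <- op
  reg$operation_date_status <- emr$operation_date_status <- "present"
  reg <- set_item(reg, 1:n, "examined_lymph_nodes", rep(c(12L, 8L), 10))
  emr <- set_item(emr, 1:n, "examined_lymph_nodes", rep(c(17L, 9L), 10))
  m <- pairwise_match(reg, emr)
  # 12 vs 17 and 8 vs 9: same side of the 10-node threshold everywhere
  expect_equal(correctness(reg, emr, m, "examined_lymph_nodes")$percent, 100)
  # urgency compared after harmonisation: scheduled == elective in effect
  reg <- set_item(reg, 1:n, "operation_urgency", "elective")
  emr <- set_item(emr, 1:n, "operation_urgency",
                  rep(c("scheduled", "urgent"), c(15, 5)))
  expect_equal(correctness(reg, emr, m, "operation_urgency")$percent, 75)
  # symmetry under swapping sources
  ms <- structure(list(pairs = data.frame(registry_id = emr$patient_id,
                                          emr_id = reg$patient_id,
                                          similarity = 1)),
                  class = "qi_match")
  expect_equal(correctness(emr, reg, ms, "operation_urgency")$percent, 75)
})

test_that("a byte-identical pair of datasets is 100% correct on every item", {
  cfg <- generator_config(
    n_patients = 40, registry_coverage = 1,
    emr_extract_noise = c(missing_diagnosis = 0, diagnosis_after_operation = 0,
                          imprecise_code = 0, wrong_procedure_class = 0),
    per_item_completeness = list(
      registry = setNames(rep(1, 14), qi_items()),
      emr = setNames(rep(1, 14), qi_items())),
    per_item_error = setNames(rep(0, 14), qi_items()),
    unstructured_items = character(0), seed = 9)
  g <- generate_paired_cohort(cfg)
  m <- match_patients(g$registry, g$emr)
  q <- data_quality_report(g$registry, g$emr, m)
  expect_true(all(q$correctness[!is.na(q$correctness)] == 100))
  # radiotherapy applies only to treated patients; all other items complete
  uni <- q[q$universal, ]
  expect_true(all(uni$completeness_registry == 100))
  expect_true(all(uni$completeness_emr == 100))
})

test_that("aggregate averages use universal items only, items counted 0 when unstructured", {
  q <- data.frame(
    item = qi_items(),
    universal = !(qi_items() %in% qi_bracketed_items()),
    available_registry = TRUE,
    available_emr = !(qi_items() %in% c("ct", "pn", "pm", "examined_lymph_nodes",
                                        "circumferential_margin")),
    completeness_registry = c(100, 100, 100, 100, 100, 39, 100, 100, 99, 24,
                              100, 99, 85, 33),
    completeness_emr = c(100, 100, 100, 100, 100, 0, 0, 0, 0, 0,
                         80, 97, 79, 24),
    correctness = c(100, 100, 97, 95, 91, NA, NA, NA, NA, NA, 83, 21, 98, 100)
  )
  class(q) <- c("qi_quality", "data.frame")
  a <- aggregate_quality(q)
  expect_equal(a$completeness_registry_rounded, 86)
  expect_equal(a$completeness_emr_rounded, 50)
  expect_equal(a$correctness_rounded, 87)
})

test_that("completeness is monotone in filling absent values", {
  set.seed(41)
  for (rep in 1:20) {
    co <- random_cohort(10)
    it <- sample(qi_items(), 1)
    before <- completeness(co, it)$percent
    i <- which(co[[paste0(it, "_status")]] != "present")
    if (!length(i)) next
    co[[paste0(it, "_status")]][i[1]] <- "present"
    main <- crcqi:::item_value_columns(it)[1]
    if (is.na(co[[main]][i[1]])) co[[main]][i[1]] <- co[[main]][!is.na(co[[main]])][1]
    expect_gte(completeness(co, it)$percent, before)
  }
})
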
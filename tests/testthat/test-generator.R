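# Synthetic paired-cohort generator and fixture builder.

test_that("configuration validation rejects bad inputs", {
  expect_error(generator_config(n_patients = 0), class = "crcqi_empty_cohort")
  expect_error(generator_config(registry_coverage = 1.2),
               class = "crcqi_config_error")
  expect_error(generator_config(per_item_error = c(chemotherapy = -0.1)),
               class = "crcqi_config_error")
  expect_error(generator_config(unstructured_items = "bogus"),
               class = "crcqi_config_error")
})

test_that("identical config and seed reproduce identical datasets", {
  g1 <- generate_paired_cohort(generator_config(n_patients = 40, seed = 123))
  g2 <- generate_paired_cohort(generator_config(n_patients = 40, seed = 123))
  expect_identical(g1$registry, g2$registry)
  expect_identical(g1$emr, g2$emr)
  expect_identical(g1$truth$identity, g2$truth$identity)
  g3 <- generate_paired_cohort(generator_config(n_patients = 40, seed = 124))
  expect_false(identical(g1$emr, g3$emr))
})

test_that("no degradation means both sources agree on every item", {
  cfg <- generator_config(
    n_patients = 30, registry_coverage = 1,
    emr_extract_noise = c(missing_diagnosis = 0, diagnosis_after_operation = 0,
                          imprecise_code = 0, wrong_procedure_class = 0),
    per_item_completeness = list(
      registry = setNames(rep(1, 14), qi_items()),
      emr = setNames(rep(1, 14), qi_items())),
    per_item_error = setNames(rep(0, 14), qi_items()),
    unstructured_items = character(0), seed = 3)
  g <- generate_paired_cohort(cfg)
  emr_in_truth_order <- g$emr[match(g$truth$identity$emr_id, g$emr$patient_id), ]
  for (col in setdiff(names(g$registry), c("patient_id", "source")))
    expect_equal(g$registry[[col]], emr_in_truth_order[[col]], info = col,
                 ignore_attr = TRUE)
  # and the computed indicators coincide
  rr <- compute_indicators(g$registry)
  re <- compute_indicators(g$emr)
  for (id in names(rr))
    expect_equal(rr[[id]]$percentage, re[[id]]$percentage, info = id)
})

test_that("truth-ledger memberships are consistent under re-evaluation", {
  g <- generate_paired_cohort(generator_config(n_patients = 50, seed = 17))
  defs <- indicator_definitions()
  mem <- g$truth$memberships
  for (id in c("2", "3", "5a", "8b")) {
    want <- sort(mem$truth_id[mem$indicator == id & mem$element == "denominator"])
    got <- select_patients(g$truth$truth, defs[[id]], "denominator")
    expect_equal(got, want, info = id)
  }
  expect_false(anyDuplicated(g$truth$identity$truth_id) > 0)
  expect_equal(nrow(g$truth$identity), 50)
})

test_that("configured rates are recovered at n = 5000", {
  cfg <- generator_config(n_patients = 5000, registry_coverage = 1, seed = 29)
  g <- generate_paired_cohort(cfg)
  # completeness: EMR meeting date configured at 0.79
  ce <- completeness(g$emr, "meeting_date")
  expect_lt(abs(ce$percent - 79), 2)
  # correctness: chemotherapy effect-error 0.79 -> ~21% consistent
  id <- g$truth$identity
  m <- structure(list(pairs = data.frame(registry_id = id$registry_id,
                                         emr_id = id$emr_id, similarity = 1)),
                 class = "qi_match")
  co <- correctness(g$registry, g$emr, m, "chemotherapy")
  expect_lt(abs(co$percent - 21), 2)
})

test_that("fixtures reproduce requested cross-classifications exactly", {
  # worked example: audit-meeting numerator
  fx <- build_fixture_from_crosstab("3.numerator", tp = 23, ref_only = 6,
                                    test_only = 0, tn = 0)
  ct <- cross_classify_element(fx, "3.numerator")
  expect_equal(ct$tp, 23); expect_equal(ct$ref_only, 6)
  expect_equal(ct$test_only, 0)
  # empty fixture: everything undefined downstream
  fx0 <- build_fixture_from_crosstab("3.numerator", 0, 0, 0, 0)
  ct0 <- cross_classify_element(fx0, "3.numerator")
  a0 <- accuracy_stats(ct0)
  expect_true(all(is.na(unlist(a0[c("sensitivity", "specificity", "ppv",
                                    "npv", "plr", "nlr")]))))
  expect_error(build_fixture_from_crosstab("9z.numerator", 1, 0, 0, 0),
               class = "crcqi_definition_error")
  expect_error(build_fixture_from_crosstab("1.numerator", 1, 0, 0, 0),
               class = "crcqi_definition_error")
})

test_that("fixture round-trip holds for random count vectors across elements", {
  set.seed(53)
  els <- c("2.numerator", "3.numerator", "4.numerator", "6b.numerator",
           "1.denominator", "8b.count", "3.denominator")
  for (rep in 1:25) {
    el <- sample(els, 1)
    k <- as.list(rpois(6, 4))
    names(k) <- c("tp", "ref_only", "test_only", "tn",
                  "extra_unmatched_ref", "extra_unmatched_test")
    fx <- do.call(build_fixture_from_crosstab, c(list(el), k))
    ct <- cross_classify_element(fx, el)
    expect_equal(ct$tp, k$tp, info = paste(rep, el))
    expect_equal(ct$ref_only, k$ref_only + k$extra_unmatched_ref,
                 info = paste(rep, el))
    expect_equal(ct$test_only, k$test_only + k$extra_unmatched_test,
                 info = paste(rep, el))
    expect_equal(ct$tn, k$tn, info = paste(rep, el))
  }
})

test_that("generated output is schema-valid and CSV round-trips", {
  g <- generate_paired_cohort(generator_config(n_patients = 25, seed = 31))
  expect_silent(validate_cohort(g$registry))
  expect_silent(validate_cohort(g$emr))
  tmp <- tempfile(fileext = ".csv")
  write_cohort_csv(g$emr, tmp)
  back <- read_cohort_csv(tmp)
  expect_equal(as.data.frame(back), as.data.frame(g$emr), ignore_attr = TRUE)
})
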
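# Cross-classification, accuracy statistics, overlapping-samples test.

mk_match <- function(reg_ids, emr_ids) {
  structure(list(pairs = data.frame(registry_id = reg_ids, emr_id = emr_ids,
                                    similarity = rep(1, length(reg_ids))),
                 unmatched_registry = data.frame(id = character(),
                                                 reason = character()),
                 unmatched_emr = data.frame(id = character(),
                                            reason = character()),
                 ambiguous = list()),
            class = "qi_match")
}

test_that("cross_classify counts pairs and singletons correctly", {
  m <- mk_match(paste0("R", 1:6), paste0("E", 1:6))
  ct <- cross_classify(c("R1", "R2", "R3"), c("E1", "E4"),
                       paste0("R", 1:6), paste0("E", 1:6), m)
  expect_equal(ct$tp, 1)        # R1/E1
  expect_equal(ct$ref_only, 2)  # R2, R3
  expect_equal(ct$test_only, 1) # E4
  expect_equal(ct$tn, 2)        # pairs 5 and 6
  # disjoint universes, no matches
  m0 <- mk_match(character(0), character(0))
  ct0 <- cross_classify("R1", "E9", c("R1", "R2"), c("E8", "E9"), m0)
  expect_equal(ct0$tp, 0); expect_equal(ct0$tn, 0)
  expect_equal(ct0$ref_only, 1); expect_equal(ct0$test_only, 1)
  expect_error(cross_classify("R9", "E1", c("R1"), c("E1"), m),
               class = "crcqi_consistency_error")
})

test_that("cross_classify equals a brute-force scan over matched pairs", {
  set.seed(11)
  for (rep in 1:50) {
    n <- 200
    rid <- sprintf("R%03d", 1:n); eid <- sprintf("E%03d", sample(n))
    keep <- runif(n) < 0.8
    m <- mk_match(rid[keep], eid[keep])
    uni_r <- sample(rid, 150); uni_e <- sample(eid, 150)
    sel_r <- sample(uni_r, 60); sel_e <- sample(uni_e, 60)
    ct <- cross_classify(sel_r, sel_e, uni_r, uni_e, m)
    tp <- 0; tn <- 0
    for (k in seq_len(sum(keep))) {
      r <- m$pairs$registry_id[k]; e <- m$pairs$emr_id[k]
      if (r %in% sel_r && e %in% sel_e) tp <- tp + 1
      if (r %in% uni_r && e %in% uni_e && !(r %in% sel_r) && !(e %in% sel_e))
        tn <- tn + 1
    }
    expect_equal(ct$tp, tp, info = rep)
    expect_equal(ct$tn, tn, info = rep)
    expect_equal(ct$ref_only, length(sel_r) - tp, info = rep)
    expect_equal(ct$test_only, length(sel_e) - tp, info = rep)
  }
})

test_that("accuracy statistics reproduce the frozen worked examples", {
  ct3 <- structure(list(element = "3.numerator", tp = 23, ref_only = 6,
                        test_only = 0, tn = 0, n_ref = 29, n_test = 33),
                   class = "qi_crosstab")
  a3 <- accuracy_stats(ct3)
  expect_equal(a3$sensitivity, 23 / 29, tolerance = 1e-12)
  expect_equal(a3$ppv, 1)
  expect_equal(a3$npv, 0)
  expect_true(is.na(a3$specificity))  # 0/0
  expect_true(is.na(a3$plr))
  ct4 <- structure(list(element = "4.numerator", tp = 21, ref_only = 15,
                        test_only = 10, tn = 3, n_ref = 41, n_test = 53),
                   class = "qi_crosstab")
  a4 <- accuracy_stats(ct4)
  expect_equal(a4$sensitivity, 21 / 36, tolerance = 1e-12)
  expect_equal(a4$specificity, 3 / 5, tolerance = 1e-12)
  expect_equal(a4$ppv, 21 / 31, tolerance = 1e-12)
  expect_equal(a4$plr, (21 / 36) / (1 - 3 / 5), tolerance = 1e-12)
  expect_equal(a4$nlr, (1 - 21 / 36) / (3 / 5), tolerance = 1e-12)
})

test_that("likelihood-ratio identities hold on random cross-tabulations", {
  set.seed(21)
  for (rep in 1:200) {
    tp <- rpois(1, 20); fn <- rpois(1, 10); fp <- rpois(1, 10); tn <- rpois(1, 15)
    extra_r <- rpois(1, 5); extra_t <- rpois(1, 5)
    ct <- structure(list(tp = tp, ref_only = fn, test_only = fp, tn = tn,
                         n_ref = tp + fn + tn + extra_r,
                         n_test = tp + fp + tn + extra_t),
                    class = "qi_crosstab")
    a <- accuracy_stats(ct)
    for (v in c("sensitivity", "specificity", "ppv", "npv"))
      if (!is.na(a[[v]])) expect_true(a[[v]] >= 0 && a[[v]] <= 1)
    if (!is.na(a$plr))
      expect_equal(a$plr, a$sensitivity / (1 - a$specificity), tolerance = 1e-12)
    if (!is.na(a$nlr))
      expect_equal(a$nlr, (1 - a$sensitivity) / a$specificity, tolerance = 1e-12)
  }
})

test_that("zero denominators yield undefined statistics, not errors", {
  ct <- structure(list(tp = 0, ref_only = 0, test_only = 0, tn = 0,
                       n_ref = 0, n_test = 0), class = "qi_crosstab")
  a <- accuracy_stats(ct)
  expect_true(all(is.na(unlist(a[c("sensitivity", "specificity", "ppv",
                                   "npv", "plr", "nlr")]))))
})

test_that("zero overlap reduces exactly to the unpooled two-proportion z-test", {
  cases <- list(c(30, 50, 20, 60), c(5, 10, 9, 12), c(40, 80, 41, 79))
  for (cs in cases) {
    r <- suppressWarnings(
      overlapping_proportions_test(cs[1], cs[2], cs[3], cs[4]))
    p1 <- cs[1] / cs[2]; p2 <- cs[3] / cs[4]
    se <- sqrt(p1 * (1 - p1) / cs[2] + p2 * (1 - p2) / cs[4])
    expect_equal(r$covariance, 0)
    expect_equal(r$z, (p1 - p2) / se, tolerance = 1e-12)
    expect_equal(r$p_value, 2 * pnorm(-abs((p1 - p2) / se)), tolerance = 1e-12)
  }
})

test_that("fully shared samples with identical outcomes give p = 1", {
  o <- cbind(c(TRUE, TRUE, FALSE, TRUE, FALSE), c(TRUE, TRUE, FALSE, TRUE, FALSE))
  r <- suppressWarnings(overlapping_proportions_test(3, 5, 3, 5, o))
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)
})

test_that("degenerate variance with unequal proportions is an error", {
  # constant outcomes on both sides, zero variance terms, p1 != p2
  o <- cbind(rep(TRUE, 4), rep(FALSE, 4))
  expect_error(
    suppressWarnings(overlapping_proportions_test(4, 4, 0, 4, o)),
    class = "crcqi_degenerate_variance")
})

test_that("the overlap correction shrinks the standard error under positive correlation", {
  set.seed(31)
  o <- cbind(runif(40) < 0.6, logical(40))
  o[, 2] <- ifelse(runif(40) < 0.85, o[, 1], runif(40) < 0.6)
  r_cor <- suppressWarnings(overlapping_proportions_test(35, 60, 33, 60, o))
  r_ind <- suppressWarnings(overlapping_proportions_test(35, 60, 33, 60))
  expect_true(r_cor$covariance > 0)
  expect_lt(r_cor$standard_error, r_ind$standard_error)
})
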
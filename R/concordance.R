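# Cross-source agreement: cross-classification of indicator selections,
# diagnostic-accuracy statistics, and the covariance-corrected z-test for
# proportions estimated from overlapping samples.

#' Cross-classify an indicator element across the two sources
#'
#' Counts, with the registry as reference standard: `tp` — matched pairs
#' selected on both sides; `ref_only` — reference-selected patients not
#' counted in `tp` (including unmatched ones); `test_only` — symmetric;
#' `tn` — matched pairs inside both universes selected by neither side. The
#' universes are the element's eligible populations (for a numerator element,
#' each source's denominator selection), whose sizes `n_ref` / `n_test` fix
#' the negatives used by specificity and NPV.
#'
#' @param reference_selected,test_selected character id vectors.
#' @param reference_universe,test_universe character id vectors; selections
#'   must be subsets of their universes.
#' @param matches a `qi_match` from [match_patients()].
#' @param element optional element label carried into the result.
#' @return a `qi_crosstab` list with fields `tp`, `ref_only`, `test_only`,
#'   `tn`, `n_ref`, `n_test`.
#' @export
cross_classify <- function(reference_selected, test_selected,
                           reference_universe, test_universe, matches,
                           element = NULL) {
  if (!all(reference_selected %in% reference_universe))
    stop_crcqi("reference selection is not a subset of its universe",
               "crcqi_consistency_error")
  if (!all(test_selected %in% test_universe))
    stop_crcqi("test selection is not a subset of its universe",
               "crcqi_consistency_error")
  pr <- matches$pairs$registry_id
  pe <- matches$pairs$emr_id
  rsel <- pr %in% reference_selected
  esel <- pe %in% test_selected
  tp <- sum(rsel & esel)
  tn <- sum(pr %in% reference_universe & pe %in% test_universe & !rsel & !esel)
  out <- list(element = element,
              tp = tp,
              ref_only = length(reference_selected) - tp,
              test_only = length(test_selected) - tp,
              tn = tn,
              n_ref = length(reference_universe),
              n_test = length(test_universe))
  class(out) <- "qi_crosstab"
  out
}

#' Diagnostic-accuracy statistics from a cross-classification
#'
#' With the registry as reference: sensitivity `tp / (tp + ref_only)`, PPV
#' `tp / (tp + test_only)`. Negatives are defined within each source's
#' eligible universe: reference negatives `n_ref - (tp + ref_only)`, test
#' negatives `n_test - (tp + test_only)`; specificity is `tn` over reference
#' negatives and NPV `tn` over test negatives. Likelihood ratios derive from
#' sensitivity and specificity. Any statistic with a zero denominator (or a
#' degenerate specificity for a ratio) is undefined (`NA`), never an error.
#'
#' @param crosstab a `qi_crosstab` from [cross_classify()].
#' @return a `qi_accuracy` list: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `plr`, `nlr`, plus the `counts` behind each proportion.
#' @export
accuracy_stats <- function(crosstab) {
  ct <- crosstab
  ref_neg <- ct$n_ref - (ct$tp + ct$ref_only)
  test_neg <- ct$n_test - (ct$tp + ct$test_only)
  if (ref_neg < 0 || test_neg < 0)
    stop_crcqi("selection larger than its universe", "crcqi_consistency_error")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(ct$tp, ct$tp + ct$ref_only)
  spec <- ratio(ct$tn, ref_neg)
  out <- list(
    sensitivity = sens,
    specificity = spec,
    ppv = ratio(ct$tp, ct$tp + ct$test_only),
    npv = ratio(ct$tn, test_neg),
    plr = if (!is.na(sens) && !is.na(spec) && spec < 1) sens / (1 - spec) else NA_real_,
    nlr = if (!is.na(sens) && !is.na(spec) && spec > 0) (1 - sens) / spec else NA_real_,
    counts = list(
      sensitivity = c(ct$tp, ct$tp + ct$ref_only),
      specificity = c(ct$tn, ref_neg),
      ppv = c(ct$tp, ct$tp + ct$test_only),
      npv = c(ct$tn, test_neg))
  )
  class(out) <- "qi_accuracy"
  out
}

#' Compare two proportions estimated from overlapping samples
#'
#' z-test for `p1 - p2` when the two samples share `m` subjects, so the two
#' estimators are correlated. Among the shared subjects let `q1`, `q2` and
#' `q11` be the proportions positive on measure 1, on measure 2 and on both;
#' the covariance of the estimators is `m (q11 - q1 q2) / (n1 n2)` and the
#' variance of the difference is
#' `p1 (1 - p1) / n1 + p2 (1 - p2) / n2 - 2 cov` (floored at zero). With
#' `m = 0` this is exactly the unpooled two-proportion z-test. Normal
#' approximation, no continuity correction; a small-sample warning is issued
#' when any expected cell is below 5.
#'
#' @param x1,n1 successes and size of sample 1.
#' @param x2,n2 successes and size of sample 2.
#' @param overlap paired outcomes for the shared subjects: a two-column
#'   logical/0-1 matrix or data.frame (columns: outcome under measure 1,
#'   outcome under measure 2), or `NULL` for disjoint samples.
#' @return a `qi_overlap_test` list: `p1`, `p2`, `n1`, `n2`, `m`, `q1`, `q2`,
#'   `q11`, `covariance`, `standard_error`, `z`, `p_value` (two-sided).
#' @export
overlapping_proportions_test <- function(x1, n1, x2, n2, overlap = NULL) {
  stopifnot(x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2, n1 > 0, n2 > 0)
  if (is.null(overlap)) overlap <- matrix(logical(0), ncol = 2)
  overlap <- as.matrix(overlap)
  if (ncol(overlap) != 2)
    stop_crcqi("overlap must have two outcome columns", "crcqi_consistency_error")
  m <- nrow(overlap)
  if (m > min(n1, n2))
    stop_crcqi("overlap larger than a sample", "crcqi_consistency_error")
  p1 <- x1 / n1; p2 <- x2 / n2
  if (m > 0) {
    o1 <- as.logical(overlap[, 1]); o2 <- as.logical(overlap[, 2])
    q1 <- mean(o1); q2 <- mean(o2); q11 <- mean(o1 & o2)
  } else q1 <- q2 <- q11 <- NA_real_
  covv <- if (m > 0) m * (q11 - q1 * q2) / (n1 * n2) else 0
  v <- p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2 - 2 * covv
  v <- max(v, 0)
  se <- sqrt(v)
  if (p1 == p2) {
    z <- 0; p <- 1
  } else if (se == 0) {
    stop_crcqi("degenerate variance with unequal proportions",
               "crcqi_degenerate_variance")
  } else {
    z <- (p1 - p2) / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  if (min(x1, n1 - x1, x2, n2 - x2) < 5)
    warning("small expected cell count (< 5); normal approximation may be poor",
            call. = FALSE)
  structure(list(p1 = p1, p2 = p2, n1 = n1, n2 = n2, m = m,
                 q1 = q1, q2 = q2, q11 = q11,
                 covariance = covv, standard_error = se,
                 z = z, p_value = p),
            class = "qi_overlap_test")
}

# Render a value-or-NA as text with "-" for undefined, as in printed reports.
fmt_undef <- function(x, digits = 2) {
  ifelse(is.na(x), "-", formatC(x, digits = digits, format = "f"))
}

#' Accuracy/comparison table across sources
#'
#' One row per indicator with defined numerators on both sources: registry
#' and EMR percentages, accuracy statistics and the overlapping-samples
#' p-value. Undefined entries are `NA` (rendered `-` on write).
#'
#' @param rows a list of lists with fields `indicator`, `registry`, `emr`
#'   (qi_result), `accuracy` (qi_accuracy), `test` (qi_overlap_test or NULL).
#' @param locale `"point"` (default) or `"comma"` for decimal rendering of
#'   the formatted columns.
#' @return data.frame.
#' @export
accuracy_table <- function(rows, locale = "point") {
  fmt <- function(x, d = 2) {
    s <- fmt_undef(x, d)
    if (locale == "comma") gsub(".", ",", s, fixed = TRUE) else s
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    a <- r$accuracy
    data.frame(
      indicator = r$indicator,
      registry_pct = r$registry$percentage_rounded,
      registry_fraction = sprintf("%d/%d", r$registry$count$numerator,
                                  r$registry$count$denominator),
      emr_pct = r$emr$percentage_rounded,
      emr_fraction = sprintf("%d/%d", r$emr$count$numerator,
                             r$emr$count$denominator),
      sensitivity = a$sensitivity, specificity = a$specificity,
      ppv = a$ppv, npv = a$npv,
      plr = fmt(a$plr), nlr = fmt(a$nlr),
      p_value = if (is.null(r$test)) NA_real_ else r$test$p_value
    )
  }))
  rownames(out) <- NULL
  out
}
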
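# Deterministic cross-source record linkage without shared identifiers.
#
# Patients are blocked on the exact compound key (gender, year of birth,
# operation date). Within a block, candidate pairs are ranked by Jaccard
# similarity of their procedure-class sets, and the block is resolved to the
# assignment(s) of maximal cardinality and, among those, maximal total
# similarity. Pairs common to every optimal assignment are matched; records
# whose partner differs between optimal assignments are reported ambiguous
# and counted unmatched — identity cannot be decided from the available
# fields, and guessing silently would corrupt every downstream statistic.

jaccard_sets <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

procedure_set <- function(cohort, i) {
  if (cohort$procedure_status[i] != "present" || is.na(cohort$procedure[i]))
    return(character(0))
  sort(unique(strsplit(cohort$procedure[i], ";", fixed = TRUE)[[1]]))
}

# All injective assignments from the smaller side into the larger; blocks are
# small (patients sharing gender, birth year and operation date), so full
# enumeration is feasible. A safety cap guards pathological inputs.
enumerate_assignments <- function(nr, ne, cap = 50000L) {
  swap <- nr > ne
  k <- min(nr, ne); n <- max(nr, ne)
  if (k == 0) {
    res <- list(integer(0))
    attr(res, "swapped") <- swap
    return(res)
  }
  count <- prod(seq(n, n - k + 1))
  if (count > cap)
    stop_crcqi("matching block too large to resolve exactly", "crcqi_match_error")
  res <- list()
  rec <- function(chosen, remaining) {
    if (length(chosen) == k) { res[[length(res) + 1L]] <<- chosen; return() }
    for (j in remaining) rec(c(chosen, j), setdiff(remaining, j))
  }
  rec(integer(0), seq_len(n))
  attr(res, "swapped") <- swap
  res
}

resolve_block <- function(reg, emr, sim) {
  nr <- nrow(reg); ne <- nrow(emr)
  asg <- enumerate_assignments(nr, ne)
  swapped <- isTRUE(attr(asg, "swapped"))
  score <- vapply(asg, function(a) {
    if (length(a) == 0) return(0)
    if (swapped) sum(sim[cbind(a, seq_along(a))]) else sum(sim[cbind(seq_along(a), a)])
  }, numeric(1))
  best <- which(score >= max(score) - 1e-12)
  # pairs present in every optimal assignment are safe; the rest are ambiguous
  pair_key <- function(a) {
    if (swapped) paste(a, seq_along(a)) else paste(seq_along(a), a)
  }
  keys <- lapply(asg[best], pair_key)
  stable <- Reduce(intersect, keys)
  all_pairs <- unique(unlist(keys))
  amb_keys <- setdiff(all_pairs, stable)
  parse_pairs <- function(kk) {
    if (length(kk) == 0) return(matrix(integer(0), ncol = 2))
    do.call(rbind, lapply(strsplit(kk, " "), as.integer))
  }
  list(matched = parse_pairs(stable), ambiguous = parse_pairs(amb_keys))
}

#' Match patients across the registry and EMR datasets
#'
#' Exact agreement on gender, year of birth and operation date defines
#' candidate blocks; procedure-set Jaccard similarity resolves blocks with
#' several candidates. Records lacking any key field are reported unmatched
#' with a reason. Groups whose optimal pairing is not unique are reported
#' ambiguous (and counted unmatched), never silently assigned. The result is
#' independent of input row order, and swapping the two datasets transposes
#' the matched pairs.
#'
#' @param registry_dataset,emr_dataset cohort data.frames.
#' @param date_window days of tolerated operation-date disagreement within a
#'   gender/year-of-birth block; default 0 (exact-date matching).
#' @return a `qi_match` list: `pairs` (data.frame `registry_id`, `emr_id`,
#'   `similarity`), `unmatched_registry` / `unmatched_emr` (data.frames with a
#'   `reason`), `ambiguous` (list of candidate groups).
#' @export
match_patients <- function(registry_dataset, emr_dataset, date_window = 0) {
  key_ok <- function(d) {
    !is.na(d$gender) &
      d$year_of_birth_status == "present" & !is.na(d$year_of_birth) &
      d$operation_date_status == "present" & !is.na(d$operation_date)
  }
  rok <- key_ok(registry_dataset); eok <- key_ok(emr_dataset)
  reg <- registry_dataset[rok, , drop = FALSE]
  emr <- emr_dataset[eok, , drop = FALSE]
  # canonical order for determinism
  reg <- reg[order(reg$patient_id), , drop = FALSE]
  emr <- emr[order(emr$patient_id), , drop = FALSE]

  block_of <- function(d) paste(d$gender, d$year_of_birth)
  pairs <- data.frame(registry_id = character(), emr_id = character(),
                      similarity = numeric())
  ambiguous <- list()
  matched_r <- character(); matched_e <- character()
  amb_r <- character(); amb_e <- character()

  rb <- block_of(reg); eb <- block_of(emr)
  for (b in sort(unique(intersect(rb, eb)))) {
    r1 <- reg[rb == b, , drop = FALSE]
    e1 <- emr[eb == b, , drop = FALSE]
    # sub-block on operation date (exact, or linked within the date window)
    if (date_window == 0) {
      sub_keys <- sort(unique(intersect(format(r1$operation_date),
                                        format(e1$operation_date))))
      subs <- lapply(sub_keys, function(k) list(
        r = r1[format(r1$operation_date) == k, , drop = FALSE],
        e = e1[format(e1$operation_date) == k, , drop = FALSE]))
    } else {
      # connected components under |date difference| <= window
      all_d <- sort(unique(c(r1$operation_date, e1$operation_date)))
      comp <- cumsum(c(1, diff(all_d) > date_window))
      subs <- lapply(unique(comp), function(ci) {
        ds <- all_d[comp == ci]
        list(r = r1[r1$operation_date %in% ds, , drop = FALSE],
             e = e1[e1$operation_date %in% ds, , drop = FALSE])
      })
    }
    for (s in subs) {
      if (nrow(s$r) == 0 || nrow(s$e) == 0) next
      rsets <- lapply(seq_len(nrow(s$r)), function(i) procedure_set(s$r, i))
      esets <- lapply(seq_len(nrow(s$e)), function(j) procedure_set(s$e, j))
      sim <- outer(seq_along(rsets), seq_along(esets),
                   Vectorize(function(i, j) jaccard_sets(rsets[[i]], esets[[j]])))
      res <- resolve_block(s$r, s$e, sim)
      if (nrow(res$matched)) {
        pairs <- rbind(pairs, data.frame(
          registry_id = s$r$patient_id[res$matched[, 1]],
          emr_id = s$e$patient_id[res$matched[, 2]],
          similarity = sim[res$matched]))
        matched_r <- c(matched_r, s$r$patient_id[res$matched[, 1]])
        matched_e <- c(matched_e, s$e$patient_id[res$matched[, 2]])
      }
      if (nrow(res$ambiguous)) {
        ambiguous[[length(ambiguous) + 1L]] <- list(
          registry_ids = sort(unique(s$r$patient_id[res$ambiguous[, 1]])),
          emr_ids = sort(unique(s$e$patient_id[res$ambiguous[, 2]])))
        amb_r <- c(amb_r, s$r$patient_id[res$ambiguous[, 1]])
        amb_e <- c(amb_e, s$e$patient_id[res$ambiguous[, 2]])
      }
    }
  }
  reason <- function(ids_all, ok, matched, amb) {
    ids <- ids_all[ok]
    un <- setdiff(ids, matched)
    r <- ifelse(un %in% amb, "ambiguous_candidates", "no_key_agreement")
    rbind(data.frame(id = un, reason = r),
          data.frame(id = ids_all[!ok],
                     reason = rep("missing_key_field", sum(!ok))))
  }
  out <- list(
    pairs = pairs[order(pairs$registry_id), , drop = FALSE],
    unmatched_registry = reason(registry_dataset$patient_id, rok, matched_r,
                                unique(amb_r)),
    unmatched_emr = reason(emr_dataset$patient_id, eok, matched_e, unique(amb_e)),
    ambiguous = ambiguous
  )
  rownames(out$pairs) <- NULL
  class(out) <- "qi_match"
  out
}

#' Matching flow summary
#'
#' Flow counts in the shape of a patient-inclusion diagram: included per
#' source, matched, selected by the EMR cohort query, and unmatched with
#' reasons.
#'
#' @param match a `qi_match` from [match_patients()].
#' @param registry_dataset,emr_dataset the matched cohorts.
#' @param emr_selected optional character vector: EMR patients selected by
#'   the inclusion query (e.g. the audit-indicator denominator).
#' @return data.frame of `step`, `n`.
#' @export
match_flow_summary <- function(match, registry_dataset, emr_dataset,
                               emr_selected = NULL) {
  rows <- list(
    c("included_registry", nrow(registry_dataset)),
    c("included_emr", nrow(emr_dataset)),
    c("matched_pairs", nrow(match$pairs)),
    c("unmatched_registry", nrow(match$unmatched_registry)),
    c("unmatched_emr", nrow(match$unmatched_emr)),
    c("ambiguous_groups", length(match$ambiguous))
  )
  if (!is.null(emr_selected)) {
    sel_matched <- sum(match$pairs$emr_id %in% emr_selected)
    rows <- c(rows, list(
      c("emr_selected_by_query", length(emr_selected)),
      c("matched_and_selected", sel_matched),
      c("matched_not_selected", nrow(match$pairs) - sel_matched)))
  }
  data.frame(step = vapply(rows, `[`, character(1), 1),
             n = as.integer(vapply(rows, `[`, character(1), 2)))
}
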
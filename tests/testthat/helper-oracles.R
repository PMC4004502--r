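# Independent reference implementations used as oracles. Deliberately naive
# and per-record: no vectorisation, explicit Kleene truth tables, plain
# loops. They must stay structurally independent of the package internals
# they check.

S <- "satisfied"; N <- "not_satisfied"; U <- "undetermined"

k_and2 <- function(a, b) if (a == N || b == N) N else if (a == U || b == U) U else S
k_or2 <- function(a, b) if (a == S || b == S) S else if (a == U || b == U) U else N
k_not <- function(a) if (a == S) N else if (a == N) S else U

oracle_eval <- function(rec, p, strict = FALSE, umap = default_urgency_map()) {
  st <- function(item) rec[[paste0(item, "_status")]]
  pres <- function(item) identical(st(item), "present")
  if (p$type == "and") return(Reduce(k_and2, lapply(p$args, oracle_eval, rec = rec,
                                                    strict = strict, umap = umap)))
  if (p$type == "or") return(Reduce(k_or2, lapply(p$args, oracle_eval, rec = rec,
                                                  strict = strict, umap = umap)))
  if (p$type == "not") return(k_not(oracle_eval(rec, p$args[[1]], strict, umap)))
  if (p$type == "cmp") {
    cols <- switch(p$item,
      diagnosis = c("diagnosis_location", "diagnosis_primary", "diagnosis_date"),
      colonoscopy = c("colonoscopy_performed", "colonoscopy_complete",
                      "colonoscopy_date"),
      p$item)
    col <- if (is.null(p$field)) cols[1] else cols[endsWith(cols, p$field)]
    v <- rec[[col]]
    if (!pres(p$item) || is.na(v)) return(U)
    r <- switch(p$op, eq = v == p$value, ne = v != p$value, lt = v < p$value,
                le = v <= p$value, gt = v > p$value, ge = v >= p$value,
                "in" = v %in% p$value)
    return(if (is.na(r)) U else if (r) S else N)
  }
  if (p$type == "date_before") {
    cols <- switch(p$item,
      colonoscopy = c("colonoscopy_performed", "colonoscopy_complete",
                      "colonoscopy_date"),
      p$item)
    col <- if (is.null(p$field)) cols[1] else cols[endsWith(cols, p$field)]
    v <- rec[[col]]
    if (!pres(p$item) || is.na(v) || !pres("operation_date") ||
        is.na(rec$operation_date)) return(U)
    return(if (v < rec$operation_date) S else N)
  }
  if (p$type == "diagnosis") {
    if (!pres("diagnosis") || is.na(rec$diagnosis_location)) return(U)
    ok <- rec$diagnosis_location %in% p$locations
    if (!is.na(rec$diagnosis_primary) && !rec$diagnosis_primary) ok <- FALSE
    if (!is.na(rec$diagnosis_date) && !is.na(rec$operation_date) &&
        rec$diagnosis_date > rec$operation_date) ok <- FALSE
    return(if (ok) S else N)
  }
  if (p$type == "procedure") {
    if (!pres("procedure") || is.na(rec$procedure)) return(U)
    codes <- strsplit(rec$procedure, ";", fixed = TRUE)[[1]]
    return(if (length(intersect(codes, p$classes)) > 0) S else N)
  }
  if (p$type == "elective") {
    if (!pres("operation_urgency") || is.na(rec$operation_urgency)) return(U)
    mapped <- umap[[rec$operation_urgency]] %||NA% NA
    if (is.na(mapped)) return(U)
    return(if (mapped == "elective") S else N)
  }
  if (p$type == "age") {
    if (!pres("year_of_birth") || is.na(rec$year_of_birth) ||
        !pres("operation_date") || is.na(rec$operation_date)) return(U)
    age <- as.integer(format(rec$operation_date, "%Y")) - rec$year_of_birth
    r <- switch(p$op, lt = age < p$value, ge = age >= p$value,
                le = age <= p$value, gt = age > p$value)
    return(if (r) S else N)
  }
  if (p$type == "exclusion") {
    v <- rec[[p$item]]
    if (identical(st(p$item), "present") && !is.na(v))
      return(if (v) S else N)
    return(if (strict) U else N)
  }
  stop("oracle: unknown predicate type ", p$type)
}

`%||NA%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

oracle_select <- function(dataset, def, element, strict = FALSE) {
  out <- character(0)
  for (i in seq_len(nrow(dataset))) {
    rec <- dataset[i, , drop = FALSE]
    den <- oracle_eval(rec, def$denominator, strict)
    ex <- if (is.null(def$exclusion)) N else oracle_eval(rec, def$exclusion, strict)
    excluded <- if (strict) ex != N else ex == S
    sel <- if (element == "denominator") den == S && !excluded
    else den == S && oracle_eval(rec, def$numerator, strict) == S && !excluded
    if (sel) out <- c(out, dataset$patient_id[i])
  }
  sort(out)
}

# --- brute-force matcher -----------------------------------------------------

oracle_jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(unique(c(a, b)))
}

oracle_proc_set <- function(d, i) {
  if (d$procedure_status[i] != "present" || is.na(d$procedure[i])) return(character(0))
  unique(strsplit(d$procedure[i], ";", fixed = TRUE)[[1]])
}

# all injective assignments registry-side -> emr-side (indices)
oracle_assignments <- function(nr, ne) {
  if (nr == 0) return(list(integer(0)))
  out <- list()
  gen <- function(prefix, used) {
    i <- length(prefix) + 1
    if (i > min(nr, ne)) { out[[length(out) + 1]] <<- prefix; return() }
    for (j in setdiff(seq_len(ne), used)) gen(c(prefix, j), c(used, j))
  }
  if (nr <= ne) { gen(integer(0), integer(0)); lapply(out, identity) }
  else {
    # enumerate which registry records get a partner, in order
    combs <- utils::combn(nr, ne, simplify = FALSE)
    res <- list()
    for (rows in combs) {
      perms <- oracle_perms(ne)
      for (p in perms) {
        a <- rep(NA_integer_, nr); a[rows] <- p
        res[[length(res) + 1]] <- a
      }
    }
    res
  }
}

oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) for (p in oracle_perms(n - 1)) {
    q <- ifelse(p >= i, p + 1L, p)
    out[[length(out) + 1]] <- c(i, q)
  }
  out
}

oracle_match <- function(reg, emr) {
  key <- function(d) paste(d$gender, d$year_of_birth, format(d$operation_date))
  ok <- function(d) !is.na(d$gender) & d$year_of_birth_status == "present" &
    d$operation_date_status == "present"
  reg <- reg[ok(reg), , drop = FALSE]; emr <- emr[ok(emr), , drop = FALSE]
  pairs <- data.frame(registry_id = character(), emr_id = character())
  amb_ids <- character(0)
  for (b in unique(key(reg))) {
    r <- reg[key(reg) == b, , drop = FALSE]
    e <- emr[key(emr) == b, , drop = FALSE]
    if (nrow(e) == 0) next
    r <- r[order(r$patient_id), , drop = FALSE]
    e <- e[order(e$patient_id), , drop = FALSE]
    sims <- matrix(0, nrow(r), nrow(e))
    for (i in seq_len(nrow(r))) for (j in seq_len(nrow(e)))
      sims[i, j] <- oracle_jaccard(oracle_proc_set(r, i), oracle_proc_set(e, j))
    asg <- oracle_assignments(nrow(r), nrow(e))
    score <- sapply(asg, function(a) {
      s <- 0
      for (i in seq_along(a)) if (!is.na(a[i])) s <- s + sims[i, a[i]]
      s
    })
    best <- asg[score >= max(score) - 1e-12]
    keyset <- lapply(best, function(a) {
      ks <- character(0)
      for (i in seq_along(a)) if (!is.na(a[i]))
        ks <- c(ks, paste(r$patient_id[i], e$patient_id[a[i]]))
      ks
    })
    stable <- Reduce(intersect, keyset)
    unstable <- setdiff(unique(unlist(keyset)), stable)
    for (k in stable) {
      ids <- strsplit(k, " ")[[1]]
      pairs <- rbind(pairs, data.frame(registry_id = ids[1], emr_id = ids[2]))
    }
    amb_ids <- c(amb_ids, unique(unlist(strsplit(unstable, " "))))
  }
  pairs <- pairs[order(pairs$registry_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, ambiguous_ids = sort(unique(amb_ids)))
}

# --- random data -------------------------------------------------------------

# random small cohort exercising all statuses; uses the caller's RNG stream
random_cohort <- function(n, source = "registry", p_present = 0.7,
                          key_pool = 3) {
  co <- new_cohort(n, source = source)
  base <- as.Date("2011-06-01")
  keys <- data.frame(g = sample(c("male", "female"), key_pool, TRUE),
                     y = sample(1940:1944, key_pool, TRUE),
                     d = base + sample(0:2, key_pool, TRUE))
  pick <- sample(key_pool, n, TRUE)
  co$gender <- keys$g[pick]
  sts <- function() sample(qi_statuses(), n, TRUE,
                           prob = c(p_present, rep((1 - p_present) / 3, 3)))
  rnd_date <- function(lo, hi) base + sample(lo:hi, n, TRUE)
  co$year_of_birth <- keys$y[pick]; co$year_of_birth_status <- sts()
  co$operation_date <- keys$d[pick]; co$operation_date_status <- sts()
  co$procedure <- sample(c("colectomy", "rectum_resection",
                           "colectomy;stoma_formation", "appendectomy"), n, TRUE)
  co$procedure_status <- sts()
  co$operation_urgency <- sample(c("elective", "urgent", "emergency", "acute",
                                   "scheduled", "extra"), n, TRUE)
  co$operation_urgency_status <- sts()
  co$diagnosis_location <- sample(c("colon", "rectosigmoid", "rectum"), n, TRUE)
  co$diagnosis_primary <- sample(c(TRUE, TRUE, FALSE, NA), n, TRUE)
  co$diagnosis_date <- rnd_date(-60, 20)
  co$diagnosis_status <- sts()
  co$ct <- sample(c("T1", "T2", "T3", "T4"), n, TRUE); co$ct_status <- sts()
  co$pn <- sample(c("N0", "N1", "N2"), n, TRUE); co$pn_status <- sts()
  co$pm <- sample(c("M0", "M1"), n, TRUE); co$pm_status <- sts()
  co$examined_lymph_nodes <- sample(0:20, n, TRUE)
  co$examined_lymph_nodes_status <- sts()
  co$circumferential_margin <- round(stats::runif(n, 0, 5), 1)
  co$circumferential_margin_status <- sts()
  co$colonoscopy_performed <- sample(c(TRUE, FALSE), n, TRUE)
  co$colonoscopy_complete <- sample(c(TRUE, FALSE, NA), n, TRUE)
  co$colonoscopy_date <- rnd_date(-50, 10)
  co$colonoscopy_status <- sts()
  co$chemotherapy <- sample(c(TRUE, FALSE), n, TRUE)
  co$chemotherapy_status <- sts()
  co$meeting_date <- rnd_date(-20, 20); co$meeting_date_status <- sts()
  co$radiotherapy_start_date <- rnd_date(-40, 15)
  co$radiotherapy_start_date_status <- sts()
  for (it in qi_exclusion_items()) {
    co[[it]] <- sample(c(TRUE, FALSE), n, TRUE)
    co[[paste0(it, "_status")]] <- sample(c("absent", "present"), n, TRUE,
                                          prob = c(0.8, 0.2))
  }
  co
}
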
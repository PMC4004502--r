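# Small shared helpers.

#' Round half away from zero
#'
#' Printed indicator and data-quality percentages use commercial ("half-up")
#' rounding, not the IEEE round-half-even rule of [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percentage with explicit NA on a zero/undefined denominator.
pct_of <- function(num, den) {
  if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
  100 * num / den
}

# Run an expression with a local RNG state seeded at `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a classed condition so callers can test for specific failures.
stop_crcqi <- function(msg, class) {
  stop(structure(
    class = c(class, "crcqi_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
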
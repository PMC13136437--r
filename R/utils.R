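#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rnorm rbinom runif rlnorm rgamma qt sd var coef lm
#' @importFrom utils read.csv write.csv
NULL

# Canonical level orderings used throughout the pipeline.  HOLC grades run
# best -> hazardous (severity order); "unclassified" means the tract lay
# outside the 1930s graded area.
holc_levels <- function() {
  c("best", "still_desirable", "definitely_declining", "hazardous",
    "unclassified")
}

gentrification_levels <- function() {
  c("ineligible", "earlier", "recent", "none")
}

income_class_levels <- function() c("lower", "moderate", "higher")

magnitude_levels <- function() {
  c("major_decline", "minor_decline", "minor_increase", "major_increase")
}

mover_type_levels <- function() {
  c("non_mover", "within_metro_mover", "out_of_metro_or_lost",
    "in_from_outside")
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; report percentages use the
#' half-up convention so printed one-decimal figures match conventional
#' arithmetic (e.g. 55/1457 = 3.7748... -> 3.8).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage with one-decimal half-up rounding
#'
#' @param num numerator count
#' @param den denominator count
#' @return percentage rounded to one decimal
#' @export
pct_report <- function(num, den) {
  stopifnot(den > 0)
  round_half_up(100 * num / den, 1)
}

# Empirical quartile cut with lower-value tie assignment: an observation
# exactly at a cut point goes to the lower category.  Uses type-1
# (inverse-CDF) quantiles so cuts are observed values, integer-friendly.
quartile_bin <- function(x) {
  qs <- quantile(x, probs = c(0.25, 0.50, 0.75), type = 1, names = FALSE)
  findInterval(x, qs, left.open = TRUE) + 1L
}

# Simple structured log message; every exclusion rule reports
# (rule, n removed, percent to one decimal).
log_filter <- function(rule, n_removed, n_total, verbose = TRUE) {
  pct <- if (n_total > 0) pct_report(n_removed, n_total) else 0
  if (verbose) {
    message(sprintf("[%s] removed %d of %d (%.1f%%)",
                    rule, n_removed, n_total, pct))
  }
  list(rule = rule, n_removed = as.integer(n_removed),
       n_total = as.integer(n_total), percent = pct)
}

# Derive a bounded child seed from a base seed and a stage label so that
# stages are independently reproducible.  Kept below 2^31.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1103515245 + h) %% 2147483647)
}
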
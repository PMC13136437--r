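# Independent brute-force oracles used to cross-check the package's
# classifiers and tallies.  These are deliberately written as plain loops
# over definitions, sharing no code with the implementation.

# Income classes by sorting and cutting at the 25th/75th percentile
# (type-7, matching the documented quartile estimator).
oracle_income_class <- function(income) {
  q1 <- quantile(income, 0.25, type = 7, names = FALSE)
  q3 <- quantile(income, 0.75, type = 7, names = FALSE)
  out <- character(length(income))
  for (i in seq_along(income)) {
    out[i] <- if (income[i] <= q1) "lower"
              else if (income[i] > q3) "higher" else "moderate"
  }
  out
}

# Magnitude categories by sorting and cutting at type-1 quartiles with
# lower-value tie assignment, zero mapped to minor_decline.
oracle_magnitude <- function(nets) {
  xs <- sort(nets)
  q <- function(p) xs[max(1, ceiling(p * length(xs)))]
  cuts <- c(q(0.25), q(0.50), q(0.75))
  out <- character(length(nets))
  for (i in seq_along(nets)) {
    x <- nets[i]
    out[i] <- if (x == 0) "minor_decline"
      else if (x <= cuts[1]) "major_decline"
      else if (x <= cuts[2]) "minor_decline"
      else if (x <= cuts[3]) "minor_increase"
      else "major_increase"
  }
  out
}

# Gentrification status from first principles: eligibility by the 1.4 x
# metro-mean income rule, thresholds mean + 1 sd of eligible scores.
oracle_gentrification <- function(income, score1, score2) {
  elig <- income < 1.4 * mean(income)
  thr1 <- mean(score1[elig]) + sd(score1[elig])
  thr2 <- mean(score2[elig]) + sd(score2[elig])
  out <- character(length(income))
  for (i in seq_along(income)) {
    out[i] <- if (!elig[i]) "ineligible"
      else if (score1[i] >= thr1) "earlier"
      else if (score2[i] >= thr2) "recent"
      else "none"
  }
  out
}

# Event-by-event tally of net changes from mover contributions.
oracle_net_tally <- function(moves, classes, tract_ids) {
  net <- matrix(0L, length(tract_ids), 3,
                dimnames = list(tract_ids,
                                c("lower", "moderate", "higher")))
  for (i in seq_len(nrow(moves))) {
    k <- classes$income_class[classes$household_id ==
                                moves$household_id[i]]
    if (!is.na(moves$in_tract[i])) {
      net[moves$in_tract[i], k] <- net[moves$in_tract[i], k] + 1L
    }
    if (!is.na(moves$out_tract[i])) {
      net[moves$out_tract[i], k] <- net[moves$out_tract[i], k] - 1L
    }
  }
  net
}

# Closed-form normal-equations OLS.
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Mover type per the first/last-location coding rules, written as a
# direct transcription of the definitions.
oracle_mover_type <- function(res_seq, years, tract_ids) {
  obs <- which(!is.na(res_seq))
  first <- res_seq[obs[1]]
  last <- res_seq[obs[length(obs)]]
  gone_early <- years[obs[length(obs)]] < max(years)
  fin <- first %in% tract_ids
  lin <- last %in% tract_ids
  if (fin && lin && !gone_early) {
    if (first == last) "non_mover" else "within_metro_mover"
  } else if (fin) {
    "out_of_metro_or_lost"
  } else if (lin) {
    "in_from_outside"
  } else NA_character_
}

# Small metro config used across tests (fast to simulate).
quick_config <- function(...) {
  metro_config(n_rows = 6, n_cols = 6, n_households_per_tract = 30, ...)
}

# Long-format panel from a named list of residence vectors plus incomes.
make_panel <- function(residences, incomes, years = 2011:2018) {
  rows <- list()
  for (id in names(residences)) {
    rows[[id]] <- data.frame(household_id = id, year = years,
                             tract_id = residences[[id]],
                             income = incomes[[id]],
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
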
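#' Exclude tracts with missing life expectancy or population
#'
#' Tracts lacking a life-expectancy estimate or with missing/zero total
#' population are removed from the analysis set; the count and one-decimal
#' percentage are logged.
#'
#' @param tracts raw tract table with `life_expectancy` and `population`.
#' @param verbose log the exclusion summary.
#' @return list: `analysis` (retained tracts), `excluded_count`, `log`.
#' @export
filter_tracts <- function(tracts, verbose = TRUE) {
  bad <- is.na(tracts$life_expectancy) | is.na(tracts$population) |
    tracts$population <= 0
  if (all(bad)) {
    stop("filter_tracts: all tracts excluded (missing life expectancy ",
         "or population)", call. = FALSE)
  }
  lg <- log_filter("tract_missing_le_or_population", sum(bad), nrow(tracts),
                   verbose = verbose)
  list(analysis = tracts[!bad, , drop = FALSE],
       excluded_count = sum(bad), log = lg)
}

#' Population-weighted life expectancy by group
#'
#' Within each group, the mean is `sum(pop * LE) / sum(pop)` and the 95%
#' confidence interval is `mean +/- 1.96 * s_w / sqrt(m)`, where `s_w` is
#' the population-weighted standard deviation of tract life expectancy
#' (with an `m/(m-1)` small-sample correction) and `m` the number of
#' tracts in the group.  Input life-expectancy uncertainty is ignored.
#' Groups are returned in a stable canonical order (factor level order
#' where the grouping variable is one of the pipeline's categorical
#' labels, otherwise sorted).
#'
#' @param analysis analysis tract set (from [filter_tracts()]) with
#'   `life_expectancy`, `population` and the grouping column.
#' @param group name of the grouping column, or a character vector of two
#'   column names to cross-classify (e.g. HOLC grade x gentrification
#'   status, the "transformation status").
#' @return data.frame: `group`, `n_tracts`, `weighted_mean_le`, `ci_low`,
#'   `ci_high`.
#' @export
weighted_le_summary <- function(analysis, group) {
  if (length(group) == 2) {
    labels <- paste(analysis[[group[1]]], analysis[[group[2]]], sep = " / ")
  } else {
    labels <- as.character(analysis[[group]])
  }
  canon <- c(holc_levels(), gentrification_levels())
  if (length(group) == 1 && all(unique(labels) %in% canon)) {
    lev <- canon[canon %in% unique(labels)]
  } else if (length(group) == 2) {
    g1 <- holc_levels()[holc_levels() %in% unique(analysis[[group[1]]])]
    g2 <- gentrification_levels()[
      gentrification_levels() %in% unique(analysis[[group[2]]])]
    lev <- as.vector(t(outer(g1, g2, paste, sep = " / ")))
    lev <- lev[lev %in% unique(labels)]
  } else {
    lev <- sort(unique(labels))
  }
  rows <- lapply(lev, function(lv) {
    sub <- analysis[labels == lv, , drop = FALSE]
    w <- sub$population; x <- sub$life_expectancy
    m <- nrow(sub)
    mu <- sum(w * x) / sum(w)
    if (m == 1) {
      warning("weighted_le_summary: group '", lv,
              "' has a single tract; CI collapses to the point estimate")
      se <- 0
    } else {
      vw <- sum(w * (x - mu)^2) / sum(w) * m / (m - 1)
      se <- sqrt(vw) / sqrt(m)
    }
    data.frame(group = lv, n_tracts = m, weighted_mean_le = mu,
               ci_low = mu - 1.96 * se, ci_high = mu + 1.96 * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
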
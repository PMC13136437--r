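#' Assign an HOLC grade from overlay proportions
#'
#' A modern census tract can intersect several 1930s HOLC neighborhood
#' polygons; the tract's grade is the one covering the largest fraction of
#' the tract.  Tracts with no graded overlay are "unclassified".  Tied
#' overlay fractions resolve to the worse (more hazardous) grade, a
#' conservative convention toward the exposure of interest.
#'
#' @param overlay named numeric vector of overlay fractions; names among
#'   `best`, `still_desirable`, `definitely_declining`, `hazardous`.
#'   Fractions must be nonnegative and sum to at most 1 (the remainder is
#'   ungraded area).  An empty vector means no graded overlay.
#' @return one of the five HOLC grade strings.
#' @export
assign_holc_grade <- function(overlay) {
  grades <- setdiff(holc_levels(), "unclassified")
  if (length(overlay) == 0) return("unclassified")
  if (is.null(names(overlay)) || !all(names(overlay) %in% grades)) {
    stop("assign_holc_grade: overlay names must be HOLC grades",
         call. = FALSE)
  }
  if (any(overlay < 0)) {
    stop("assign_holc_grade: negative overlay fraction", call. = FALSE)
  }
  if (sum(overlay) > 1 + 1e-9) {
    stop("assign_holc_grade: overlay fractions sum to more than 1",
         call. = FALSE)
  }
  if (all(overlay == 0)) return("unclassified")
  # iterate worst -> best so ties resolve to the worse grade
  best_g <- NA_character_; best_f <- -Inf
  for (g in rev(grades)) {
    f <- if (g %in% names(overlay)) overlay[[g]] else 0
    if (f > best_f) { best_f <- f; best_g <- g }
  }
  best_g
}

#' Composite gentrification score over a time window
#'
#' The score is the weighted sum of percentage-point changes (end minus
#' start) in three tract attributes: percent college-educated residents,
#' percent short-tenured (<5 years) residents, and percent owner-occupied
#' housing units.  Default weights are equal.
#'
#' @param panel_start,panel_end lists or one-row data.frames carrying
#'   `pct_college`, `pct_short_tenure`, `pct_owner_occupied` in percent.
#' @param weights nonnegative weights for the three attributes, in the
#'   order above.
#' @return numeric score (weighted percentage points).
#' @export
composite_score <- function(panel_start, panel_end, weights = c(1, 1, 1)) {
  attrs <- c("pct_college", "pct_short_tenure", "pct_owner_occupied")
  for (a in attrs) {
    for (p in list(panel_start, panel_end)) {
      if (is.null(p[[a]]) || any(is.na(p[[a]]))) {
        stop("composite_score: attribute missing: ", a, call. = FALSE)
      }
    }
  }
  if (length(weights) != 3 || any(weights < 0)) {
    stop("composite_score: need three nonnegative weights", call. = FALSE)
  }
  delta <- vapply(attrs, function(a) {
    unname(panel_end[[a]] - panel_start[[a]])
  }, numeric(length(panel_start[[attrs[1]]])))
  if (is.null(dim(delta))) delta <- matrix(delta, nrow = 1)
  as.numeric(delta %*% weights)
}

#' Classify tract gentrification status
#'
#' Implements the Sutton-style two-window classification.  A tract is
#' *ineligible* when its baseline (2011) median household income is at
#' least 40% above the metropolitan-area average (inclusive).  Among
#' eligible tracts, a tract gentrified in a window when its composite
#' score is at least one standard deviation above the mean of eligible
#' tracts' scores in that window: *earlier* for the 2000-2010 window,
#' *recent* for 2011-2018, with earlier taking precedence when both
#' windows exceed their thresholds; otherwise *none*.  Score means and
#' standard deviations are computed over eligible tracts only.
#'
#' @param tracts tract table with `tract_id`, `median_income_2011` and
#'   attribute columns suffixed `_2000`, `_2011`, `_2018` for
#'   `pct_college`, `pct_short_tenure`, `pct_owner_occupied`.
#' @param weights composite-score weights (see [composite_score()]).
#' @return data.frame: `tract_id`, `gentrification_status`, `score_p1`
#'   (2000-2010 window), `score_p2` (2011-2018 window), plus the
#'   thresholds used as attributes `threshold_p1`, `threshold_p2`,
#'   `metro_income_mean`.
#' @export
classify_gentrification <- function(tracts, weights = c(1, 1, 1)) {
  slice <- function(suffix) {
    list(pct_college = tracts[[paste0("pct_college_", suffix)]],
         pct_short_tenure = tracts[[paste0("pct_short_tenure_", suffix)]],
         pct_owner_occupied =
           tracts[[paste0("pct_owner_occupied_", suffix)]])
  }
  score_p1 <- composite_score(slice("2000"), slice("2011"), weights)
  score_p2 <- composite_score(slice("2011"), slice("2018"), weights)

  metro_mean <- mean(tracts$median_income_2011)
  eligible <- tracts$median_income_2011 < 1.4 * metro_mean
  if (sum(eligible) < 2) {
    stop("classify_gentrification: fewer than 2 eligible tracts; ",
         "cannot form score standard deviation", call. = FALSE)
  }

  thr1 <- mean(score_p1[eligible]) + sd(score_p1[eligible])
  thr2 <- mean(score_p2[eligible]) + sd(score_p2[eligible])

  status <- ifelse(!eligible, "ineligible",
                   ifelse(score_p1 >= thr1, "earlier",
                          ifelse(score_p2 >= thr2, "recent", "none")))

  out <- data.frame(tract_id = tracts$tract_id,
                    gentrification_status = status,
                    score_p1 = score_p1, score_p2 = score_p2,
                    stringsAsFactors = FALSE)
  attr(out, "threshold_p1") <- thr1
  attr(out, "threshold_p2") <- thr2
  attr(out, "metro_income_mean") <- metro_mean
  out
}

#' Tract status table: HOLC grade plus gentrification status
#'
#' Convenience wrapper running [assign_holc_grade()] on the overlay
#' columns and [classify_gentrification()] on the attribute panel, and
#' combining both into the transformation-status table consumed by the
#' summaries and models.
#'
#' @param tracts tract table (see [classify_gentrification()]; overlay
#'   columns `holc_best`, `holc_still_desirable`,
#'   `holc_definitely_declining`, `holc_hazardous`).
#' @param weights composite-score weights.
#' @return data.frame: `tract_id`, `holc_grade`, `gentrification_status`,
#'   `score_p1`, `score_p2`.
#' @export
tract_status <- function(tracts, weights = c(1, 1, 1)) {
  ov_cols <- c(best = "holc_best", still_desirable = "holc_still_desirable",
               definitely_declining = "holc_definitely_declining",
               hazardous = "holc_hazardous")
  grade <- vapply(seq_len(nrow(tracts)), function(i) {
    ov <- vapply(ov_cols, function(cn) {
      if (cn %in% names(tracts)) tracts[[cn]][i] else 0
    }, numeric(1))
    assign_holc_grade(ov)
  }, character(1))
  g <- classify_gentrification(tracts, weights)
  data.frame(tract_id = tracts$tract_id, holc_grade = grade,
             gentrification_status = g$gentrification_status,
             score_p1 = g$score_p1, score_p2 = g$score_p2,
             stringsAsFactors = FALSE)
}
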
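# Household panel utilities: the long table (household_id, year, tract_id,
# income) is reshaped once into per-household residence/income matrices so
# the per-household rules are simple row operations.
panel_matrices <- function(households) {
  if (nrow(households) == 0) {
    stop("mobility: empty household panel", call. = FALSE)
  }
  years <- sort(unique(households$year))
  ids <- unique(households$household_id)
  ri <- match(households$household_id, ids)
  ci <- match(households$year, years)
  res <- matrix(NA_character_, length(ids), length(years),
                dimnames = list(ids, years))
  inc <- matrix(NA_real_, length(ids), length(years),
                dimnames = list(ids, years))
  tr <- households$tract_id
  tr[!is.na(tr) & tr == ""] <- NA_character_
  res[cbind(ri, ci)] <- tr
  inc[cbind(ri, ci)] <- households$income
  list(ids = ids, years = years, res = res, inc = inc)
}

#' Exclude households with incomplete records
#'
#' A household is retained iff (i) its residence sequence has no internal
#' gap — missing years may appear only as a terminal run, which encodes
#' exit from the database — and (ii) its income is available at the most
#' recent observed year.  Households failing either rule are excluded to
#' avoid attrition bias, and the exclusion count and percentage are
#' logged.
#'
#' @param households long-format panel (`household_id`, `year`,
#'   `tract_id`, `income`).
#' @param verbose log the exclusion summary.
#' @return list: `retained` (long panel), `excluded_count`,
#'   `excluded_ids`, `log` (rule, counts, percent).
#' @export
filter_complete <- function(households, verbose = TRUE) {
  pm <- panel_matrices(households)
  n <- length(pm$ids)
  ok <- logical(n)
  for (i in seq_len(n)) {
    obs <- which(!is.na(pm$res[i, ]))
    if (length(obs) == 0) { ok[i] <- FALSE; next }
    contiguous <- all(diff(obs) == 1) && obs[1] == 1
    has_income <- !is.na(pm$inc[i, obs[length(obs)]])
    ok[i] <- contiguous && has_income
  }
  excluded_ids <- pm$ids[!ok]
  lg <- log_filter("incomplete_household_records", length(excluded_ids), n,
                   verbose = verbose)
  retained <- households[households$household_id %in% pm$ids[ok], ,
                         drop = FALSE]
  list(retained = retained, excluded_count = length(excluded_ids),
       excluded_ids = excluded_ids, log = lg)
}

#' Assign household income classes by pooled quartiles
#'
#' Each retained household's final income (income at its most recent
#' observed year) is pooled; the 25th and 75th percentiles define the
#' class boundaries: lower (<= Q1), higher (> Q3), moderate otherwise.
#'
#' @param households retained long-format panel.
#' @return list: `classes` (data.frame `household_id`, `final_income`,
#'   `income_class`), `thresholds` (named Q1/Q3).
#' @export
assign_income_class <- function(households) {
  pm <- panel_matrices(households)
  final_income <- vapply(seq_along(pm$ids), function(i) {
    obs <- which(!is.na(pm$res[i, ]))
    pm$inc[i, obs[length(obs)]]
  }, numeric(1))
  if (anyNA(final_income)) {
    stop("assign_income_class: final income missing; run filter_complete",
         call. = FALSE)
  }
  qs <- quantile(final_income, c(0.25, 0.75), type = 7, names = FALSE)
  if (qs[1] == qs[2]) {
    warning("assign_income_class: degenerate income quartiles; ",
            "all households classified moderate")
    cls <- rep("moderate", length(final_income))
  } else {
    cls <- ifelse(final_income <= qs[1], "lower",
                  ifelse(final_income > qs[2], "higher", "moderate"))
  }
  list(classes = data.frame(household_id = pm$ids,
                            final_income = final_income,
                            income_class = cls, stringsAsFactors = FALSE),
       thresholds = c(q1 = qs[1], q3 = qs[2]))
}

#' Classify household mobility from first and last observed locations
#'
#' Only the first and last observed locations matter (intermediate stays
#' are ignored).  A household present in a metro tract in both is a
#' non-mover if the tracts coincide, otherwise a within-metro mover
#' contributing an out-move at its origin and an in-move at its
#' destination.  A household starting in a metro tract but last seen
#' outside the metro — or no longer in the database by the final panel
#' year — contributes only an out-move at its origin.  A household
#' entering from outside contributes only an in-move at its destination.
#'
#' @param households retained long-format panel.
#' @param tract_ids character vector of metro tract ids.
#' @return data.frame per household: `household_id`, `mover_type`,
#'   `origin_tract`, `destination_tract`, `out_tract`, `in_tract` (NA
#'   where no contribution).  Households with neither end in the metro
#'   get `mover_type = NA` and are counted in attribute `n_no_contact`.
#' @export
classify_mobility <- function(households, tract_ids) {
  pm <- panel_matrices(households)
  n <- length(pm$ids)
  last_year <- pm$years[length(pm$years)]
  mover <- character(n); origin <- character(n); dest <- character(n)
  out_t <- character(n); in_t <- character(n)
  for (i in seq_len(n)) {
    obs <- which(!is.na(pm$res[i, ]))
    first_loc <- pm$res[i, obs[1]]
    last_loc <- pm$res[i, obs[length(obs)]]
    absent_by_end <- pm$years[obs[length(obs)]] < last_year
    first_in <- first_loc %in% tract_ids
    last_in <- last_loc %in% tract_ids
    origin[i] <- if (first_in) first_loc else NA_character_
    dest[i] <- if (last_in) last_loc else NA_character_
    out_t[i] <- NA_character_; in_t[i] <- NA_character_
    if (first_in && last_in && !absent_by_end) {
      if (first_loc == last_loc) {
        mover[i] <- "non_mover"
      } else {
        mover[i] <- "within_metro_mover"
        out_t[i] <- first_loc; in_t[i] <- last_loc
      }
    } else if (first_in) {
      # left the metro, or left the database before the final year
      mover[i] <- "out_of_metro_or_lost"
      out_t[i] <- first_loc
    } else if (last_in) {
      mover[i] <- "in_from_outside"
      in_t[i] <- last_loc
    } else {
      mover[i] <- NA_character_   # never in the metro: no contribution
    }
  }
  out <- data.frame(household_id = pm$ids, mover_type = mover,
                    origin_tract = origin, destination_tract = dest,
                    out_tract = out_t, in_tract = in_t,
                    stringsAsFactors = FALSE)
  attr(out, "n_no_contact") <- sum(is.na(mover))
  out
}

#' Per-tract net household change by income class
#'
#' Tallies, for every tract and income class, in-moves minus out-moves
#' from the mobility contributions.  Tracts with no movement get zero.
#'
#' @param moves output of [classify_mobility()].
#' @param classes `classes` data.frame from [assign_income_class()].
#' @param tract_ids metro tract ids (defines the output universe).
#' @return data.frame: `tract_id`, `net_lower`, `net_moderate`,
#'   `net_higher` (integers).
#' @export
net_changes <- function(moves, classes, tract_ids) {
  m <- merge(moves, classes[, c("household_id", "income_class")],
             by = "household_id")
  bad <- c(m$out_tract, m$in_tract)
  bad <- bad[!is.na(bad) & !(bad %in% tract_ids)]
  if (length(bad) > 0) {
    stop("net_changes: contribution references unknown tract id: ",
         bad[1], call. = FALSE)
  }
  tally <- function(col, k) {
    t0 <- table(factor(m[[col]][m$income_class == k], levels = tract_ids))
    as.integer(t0)
  }
  out <- data.frame(tract_id = tract_ids, stringsAsFactors = FALSE)
  for (k in income_class_levels()) {
    out[[paste0("net_", k)]] <- tally("in_tract", k) - tally("out_tract", k)
  }
  out
}

#' Quartile-based magnitude categories for net changes
#'
#' Within each income class, the distribution of tract net changes is cut
#' at its 25th, 50th and 75th percentiles (type-1 quantiles; a tract
#' exactly at a cut point goes to the lower category): major decline,
#' minor decline, minor increase, major increase.  A net change of
#' exactly zero is assigned minor decline (zero is "no increase").  The
#' realized category ranges are attached for reporting.
#'
#' @param nets data.frame from [net_changes()].
#' @return `nets` with added `cat_lower`, `cat_moderate`, `cat_higher`
#'   columns; attribute `ranges` lists each category's realized
#'   min..max per class.
#' @export
categorize_magnitude <- function(nets) {
  if (nrow(nets) < 4) {
    stop("categorize_magnitude: need at least 4 tracts", call. = FALSE)
  }
  ranges <- list()
  for (k in income_class_levels()) {
    x <- nets[[paste0("net_", k)]]
    bin <- quartile_bin(x)
    bin[x == 0] <- 2L            # zero net counts as (minor) decline
    cat_k <- magnitude_levels()[bin]
    nets[[paste0("cat_", k)]] <- cat_k
    ranges[[k]] <- lapply(stats::setNames(nm = magnitude_levels()),
                          function(lv) {
      if (any(cat_k == lv)) range(x[cat_k == lv]) else c(NA_real_, NA_real_)
    })
  }
  attr(nets, "ranges") <- ranges
  nets
}

#' Full mobility profile from a raw household panel
#'
#' Runs the exclusion filter, income-class assignment, mover
#' classification, net-change tally and magnitude categorization, and
#' returns the per-tract mobility profile plus per-stratum summaries of
#' increasing/decreasing tracts by gentrification status.
#'
#' @param households raw long-format panel.
#' @param tract_ids metro tract ids.
#' @param status optional data.frame (`tract_id`,
#'   `gentrification_status`) enabling the per-stratum summary.
#' @param verbose log filter counts.
#' @return list: `profile` (tract_id, nets, categories), `summary`
#'   (per-stratum proportions, or NULL), `excluded_count`,
#'   `income_thresholds`, `moves`, `classes`.
#' @export
mobility_profile <- function(households, tract_ids, status = NULL,
                             verbose = TRUE) {
  fc <- filter_complete(households, verbose = verbose)
  ic <- assign_income_class(fc$retained)
  mv <- classify_mobility(fc$retained, tract_ids)
  nets <- net_changes(mv, ic$classes, tract_ids)
  prof <- categorize_magnitude(nets)
  smry <- if (!is.null(status)) mobility_summary(prof, status) else NULL
  list(profile = prof, summary = smry,
       excluded_count = fc$excluded_count,
       income_thresholds = ic$thresholds, moves = mv,
       classes = ic$classes)
}

#' Proportion of increasing/decreasing tracts by gentrification status
#'
#' For each gentrification stratum and income class, the percentage of
#' tracts with a net increase (net > 0) and a net decline (net < 0).
#'
#' @param profile output `profile` of [mobility_profile()].
#' @param status data.frame `tract_id`, `gentrification_status`.
#' @return data.frame: `gentrification_status`, `income_class`,
#'   `n_tracts`, `pct_increase`, `pct_decline` (one-decimal, half-up).
#' @export
mobility_summary <- function(profile, status) {
  m <- merge(profile, status[, c("tract_id", "gentrification_status")],
             by = "tract_id")
  rows <- list()
  for (s in gentrification_levels()) {
    sub <- m[m$gentrification_status == s, , drop = FALSE]
    if (nrow(sub) == 0) next
    for (k in income_class_levels()) {
      x <- sub[[paste0("net_", k)]]
      rows[[length(rows) + 1]] <- data.frame(
        gentrification_status = s, income_class = k,
        n_tracts = nrow(sub),
        pct_increase = pct_report(sum(x > 0), nrow(sub)),
        pct_decline = pct_report(sum(x < 0), nrow(sub)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
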
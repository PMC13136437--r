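#' Generate the tract lattice, HOLC overlays and attribute panels
#'
#' Lays out `n_rows x n_cols` square census tracts with rook adjacency.
#' Historical HOLC grades are seeded as spatially contiguous rings around
#' the lattice center — "hazardous" innermost, then "definitely declining",
#' "still desirable" and "best" — mirroring the inner-city clustering of
#' 1930s graded areas; tracts outside the graded core are "unclassified".
#' Census attribute panels (percent college-educated, percent
#' short-tenured, percent owner-occupied) are generated at three time
#' points (2000, 2011, 2018) with drift planted so that, by construction,
#' every gentrification category (ineligible / earlier / recent / none)
#' is realized, and earlier/recent drift appears within every HOLC grade
#' that has at least three eligible tracts.
#'
#' @param config a [metro_config()].
#' @return list with `tracts` (data.frame), `adjacency` (data.frame with
#'   columns `from`, `to`, undirected, each pair once, lexicographic) and
#'   `truth` (planted statuses and structural parameters).
#' @export
generate_tracts <- function(config) {
  validate_metro_config(config)
  set.seed(child_seed(config$rng_seed, "tracts"))
  nr <- config$n_rows; nc <- config$n_cols
  n <- nr * nc
  idx <- seq_len(n)
  row <- rep(seq_len(nr), each = nc)
  col <- rep(seq_len(nc), times = nr)
  tract_id <- sprintf("T%04d", idx)

  adjacency <- lattice_adjacency(nr, nc, tract_id)

  # HOLC grades: concentric bands around the lattice center.
  d <- sqrt((row - (nr + 1) / 2)^2 + (col - (nc + 1) / 2)^2)
  ord <- order(d, idx)
  n_graded <- round(config$holc_seed_fraction * n)
  grade <- rep("unclassified", n)
  if (n_graded > 0) {
    graded_idx <- ord[seq_len(n_graded)]
    # innermost -> outermost shares of the graded core
    shares <- c(hazardous = 0.36, definitely_declining = 0.24,
                still_desirable = 0.30, best = 0.10)
    cnt <- floor(shares * n_graded)
    if (n_graded >= 4) cnt[cnt == 0] <- 1
    while (sum(cnt) < n_graded) {
      i <- which.max(shares * n_graded - cnt)
      cnt[i] <- cnt[i] + 1
    }
    while (sum(cnt) > n_graded) {
      i <- which.max(cnt)
      cnt[i] <- cnt[i] - 1
    }
    grade[graded_idx] <- rep(names(cnt), times = cnt)
  }

  # Planted gentrification statuses.  Ineligible tracts sit in the outer
  # (suburban) ring and never carry the two worst grades, matching the
  # empirical absence of ineligible redlined tracts.
  status <- rep("none", n)
  n_inel <- max(1L, round(config$frac_ineligible * n))
  inel_cand <- idx[!(grade %in% c("hazardous", "definitely_declining"))]
  inel_cand <- inel_cand[order(-d[inel_cand], inel_cand)]
  inel <- inel_cand[seq_len(min(n_inel, length(inel_cand)))]
  status[inel] <- "ineligible"

  for (g in holc_levels()) {
    elig_g <- idx[grade == g & status != "ineligible"]
    m <- length(elig_g)
    if (m == 0) next
    ne <- if (m >= 3) max(1L, round(config$frac_earlier * m)) else 0L
    nrcn <- if (m >= 3) max(1L, round(config$frac_recent * m)) else 0L
    if (ne + nrcn > m - 1) {       # always keep one "none" tract per grade
      ne <- max(0L, min(ne, (m - 1) %/% 2))
      nrcn <- max(0L, min(nrcn, m - 1 - ne))
    }
    picked <- sample(elig_g, ne + nrcn)
    if (ne > 0) status[picked[seq_len(ne)]] <- "earlier"
    if (nrcn > 0) status[picked[ne + seq_len(nrcn)]] <- "recent"
  }

  # Attribute panels: baseline levels plus planted drift.  Earlier
  # gentrifiers transform in 2000-2011, recent ones in 2011-2018; other
  # tracts drift by small noise only.
  base_college <- runif(n, 10, 40) + 15 * (grade %in% c("best", "still_desirable"))
  base_tenure <- runif(n, 10, 30)
  base_owner <- runif(n, 30, 70)
  drift <- function(active, lo, hi) {
    ifelse(active, runif(n, lo, hi), rnorm(n, 0, 2))
  }
  e1 <- status == "earlier"; e2 <- status == "recent"
  college_2000 <- base_college
  college_2011 <- clip_pct(college_2000 + drift(e1, 12, 18))
  college_2018 <- clip_pct(college_2011 + drift(e2, 12, 18))
  tenure_2000 <- base_tenure
  tenure_2011 <- clip_pct(tenure_2000 + drift(e1, 10, 16))
  tenure_2018 <- clip_pct(tenure_2011 + drift(e2, 10, 16))
  owner_2000 <- base_owner
  owner_2011 <- clip_pct(owner_2000 + drift(e1, 8, 14))
  owner_2018 <- clip_pct(owner_2011 + drift(e2, 8, 14))

  # Baseline median income: eligible tracts well below, ineligible well
  # above, the 1.4 x metro-mean cutoff, so planted eligibility is exact.
  median_income <- ifelse(status == "ineligible",
                          runif(n, 140000, 200000),
                          runif(n, 35000, 70000))
  metro_mean <- mean(median_income)
  planted_inel <- status == "ineligible"
  if (!identical(planted_inel, median_income >= 1.4 * metro_mean)) {
    stop("generate_tracts: planted eligibility inconsistent with incomes; ",
         "adjust frac_ineligible")
  }

  pct_nw_2011 <- ifelse(grade %in% c("hazardous", "definitely_declining"),
                        runif(n, 50, 90), runif(n, 5, 50))
  pct_nw_2018 <- clip_pct(pct_nw_2011 + rnorm(n, 0, 5))

  population <- round(runif(n, 1500, 6000))

  # HOLC overlay fractions: the planted grade strictly dominates, with a
  # severity-adjacent secondary grade sharing part of the tract.
  ov <- matrix(0, n, 4,
               dimnames = list(NULL, c("holc_best", "holc_still_desirable",
                                       "holc_definitely_declining",
                                       "holc_hazardous")))
  graded_mask <- grade != "unclassified"
  sev <- c(best = 1, still_desirable = 2, definitely_declining = 3,
           hazardous = 4)
  f1 <- runif(n, 0.55, 0.85)
  f2 <- runif(n, 0, 1) * pmin(f1 - 0.05, 1 - f1)
  for (i in idx[graded_mask]) {
    k <- sev[[grade[i]]]
    ov[i, k] <- f1[i]
    k2 <- if (k == 4) 3 else k + 1
    ov[i, k2] <- f2[i]
  }

  tracts <- data.frame(
    tract_id = tract_id, row = row, col = col,
    population = population,
    median_income_2011 = median_income,
    pct_college_2000 = college_2000, pct_college_2011 = college_2011,
    pct_college_2018 = college_2018,
    pct_short_tenure_2000 = tenure_2000,
    pct_short_tenure_2011 = tenure_2011,
    pct_short_tenure_2018 = tenure_2018,
    pct_owner_occupied_2000 = owner_2000,
    pct_owner_occupied_2011 = owner_2011,
    pct_owner_occupied_2018 = owner_2018,
    pct_non_white_2011 = pct_nw_2011, pct_non_white_2018 = pct_nw_2018,
    stringsAsFactors = FALSE)
  tracts <- cbind(tracts, as.data.frame(ov))
  tracts$holc_grade_true <- grade

  miss <- setdiff(gentrification_levels(), unique(status))
  if (length(miss) > 0) {
    stop("generate_tracts: category not realized: ",
         paste(miss, collapse = ", "))
  }

  truth <- list(
    tract_id = tract_id,
    true_gentrification_status = status,
    true_holc_grade = grade,
    true_coefficients = list(
      le_baseline = config$le_baseline,
      effect_income_composition = config$effect_income_composition,
      holc_effects = as.list(config$holc_effects)))

  list(tracts = tracts, adjacency = adjacency, truth = truth)
}

clip_pct <- function(x) pmin(100, pmax(0, x))

# Rook adjacency of an nr x nc lattice: undirected edge list, each pair
# once, lexicographic by tract id.  Diagonal neighbors are excluded.
lattice_adjacency <- function(nr, nc, tract_id) {
  row <- rep(seq_len(nr), each = nc)
  col <- rep(seq_len(nc), times = nr)
  id_at <- function(r, c) (r - 1L) * nc + c
  right <- col < nc
  down <- row < nr
  from <- c(id_at(row[right], col[right]), id_at(row[down], col[down]))
  to <- c(id_at(row[right], col[right] + 1L),
          id_at(row[down] + 1L, col[down]))
  e <- data.frame(from = tract_id[pmin(from, to)],
                  to = tract_id[pmax(from, to)], stringsAsFactors = FALSE)
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Simulate the annual household residence and income panel
#'
#' Seeds `n_households_per_tract` households per tract in the first panel
#' year plus a pool of outside entrants.  Each year, households may leave
#' the database (attrition; terminal missing years), relocate to another
#' tract, or move out of the metro.  The relocation hazard depends on the
#' household's income class, and destination choice reproduces the
#' socio-spatial structure of gentrification: higher-income movers favor
#' gentrifying (earlier/recent) tracts while lower-income movers favor
#' non-gentrified tracts.  A `missing_prob` fraction of households is
#' given an incomplete record (internal residence gap or missing final
#' income) to exercise the downstream exclusion filter.
#'
#' @param config a [metro_config()].
#' @param tracts the tract table from [generate_tracts()] (needs
#'   `tract_id`); planted statuses are read from `truth`.
#' @param truth the `truth` element from [generate_tracts()].
#' @return data.frame in long format: `household_id`, `year`, `tract_id`
#'   (a tract id, `"OUTSIDE"`, or `NA` for missing), `income`.
#' @export
generate_households <- function(config, tracts, truth) {
  set.seed(child_seed(config$rng_seed, "households"))
  years <- config$years
  ny <- length(years)
  tract_ids <- tracts$tract_id
  n_tr <- length(tract_ids)
  status <- truth$true_gentrification_status

  n_res <- n_tr * config$n_households_per_tract
  n_out <- round(config$outside_entry_frac * n_res)
  n <- n_res + n_out
  hh_id <- sprintf("H%06d", seq_len(n))

  home0 <- c(rep(tract_ids, each = config$n_households_per_tract),
             rep(NA_character_, n_out))
  is_entrant <- c(rep(FALSE, n_res), rep(TRUE, n_out))
  entry_year <- rep(NA_integer_, n)
  if (n_out > 0 && ny > 1) {
    entry_year[is_entrant] <- sample(years[-1], n_out, replace = TRUE)
  }

  # Initial income: lognormal, higher in ineligible (wealthy) tracts;
  # entrants drawn from an intermediate distribution.
  inel_tract <- tract_ids[status == "ineligible"]
  meanlog <- rep(log(45000), n)
  meanlog[!is_entrant & home0 %in% inel_tract] <- log(120000)
  meanlog[is_entrant] <- log(60000)
  income0 <- rlnorm(n, meanlog = meanlog, sdlog = 0.5)

  # Generator-internal income class (quartiles of initial income) drives
  # the relocation hazard; the analysis module re-derives classes from
  # final incomes independently.
  qs <- quantile(income0, c(0.25, 0.75), type = 7, names = FALSE)
  cls <- ifelse(income0 <= qs[1], "lower",
                ifelse(income0 > qs[2], "higher", "moderate"))
  move_p <- config$move_prob_by_income[cls]

  # Destination weights per income class over tracts.  Higher-income
  # movers favor gentrifying tracts and wealthy (ineligible) suburbs;
  # lower-income movers favor non-gentrified tracts.  A lognormal
  # per-tract attractiveness factor adds within-status variation in
  # flows (tract desirability is heterogeneous in any real metro).
  attract <- rlnorm(n_tr, 0, 0.5)
  w_higher <- ifelse(status %in% c("earlier", "recent", "ineligible"), 4, 1)
  w_lower <- ifelse(status == "none", 4,
                    ifelse(status == "ineligible", 0.25, 1))
  w_moderate <- rep(1, n_tr)
  wts <- list(lower = w_lower * attract, moderate = w_moderate * attract,
              higher = w_higher * attract)

  res <- matrix(NA_character_, n, ny)
  res[, 1] <- ifelse(is_entrant, "OUTSIDE", home0)
  cur <- res[, 1]

  for (t in seq_len(ny)[-1]) {
    alive <- !is.na(cur)
    # attrition: terminal exit from the database
    if (config$attrition_prob > 0) {
      gone <- alive & (runif(n) < config$attrition_prob)
      cur[gone] <- NA_character_
      alive <- !is.na(cur)
    }
    # outside entrants arriving this year
    entering <- alive & is_entrant & !is.na(entry_year) &
      entry_year == years[t] & cur == "OUTSIDE"
    if (any(entering)) {
      for (k in income_class_levels()) {
        sel <- entering & cls == k
        if (any(sel)) {
          cur[sel] <- sample(tract_ids, sum(sel), replace = TRUE,
                             prob = wts[[k]])
        }
      }
    }
    # relocation of in-metro households
    in_metro <- alive & cur %in% tract_ids & !entering
    moving <- in_metro & (runif(n) < move_p)
    if (any(moving)) {
      to_outside <- moving & (runif(n) < config$outside_move_prob)
      cur[to_outside] <- "OUTSIDE"
      stay_in <- moving & !to_outside
      for (k in income_class_levels()) {
        sel <- which(stay_in & cls == k)
        if (length(sel) > 0) {
          dest <- sample(tract_ids, length(sel), replace = TRUE,
                         prob = wts[[k]])
          same <- dest == cur[sel]
          tries <- 0L
          while (any(same) && tries < 20L) {
            dest[same] <- sample(tract_ids, sum(same), replace = TRUE,
                                 prob = wts[[k]])
            same <- dest == cur[sel]
            tries <- tries + 1L
          }
          cur[sel] <- dest
        }
      }
    }
    res[, t] <- cur
  }

  # Annual income: multiplicative random walk from the initial draw.
  growth <- matrix(1 + rnorm(n * (ny - 1), 0, 0.03), n, ny - 1)
  income <- income0 * cbind(1, t(apply(growth, 1, cumprod)))
  income[is.na(res)] <- NA_real_

  # Incomplete records: internal residence gap when the observed span
  # allows one, otherwise missing income at the last observed year.
  flagged <- which(runif(n) < config$missing_prob)
  for (i in flagged) {
    obs <- which(!is.na(res[i, ]))
    if (length(obs) >= 3) {
      gap <- obs[ceiling(length(obs) / 2)]
      res[i, gap] <- NA_character_
      income[i, gap] <- NA_real_
    } else if (length(obs) >= 1) {
      income[i, obs[length(obs)]] <- NA_real_
    }
  }

  data.frame(
    household_id = rep(hh_id, each = ny),
    year = rep(years, times = n),
    tract_id = as.vector(t(res)),
    income = as.vector(t(income)),
    stringsAsFactors = FALSE)
}

#' Generate tract life expectancy from structural components
#'
#' Life expectancy is built additively: a metro baseline, a per-grade
#' HOLC offset, an income-composition effect proportional to the tract's
#' deviation (in 10-percentage-point units) of higher-income household
#' share from the metro mean, a smooth spatial field, and iid noise.
#' Values are clipped to 60-95 years.  All components are recorded in the
#' returned truth object so parameter-recovery tests can regress against
#' them.
#'
#' @param tracts tract table from [generate_tracts()].
#' @param households household panel from [generate_households()].
#' @param adjacency rook edge list (used to smooth the spatial field).
#' @param truth truth list from [generate_tracts()] (extended in place).
#' @param config a [metro_config()].
#' @param bump optional planted spatial anomaly: a list with `rows`,
#'   `cols` (lattice index vectors) and `effect` (years) added on top of
#'   the smooth field.
#' @return list with `life_expectancy` (numeric per tract, tract order)
#'   and the extended `truth`.
#' @export
generate_life_expectancy <- function(tracts, households, adjacency, truth,
                                     config, bump = NULL) {
  set.seed(child_seed(config$rng_seed, "lifeexp"))
  n <- nrow(tracts)
  tract_ids <- tracts$tract_id
  grade <- truth$true_holc_grade

  share <- higher_income_share(households, tract_ids, config$years)
  share[is.na(share)] <- mean(share, na.rm = TRUE)
  dev10 <- (share - mean(share)) / 10   # 10-pp units

  spatial <- smooth_spatial_field(n, adjacency, tract_ids,
                                  config$spatial_sd)
  if (!is.null(bump)) {
    hit <- tracts$row %in% bump$rows & tracts$col %in% bump$cols
    spatial[hit] <- spatial[hit] + bump$effect
  }
  noise <- rnorm(n, 0, config$noise_sd)
  holc_off <- unname(config$holc_effects[grade])

  le <- config$le_baseline + holc_off +
    config$effect_income_composition * dev10 + spatial + noise
  le <- pmin(95, pmax(60, le))
  if (config$le_missing_prob > 0) {
    le[runif(n) < config$le_missing_prob] <- NA_real_
  }

  truth$true_spatial_field <- spatial
  truth$higher_income_share <- share
  truth$holc_offset <- holc_off
  truth$income_component <- config$effect_income_composition * dev10
  truth$noise <- noise
  truth$bump <- bump

  list(life_expectancy = le, truth = truth)
}

# Percent of a tract's final-panel-year residents whose final income falls
# in the metro-wide top quartile.
higher_income_share <- function(households, tract_ids, years) {
  last_year <- max(years)
  fin <- households[households$year == last_year &
                      !is.na(households$tract_id) &
                      households$tract_id %in% tract_ids &
                      !is.na(households$income), , drop = FALSE]
  share <- rep(NA_real_, length(tract_ids))
  names(share) <- tract_ids
  if (nrow(fin) == 0) return(unname(share))
  thr <- quantile(fin$income, 0.75, type = 7, names = FALSE)
  tot <- table(factor(fin$tract_id, levels = tract_ids))
  hi <- table(factor(fin$tract_id[fin$income > thr], levels = tract_ids))
  share <- ifelse(tot > 0, 100 * as.numeric(hi) / as.numeric(tot),
                  NA_real_)
  unname(share)
}

# Smooth mean-zero Gaussian field on the tract graph: iid draws averaged
# repeatedly with rook neighbors, then rescaled to the target sd.
smooth_spatial_field <- function(n, adjacency, tract_ids, spatial_sd) {
  if (spatial_sd <= 0) return(rep(0, n))
  z <- rnorm(n)
  fi <- match(adjacency$from, tract_ids)
  ti <- match(adjacency$to, tract_ids)
  deg <- tabulate(c(fi, ti), nbins = n)
  for (sweep in 1:8) {
    nb_sum <- numeric(n)
    acc <- rowsum(c(z[ti], z[fi]), c(fi, ti))
    nb_sum[as.integer(rownames(acc))] <- acc[, 1]
    z <- 0.5 * z + 0.5 * nb_sum / pmax(deg, 1)
  }
  z <- z - mean(z)
  s <- sd(z)
  if (s == 0) return(rep(0, n))
  z * spatial_sd / s
}

#' Generate a complete synthetic metropolitan area
#'
#' Runs [generate_tracts()], [generate_households()] and
#' [generate_life_expectancy()] under one seed and returns the assembled
#' metro.  Identical configs reproduce identical output.
#'
#' @param config a [metro_config()].
#' @param bump optional planted spatial anomaly (see
#'   [generate_life_expectancy()]).
#' @return list with `tracts` (including `life_expectancy`), `adjacency`,
#'   `households`, `truth` and `config`.
#' @export
generate_metro <- function(config = metro_config(), bump = NULL) {
  g <- generate_tracts(config)
  hh <- generate_households(config, g$tracts, g$truth)
  le <- generate_life_expectancy(g$tracts, hh, g$adjacency, g$truth,
                                 config, bump = bump)
  g$tracts$life_expectancy <- le$life_expectancy
  list(tracts = g$tracts, adjacency = g$adjacency, households = hh,
       truth = le$truth, config = config)
}

#' Write a synthetic metro to disk
#'
#' Emits `tracts.csv`, `adjacency.csv` (undirected edge list, each pair
#' once, lexicographic), `households.csv` (long format), `tracts.geojson`
#' (planar unit-square polygons per tract) and `truth.json`.
#'
#' @param metro result of [generate_metro()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_metro <- function(metro, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tracts = file.path(dir, "tracts.csv"),
    adjacency = file.path(dir, "adjacency.csv"),
    households = file.path(dir, "households.csv"),
    geojson = file.path(dir, "tracts.geojson"),
    truth = file.path(dir, "truth.json"))
  write.csv(metro$tracts, paths["tracts"], row.names = FALSE)
  write.csv(metro$adjacency, paths["adjacency"], row.names = FALSE)
  hh <- metro$households
  hh$tract_id[is.na(hh$tract_id)] <- ""
  write.csv(hh, paths["households"], row.names = FALSE, na = "")
  writeLines(tracts_geojson(metro$tracts), paths["geojson"])
  jsonlite::write_json(metro$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

# GeoJSON FeatureCollection of unit squares in a planar WGS84-like frame;
# property tract_id allows joining model outputs.
tracts_geojson <- function(tracts) {
  feats <- lapply(seq_len(nrow(tracts)), function(i) {
    x0 <- tracts$col[i] - 1; y0 <- tracts$row[i] - 1
    ring <- list(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1),
                 c(x0, y0 + 1), c(x0, y0))
    list(type = "Feature",
         properties = list(tract_id = tracts$tract_id[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                   auto_unbox = TRUE, digits = NA)
}
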
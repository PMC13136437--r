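#' Configuration for the synthetic metropolitan area generator
#'
#' Bundles every structural parameter of the synthetic metro: lattice size,
#' household panel size, annual relocation hazards by income class,
#' attrition and record-incompleteness rates, and the structural effects
#' that drive generated life expectancy.  The defaults define the study
#' conditions used throughout the test suite: a 12x12 tract lattice with
#' 100 households per tract (~14,400 household traces over 2011-2018),
#' 30% of tracts carrying a historical HOLC grade, and an 8.7% rate of
#' incomplete household records.
#'
#' @param n_rows,n_cols lattice dimensions; the metro has
#'   `n_rows * n_cols` square census tracts with rook adjacency.  Must be
#'   at least 4x4 so downstream quartile categories are non-degenerate.
#' @param n_households_per_tract households seeded in each tract in 2011.
#' @param years inclusive integer range of the household panel.
#' @param holc_seed_fraction fraction of tracts receiving a historical
#'   grade (the rest are "unclassified", i.e. not urban in the 1930s).
#' @param move_prob_by_income named annual relocation probabilities for
#'   `lower`, `moderate` and `higher` income households.
#' @param attrition_prob annual probability a household leaves the
#'   database (terminal missing years; coded out-movers downstream).
#' @param missing_prob probability a household record is incomplete (an
#'   internal residence gap or missing final income); such households are
#'   excluded by the mobility filter.
#' @param frac_ineligible fraction of tracts planted as ineligible for
#'   gentrification (baseline median income >= 40% above the metro mean).
#' @param frac_earlier,frac_recent fraction of *eligible* tracts per HOLC
#'   grade planted with earlier (2000-2010) / recent (2011-2018)
#'   gentrification-scale attribute drift.
#' @param outside_entry_frac extra households (as a fraction of the
#'   resident panel) that enter the metro from outside during the panel.
#' @param outside_move_prob probability that a relocating household moves
#'   out of the metro rather than to another tract; 0 gives a closed
#'   metro.
#' @param le_missing_prob probability a tract's life-expectancy estimate
#'   is missing (emulating non-residential tracts without published
#'   estimates); exercised by the tract exclusion filter.
#' @param le_baseline metro-wide baseline life expectancy in years.
#' @param effect_income_composition years of life expectancy per
#'   10-percentage-point shift in a tract's higher-income household share.
#' @param holc_effects named per-grade life-expectancy offsets in years.
#' @param spatial_sd standard deviation (years) of the smooth spatial
#'   field added to life expectancy.
#' @param noise_sd standard deviation (years) of iid tract noise.
#' @param rng_seed integer seed; identical configs (including the seed)
#'   reproduce byte-identical outputs.
#' @return a validated list of class `metro_config`.
#' @export
metro_config <- function(n_rows = 12, n_cols = 12,
                         n_households_per_tract = 100,
                         years = 2011:2018,
                         holc_seed_fraction = 0.30,
                         move_prob_by_income = c(lower = 0.10,
                                                 moderate = 0.06,
                                                 higher = 0.07),
                         attrition_prob = 0.02,
                         missing_prob = 0.087,
                         frac_ineligible = 0.15,
                         frac_earlier = 0.15,
                         frac_recent = 0.15,
                         outside_entry_frac = 0.10,
                         outside_move_prob = 0.15,
                         le_missing_prob = 0,
                         le_baseline = 78,
                         effect_income_composition = 2.5,
                         holc_effects = c(best = 1.5,
                                          still_desirable = 1.0,
                                          definitely_declining = -2.5,
                                          hazardous = -3.5,
                                          unclassified = 0),
                         spatial_sd = 1.0,
                         noise_sd = 0.8,
                         rng_seed = 20180101) {
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              n_households_per_tract = as.integer(n_households_per_tract),
              years = as.integer(years),
              holc_seed_fraction = holc_seed_fraction,
              move_prob_by_income = move_prob_by_income,
              attrition_prob = attrition_prob,
              missing_prob = missing_prob,
              frac_ineligible = frac_ineligible,
              frac_earlier = frac_earlier,
              frac_recent = frac_recent,
              outside_entry_frac = outside_entry_frac,
              outside_move_prob = outside_move_prob,
              le_missing_prob = le_missing_prob,
              le_baseline = le_baseline,
              effect_income_composition = effect_income_composition,
              holc_effects = holc_effects,
              spatial_sd = spatial_sd,
              noise_sd = noise_sd,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "metro_config"
  validate_metro_config(cfg)
  cfg
}

validate_metro_config <- function(cfg) {
  if (cfg$n_rows < 4 || cfg$n_cols < 4) {
    stop("metro_config: lattice must be at least 4x4 (",
         cfg$n_rows, "x", cfg$n_cols, " given)", call. = FALSE)
  }
  probs <- c(cfg$move_prob_by_income, cfg$attrition_prob, cfg$missing_prob,
             cfg$holc_seed_fraction, cfg$frac_ineligible, cfg$frac_earlier,
             cfg$frac_recent, cfg$outside_entry_frac, cfg$outside_move_prob,
             cfg$le_missing_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("metro_config: all probabilities/fractions must lie in [0, 1]",
         call. = FALSE)
  }
  if (!all(c("lower", "moderate", "higher") %in%
           names(cfg$move_prob_by_income))) {
    stop("metro_config: move_prob_by_income needs lower/moderate/higher",
         call. = FALSE)
  }
  if (!all(holc_levels() %in% names(cfg$holc_effects))) {
    stop("metro_config: holc_effects must name all five grades",
         call. = FALSE)
  }
  if (length(cfg$years) < 2 || any(diff(cfg$years) != 1L)) {
    stop("metro_config: years must be a consecutive integer range",
         call. = FALSE)
  }
  if (cfg$spatial_sd < 0 || cfg$noise_sd < 0) {
    stop("metro_config: spatial_sd and noise_sd must be nonnegative",
         call. = FALSE)
  }
  invisible(cfg)
}
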
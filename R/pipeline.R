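#' Read pipeline input tables
#'
#' @param path CSV path.
#' @return data.frame.
#' @name readers
NULL

#' @rdname readers
#' @export
read_tracts <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readers
#' @export
read_adjacency <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' @rdname readers
#' @export
read_households <- function(path) {
  hh <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(household_id = "character",
                                year = "integer", tract_id = "character",
                                income = "numeric"))
  hh$tract_id[!is.na(hh$tract_id) & hh$tract_id == ""] <- NA_character_
  hh
}

#' Assemble a run configuration
#'
#' Either `input_dir` (holding `tracts.csv`, `adjacency.csv` and
#' optionally `households.csv`) or a synthetic [metro_config()] must be
#' given.  The serialized configuration is written verbatim into the
#' output directory.
#'
#' @param metro a [metro_config()] for a synthetic run, or NULL.
#' @param input_dir directory of input CSVs for a data run, or NULL.
#' @param output_dir where result tables are written.
#' @param weights composite-score weights.
#' @param mcmc list with `iterations`, `burn_in`, `thin`.
#' @param seed seed for model fitting (the generator uses the metro
#'   config's own seed).
#' @return list of class `run_config`.
#' @export
run_config <- function(metro = metro_config(), input_dir = NULL,
                       output_dir = tempfile("gentriflow_run_"),
                       weights = c(1, 1, 1),
                       mcmc = list(iterations = 12000, burn_in = 2000,
                                   thin = 5),
                       seed = 20180101) {
  if (is.null(metro) && is.null(input_dir)) {
    stop("run_config: either a synthetic metro config or an input ",
         "directory is required", call. = FALSE)
  }
  structure(list(metro = metro, input_dir = input_dir,
                 output_dir = output_dir, weights = weights, mcmc = mcmc,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the complete sequence: tract filtering, HOLC grade and
#' gentrification classification, household exclusion, income classes,
#' mobility coding, net changes and magnitude categories,
#' population-weighted life-expectancy summaries, the OLS battery
#' (mobility models, HOLC-stratified unadjusted/adjusted gentrification
#' models) and the unstratified Bayesian spatial model with tract flags.
#' All result tables are written to `config$output_dir` along with a JSON
#' manifest recording the configuration, seed and exclusion counts.
#' Without household data, mobility-dependent stages are skipped and the
#' manifest records the skip.
#'
#' @param config a [run_config()].
#' @param verbose log stage progress and filter percentages.
#' @return the run manifest (list), invisibly; result tables are also
#'   returned in the `results` element.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[pipeline] ", ...)

  if (!is.null(config$input_dir)) {
    say("reading inputs from ", config$input_dir)
    tracts <- read_tracts(file.path(config$input_dir, "tracts.csv"))
    adjacency <- read_adjacency(file.path(config$input_dir,
                                          "adjacency.csv"))
    hh_path <- file.path(config$input_dir, "households.csv")
    households <- if (file.exists(hh_path)) read_households(hh_path)
                  else NULL
  } else {
    say("generating synthetic metro (seed ", config$metro$rng_seed, ")")
    metro <- generate_metro(config$metro)
    tracts <- metro$tracts
    adjacency <- metro$adjacency
    households <- metro$households
    write_metro(metro, file.path(config$output_dir, "inputs"))
  }

  # --- tract filter -------------------------------------------------
  ft <- filter_tracts(tracts, verbose = verbose)
  analysis <- ft$analysis

  # --- HOLC grade + gentrification status ---------------------------
  status <- tract_status(analysis, weights = config$weights)
  analysis <- merge(analysis, status, by = "tract_id", sort = TRUE)
  write.csv(status, file.path(config$output_dir, "tract_status.csv"),
            row.names = FALSE)

  # --- mobility ------------------------------------------------------
  mob <- NULL
  hh_excluded <- NA_integer_
  if (!is.null(households)) {
    mob <- mobility_profile(households, analysis$tract_id,
                            status = status, verbose = verbose)
    hh_excluded <- mob$excluded_count
    write.csv(mob$profile,
              file.path(config$output_dir, "mobility_profile.csv"),
              row.names = FALSE)
    write.csv(mob$summary,
              file.path(config$output_dir, "mobility_summary.csv"),
              row.names = FALSE)
    analysis <- merge(analysis,
                      mob$profile[, c("tract_id", "cat_lower",
                                      "cat_moderate", "cat_higher")],
                      by = "tract_id", sort = TRUE)
  } else {
    say("no household data: mobility and adjusted models skipped")
  }

  # --- weighted LE summaries ----------------------------------------
  le_groups <- rbind(
    cbind(grouping = "holc_grade",
          weighted_le_summary(analysis, "holc_grade")),
    cbind(grouping = "gentrification_status",
          weighted_le_summary(analysis, "gentrification_status")),
    cbind(grouping = "transformation_status",
          weighted_le_summary(analysis, c("holc_grade",
                                          "gentrification_status"))))
  write.csv(le_groups, file.path(config$output_dir, "le_by_group.csv"),
            row.names = FALSE)

  # --- OLS battery ---------------------------------------------------
  fig2 <- fit_stratified_ols(analysis, adjusted = FALSE)
  fig2$variant <- "unadjusted"
  table1 <- NULL
  if (!is.null(mob)) {
    table1 <- fit_mobility_ols(analysis)
    write.csv(table1, file.path(config$output_dir, "model_table1.csv"),
              row.names = FALSE)
    adj <- fit_stratified_ols(analysis, adjusted = TRUE)
    adj$variant <- "adjusted"
    fig2 <- rbind(fig2, adj)
  }
  write.csv(fig2, file.path(config$output_dir, "model_fig2.csv"),
            row.names = FALSE)

  # --- spatial model -------------------------------------------------
  analysis$transformation_status <- transformation_status(
    analysis$holc_grade, analysis$gentrification_status)
  ref_ts <- "unclassified / ineligible"
  if (!ref_ts %in% analysis$transformation_status) {
    ref_ts <- analysis$transformation_status[1]
  }
  des <- build_design(analysis, "transformation_status",
                      list(transformation_status = ref_ts))
  coords <- if (all(c("row", "col") %in% names(analysis))) {
    analysis[, c("row", "col")]
  } else NULL
  sp <- fit_spatial(des, analysis$life_expectancy, adjacency,
                    analysis$tract_id, coords = coords,
                    iterations = config$mcmc$iterations,
                    burn_in = config$mcmc$burn_in,
                    thin = config$mcmc$thin, seed = config$seed)
  write.csv(sp$spatial, file.path(config$output_dir, "spatial_flags.csv"),
            row.names = FALSE)
  jsonlite::write_json(sp$diagnostics,
                       file.path(config$output_dir,
                                 "mcmc_diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    seed = config$seed,
    weights = config$weights,
    mcmc = config$mcmc,
    synthetic = is.null(config$input_dir),
    metro_config = if (is.null(config$input_dir)) {
      unclass(config$metro)
    } else NULL,
    input_dir = config$input_dir,
    n_tracts_raw = nrow(tracts),
    n_tracts_analysis = nrow(analysis),
    tracts_excluded = ft$excluded_count,
    tracts_excluded_pct = pct_report(ft$excluded_count, nrow(tracts)),
    households_excluded = hh_excluded,
    mobility_skipped = is.null(households),
    outputs = list.files(config$output_dir, recursive = TRUE))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("done: ", config$output_dir)
  invisible(c(manifest,
              list(results = list(analysis = analysis,
                                  le_by_group = le_groups,
                                  table1 = table1, fig2 = fig2,
                                  spatial = sp, mobility = mob))))
}
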
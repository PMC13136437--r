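years <- 2011:2018

test_that("complete records are retained, internal gaps excluded", {
  panel <- make_panel(
    list(full = rep("T01", 8),
         gap = c("T01", "T01", "T01", NA, "T02", "T02", "T02", "T02"),
         exited = c("T01", "T01", "T01", NA, NA, NA, NA, NA)),
    list(full = rep(100, 8), gap = rep(100, 8),
         exited = c(100, 100, 100, NA, NA, NA, NA, NA)))
  fc <- filter_complete(panel, verbose = FALSE)
  kept <- unique(fc$retained$household_id)
  expect_true("full" %in% kept)
  expect_false("gap" %in% kept)       # internal gap
  expect_true("exited" %in% kept)     # terminal missing run is exit
  expect_equal(fc$excluded_count, 1)
})

test_that("missing income at the last observed year excludes a household", {
  panel <- make_panel(
    list(noinc = rep("T01", 8), ok = rep("T02", 8)),
    list(noinc = c(rep(100, 7), NA), ok = rep(100, 8)))
  fc <- filter_complete(panel, verbose = FALSE)
  expect_identical(unique(fc$retained$household_id), "ok")
})

test_that("exclusion fraction tracks the configured incompleteness rate", {
  cfg <- metro_config(n_rows = 8, n_cols = 8, n_households_per_tract = 60,
                      missing_prob = 0.087, rng_seed = 13)
  g <- generate_tracts(cfg)
  hh <- generate_households(cfg, g$tracts, g$truth)
  fc <- filter_complete(hh, verbose = FALSE)
  n <- length(unique(hh$household_id))
  ci <- qbinom(c(0.005, 0.995), n, 0.087)
  expect_gte(fc$excluded_count, ci[1])
  expect_lte(fc$excluded_count, ci[2])
})

test_that("income quartiles cut at Q1 and Q3 with moderate between", {
  panel <- make_panel(
    list(a = rep("T01", 8), b = rep("T01", 8), c = rep("T01", 8),
         d = rep("T01", 8)),
    list(a = rep(10, 8), b = rep(20, 8), c = rep(30, 8), d = rep(40, 8)))
  ic <- assign_income_class(panel)
  expect_equal(ic$classes$income_class[match(c("a", "b", "c", "d"),
                                             ic$classes$household_id)],
               c("lower", "moderate", "moderate", "higher"))
})

test_that("income classes equal a sort-and-cut oracle on random incomes", {
  set.seed(303)
  for (rep in 1:20) {
    n <- sample(8:60, 1)
    inc <- round(rlnorm(n, log(5e4), 0.7))
    ids <- sprintf("H%03d", seq_len(n))
    panel <- make_panel(setNames(lapply(seq_len(n), function(i) rep("T01", 8)),
                                 ids),
                        setNames(lapply(inc, rep, 8), ids))
    ic <- assign_income_class(panel)
    expect_identical(
      ic$classes$income_class[match(ids, ic$classes$household_id)],
      oracle_income_class(inc))
  }
})

test_that("identical incomes degrade to all-moderate with a warning", {
  panel <- make_panel(
    setNames(lapply(1:6, function(i) rep("T01", 8)), letters[1:6]),
    setNames(lapply(1:6, function(i) rep(100, 8)), letters[1:6]))
  expect_warning(ic <- assign_income_class(panel), "degenerate")
  expect_true(all(ic$classes$income_class == "moderate"))
})

test_that("mover coding follows the first/last-location rules", {
  tract_ids <- c("A", "B", "C")
  panel <- make_panel(
    list(stay = rep("A", 8),
         move = c("A", "A", "A", "B", "B", "B", "B", "B"),
         roundtrip = c("A", "A", "A", "C", "C", "A", "A", "A"),
         leaver = c("A", "A", "OUTSIDE", "OUTSIDE", "OUTSIDE",
                    "OUTSIDE", "OUTSIDE", "OUTSIDE"),
         lost = c("A", "A", "A", NA, NA, NA, NA, NA),
         entrant = c("OUTSIDE", "OUTSIDE", "OUTSIDE", "B", "B", "B",
                     "B", "B"),
         never = rep("OUTSIDE", 8)),
    lapply(setNames(nm = c("stay", "move", "roundtrip", "leaver", "lost",
                           "entrant", "never")),
           function(i) rep(100, 8)))
  mv <- classify_mobility(panel, tract_ids)
  got <- setNames(mv$mover_type, mv$household_id)
  expect_equal(got[["stay"]], "non_mover")
  expect_equal(got[["move"]], "within_metro_mover")
  expect_equal(got[["roundtrip"]], "non_mover")   # first/last rule
  expect_equal(got[["leaver"]], "out_of_metro_or_lost")
  expect_equal(got[["lost"]], "out_of_metro_or_lost")
  expect_equal(got[["entrant"]], "in_from_outside")
  expect_true(is.na(got[["never"]]))
  # contribution sides
  expect_equal(mv$out_tract[mv$household_id == "move"], "A")
  expect_equal(mv$in_tract[mv$household_id == "move"], "B")
  expect_true(is.na(mv$in_tract[mv$household_id == "lost"]))
  expect_equal(mv$out_tract[mv$household_id == "lost"], "A")
  expect_true(is.na(mv$out_tract[mv$household_id == "entrant"]))
})

test_that("mover types match the rule-transcription oracle on generated panels", {
  cfg <- quick_config(rng_seed = 21)
  g <- generate_tracts(cfg)
  hh <- generate_households(cfg, g$tracts, g$truth)
  fc <- filter_complete(hh, verbose = FALSE)
  mv <- classify_mobility(fc$retained, g$tracts$tract_id)
  pm <- matrix(fc$retained$tract_id, ncol = length(cfg$years),
               byrow = TRUE)
  ids <- unique(fc$retained$household_id)
  for (i in sample(seq_along(ids), 200)) {
    expect_identical(mv$mover_type[mv$household_id == ids[i]],
                     oracle_mover_type(pm[i, ], cfg$years,
                                       g$tracts$tract_id))
  }
})

test_that("a single in-mover yields net +1 and unknown tracts error", {
  moves <- data.frame(household_id = "h1", mover_type = "in_from_outside",
                      origin_tract = NA, destination_tract = "A",
                      out_tract = NA_character_, in_tract = "A",
                      stringsAsFactors = FALSE)
  classes <- data.frame(household_id = "h1", final_income = 1,
                        income_class = "lower", stringsAsFactors = FALSE)
  nets <- net_changes(moves, classes, c("A", "B"))
  expect_equal(nets$net_lower, c(1L, 0L))
  expect_equal(nets$net_moderate, c(0L, 0L))
  moves$in_tract <- "Z"
  expect_error(net_changes(moves, classes, c("A", "B")), "unknown tract")
})

test_that("closed metros conserve every class-wise net to zero", {
  cfg <- quick_config(attrition_prob = 0, missing_prob = 0,
                      outside_entry_frac = 0, outside_move_prob = 0,
                      rng_seed = 19)
  g <- generate_tracts(cfg)
  hh <- generate_households(cfg, g$tracts, g$truth)
  mob <- mobility_profile(hh, g$tracts$tract_id, verbose = FALSE)
  expect_equal(sum(mob$profile$net_lower), 0L)
  expect_equal(sum(mob$profile$net_moderate), 0L)
  expect_equal(sum(mob$profile$net_higher), 0L)
})

test_that("nets equal an event-by-event tally oracle", {
  cfg <- quick_config(rng_seed = 29)
  g <- generate_tracts(cfg)
  hh <- generate_households(cfg, g$tracts, g$truth)
  mob <- mobility_profile(hh, g$tracts$tract_id, verbose = FALSE)
  oracle <- oracle_net_tally(mob$moves, mob$classes, g$tracts$tract_id)
  expect_equal(mob$profile$net_lower, unname(oracle[, "lower"]))
  expect_equal(mob$profile$net_moderate, unname(oracle[, "moderate"]))
  expect_equal(mob$profile$net_higher, unname(oracle[, "higher"]))
})

test_that("accounting identity: class nets sum to the total net ledger", {
  cfg <- quick_config(rng_seed = 37)
  g <- generate_tracts(cfg)
  hh <- generate_households(cfg, g$tracts, g$truth)
  mob <- mobility_profile(hh, g$tracts$tract_id, verbose = FALSE)
  total_in <- table(factor(mob$moves$in_tract, levels = g$tracts$tract_id))
  total_out <- table(factor(mob$moves$out_tract,
                            levels = g$tracts$tract_id))
  expect_equal(mob$profile$net_lower + mob$profile$net_moderate +
                 mob$profile$net_higher,
               as.integer(total_in) - as.integer(total_out))
})

test_that("magnitude categories assign one tract per quartile and honor zero", {
  nets <- data.frame(tract_id = c("A", "B", "C", "D"),
                     net_lower = c(-4L, -2L, 1L, 3L),
                     net_moderate = c(0L, 0L, 0L, 1L),
                     net_higher = c(-1L, -1L, 2L, 2L),
                     stringsAsFactors = FALSE)
  cm <- categorize_magnitude(nets)
  expect_equal(cm$cat_lower, c("major_decline", "minor_decline",
                               "minor_increase", "major_increase"))
  # zero nets are minor_decline by convention
  expect_true(all(cm$cat_moderate[1:3] == "minor_decline"))
})

test_that("a +31 net is a major increase under Table-1-like cut points", {
  # construct a net distribution whose type-1 quartiles are -18, -1, +30
  x <- c(-277, -18, -17, -1, 1, 30, 31, 380)
  nets <- data.frame(tract_id = sprintf("T%02d", 1:8), net_lower = x,
                     net_moderate = x, net_higher = x,
                     stringsAsFactors = FALSE)
  cm <- categorize_magnitude(nets)
  expect_equal(cm$cat_lower[x == 31], "major_increase")
  expect_equal(cm$cat_lower[x == 30], "minor_increase")
  expect_equal(cm$cat_lower[x == -18], "major_decline")
  expect_equal(cm$cat_lower[x == -1], "minor_decline")
})

test_that("magnitude categories equal the sort-and-cut oracle with ties", {
  set.seed(404)
  for (rep in 1:20) {
    n <- sample(8:80, 1)
    x <- as.integer(sample(-20:20, n, replace = TRUE))
    nets <- data.frame(tract_id = sprintf("T%03d", seq_len(n)),
                       net_lower = x, net_moderate = x, net_higher = x,
                       stringsAsFactors = FALSE)
    cm <- categorize_magnitude(nets)
    expect_identical(cm$cat_lower, oracle_magnitude(x))
  }
})

test_that("re-running categorization on its own output is a no-op", {
  cfg <- quick_config(rng_seed = 41)
  g <- generate_tracts(cfg)
  hh <- generate_households(cfg, g$tracts, g$truth)
  mob <- mobility_profile(hh, g$tracts$tract_id, verbose = FALSE)
  again <- categorize_magnitude(mob$profile[, c("tract_id", "net_lower",
                                                "net_moderate",
                                                "net_higher")])
  expect_identical(again$cat_lower, mob$profile$cat_lower)
  expect_identical(again$cat_higher, mob$profile$cat_higher)
})

test_that("gentrifying strata gain higher-income households more often", {
  cfg <- metro_config(rng_seed = 43)
  m <- generate_metro(cfg)
  st <- tract_status(m$tracts)
  mob <- mobility_profile(m$households, m$tracts$tract_id, status = st,
                          verbose = FALSE)
  sm <- mob$summary
  up <- function(s) sm$pct_increase[sm$gentrification_status == s &
                                      sm$income_class == "higher"]
  expect_gt(up("earlier"), up("none"))
  expect_gt(up("recent"), up("none"))
})
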
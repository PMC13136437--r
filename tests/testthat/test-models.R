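test_that("design matrices dummy-code with the stated reference first", {
  d <- data.frame(g = c("a", "b", "c", "a"), x = 1:4,
                  stringsAsFactors = FALSE)
  des <- build_design(d, c("g", "x"), list(g = "a"))
  expect_equal(colnames(des$X), c("(Intercept)", "g:b", "g:c", "x"))
  expect_equal(des$X[, "g:b"], c(0, 1, 0, 0))
  expect_equal(nrow(des$X), 4)
  # reference-only data gives an intercept-only design
  d2 <- data.frame(g = c("a", "a"), stringsAsFactors = FALSE)
  des2 <- build_design(d2, "g", list(g = "a"))
  expect_equal(colnames(des2$X), "(Intercept)")
})

test_that("an absent reference level is dropped with a warning", {
  d <- data.frame(g = c("b", "c", "b"), stringsAsFactors = FALSE)
  expect_warning(des <- build_design(d, "g", list(g = "a")), "absent")
  expect_equal(sum(!is.na(des$labels$level) &
                     is.na(des$labels$column)), 1)
})

test_that("design indicators equal a per-row oracle on random factors", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    g <- sample(c("u", "v", "w"), n, replace = TRUE)
    g[1:3] <- c("u", "v", "w")
    d <- data.frame(g = g, stringsAsFactors = FALSE)
    des <- build_design(d, "g", list(g = "u"))
    for (lv in c("v", "w")) {
      expect_equal(des$X[, paste0("g:", lv)], as.numeric(g == lv))
    }
  }
})

test_that("OLS on two groups recovers the mean difference", {
  d <- data.frame(g = rep(c("a", "b"), each = 10),
                  stringsAsFactors = FALSE)
  y <- c(rep(70, 10), rep(75, 10))
  fit <- fit_ols(build_design(d, "g", list(g = "a")), y)
  expect_equal(fit$coefficient[which(fit$level == "b" & !fit$is_ref)], 5.0)
  expect_true(fit$is_ref[which(fit$level == "a")])
  expect_equal(fit$coefficient[which(fit$level == "a")], 0)
})

test_that("constant outcomes zero all non-intercept coefficients", {
  set.seed(111)
  d <- data.frame(g = sample(c("a", "b", "c"), 30, replace = TRUE),
                  stringsAsFactors = FALSE)
  fit <- fit_ols(build_design(d, "g", list(g = "a")), rep(77, 30))
  expect_equal(fit$coefficient[fit$term == "g" & !fit$is_ref],
               c(0, 0), tolerance = 1e-12)
})

test_that("coefficients match the normal-equations oracle", {
  set.seed(222)
  for (rep in 1:20) {
    n <- sample(15:50, 1)
    d <- data.frame(g = sample(c("a", "b", "c"), n, replace = TRUE),
                    x = rnorm(n), stringsAsFactors = FALSE)
    d$g[1:3] <- c("a", "b", "c")
    y <- rnorm(n, 70, 5)
    des <- build_design(d, c("g", "x"), list(g = "a"))
    fit <- fit_ols(des, y)
    beta <- oracle_ols(des$X, y)
    got <- fit$coefficient[!fit$is_ref]
    expect_equal(got, unname(beta), tolerance = 1e-8)
  }
})

test_that("rank-deficient designs error naming the collinear columns", {
  d <- data.frame(g = rep(c("a", "b"), 10), stringsAsFactors = FALSE)
  des <- build_design(d, "g", list(g = "a"))
  des$X <- cbind(des$X, dup = des$X[, "g:b"])
  des$labels <- rbind(des$labels,
                      data.frame(term = "dup", level = NA, column = "dup"))
  expect_error(fit_ols(des, rnorm(20)), "collinear")
})

test_that("stratified models use ineligible reference where it exists", {
  m <- generate_metro(metro_config(rng_seed = 47))
  ft <- filter_tracts(m$tracts, verbose = FALSE)
  st <- tract_status(ft$analysis)
  an <- merge(ft$analysis, st, by = "tract_id")
  fit <- fit_stratified_ols(an, adjusted = FALSE)
  un <- fit[fit$stratum == "unclassified" &
              fit$term == "gentrification_status", ]
  expect_equal(un$level[un$is_ref], "ineligible")
  hz <- fit[fit$stratum == "hazardous" &
              fit$term == "gentrification_status", ]
  expect_equal(hz$level[hz$is_ref], "earlier")
})

test_that("the spatial sampler is reproducible and flags cohere", {
  m <- generate_metro(quick_config(rng_seed = 53))
  ft <- filter_tracts(m$tracts, verbose = FALSE)
  st <- tract_status(ft$analysis)
  an <- merge(ft$analysis, st, by = "tract_id")
  an$ts <- transformation_status(an$holc_grade, an$gentrification_status)
  des <- build_design(an, "ts", list(ts = "unclassified / ineligible"))
  fit1 <- fit_spatial(des, an$life_expectancy, m$adjacency, an$tract_id,
                      coords = an[, c("row", "col")], iterations = 600,
                      burn_in = 100, thin = 2, seed = 7)
  fit2 <- fit_spatial(des, an$life_expectancy, m$adjacency, an$tract_id,
                      coords = an[, c("row", "col")], iterations = 600,
                      burn_in = 100, thin = 2, seed = 7)
  expect_identical(fit1$spatial, fit2$spatial)
  expect_identical(fit1$fixed, fit2$fixed)
  # posterior-mean spatial effects satisfy the sum-to-zero constraint
  expect_lt(abs(sum(fit1$spatial$s_mean)), 1e-6 * nrow(an))
  # a tract is never both lower and higher
  expect_true(all(fit1$spatial$flag %in%
                    c("lower", "higher", "not_significant")))
  expect_true(all(fit1$spatial$s_low <= fit1$spatial$s_mean))
  expect_true(all(fit1$spatial$s_high >= fit1$spatial$s_mean))
})

test_that("spatial flags are invariant to shifting all outcomes", {
  m <- generate_metro(quick_config(rng_seed = 59))
  ft <- filter_tracts(m$tracts, verbose = FALSE)
  st <- tract_status(ft$analysis)
  an <- merge(ft$analysis, st, by = "tract_id")
  an$ts <- transformation_status(an$holc_grade, an$gentrification_status)
  des <- build_design(an, "ts", list(ts = "unclassified / ineligible"))
  f1 <- fit_spatial(des, an$life_expectancy, m$adjacency, an$tract_id,
                    coords = an[, c("row", "col")], iterations = 600,
                    burn_in = 100, thin = 2, seed = 7)
  f2 <- fit_spatial(des, an$life_expectancy + 5, m$adjacency,
                    an$tract_id, coords = an[, c("row", "col")],
                    iterations = 600, burn_in = 100, thin = 2, seed = 7)
  expect_identical(f1$spatial$flag, f2$spatial$flag)
  expect_equal(f1$spatial$s_mean, f2$spatial$s_mean, tolerance = 1e-8)
})

test_that("a constant outcome yields no significant spatial deviations", {
  cfg <- quick_config(rng_seed = 61)
  m <- generate_metro(cfg)
  an <- m$tracts
  an$ts <- "all"
  des <- build_design(an, character(0))
  fit <- fit_spatial(des, rep(78, nrow(an)), m$adjacency, an$tract_id,
                     coords = an[, c("row", "col")], iterations = 600,
                     burn_in = 100, thin = 2, seed = 7)
  expect_true(all(fit$spatial$flag == "not_significant"))
  expect_lt(max(abs(fit$spatial$s_mean)), 0.1)
})

test_that("disconnected subgraphs are refused without island repair", {
  m <- generate_metro(quick_config(rng_seed = 67))
  an <- m$tracts
  # two tracts from opposite corners: no connecting edge between them
  sub <- an[an$tract_id %in% c("T0001", sprintf("T%04d", nrow(an))), ]
  des <- build_design(sub, character(0))
  expect_error(
    fit_spatial(des, sub$life_expectancy, m$adjacency, sub$tract_id,
                coords = sub[, c("row", "col")], iterations = 200,
                burn_in = 50, thin = 1, seed = 1,
                repair_islands = FALSE),
    "disconnected")
})

test_that("island repair reconnects excluded-tract holes with a warning", {
  m <- generate_metro(quick_config(rng_seed = 71))
  an <- m$tracts
  # excise a full column of the 6x6 lattice to split the graph
  an <- an[an$col != 3, ]
  des <- build_design(an, character(0))
  expect_warning(
    fit <- fit_spatial(des, an$life_expectancy, m$adjacency, an$tract_id,
                       coords = an[, c("row", "col")], iterations = 200,
                       burn_in = 50, thin = 1, seed = 1),
    "island")
  expect_equal(nrow(fit$spatial), nrow(an))
})
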
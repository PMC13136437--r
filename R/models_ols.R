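#' Build a dummy-coded design matrix with explicit reference levels
#'
#' Categorical terms are expanded to indicator columns for every level
#' present in the data except the stated reference; numeric terms pass
#' through unchanged.  The intercept column comes first and label order is
#' stable (canonical pipeline orderings where applicable, data order of
#' first appearance otherwise).  A requested reference level absent from
#' the data is dropped with a warning and the first available level
#' becomes the reference.
#'
#' @param data data.frame holding the term columns.
#' @param terms character vector of column names to enter the model.
#' @param ref_levels named list/character: reference level per categorical
#'   term.
#' @return list: `X` (numeric matrix, first column intercept), `labels`
#'   (data.frame `term`, `level`, `column`; reference rows have
#'   `column = NA`), `ref_levels` (as used).
#' @export
build_design <- function(data, terms, ref_levels = list()) {
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  labels <- data.frame(term = "(Intercept)", level = NA_character_,
                       column = "(Intercept)", stringsAsFactors = FALSE)
  canon <- list(gentrification = gentrification_levels(),
                holc = holc_levels(), magnitude = magnitude_levels())
  for (tm in terms) {
    v <- data[[tm]]
    if (is.null(v)) stop("build_design: no column '", tm, "'", call. = FALSE)
    if (is.numeric(v)) {
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- tm
      labels <- rbind(labels, data.frame(term = tm, level = NA_character_,
                                         column = tm,
                                         stringsAsFactors = FALSE))
      next
    }
    v <- as.character(v)
    present <- unique(v)
    lev <- NULL
    for (cn in canon) {
      if (all(present %in% cn)) { lev <- cn[cn %in% present]; break }
    }
    if (is.null(lev)) lev <- present
    ref <- ref_levels[[tm]]
    if (is.null(ref)) ref <- lev[1]
    if (!ref %in% lev) {
      warning("build_design: reference level '", ref, "' of '", tm,
              "' absent from data; using '", lev[1], "'")
      ref <- lev[1]
    }
    labels <- rbind(labels, data.frame(term = tm, level = ref,
                                       column = NA_character_,
                                       stringsAsFactors = FALSE))
    for (lv in setdiff(lev, ref)) {
      cname <- paste0(tm, ":", lv)
      X <- cbind(X, as.numeric(v == lv))
      colnames(X)[ncol(X)] <- cname
      labels <- rbind(labels, data.frame(term = tm, level = lv,
                                         column = cname,
                                         stringsAsFactors = FALSE))
    }
  }
  list(X = X, labels = labels, ref_levels = ref_levels)
}

#' Ordinary least squares with t-based confidence intervals
#'
#' Solves the least-squares problem for a design built by
#' [build_design()], returning a coefficient table in which each
#' categorical term's reference level appears as a row with coefficient
#' exactly 0 marked `Ref`.  95% confidence intervals use the t
#' distribution with `n - p` degrees of freedom.
#'
#' @param design list from [build_design()].
#' @param y numeric outcome (life expectancy, years).
#' @param level confidence level (default 0.95).
#' @return data.frame: `term`, `level`, `coefficient`, `ci_low`,
#'   `ci_high`, `is_ref`; attributes `n_obs`, `sigma2`, `df`.
#' @export
fit_ols <- function(design, y, level = 0.95) {
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("fit_ols: fewer observations than parameters",
                   call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("fit_ols: rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_x, y)
  resid <- y - X %*% beta
  df <- n - p
  sigma2 <- sum(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(X)
  tcrit <- qt(1 - (1 - level) / 2, df)

  lab <- design$labels
  out <- data.frame(term = lab$term, level = lab$level,
                    coefficient = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, is_ref = is.na(lab$column),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(lab))) {
    if (is.na(lab$column[i])) {
      out$coefficient[i] <- 0
    } else {
      b <- beta[[lab$column[i]]]
      s <- se[[lab$column[i]]]
      out$coefficient[i] <- b
      out$ci_low[i] <- b - tcrit * s
      out$ci_high[i] <- b + tcrit * s
    }
  }
  attr(out, "n_obs") <- n
  attr(out, "sigma2") <- sigma2
  attr(out, "df") <- df
  out
}

#' Unadjusted mobility-characteristic models (one per income class)
#'
#' For each of the three socio-spatial mobility characteristics (net
#' change magnitude category in lower-, moderate- and higher-income
#' households), fits an unadjusted linear model of life expectancy on the
#' four-level category with `major_decline` as reference.
#'
#' @param data analysis tract table joined with mobility categories
#'   (`cat_lower`, `cat_moderate`, `cat_higher`) and `life_expectancy`.
#' @return data.frame of stacked coefficient tables with a
#'   `characteristic` column.
#' @export
fit_mobility_ols <- function(data) {
  rows <- lapply(income_class_levels(), function(k) {
    tm <- paste0("cat_", k)
    d <- build_design(data, tm,
                      ref_levels = stats::setNames(list("major_decline"), tm))
    fit <- fit_ols(d, data$life_expectancy)
    fit$characteristic <- paste0("net_change_", k)
    fit
  })
  do.call(rbind, rows)
}

#' HOLC-stratified models of gentrification status on life expectancy
#'
#' Within each HOLC grade, fits life expectancy on gentrification status,
#' optionally adjusted for the three mobility magnitude categories and,
#' as a sensitivity analysis, for the tract-level percentage-point change
#' in non-White population.  The gentrification reference level is
#' `ineligible` where that level exists in the stratum and `earlier`
#' otherwise (the two worst HOLC grades have no ineligible tracts).
#'
#' @param data analysis tract table with `holc_grade`,
#'   `gentrification_status`, `life_expectancy` and (if `adjusted`)
#'   `cat_lower`, `cat_moderate`, `cat_higher`; (if `sensitivity`)
#'   `pct_non_white_change`.
#' @param adjusted include the mobility category terms.
#' @param sensitivity also include the non-White population change term.
#' @param ref_fallback gentrification reference when `ineligible` is
#'   absent from a stratum.
#' @return stacked coefficient tables with `stratum` and `model` columns.
#' @export
fit_stratified_ols <- function(data, adjusted = FALSE,
                               sensitivity = FALSE,
                               ref_fallback = "earlier") {
  strata <- holc_levels()[holc_levels() %in% unique(data$holc_grade)]
  rows <- list()
  for (g in strata) {
    sub <- data[data$holc_grade == g, , drop = FALSE]
    levs <- unique(sub$gentrification_status)
    if (length(levs) < 2) next
    ref <- if ("ineligible" %in% levs) "ineligible" else ref_fallback
    if (!ref %in% levs) ref <- levs[1]
    terms <- "gentrification_status"
    refs <- list(gentrification_status = ref)
    if (adjusted) {
      terms <- c(terms, "cat_lower", "cat_moderate", "cat_higher")
      refs <- c(refs, list(cat_lower = "major_decline",
                           cat_moderate = "major_decline",
                           cat_higher = "major_decline"))
    }
    if (sensitivity) terms <- c(terms, "pct_non_white_change")
    fit <- tryCatch({
      d <- build_design(sub, terms, refs)
      fit_ols(d, sub$life_expectancy)
    }, error = function(e) {
      warning("fit_stratified_ols: stratum '", g, "' skipped: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(fit)) next
    fit$stratum <- g
    fit$model <- if (sensitivity) "sensitivity"
                 else if (adjusted) "adjusted" else "unadjusted"
    rows[[length(rows) + 1]] <- fit
  }
  do.call(rbind, rows)
}

#' Cross-classified transformation status
#'
#' Combines HOLC grade and gentrification status into the single label
#' used as the fixed effect of the unstratified spatial model, with
#' reference "unclassified / ineligible".
#'
#' @param holc_grade,gentrification_status character vectors.
#' @return character vector "grade / status".
#' @export
transformation_status <- function(holc_grade, gentrification_status) {
  paste(holc_grade, gentrification_status, sep = " / ")
}
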
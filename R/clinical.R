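#' Fisher's exact test for an r x c contingency table
#'
#' Two-sided exact test (Freeman-Halton generalisation for tables beyond
#' 2 x 2): the p-value sums the probabilities, under fixed margins, of every
#' table whose hypergeometric probability does not exceed the observed
#' table's. Degenerate tables (a zero margin) return p = 1 with a warning.
#'
#' @param tab matrix of non-negative integer counts, at least 2 x 2.
#' @return list with `p` and the observed table's `table_probability`.
#' @export
fisher_exact_rc <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stopf("need at least a 2 x 2 table")
  if (any(tab < 0) || any(tab != round(tab))) stopf("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warnf("zero margin: test degenerate, p = 1")
    return(list(p = 1, table_probability = 1))
  }
  ft <- stats::fisher.test(tab, workspace = 2e7)
  list(p = ft$p.value, table_probability = table_prob(tab))
}

# hypergeometric probability of a table given its margins
table_prob <- function(tab) {
  exp(sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
        lgamma(sum(tab) + 1) - sum(lgamma(tab + 1)))
}

#' One-way ANOVA from raw vectors or group summaries
#'
#' Classic between/within decomposition. In summary mode each group supplies
#' `n`, `mean`, `sd`: the between sum of squares comes from the means and
#' sizes, the within sum of squares is \eqn{\sum (n_i - 1) sd_i^2} — an
#' algebraic identity with the raw computation, so both modes agree exactly
#' on consistent inputs. Summary mode is what reproduces a published table's
#' test from its printed "mean (sd)" cells.
#'
#' @param groups either a list of numeric vectors (raw mode) or a
#'   `data.frame` with columns `n`, `mean`, `sd` (summary mode).
#' @return list with `F`, `df` (length 2), `p`, `grand_mean`.
#' @export
anova_oneway <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("n", "mean", "sd") %in% names(groups)))
      stopf("summary mode needs columns n, mean, sd")
    if (any(groups$n < 2)) stopf("summary mode needs n >= 2 per group")
    n <- groups$n; m <- groups$mean; s <- groups$sd
  } else {
    if (length(groups) < 2) stopf("need >= 2 groups")
    n <- lengths(groups)
    m <- vapply(groups, mean, numeric(1))
    s <- vapply(groups, stats::sd, numeric(1))
  }
  if (length(n) < 2) stopf("need >= 2 groups")
  gm <- sum(n * m) / sum(n)
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * s^2)
  dfb <- length(n) - 1
  dfw <- sum(n) - length(n)
  if (ssw == 0) {
    f <- if (ssb == 0) 0 else Inf
  } else f <- (ssb / dfb) / (ssw / dfw)
  p <- if (ssb == 0) 1 else stats::pf(f, dfb, dfw, lower.tail = FALSE)
  list(F = f, df = c(dfb, dfw), p = p, grand_mean = gm)
}

#' Reference cohort clinical profile
#'
#' The clinical profile of the esophageal case-control reference cohort the
#' package's defaults emulate: 13 healthy controls, 10 early-lesion (ESIN)
#' and 12 carcinoma (ESCC) patients, with per-group yes-counts for the
#' questionnaire covariates and the per-group age summaries (mean, sd).
#' These are the worked-example inputs for [fisher_exact_rc()] and
#' [anova_oneway()] in summary mode.
#'
#' @return list with `n` (named group sizes), `categorical` (`data.frame`
#'   covariate x group yes-counts) and `age` (`data.frame` group, mean, sd).
#' @export
reference_cohort <- function() {
  list(
    n = c(HC = 13L, ESIN = 10L, ESCC = 12L),
    categorical = data.frame(
      covariate = c("male", "married", "agriculturalist",
                    "below_junior_high", "current_smoking",
                    "alcohol_flushing", "current_alcohol",
                    "vegetables_daily", "fruit_daily", "eating_fast",
                    "salty_diet", "family_history_cancer",
                    "hot_food_preference", "low_income"),
      HC = c(9L, 13L, 5L, 11L, 5L, 7L, 4L, 1L, 0L, 3L, 1L, 0L, 0L, 5L),
      ESIN = c(9L, 8L, 3L, 6L, 6L, 7L, 7L, 5L, 2L, 6L, 5L, 3L, 5L, 6L),
      ESCC = c(11L, 10L, 9L, 10L, 10L, 7L, 11L, 3L, 1L, 3L, 2L, 0L, 3L, 11L),
      stringsAsFactors = FALSE),
    age = data.frame(group = c("HC", "ESIN", "ESCC"),
                     mean = c(64.3, 63.5, 66.8),
                     sd = c(11.0, 9.80, 5.94),
                     stringsAsFactors = FALSE))
}

#' Clinical characteristics table with per-row tests
#'
#' Builds a cohort-description table in the conventional layout: one row per
#' covariate, an overall column plus one column per group; categorical
#' covariates (logical or factor-like) shown as "count (percent)" with a
#' Fisher exact p-value across groups, numeric covariates as "mean (sd)"
#' with a one-way ANOVA p-value.
#'
#' @param meta metadata `data.frame` with `sample_id`, `group`, covariates.
#' @param covariates character vector of covariate column names.
#' @param digits decimals for the rendered p-values (default 3; the `p`
#'   column keeps full precision).
#' @return `data.frame` with `characteristic`, `overall`, one column per
#'   group, `p`, `p_rendered`.
#' @export
summary_table <- function(meta, covariates, digits = 3) {
  miss <- setdiff(covariates, names(meta))
  if (length(miss)) stopf("covariate(s) missing: %s", paste(miss, collapse = ", "))
  g <- droplevels(factor(meta$group))
  lev <- levels(g)
  rows <- lapply(covariates, function(cv) {
    v <- meta[[cv]]
    if (is.numeric(v) && !all(v %in% c(0, 1))) {
      cell <- function(x) sprintf("%.1f (%.3g)", mean(x), stats::sd(x))
      summ <- data.frame(n = as.integer(table(g)),
                         mean = as.numeric(tapply(v, g, mean)),
                         sd = as.numeric(tapply(v, g, sd)))
      p <- anova_oneway(summ)$p
      vals <- c(cell(v), vapply(lev, function(l) cell(v[g == l]), character(1)))
    } else {
      yes <- as.logical(v)
      tab <- rbind(yes = tapply(yes, g, sum), no = tapply(!yes, g, sum))
      p <- fisher_exact_rc(tab)$p
      cell <- function(k, n) sprintf("%d (%s%%)", k, formatC(100 * k / n, format = "fg", digits = 3))
      vals <- c(cell(sum(yes), length(yes)),
                vapply(lev, function(l) cell(sum(yes[g == l]), sum(g == l)), character(1)))
    }
    out <- data.frame(characteristic = cv, t(vals), p = p,
                      p_rendered = formatC(p, format = "f", digits = digits),
                      stringsAsFactors = FALSE)
    names(out)[2:(2 + length(lev))] <- c("overall", lev)
    out
  })
  do.call(rbind, rows)
}
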
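#' Per-sample mean/variance points for Type-I Taylor power-law extension
#'
#' For each sample, M is the mean and V the (n-1 denominator) variance of
#' per-taxon abundances within that sample. By default only taxa with a
#' nonzero count in the sample enter the summary — Type-I community
#' heterogeneity concerns species present in the community; setting
#' `include_zeros = TRUE` instead summarises over every taxon row, which
#' shifts b systematically, so the choice is recorded on the result.
#' Degenerate points (M = 0 or V = 0) are excluded with a warning.
#'
#' @param x a `feature_table` (counts by default; proportions are accepted
#'   and flagged by the caller's choice of input).
#' @param samples optional subset of sample ids.
#' @param include_zeros include zero-count taxa in the per-sample summary.
#' @return `data.frame` with `sample_id`, `M`, `V`; attribute
#'   `"include_zeros"` records the zero-handling mode.
#' @export
tple_points <- function(x, samples = NULL, include_zeros = FALSE) {
  ids <- samples %||% sample_ids(x)
  pts <- lapply(ids, function(s) {
    v <- x$counts[, s]
    if (!include_zeros) v <- v[v > 0]
    if (length(v) < 2) return(data.frame(sample_id = s, M = NA_real_, V = NA_real_))
    data.frame(sample_id = s, M = mean(v), V = stats::var(v))
  })
  pts <- do.call(rbind, pts)
  bad <- is.na(pts$V) | pts$V <= 0 | pts$M <= 0
  if (any(bad))
    warnf("excluding %d degenerate sample point(s): %s", sum(bad),
          paste(pts$sample_id[bad], collapse = ", "))
  pts <- pts[!bad, , drop = FALSE]
  if (nrow(pts) < 3) stopf("fewer than 3 usable (M, V) points")
  attr(pts, "include_zeros") <- include_zeros
  pts
}

#' Fit a Type-I Taylor power-law extension
#'
#' Ordinary least squares of ln V on ln M across samples: V = a M^b, so the
#' slope b indexes community spatial heterogeneity (aggregation) — higher b,
#' more heterogeneous. R and the two-sided p come from the Pearson
#' correlation test on the log-log points.
#'
#' @param points output of [tple_points()] (or any data.frame with positive
#'   `M`, `V` columns).
#' @param group optional group label stored on the fit.
#' @return object of class `tple_fit` with fields `b`, `ln_a`, `R`, `p`,
#'   `n`, `group`, `points`.
#' @export
tple_fit <- function(points, group = NA_character_) {
  if (nrow(points) < 3) stopf("need >= 3 points")
  lm_ <- log(points$M); lv <- log(points$V)
  if (stats::sd(lm_) == 0) stopf("degenerate fit: all sample means equal")
  fit <- stats::lm(lv ~ lm_)
  ct <- stats::cor.test(lm_, lv)
  structure(list(group = group,
                 b = unname(stats::coef(fit)[2]),
                 ln_a = unname(stats::coef(fit)[1]),
                 R = unname(ct$estimate),
                 p = ct$p.value,
                 n = nrow(points),
                 include_zeros = isTRUE(attr(points, "include_zeros")),
                 points = points),
            class = "tple_fit")
}

#' @export
print.tple_fit <- function(x, ...) {
  cat(sprintf("Type-I TPLE fit%s: b = %.3f, ln(a) = %.3f, R = %.3f, p = %.3g, n = %d\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              x$b, x$ln_a, x$R, x$p, x$n))
  invisible(x)
}

#' @export
coef.tple_fit <- function(object, ...) c(ln_a = object$ln_a, b = object$b)

#' Fit TPLE per group
#'
#' @param x a `feature_table`.
#' @param meta sample metadata.
#' @param include_zeros passed to [tple_points()].
#' @return named list of `tple_fit`, one per group present.
#' @export
tple_by_group <- function(x, meta, include_zeros = FALSE) {
  g <- group_vector(meta, sample_ids(x))
  fits <- lapply(split(names(g), g), function(ids) {
    tryCatch(tple_fit(tple_points(x, ids, include_zeros), group = unique(g[ids])),
             error = function(e) {
               warnf("group %s: %s; fit skipped", unique(g[ids]), conditionMessage(e))
               NULL
             })
  })
  Filter(Negate(is.null), fits)
}

#' Permutation contrast of TPLE parameters between two groups
#'
#' Pools the two groups' samples, reassigns group membership at the original
#' sizes, refits both groups and records |delta b| (and |delta ln a|); p is
#' the add-one proportion of permuted |delta| at least the observed one. If
#' the number of distinct reassignments is below `n_perm`, all distinct
#' splits are enumerated instead (with a warning).
#'
#' @param x a `feature_table` holding both groups' samples.
#' @param samples_a,samples_b sample ids of the two groups.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param include_zeros passed to [tple_points()].
#' @return list with `delta_b`, `p_b`, `delta_ln_a`, `p_ln_a`, `n_perm`,
#'   `seed`.
#' @export
tple_compare <- function(x, samples_a, samples_b, n_perm = 999, seed = 1,
                         include_zeros = FALSE) {
  fit_pair <- function(ids_a, ids_b) {
    fa <- tple_fit(suppressWarnings(tple_points(x, ids_a, include_zeros)))
    fb <- tple_fit(suppressWarnings(tple_points(x, ids_b, include_zeros)))
    c(db = abs(fa$b - fb$b), da = abs(fa$ln_a - fb$ln_a))
  }
  obs <- fit_pair(samples_a, samples_b)
  pool <- c(samples_a, samples_b)
  na <- length(samples_a)
  n_distinct <- choose(length(pool), na)
  set.seed(derive_seed(seed, 21L))
  if (n_distinct <= n_perm) {
    warnf("only %d distinct reassignments; enumerating exactly", n_distinct)
    splits <- utils::combn(pool, na, simplify = FALSE)
    perm <- vapply(splits, function(a) fit_pair(a, setdiff(pool, a)), numeric(2))
    n_used <- length(splits)
  } else {
    perm <- vapply(seq_len(n_perm), function(i) {
      a <- sample(pool, na)
      fit_pair(a, setdiff(pool, a))
    }, numeric(2))
    n_used <- n_perm
  }
  list(delta_b = unname(obs["db"]),
       p_b = perm_pvalue(sum(perm["db", ] >= obs["db"] - 1e-12), n_used),
       delta_ln_a = unname(obs["da"]),
       p_ln_a = perm_pvalue(sum(perm["da", ] >= obs["da"] - 1e-12), n_used),
       n_perm = n_used, seed = seed)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Assigns letters so that two groups share a letter if and only if they are
#' not significantly different at `alpha` (insertion-absorption algorithm).
#' Used to annotate per-group heterogeneity contrasts: a group differing from
#' every other receives a unique letter.
#'
#' @param p symmetric matrix of pairwise p-values with group dimnames.
#' @param alpha significance threshold.
#' @return named character vector of letter strings per group.
#' @export
compact_letters <- function(p, alpha = 0.05) {
  groups <- rownames(p)
  k <- length(groups)
  # letters as a list of member sets; start with one letter containing all
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (p[i, j] >= alpha) next
    # i and j must not share any letter: split every set containing both
    for (s in seq_along(sets)) {
      if (all(c(i, j) %in% sets[[s]])) {
        a <- setdiff(sets[[s]], j)
        b <- setdiff(sets[[s]], i)
        sets[[s]] <- a
        sets[[length(sets) + 1]] <- b
      }
    }
    # absorb sets fully contained in another
    keep <- rep(TRUE, length(sets))
    for (s in seq_along(sets)) for (t in seq_along(sets)) {
      if (s != t && keep[s] && keep[t] && all(sets[[s]] %in% sets[[t]]))
        keep[s] <- FALSE
    }
    sets <- sets[keep]
  }
  sets <- sets[order(vapply(sets, min, integer(1)))]
  out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  stats::setNames(out, groups)
}
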
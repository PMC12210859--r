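#' Hill number of a relative-abundance vector
#'
#' Effective number of species of order `q`:
#' \deqn{^qD = \left(\sum_i p_i^q\right)^{1/(1-q)}}
#' with the Shannon limit \eqn{\exp(-\sum_i p_i \log p_i)} at `q = 1`.
#' `q = 0` is richness, `q = 2` the inverse Simpson concentration. Zeros are
#' excluded from the sums; the limit form is computed exactly at `q = 1`
#' rather than by approaching it numerically.
#'
#' @param p non-negative abundance vector; normalised internally.
#' @param q diversity order, non-negative real (vectorised).
#' @return Hill number(s), one per `q`.
#' @examples
#' hill_number(rep(1, 5), 0:2)        # uniform: always 5
#' hill_number(c(0.9, 0.1), 1)        # exp(Shannon) = 1.38417
#' @export
hill_number <- function(p, q) {
  if (length(p) == 0 || all(p == 0)) stopf("empty or all-zero abundance vector")
  if (any(p < 0)) stopf("negative abundances")
  p <- p[p > 0]
  p <- p / sum(p)
  vapply(q, function(qi) {
    if (qi < 0) stopf("diversity order q must be >= 0")
    if (abs(qi - 1) < .Machine$double.eps^0.5)
      exp(-sum(p * log(p)))
    else
      sum(p^qi)^(1 / (1 - qi))
  }, numeric(1))
}

#' Hill diversity profile for every sample of a table
#'
#' @param x a `feature_table`.
#' @param q vector of diversity orders (default 0, 1, 2).
#' @return long `data.frame` with `sample_id`, `q`, `value`.
#' @export
hill_profile <- function(x, q = c(0, 1, 2)) {
  res <- expand.grid(sample_id = sample_ids(x), q = q,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$value <- mapply(function(s, qi) hill_number(x$counts[, s], qi),
                      res$sample_id, res$q)
  res[order(res$sample_id, res$q), , drop = FALSE]
}

#' Pairwise Wilcoxon contrasts of alpha diversity between groups
#'
#' Two-sided rank-sum test of Hill numbers at a fixed order for every
#' unordered pair of groups (exact where sample sizes allow and ties are
#' absent, normal approximation otherwise), with Benjamini-Hochberg
#' adjustment across the family of pairs.
#'
#' @param profile output of [hill_profile()].
#' @param meta sample metadata (see [read_metadata()]).
#' @param q the diversity order to contrast.
#' @return `data.frame` with `group_a`, `group_b`, `p`, `p_adjusted`.
#' @export
alpha_contrasts <- function(profile, meta, q) {
  sub <- profile[profile$q == q, ]
  g <- group_vector(meta, sub$sample_id)
  tab <- table(g)
  if (any(tab < 2)) stopf("each group needs >= 2 samples (offending: %s)",
                          paste(names(tab)[tab < 2], collapse = ", "))
  groups <- names(tab)
  pairs <- utils::combn(groups, 2)
  p <- apply(pairs, 2, function(pr) {
    suppressWarnings(stats::wilcox.test(sub$value[g == pr[1]],
                                        sub$value[g == pr[2]],
                                        exact = NULL)$p.value)
  })
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
             p = p, p_adjusted = bh_adjust(p), stringsAsFactors = FALSE)
}

#' Hellinger transformation
#'
#' Per sample, each entry becomes the square root of its relative abundance,
#' so every transformed column has unit Euclidean norm.
#'
#' @param x a `feature_table` (counts or proportions).
#' @return a `feature_table` of Hellinger-transformed values.
#' @export
hellinger <- function(x) {
  cs <- colSums(x$counts)
  if (any(cs <= 0)) stopf("zero-total sample(s): %s",
                          paste(sample_ids(x)[cs <= 0], collapse = ", "))
  out <- sqrt(sweep(x$counts, 2, cs, "/"))
  structure(list(counts = out, is_relative = FALSE), class = "feature_table")
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}; computed with
#' `vegan::vegdist`. For the beta-diversity workflow apply [hellinger()]
#' first.
#'
#' @param x a `feature_table`.
#' @return a `dist` object over samples.
#' @export
bray_curtis <- function(x) {
  zero <- colSums(x$counts) == 0
  if (sum(zero) >= 2)
    stopf("Bray-Curtis undefined between all-zero samples: %s",
          paste(sample_ids(x)[zero], collapse = ", "))
  vegan::vegdist(t(x$counts), method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of the double-centred squared-distance matrix.
#' Negative eigenvalues (non-Euclidean input) are reported, never silently
#' dropped.
#'
#' @param d a `dist` or symmetric matrix of dissimilarities.
#' @param k number of coordinate axes to return.
#' @return list with `coordinates` (n x k), `eigenvalues` (all n), and
#'   `proportion_explained` (relative to the sum of positive eigenvalues).
#' @export
pcoa <- function(d, k = 2) {
  n <- attr(stats::as.dist(d), "Size")
  if (k < 1 || k > n - 1) stopf("k must lie in 1..%d", n - 1)
  sc <- stats::cmdscale(d, k = k, eig = TRUE)
  pos <- sc$eig[sc$eig > 0]
  list(coordinates = sc$points,
       eigenvalues = sc$eig,
       proportion_explained = sc$eig[seq_len(k)] / sum(pos))
}

#' PERMANOVA on a distance matrix
#'
#' One-factor permutational multivariate analysis of variance
#' (`vegan::adonis2`): the total sum of squared dissimilarities is
#' partitioned into between- and within-group parts, R-squared is their
#' ratio, and the p-value is the add-one proportion of label permutations
#' whose pseudo-F reaches the observed one.
#'
#' @param d `dist` or symmetric matrix.
#' @param labels group label per sample, in `d`'s sample order.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return list with `R2`, `F`, `p`, `n_perm`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1) {
  d <- stats::as.dist(d)
  check_group_sizes(labels, attr(d, "Size"), n_perm)
  if (all(d < .Machine$double.eps)) {
    warnf("all pairwise dissimilarities are zero; R2 reported as 0")
    return(list(R2 = 0, F = NA_real_, p = 1, n_perm = n_perm))
  }
  df <- data.frame(g = factor(labels))
  set.seed(derive_seed(seed, 11L))
  fit <- vegan::adonis2(d ~ g, data = df, permutations = n_perm)
  list(R2 = fit$R2[1], F = fit$F[1], p = fit$`Pr(>F)`[1], n_perm = n_perm)
}

#' ANOSIM on a distance matrix
#'
#' Rank-based analysis of similarities (`vegan::anosim`):
#' R = (mean between-group rank - mean within-group rank) / (M/2),
#' M = n(n-1)/2, with an add-one permutation p-value.
#'
#' @inheritParams permanova
#' @return list with `R`, `p`, `n_perm`.
#' @export
anosim <- function(d, labels, n_perm = 999, seed = 1) {
  d <- stats::as.dist(d)
  check_group_sizes(labels, attr(d, "Size"), n_perm)
  set.seed(derive_seed(seed, 12L))
  fit <- vegan::anosim(d, grouping = factor(labels), permutations = n_perm)
  list(R = unname(fit$statistic), p = fit$signif, n_perm = n_perm)
}

check_group_sizes <- function(labels, n, n_perm) {
  if (length(labels) != n) stopf("labels length (%d) != matrix size (%d)", length(labels), n)
  tab <- table(labels)
  if (length(tab) < 2) stopf("need >= 2 groups")
  if (any(tab < 2)) stopf("each group needs >= 2 samples")
  if (n_perm < 1) stopf("n_perm must be >= 1")
}

#' Pairwise beta-diversity contrasts with BH adjustment
#'
#' Runs PERMANOVA (default) or ANOSIM on the sub-distance-matrix of every
#' requested unordered group pair (distances are not recomputed — a
#' dissimilarity between two samples does not depend on the rest), then
#' adjusts the family of p-values by Benjamini-Hochberg.
#'
#' @param d `dist` or symmetric matrix over all samples.
#' @param labels group label per sample in `d`'s order.
#' @param statistic `"permanova_R2"` or `"anosim_R"`.
#' @param pairs optional 2-column matrix / list of group pairs to test;
#'   default all unordered pairs.
#' @param n_perm permutations per contrast.
#' @param seed integer seed.
#' @return `data.frame` with `group_a`, `group_b`, `statistic_kind`,
#'   `statistic`, `p`, `p_adjusted`.
#' @export
pairwise_beta <- function(d, labels, statistic = c("permanova_R2", "anosim_R"),
                          pairs = NULL, n_perm = 999, seed = 1) {
  statistic <- match.arg(statistic)
  m <- as.matrix(stats::as.dist(d))
  labels <- as.character(labels)
  if (is.null(pairs)) pairs <- t(utils::combn(unique(labels), 2))
  pairs <- as.matrix(pairs)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- pairs[i, ]
    sel <- labels %in% pr
    if (sum(labels == pr[1]) < 2 || sum(labels == pr[2]) < 2)
      stopf("pair %s vs %s: each group needs >= 2 samples", pr[1], pr[2])
    dsub <- stats::as.dist(m[sel, sel])
    if (statistic == "permanova_R2") {
      f <- permanova(dsub, labels[sel], n_perm, derive_seed(seed, 100L + i))
      data.frame(group_a = pr[1], group_b = pr[2],
                 statistic_kind = statistic, statistic = f$R2, p = f$p,
                 stringsAsFactors = FALSE)
    } else {
      f <- anosim(dsub, labels[sel], n_perm, derive_seed(seed, 100L + i))
      data.frame(group_a = pr[1], group_b = pr[2],
                 statistic_kind = statistic, statistic = f$R, p = f$p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p)
  out
}
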
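#' Kruskal-Wallis screen of taxa across groups
#'
#' First stage of the effect-size biomarker screen: a tie-corrected
#' Kruskal-Wallis rank-sum test per taxon across all groups. With more than
#' two groups, a one-against-all consistency check is added: for the
#' candidate enriched group (largest mean relative abundance), every pairwise
#' Wilcoxon comparison against each other group must agree in direction
#' (enriched-group median rank above) for the taxon to keep its pass flag.
#' Constant taxa get p = 1.
#'
#' @param x a relative `feature_table`.
#' @param labels group label per sample (in sample order).
#' @param alpha screen significance threshold (default 0.05).
#' @return `data.frame` with `taxon_id`, `p`, `enriched_group`, `pass`.
#' @export
kw_screen <- function(x, labels, alpha = 0.05) {
  if (!x$is_relative) stopf("kw_screen expects relative abundances (see to_relative)")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stopf("need >= 2 groups")
  g <- factor(labels)
  res <- lapply(taxon_ids(x), function(tid) {
    v <- x$counts[tid, ]
    if (stats::sd(v) == 0)
      return(data.frame(taxon_id = tid, p = 1, enriched_group = NA_character_,
                        pass = FALSE, stringsAsFactors = FALSE))
    # two groups: the Kruskal-Wallis statistic is the rank-sum test, so use
    # the exact two-sided rank-sum p where it exists
    p <- if (nlevels(g) == 2)
      suppressWarnings(stats::wilcox.test(v[g == levels(g)[1]],
                                          v[g == levels(g)[2]])$p.value)
    else suppressWarnings(stats::kruskal.test(v, g)$p.value)
    means <- tapply(v, g, mean)
    top <- names(means)[which.max(means)]
    consistent <- TRUE
    if (nlevels(g) > 2 && p < alpha) {
      others <- setdiff(levels(g), top)
      consistent <- all(vapply(others, function(o) {
        w <- suppressWarnings(stats::wilcox.test(v[labels == top], v[labels == o]))
        # direction: enriched group ranks above this one
        mean(rank(c(v[labels == top], v[labels == o]))[seq_len(sum(labels == top))]) >
          (sum(labels %in% c(top, o)) + 1) / 2
      }, logical(1)))
    }
    data.frame(taxon_id = tid, p = p, enriched_group = top,
               pass = p < alpha && consistent, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' LDA effect size of screened taxa (LEfSe-style)
#'
#' For taxa passing [kw_screen()], abundances are rescaled to sum 1e6 per
#' sample and an effect size is estimated by bootstrapped two-class linear
#' discriminant analysis of the enriched group against the rest: in each of
#' `n_boot` bootstraps a fraction of samples per class is drawn, an LDA with
#' pooled covariance shrunk toward its diagonal (factor 0.1, needed at
#' small n) is fitted, and the per-taxon effect is
#' 0.5 (|difference of raw class means| + |difference of projected class
#' means|). The reported LDA score is log10(1 + mean bootstrap effect); taxa
#' with score at or above `lda_threshold` (3.0 by convention) and a passing
#' screen are flagged.
#'
#' @param x a relative `feature_table`.
#' @param labels group label per sample.
#' @param screen optional precomputed [kw_screen()] result.
#' @param n_boot bootstrap rounds (default 30).
#' @param subsample_fraction per-class fraction drawn each round (default 2/3).
#' @param lda_threshold score threshold for the pass flag (default 3.0).
#' @param alpha screen threshold passed to [kw_screen()] when not supplied.
#' @param seed integer seed.
#' @return `data.frame` with `taxon_id`, `enriched_group`, `kw_p`,
#'   `lda_score`, `passes_threshold`.
#' @export
lda_effect_size <- function(x, labels, screen = NULL, n_boot = 30,
                            subsample_fraction = 2 / 3, lda_threshold = 3.0,
                            alpha = 0.05, seed = 1) {
  if (!x$is_relative) stopf("lda_effect_size expects relative abundances")
  labels <- as.character(labels)
  if (is.null(screen)) screen <- kw_screen(x, labels, alpha = alpha)
  cand <- screen[screen$pass, , drop = FALSE]
  out <- data.frame(taxon_id = screen$taxon_id,
                    enriched_group = screen$enriched_group,
                    kw_p = screen$p,
                    lda_score = 0,
                    passes_threshold = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(cand) == 0) return(out)
  scaled <- x$counts * 1e6   # per-sample sum 1e6
  set.seed(derive_seed(seed, 41L))
  for (i in seq_len(nrow(cand))) {
    tid <- cand$taxon_id[i]
    y <- labels == cand$enriched_group[i]
    eff <- lda_bootstrap_effect(scaled, tid, y, n_boot, subsample_fraction)
    j <- match(tid, out$taxon_id)
    out$lda_score[j] <- log10(1 + eff)
    out$passes_threshold[j] <- out$lda_score[j] >= lda_threshold
  }
  out
}

# mean bootstrap effect for one taxon: two-class regularized LDA on the
# candidate feature plus the per-sample remainder (so the discriminant sees
# the compositional context), effect combines raw and projected mean gaps
lda_bootstrap_effect <- function(scaled, tid, y, n_boot, frac) {
  v <- scaled[tid, ]
  rest <- colSums(scaled) - v   # complement channel, constant 1e6 - v
  X <- cbind(feat = v, ctx = rest)
  n1 <- sum(y); n0 <- sum(!y)
  effects <- numeric(0)
  tries <- 0
  while (length(effects) < n_boot && tries < n_boot * 5) {
    tries <- tries + 1
    i1 <- sample(which(y), max(3, ceiling(frac * n1)), replace = TRUE)
    i0 <- sample(which(!y), max(3, ceiling(frac * n0)), replace = TRUE)
    xb <- X[c(i1, i0), , drop = FALSE]
    yb <- rep(c(TRUE, FALSE), c(length(i1), length(i0)))
    if (length(unique(xb[yb, "feat"])) < 1 || stats::sd(xb[, "feat"]) == 0) next
    m1 <- colMeans(xb[yb, , drop = FALSE]); m0 <- colMeans(xb[!yb, , drop = FALSE])
    S <- (crossprod(sweep(xb[yb, , drop = FALSE], 2, m1)) +
            crossprod(sweep(xb[!yb, , drop = FALSE], 2, m0))) /
      (nrow(xb) - 2)
    S <- 0.9 * S + 0.1 * diag(diag(S), ncol(S))   # shrink toward diagonal
    diag(S) <- pmax(diag(S), 1e-8)
    w <- tryCatch(solve(S, m1 - m0), error = function(e) NULL)
    if (is.null(w)) next
    w <- w / sqrt(sum(w^2))
    proj_gap <- abs(sum(w * (m1 - m0)))
    raw_gap <- abs(m1["feat"] - m0["feat"])
    effects <- c(effects, 0.5 * (raw_gap + proj_gap))
  }
  if (!length(effects)) {
    warnf("taxon %s: persistent bootstrap failure, effect set to 0", tid)
    return(0)
  }
  mean(effects)
}

#' ROC area under the curve for a diagnostic score
#'
#' AUC via the Mann-Whitney identity: the proportion of case-control pairs
#' where the case scores higher, ties counted one half. The ROC curve points
#' (false/true positive rate at every threshold) are attached.
#'
#' @param scores numeric per-sample score.
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive class.
#' @return list with `auc`, `curve` (`data.frame` fpr, tpr, threshold),
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stopf("both classes must be non-empty")
  pos <- scores[labels]; neg <- scores[!labels]
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  auc <- u / (length(pos) * length(neg))
  th <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, th),
    tpr = c(0, vapply(th, function(t) mean(pos >= t), numeric(1))),
    fpr = c(0, vapply(th, function(t) mean(neg >= t), numeric(1))))
  list(auc = auc, curve = curve, n_pos = length(pos), n_neg = length(neg))
}

#' Combine two markers for ROC analysis
#'
#' Combined per-sample score from a two-feature logistic discriminant fitted
#' on the given samples: deterministic iteratively reweighted least squares
#' on standardized features with a small ridge penalty (1e-6) and
#' convergence tolerance 1e-8. The ridge keeps the fit defined under
#' perfect separation — where unpenalised maximum likelihood diverges — in
#' which case the direction still separates the classes (so a marker that
#' alone classifies perfectly yields a combined AUC of 1) and the result is
#' flagged. A simple `"sum"` rule (rank sum of standardized features) is
#' available as the alternative combination.
#'
#' @param score_a,score_b per-sample marker scores.
#' @param labels logical or 0/1 class labels.
#' @param rule `"logistic"` (default) or `"sum"`.
#' @return list with `auc_combined` (apparent, fitted on all samples),
#'   `auc_combined_cv` (leave-one-out cross-validated — the apparent AUC of
#'   a fitted combination is optimistic at small n, so the cross-validated
#'   value is the honest null-calibrated one; `NA` for the `"sum"` rule,
#'   which fits nothing), `auc_a`, `auc_b`, `combined_score`, `rule_used`,
#'   `separation_fallback`.
#' @export
combine_markers <- function(score_a, score_b, labels, rule = c("logistic", "sum")) {
  rule <- match.arg(rule)
  labels <- as.logical(labels)
  zs <- function(v) if (stats::sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / stats::sd(v)
  fallback <- FALSE
  auc_cv <- NA_real_
  if (rule == "sum") {
    comb <- rank(zs(score_a)) + rank(zs(score_b))
  } else {
    X <- cbind(1, zs(score_a), zs(score_b))
    fit <- ridge_logistic(X, labels, lambda = 1e-6, tol = 1e-8)
    fallback <- fit$separation
    comb <- as.numeric(X %*% fit$beta)
    # stratified 5-fold CV, deterministic round-robin fold assignment;
    # per-fold AUCs averaged (pooling left-out scores would bias AUC down)
    fold <- integer(length(labels))
    fold[labels] <- (seq_len(sum(labels)) - 1L) %% 5L + 1L
    fold[!labels] <- (seq_len(sum(!labels)) - 1L) %% 5L + 1L
    fold_aucs <- vapply(1:5, function(k) {
      tr <- fold != k
      if (length(unique(labels[tr])) < 2 || length(unique(labels[!tr])) < 2)
        return(NA_real_)
      f <- ridge_logistic(X[tr, , drop = FALSE], labels[tr], lambda = 1e-6,
                          tol = 1e-6, max_iter = 50)
      roc_auc(as.numeric(X[!tr, , drop = FALSE] %*% f$beta), labels[!tr])$auc
    }, numeric(1))
    auc_cv <- mean(fold_aucs, na.rm = TRUE)
  }
  list(auc_combined = roc_auc(comb, labels)$auc,
       auc_combined_cv = auc_cv,
       auc_a = roc_auc(score_a, labels)$auc,
       auc_b = roc_auc(score_b, labels)$auc,
       combined_score = unname(comb),
       rule_used = rule,
       separation_fallback = fallback)
}

# deterministic ridge-penalised logistic regression by IRLS; the intercept
# (first column) is not penalised
ridge_logistic <- function(X, y, lambda = 1e-6, tol = 1e-8, max_iter = 200) {
  beta <- numeric(ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1)))
  for (i in seq_len(max_iter)) {
    eta <- pmin(pmax(as.numeric(X %*% beta), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- as.numeric(X %*% beta)
  separation <- all((eta > 0) == y) && (min(abs(eta)) > 8)
  list(beta = beta, separation = separation)
}

#' Summed relative abundance of a species list
#'
#' Per-sample sum of relative abundances over a set of taxa — the score used
#' for a multi-species functional group marker.
#'
#' @param x a relative `feature_table`.
#' @param taxa taxon ids to sum (missing ids error).
#' @return named numeric vector per sample.
#' @export
group_abundance_score <- function(x, taxa) {
  miss <- setdiff(taxa, taxon_ids(x))
  if (length(miss)) stopf("taxa absent from table: %s", paste(miss, collapse = ", "))
  colSums(x$counts[taxa, , drop = FALSE])
}
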
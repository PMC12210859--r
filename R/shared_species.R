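#' Observed shared-taxon count between two sample groups
#'
#' A taxon is shared when it has at least one read in at least one sample of
#' each group (presence threshold: one read).
#'
#' @param x a `feature_table` of counts.
#' @param samples_a,samples_b disjoint sample-id sets.
#' @return integer count; attribute `"taxa"` holds the shared taxon ids.
#' @export
shared_observed <- function(x, samples_a, samples_b) {
  if (length(intersect(samples_a, samples_b)))
    stopf("sample sets overlap: %s",
          paste(intersect(samples_a, samples_b), collapse = ", "))
  in_a <- rowSums(x$counts[, samples_a, drop = FALSE] >= 1) > 0
  in_b <- rowSums(x$counts[, samples_b, drop = FALSE] >= 1) > 0
  structure(sum(in_a & in_b), taxa = taxon_ids(x)[in_a & in_b])
}

#' Shared-species permutation null (A2)
#'
#' Expected shared-taxon count between two groups when group membership is
#' exchangeable. Each permutation reshuffles sample-to-group labels at the
#' original group sizes and recomputes the shared count; the two-sided
#' p-value is the add-one proportion of permuted counts at least as far from
#' the null mean as the observed count.
#'
#' Two null variants are provided. `"labels"` (default) permutes labels
#' only. `"reads"` adds a second stage: within each pseudo-group, every
#' sample's reads are redrawn from the pseudo-group's pooled taxon profile by
#' multinomial resampling at that sample's original depth, propagating
#' read-level exchangeability into the null.
#'
#' @param x a counts `feature_table`.
#' @param samples_a,samples_b disjoint sample-id sets.
#' @param n_perm number of permutations (>= 100 recommended; fewer warns).
#' @param seed integer seed.
#' @param variant `"labels"` or `"reads"`.
#' @return list with `observed`, `null_mean`, `null_sd`, `p`, `n_perm`,
#'   `seed`, `variant`, and the permuted counts in `null`.
#' @export
a2_null <- function(x, samples_a, samples_b, n_perm = 999, seed = 1,
                    variant = c("labels", "reads")) {
  variant <- match.arg(variant)
  if (length(samples_a) < 2 || length(samples_b) < 2)
    stopf("both groups need >= 2 samples")
  if (n_perm < 100) warnf("n_perm < 100: null SD will be unstable")
  obs <- as.integer(shared_observed(x, samples_a, samples_b))
  pool <- c(samples_a, samples_b)
  na <- length(samples_a)
  counts <- x$counts[, pool, drop = FALSE]
  depths <- colSums(counts)
  set.seed(derive_seed(seed, 31L))
  null <- vapply(seq_len(n_perm), function(i) {
    idx <- sample(length(pool))
    a <- pool[idx[seq_len(na)]]
    b <- pool[idx[-seq_len(na)]]
    if (variant == "labels") {
      as.integer(shared_observed(x, a, b))
    } else {
      shared_after_read_resample(counts, a, b, depths)
    }
  }, integer(1))
  mu <- mean(null)
  sum(abs(null - mu) >= abs(obs - mu) - 1e-12) -> n_extreme
  list(observed = obs, null_mean = mu, null_sd = stats::sd(null),
       p = perm_pvalue(n_extreme, n_perm), n_perm = n_perm, seed = seed,
       variant = variant, null = null)
}

# second-stage read permutation: redraw each pseudo-group sample from the
# pooled group profile at fixed per-sample depth, then count shared taxa
shared_after_read_resample <- function(counts, a, b, depths) {
  present <- function(ids) {
    prof <- rowSums(counts[, ids, drop = FALSE])
    if (sum(prof) == 0) return(rep(FALSE, nrow(counts)))
    p <- prof / sum(prof)
    drawn <- vapply(ids, function(s) {
      stats::rmultinom(1, depths[[s]], p)[, 1]
    }, numeric(nrow(counts)))
    rowSums(drawn >= 1) > 0
  }
  as.integer(sum(present(a) & present(b)))
}
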
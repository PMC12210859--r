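#' SparCC correlation inference for compositional counts
#'
#' Estimates taxon-taxon correlations from compositional count data.
#' Per iteration: taxon fractions are drawn by Dirichlet smoothing of each
#' sample's counts (pseudocount 1; in the deterministic `resample = FALSE`
#' mode the posterior mean fractions are used instead), the log-ratio
#' variance matrix \eqn{t_{ij} = Var(\ln(x_i/x_j))} is computed, basis
#' variances \eqn{\omega} are solved from the sparsity-approximated linear
#' system, and correlations follow as
#' \eqn{\rho_{ij} = (\omega_i + \omega_j - t_{ij}) / (2\sqrt{\omega_i\omega_j})},
#' clipped to \[-1, 1\]. Pairs whose |correlation| exceeds
#' `exclusion_threshold` are excluded one at a time (strongest first, at most
#' `D - 3` exclusions per taxon) and the system re-solved, so that a few
#' strongly coupled pairs do not contaminate the sparse basis. The final
#' estimate is the entrywise median over iterations.
#'
#' @param x a counts `feature_table` (taxa x samples); needs >= 4 taxa and
#'   >= 10 samples for a stable basis system.
#' @param n_iterations outer resampling iterations (study-scale default 100;
#'   ignored when `resample = FALSE`).
#' @param exclusion_threshold correlation magnitude above which a pair is
#'   excluded from the basis system (default 0.1, the reference
#'   implementation's value).
#' @param max_exclusion_rounds cap on exclusion/re-solve rounds per iteration.
#' @param resample draw Dirichlet fractions (`TRUE`) or use deterministic
#'   posterior-mean fractions (`FALSE`).
#' @param seed integer seed.
#' @return object of class `sparcc_fit`: list with `rho` (correlation
#'   matrix), `omega` (basis variances), `n_iterations`, `dropped` (taxa
#'   removed for non-positive basis variance).
#' @export
sparcc <- function(x, n_iterations = 20, exclusion_threshold = 0.1,
                   max_exclusion_rounds = 10, resample = TRUE, seed = 1) {
  counts <- t(x$counts)  # samples x taxa
  n <- nrow(counts); D <- ncol(counts)
  if (D < 3) stopf("SparCC needs >= 3 taxa (got %d)", D)
  if (n < 10) warnf("only %d samples; SparCC estimates will be noisy", n)
  set.seed(derive_seed(seed, 51L))
  if (!resample) n_iterations <- 1
  rhos <- array(NA_real_, c(D, D, n_iterations))
  omega_last <- NULL
  for (it in seq_len(n_iterations)) {
    f <- draw_fractions(counts, resample)
    est <- sparcc_once(log(f), exclusion_threshold, max_exclusion_rounds)
    rhos[, , it] <- est$rho
    omega_last <- est$omega
  }
  rho <- apply(rhos, c(1, 2), stats::median, na.rm = TRUE)
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2
  dimnames(rho) <- list(taxon_ids(x), taxon_ids(x))
  dropped <- taxon_ids(x)[is.na(omega_last) | omega_last <= 0]
  if (length(dropped))
    warnf("non-positive basis variance, correlations zeroed for: %s",
          paste(dropped, collapse = ", "))
  structure(list(rho = rho, omega = stats::setNames(omega_last, taxon_ids(x)),
                 n_iterations = n_iterations, dropped = dropped),
            class = "sparcc_fit")
}

#' @export
print.sparcc_fit <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf("<sparcc_fit> %d taxa; median |rho| = %.3f, max |rho| = %.3f (%d iterations)\n",
              nrow(x$rho), stats::median(abs(off)), max(abs(off)), x$n_iterations))
  invisible(x)
}

draw_fractions <- function(counts, resample) {
  a <- counts + 1
  if (!resample) return(a / rowSums(a))
  # Dirichlet draw per sample via gamma variates
  g <- matrix(stats::rgamma(length(a), shape = a), nrow(a), ncol(a))
  g[g == 0] <- .Machine$double.xmin
  g / rowSums(g)
}

# one SparCC basis solve on log-fractions (samples x taxa)
sparcc_once <- function(logf, excl_thr, max_rounds) {
  D <- ncol(logf)
  V <- stats::var(logf)              # covariance of log fractions
  dv <- diag(V)
  Tmat <- outer(dv, dv, "+") - 2 * V # t_ij = var(log(xi/xj))
  M <- matrix(1, D, D) + diag(D - 2, D)
  trow <- rowSums(Tmat)
  excluded <- matrix(FALSE, D, D)
  t_use <- Tmat
  for (round in seq_len(max_rounds + 1)) {
    omega <- solve(M, trow)
    den <- outer(omega, omega)
    rho <- (outer(omega, omega, "+") - t_use) / (2 * sqrt(pmax(den, 1e-300)))
    rho[den <= 0] <- 0
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (round > max_rounds) break
    # strongest not-yet-excluded off-diagonal pair above threshold
    cand <- abs(rho)
    cand[lower.tri(cand, diag = TRUE)] <- 0
    cand[excluded] <- 0
    # per-taxon exclusion cap D-3
    n_excl <- rowSums(excluded) + colSums(excluded)
    m <- max(cand)
    if (m <= excl_thr) break
    ij <- which(cand == m, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    if (n_excl[i] >= D - 3 || n_excl[j] >= D - 3) break
    excluded[i, j] <- TRUE
    trow[i] <- trow[i] - Tmat[i, j]
    trow[j] <- trow[j] - Tmat[i, j]
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    M[i, j] <- M[i, j] - 1
    M[j, i] <- M[j, i] - 1
  }
  bad <- omega <= 0
  if (any(bad)) { rho[bad, ] <- 0; rho[, bad] <- 0; diag(rho) <- 1; omega[bad] <- NA_real_ }
  list(rho = rho, omega = omega)
}

#' Edge significance for a SparCC correlation matrix
#'
#' Permutation p-values with bootstrap stability. The null shuffles each
#' taxon's sample vector independently (destroying all inter-taxon
#' dependence while keeping margins) and re-estimates SparCC; each edge's
#' two-sided p is the add-one fraction of null estimates whose magnitude
#' reaches the observed one, pooled over permutations. Bootstrap resampling
#' of samples (with replacement) quantifies estimate stability as a per-edge
#' SD. Benjamini-Hochberg q-values are computed across the upper triangle.
#' Study-scale settings are 1000 permutations and 1000 bootstraps; defaults
#' here are smaller.
#'
#' @param x the counts `feature_table` used for the fit.
#' @param fit a `sparcc_fit`.
#' @param n_perm permutation datasets (warns below 100).
#' @param n_bootstrap bootstrap datasets (0 skips the stability pass).
#' @param seed integer seed.
#' @return the `sparcc_fit` augmented with matrices `p`, `q`, and
#'   `bootstrap_sd` (NULL if skipped).
#' @export
edge_significance <- function(x, fit, n_perm = 200, n_bootstrap = 0, seed = 1) {
  if (n_perm < 100) warnf("n_perm < 100: p-values will be coarse")
  counts <- x$counts
  D <- nrow(counts)
  obs <- abs(fit$rho)
  set.seed(derive_seed(seed, 52L))
  exceed <- matrix(0, D, D)
  for (b in seq_len(n_perm)) {
    perm <- apply(counts, 1, sample)          # samples x taxa, per-taxon shuffle
    pt <- feature_table(t(structure(perm, dimnames = list(sample_ids(x), taxon_ids(x)))))
    r0 <- sparcc(pt, resample = FALSE, exclusion_threshold = 0.1,
                 seed = derive_seed(seed, 520L + b))$rho
    exceed <- exceed + (abs(r0) >= obs - 1e-12)
  }
  p <- (1 + exceed) / (1 + n_perm)
  diag(p) <- NA_real_
  q <- matrix(NA_real_, D, D, dimnames = dimnames(p))
  ut <- upper.tri(q)
  q[ut] <- bh_adjust(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  bsd <- NULL
  if (n_bootstrap > 0) {
    acc <- array(NA_real_, c(D, D, n_bootstrap))
    for (b in seq_len(n_bootstrap)) {
      idx <- sample(ncol(counts), replace = TRUE)
      bt <- counts[, idx, drop = FALSE]
      colnames(bt) <- paste0("b", seq_len(ncol(bt)))
      acc[, , b] <- sparcc(feature_table(bt), resample = FALSE,
                           seed = derive_seed(seed, 530L + b))$rho
    }
    bsd <- apply(acc, c(1, 2), stats::sd)
    dimnames(bsd) <- dimnames(p)
  }
  fit$p <- p
  fit$q <- q
  fit$bootstrap_sd <- bsd
  fit
}
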
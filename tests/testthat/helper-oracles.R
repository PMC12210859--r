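# independent oracles used by module and acceptance tests; each is a direct
# transcription of the defining formula, kept free of package internals

# SparCC basis variances at D = 3 have the closed form
# omega_i = (t_ij + t_ik - t_jk) / 2 on the log-ratio variances t
sparcc_d3_oracle <- function(counts) {
  f <- t((counts + 1) / rep(colSums(counts + 1), each = 3))
  lf <- log(f)
  V <- stats::var(lf); dv <- diag(V)
  Tm <- outer(dv, dv, "+") - 2 * V
  om <- c((Tm[1, 2] + Tm[1, 3] - Tm[2, 3]) / 2,
          (Tm[1, 2] + Tm[2, 3] - Tm[1, 3]) / 2,
          (Tm[1, 3] + Tm[2, 3] - Tm[1, 2]) / 2)
  rho <- (outer(om, om, "+") - Tm) / (2 * sqrt(outer(om, om)))
  diag(rho) <- 1
  pmin(pmax(rho, -1), 1)
}

# Freeman-Halton by brute force for 2 x c tables: enumerate every table with
# the observed margins, sum probabilities <= the observed table's
fisher_oracle_2xc <- function(tab) {
  stopifnot(nrow(tab) == 2)
  cs <- colSums(tab); r1 <- sum(tab[1, ])
  grid <- do.call(expand.grid, lapply(cs, function(n) 0:n))
  grid <- grid[rowSums(grid) == r1, , drop = FALSE]
  probs <- apply(grid, 1, function(y) {
    t2 <- rbind(y, cs - y)
    exp(sum(lgamma(rowSums(t2) + 1)) + sum(lgamma(cs + 1)) -
          lgamma(sum(t2) + 1) - sum(lgamma(t2 + 1)))
  })
  obs <- probs[apply(grid, 1, function(y) all(y == tab[1, ]))]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# AUC by exhaustive case-control pair enumeration
auc_oracle <- function(scores, labels) {
  pairs <- expand.grid(p = scores[as.logical(labels)],
                       n = scores[!as.logical(labels)])
  mean(ifelse(pairs$p > pairs$n, 1, ifelse(pairs$p == pairs$n, 0.5, 0)))
}
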
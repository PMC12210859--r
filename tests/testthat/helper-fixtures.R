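# fixtures are built in code; nothing is read from disk except round-trip
# temp files the tests themselves write

make_ft <- function(m, taxa = NULL, samples = NULL, relative = FALSE) {
  m <- as.matrix(m)
  rownames(m) <- taxa %||% sprintf("t%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  feature_table(m, relative = relative)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small random counts table
random_ft <- function(n_taxa, n_samples, seed = 1, lambda = 20) {
  set.seed(seed)
  make_ft(matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples))
}

toy_taxonomy <- function(ids, kingdom = "bacteria", genus = NULL, oral = NULL) {
  n <- length(ids)
  genus <- genus %||% rep("GenusA", n)
  data.frame(
    taxon_id = ids, kingdom = kingdom,
    lineage = sprintf("k__King;p__Phy;c__Cla;o__Ord;f__Fam;g__%s;s__sp_%s",
                      genus, ids),
    oral = oral %||% rep(FALSE, n),
    stringsAsFactors = FALSE)
}

# compositional counts with a planted latent correlation between taxa 1 and 2
planted_corr_counts <- function(n_samples, n_taxa, r, seed, depth = 30000,
                                sigma = 1.5) {
  set.seed(seed)
  z <- rnorm(n_samples)
  lat <- matrix(rnorm(n_samples * n_taxa), n_samples, n_taxa)
  lat[, 1] <- sqrt(r) * z + sqrt(1 - r) * rnorm(n_samples)
  lat[, 2] <- sqrt(r) * z + sqrt(1 - r) * rnorm(n_samples)
  lam <- exp(2 + sigma * lat)
  cnt <- sapply(seq_len(n_samples), function(s)
    rmultinom(1, depth, lam[s, ] / sum(lam[s, ]))[, 1])
  rownames(cnt) <- sprintf("t%02d", seq_len(n_taxa))
  colnames(cnt) <- sprintf("s%02d", seq_len(n_samples))
  feature_table(cnt)
}

# hand-built co-occurrence network from a 2-column edge matrix
toy_network <- function(edges, rho = NULL) {
  e <- data.frame(from = edges[, 1], to = edges[, 2],
                  rho = rho %||% rep(0.8, nrow(edges)),
                  q = rep(0.01, nrow(edges)),
                  sign = rep("positive", nrow(edges)),
                  backbone = logical(nrow(edges)),
                  stringsAsFactors = FALSE)
  ids <- sort(unique(c(e$from, e$to)))
  deg <- table(factor(c(e$from, e$to), levels = ids))
  structure(list(nodes = data.frame(taxon_id = ids, degree = as.integer(deg),
                                    role = rep(NA_character_, length(ids)),
                                    cluster = rep(NA_integer_, length(ids)),
                                    stringsAsFactors = FALSE),
                 edges = e), class = "cooccurrence_network")
}

# independent-taxa null counts (no inter-taxon dependence beyond closure)
null_counts <- function(n_samples, n_taxa, seed, depth = 20000, sigma = 1) {
  set.seed(seed)
  lam <- exp(matrix(rnorm(n_samples * n_taxa, 0, sigma), n_samples, n_taxa))
  cnt <- sapply(seq_len(n_samples), function(s)
    rmultinom(1, depth, lam[s, ] / sum(lam[s, ]))[, 1])
  rownames(cnt) <- sprintf("t%02d", seq_len(n_taxa))
  colnames(cnt) <- sprintf("s%02d", seq_len(n_samples))
  feature_table(cnt)
}
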
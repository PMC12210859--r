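test_that("SparCC matches the D = 3 closed form in deterministic mode", {
  set.seed(11)
  n <- 40
  lat <- cbind(rnorm(n, 0, 1.0), rnorm(n, 1, 0.6), rnorm(n, 2, 1.4))
  lam <- exp(lat)
  cnt <- sapply(1:n, function(s) rmultinom(1, 50000, lam[s, ] / sum(lam[s, ]))[, 1])
  rownames(cnt) <- paste0("t", 1:3); colnames(cnt) <- paste0("s", 1:n)
  fit <- sparcc(feature_table(cnt), resample = FALSE, exclusion_threshold = 1)
  expect_equal(fit$rho, sparcc_d3_oracle(cnt), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("SparCC stays quiet on independent data and recovers a planted pair", {
  # null: independent lognormal latents -> modest spurious correlations only
  spurious <- vapply(1:6, function(r) {
    ft <- null_counts(100, 25, seed = 300 + r, depth = 20000)
    fit <- sparcc(ft, n_iterations = 5, seed = r)
    max(abs(fit$rho[upper.tri(fit$rho)]))
  }, numeric(1))
  expect_gte(mean(spurious < 0.35), 0.8)
  # planted latent correlation 0.8 between two abundant taxa
  ft <- planted_corr_counts(100, 20, r = 0.8, seed = 2)
  fit <- sparcc(ft, n_iterations = 10, seed = 5)
  expect_gt(fit$rho["t01", "t02"], 0.4)
  expect_equal(max(abs(fit$rho["t01", setdiff(colnames(fit$rho), "t01")])),
               abs(fit$rho["t01", "t02"]))
  # determinism
  fit2 <- sparcc(ft, n_iterations = 10, seed = 5)
  expect_identical(fit$rho, fit2$rho)
})

test_that("edge significance: q >= p entrywise, planted edge passes, null edges mostly do not", {
  ft <- planted_corr_counts(150, 8, r = 0.9, seed = 4, sigma = 1.2)
  fit <- sparcc(ft, n_iterations = 5, seed = 1)
  fit <- edge_significance(ft, fit, n_perm = 700, seed = 3)
  ut <- upper.tri(fit$p)
  expect_true(all(fit$q[ut] >= fit$p[ut] - 1e-12))
  expect_lt(fit$q["t01", "t02"], 0.05)
  # bootstrap stability pass runs and returns a finite SD matrix
  fit_b <- edge_significance(ft, sparcc(ft, n_iterations = 3, seed = 1),
                             n_perm = 100, n_bootstrap = 20, seed = 6)
  expect_true(all(is.finite(fit_b$bootstrap_sd[ut])))
})

test_that("network construction applies strict boundary semantics", {
  ids <- c("a", "b", "c")
  rho <- diag(3); dimnames(rho) <- list(ids, ids)
  rho["a", "b"] <- rho["b", "a"] <- 0.41
  rho["a", "c"] <- rho["c", "a"] <- 0.40
  rho["b", "c"] <- rho["c", "b"] <- 0.90
  q <- matrix(0.04, 3, 3, dimnames = dimnames(rho))
  q["b", "c"] <- q["c", "b"] <- 0.2
  fit <- structure(list(rho = rho, q = q), class = "sparcc_fit")
  net <- build_network(fit, r_min = 0.4, q_max = 0.05)
  # 0.41/q=0.04 kept; 0.40 exactly dropped (strict >); 0.90/q=0.2 dropped
  expect_equal(nrow(net$edges), 1)
  expect_setequal(c(net$edges$from, net$edges$to), c("a", "b"))
  # empty result warns, does not error
  expect_warning(empty <- build_network(fit, r_min = 0.99), "empty")
  expect_equal(nrow(empty$edges), 0)
})

test_that("edge counts are monotone in the thresholds", {
  ft <- planted_corr_counts(50, 10, r = 0.7, seed = 9)
  fit <- edge_significance(ft, sparcc(ft, n_iterations = 5, seed = 2),
                           n_perm = 120, seed = 2)
  n_edges <- function(r_min, q_max) suppressWarnings(
    nrow(build_network(fit, r_min, q_max)$edges))
  expect_true(n_edges(0.2, 0.05) >= n_edges(0.4, 0.05))
  expect_true(n_edges(0.4, 0.05) >= n_edges(0.6, 0.05))
  expect_true(n_edges(0.3, 0.10) >= n_edges(0.3, 0.02))
})

test_that("MCODE-style cores: a 5-clique with pendants yields one core and peripherals", {
  clique <- t(combn(paste0("c", 1:5), 2))
  pendants <- cbind(paste0("c", 1:3), paste0("p", 1:3))
  net <- mcode_cores(toy_network(rbind(clique, pendants)))
  cl <- attr(net, "clusters")
  expect_equal(length(cl), 1)
  expect_setequal(cl[[1]], paste0("c", 1:5))
  roles <- setNames(net$nodes$role, net$nodes$taxon_id)
  expect_true(all(roles[paste0("c", 1:5)] == "core"))
  expect_true(all(roles[paste0("p", 1:3)] == "peripheral"))
  # peripheral nodes touch a core node and never each other
  per <- net$nodes$taxon_id[net$nodes$role %in% "peripheral"]
  pp <- net$edges$from %in% per & net$edges$to %in% per
  expect_false(any(pp))
})

test_that("MCODE-style cores: two disjoint cliques give two clusters, deterministic order", {
  g1 <- t(combn(paste0("a", 1:4), 2))
  g2 <- t(combn(paste0("b", 1:5), 2))
  net <- mcode_cores(toy_network(rbind(g1, g2)))
  cl <- attr(net, "clusters")
  expect_equal(length(cl), 2)
  expect_setequal(cl[[1]], paste0("b", 1:5))   # larger clique scores higher
  expect_setequal(cl[[2]], paste0("a", 1:4))
  # edgeless graph: no cores
  empty <- toy_network(matrix(character(0), 0, 2))
  expect_equal(length(attr(mcode_cores(empty), "clusters")), 0)
})

test_that("backbone is the maximum spanning forest on |rho|", {
  tri <- rbind(c("x", "y"), c("y", "z"), c("x", "z"))
  net <- backbone(toy_network(tri, rho = c(0.9, 0.8, 0.7)))
  expect_equal(net$edges$backbone, c(TRUE, TRUE, FALSE))
  # tree input: every edge flagged
  tree <- rbind(c("a", "b"), c("b", "c"), c("b", "d"))
  nt <- backbone(toy_network(tree, rho = c(0.5, 0.4, 0.3)))
  expect_true(all(nt$edges$backbone))
  # forest identity over components
  two <- rbind(t(combn(paste0("u", 1:4), 2)), t(combn(paste0("v", 1:3), 2)))
  nf <- backbone(toy_network(two, rho = runif(9, 0.4, 1)))
  expect_equal(sum(nf$edges$backbone), 7 - 2)   # n_nodes - n_components
})

test_that("functional group reproduces the three-step hand trace", {
  hc <- toy_network(rbind(c("a", "b"), c("b", "c")))
  esin <- toy_network(rbind(c("a", "b"), c("c", "d")))
  escc <- toy_network(rbind(c("a", "c"), c("c", "d")))  # nodes {a, c, d}
  fg <- functional_group(hc, esin, escc)
  expect_equal(fg$common_edges, data.frame(from = "a", to = "b",
                                           stringsAsFactors = FALSE))
  expect_setequal(fg$candidates, c("a", "b"))
  expect_equal(fg$species, "a")
  # identical networks: every edge-participating species retained
  fg2 <- functional_group(hc, hc, hc)
  expect_setequal(fg2$species, c("a", "b", "c"))
  # disjoint edge sets: empty with warning
  expect_warning(fg3 <- functional_group(hc, toy_network(rbind(c("x", "y"))), escc),
                 "common")
  expect_equal(length(fg3$species), 0)
})

test_that("sign handling in the common-interaction rule is configurable", {
  hc <- toy_network(rbind(c("a", "b")))
  esin <- toy_network(rbind(c("a", "b")))
  esin$edges$sign <- "negative"   # sign flip between stages
  escc <- toy_network(rbind(c("a", "b")))
  expect_setequal(functional_group(hc, esin, escc)$species, c("a", "b"))
  expect_warning(strict <- functional_group(hc, esin, escc, sign_strict = TRUE))
  expect_equal(length(strict$species), 0)
})

test_that("network TSV export round-trips the edge list", {
  net <- backbone(toy_network(rbind(c("a", "b"), c("b", "c")), rho = c(0.5, -0.6)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- utils::read.delim(path)
  expect_equal(back$source, c("a", "b"))
  expect_equal(back$rho, c(0.5, -0.6))
  expect_equal(back$backbone, c(TRUE, TRUE))
})
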
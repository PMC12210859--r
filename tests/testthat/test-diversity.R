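test_that("Hill numbers match closed forms and the q = 1 limit", {
  expect_equal(hill_number(rep(1, 5), c(0, 0.5, 1, 2)), rep(5, 4))
  expect_equal(hill_number(c(0.9, 0.1), 0), 2)
  expect_equal(hill_number(c(0.9, 0.1), 2), 1 / 0.82, tolerance = 1e-9)
  q1 <- hill_number(c(0.9, 0.1), 1)
  expect_equal(q1, exp(-(0.9 * log(0.9) + 0.1 * log(0.1))), tolerance = 1e-9)
  # limit check: general form approaches the entropy form near q = 1
  expect_equal(hill_number(c(0.9, 0.1), 1 + 1e-4), q1, tolerance = 1e-4)
  expect_equal(hill_number(c(0.9, 0.1), 1 - 1e-4), q1, tolerance = 1e-4)
  # zeros excluded, not poisoning the entropy
  expect_equal(hill_number(c(0.9, 0.1, 0), 1), q1)
  expect_error(hill_number(numeric(0), 1), "empty")
  expect_error(hill_number(c(0, 0), 1), "empty|zero")
})

test_that("Hill profile is non-increasing in q on random compositions", {
  set.seed(7)
  for (i in 1:25) {
    p <- rgamma(sample(3:40, 1), shape = 0.5)
    qs <- sort(runif(6, 0, 4))
    vals <- hill_number(p, qs)
    expect_true(all(diff(vals) <= 1e-9))
    expect_true(all(vals >= 1 - 1e-12))
  }
})

test_that("alpha contrasts reproduce exact rank-sum p-values", {
  prof <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    q = 0,
    value = c(1, 2, 3, 10, 11, 12))
  meta <- data.frame(sample_id = prof$sample_id,
                     group = factor(rep(c("A", "B"), each = 3)))
  res <- alpha_contrasts(prof, meta, q = 0)
  # extreme ranking with n = 3, 3: two-sided p = 2 / C(6,3) = 0.1
  expect_equal(res$p, 0.1)
  expect_equal(res$p_adjusted, res$p)   # single pair: BH is the identity
  # identical multisets -> p = 1
  prof$value <- rep(c(5, 6, 7), 2)
  expect_equal(alpha_contrasts(prof, meta, 0)$p, 1)
  # symmetry under swapping the group labels
  meta2 <- meta; meta2$group <- factor(rep(c("B", "A"), each = 3))
  prof$value <- c(1, 5, 3, 2, 8, 4)
  expect_equal(alpha_contrasts(prof, meta, 0)$p, alpha_contrasts(prof, meta2, 0)$p)
})

test_that("Hellinger transform has the closed form and unit column norms", {
  ft <- make_ft(cbind(c(1, 4), c(3, 3)))
  h <- hellinger(ft)
  expect_equal(h$counts[, 1], c(t01 = sqrt(0.2), t02 = sqrt(0.8)), tolerance = 1e-9)
  expect_equal(unname(sqrt(colSums(h$counts^2))), c(1, 1), tolerance = 1e-12)
  ft4 <- make_ft(matrix(2, 4, 1))
  expect_equal(unname(hellinger(ft4)$counts[, 1]), rep(0.5, 4))
})

test_that("Bray-Curtis matches hand formulas and is order-invariant", {
  ft <- make_ft(cbind(c(1, 0), c(0, 1)))
  expect_equal(as.numeric(bray_curtis(ft)), 1)
  ft2 <- make_ft(cbind(c(2, 0), c(1, 1)))
  expect_equal(as.numeric(bray_curtis(ft2)), 0.5)
  ft3 <- make_ft(cbind(c(3, 1), c(3, 1)))
  expect_equal(as.numeric(bray_curtis(ft3)), 0)
  # invariance to taxon order; equivariance to sample order
  ft4 <- random_ft(8, 4, seed = 5)
  d1 <- as.matrix(bray_curtis(ft4))
  shuf <- feature_table(ft4$counts[sample(8), ])
  expect_equal(as.matrix(bray_curtis(shuf)), d1, tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  d2 <- as.matrix(bray_curtis(feature_table(ft4$counts[, perm])))
  expect_equal(d2, d1[perm, perm], tolerance = 1e-12)
})

test_that("PCoA reproduces Euclidean geometry and reports negative eigenvalues", {
  # equilateral triangle: two equal positive eigenvalues, distances recovered
  d <- matrix(1, 3, 3) - diag(3)
  rownames(d) <- colnames(d) <- paste0("s", 1:3)
  res <- pcoa(d, 2)
  expect_equal(res$eigenvalues[1], res$eigenvalues[2], tolerance = 1e-9)
  expect_equal(as.matrix(dist(res$coordinates)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  # points on a line: one dominant positive eigenvalue
  x <- c(0, 1, 2, 5)
  dl <- as.matrix(dist(x))
  rl <- pcoa(dl, 2)
  expect_gt(rl$eigenvalues[1] / sum(abs(rl$eigenvalues)), 0.99)
  # general Euclidean input round-trips
  set.seed(2)
  pts <- matrix(rnorm(20), 5, 4)
  de <- dist(pts)
  re <- pcoa(de, 4)
  expect_equal(as.matrix(dist(re$coordinates)), as.matrix(de), tolerance = 1e-9)
  expect_error(pcoa(de, 10), "k must lie")
})

test_that("PERMANOVA partitions squared distances per the hand-worked case", {
  # two groups of 2: within-pair d = 1 in both, cross pairs d = 1
  d <- matrix(1, 4, 4) - diag(4)
  rownames(d) <- colnames(d) <- paste0("s", 1:4)
  res <- permanova(d, c("A", "A", "B", "B"), n_perm = 99, seed = 1)
  expect_equal(res$F, 1, tolerance = 1e-9)
  expect_equal(res$R2, 1 / 3, tolerance = 1e-9)
  # degenerate all-zero distances
  d0 <- matrix(0, 4, 4, dimnames = dimnames(d))
  expect_warning(r0 <- permanova(d0, c("A", "A", "B", "B"), 49, 1), "zero")
  expect_equal(r0$R2, 0)
})

test_that("permutation p-values are valid, seeded, and reproducible", {
  ft <- random_ft(10, 12, seed = 8)
  d <- bray_curtis(ft)
  lab <- rep(c("A", "B"), each = 6)
  p1 <- permanova(d, lab, 199, seed = 5)
  p2 <- permanova(d, lab, 199, seed = 5)
  expect_identical(p1$p, p2$p)
  expect_gte(p1$p, 1 / 200)
  a1 <- anosim(d, lab, 199, seed = 5)
  a2 <- anosim(d, lab, 199, seed = 5)
  expect_identical(a1$p, a2$p)
  expect_gte(a1$p, 1 / 200)
})

test_that("ANOSIM attains R = 1 under complete separation and is rank-based", {
  # two tight clusters far apart: all within < all between
  set.seed(3)
  pts <- rbind(matrix(rnorm(10, 0, 0.01), 5), matrix(rnorm(10, 10, 0.01), 5))
  d <- dist(pts)
  lab <- rep(c("A", "B"), each = 5)
  expect_equal(anosim(d, lab, 99, 1)$R, 1, tolerance = 1e-12)
  # invariance under a monotone transform of the distances
  r1 <- anosim(d, lab, 99, 1)$R
  r2 <- anosim(sqrt(d), lab, 99, 1)$R
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("pairwise contrasts apply BH across the family of pairs", {
  # BH by hand on (0.001, 0.005, 0.424) -> (0.003, 0.0075, 0.424)
  expect_equal(stats::p.adjust(c(0.001, 0.005, 0.424), "BH"),
               c(0.003, 0.0075, 0.424))
  set.seed(10)
  base <- matrix(rpois(20 * 20, 30), 20, 20)
  base[1:8, 16:20] <- base[1:8, 16:20] + 60   # one shifted group
  rownames(base) <- sprintf("t%02d", 1:20)
  colnames(base) <- sprintf("s%02d", 1:20)
  d <- bray_curtis(hellinger(feature_table(base)))
  lab <- rep(c("G1", "G2", "G3", "G4"), each = 5)
  res <- pairwise_beta(d, lab, "permanova_R2", n_perm = 199, seed = 2)
  expect_equal(nrow(res), 6)   # all unordered pairs of 4 groups
  expect_true(all(res$p_adjusted >= res$p - 1e-12))
  expect_true(all(res$p_adjusted <= 1))
  sel <- pairwise_beta(d, lab, "anosim_R", pairs = rbind(c("G1", "G4")),
                       n_perm = 99, seed = 2)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$p_adjusted, sel$p)
})
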
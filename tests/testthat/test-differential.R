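make_rel <- function(m, ...) to_relative(make_ft(m, ...))

test_that("KW screen: constant taxa fail, two-group case matches the exact rank test", {
  m <- rbind(rep(0.2, 6),
             c(0.4, 0.5, 0.6, 0.1, 0.2, 0.3))
  m <- rbind(m, 1 - colSums(m))  # filler so columns sum to 1
  rel <- feature_table(matrix(m, 3, 6,
                              dimnames = list(c("const", "shift", "fill"),
                                              sprintf("s%d", 1:6))),
                       relative = TRUE)
  lab <- rep(c("A", "B"), each = 3)
  res <- kw_screen(rel, lab, alpha = 0.05)
  expect_equal(res$p[res$taxon_id == "const"], 1)
  expect_false(res$pass[res$taxon_id == "const"])
  # extreme two-group ranking at n = 3,3: exact two-sided p = 0.1 (KW == rank-sum)
  expect_equal(res$p[res$taxon_id == "shift"], 0.1, tolerance = 1e-9)
  expect_false(res$pass[res$taxon_id == "shift"])   # n too small at alpha 0.05
})

test_that("KW screen p-values are uniform under an exchangeable null", {
  set.seed(21)
  ps <- unlist(lapply(1:30, function(r) {
    rel <- to_relative(null_counts(18, 10, seed = 400 + r, depth = 5000))
    kw_screen(rel, rep(c("A", "B", "C"), each = 6))$p
  }))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("LDA effect size separates a strongly shifted taxon and is seed-stable", {
  set.seed(13)
  n <- 24
  lab <- rep(c("CASE", "CTRL"), each = n / 2)
  base <- matrix(rgamma(30 * n, 2, 2), 30, n)
  base[1, lab == "CASE"] <- base[1, lab == "CASE"] * 60  # planted enrichment
  rownames(base) <- sprintf("t%02d", 1:30); colnames(base) <- sprintf("s%02d", 1:n)
  rel <- to_relative(feature_table(base))
  r1 <- lda_effect_size(rel, lab, seed = 5)
  r2 <- lda_effect_size(rel, lab, seed = 5)
  expect_identical(r1$lda_score, r2$lda_score)
  expect_true(r1$passes_threshold[r1$taxon_id == "t01"])
  expect_equal(r1$enriched_group[r1$taxon_id == "t01"], "CASE")
  expect_gte(r1$lda_score[r1$taxon_id == "t01"], 3)
  # different seeds move scores only slightly
  r3 <- lda_effect_size(rel, lab, seed = 6)
  expect_lt(abs(r3$lda_score[r3$taxon_id == "t01"] -
                r1$lda_score[r1$taxon_id == "t01"]), 0.2)
  # a taxon identical across classes scores ~0
  flat <- which(r1$kw_p > 0.9)
  if (length(flat)) expect_true(all(r1$lda_score[flat] < 1))
})

test_that("noiseless two-class means give the closed-form effect magnitude", {
  # class means 1e5 vs 1e2 in scaled (per-million) units
  n <- 12
  lab <- rep(c("A", "B"), each = n / 2)
  v <- c(rep(1e5, n / 2), rep(1e2, n / 2)) + rep(c(0, 1, -1), length.out = n)
  m <- rbind(v, 1e6 - v)
  rownames(m) <- c("hit", "rest"); colnames(m) <- sprintf("s%02d", 1:n)
  rel <- feature_table(m / 1e6, relative = TRUE)
  res <- lda_effect_size(rel, lab, seed = 2)
  sc <- res$lda_score[res$taxon_id == "hit"]
  expect_gte(sc, 3)
  expect_lt(abs(sc - log10(1 + 0.5 * ((1e5 - 1e2) + sqrt(2) * (1e5 - 1e2)))), 0.5)
})

test_that("AUC matches pairwise enumeration and the reflection identity", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))$auc, 1)
  expect_equal(roc_auc(rep(5, 8), rep(c(0, 1), 4))$auc, 0.5)
  set.seed(3)
  for (i in 1:20) {
    s <- rnorm(14); l <- sample(c(TRUE, FALSE), 14, TRUE)
    if (!any(l) || all(l)) next
    # brute-force pair enumeration oracle
    pairs <- expand.grid(p = s[l], n = s[!l])
    oracle <- mean(ifelse(pairs$p > pairs$n, 1, ifelse(pairs$p == pairs$n, 0.5, 0)))
    expect_equal(roc_auc(s, l)$auc, oracle, tolerance = 1e-12)
    expect_equal(roc_auc(s, l)$auc + roc_auc(-s, l)$auc, 1, tolerance = 1e-12)
    # invariance under a strictly increasing transform
    expect_equal(roc_auc(exp(s), l)$auc, roc_auc(s, l)$auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "non-empty")
  # independent library cross-check
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(9)
    s <- rnorm(30); l <- rep(c(TRUE, FALSE), 15)
    expect_equal(roc_auc(s, l)$auc,
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("marker combination dominates and calibrates", {
  # a perfectly separating marker keeps AUC 1 after combination
  set.seed(4)
  lab <- rep(c(TRUE, FALSE), each = 10)
  good <- c(rnorm(10, 5, 0.2), rnorm(10, 0, 0.2))
  noise <- rnorm(20)
  cm <- combine_markers(noise, good, lab)
  expect_equal(cm$auc_b, 1)
  expect_equal(cm$auc_combined, 1)
  expect_true(cm$separation_fallback)
  # sum rule is available
  cs <- combine_markers(noise, good, lab, rule = "sum")
  expect_equal(cs$rule_used, "sum")
  expect_gte(cs$auc_combined, 0.9)
  # two weak markers: combination does not lose more than a whisker
  set.seed(8)
  ok <- 0
  for (r in 1:10) {
    z1 <- c(rnorm(25, 0.8), rnorm(25)); z2 <- c(rnorm(25, 0.8), rnorm(25))
    l <- rep(c(TRUE, FALSE), each = 25)
    res <- combine_markers(z1, z2, l)
    ok <- ok + (res$auc_combined >= max(res$auc_a, res$auc_b) - 0.02)
  }
  expect_gte(ok, 8)
})

test_that("shuffled labels give chance-level cross-validated combined AUC", {
  set.seed(12)
  aucs <- vapply(1:60, function(r) {
    z1 <- rnorm(50); z2 <- rnorm(50)
    l <- sample(rep(c(TRUE, FALSE), each = 25))
    combine_markers(z1, z2, l)$auc_combined_cv
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})

test_that("multi-species marker score is an order-invariant sum conserved by collapse", {
  ids <- sprintf("sp%02d", 1:6)
  rel <- to_relative(make_ft(matrix(rpois(6 * 4, 30) + 1, 6, 4), taxa = ids))
  sel <- c("sp02", "sp05", "sp03")
  s1 <- group_abundance_score(rel, sel)
  s2 <- group_abundance_score(rel, rev(sel))
  expect_equal(s1, s2)
  expect_true(all(s1 <= 1 + 1e-12))
  expect_error(group_abundance_score(rel, c("sp02", "nope")), "absent")
})
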
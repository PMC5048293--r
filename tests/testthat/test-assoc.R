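test_that("spearman_scan reproduces hand examples and skips flat features", {
  s <- setNames(c(1, 2, 3, 4), c("a", "b", "c", "d"))
  feats <- rbind(self = c(1, 2, 3, 4), flat = c(5, 5, 5, 5))
  colnames(feats) <- names(s)
  tab <- spearman_scan(s, feats)
  expect_equal(tab$rho[tab$feature == "self"], 1)
  expect_identical(attr(tab, "skipped"), "flat")
  # hand value: scores (1,2,3), feature (3,1,2) -> rho = -0.5
  st <- exprest:::spearman_test(c(1, 2, 3), c(3, 1, 2))
  expect_equal(st$rho, -0.5)
  expect_error(spearman_scan(s[1:3], feats[, 1:3]), "4 shared samples")
})

test_that("exact permutation Spearman p matches an independent oracle", {
  set.seed(14)
  for (rep in 1:8) {
    n <- sample(5:7, 1)
    x <- rnorm(n)
    y <- if (rep %% 2 == 0) rnorm(n) else x + rnorm(n, sd = 0.5)
    st <- exprest:::spearman_test(x, y)
    expect_equal(st$p, spearman_perm_oracle(x, y), tolerance = 1e-12)
  }
  # with ties (midranks) the oracle still agrees
  x <- c(1, 1, 2, 3, 4)
  y <- c(2, 3, 3, 1, 5)
  expect_equal(exprest:::spearman_test(x, y)$p,
               spearman_perm_oracle(x, y), tolerance = 1e-12)
})

test_that("spearman_scan is invariant to strictly monotone transforms", {
  set.seed(15)
  s <- setNames(rnorm(30), sprintf("s%d", 1:30))
  feats <- matrix(rnorm(5 * 30), 5, 30,
                  dimnames = list(sprintf("f%d", 1:5), names(s)))
  base <- spearman_scan(s, feats)
  warped <- spearman_scan(exp(s / 2), feats^3 + feats)
  expect_equal(base$rho, warped$rho, tolerance = 1e-12)
  expect_equal(base$p, warped$p, tolerance = 1e-12)
})

test_that("bh_adjust equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(16)
  for (rep in 1:100) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("mean_shift_ttest matches the hand example and rejects degenerate groups", {
  res <- mean_shift_ttest(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(res$delta, 3)
  expect_equal(res$t, 3 / sqrt(2 / 3), tolerance = 1e-9)  # = 3.6742
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  expect_equal(res$cohen_d, 3)  # pooled sd = 1
  same <- mean_shift_ttest(c(1, 2, 3, 1, 2, 3), c(0, 0, 0, 1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(mean_shift_ttest(1:5, c(0, 0, 0, 0, 1)), "at least 2")
  expect_error(mean_shift_ttest(c(1, 1, 2, 2), c(0, 0, 1, 1)),
               "zero pooled variance")
})

test_that("anova_tukey reproduces hand sums of squares", {
  res <- anova_tukey(c(1, 2, 3, 4, 5, 6),
                     rep(c("a", "b", "c"), each = 2))
  expect_equal(res$F, 16)  # SSB 16 / 2 over SSW 1.5 / 3
  expect_equal(nrow(res$tukey), 3L)
  flat <- anova_tukey(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(flat$F, 0)
  expect_true(all(flat$tukey$p_adj == 1))
  expect_error(anova_tukey(1:5, c("a", "a", "b", "b", "c")), "singleton")
  expect_error(anova_tukey(1:4, rep("a", 4)), "2 groups")
})

test_that("pearson_assoc matches the Pearson formula", {
  expect_equal(pearson_assoc(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_assoc(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6)
  expect_error(pearson_assoc(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_assoc(1:2, 1:2), "at least 3")
})

test_that("fisher_enrichment equals full enumeration on all small tables", {
  res <- fisher_enrichment(3, 4, 4, 8)
  expect_equal(res$p, 17 / 70, tolerance = 1e-12)
  expect_equal(fisher_enrichment(0, 4, 4, 8)$p, 1)
  expect_error(fisher_enrichment(5, 4, 4, 8), "margins")
  expect_error(fisher_enrichment(1, 6, 6, 8), "universe too small")
  for (N in 4:12) {
    for (K in 1:(N - 1)) {
      for (n in 1:(N - 1)) {
        for (k in max(0, K + n - N):min(K, n)) {
          expect_equal(fisher_enrichment(k, K, n, N)$p,
                       fisher_oracle_greater(k, K, n, N), tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("ks_shift_test detects stochastic ordering of p-values", {
  same <- ks_shift_test(1:50 / 50, 1:50 / 50)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  disjoint <- ks_shift_test(runif(50, 0, 0.5), runif(50, 0.5, 1))
  expect_equal(disjoint$D, 1)
  expect_lt(disjoint$p, 1e-10)
  expect_error(ks_shift_test(numeric(0), 1:3), "non-empty")
})

test_that("hypergeom_geneset_scan is consistent with fisher_enrichment", {
  universe <- sprintf("g%03d", 1:100)
  coll <- gene_set_collection(list(hit = universe[1:10],
                                   decoy = universe[51:70],
                                   tiny = universe[99:100]))
  query <- universe[1:10]
  tab <- hypergeom_geneset_scan(query, coll, universe)
  expect_identical(tab$set[1], "hit")
  for (i in seq_len(nrow(tab))) {
    direct <- fisher_enrichment(tab$overlap[i], tab$set_size[i],
                                tab$query_size[i], tab$universe_size[i])
    expect_equal(tab$p[i], direct$p, tolerance = 1e-12)
  }
  expect_true(all(tab$p_adj >= tab$p - 1e-12))
  expect_error(hypergeom_geneset_scan(c("nope"), coll, universe), "universe")
  expect_error(hypergeom_geneset_scan(query, coll, character()), "empty")
})

test_that("drug_sensitivity_scan computes fold changes and skips thin arms", {
  groups <- setNames(factor(rep(c("low", "high"), each = 2),
                            levels = c("low", "high")),
                     c("c1", "c2", "c3", "c4"))
  ic50 <- rbind(drugA = c(0, 0, -2, -2), drugB = c(1, 1, 1, 1),
                drugC = c(0, NA, NA, 1))
  colnames(ic50) <- names(groups)
  tab <- suppressWarnings(drug_sensitivity_scan(groups, ic50))
  expect_equal(tab$fold_change[tab$drug == "drugA"], exp(-2))
  expect_equal(tab$fold_change[tab$drug == "drugB"], 1)
  expect_equal(tab$p[tab$drug == "drugB"], 1)
  expect_identical(attr(tab, "skipped"), "drugC")
  expect_error(drug_sensitivity_scan(setNames(rep("low", 4), names(groups)),
                                     ic50), "two groups")
})

test_that("ward clustering on 1-Pearson matches the Lance-Williams oracle", {
  two <- make_expr(c(1, 2, 4), c(9, 3, 5), genes = c("g1", "g2"),
                   samples = c("a", "b", "c"))
  expect_identical(ward_corr_cluster_order(two)$order, c("g1", "g2"))
  # duplicated profiles merge first and sit adjacent
  set.seed(20)
  base <- matrix(rnorm(4 * 12), 4, 12)
  dup <- expression_matrix(rbind(base[1, ], base, base[3, ]),
                           gene_ids = c("dupA", "g1", "g2", "g3", "g4", "dupB"),
                           sample_ids = sprintf("s%d", 1:12))
  ord <- ward_corr_cluster_order(dup)$order
  expect_equal(abs(which(ord == "dupA") - which(ord == "g1")), 1)
  expect_equal(abs(which(ord == "dupB") - which(ord == "g3")), 1)
  # merge heights equal the brute-force Ward recurrence on a 6-gene fixture
  set.seed(21)
  expr6 <- expression_matrix(matrix(rnorm(6 * 15), 6, 15),
                             gene_ids = sprintf("g%d", 1:6),
                             sample_ids = sprintf("s%d", 1:15))
  res <- ward_corr_cluster_order(expr6)
  d_mat <- 1 - cor(t(expr6))
  expect_equal(sort(res$heights), ward_heights_oracle(d_mat),
               tolerance = 1e-8)
  flat <- expression_matrix(rbind(rep(1, 5), rnorm(5)),
                            gene_ids = c("flatgene", "ok"),
                            sample_ids = sprintf("s%d", 1:5))
  expect_error(ward_corr_cluster_order(flat), "flatgene")
})
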
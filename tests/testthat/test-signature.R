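test_that("pearson_profile matches hand-computed correlations", {
  expr <- make_expr(c(1, 2, 3, 4), c(2, 4, 6, 8), c(-1, -2, -3, -4),
                    c(2, 1, 4, 3),
                    genes = c("REST", "double", "anti", "shuffled"),
                    samples = sprintf("s%d", 1:4))
  prof <- pearson_profile(expr, "REST")
  expect_equal(unname(prof$r["REST"]), 1)
  expect_equal(unname(prof$r["double"]), 1)
  expect_equal(unname(prof$r["anti"]), -1)
  expect_equal(unname(prof$r["shuffled"]), 0.6)  # hand Pearson on (1..4),(2,1,4,3)
})

test_that("pearson_profile rejects degenerate input and drops flat genes", {
  expr <- make_expr(c(1, 2, 3), c(5, 5, 5), genes = c("REST", "flat"),
                    samples = c("a", "b", "c"))
  prof <- pearson_profile(expr, "REST")
  expect_identical(prof$dropped, "flat")
  expect_false("flat" %in% names(prof$r))
  expect_error(pearson_profile(expr, "MISSING"), "not found")
  flat_seed <- make_expr(c(1, 1, 1), c(1, 2, 3), genes = c("REST", "g"),
                         samples = c("a", "b", "c"))
  expect_error(pearson_profile(flat_seed, "REST"), "zero variance")
  expect_error(pearson_profile(expr[, 1:2], "REST"), "3 samples")
})

test_that("derive_signature applies sign-consistency and cutoff rules", {
  pa <- make_profile(c(seed = 1, A = 0.9, B = 0.5, C = -0.2, D = -0.6), "seed")
  pb <- make_profile(c(seed = 1, A = 0.8, B = -0.4, C = -0.25, D = -0.35), "seed")
  sig <- derive_signature(pa, pb, cutoff = 0.3)
  expect_setequal(rest_type_genes(sig), c("seed", "A"))
  expect_setequal(restless_type_genes(sig), "D")

  # exhaustive filter oracle over random profiles
  set.seed(7)
  for (rep in 1:25) {
    genes <- c("seed", sprintf("g%d", 1:30))
    ra <- setNames(c(1, round(runif(30, -1, 1), 3)), genes)
    rb <- setNames(c(1, round(runif(30, -1, 1), 3)), genes)
    cut <- runif(1, 0.1, 0.6)
    sig <- tryCatch(derive_signature(make_profile(ra, "seed"),
                                     make_profile(rb, "seed"), cutoff = cut),
                    error = function(e) NULL)
    expected <- genes[sign(ra) == sign(rb) & abs(ra) >= cut & abs(rb) >= cut]
    expected <- union(expected, "seed")
    if (is.null(sig)) {
      expect_identical(expected, "seed")
    } else {
      expect_setequal(sig$genes$gene, expected)
      expect_setequal(rest_type_genes(sig),
                      intersect(expected, genes[ra > 0]))
    }
  }
})

test_that("derive_signature degenerate cases behave", {
  pa <- make_profile(c(seed = 1, A = 0.4, B = -0.6), "seed")
  pb <- make_profile(c(seed = 1, A = 0.2, B = -0.1), "seed")
  sig0 <- derive_signature(pa, pb, cutoff = 0)
  expect_setequal(sig0$genes$gene, c("seed", "A", "B"))  # all sign-consistent
  expect_error(derive_signature(pa, make_profile(c(seed = 1, A = -0.9), "seed"),
                                cutoff = 0.95, include_seed = FALSE),
               "empty signature")
  expect_error(derive_signature(pa, make_profile(c(seed = 1), "seed")),
               "no genes beyond the seed")
  expect_error(derive_signature(pa, make_profile(c(seed = 1, A = 1), "other")),
               "different seed genes")
})

test_that("REST score reproduces the worked arithmetic and shift invariance", {
  expr <- make_expr(c(2, 1), c(4, 5), c(1, 2),
                    genes = c("gr1", "gr2", "gl1"),
                    samples = c("s1", "s2"))
  sig <- exprest:::new_exprest(
    genes = data.frame(gene = c("gr1", "gr2", "gl1"),
                       set = c("REST", "REST", "RESTless"),
                       r_cohort_a = c(0.5, 0.5, -0.5),
                       r_cohort_b = c(0.5, 0.5, -0.5)),
    seed_gene = "gr1", cutoff = 0.3, cohorts = c("a", "b"))
  sc <- rest_score(expr, sig, standardize = "none")
  expect_equal(sc$score[1], (2 + 4) / 2 - 1)  # = 2, the worked example
  # additive per-sample shift cancels when both sets are non-empty
  shifted <- expr + matrix(c(10, -3), nrow = 3, ncol = 2, byrow = TRUE)
  expect_equal(rest_score(shifted, sig, standardize = "none")$score, sc$score)
  # positive scaling scales the score (standardize = none)
  expect_equal(rest_score(expr * 3, sig, standardize = "none")$score,
               3 * sc$score)
})

test_that("z-scored REST score is invariant to per-gene affine transforms", {
  set.seed(10)
  expr <- expression_matrix(matrix(rnorm(5 * 20), 5, 20),
                            gene_ids = c("a", "b", "c", "d", "e"),
                            sample_ids = sprintf("s%d", 1:20))
  sig <- exprest:::new_exprest(
    genes = data.frame(gene = c("a", "b", "c", "d"),
                       set = c("REST", "REST", "RESTless", "RESTless"),
                       r_cohort_a = c(.5, .5, -.5, -.5),
                       r_cohort_b = c(.5, .5, -.5, -.5)),
    seed_gene = "a", cutoff = 0.3, cohorts = c("a", "b"))
  base <- rest_score(expr, sig, standardize = "zscore")
  tr <- expr * runif(5, 0.5, 3) + rnorm(5)
  expect_equal(rest_score(tr, sig, standardize = "zscore")$score, base$score,
               tolerance = 1e-12)
  # swapping the two sets negates the score exactly
  swapped <- sig
  swapped$genes$set <- ifelse(sig$genes$set == "REST", "RESTless", "REST")
  expect_equal(rest_score(expr, swapped, standardize = "none")$score,
               -rest_score(expr, sig, standardize = "none")$score)
})

test_that("scoring handles missing signature genes and empty G_L", {
  expr <- make_expr(c(2, 4), c(6, 2), genes = c("gr1", "gr2"),
                    samples = c("s1", "s2"))
  sig <- exprest:::new_exprest(
    genes = data.frame(gene = c("gr1", "gr2", "gl1", "gl2", "gl3",
                                "gl4", "gl5", "gl6"),
                       set = c("REST", "REST", rep("RESTless", 6)),
                       r_cohort_a = 0.5, r_cohort_b = 0.5),
    seed_gene = "gr1", cutoff = 0.3, cohorts = c("a", "b"))
  expect_warning(sc <- rest_score(expr, sig, standardize = "none"),
                 "coverage")
  expect_equal(sc$score, c((2 + 6) / 2, (4 + 2) / 2))  # mean over G_R only
  none <- make_expr(c(1, 2), genes = "unrelated", samples = c("s1", "s2"))
  expect_error(suppressWarnings(rest_score(none, sig)), "no signature gene")
})

test_that("median dichotomization follows the tie-at-median rule", {
  sc <- data.frame(sample = sprintf("s%d", 1:4), score = c(1, 2, 3, 4))
  out <- dichotomize_by_median(sc)
  expect_identical(as.character(out$group), c("low", "low", "high", "high"))
  sc3 <- data.frame(sample = c("a", "b", "c"), score = c(1, 2, 3))
  out3 <- dichotomize_by_median(sc3)
  expect_identical(as.character(out3$group), c("low", "low", "high"))
  expect_error(dichotomize_by_median(data.frame(sample = "a", score = 1)),
               "at least 2")
  expect_error(dichotomize_by_median(data.frame(sample = c("a", "b"),
                                                score = c(2, 2))),
               "degenerate")
  # property: even n with distinct scores splits evenly
  set.seed(8)
  for (rep in 1:100) {
    n <- 2 * sample(2:30, 1)
    s <- sample(seq_len(1000), n)  # distinct
    out <- dichotomize_by_median(data.frame(sample = seq_len(n), score = s))
    expect_equal(sum(out$group == "low"), n / 2)
  }
})

test_that("fitted signature recovers planted genes and scores track z", {
  st <- simulate_study(n_tumors = 400, n_cell_lines = 50, seed = 5)
  fit <- exprest(st$cell_lines$expr, st$tumors$expr)
  truth <- st$tumors$truth
  members <- setdiff(fit$genes$gene, "REST")
  planted <- c(truth$planted_pos, truth$planted_neg)
  expect_gt(mean(planted %in% members), 0.8)
  expect_lt(mean(!(members %in% planted)), 0.15)
  sc <- predict(fit, st$tumors$expr)
  expect_gt(cor(sc$score, truth$z), 0.9)
  # sign semantics: members correlate with the score in their set's direction
  r_with_score <- cor(t(st$tumors$expr[fit$genes$gene, ]), sc$score)[, 1]
  expect_true(all(sign(r_with_score[rest_type_genes(fit)]) == 1))
  expect_true(all(sign(r_with_score[restless_type_genes(fit)]) == -1))
})

test_that("exprest S3 surface works: print, summary, coef, plot, simulate", {
  st <- simulate_study(n_tumors = 80, n_cell_lines = 30, n_null = 40,
                       seed = 9)
  fit <- exprest(st$cell_lines$expr, st$tumors$expr)
  expect_output(print(fit), "Seed-guided")
  expect_output(print(summary(fit)), "Strongest members")
  co <- coef(fit)
  expect_identical(names(co), fit$genes$gene)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
  sims <- simulate(fit, nsim = 2, seed = 4, n_samples = 30, n_null = 20)
  expect_length(sims, 2L)
  expect_setequal(sims[[1]]$truth$planted_pos,
                  setdiff(rest_type_genes(fit), fit$seed_gene))
})
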
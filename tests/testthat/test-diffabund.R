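test_that("cohort test computes directional folds and handles degeneracy", {
  rel <- rbind(matrix(rep(c(3, 1) / 4, each = 3), 3),
               matrix(rep(c(1, 3) / 4, each = 3), 3)) / 1
  rel <- cbind(rel, 0)
  colnames(rel) <- c("up", "down", "absent")
  rownames(rel) <- paste0("s", 1:6)
  g <- rep(c("case", "control"), each = 3)
  res <- cohort_test(rel, g, epsilon = 1e-12)
  expect_equal(res$fold[res$votu_id == "up"], 3, tolerance = 1e-6)
  expect_identical(res$direction[res$votu_id == "up"], "case")
  expect_identical(res$direction[res$votu_id == "down"], "control")
  # all-zero vOTU: p = 1, fold = 1, flagged
  abs_row <- res[res$votu_id == "absent", ]
  expect_equal(abs_row$fold, 1)
  expect_equal(abs_row$p, 1)
  expect_true(abs_row$flagged)
  # identical distributions: fold 1, p 1
  same <- matrix(rep(c(1, 2, 3, 1, 2, 3) / 6, 2), 6, 2,
                 dimnames = list(paste0("s", 1:6), c("a", "b")))
  res2 <- cohort_test(same, g)
  expect_equal(res2$fold, c(1, 1))
  expect_equal(res2$p, c(1, 1), tolerance = 1e-9)
  expect_error(cohort_test(same, rep("case", 6)), "non-empty")
})

test_that("Fisher's method matches the closed-form survival function", {
  expect_equal(combine_pvalues(0.2), 0.2)                      # identity at k=1
  expect_equal(combine_pvalues(c(1, 1)), 1)
  expect_equal(combine_pvalues(c(0.05, 0.05)),
               oracle_fisher_combine(c(0.05, 0.05)), tolerance = 1e-12)
  expect_equal(combine_pvalues(c(0.05, 0.05)), 0.0175, tolerance = 2e-3)
  expect_warning(p0 <- combine_pvalues(c(0, 0.5)), "floored")
  expect_lt(p0, 1e-100)
  expect_error(combine_pvalues(numeric(0)), "empty")
  expect_error(combine_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("signature selection applies inclusive fold/q and strict combined p", {
  mk <- function(fold, dir, q, p) {
    data.frame(votu_id = "v1", mean_case = 1, mean_control = 1,
               fold = fold, direction = dir, p = p, q = q, flagged = FALSE,
               stringsAsFactors = FALSE)
  }
  # all thresholds met
  s <- select_signatures(mk(1.5, "case", 0.1, 1e-4), mk(1.3, "case", 0.05, 1e-4))
  expect_true(s$is_signature)
  expect_identical(s$direction, "case")
  # direction conflict
  s2 <- select_signatures(mk(1.5, "case", 0.1, 1e-4),
                          mk(1.5, "control", 0.1, 1e-4))
  expect_false(s2$is_signature)
  expect_identical(s2$direction, "none")
  # boundary: fold = 1.2 and q = 0.2 inclusive, combined p strict
  p_each <- 0.012                       # combined p ~ 0.00125 > 0.001
  s3 <- select_signatures(mk(1.2, "case", 0.2, p_each),
                          mk(1.2, "case", 0.2, p_each))
  expect_false(s3$is_signature)
  combined <- combine_pvalues(c(p_each, p_each))
  s4 <- select_signatures(mk(1.2, "case", 0.2, p_each),
                          mk(1.2, "case", 0.2, p_each),
                          max_combined_p = combined)
  expect_false(s4$is_signature)         # equality fails the strict rule
  s5 <- select_signatures(mk(1.2, "case", 0.2, p_each),
                          mk(1.2, "case", 0.2, p_each),
                          max_combined_p = combined + 1e-12)
  expect_true(s5$is_signature)
})

test_that("BH q-values are monotone in p and bounded below by p", {
  set.seed(51)
  n <- 60
  rel <- matrix(rexp(20 * n), 20, n,
                dimnames = list(paste0("s", 1:20), paste0("v", 1:n)))
  rel <- rel / rowSums(rel)
  res <- cohort_test(rel, rep(c("case", "control"), each = 10))
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("covariate adjustment isolates the group association", {
  set.seed(52)
  n <- 80
  covs <- data.frame(sex = sample(c("F", "M"), n, TRUE),
                     age = rnorm(n, 55, 8), BMI = rnorm(n, 24, 3))
  g <- rep(c("case", "control"), each = n / 2)
  # abundance driven only by age, labels random: group p ~ uniform
  rel_age <- matrix(rep(covs$age, 5), n, 5) + matrix(rnorm(n * 5), n, 5)
  colnames(rel_age) <- paste0("v", 1:5)
  adj <- adjust_covariates(rel_age, sample(g), covs)
  expect_true(all(adj$adj_p > 1e-4))
  # true group effect survives adjustment
  rel_g <- matrix(rnorm(n * 3), n, 3) + (g == "case") * 2
  colnames(rel_g) <- paste0("w", 1:3)
  adj2 <- adjust_covariates(rel_g, g, covs)
  expect_true(all(adj2$adj_p < 0.05))
  # zero-variance vOTU flagged with p = 1
  rel_c <- matrix(1, n, 1, dimnames = list(NULL, "const"))
  adj3 <- adjust_covariates(rel_c, g, covs)
  expect_equal(adj3$adj_p, 1)
  expect_true(adj3$flagged)
})

test_that("adjusted p-values track unadjusted ranking under null covariates", {
  set.seed(53)
  n <- 60; m <- 40
  g <- rep(c("case", "control"), each = n / 2)
  covs <- data.frame(sex = sample(c("F", "M"), n, TRUE),
                     age = rnorm(n), BMI = rnorm(n))
  rel <- matrix(rexp(n * m), n, m, dimnames = list(NULL, paste0("v", 1:m)))
  rel[, 1:10] <- rel[, 1:10] + (g == "case") * seq(0.2, 2, length.out = 10)
  rel <- rel / rowSums(rel)
  res <- cohort_test(rel, g)
  adj <- adjust_covariates(rel, g, covs)
  expect_gt(cor(rank(res$p), rank(adj$adj_p), method = "spearman"), 0.9)
})
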
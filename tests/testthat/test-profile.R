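test_that("mapping rates divide by clean totals and sum within families", {
  counts <- matrix(c(10L, 20L, 0L, 30L), 2, 2,
                   dimnames = list(c("s1", "s2"), c("v1", "v2")))
  totals <- c(s1 = 100, s2 = 100)
  mr <- mapping_rates(counts, totals, family_map = c(v1 = "F", v2 = "F"))
  expect_equal(mr$votu_rates["s1", "v1"], 0.10)
  expect_equal(unname(mr$family_rates[, "F"]), c(0.10, 0.50))
  expect_equal(unname(mr$overall), c(0.10, 0.50))
  zero <- mapping_rates(counts * 0L, totals)
  expect_true(all(zero$votu_rates == 0))
})

test_that("rarefaction subsamples without replacement to exact depth", {
  m <- matrix(c(5L, 0L, 3L), 1, 3, dimnames = list("s1", c("a", "b", "c")))
  r <- rarefy_counts(m, 4L, seed = 1)
  expect_identical(sum(r), 4L)
  expect_identical(r[1, "b"], 0L)
  expect_true(all(r <= m))
  # target equal to the sample total: unchanged
  expect_identical(rarefy_counts(m, 8L, seed = 1), m)
  # deterministic given seed
  big <- matrix(rpois(200, 50L), 4, 50,
                dimnames = list(paste0("s", 1:4), paste0("v", 1:50)))
  storage.mode(big) <- "integer"
  expect_identical(rarefy_counts(big, 1000L, seed = 9),
                   rarefy_counts(big, 1000L, seed = 9))
  # shallow samples are dropped with a warning
  shallow <- rbind(big, s5 = rep(1L, 50))
  expect_warning(out <- rarefy_counts(shallow, 1000L, seed = 9), "dropped")
  expect_false("s5" %in% rownames(out))
  expect_error(rarefy_counts(big, 0L), "configuration error")
})

test_that("relative abundance and family rollup preserve row sums", {
  r <- matrix(c(400L, 600L), 1, 2, dimnames = list("s1", c("v1", "v2")))
  rel <- relative_abundance(r, 1000L)
  expect_equal(unname(rel[1, ]), c(0.4, 0.6))
  fam <- family_rollup(rel, c(v1 = "F", v2 = "F"))
  expect_equal(unname(fam[1, 1]), 1.0)
  # rollup-then-sum equals sum-then-rollup
  rel2 <- matrix(runif(12), 3, 4,
                 dimnames = list(paste0("s", 1:3), paste0("v", 1:4)))
  map <- c(v1 = "A", v2 = "A", v3 = "B", v4 = "B")
  expect_equal(rowSums(family_rollup(rel2, map)), rowSums(rel2))
})

test_that("alpha diversity matches the closed forms", {
  uni <- matrix(rep(0.1, 10), 1, dimnames = list("s", paste0("v", 1:10)))
  a <- alpha_diversity(uni)
  expect_equal(a$shannon, log(10))
  expect_equal(a$simpson, 0.9)
  expect_identical(a$observed, 10)
  single <- matrix(c(1, 0), 1, dimnames = list("s", c("v1", "v2")))
  s <- alpha_diversity(single)
  expect_identical(unname(unlist(s)), c(1, 0, 0))
  half <- matrix(c(0.5, 0.5), 1, dimnames = list("s", c("v1", "v2")))
  expect_equal(alpha_diversity(half)$shannon, log(2))
})

test_that("Bray-Curtis distances follow the definition", {
  rel <- rbind(a = c(0.5, 0.5), b = c(1, 0), c = c(0.5, 0.5),
               d = c(0, 1))
  bc <- bray_curtis(rel)
  expect_equal(bc["a", "c"], 0)          # identical rows
  expect_equal(bc["b", "d"], 1)          # disjoint supports
  expect_equal(bc["a", "b"], 0.5)        # |0.5-1| + |0.5-0| over 2
  expect_true(isSymmetric(bc))
})

test_that("PCoA reproduces Euclidean configurations and normalises variance", {
  # 1-D points at 0, 3, 7: PC1 carries all variance
  x <- c(0, 3, 7)
  d <- as.matrix(dist(x))
  ord <- pcoa_ord(d)
  expect_equal(ord$variance_fraction[1], 1)
  got <- as.matrix(dist(ord$coordinates[, 1]))
  expect_equal(got, d, tolerance = 1e-8, ignore_attr = TRUE)
  # a Euclidean 2-D configuration is reproduced up to rotation
  set.seed(41)
  pts <- matrix(rnorm(20), 10, 2)
  d2 <- as.matrix(dist(pts))
  ord2 <- pcoa_ord(d2)
  expect_equal(as.matrix(dist(ord2$coordinates)), d2,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(ord2$variance_fraction), 1)
  # identical points: all-zero coordinates
  d0 <- matrix(0, 4, 4)
  expect_true(all(pcoa_ord(d0)$coordinates == 0))
})

test_that("PERMANOVA partitions variance and is relabelling invariant", {
  set.seed(42)
  rel <- matrix(rexp(30 * 12), 30, 12,
                dimnames = list(sprintf("s%02d", 1:30), paste0("v", 1:12)))
  rel <- rel / rowSums(rel)
  meta <- data.frame(group = rep(c("case", "control"), 15),
                     age = rnorm(30, 50, 8),
                     row.names = rownames(rel))
  d <- bray_curtis(rel)
  fit <- permanova(d, meta, c("age", "group"), n_perm = 99, seed = 1)
  expect_equal(sum(fit$R2[fit$term != "Total"]), 1)
  # permuting rows and labels together leaves R2 unchanged
  perm <- sample(30)
  fit_p <- permanova(d[perm, perm], meta[perm, , drop = FALSE],
                     c("age", "group"), n_perm = 99, seed = 1)
  expect_equal(sort(fit$R2), sort(fit_p$R2), tolerance = 1e-10)
  # single-level factor is degenerate
  meta$one <- "x"
  expect_error(permanova(d, meta, "one"), "degenerate")
})

test_that("complete group separation attains the minimal permutation p", {
  n <- 12
  d <- matrix(1, n, n); diag(d) <- 0
  d[1:6, 1:6] <- 0; d[7:12, 7:12] <- 0
  rownames(d) <- colnames(d) <- paste0("s", 1:n)
  meta <- data.frame(group = rep(c("a", "b"), each = 6),
                     row.names = rownames(d))
  fit <- permanova(d, meta, "group", n_perm = 199, seed = 2)
  p <- fit$p[fit$term == "group"]
  # minimum attainable given permutations that recreate the split
  expect_lte(p, 3 / 200)
})

test_that("alpha-diversity group comparison behaves under symmetry", {
  set.seed(43)
  alpha <- data.frame(observed = c(rnorm(10, 50), rnorm(10, 50)),
                      shannon = rnorm(20, 2))
  g <- rep(c("case", "control"), each = 10)
  p1 <- compare_alpha(alpha, g)
  p2 <- compare_alpha(alpha, rev(g))
  expect_equal(p1, p2)
  same <- data.frame(x = rep(1:10, 2))
  expect_equal(unname(compare_alpha(same, g)["x"]), 1)
})
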
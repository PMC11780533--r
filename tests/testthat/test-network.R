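test_that("SparCC estimates are symmetric with unit diagonal and bounded", {
  counts <- synth_sparcc_counts(60, 8, 20000, seed = 61)
  r <- sparcc(counts)
  expect_true(isSymmetric(unname(r)))
  expect_equal(unname(diag(r)), rep(1, 8))
  expect_true(all(r >= -1 & r <= 1))
  expect_error(sparcc(counts[, 1:3]), "4 features")
  expect_error(sparcc(counts[1:5, ]), "10 samples")
})

test_that("constant features are excluded with a warning", {
  counts <- synth_sparcc_counts(40, 6, 10000, seed = 62)
  counts[, 6] <- 7L
  expect_warning(r <- sparcc(counts), "constant")
  expect_identical(ncol(r), 5L)
})

test_that("SparCC recovers a planted correlation and stays near zero under independence", {
  counts <- synth_sparcc_counts(200, 30, 50000,
                                planted = data.frame(i = 1L, j = 2L,
                                                     rho = 0.8),
                                seed = 63)
  r <- sparcc(counts)
  expect_equal(r[1, 2], 0.8, tolerance = 0.15)
  null_counts <- synth_sparcc_counts(200, 30, 50000, seed = 64)
  rn <- sparcc(null_counts)
  expect_lt(median(abs(rn[upper.tri(rn)])), 0.1)
})

test_that("bootstrap p-values respect the add-one lower bound", {
  counts <- synth_sparcc_counts(50, 6, 20000,
                                planted = data.frame(i = 1L, j = 2L,
                                                     rho = 0.9),
                                seed = 65)
  r <- sparcc(counts)
  pq <- sparcc_pvalues(counts, r, n_boot = 39, seed = 1)
  expect_true(all(pq$p[upper.tri(pq$p)] >= 1 / 40))
  expect_lte(pq$p[1, 2], 3 / 40)         # planted pair near the minimum
  expect_true(isSymmetric(unname(pq$q)))
})

test_that("co-occurrence matches the hypergeometric enumeration oracle", {
  mk <- function(v, s) {
    list(v = matrix(as.integer(v), ncol = 1,
                    dimnames = list(NULL, "v1")),
         s = matrix(as.integer(s), ncol = 1,
                    dimnames = list(NULL, "sp1")))
  }
  # perfect independence: [[5,5],[5,5]]
  x <- mk(rep(c(1, 0), each = 10), rep(c(1, 0, 1, 0), each = 5))
  expect_equal(cooccurrence(x$v, x$s)$p, 1)
  # perfect association: [[10,0],[0,10]] -> 2 / C(20,10)
  y <- mk(rep(c(1, 0), each = 10), rep(c(1, 0), each = 10))
  expect_equal(cooccurrence(y$v, y$s)$p, 2 / choose(20, 10),
               tolerance = 1e-12)
  # zero margin: species never present
  z <- mk(rep(c(1, 0), each = 10), rep(0, 20))
  expect_equal(cooccurrence(z$v, z$s)$p, 1)
  # random tables agree with the enumeration oracle
  set.seed(66)
  for (i in 1:25) {
    n <- sample(8:30, 1)
    v <- rbinom(n, 1, runif(1, 0.2, 0.8))
    s <- rbinom(n, 1, runif(1, 0.2, 0.8))
    got <- cooccurrence(mk(v, s)$v, mk(v, s)$s)$p
    a <- sum(v == 1 & s == 1); b <- sum(v == 1 & s == 0)
    c_ <- sum(v == 0 & s == 1); d <- sum(v == 0 & s == 0)
    expect_equal(got, oracle_fisher_exact(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("dependency classification partitions signatures by evidence", {
  sigs <- c("v1", "v2", "v3", "v4")
  hl <- data.frame(votu_id = "v1", species_id = "s1",
                   stringsAsFactors = FALSE)
  r <- matrix(c(0.3, 0.65, 0.1, 0.5), 4, 1,
              dimnames = list(sigs, "s2"))
  q <- matrix(c(1e-4, 1e-4, 0.5, 1e-4), 4, 1,
              dimnames = list(sigs, "s2"))
  co <- data.frame(votu_id = "v4", species_id = "s3", odds_ratio = 20,
                   p = 1e-6, q = 1e-5, stringsAsFactors = FALSE)
  dep <- classify_dependency(sigs, host_links = hl, sparcc_r = r,
                             sparcc_q = q, cooccur = co,
                             cooccur_q_max = 1e-3)
  lab <- setNames(dep$labels$label, dep$labels$votu_id)
  # v1 host only; v2 co-abundant (0.65 > 0.60, q < 1e-3); v3 nothing;
  # v4 co-occurrent only (its r 0.5 misses the 0.60 threshold)
  expect_identical(unname(lab[c("v1", "v2", "v3", "v4")]),
                   c("dependent", "dependent", "independent", "dependent"))
  expect_setequal(dep$edges$evidence[dep$edges$votu_id == "v1"], "host")
  expect_setequal(dep$edges$evidence[dep$edges$votu_id == "v2"],
                  "co-abundance")
  expect_setequal(dep$edges$evidence[dep$edges$votu_id == "v4"],
                  "co-occurrence")
  expect_identical(nrow(dep$labels), length(sigs))
  # no evidence at all: everything independent
  dep0 <- classify_dependency(sigs)
  expect_true(all(dep0$labels$label == "independent"))
})

test_that("signed (not absolute) SparCC correlations provide co-abundance evidence", {
  sigs <- "v1"
  r <- matrix(-0.9, 1, 1, dimnames = list("v1", "s1"))
  q <- matrix(1e-6, 1, 1, dimnames = list("v1", "s1"))
  dep <- classify_dependency(sigs, sparcc_r = r, sparcc_q = q)
  expect_identical(dep$labels$label, "independent")
})

test_that("AMG occurrence rates are compared with Fisher's exact test", {
  amg_sets <- c(
    setNames(lapply(1:100, function(i) if (i <= 50) "K01916" else character()),
             paste0("e", 1:100)),
    setNames(lapply(1:100, function(i) if (i <= 10) "K01916" else character()),
             paste0("d", 1:100)))
  res <- amg_occurrence_compare(amg_sets, paste0("e", 1:100), paste0("d", 1:100))
  expect_equal(res$rate_enriched, 0.5)
  expect_equal(res$rate_depleted, 0.1)
  expect_equal(res$p, oracle_fisher_exact(50, 50, 10, 90), tolerance = 1e-9)
  expect_lt(res$p, 1e-8)
  # enzyme absent from both groups (panel forcing): rates 0, p = 1
  res2 <- amg_occurrence_compare(amg_sets, paste0("e", 1:100),
                                 paste0("d", 1:100), panel = c("K01916",
                                                               "K99999"))
  row9 <- res2[res2$ko == "K99999", ]
  expect_equal(row9$rate_enriched, 0)
  expect_equal(row9$p, 1)
  # identical carriage: p = 1
  res3 <- amg_occurrence_compare(amg_sets, paste0("e", 1:10), paste0("e", 1:10))
  expect_equal(res3$p, 1)
})

test_that("v4 at r 0.5 is not co-abundant at the default 0.60 threshold", {
  r <- matrix(0.5, 1, 1, dimnames = list("v1", "s1"))
  q <- matrix(1e-9, 1, 1, dimnames = list("v1", "s1"))
  dep <- classify_dependency("v1", sparcc_r = r, sparcc_q = q)
  expect_identical(dep$labels$label, "independent")
})
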
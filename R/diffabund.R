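#' Per-cohort differential-abundance test
#'
#' For each vOTU, compares relative abundances between cases and
#' controls with a two-sided Wilcoxon rank-sum test (normal
#' approximation with tie correction) and computes a fold change from
#' the group means, \code{(mean_case + eps) / (mean_control + eps)},
#' with a pseudo-abundance \code{eps} preventing infinite folds for
#' absent taxa (default: half the smallest nonzero relative abundance in
#' the cohort). Benjamini-Hochberg q-values are computed over all vOTUs
#' of the cohort. vOTUs absent from every sample get p = 1, fold = 1 and
#' are flagged.
#'
#' @param rel samples x vOTUs relative-abundance matrix.
#' @param group character/factor aligned with rows; must contain the
#'   levels "case" and "control".
#' @param epsilon pseudo-abundance; default NULL = half the minimum
#'   nonzero value of \code{rel}.
#' @return data.frame with one row per vOTU: \code{votu_id},
#'   \code{mean_case}, \code{mean_control}, \code{fold} (always >= 1),
#'   \code{direction} ("case", "control" or "none"), \code{p}, \code{q},
#'   \code{flagged}.
#' @export
cohort_test <- function(rel, group, epsilon = NULL) {
  group <- as.character(group)
  if (!all(c("case", "control") %in% group))
    stop("both groups must be non-empty", call. = FALSE)
  is_case <- group == "case"
  if (is.null(epsilon)) {
    nz <- rel[rel > 0]
    epsilon <- if (length(nz)) min(nz) / 2 else .Machine$double.eps
  }
  mean_case <- colMeans(rel[is_case, , drop = FALSE])
  mean_control <- colMeans(rel[!is_case, , drop = FALSE])
  fold_dir <- (mean_case + epsilon) / (mean_control + epsilon)
  fold <- pmax(fold_dir, 1 / fold_dir)
  direction <- ifelse(fold_dir > 1, "case",
                      ifelse(fold_dir < 1, "control", "none"))
  all_zero <- mean_case == 0 & mean_control == 0
  p <- vapply(seq_len(ncol(rel)), function(j) {
    if (all_zero[j]) return(1)
    stats::wilcox.test(rel[is_case, j], rel[!is_case, j],
                       exact = FALSE, correct = TRUE)$p.value
  }, numeric(1))
  p[is.na(p)] <- 1  # zero-variance columns
  fold[all_zero] <- 1
  direction[all_zero] <- "none"
  data.frame(votu_id = colnames(rel), mean_case = mean_case,
             mean_control = mean_control, fold = unname(fold),
             direction = direction, p = p,
             q = stats::p.adjust(p, method = "BH"),
             flagged = unname(all_zero), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Combine independent p-values with Fisher's method
#'
#' \code{X = -2 sum(ln p_i)} follows a chi-squared distribution with
#' \code{2k} degrees of freedom under the joint null; the combined
#' p-value is its upper tail. p-values of exactly zero are floored at
#' the smallest positive double, with a warning.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return combined p-value.
#' @export
combine_pvalues <- function(p) {
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  if (any(p == 0)) {
    warning("p-value(s) of exactly 0 floored at the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Select disease-associated vOTU signatures across two cohorts
#'
#' A vOTU is a signature when, in both cohorts, its fold change is at
#' least \code{min_fold} and its q-value at most \code{max_q} with the
#' same enrichment direction, and the Fisher-combined p-value of the two
#' cohort tests is strictly below \code{max_combined_p}. Fold and q
#' thresholds are inclusive; the combined-p threshold is exclusive.
#'
#' @param res1,res2 cohort results from [cohort_test()] (same vOTU set).
#' @param min_fold per-cohort fold-change threshold (default 1.2).
#' @param max_q per-cohort FDR threshold (default 0.2).
#' @param max_combined_p combined-p threshold (default 0.001).
#' @return data.frame with per-vOTU cohort folds and q-values,
#'   \code{combined_p}, \code{direction} ("case", "control" or "none")
#'   and \code{is_signature}.
#' @export
select_signatures <- function(res1, res2, min_fold = 1.2, max_q = 0.2,
                              max_combined_p = 0.001) {
  stopifnot(identical(res1$votu_id, res2$votu_id))
  combined_p <- vapply(seq_len(nrow(res1)), function(i)
    combine_pvalues(c(res1$p[i], res2$p[i])), numeric(1))
  pass1 <- res1$fold >= min_fold & res1$q <= max_q
  pass2 <- res2$fold >= min_fold & res2$q <= max_q
  same_dir <- res1$direction == res2$direction & res1$direction != "none"
  is_sig <- pass1 & pass2 & same_dir & combined_p < max_combined_p
  data.frame(votu_id = res1$votu_id,
             fold_c1 = res1$fold, q_c1 = res1$q,
             fold_c2 = res2$fold, q_c2 = res2$q,
             combined_p = combined_p,
             direction = ifelse(is_sig | same_dir, res1$direction, "none"),
             is_signature = is_sig, stringsAsFactors = FALSE)
}

#' Covariate-adjusted association check
#'
#' Rank-transforms each vOTU's relative abundance and fits the linear
#' model \code{rank ~ sex + age + BMI + group}; the reported adjusted
#' p-value is that of the group term, i.e. the case/control association
#' remaining after sex, age and BMI are controlled for. Collinear
#' covariates are dropped by the least-squares fit and flagged;
#' zero-variance vOTUs get p = 1.
#'
#' @param rel samples x vOTUs relative-abundance matrix.
#' @param group character/factor with levels "case"/"control".
#' @param covariates data.frame with columns \code{sex}, \code{age},
#'   \code{BMI} aligned with rows of \code{rel}.
#' @return data.frame with \code{votu_id}, \code{adj_p}, \code{flagged}.
#' @export
adjust_covariates <- function(rel, group, covariates) {
  assert_cols(covariates, c("sex", "age", "BMI"), "covariates")
  if (nrow(covariates) != nrow(rel))
    stop("covariates do not match samples", call. = FALSE)
  grp <- as.integer(as.character(group) == "case")
  X <- data.frame(sex = as.factor(covariates$sex),
                  age = as.numeric(covariates$age),
                  BMI = as.numeric(covariates$BMI), group = grp)
  out <- lapply(seq_len(ncol(rel)), function(j) {
    y <- rank(rel[, j])
    if (stats::var(y) == 0)
      return(data.frame(votu_id = colnames(rel)[j], adj_p = 1, flagged = TRUE,
                        stringsAsFactors = FALSE))
    fit <- stats::lm(y ~ sex + age + BMI + group, data = X)
    coefs <- summary(fit)$coefficients
    dropped <- any(is.na(stats::coef(fit)))
    if (!"group" %in% rownames(coefs))
      return(data.frame(votu_id = colnames(rel)[j], adj_p = 1, flagged = TRUE,
                        stringsAsFactors = FALSE))
    data.frame(votu_id = colnames(rel)[j], adj_p = coefs["group", 4],
               flagged = dropped, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
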
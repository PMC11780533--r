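#' Consistency rate of a signature set in an external cohort
#'
#' For each signature vOTU the external trend is the sign of
#' (mean abundance in cases - mean abundance in controls); the vOTU is
#' consistent when that trend matches the signature's enrichment
#' direction from the discovery cohorts. vOTUs with exactly zero mean
#' difference are excluded from numerator and denominator; the number of
#' evaluable vOTUs is reported.
#'
#' @param rel samples x vOTUs relative-abundance matrix of the external
#'   cohort (must contain all signature vOTUs as columns).
#' @param group character/factor with levels "case"/"control".
#' @param directions named character vector, signature vOTU id ->
#'   "case" or "control" (the discovery direction).
#' @return list with \code{rate}, \code{n_evaluable},
#'   \code{n_consistent}.
#' @export
consistency_rate <- function(rel, group, directions) {
  sig <- names(directions)
  miss <- setdiff(sig, colnames(rel))
  if (length(miss))
    stop("signature vOTU(s) absent from external profile: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  is_case <- as.character(group) == "case"
  if (!any(is_case) || all(is_case))
    stop("both groups must be non-empty", call. = FALSE)
  diff <- colMeans(rel[is_case, sig, drop = FALSE]) -
    colMeans(rel[!is_case, sig, drop = FALSE])
  evaluable <- diff != 0
  if (!any(evaluable))
    stop("undefined consistency rate: no evaluable vOTU", call. = FALSE)
  trend <- ifelse(diff > 0, "case", "control")
  consistent <- trend[evaluable] == directions[sig][evaluable]
  list(rate = mean(consistent), n_evaluable = sum(evaluable),
       n_consistent = sum(consistent))
}

#' Permutation test of the consistency rate
#'
#' Case/control labels of the external cohort are permuted
#' \code{n_perm} times and the consistency rate recomputed;
#' \code{p = (1 + #rate* >= rate_obs) / (1 + n_perm)} (one-sided: high
#' consistency is the alternative).
#'
#' @inheritParams consistency_rate
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed.
#' @return list with \code{rate}, \code{n_evaluable},
#'   \code{permutation_p}, \code{n_perm}.
#' @export
consistency_permutation_test <- function(rel, group, directions,
                                         n_perm = 1000L, seed = 1L) {
  obs <- consistency_rate(rel, group, directions)
  set.seed(as.integer(seed))
  group <- as.character(group)
  sig <- names(directions)
  sub <- rel[, sig, drop = FALSE]
  dirs <- directions[sig]
  hits <- 0L
  for (b in seq_len(n_perm)) {
    g <- sample(group)
    is_case <- g == "case"
    diff <- colMeans(sub[is_case, , drop = FALSE]) -
      colMeans(sub[!is_case, , drop = FALSE])
    evaluable <- diff != 0
    if (!any(evaluable)) next
    trend <- ifelse(diff > 0, "case", "control")
    rate_b <- mean(trend[evaluable] == dirs[evaluable])
    if (rate_b >= obs$rate) hits <- hits + 1L
  }
  list(rate = obs$rate, n_evaluable = obs$n_evaluable,
       permutation_p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}

#' Detection rate of signature vOTUs in an external cohort
#'
#' A signature is detected when it is present (count > 0) in strictly
#' more than \code{min_prevalence} of the cohort's individuals.
#'
#' @param counts samples x vOTUs count matrix of the external cohort.
#' @param signatures vOTU ids to evaluate.
#' @param min_prevalence prevalence threshold (default 0.20).
#' @return fraction of signatures detected.
#' @export
detection_rate <- function(counts, signatures, min_prevalence = 0.20) {
  if (!nrow(counts)) stop("empty cohort", call. = FALSE)
  miss <- setdiff(signatures, colnames(counts))
  if (length(miss))
    stop("signature vOTU(s) absent from counts: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  prev <- colMeans(counts[, signatures, drop = FALSE] > 0)
  mean(prev > min_prevalence)
}

#' Gross abundance of signature sets, compared between groups
#'
#' The gross abundance of a signature set in a sample is the sum of the
#' set's relative abundances. Case and control gross abundances are
#' compared with a two-sided equal-variance two-sample t-test for the
#' enriched and the depleted set separately, with BH adjustment across
#' the reported tests.
#'
#' @param rel samples x vOTUs relative-abundance matrix.
#' @param group character/factor with levels "case"/"control".
#' @param enriched_ids,depleted_ids signature id vectors.
#' @return data.frame per set: \code{set}, \code{mean_case},
#'   \code{mean_control}, \code{t}, \code{p}, \code{q}.
#' @export
gross_abundance_compare <- function(rel, group, enriched_ids, depleted_ids) {
  is_case <- as.character(group) == "case"
  one <- function(ids, label) {
    gross <- rowSums(rel[, intersect(ids, colnames(rel)), drop = FALSE])
    tt <- stats::t.test(gross[is_case], gross[!is_case], var.equal = TRUE)
    data.frame(set = label, mean_case = mean(gross[is_case]),
               mean_control = mean(gross[!is_case]),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(enriched_ids, "enriched"), one(depleted_ids, "depleted"))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' @keywords internal
#' @noRd
auc_of <- function(response, scores) {
  r <- pROC::roc(response = response, predictor = scores,
                 levels = c("control", "case"), direction = "<",
                 quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Random-forest classification of case/control status
#'
#' Within-cohort performance: for each of \code{repeats} random
#' stratified splits, a random forest (500 trees) is trained on
#' \code{split} of the samples and the AUC of the predicted case
#' probability is evaluated on the rest; the mean AUC over repeats is
#' the performance measure. Cross-cohort transfer: a forest trained on
#' the full training cohort predicts an external cohort's labels.
#'
#' @param rel samples x features (signature vOTU) relative-abundance
#'   matrix of the training cohort.
#' @param group character/factor with levels "case"/"control".
#' @param split training fraction per repeat (default 0.7).
#' @param repeats number of random splits (default 10).
#' @param n_trees forest size (default 500).
#' @param seed integer seed; results are deterministic given it.
#' @param eval_rel,eval_group optional external cohort for transfer
#'   AUC.
#' @return list with \code{mean_auc}, \code{aucs} (per repeat) and
#'   \code{cross_auc} (NA when no external cohort given).
#' @export
rf_transfer <- function(rel, group, split = 0.7, repeats = 10L,
                        n_trees = 500L, seed = 1L,
                        eval_rel = NULL, eval_group = NULL) {
  group <- factor(as.character(group), levels = c("control", "case"))
  if (any(is.na(group))) stop("group must be case/control", call. = FALSE)
  set.seed(as.integer(seed))
  x <- as.data.frame(rel)
  colnames(x) <- make.names(colnames(x))
  aucs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    train_idx <- unlist(lapply(levels(group), function(lv) {
      idx <- which(group == lv)
      sample(idx, max(1L, round(split * length(idx))))
    }))
    fit <- randomForest::randomForest(x[train_idx, , drop = FALSE],
                                      y = group[train_idx], ntree = n_trees)
    test_idx <- setdiff(seq_along(group), train_idx)
    prob <- stats::predict(fit, x[test_idx, , drop = FALSE],
                           type = "prob")[, "case"]
    aucs[r] <- auc_of(as.character(group[test_idx]), prob)
  }
  cross_auc <- NA_real_
  if (!is.null(eval_rel)) {
    fit_full <- randomForest::randomForest(x, y = group, ntree = n_trees)
    xe <- as.data.frame(eval_rel)
    colnames(xe) <- make.names(colnames(xe))
    xe <- xe[, colnames(x), drop = FALSE]
    prob <- stats::predict(fit_full, xe, type = "prob")[, "case"]
    cross_auc <- auc_of(as.character(eval_group), prob)
  }
  list(mean_auc = mean(aucs), aucs = aucs, cross_auc = cross_auc)
}
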
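#' Per-sample vOTU and family mapping rates
#'
#' The mapping rate of a vOTU in a sample is its read count divided by
#' the sample's total clean reads; a family's rate is the sum of its
#' member vOTUs' rates, and the overall viral rate the sum over all
#' vOTUs.
#'
#' @param counts samples x vOTUs integer matrix.
#' @param clean_read_totals named numeric vector of clean-read totals
#'   per sample.
#' @param family_map named character vector, vOTU id -> family.
#' @return list with \code{votu_rates} (samples x vOTUs),
#'   \code{family_rates} (samples x families) and \code{overall}
#'   (per-sample viral mapping rate).
#' @export
mapping_rates <- function(counts, clean_read_totals, family_map = NULL) {
  stopifnot(all(rownames(counts) %in% names(clean_read_totals)))
  totals <- clean_read_totals[rownames(counts)]
  if (any(totals <= 0)) stop("clean read totals must be positive", call. = FALSE)
  rates <- sweep(counts, 1L, totals, "/")
  fam_rates <- NULL
  if (!is.null(family_map)) {
    fam <- family_map[colnames(counts)]
    fam[is.na(fam)] <- "unclassified"
    fam_rates <- t(rowsum(t(rates), group = fam))
  }
  list(votu_rates = rates, family_rates = fam_rates,
       overall = rowSums(rates))
}

#' Rarefy a count matrix to fixed depth
#'
#' Random subsampling without replacement from each sample's read pool
#' (multivariate hypergeometric), so every retained sample sums exactly
#' to \code{depth_target}. Samples whose total is below the target
#' cannot be rarefied and are dropped with a warning. Deterministic
#' given \code{seed}.
#'
#' @param counts samples x features integer matrix.
#' @param depth_target subsampling depth.
#' @param seed integer seed.
#' @return rarefied integer matrix (possibly with fewer rows).
#' @export
rarefy_counts <- function(counts, depth_target, seed = 1L) {
  if (depth_target <= 0) stop("configuration error: depth_target must be positive",
                              call. = FALSE)
  totals <- rowSums(counts)
  drop <- totals < depth_target
  if (any(drop)) {
    warning(sum(drop), " sample(s) below rarefaction depth dropped: ",
            paste(utils::head(rownames(counts)[drop], 10L), collapse = ", "))
    counts <- counts[!drop, , drop = FALSE]
    totals <- totals[!drop]
  }
  if (!nrow(counts)) stop("no sample reaches the rarefaction depth", call. = FALSE)
  set.seed(as.integer(seed))
  exact <- totals == depth_target
  out <- counts
  if (any(!exact)) {
    # rrarefy heuristically warns when the smallest nonzero count
    # exceeds 1; inputs here are validated integer read counts
    sub <- suppressWarnings(
      vegan::rrarefy(counts[!exact, , drop = FALSE], depth_target))
    out[!exact, ] <- sub
  }
  storage.mode(out) <- "integer"
  out
}

#' Relative abundance from rarefied counts
#'
#' @param rarefied rarefied samples x features matrix (rows sum to the
#'   rarefaction depth).
#' @param depth_target the rarefaction depth used as denominator.
#' @return samples x features matrix of proportions; rows sum to 1.
#' @export
relative_abundance <- function(rarefied, depth_target) {
  if (any(abs(rowSums(rarefied) - depth_target) > 0))
    stop("rows do not sum to depth_target; rarefy first", call. = FALSE)
  rarefied / depth_target
}

#' Aggregate vOTU relative abundances to family level
#'
#' Abundances of vOTUs sharing a family are added; vOTUs without a
#' family label are pooled as "unclassified". Row sums are preserved.
#'
#' @param rel samples x vOTUs relative-abundance matrix.
#' @param family_map named character vector, vOTU id -> family.
#' @return samples x families matrix.
#' @export
family_rollup <- function(rel, family_map) {
  fam <- family_map[colnames(rel)]
  fam[is.na(fam)] <- "unclassified"
  t(rowsum(t(rel), group = fam))
}

#' Alpha diversity per sample
#'
#' Observed richness (features with nonzero abundance), Shannon index
#' (natural log) and Simpson index (1 - sum p^2), the conventional
#' defaults for gut-virome profiles.
#'
#' @param rel samples x features relative-abundance matrix.
#' @return data.frame with columns \code{observed}, \code{shannon},
#'   \code{simpson}, one row per sample.
#' @export
alpha_diversity <- function(rel) {
  data.frame(observed = rowSums(rel > 0),
             shannon = vegan::diversity(rel, index = "shannon"),
             simpson = vegan::diversity(rel, index = "simpson"),
             row.names = rownames(rel))
}

#' Bray-Curtis dissimilarity matrix
#'
#' \code{d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)}; 0 for identical
#' profiles, 1 for disjoint supports.
#'
#' @param rel samples x features relative-abundance matrix.
#' @return symmetric samples x samples distance matrix.
#' @export
bray_curtis <- function(rel) {
  as.matrix(vegan::vegdist(rel, method = "bray"))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers \code{-D^2/2}, eigendecomposes, and keeps axes with
#' positive eigenvalues; per-axis variance fractions are computed over
#' the positive eigenvalues only (negative eigenvalues from non-Euclidean
#' distances are dropped without correction). Axis signs are arbitrary.
#'
#' @param distances symmetric distance matrix (or \code{dist}).
#' @param k maximum number of axes to return.
#' @return list with \code{coordinates} (samples x axes),
#'   \code{eigenvalues} (positive ones) and \code{variance_fraction}.
#' @export
pcoa_ord <- function(distances, k = NULL) {
  d <- as.dist(distances)
  n <- attr(d, "Size")
  # non-Euclidean distances yield some negative eigenvalues; cmdscale
  # warns about them but we drop them explicitly below
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  pos <- fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig), 1)
  eig <- fit$eig[pos]
  n_axes <- min(sum(pos), ncol(fit$points))
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  if (!n_axes) {
    coords <- matrix(0, n, 1L,
                     dimnames = list(labels(d), "PC1"))
    return(list(coordinates = coords, eigenvalues = numeric(0),
                variance_fraction = numeric(0)))
  }
  if (!is.null(k) && k < ncol(coords)) {
    coords <- coords[, seq_len(k), drop = FALSE]
  }
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       variance_fraction = eig / sum(eig))
}

#' PERMANOVA with sequential terms and adjusted R-squared
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' with terms entered sequentially in the given order (Type-I
#' partitioning); p-values by free permutation of observations. Each
#' term's R-squared is additionally adjusted for its degrees of freedom
#' (Ezekiel adjustment via \code{vegan::RsquareAdj}).
#'
#' @param distances symmetric distance matrix or \code{dist} object.
#' @param factors data.frame of per-sample covariates, rows aligned with
#'   the distance matrix.
#' @param terms character vector naming the model terms in entry order.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return data.frame with one row per term: \code{df}, \code{R2},
#'   \code{adj_R2}, \code{F}, \code{p}, plus Residual/Total rows.
#' @export
permanova <- function(distances, factors, terms, n_perm = 1000L, seed = 1L) {
  d <- stats::as.dist(distances)
  n <- attr(d, "Size")
  if (nrow(factors) != n)
    stop("factors table does not match the distance matrix", call. = FALSE)
  miss <- setdiff(terms, names(factors))
  if (length(miss)) stop("unknown term(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  for (tm in terms) {
    v <- factors[[tm]]
    if ((is.character(v) || is.factor(v)) && length(unique(v)) < 2L)
      stop("degenerate term '", tm, "': fewer than two levels", call. = FALSE)
    if (anyNA(v)) stop("term '", tm, "' contains missing values", call. = FALSE)
  }
  dat <- factors[, terms, drop = FALSE]
  form <- stats::as.formula(paste("d ~", paste(terms, collapse = " + ")))
  set.seed(as.integer(seed))
  fit <- vegan::adonis2(form, data = dat, permutations = n_perm, by = "terms")
  out <- data.frame(term = rownames(fit), df = fit$Df, R2 = fit$R2,
                    F = fit$F, p = fit$`Pr(>F)`, stringsAsFactors = FALSE)
  out$adj_R2 <- ifelse(out$term %in% terms,
                       vapply(seq_len(nrow(out)), function(i)
                         vegan::RsquareAdj(out$R2[i], n, out$df[i]),
                         numeric(1)),
                       NA_real_)
  rownames(out) <- NULL
  out[, c("term", "df", "R2", "adj_R2", "F", "p")]
}

#' Two-group comparison of alpha-diversity indexes
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) per diversity index.
#'
#' @param alpha data.frame from [alpha_diversity()].
#' @param group two-level factor or character vector aligned with rows.
#' @return named numeric vector of p-values, one per index.
#' @export
compare_alpha <- function(alpha, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels",
                                 call. = FALSE)
  vapply(alpha, function(x) {
    stats::wilcox.test(x[group == levels(group)[1]],
                       x[group == levels(group)[2]],
                       exact = FALSE, correct = TRUE)$p.value
  }, numeric(1))
}
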
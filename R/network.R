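# SparCC basis-variance solve for one fraction matrix.
# frac: samples x features matrix of proportions (no zeros).
#' @keywords internal
#' @noRd
sparcc_once <- function(frac, exclusion_threshold, max_exclusions) {
  logf <- log(frac)
  D <- ncol(logf)
  # variation matrix: t_ij = var(log(x_i / x_j))
  V <- stats::var(logf)
  Tm <- outer(diag(V), diag(V), "+") - 2 * V
  M <- matrix(1, D, D)
  diag(M) <- D - 1
  t_row <- rowSums(Tm)
  solve_r <- function(M, t_row) {
    omega <- as.numeric(solve(M, t_row))
    omega <- pmax(omega, .Machine$double.eps)
    denom <- 2 * sqrt(outer(omega, omega))
    r <- (outer(omega, omega, "+") - Tm) / denom
    r <- pmin(pmax(r, -1), 1)
    diag(r) <- 1
    r
  }
  r <- solve_r(M, t_row)
  excluded <- matrix(FALSE, D, D)
  for (it in seq_len(max_exclusions)) {
    cand <- abs(r)
    cand[excluded] <- -Inf
    diag(cand) <- -Inf
    top <- which(cand == max(cand), arr.ind = TRUE)[1L, ]
    i <- top[1L]; j <- top[2L]
    if (cand[i, j] <= exclusion_threshold) break
    # keep every feature in at least two pairs of the linear system
    if (M[i, i] <= 2 || M[j, j] <= 2) break
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    M[i, j] <- M[j, i] <- 0
    t_row[i] <- t_row[i] - Tm[i, j]
    t_row[j] <- t_row[j] - Tm[i, j]
    excluded[i, j] <- excluded[j, i] <- TRUE
    r <- solve_r(M, t_row)
  }
  r
}

#' SparCC correlation inference for compositional counts
#'
#' Estimates linear (basis) correlations between features of a
#' compositional count matrix from log-ratio variances: with
#' \code{t_ij = var(log(x_i / x_j))}, the basis variances \code{omega}
#' solve a linear system under a sparsity assumption, and
#' \code{r_ij = (omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j))},
#' clipped to [-1, 1]. The most strongly correlated pair with
#' \code{|r|} above \code{exclusion_threshold} is iteratively removed
#' from the system and the basis re-solved (up to
#' \code{max_exclusions} times), so that a few true correlations do not
#' bias the sparse solve.
#'
#' By default a fixed pseudocount of 1 makes the estimate
#' deterministic; with \code{dirichlet = TRUE} fractions are resampled
#' from Dirichlet(counts + 1) for each of \code{n_iterations} draws and
#' the median correlation is returned.
#'
#' @param counts samples x features integer matrix (vOTUs and/or
#'   bacterial species); needs >= 4 features and >= 10 samples.
#' @param n_iterations Dirichlet resampling iterations (default 20;
#'   ignored unless \code{dirichlet = TRUE}).
#' @param exclusion_threshold correlation magnitude above which a pair
#'   is excluded from the basis solve (default 0.1).
#' @param max_exclusions maximum excluded pairs per solve (default 10).
#' @param dirichlet use Dirichlet resampling instead of the fixed
#'   pseudocount.
#' @param seed integer seed (used only in Dirichlet mode).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sparcc <- function(counts, n_iterations = 20L, exclusion_threshold = 0.1,
                   max_exclusions = 10L, dirichlet = FALSE, seed = 1L) {
  if (ncol(counts) < 4L) stop("need at least 4 features", call. = FALSE)
  if (nrow(counts) < 10L) stop("need at least 10 samples", call. = FALSE)
  keep <- apply(counts, 2L, function(x) stats::var(x) > 0)
  if (!all(keep)) {
    warning("constant feature(s) excluded: ",
            paste(colnames(counts)[!keep], collapse = ", "))
    counts <- counts[, keep, drop = FALSE]
    if (ncol(counts) < 4L) stop("fewer than 4 variable features", call. = FALSE)
  }
  if (dirichlet) {
    set.seed(as.integer(seed))
    rs <- vector("list", n_iterations)
    for (b in seq_len(n_iterations)) {
      g <- matrix(stats::rgamma(length(counts), shape = counts + 1, rate = 1),
                  nrow(counts), ncol(counts))
      frac <- g / rowSums(g)
      rs[[b]] <- sparcc_once(frac, exclusion_threshold, max_exclusions)
    }
    r <- apply(simplify2array(rs), c(1L, 2L), stats::median)
  } else {
    pc <- counts + 1
    frac <- pc / rowSums(pc)
    r <- sparcc_once(frac, exclusion_threshold, max_exclusions)
  }
  dimnames(r) <- list(colnames(counts), colnames(counts))
  r
}

#' Bootstrap p-values for SparCC correlations
#'
#' Null distribution by permuting every feature's values independently
#' across samples and recomputing the SparCC estimate; two-sided p-value
#' \code{(1 + #|r*| >= |r|) / (1 + n_boot)} per pair, with
#' Benjamini-Hochberg adjustment over the upper triangle.
#'
#' @param counts samples x features count matrix.
#' @param r_obs observed correlation matrix from [sparcc()].
#' @param n_boot number of permutation replicates (default 1000).
#' @param seed integer seed.
#' @param ... passed to the internal SparCC solve (thresholds).
#' @return list with matrices \code{p} and \code{q}.
#' @export
sparcc_pvalues <- function(counts, r_obs, n_boot = 1000L, seed = 1L, ...) {
  stopifnot(ncol(counts) == ncol(r_obs))
  set.seed(as.integer(seed))
  D <- ncol(counts)
  hits <- matrix(0L, D, D)
  for (b in seq_len(n_boot)) {
    perm <- apply(counts, 2L, sample)
    r_b <- sparcc(perm, dirichlet = FALSE, ...)
    hits <- hits + (abs(r_b) >= abs(r_obs))
  }
  p <- (1 + hits) / (1 + n_boot)
  diag(p) <- NA_real_
  up <- upper.tri(p)
  q <- p
  q[up] <- stats::p.adjust(p[up], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  dimnames(p) <- dimnames(q) <- dimnames(r_obs)
  list(p = p, q = q)
}

#' Fisher's exact co-occurrence test between vOTUs and species
#'
#' Presence is any nonzero rarefied count. For each (vOTU, species)
#' pair, a 2x2 contingency table of joint presence/absence across
#' samples is tested with a two-sided Fisher's exact test;
#' Benjamini-Hochberg q-values are computed over all tested pairs.
#'
#' @param votu_counts samples x vOTUs (rarefied) count matrix.
#' @param species_counts samples x species count matrix (same samples).
#' @param pairs optional data.frame (\code{votu_id}, \code{species_id})
#'   restricting which pairs are tested; default all combinations.
#' @return data.frame with \code{votu_id}, \code{species_id},
#'   \code{odds_ratio}, \code{p}, \code{q}.
#' @export
cooccurrence <- function(votu_counts, species_counts, pairs = NULL) {
  stopifnot(nrow(votu_counts) == nrow(species_counts))
  if (is.null(pairs))
    pairs <- expand.grid(votu_id = colnames(votu_counts),
                         species_id = colnames(species_counts),
                         stringsAsFactors = FALSE)
  pv <- votu_counts > 0
  ps <- species_counts > 0
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    v <- pv[, pairs$votu_id[k]]
    s <- ps[, pairs$species_id[k]]
    tab <- table(factor(v, c(TRUE, FALSE)), factor(s, c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab)
    data.frame(votu_id = pairs$votu_id[k], species_id = pairs$species_id[k],
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Classify signature vOTUs as bacterium-dependent or -independent
#'
#' A signature vOTU is bacterium-dependent when it has at least one
#' relationship with a bacterial species by any of three evidence
#' types: a predicted host link, SparCC co-abundance (signed correlation
#' above \code{r_min} with \code{q} below \code{q_max}), or Fisher
#' co-occurrence (\code{q} below \code{cooccur_q_max}); otherwise it is
#' bacterium-independent.
#'
#' @param signature_ids character vector of signature vOTU ids.
#' @param host_links data.frame with \code{votu_id}, \code{species_id}
#'   (CRISPR and/or homology links).
#' @param sparcc_r,sparcc_q correlation and q matrices whose rows are
#'   vOTUs and whose columns include the species (as produced by running
#'   [sparcc()] on a combined vOTU + species matrix and subsetting), or
#'   NULL to skip this evidence.
#' @param cooccur result of [cooccurrence()], or NULL.
#' @param r_min SparCC threshold on the signed correlation (default
#'   0.60).
#' @param q_max SparCC q threshold (default 0.001).
#' @param cooccur_q_max co-occurrence q threshold (default 0.001).
#' @return list with \code{labels} (data.frame votu_id/label),
#'   \code{edges} (data.frame votu_id/species_id/evidence) and
#'   \code{species_degree} (connections per species).
#' @export
classify_dependency <- function(signature_ids, host_links = NULL,
                                sparcc_r = NULL, sparcc_q = NULL,
                                cooccur = NULL, r_min = 0.60,
                                q_max = 0.001, cooccur_q_max = 0.001) {
  edges <- list()
  if (!is.null(host_links) && nrow(host_links)) {
    hl <- host_links[host_links$votu_id %in% signature_ids, , drop = FALSE]
    if (nrow(hl))
      edges[[length(edges) + 1L]] <- data.frame(
        votu_id = hl$votu_id, species_id = hl$species_id, evidence = "host",
        stringsAsFactors = FALSE)
  }
  if (!is.null(sparcc_r)) {
    stopifnot(!is.null(sparcc_q))
    vs <- intersect(signature_ids, rownames(sparcc_r))
    for (v in vs) {
      hit <- which(sparcc_r[v, ] > r_min & sparcc_q[v, ] < q_max)
      if (length(hit))
        edges[[length(edges) + 1L]] <- data.frame(
          votu_id = v, species_id = colnames(sparcc_r)[hit],
          evidence = "co-abundance", stringsAsFactors = FALSE)
    }
  }
  if (!is.null(cooccur) && nrow(cooccur)) {
    co <- cooccur[cooccur$votu_id %in% signature_ids &
                    cooccur$q < cooccur_q_max, , drop = FALSE]
    if (nrow(co))
      edges[[length(edges) + 1L]] <- data.frame(
        votu_id = co$votu_id, species_id = co$species_id,
        evidence = "co-occurrence", stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(votu_id = character(), species_id = character(),
               evidence = character(), stringsAsFactors = FALSE)
  dependent <- unique(edges$votu_id)
  labels <- data.frame(
    votu_id = signature_ids,
    label = ifelse(signature_ids %in% dependent, "dependent", "independent"),
    stringsAsFactors = FALSE)
  degree <- if (nrow(edges))
    sort(table(unique(edges[, c("votu_id", "species_id")])$species_id),
         decreasing = TRUE)
  else table(character())
  list(labels = labels, edges = edges, species_degree = degree)
}

#' Compare AMG occurrence between enriched and depleted signatures
#'
#' The occurrence rate of an auxiliary metabolic enzyme in a group is
#' the fraction of that group's vOTUs carrying it. Rates of the
#' case-enriched and case-depleted signature sets are compared with a
#' two-sided Fisher's exact test per enzyme, BH-adjusted across
#' enzymes.
#'
#' @param amg_sets named list of per-vOTU KO sets (see [annotate_ko()]).
#' @param enriched_ids,depleted_ids vOTU id vectors of the two signature
#'   groups.
#' @param panel optional KO vector restricting the tested enzymes (e.g.
#'   \code{amg_panel("nad")}).
#' @return data.frame per enzyme: \code{ko}, \code{rate_enriched},
#'   \code{rate_depleted}, \code{carriers_enriched},
#'   \code{carriers_depleted}, \code{p}, \code{q}.
#' @export
amg_occurrence_compare <- function(amg_sets, enriched_ids, depleted_ids,
                                   panel = NULL) {
  if (!length(enriched_ids) || !length(depleted_ids))
    stop("both signature groups must be non-empty", call. = FALSE)
  enzymes <- if (is.null(panel))
    sort(unique(unlist(amg_sets[c(enriched_ids, depleted_ids)])))
  else sort(unique(panel))
  ne <- length(enriched_ids); nd <- length(depleted_ids)
  res <- lapply(enzymes, function(ko) {
    ce <- sum(vapply(amg_sets[enriched_ids], function(s) ko %in% s, logical(1)))
    cd <- sum(vapply(amg_sets[depleted_ids], function(s) ko %in% s, logical(1)))
    p <- stats::fisher.test(matrix(c(ce, ne - ce, cd, nd - cd), 2L,
                                   byrow = TRUE))$p.value
    data.frame(ko = ko, rate_enriched = ce / ne, rate_depleted = cd / nd,
               carriers_enriched = ce, carriers_depleted = cd, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(ko = character(), rate_enriched = numeric(),
                      rate_depleted = numeric(), carriers_enriched = integer(),
                      carriers_depleted = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
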
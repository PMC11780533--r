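# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-derivations (position-wise vectors, closed
# forms, full enumeration) kept separate from the package's own code
# paths.

# Fisher's method via the Erlang (integer-shape gamma) survival series:
# X ~ chi2(2k) upper tail = exp(-X/2) * sum_{i<k} (X/2)^i / i!
oracle_fisher_combine <- function(p) {
  X <- -2 * sum(log(p))
  k <- length(p)
  x2 <- X / 2
  terms <- vapply(0:(k - 1), function(i) exp(-x2 + i * log(x2) - lgamma(i + 1)),
                  numeric(1))
  min(1, sum(terms))
}

# Two-sided Fisher exact p by full enumeration over one margin, using
# log-binomials directly (mirrors the sum-of-small-probabilities rule
# with the conventional 1e-7 relative tolerance).
oracle_fisher_exact <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  probs <- exp(logp)
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force greedy vOTU clustering: per-base coverage vectors on the
# shorter sequence, then the longest-first/absorb-linked loop written
# out directly.
oracle_cluster <- function(hits, records, min_identity = 95,
                           min_coverage = 0.75) {
  len <- setNames(records$length, records$id)
  linked_pair <- function(a, b) {
    sh <- if (len[[a]] <= len[[b]]) a else b
    cov <- rep(FALSE, len[[sh]])
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      if (h$pident < min_identity) next
      ids <- c(h$qseqid, h$sseqid)
      if (!setequal(ids, c(a, b)) || a == b) next
      if (h$qseqid == sh) {
        lo <- min(h$qstart, h$qend); hi <- max(h$qstart, h$qend)
      } else if (h$sseqid == sh) {
        lo <- min(h$sstart, h$send); hi <- max(h$sstart, h$send)
      } else next
      cov[lo:hi] <- TRUE
    }
    mean(cov) >= min_coverage
  }
  ord <- records$id[order(-records$length, records$id)]
  rep_of <- setNames(rep(NA_character_, length(ord)), ord)
  for (s in ord) {
    if (!is.na(rep_of[[s]])) next
    rep_of[[s]] <- s
    for (m in ord) {
      if (is.na(rep_of[[m]]) && linked_pair(s, m)) rep_of[[m]] <- s
    }
  }
  rep_of
}

# Random clustering instance: records plus a random alignment table in
# outfmt-6 layout with coordinates valid for both sequences.
random_cluster_instance <- function(n_max = 20L) {
  n <- sample(2:n_max, 1)
  records <- data.frame(id = sprintf("s%02d", seq_len(n)),
                        length = sample(5000:20000, n, replace = TRUE),
                        stringsAsFactors = FALSE)
  n_hits <- sample(0:(2 * n), 1)
  if (n_hits == 0) {
    hits <- data.frame(qseqid = character(), sseqid = character(),
                       pident = numeric(), length = integer(),
                       mismatch = integer(), gapopen = integer(),
                       qstart = integer(), qend = integer(),
                       sstart = integer(), send = integer(),
                       evalue = numeric(), bitscore = numeric())
    return(list(records = records, hits = hits))
  }
  rows <- lapply(seq_len(n_hits), function(i) {
    pair <- sample(records$id, 2)
    lq <- records$length[records$id == pair[1]]
    ls <- records$length[records$id == pair[2]]
    span <- sample(1000:15000, 1)
    qs <- sample(seq_len(max(1, lq - span)), 1)
    qe <- min(lq, qs + span)
    ss <- sample(seq_len(max(1, ls - span)), 1)
    se <- min(ls, ss + span)
    if (runif(1) < 0.3) { tmp <- ss; ss <- se; se <- tmp }  # reverse strand
    data.frame(qseqid = pair[1], sseqid = pair[2],
               pident = round(runif(1, 90, 100), 1), length = span,
               mismatch = 0L, gapopen = 0L, qstart = qs, qend = qe,
               sstart = ss, send = se, evalue = 1e-10, bitscore = span,
               stringsAsFactors = FALSE)
  })
  list(records = records, hits = do.call(rbind, rows))
}

# Small default configuration for quick end-to-end fixtures.
tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_votus = 30L, n_species = 8L,
               n_cases = 15L, n_controls = 15L, n_enriched = 6L,
               n_depleted = 6L, n_host_links = 6L, n_coabund = 3L,
               depth_range = c(4000L, 6000L), n_contaminants = 3L,
               n_duplicates = 3L)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}
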
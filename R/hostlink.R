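#' CRISPR-spacer matching with Karlin-Altschul bit scores
#'
#' Scans each spacer against both strands of every vOTU sequence with an
#' exhaustive full-length ungapped alignment: a candidate must span the
#' entire spacer within the sequence. The raw score is
#' \code{matches * match + mismatches * mismatch} and is converted to
#' bits as \code{(lambda * S - ln K) / ln 2}; a host link is emitted
#' when the bit score reaches \code{min_bits}. Positions containing N
#' score as mismatches. One link per (vOTU, species) pair is kept, at
#' the best score; a vOTU may be linked to several species.
#'
#' The default constants (+1/-2 with lambda = 1.28, K = 0.46) are the
#' standard ungapped Karlin-Altschul values for that reward/penalty
#' pair; a 32-nt perfect match scores about 60 bits and a 20-nt perfect
#' match about 38, so the default 45-bit cutoff requires roughly 24
#' perfectly matching positions.
#'
#' @param spacers data.frame with columns \code{spacer_id},
#'   \code{species_id}, \code{sequence} (ACGTN alphabet).
#' @param sequences named \code{Biostrings::DNAStringSet} (or named
#'   character vector) of vOTU sequences.
#' @param match,mismatch per-position reward and penalty.
#' @param lambda,K Karlin-Altschul parameters for the scoring pair.
#' @param min_bits minimum bit score for a link (default 45).
#' @return data.frame of host links: \code{votu_id}, \code{species_id},
#'   \code{evidence} ("crispr"), \code{score} (bit score).
#' @export
match_spacers <- function(spacers, sequences, match = 1, mismatch = -2,
                          lambda = 1.28, K = 0.46, min_bits = 45) {
  assert_cols(spacers, c("spacer_id", "species_id", "sequence"), "spacers")
  if (!inherits(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences)))
    stop("sequences must be named by vOTU id", call. = FALSE)
  bad <- grepl("[^ACGTN]", toupper(spacers$sequence))
  if (any(bad))
    stop("data error: non-ACGTN spacer sequence(s): ",
         paste(spacers$spacer_id[bad], collapse = ", "), call. = FALSE)
  stopifnot(lambda > 0, match > mismatch)

  s_min <- (min_bits * log(2) + log(K)) / lambda
  links <- list()
  for (k in seq_len(nrow(spacers))) {
    sp <- toupper(spacers$sequence[k])
    L <- nchar(sp)
    # worst acceptable mismatch count for a full-length candidate
    mm_max <- floor((L * match - s_min) / (match - mismatch))
    if (mm_max < 0) next
    pats <- list(Biostrings::DNAString(sp),
                 Biostrings::reverseComplement(Biostrings::DNAString(sp)))
    for (v in names(sequences)) {
      subj <- sequences[[v]]
      best_bits <- -Inf
      for (pat in pats) {
        m <- Biostrings::matchPattern(pat, subj, max.mismatch = mm_max,
                                      with.indels = FALSE)
        if (!length(m)) next
        st <- Biostrings::start(m); en <- Biostrings::end(m)
        # the entire spacer must lie within the sequence
        ok <- st >= 1L & en <= length(subj)
        if (!any(ok)) next
        mm <- Biostrings::neditStartingAt(pat, subj, starting.at = st[ok],
                                          with.indels = FALSE)
        S <- (L - mm) * match + mm * mismatch
        bits <- (lambda * S - log(K)) / log(2)
        best_bits <- max(best_bits, bits)
      }
      if (is.finite(best_bits) && best_bits >= min_bits) {
        links[[length(links) + 1L]] <- data.frame(
          votu_id = v, species_id = spacers$species_id[k],
          evidence = "crispr", score = best_bits, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(links))
    return(data.frame(votu_id = character(), species_id = character(),
                      evidence = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, links)
  # best score per (vOTU, species)
  out <- out[order(out$votu_id, out$species_id, -out$score), , drop = FALSE]
  out <- out[!duplicated(out[, c("votu_id", "species_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Homology-based virus-host links
#'
#' A prokaryotic species is called a host of a vOTU when alignments of
#' the vOTU against that species' genomes, restricted to rows with at
#' least \code{min_identity} percent identity and merged by interval
#' union on the vOTU, cover at least \code{min_cov} of the vOTU length.
#'
#' @param hits BLAST outfmt-6 table with vOTUs as queries and genomes as
#'   subjects.
#' @param genome2species data.frame mapping \code{genome_id} to
#'   \code{species_id}.
#' @param votu_lengths named integer vector of vOTU lengths (bp).
#' @param min_identity percent identity threshold (default 90).
#' @param min_cov covered fraction of the vOTU (default 0.30).
#' @return data.frame of host links: \code{votu_id}, \code{species_id},
#'   \code{evidence} ("homology"), \code{score} (covered fraction).
#' @export
homology_links <- function(hits, genome2species, votu_lengths,
                           min_identity = 90, min_cov = 0.30) {
  empty <- data.frame(votu_id = character(), species_id = character(),
                      evidence = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  assert_cols(hits, c("qseqid", "sseqid", "pident", "qstart", "qend"), "hits")
  assert_cols(genome2species, c("genome_id", "species_id"), "genome2species")
  sp <- stats::setNames(genome2species$species_id, genome2species$genome_id)
  unknown <- setdiff(unique(hits$sseqid), names(sp))
  if (length(unknown))
    stop("data error: unknown genome -> species mapping for: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  hits <- hits[hits$pident >= min_identity, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  hits$species_id <- unname(sp[hits$sseqid])
  key <- paste(hits$qseqid, hits$species_id, sep = "\r")
  out <- lapply(unique(key), function(k) {
    sub <- hits[key == k, , drop = FALSE]
    v <- sub$qseqid[1]
    if (is.na(votu_lengths[v]))
      stop("data error: unknown vOTU length for ", v, call. = FALSE)
    frac <- interval_union_length(sub$qstart, sub$qend) / votu_lengths[[v]]
    if (frac >= min_cov)
      data.frame(votu_id = v, species_id = sub$species_id[1],
                 evidence = "homology", score = frac, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Host-range breadth of annotated vOTUs
#'
#' Summarises, over vOTUs with at least one host link, the fractions
#' whose hosts span multiple species, multiple bacterial families and
#' multiple phyla.
#'
#' @param links host links from [match_spacers()] and/or
#'   [homology_links()].
#' @param taxonomy data.frame with columns \code{species_id},
#'   \code{family}, \code{phylum}.
#' @return list with \code{hosts} (named list of species per vOTU) and
#'   \code{fractions} (named numeric: multi_species, multi_family,
#'   multi_phylum) plus \code{n_annotated}.
#' @export
host_range_summary <- function(links, taxonomy) {
  assert_cols(taxonomy, c("species_id", "family", "phylum"), "taxonomy")
  if (!nrow(links))
    return(list(hosts = list(),
                fractions = c(multi_species = NA_real_,
                              multi_family = NA_real_,
                              multi_phylum = NA_real_),
                n_annotated = 0L))
  hosts <- split(links$species_id, links$votu_id)
  hosts <- lapply(hosts, unique)
  fam <- stats::setNames(taxonomy$family, taxonomy$species_id)
  phy <- stats::setNames(taxonomy$phylum, taxonomy$species_id)
  n_fam <- vapply(hosts, function(s) length(unique(fam[s])), integer(1))
  n_phy <- vapply(hosts, function(s) length(unique(phy[s])), integer(1))
  n_sp <- lengths(hosts)
  list(hosts = hosts,
       fractions = c(multi_species = mean(n_sp > 1L),
                     multi_family = mean(n_fam > 1L),
                     multi_phylum = mean(n_phy > 1L)),
       n_annotated = length(hosts))
}
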
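#' Remove BUSCO-contaminated viral sequences
#'
#' Putative viral sequences carrying bacterial universal single-copy
#' orthologs (BUSCOs) are likely bacterial contamination. The BUSCO
#' ratio of a sequence is the number of BUSCO hits relative to its total
#' gene count; sequences with a ratio at or above \code{max_ratio} are
#' removed. Sequences with zero predicted genes have ratio 0 and are
#' kept.
#'
#' @param records data.frame with columns \code{id}, \code{n_genes},
#'   \code{n_busco} (see [synth_evidence()] for the full record layout).
#' @param max_ratio removal threshold; the default 0.05 removes
#'   sequences with a BUSCO ratio >= 5\%.
#' @return the kept subset of \code{records}.
#' @export
busco_filter <- function(records, max_ratio = 0.05) {
  assert_cols(records, c("id", "n_genes", "n_busco"), "records")
  if (any(records$n_busco > records$n_genes))
    stop("data error: n_busco exceeds n_genes for ",
         paste(records$id[records$n_busco > records$n_genes], collapse = ", "),
         call. = FALSE)
  ratio <- ifelse(records$n_genes == 0L, 0, records$n_busco / records$n_genes)
  records[ratio < max_ratio, , drop = FALSE]
}

# Aligned fraction of the shorter sequence of a pair, from BLAST-6 rows
# in either orientation, counting only rows at or above min_identity and
# merging their intervals before dividing by the shorter length.
#' @keywords internal
#' @noRd
pair_coverage <- function(hits, id_short, len_short, min_identity) {
  rows <- hits[hits$pident >= min_identity &
                 ((hits$qseqid == id_short) | (hits$sseqid == id_short)), ,
               drop = FALSE]
  if (!nrow(rows)) return(0)
  starts <- ifelse(rows$qseqid == id_short, rows$qstart, rows$sstart)
  ends <- ifelse(rows$qseqid == id_short, rows$qend, rows$send)
  interval_union_length(starts, ends) / len_short
}

#' Cluster viral sequences into species-level vOTUs
#'
#' Two sequences are linked when they share at least \code{min_identity}
#' percent nucleotide identity across at least \code{min_coverage} of
#' the shorter sequence's length (alignment rows are filtered by
#' identity individually, then merged by interval union on the shorter
#' sequence). Clustering is greedy: sequences are sorted by length
#' descending (ties broken lexicographically by id), the longest
#' unassigned sequence seeds a cluster and absorbs every unassigned
#' sequence linked to it; the seed is the representative. Linkage is to
#' the seed only, never transitive through other members.
#'
#' @param hits pairwise nucleotide alignments in BLAST outfmt-6 layout
#'   (columns qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#'   qend, sstart, send, evalue, bitscore); self-hits are ignored;
#'   reverse-strand hits have sstart > send.
#' @param records data.frame with at least \code{id} and \code{length}.
#' @param min_identity percent identity threshold (default 95).
#' @param min_coverage covered-fraction threshold on the shorter
#'   sequence (default 0.75).
#' @return data.frame with columns \code{member_id} and
#'   \code{representative_id}; every record appears exactly once.
#' @export
cluster_votus <- function(hits, records, min_identity = 95,
                          min_coverage = 0.75) {
  assert_cols(records, c("id", "length"), "records")
  ids <- records$id
  if (anyDuplicated(ids)) stop("data error: duplicate record ids", call. = FALSE)
  if (nrow(hits)) {
    assert_cols(hits, c("qseqid", "sseqid", "pident", "qstart", "qend",
                        "sstart", "send"), "hits")
    unknown <- setdiff(unique(c(hits$qseqid, hits$sseqid)), ids)
    if (length(unknown))
      stop("data error: hits reference unknown id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  }
  len <- stats::setNames(records$length, ids)

  # linked pairs: merged aligned fraction on the shorter sequence
  linked <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(hits)) {
    key <- ifelse(hits$qseqid < hits$sseqid,
                  paste(hits$qseqid, hits$sseqid),
                  paste(hits$sseqid, hits$qseqid))
    for (k in unique(key)) {
      sub <- hits[key == k, , drop = FALSE]
      a <- sub$qseqid[1]; b <- sub$sseqid[1]
      id_short <- if (len[[a]] <= len[[b]]) a else b
      cov <- pair_coverage(sub, id_short, len[[id_short]], min_identity)
      if (cov >= min_coverage) assign(k, TRUE, envir = linked)
    }
  }
  is_linked <- function(a, b) {
    k <- if (a < b) paste(a, b) else paste(b, a)
    !is.null(linked[[k]])
  }

  ord <- ids[order(-records$length, records$id)]
  assigned <- stats::setNames(rep(NA_character_, length(ord)), ord)
  for (seed in ord) {
    if (!is.na(assigned[[seed]])) next
    assigned[[seed]] <- seed
    for (m in ord) {
      if (is.na(assigned[[m]]) && is_linked(seed, m)) assigned[[m]] <- seed
    }
  }
  out <- data.frame(member_id = names(assigned),
                    representative_id = unname(assigned),
                    stringsAsFactors = FALSE)
  out[order(match(out$representative_id, ord), out$member_id), ,
      drop = FALSE]
}

#' Genome-completeness tiers of a catalogue
#'
#' Counts sequences in the conventional completeness tiers:
#' high (> 90\%), medium (50-90\%), and low/unknown (everything else,
#' including missing estimates).
#'
#' @param records data.frame with a \code{completeness} column (percent
#'   in [0, 100] or NA).
#' @return named integer vector with elements \code{high},
#'   \code{medium}, \code{low_unknown}.
#' @export
completeness_tiers <- function(records) {
  assert_cols(records, "completeness", "records")
  x <- records$completeness
  if (any(!is.na(x) & (x < 0 | x > 100)))
    stop("data error: completeness outside [0, 100]", call. = FALSE)
  high <- sum(!is.na(x) & x > 90)
  medium <- sum(!is.na(x) & x >= 50 & x <= 90)
  c(high = high, medium = medium,
    low_unknown = length(x) - high - medium)
}
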
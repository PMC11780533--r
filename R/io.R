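# Table dialects: all tables are tab-separated UTF-8 with a header row;
# missing values are written as "NA".

#' Read a FASTA file into a DNAStringSet
#'
#' @param path file path.
#' @return named \code{Biostrings::DNAStringSet}.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    stop("FASTA parse error: duplicate id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named \code{DNAStringSet} or character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a BLAST outfmt-6 style alignment table
#'
#' Expects exactly 12 tab-separated columns in the standard order
#' (qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore), no header; coordinates are 1-based
#' inclusive and reverse-strand subject hits have sstart > send.
#'
#' @param path file path.
#' @return data.frame with the 12 named columns.
#' @export
read_hits_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      mismatch = integer(), gapopen = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("alignment table parse error: line(s) ",
         paste(utils::head(which(nf != 12L), 5L), collapse = ", "),
         " do not have 12 columns", call. = FALSE)
  m <- do.call(rbind, fields)
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
                    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
                    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
                    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$pident) | is.na(out$qstart) | is.na(out$qend))
  if (length(bad))
    stop("alignment table parse error: non-numeric field(s) on line(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  out
}

#' Write an alignment table in outfmt-6 layout (no header)
#' @param hits data.frame with the 12 standard columns.
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a counts matrix (samples as rows, features as columns)
#'
#' @param path TSV with a header row of feature ids and first column of
#'   sample ids.
#' @return integer matrix with dimnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  if (anyDuplicated(rownames(df)))
    stop("counts parse error: duplicate sample id(s)", call. = FALSE)
  m <- as.matrix(df)
  if (any(is.na(m)) || any(m != round(m)) || any(m < 0))
    stop("counts parse error: cells must be non-negative integers",
         call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Write a counts (or abundance) matrix as TSV
#' @param m matrix with sample rownames and feature colnames.
#' @param path output path.
#' @param id_col name of the leading id column (default "sample_id").
#' @export
write_counts_tsv <- function(m, path, id_col = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV with columns sample_id, cohort, group, sex, age,
#'   BMI, stage, protopathy.
#' @return data.frame with sample ids as rownames.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  assert_cols(df, c("sample_id", "group"), "metadata")
  if (anyDuplicated(df$sample_id))
    stop("metadata parse error: duplicate sample id(s)", call. = FALSE)
  bad <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad))
    stop("metadata parse error: unknown group level(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  rownames(df) <- df$sample_id
  df
}

#' Write a generic report table as TSV
#' @param df data.frame.
#' @param path output path.
#' @export
write_report_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
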
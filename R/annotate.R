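#' Family-level taxonomy by protein voting
#'
#' A vOTU is assigned to a viral family when more than
#' \code{min_fraction} of its predicted proteins have their best hit in
#' that family (strictly greater than; the default 0.25 implements the
#' "over 25\%" rule). Each protein contributes at most one vote, taken
#' from its highest-bitscore hit. The vote denominator is the total
#' number of predicted proteins, including proteins without any hit.
#' Ties for the top family yield "unclassified".
#'
#' @param hits data.frame of protein hits with columns
#'   \code{protein_id}, \code{votu_id}, \code{family}, \code{bitscore};
#'   rows with missing family are ignored.
#' @param votu_proteins data.frame with columns \code{votu_id} and
#'   \code{n_proteins} (total predicted proteins per vOTU).
#' @param min_fraction voting threshold (strict).
#' @return data.frame with one row per vOTU in \code{votu_proteins}:
#'   \code{votu_id}, \code{family}, \code{vote_fraction},
#'   \code{n_proteins}, \code{flagged} (TRUE when a vOTU has no
#'   proteins).
#' @export
assign_family <- function(hits, votu_proteins, min_fraction = 0.25) {
  assert_cols(votu_proteins, c("votu_id", "n_proteins"), "votu_proteins")
  assert_cols(hits, c("protein_id", "votu_id", "family", "bitscore"), "hits")
  fam_hits <- hits[!is.na(hits$family), , drop = FALSE]
  # one vote per protein: best hit by bitscore (ties: first after a
  # deterministic sort by family name)
  if (nrow(fam_hits)) {
    fam_hits <- fam_hits[order(fam_hits$protein_id, -fam_hits$bitscore,
                               fam_hits$family), , drop = FALSE]
    fam_hits <- fam_hits[!duplicated(fam_hits$protein_id), , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(votu_proteins)), function(i) {
    v <- votu_proteins$votu_id[i]
    n <- votu_proteins$n_proteins[i]
    if (n == 0L) {
      return(data.frame(votu_id = v, family = "unclassified",
                        vote_fraction = 0, n_proteins = 0L, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    votes <- fam_hits$family[fam_hits$votu_id == v]
    if (!length(votes)) {
      return(data.frame(votu_id = v, family = "unclassified",
                        vote_fraction = 0, n_proteins = n, flagged = FALSE,
                        stringsAsFactors = FALSE))
    }
    tab <- sort(table(votes), decreasing = TRUE)
    top_frac <- as.numeric(tab[1]) / n
    tied <- sum(tab == tab[1]) > 1L
    if (!tied && top_frac > min_fraction) {
      data.frame(votu_id = v, family = names(tab)[1],
                 vote_fraction = top_frac, n_proteins = n, flagged = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(votu_id = v, family = "unclassified",
                 vote_fraction = top_frac, n_proteins = n, flagged = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Accuracy of the family-voting classifier against known labels
#'
#' Accuracy is computed over vOTUs that received a family (unclassified
#' assignments are excluded from the denominator).
#'
#' @param assignments output of [assign_family()].
#' @param truth_families named character vector, vOTU id -> true family.
#' @return accuracy fraction in [0, 1].
#' @export
benchmark_voting <- function(assignments, truth_families) {
  assert_cols(assignments, c("votu_id", "family"), "assignments")
  classified <- assignments[assignments$family != "unclassified", , drop = FALSE]
  if (!nrow(classified))
    stop("benchmark error: no vOTU was assigned a family", call. = FALSE)
  truth <- truth_families[classified$votu_id]
  if (anyNA(truth))
    stop("benchmark error: missing truth label for ",
         paste(classified$votu_id[is.na(truth)], collapse = ", "), call. = FALSE)
  mean(classified$family == truth)
}

#' KO and AMG annotation from best-hit protein tables
#'
#' Each protein receives the KEGG orthologue (KO) of its highest-bitscore
#' hit; equal-bitscore ties are broken deterministically by KO identifier
#' order and flagged. A vOTU's AMG set is the intersection of its KO set
#' with a curated list of auxiliary-metabolic-enzyme identifiers.
#'
#' @param hits data.frame with columns \code{protein_id}, \code{votu_id},
#'   \code{ko}, \code{bitscore}; rows with missing KO are ignored.
#' @param amg_list character vector of KO identifiers considered AMGs;
#'   see [amg_panel()] for the packaged lists.
#' @param votu_ids optional vOTU ids to report (defaults to those seen
#'   in \code{hits}).
#' @return list with \code{ko_sets} and \code{amg_sets} (named lists of
#'   character vectors) and \code{tie_flagged} (protein ids whose best
#'   KO was tied).
#' @export
annotate_ko <- function(hits, amg_list, votu_ids = NULL) {
  assert_cols(hits, c("protein_id", "votu_id", "ko", "bitscore"), "hits")
  ko_hits <- hits[!is.na(hits$ko), , drop = FALSE]
  tie_flagged <- character(0)
  if (nrow(ko_hits)) {
    best <- tapply(ko_hits$bitscore, ko_hits$protein_id, max)
    is_best <- ko_hits$bitscore == best[ko_hits$protein_id]
    ties <- tapply(ko_hits$ko[is_best], ko_hits$protein_id[is_best],
                   function(k) length(unique(k)) > 1L)
    tie_flagged <- names(ties)[ties]
    if (length(tie_flagged))
      warning("tied best-hit KOs for protein(s): ",
              paste(tie_flagged, collapse = ", "),
              "; broken by KO identifier order")
    ko_hits <- ko_hits[order(ko_hits$protein_id, -ko_hits$bitscore,
                             ko_hits$ko), , drop = FALSE]
    ko_hits <- ko_hits[!duplicated(ko_hits$protein_id), , drop = FALSE]
  }
  ids <- votu_ids %||% sort(unique(hits$votu_id))
  ko_sets <- stats::setNames(lapply(ids, function(v)
    sort(unique(ko_hits$ko[ko_hits$votu_id == v]))), ids)
  amg_sets <- lapply(ko_sets, function(k) intersect(k, amg_list))
  list(ko_sets = ko_sets, amg_sets = amg_sets, tie_flagged = tie_flagged)
}

#' Packaged auxiliary-metabolic-enzyme panels
#'
#' Returns one of the curated KO panels shipped with the package:
#' \code{"amg"} — frequently observed gut-phage auxiliary metabolic
#' enzymes (DNA-cytosine methyltransferase, lysozyme, dUTPase, sulfate
#' assimilation, peptidoglycan hydrolases, ...); \code{"nad"} — enzymes
#' of NAD+ de novo biosynthesis and salvage (NAD+ synthase,
#' nicotinate-nucleotide adenylyltransferase, pncA/pncB, ...).
#'
#' @param panel \code{"amg"} or \code{"nad"}.
#' @return character vector of KO identifiers.
#' @export
amg_panel <- function(panel = c("amg", "nad")) {
  panel <- match.arg(panel)
  file <- system.file("extdata",
                      if (panel == "nad") "nad_panel.txt" else "amg_ko_list.txt",
                      package = "virosig", mustWork = TRUE)
  lines <- readLines(file)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}
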
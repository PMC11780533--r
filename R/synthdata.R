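#' Configuration for the synthetic virome generator
#'
#' Builds and validates the configuration object consumed by
#' [synth_community()] and [synth_evidence()]. The defaults describe a
#' two-cohort case-control design with planted differentially abundant
#' vOTUs, planted virus-host links, planted co-abundant vOTU/species
#' pairs, planted protein family compositions and AMG carriage.
#'
#' All planted structure (which vOTUs are enriched or depleted, which
#' host links exist, family and AMG labels) is a deterministic function
#' of the configuration; the random seed only drives abundances,
#' sequences and decoy evidence. Regenerating with the same seed is
#' bit-identical.
#'
#' @param seed integer root seed; all randomness flows from it through
#'   named substreams.
#' @param n_cohorts number of independent case/control cohorts.
#' @param n_cases,n_controls samples per group in each cohort.
#' @param n_votus number of viral operational taxonomic units.
#' @param n_species number of bacterial species profiled alongside.
#' @param n_enriched,n_depleted number of planted case-enriched and
#'   case-depleted vOTUs.
#' @param effect_fold multiplicative abundance effect applied to planted
#'   vOTUs in cases before renormalisation; must be >= 1 (1 = null).
#' @param depth_range integer pair, uniform range of per-sample mapped
#'   read depth.
#' @param n_host_links number of planted (vOTU, species) host links.
#' @param spacer_len_range integer pair, lengths of planted CRISPR
#'   spacers.
#' @param family_palette viral family names used for planted taxonomy.
#' @param amg_palette KEGG orthologue identifiers used for planted
#'   auxiliary metabolic genes.
#' @param sample_noise_sd per-sample log-normal biological noise (sd of
#'   the log abundance around the baseline).
#' @param n_coabund number of signature vOTUs generated as noisy
#'   co-abundant partners of a bacterial species.
#' @param coabund_noise_sd log-scale noise of the co-abundance coupling.
#' @param seq_len_range integer pair, vOTU sequence lengths (bp).
#' @param n_contaminants extra BUSCO-contaminated records emitted by
#'   [synth_evidence()].
#' @param n_duplicates number of vOTUs that get a redundant near-copy
#'   (>=95\% identity over >=75\% length) for clustering tests.
#' @return an object of class \code{virosig_config}.
#' @export
synth_config <- function(seed = 1L,
                         n_cohorts = 2L,
                         n_cases = 60L,
                         n_controls = 60L,
                         n_votus = 200L,
                         n_species = 30L,
                         n_enriched = 40L,
                         n_depleted = 40L,
                         effect_fold = 3,
                         depth_range = c(40000L, 60000L),
                         n_host_links = 24L,
                         spacer_len_range = c(28L, 40L),
                         family_palette = c("Siphoviridae", "Myoviridae",
                                            "Podoviridae", "Microviridae",
                                            "crAss-like"),
                         amg_palette = c("K01916", "K00969", "K08281",
                                         "K00763", "K00558", "K01185"),
                         sample_noise_sd = 1,
                         n_coabund = 12L,
                         coabund_noise_sd = 0.3,
                         seq_len_range = c(5000L, 8000L),
                         n_contaminants = 8L,
                         n_duplicates = 10L) {
  cfg <- list(seed = as.integer(seed), n_cohorts = as.integer(n_cohorts),
              n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_votus = as.integer(n_votus), n_species = as.integer(n_species),
              n_enriched = as.integer(n_enriched), n_depleted = as.integer(n_depleted),
              effect_fold = effect_fold, depth_range = as.integer(depth_range),
              n_host_links = as.integer(n_host_links),
              spacer_len_range = as.integer(spacer_len_range),
              family_palette = family_palette, amg_palette = amg_palette,
              sample_noise_sd = sample_noise_sd, n_coabund = as.integer(n_coabund),
              coabund_noise_sd = coabund_noise_sd,
              seq_len_range = as.integer(seq_len_range),
              n_contaminants = as.integer(n_contaminants),
              n_duplicates = as.integer(n_duplicates))
  class(cfg) <- "virosig_config"
  validate_config(cfg)
}

#' @keywords internal
#' @noRd
validate_config <- function(cfg) {
  with(cfg, {
    if (n_cohorts < 1L || n_cases < 1L || n_controls < 1L)
      stop("configuration error: cohorts must be non-empty", call. = FALSE)
    if (n_votus < 1L || n_species < 1L)
      stop("configuration error: need at least one vOTU and one species", call. = FALSE)
    if (n_enriched < 0L || n_depleted < 0L || n_enriched + n_depleted > n_votus)
      stop("configuration error: n_enriched + n_depleted must not exceed n_votus",
           call. = FALSE)
    if (effect_fold < 1)
      stop("configuration error: effect_fold must be >= 1", call. = FALSE)
    if (length(depth_range) != 2L || any(depth_range <= 0L) ||
        depth_range[1] > depth_range[2])
      stop("configuration error: invalid depth_range", call. = FALSE)
    if (spacer_len_range[1] < 15L)
      stop("configuration error: spacers shorter than 15 nt", call. = FALSE)
    if (spacer_len_range[2] > seq_len_range[1])
      stop("configuration error: spacer longer than target sequence", call. = FALSE)
    if (n_coabund > n_enriched + n_depleted)
      stop("configuration error: n_coabund exceeds planted signature count", call. = FALSE)
  })
  cfg
}

#' Planted truth implied by a configuration
#'
#' Deterministic mapping from a \code{virosig_config} to the planted
#' structure: signature identities and directions, host links,
#' bacterium-dependent vOTUs, family labels and AMG carriage. Does not
#' consume any randomness, so the truth is identical across seeds.
#'
#' @param config a [synth_config()] object.
#' @return list with \code{votu_ids}, \code{species_ids},
#'   \code{enriched_ids}, \code{depleted_ids}, \code{host_links}
#'   (data.frame votu_id/species_id), \code{coabund} (data.frame
#'   votu_id/species_id), \code{dependent_ids}, \code{family_of} (named
#'   character), \code{amg_of} (named list of KO sets).
#' @export
synth_truth <- function(config) {
  stopifnot(inherits(config, "virosig_config"))
  votus <- sprintf("vOTU_%04d", seq_len(config$n_votus))
  species <- sprintf("sp_%03d", seq_len(config$n_species))
  enriched <- votus[seq_len(config$n_enriched)]
  depleted <- votus[config$n_enriched + seq_len(config$n_depleted)]
  signatures <- c(enriched, depleted)

  # host links: cycle through signature vOTUs first, then the rest
  link_pool <- c(signatures, setdiff(votus, signatures))
  n_links <- config$n_host_links
  host_links <- if (n_links > 0L) {
    data.frame(
      votu_id = link_pool[((seq_len(n_links) - 1L) %% length(link_pool)) + 1L],
      species_id = species[((seq_len(n_links) - 1L) %% length(species)) + 1L],
      stringsAsFactors = FALSE)
  } else {
    data.frame(votu_id = character(), species_id = character(),
               stringsAsFactors = FALSE)
  }

  # co-abundant vOTUs: taken from the tail of the signature set so they
  # only partially overlap the host-linked ones
  coabund <- if (config$n_coabund > 0L) {
    cv <- rev(signatures)[seq_len(config$n_coabund)]
    data.frame(
      votu_id = cv,
      species_id = species[((seq_along(cv) - 1L) %% length(species)) + 1L],
      stringsAsFactors = FALSE)
  } else {
    data.frame(votu_id = character(), species_id = character(),
               stringsAsFactors = FALSE)
  }

  dependent <- union(intersect(host_links$votu_id, signatures), coabund$votu_id)

  # family labels: every fifth vOTU left unclassified, rest round-robin
  fam <- rep(NA_character_, config$n_votus)
  idx <- seq_len(config$n_votus)
  classified <- idx %% 5L != 0L
  fam[classified] <- config$family_palette[
    ((which(classified) - 1L) %% length(config$family_palette)) + 1L]
  fam[!classified] <- "unclassified"
  names(fam) <- votus

  # AMG carriage: enriched vOTUs draw from the back half of the palette,
  # depleted from the front half, giving differential occurrence rates
  np <- length(config$amg_palette)
  front <- config$amg_palette[seq_len(ceiling(np / 2))]
  back <- config$amg_palette[(ceiling(np / 2) + 1L):np]
  amg <- stats::setNames(vector("list", config$n_votus), votus)
  for (i in seq_along(enriched)) {
    if (i %% 3L != 0L)
      amg[[enriched[i]]] <- back[((i - 1L) %% length(back)) + 1L]
  }
  for (i in seq_along(depleted)) {
    if (i %% 2L != 0L)
      amg[[depleted[i]]] <- front[((i - 1L) %% length(front)) + 1L]
  }
  amg <- lapply(amg, function(x) if (is.null(x)) character() else x)

  list(votu_ids = votus, species_ids = species,
       enriched_ids = enriched, depleted_ids = depleted,
       host_links = host_links, coabund = coabund,
       dependent_ids = dependent, family_of = fam, amg_of = amg)
}

#' Generate per-cohort count matrices with planted effects
#'
#' Draws per-sample vOTU read counts by multinomial sampling at a
#' variable depth from heavy-tailed log-normal baseline proportions
#' (log-sd 1.5, mimicking the dominance structure of real gut viromes).
#' In cases, planted-enriched vOTU proportions are multiplied by
#' \code{effect_fold} and planted-depleted ones divided by it before
#' renormalisation. Bacterial species counts are generated alongside;
#' the planted co-abundant vOTUs inherit their partner species'
#' per-sample log-abundance deviations.
#'
#' @param config a [synth_config()] object.
#' @return list with \code{cohorts} (one element per cohort, each with
#'   \code{counts} and \code{species_counts} integer matrices
#'   (samples x features), \code{depth}, \code{species_depth} and a
#'   \code{meta} data.frame with cohort, group, sex, age, BMI, stage and
#'   protopathy) and \code{truth} (see [synth_truth()]).
#' @export
synth_community <- function(config) {
  stopifnot(inherits(config, "virosig_config"))
  truth <- synth_truth(config)
  n_votus <- config$n_votus
  n_species <- config$n_species

  # baseline shared across cohorts: same community, different people
  set.seed(substream_seed(config$seed, "baseline"))
  base_draw <- sort(stats::rnorm(n_votus, 0, 1.5), decreasing = TRUE)
  # planted signatures take the middle abundance ranks (below the
  # dominant members): the multiplicative effects then move only a small
  # share of the total mass, so renormalisation barely disturbs the
  # unplanted background
  n_sig <- config$n_enriched + config$n_depleted
  if (n_sig > 0L) {
    n_skip <- min(ceiling(0.3 * n_votus), n_votus - n_sig)
    base_log <- numeric(n_votus)
    sig_idx <- seq_len(n_sig)                     # planted ids come first
    base_log[sig_idx] <- base_draw[n_skip + seq_len(n_sig)]
    base_log[-sig_idx] <- base_draw[-(n_skip + seq_len(n_sig))]
  } else {
    base_log <- base_draw
  }
  species_base <- stats::rnorm(n_species, 0, 1)

  enr_idx <- match(truth$enriched_ids, truth$votu_ids)
  dep_idx <- match(truth$depleted_ids, truth$votu_ids)
  co_v <- match(truth$coabund$votu_id, truth$votu_ids)
  co_s <- match(truth$coabund$species_id, truth$species_ids)
  log_effect <- log(config$effect_fold)

  cohorts <- vector("list", config$n_cohorts)
  for (c in seq_len(config$n_cohorts)) {
    set.seed(substream_seed(config$seed, paste0("counts_", c)))
    n <- config$n_cases + config$n_controls
    group <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
    sample_ids <- sprintf("c%d_s%03d", c, seq_len(n))

    sp_log <- matrix(species_base, n, n_species, byrow = TRUE) +
      matrix(stats::rnorm(n * n_species, 0, 1), n, n_species)
    log_ab <- matrix(base_log, n, n_votus, byrow = TRUE) +
      matrix(stats::rnorm(n * n_votus, 0, config$sample_noise_sd), n, n_votus)
    # co-abundance coupling precedes the disease effect so that the
    # effect shifts cases without destroying the vOTU-species correlation
    if (length(co_v)) {
      dev <- sp_log[, co_s, drop = FALSE] -
        matrix(species_base[co_s], n, length(co_s), byrow = TRUE)
      log_ab[, co_v] <- matrix(base_log[co_v], n, length(co_v), byrow = TRUE) +
        dev + matrix(stats::rnorm(n * length(co_v), 0, config$coabund_noise_sd),
                     n, length(co_v))
    }
    is_case <- group == "case"
    log_ab[is_case, enr_idx] <- log_ab[is_case, enr_idx] + log_effect
    log_ab[is_case, dep_idx] <- log_ab[is_case, dep_idx] - log_effect

    depth <- sample(seq(config$depth_range[1], config$depth_range[2]), n,
                    replace = TRUE)
    sp_depth <- sample(seq(config$depth_range[1], config$depth_range[2]), n,
                       replace = TRUE)
    counts <- matrix(0L, n, n_votus,
                     dimnames = list(sample_ids, truth$votu_ids))
    sp_counts <- matrix(0L, n, n_species,
                        dimnames = list(sample_ids, truth$species_ids))
    for (i in seq_len(n)) {
      p <- exp(log_ab[i, ] - max(log_ab[i, ]))
      counts[i, ] <- as.integer(stats::rmultinom(1L, depth[i], p / sum(p)))
      q <- exp(sp_log[i, ] - max(sp_log[i, ]))
      sp_counts[i, ] <- as.integer(stats::rmultinom(1L, sp_depth[i], q / sum(q)))
    }

    set.seed(substream_seed(config$seed, paste0("meta_", c)))
    meta <- data.frame(
      sample_id = sample_ids,
      cohort = sprintf("cohort%d", c),
      group = group,
      sex = sample(c("F", "M"), n, replace = TRUE),
      age = round(stats::rnorm(n, 55, 10)),
      BMI = round(stats::rnorm(n, 24, 3), 1),
      stage = ifelse(is_case, sample(1:5, n, replace = TRUE), 0L),
      protopathy = ifelse(is_case,
                          sample(c("diabetes", "hypertension",
                                   "glomerulonephritis", "other"),
                                 n, replace = TRUE),
                          "none"),
      stringsAsFactors = FALSE)
    rownames(meta) <- sample_ids
    cohorts[[c]] <- list(counts = counts, species_counts = sp_counts,
                         depth = stats::setNames(depth, sample_ids),
                         species_depth = stats::setNames(sp_depth, sample_ids),
                         meta = meta)
  }
  names(cohorts) <- sprintf("cohort%d", seq_len(config$n_cohorts))
  list(cohorts = cohorts, truth = truth)
}

#' @keywords internal
#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @keywords internal
#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @keywords internal
#' @noRd
mutate_dna <- function(x, n_sub) {
  if (n_sub == 0L) return(x)
  v <- strsplit(x, "")[[1]]
  pos <- sample(seq_along(v), n_sub)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  paste(v, collapse = "")
}

#' @keywords internal
#' @noRd
blast6_row <- function(q, s, pident, len, qstart, qend, sstart, send, bitscore) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
             mismatch = round(len * (100 - pident) / 100), gapopen = 0L,
             qstart = qstart, qend = qend, sstart = sstart, send = send,
             evalue = 1e-20, bitscore = bitscore, stringsAsFactors = FALSE)
}

#' Generate sequence- and alignment-level evidence with planted signals
#'
#' Emits everything the catalogue, annotation and host-prediction stages
#' consume: viral sequence records (including BUSCO-contaminated decoys
#' and redundant near-duplicates for clustering), the sequences
#' themselves, a nucleotide alignment table in BLAST outfmt-6 layout,
#' CRISPR spacer records (planted full-length matches for host links
#' plus decoys below the bit-score threshold), vOTU-to-genome homology
#' hits (planted above and decoys below the 90\%/30\% rule), per-vOTU
#' protein best-hit tables realising the planted family compositions and
#' AMG carriage, and a toy species taxonomy.
#'
#' For each planted host link, spacer evidence (exact full-length
#' substring, random strand) and homology evidence (92\% identity over
#' 35\% of the vOTU) alternate deterministically.
#'
#' @param config a [synth_config()] object.
#' @param truth planted truth from [synth_truth()] or [synth_community()].
#' @return list with \code{records}, \code{sequences}
#'   (\code{Biostrings::DNAStringSet}), \code{nucl_hits}, \code{spacers},
#'   \code{genome_hits}, \code{genome2species}, \code{taxonomy},
#'   \code{protein_hits} and \code{votu_proteins}.
#' @export
synth_evidence <- function(config, truth = synth_truth(config)) {
  stopifnot(inherits(config, "virosig_config"))
  set.seed(substream_seed(config$seed, "sequences"))
  votus <- truth$votu_ids
  lens <- sample(seq(config$seq_len_range[1], config$seq_len_range[2]),
                 length(votus), replace = TRUE)
  seqs <- vapply(lens, random_dna, character(1))
  names(seqs) <- votus

  n_genes <- pmax(3L, as.integer(round(lens / 1000)))
  completeness <- ifelse(stats::runif(length(votus)) < 0.25,
                         stats::runif(length(votus), 90.5, 100),
                         ifelse(stats::runif(length(votus)) < 0.2,
                                stats::runif(length(votus), 50, 90),
                                stats::runif(length(votus), 0, 49)))
  completeness[sample(seq_along(votus), max(1L, length(votus) %/% 10))] <- NA
  records <- data.frame(
    id = votus, length = lens, n_genes = n_genes,
    # clean viral sequences: BUSCO ratio stays below the 5% removal rule
    n_busco = pmax(0L, ceiling(n_genes * 0.05) - 1L) *
      (stats::runif(length(votus)) < 0.2),
    completeness = completeness,
    is_provirus = seq_along(votus) %% 7L == 0L,
    stringsAsFactors = FALSE)

  # contaminated decoy records (BUSCO ratio >= 5%)
  set.seed(substream_seed(config$seed, "decoy_records"))
  nc <- config$n_contaminants
  contam <- data.frame(
    id = sprintf("contam_%03d", seq_len(nc)),
    length = sample(5000:7000, nc, replace = TRUE),
    n_genes = rep(20L, nc),
    n_busco = sample(1:6, nc, replace = TRUE),
    completeness = NA_real_, is_provirus = FALSE, stringsAsFactors = FALSE)
  contam_seqs <- vapply(contam$length, random_dna, character(1))
  names(contam_seqs) <- contam$id

  # redundant near-duplicates of the first n_duplicates vOTUs
  nd <- min(config$n_duplicates, length(votus))
  dup_parent <- votus[seq_len(nd)]
  dup_ids <- sprintf("dup_%s", dup_parent)
  nucl_hits <- list()
  dup_seqs <- character(0)
  dup_rec <- list()
  for (k in seq_len(nd)) {
    par <- dup_parent[k]
    plen <- nchar(seqs[[par]])
    dlen <- max(5000L, as.integer(round(plen * 0.8)))
    off <- sample(0:(plen - dlen), 1L)
    dseq <- mutate_dna(substr(seqs[[par]], off + 1L, off + dlen),
                       as.integer(round(dlen * 0.02)))
    dup_seqs[dup_ids[k]] <- dseq
    dup_rec[[k]] <- data.frame(id = dup_ids[k], length = dlen,
                               n_genes = max(3L, dlen %/% 1000), n_busco = 0L,
                               completeness = NA_real_, is_provirus = FALSE,
                               stringsAsFactors = FALSE)
    nucl_hits[[length(nucl_hits) + 1L]] <-
      blast6_row(dup_ids[k], par, 98, dlen, 1L, dlen, off + 1L, off + dlen,
                 2 * dlen)
  }
  # decoy alignment pairs below the clustering thresholds
  if (length(votus) >= 4L) {
    a <- votus[length(votus) - 1L]; b <- votus[length(votus)]
    la <- nchar(seqs[[a]]); lb <- nchar(seqs[[b]])
    short <- min(la, lb)
    nucl_hits[[length(nucl_hits) + 1L]] <-                     # coverage too low
      blast6_row(a, b, 97, as.integer(short * 0.5), 1L, as.integer(short * 0.5),
                 1L, as.integer(short * 0.5), short)
    a2 <- votus[length(votus) - 3L]; b2 <- votus[length(votus) - 2L]
    short2 <- min(nchar(seqs[[a2]]), nchar(seqs[[b2]]))
    nucl_hits[[length(nucl_hits) + 1L]] <-                     # identity too low
      blast6_row(a2, b2, 80, as.integer(short2 * 0.9), 1L,
                 as.integer(short2 * 0.9), 1L, as.integer(short2 * 0.9), short2)
  }
  nucl_hits <- do.call(rbind, nucl_hits)

  records <- rbind(records, contam, do.call(rbind, dup_rec))
  all_seqs <- c(seqs, contam_seqs, dup_seqs)

  # CRISPR spacers: planted full-length matches + sub-threshold decoys
  set.seed(substream_seed(config$seed, "spacers"))
  spacers <- list()
  genome_hits <- list()
  links <- truth$host_links
  if (nrow(links)) {
    for (k in seq_len(nrow(links))) {
      v <- links$votu_id[k]; s <- links$species_id[k]
      if (k %% 2L == 1L) {                      # CRISPR evidence
        L <- sample(seq(config$spacer_len_range[1], config$spacer_len_range[2]), 1L)
        vlen <- nchar(seqs[[v]])
        pos <- sample(seq_len(vlen - L + 1L), 1L)
        sp <- substr(seqs[[v]], pos, pos + L - 1L)
        if (stats::runif(1) < 0.5) sp <- revcomp_chr(sp)
        spacers[[length(spacers) + 1L]] <- data.frame(
          spacer_id = sprintf("spc_link_%03d", k), species_id = s,
          sequence = sp, stringsAsFactors = FALSE)
      } else {                                  # homology evidence
        vlen <- nchar(seqs[[v]])
        span <- as.integer(round(vlen * 0.35))
        genome_hits[[length(genome_hits) + 1L]] <-
          blast6_row(v, sprintf("gen_%s_1", s), 92, span, 1L, span,
                     1L, span, span)
      }
    }
  }
  # decoys: short exact spacers (full-length match but bit score < 45)
  # and random spacers that match nothing
  n_decoy <- max(4L, length(votus) %/% 20L)
  decoy_votus <- votus[seq(length(votus), by = -1L, length.out = n_decoy)]
  for (k in seq_len(n_decoy)) {
    v <- decoy_votus[k]
    pos <- sample(seq_len(nchar(seqs[[v]]) - 18L), 1L)
    spacers[[length(spacers) + 1L]] <- data.frame(
      spacer_id = sprintf("spc_short_%03d", k),
      species_id = truth$species_ids[((k - 1L) %% length(truth$species_ids)) + 1L],
      sequence = substr(seqs[[v]], pos, pos + 17L), stringsAsFactors = FALSE)
    spacers[[length(spacers) + 1L]] <- data.frame(
      spacer_id = sprintf("spc_rand_%03d", k),
      species_id = truth$species_ids[((k) %% length(truth$species_ids)) + 1L],
      sequence = random_dna(32L), stringsAsFactors = FALSE)
  }
  spacers <- do.call(rbind, spacers)

  # homology decoys: coverage below 30% or identity below 90%
  for (k in seq_len(min(4L, length(votus)))) {
    v <- votus[k + config$n_enriched]          # not a planted homology link
    vlen <- nchar(seqs[[v]])
    genome_hits[[length(genome_hits) + 1L]] <-
      blast6_row(v, sprintf("gen_%s_1", truth$species_ids[k]), 93,
                 as.integer(vlen * 0.15), 1L, as.integer(vlen * 0.15),
                 1L, as.integer(vlen * 0.15), vlen)
    genome_hits[[length(genome_hits) + 1L]] <-
      blast6_row(v, sprintf("gen_%s_2", truth$species_ids[k]), 84,
                 as.integer(vlen * 0.5), 1L, as.integer(vlen * 0.5),
                 1L, as.integer(vlen * 0.5), vlen)
  }
  genome_hits <- if (length(genome_hits)) do.call(rbind, genome_hits) else
    blast6_row(character(), character(), numeric(), integer(), integer(),
               integer(), integer(), integer(), numeric())[0, ]

  genome_ids <- unique(genome_hits$sseqid)
  genome2species <- data.frame(
    genome_id = genome_ids,
    species_id = sub("^gen_(sp_[0-9]+)_[0-9]+$", "\\1", genome_ids),
    stringsAsFactors = FALSE)

  taxonomy <- data.frame(
    species_id = truth$species_ids,
    genus = sprintf("Genus_%02d", seq_along(truth$species_ids)),
    family = sprintf("Fam_%02d", ((seq_along(truth$species_ids) - 1L) %% 8L) + 1L),
    phylum = sprintf("Phylum_%d", ((seq_along(truth$species_ids) - 1L) %% 4L) + 1L),
    stringsAsFactors = FALSE)

  # protein best-hit rows realising planted family fractions and AMGs
  set.seed(substream_seed(config$seed, "proteins"))
  prot <- list()
  n_prot <- stats::setNames(rep(10L, length(votus)), votus)
  other_fams <- config$family_palette
  for (v in votus) {
    fam <- truth$family_of[[v]]
    pid <- sprintf("%s_p%02d", v, seq_len(n_prot[[v]]))
    if (!identical(fam, "unclassified")) {
      # 5/10 proteins hit the planted family, 2 hit a decoy family
      decoy <- sample(setdiff(other_fams, fam), 1L)
      fams <- c(rep(fam, 5L), rep(decoy, 2L))
      prot[[length(prot) + 1L]] <- data.frame(
        protein_id = pid[1:7], votu_id = v,
        subject_id = sprintf("ref_%s", seq_len(7L)),
        family = fams, ko = NA_character_,
        bitscore = stats::runif(7, 60, 120), stringsAsFactors = FALSE)
    } else {
      # scattered hits, none above the 25% voting threshold
      fams <- sample(other_fams, 2L)
      prot[[length(prot) + 1L]] <- data.frame(
        protein_id = pid[1:2], votu_id = v,
        subject_id = sprintf("ref_%s", seq_len(2L)),
        family = fams, ko = NA_character_,
        bitscore = stats::runif(2, 60, 120), stringsAsFactors = FALSE)
    }
    amgs <- truth$amg_of[[v]]
    if (length(amgs)) {
      prot[[length(prot) + 1L]] <- data.frame(
        protein_id = sprintf("%s_amg%02d", v, seq_along(amgs)), votu_id = v,
        subject_id = sprintf("kegg_%s", amgs), family = NA_character_,
        ko = amgs, bitscore = stats::runif(length(amgs), 80, 150),
        stringsAsFactors = FALSE)
      n_prot[[v]] <- n_prot[[v]] + length(amgs)
    }
    # a non-AMG KO on one housekeeping-like protein
    prot[[length(prot) + 1L]] <- data.frame(
      protein_id = pid[n_prot[[v]] - length(amgs)], votu_id = v,
      subject_id = "kegg_other", family = NA_character_,
      ko = sprintf("K9%04d", sample(0:9999, 1L)),
      bitscore = stats::runif(1, 60, 90), stringsAsFactors = FALSE)
  }
  protein_hits <- do.call(rbind, prot)
  votu_proteins <- data.frame(votu_id = votus, n_proteins = as.integer(n_prot),
                              stringsAsFactors = FALSE)

  list(records = records,
       sequences = Biostrings::DNAStringSet(all_seqs),
       nucl_hits = nucl_hits, spacers = spacers,
       genome_hits = genome_hits, genome2species = genome2species,
       taxonomy = taxonomy, protein_hits = protein_hits,
       votu_proteins = votu_proteins)
}

#' Compositional counts with planted log-scale correlations
#'
#' Generates a samples x features count matrix for correlation-inference
#' tests: feature log-abundances are standard normal, except planted
#' pairs which are bivariate normal with the requested correlation;
#' counts are multinomial at fixed depth.
#'
#' @param n_samples,n_features matrix dimensions.
#' @param depth reads per sample.
#' @param planted data.frame with columns \code{i}, \code{j}, \code{rho}
#'   (feature indices and target log-scale correlation); may be empty.
#' @param mean_log,sd_log baseline log-abundance distribution.
#' @param seed integer seed.
#' @return integer matrix of counts.
#' @export
synth_sparcc_counts <- function(n_samples = 200L, n_features = 30L,
                                depth = 50000L,
                                planted = data.frame(i = integer(),
                                                     j = integer(),
                                                     rho = numeric()),
                                mean_log = 0, sd_log = 1, seed = 1L) {
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n_samples * n_features, mean_log, sd_log),
              n_samples, n_features)
  if (nrow(planted)) {
    for (k in seq_len(nrow(planted))) {
      i <- planted$i[k]; j <- planted$j[k]; rho <- planted$rho[k]
      z[, j] <- rho * scale(z[, i])[, 1] * sd_log +
        sqrt(1 - rho^2) * stats::rnorm(n_samples, 0, sd_log) + mean_log
    }
  }
  counts <- t(apply(z, 1L, function(row) {
    p <- exp(row - max(row))
    as.integer(stats::rmultinom(1L, depth, p / sum(p)))
  }))
  dimnames(counts) <- list(sprintf("s%03d", seq_len(n_samples)),
                           sprintf("f%03d", seq_len(n_features)))
  counts
}
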
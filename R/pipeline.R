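#' Demo pipeline settings
#'
#' A small configuration that exercises every stage end-to-end in well
#' under a minute: 40 vOTUs, 10 species, two cohorts of 20 + 20
#' samples, 8 + 8 planted signatures at fold 3, ~10k reads per sample
#' rarefied to 4k, reduced permutation counts.
#'
#' @param seed integer root seed.
#' @return list with elements \code{config} (a [synth_config()]) and
#'   \code{options} (run options for [run_pipeline()]).
#' @export
demo_pipeline_config <- function(seed = 1L) {
  list(config = synth_config(seed = seed, n_votus = 40L, n_species = 10L,
                             n_cases = 20L, n_controls = 20L,
                             n_enriched = 8L, n_depleted = 8L,
                             n_host_links = 8L, n_coabund = 4L,
                             depth_range = c(8000L, 12000L),
                             n_contaminants = 4L, n_duplicates = 4L),
       options = list(rarefaction_depth = 4000L, n_perm = 199L,
                      sparcc_boot = 50L, rf_repeats = 5L))
}

#' Run the full virome-signature pipeline on synthetic data
#'
#' Chains every stage in order: synthetic-data generation, catalogue
#' construction (BUSCO decontamination, species-level clustering,
#' completeness tiers), family/KO/AMG annotation, virus-host prediction
#' (CRISPR + homology), rarefied profiling (diversity, Bray-Curtis,
#' PCoA, PERMANOVA with the sex + age + BMI + group formula),
#' two-cohort differential-abundance meta-analysis, the
#' bacterium-dependency network (SparCC, co-occurrence, host links) and
#' the transfer analysis treating the second cohort as external
#' (consistency rate with permutation test, detection rate, gross
#' abundances, random-forest classification).
#'
#' All randomness derives from \code{config$seed} through named
#' substreams; rerunning with the same configuration reproduces every
#' output bit for bit.
#'
#' @param config a [synth_config()] object.
#' @param out_dir optional directory; when given, every stage's tables
#'   and the effective configuration (JSON) are written there.
#' @param rarefaction_depth subsampling depth for profiling (default
#'   20000 for the default configuration's depth range).
#' @param min_fold,max_q,max_combined_p signature thresholds (defaults
#'   1.2, 0.2, 0.001).
#' @param sparcc_r_min,sparcc_q_max,cooccur_q_max dependency-network
#'   thresholds (defaults 0.60, 0.001, 0.001).
#' @param n_perm permutations for PERMANOVA and the consistency test
#'   (default 1000).
#' @param sparcc_boot SparCC bootstrap count (default 100; the full
#'   1000 is intended for standalone [sparcc_pvalues()] runs).
#' @param rf_repeats random-forest split repeats (default 10).
#' @return (invisibly) a named list bundle with each stage's results.
#' @export
run_pipeline <- function(config = synth_config(), out_dir = NULL,
                         rarefaction_depth = 20000L,
                         min_fold = 1.2, max_q = 0.2, max_combined_p = 0.001,
                         sparcc_r_min = 0.60, sparcc_q_max = 0.001,
                         cooccur_q_max = 0.001, n_perm = 1000L,
                         sparcc_boot = 100L, rf_repeats = 10L) {
  stopifnot(inherits(config, "virosig_config"))
  log_stage <- function(...) message("[virosig] ", sprintf(...))

  # --- synthesis -------------------------------------------------------
  comm <- synth_community(config)
  truth <- comm$truth
  ev <- synth_evidence(config, truth)
  log_stage("synth: %d vOTUs, %d species, %d cohorts",
            config$n_votus, config$n_species, config$n_cohorts)

  # --- catalogue -------------------------------------------------------
  kept <- busco_filter(ev$records)
  log_stage("catalog: BUSCO filter kept %d / %d records",
            nrow(kept), nrow(ev$records))
  hits_kept <- ev$nucl_hits[ev$nucl_hits$qseqid %in% kept$id &
                              ev$nucl_hits$sseqid %in% kept$id, , drop = FALSE]
  clusters <- cluster_votus(hits_kept, kept)
  reps <- unique(clusters$representative_id)
  tiers <- completeness_tiers(kept[kept$id %in% reps, , drop = FALSE])
  log_stage("catalog: %d clusters from %d records", length(reps), nrow(kept))

  # --- annotation ------------------------------------------------------
  fam_assign <- assign_family(ev$protein_hits, ev$votu_proteins)
  vote_acc <- benchmark_voting(fam_assign, truth$family_of)
  ko <- annotate_ko(ev$protein_hits, amg_panel("amg"),
                    votu_ids = truth$votu_ids)
  log_stage("annotate: family voting accuracy %.3f on %d classified vOTUs",
            vote_acc, sum(fam_assign$family != "unclassified"))

  # --- host prediction -------------------------------------------------
  votu_seqs <- ev$sequences[truth$votu_ids]
  crispr <- match_spacers(ev$spacers, votu_seqs)
  votu_lengths <- stats::setNames(Biostrings::width(votu_seqs),
                                  names(votu_seqs))
  hom <- homology_links(ev$genome_hits, ev$genome2species, votu_lengths)
  host_links <- rbind(crispr, hom)
  hr <- host_range_summary(host_links, ev$taxonomy)
  log_stage("hostlink: %d crispr + %d homology links (%d vOTUs annotated)",
            nrow(crispr), nrow(hom), hr$n_annotated)

  # --- profiling per cohort -------------------------------------------
  fam_map <- stats::setNames(fam_assign$family, fam_assign$votu_id)
  profiles <- lapply(seq_along(comm$cohorts), function(ci) {
    co <- comm$cohorts[[ci]]
    rare <- rarefy_counts(co$counts, rarefaction_depth,
                          seed = substream_seed(config$seed,
                                                paste0("rarefy_", ci)))
    meta <- co$meta[rownames(rare), , drop = FALSE]
    rel <- relative_abundance(rare, rarefaction_depth)
    alpha <- alpha_diversity(rel)
    alpha_p <- compare_alpha(alpha, meta$group)
    bc <- bray_curtis(rel)
    ord <- pcoa_ord(bc, k = 2L)
    pmv <- permanova(bc, meta, c("sex", "age", "BMI", "group"),
                     n_perm = n_perm,
                     seed = substream_seed(config$seed,
                                           paste0("permanova_", ci)))
    rates <- mapping_rates(co$counts, co$depth, fam_map)
    list(rarefied = rare, rel = rel, family_rel = family_rollup(rel, fam_map),
         alpha = alpha, alpha_p = alpha_p, pcoa = ord, permanova = pmv,
         mapping = rates, meta = meta)
  })
  names(profiles) <- names(comm$cohorts)
  log_stage("profile: rarefied to %d reads; PERMANOVA group R2 = %.3f (cohort 1)",
            rarefaction_depth,
            profiles[[1]]$permanova$R2[profiles[[1]]$permanova$term == "group"])

  # --- differential abundance meta-analysis ---------------------------
  if (length(profiles) < 2L)
    stop("the meta-analysis requires two cohorts", call. = FALSE)
  res1 <- cohort_test(profiles[[1]]$rel, profiles[[1]]$meta$group)
  res2 <- cohort_test(profiles[[2]]$rel, profiles[[2]]$meta$group)
  sig <- select_signatures(res1, res2, min_fold = min_fold, max_q = max_q,
                           max_combined_p = max_combined_p)
  signatures <- sig[sig$is_signature, , drop = FALSE]
  adj <- adjust_covariates(
    profiles[[1]]$rel[, signatures$votu_id, drop = FALSE],
    profiles[[1]]$meta$group,
    profiles[[1]]$meta[, c("sex", "age", "BMI")])
  log_stage("diffabund: %d signature vOTUs (%d case-enriched, %d control-enriched)",
            nrow(signatures), sum(signatures$direction == "case"),
            sum(signatures$direction == "control"))

  # --- dependency network ---------------------------------------------
  network <- NULL
  if (nrow(signatures)) {
    co1 <- comm$cohorts[[1]]
    shared <- rownames(profiles[[1]]$rarefied)
    comb <- cbind(co1$counts[shared, , drop = FALSE],
                  co1$species_counts[shared, , drop = FALSE])
    r_all <- sparcc(comb)
    pq <- sparcc_pvalues(comb, r_all, n_boot = sparcc_boot,
                         seed = substream_seed(config$seed, "sparcc_boot"))
    sp_ids <- colnames(co1$species_counts)
    r_vs <- r_all[signatures$votu_id, sp_ids, drop = FALSE]
    q_vs <- pq$q[signatures$votu_id, sp_ids, drop = FALSE]
    coocc <- cooccurrence(
      profiles[[1]]$rarefied[, signatures$votu_id, drop = FALSE],
      co1$species_counts[shared, , drop = FALSE])
    dep <- classify_dependency(signatures$votu_id, host_links,
                               sparcc_r = r_vs, sparcc_q = q_vs,
                               cooccur = coocc, r_min = sparcc_r_min,
                               q_max = sparcc_q_max,
                               cooccur_q_max = cooccur_q_max)
    amg_cmp <- amg_occurrence_compare(
      ko$amg_sets,
      signatures$votu_id[signatures$direction == "case"],
      signatures$votu_id[signatures$direction == "control"])
    nad_cmp <- amg_occurrence_compare(
      ko$amg_sets,
      signatures$votu_id[signatures$direction == "case"],
      signatures$votu_id[signatures$direction == "control"],
      panel = amg_panel("nad"))
    network <- list(sparcc_r = r_all, sparcc_q = pq$q, cooccurrence = coocc,
                    dependency = dep, amg_compare = amg_cmp,
                    nad_compare = nad_cmp)
    log_stage("network: %d dependent / %d independent signature vOTUs",
              sum(dep$labels$label == "dependent"),
              sum(dep$labels$label == "independent"))
  }

  # --- transfer to the external (second) cohort -----------------------
  transfer <- NULL
  if (nrow(signatures)) {
    dirs <- stats::setNames(signatures$direction, signatures$votu_id)
    ext <- profiles[[2]]
    cons <- consistency_permutation_test(
      ext$rel, ext$meta$group, dirs, n_perm = n_perm,
      seed = substream_seed(config$seed, "transfer_perm"))
    det <- detection_rate(comm$cohorts[[2]]$counts, signatures$votu_id)
    gross <- gross_abundance_compare(
      ext$rel, ext$meta$group,
      signatures$votu_id[signatures$direction == "case"],
      signatures$votu_id[signatures$direction == "control"])
    rf <- rf_transfer(profiles[[1]]$rel[, signatures$votu_id, drop = FALSE],
                      profiles[[1]]$meta$group, repeats = rf_repeats,
                      seed = substream_seed(config$seed, "rf"),
                      eval_rel = ext$rel[, signatures$votu_id, drop = FALSE],
                      eval_group = ext$meta$group)
    transfer <- list(consistency = cons, detection_rate = det,
                     gross = gross, rf = rf)
    log_stage("transfer: consistency %.3f (p = %.4g), within-cohort AUC %.3f, cross AUC %.3f",
              cons$rate, cons$permutation_p, rf$mean_auc, rf$cross_auc)
  }

  bundle <- list(config = config, truth = truth, evidence = ev,
                 community = comm,
                 catalog = list(kept = kept, clusters = clusters,
                                tiers = tiers,
                                representatives = reps),
                 annotation = list(families = fam_assign,
                                   voting_accuracy = vote_acc, ko = ko),
                 hostlink = list(links = host_links, range = hr),
                 profiles = profiles,
                 diffabund = list(cohort1 = res1, cohort2 = res2,
                                  table = sig, signatures = signatures,
                                  adjusted = adj),
                 network = network, transfer = transfer,
                 options = list(rarefaction_depth = rarefaction_depth,
                                min_fold = min_fold, max_q = max_q,
                                max_combined_p = max_combined_p,
                                sparcc_r_min = sparcc_r_min,
                                sparcc_q_max = sparcc_q_max,
                                cooccur_q_max = cooccur_q_max,
                                n_perm = n_perm, sparcc_boot = sparcc_boot,
                                rf_repeats = rf_repeats))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

# Serialise the pipeline bundle as TSV/FASTA/JSON files.
#' @keywords internal
#' @noRd
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  cfg <- bundle$config
  jsonlite::write_json(
    c(unclass(cfg), bundle$options), fp("config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_fasta(bundle$evidence$sequences, fp("sequences.fasta"))
  write_hits_tsv(bundle$evidence$nucl_hits, fp("nucl_hits.tsv"))
  write_report_tsv(bundle$evidence$spacers, fp("spacers.tsv"))
  write_report_tsv(bundle$catalog$clusters, fp("clusters.tsv"))
  write_report_tsv(bundle$annotation$families, fp("families.tsv"))
  write_report_tsv(bundle$hostlink$links, fp("host_links.tsv"))
  for (ci in seq_along(bundle$profiles)) {
    pr <- bundle$profiles[[ci]]
    write_counts_tsv(bundle$community$cohorts[[ci]]$counts,
                     fp(sprintf("counts_cohort%d.tsv", ci)))
    write_report_tsv(cbind(sample_id = rownames(pr$alpha), pr$alpha),
                     fp(sprintf("alpha_cohort%d.tsv", ci)))
    write_report_tsv(pr$permanova, fp(sprintf("permanova_cohort%d.tsv", ci)))
    write_report_tsv(bundle$community$cohorts[[ci]]$meta,
                     fp(sprintf("metadata_cohort%d.tsv", ci)))
  }
  write_report_tsv(bundle$diffabund$table, fp("signatures.tsv"))
  if (!is.null(bundle$network)) {
    write_report_tsv(bundle$network$dependency$edges, fp("network_edges.tsv"))
    write_report_tsv(bundle$network$dependency$labels, fp("dependency.tsv"))
    write_report_tsv(bundle$network$amg_compare, fp("amg_occurrence.tsv"))
  }
  if (!is.null(bundle$transfer)) {
    tr <- bundle$transfer
    write_report_tsv(
      data.frame(consistency_rate = tr$consistency$rate,
                 n_evaluable = tr$consistency$n_evaluable,
                 permutation_p = tr$consistency$permutation_p,
                 detection_rate = tr$detection_rate,
                 mean_auc = tr$rf$mean_auc, cross_auc = tr$rf$cross_auc),
      fp("transfer_report.tsv"))
    write_report_tsv(tr$gross, fp("gross_abundance.tsv"))
  }
  invisible(out_dir)
}
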
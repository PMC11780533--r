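test_that("spacer bit scores follow the Karlin-Altschul conversion", {
  set.seed(31)
  target <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  sp32 <- substr(target, 101, 132)
  sp20 <- substr(target, 201, 220)
  seqs <- Biostrings::DNAStringSet(c(v1 = target))
  spc <- data.frame(spacer_id = c("a", "b"), species_id = c("sp1", "sp2"),
                    sequence = c(sp32, sp20), stringsAsFactors = FALSE)
  links <- match_spacers(spc, seqs)
  # 32-nt perfect match: (1.28*32 - ln 0.46)/ln 2 = 60.2 bits >= 45
  expect_identical(links$species_id, "sp1")
  expect_equal(links$score, (1.28 * 32 - log(0.46)) / log(2), tolerance = 1e-9)
  # 20-nt perfect match only reaches 38.1 bits
  expect_false("sp2" %in% links$species_id)
})

test_that("a match must span the entire spacer", {
  set.seed(32)
  base <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  spacer <- paste(sample(c("A", "C", "G", "T"), 32, TRUE), collapse = "")
  # the sequence ends with only the first 30 nt of the spacer
  target <- paste0(base, substr(spacer, 1, 30))
  links <- match_spacers(
    data.frame(spacer_id = "s", species_id = "sp1", sequence = spacer),
    Biostrings::DNAStringSet(c(v1 = target)))
  expect_identical(nrow(links), 0L)
})

test_that("spacer matching is reverse-complement invariant", {
  set.seed(33)
  target <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  sp <- substr(target, 50, 85)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sp)))
  seqs <- Biostrings::DNAStringSet(c(v1 = target))
  fwd <- match_spacers(data.frame(spacer_id = "f", species_id = "sp1",
                                  sequence = sp), seqs)
  rev <- match_spacers(data.frame(spacer_id = "r", species_id = "sp1",
                                  sequence = rc), seqs)
  expect_equal(fwd$score, rev$score)
})

test_that("invalid spacer alphabets are rejected and N counts as mismatch", {
  seqs <- Biostrings::DNAStringSet(c(v1 = strrep("ACGT", 100)))
  expect_error(match_spacers(
    data.frame(spacer_id = "s", species_id = "x", sequence = "ACGU-ACGT"),
    seqs), "non-ACGTN")
  # a 32-nt spacer with 2 Ns still passes (2 mismatches: 26*1 - 2*2 ... )
  sp <- paste0(strrep("ACGT", 8))
  spN <- paste0(substr(sp, 1, 30), "NN")
  links <- match_spacers(
    data.frame(spacer_id = "s", species_id = "x", sequence = spN),
    Biostrings::DNAStringSet(c(v1 = paste0(strrep("TTGCA", 40), sp))))
  expect_identical(nrow(links), 1L)
  perfect <- (1.28 * 32 - log(0.46)) / log(2)
  expect_equal(links$score, perfect - 1.28 * 6 / log(2), tolerance = 1e-9)
})

test_that("homology links require 90% identity over 30% merged coverage", {
  g2s <- data.frame(genome_id = c("g1", "g2"), species_id = c("spA", "spA"),
                    stringsAsFactors = FALSE)
  lens <- c(v1 = 10000L)
  row <- function(pident, qstart, qend, genome = "g1")
    data.frame(qseqid = "v1", sseqid = genome, pident = pident,
               length = qend - qstart + 1L, mismatch = 0L, gapopen = 0L,
               qstart = qstart, qend = qend, sstart = 1L,
               send = qend - qstart + 1L, evalue = 0, bitscore = 1)
  # single hit, 92% identity, 35% of the vOTU
  expect_identical(nrow(homology_links(row(92, 1L, 3500L), g2s, lens)), 1L)
  # 95% identity but 20% coverage
  expect_identical(nrow(homology_links(row(95, 1L, 2000L), g2s, lens)), 0L)
  # two disjoint 91% hits of 15% + 20% merge to 35% across genomes
  two <- rbind(row(91, 1L, 1500L, "g1"), row(91, 5001L, 7000L, "g2"))
  res <- homology_links(two, g2s, lens)
  expect_identical(res$species_id, "spA")
  expect_equal(res$score, 0.35)
  expect_error(homology_links(row(92, 1L, 3500L, "gX"),
                              g2s[1, ], lens), "unknown genome")
})

test_that("host range summary counts multi-family and multi-phylum vOTUs", {
  tax <- data.frame(species_id = c("s1", "s2", "s3"),
                    family = c("F1", "F1", "F2"),
                    phylum = c("P1", "P1", "P2"), stringsAsFactors = FALSE)
  links <- data.frame(votu_id = c("v1", "v2", "v2", "v3", "v3"),
                      species_id = c("s1", "s1", "s2", "s1", "s3"),
                      stringsAsFactors = FALSE)
  hr <- host_range_summary(links, tax)
  expect_identical(hr$n_annotated, 3L)
  # v1 single; v2 two species one family; v3 spans families and phyla
  expect_equal(unname(hr$fractions["multi_species"]), 2 / 3)
  expect_equal(unname(hr$fractions["multi_family"]), 1 / 3)
  expect_equal(unname(hr$fractions["multi_phylum"]), 1 / 3)
})

test_that("planted links are recovered and decoys rejected on synthetic data", {
  cfg <- tiny_config(seed = 12)
  truth <- synth_truth(cfg)
  ev <- synth_evidence(cfg, truth)
  crispr <- match_spacers(ev$spacers, ev$sequences[truth$votu_ids])
  lens <- setNames(Biostrings::width(ev$sequences[truth$votu_ids]),
                   truth$votu_ids)
  hom <- homology_links(ev$genome_hits, ev$genome2species, lens)
  got <- unique(rbind(crispr[, c("votu_id", "species_id")],
                      hom[, c("votu_id", "species_id")]))
  want <- unique(truth$host_links)
  expect_setequal(paste(got$votu_id, got$species_id),
                  paste(want$votu_id, want$species_id))
})
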
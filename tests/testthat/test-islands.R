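toy_contigs <- function() {
  data.frame(
    genome = "G1", contig_id = c("c40", "c15"),
    length = c(40000, 15000)
  )
}

pii_hit <- function(start, end, evalue = 1e-20, contig = "c40",
                    genome = "G1", id = "p1") {
  data.frame(
    query_id = "PII", genome = genome, contig_id = contig,
    start = start, end = end, strand = "+", evalue = evalue,
    subject_protein_id = id
  )
}

test_that("genome dereplication follows the stated priority order", {
  metas <- data.frame(
    assembly_accession = c("B", "A", "C", "D", "E"),
    species_taxid = c(1, 1, 1, 2, 2),
    assembly_level = c("complete", "contig", "scaffold", "contig", "contig"),
    refseq_category = c("na", "type strain", "na", "na", "na"),
    taxid = 1:5
  )
  sel <- dedupe_genomes(metas)
  # species 1: the type strain beats the complete assembly
  expect_identical(sel$assembly_accession[sel$species_taxid == 1], "A")
  # species 2: level tie broken by lexicographic accession
  expect_identical(sel$assembly_accession[sel$species_taxid == 2], "D")
  # one genome per species already: identity
  expect_identical(nrow(dedupe_genomes(sel)), 2L)
  # brute-force oracle on a 3-way tie
  tie <- data.frame(
    assembly_accession = c("Z9", "M5", "A1"), species_taxid = 7,
    assembly_level = "contig", refseq_category = "na"
  )
  expect_identical(dedupe_genomes(tie)$assembly_accession, "A1")
  # result is input-order independent
  sel2 <- dedupe_genomes(metas[sample(nrow(metas)), ])
  expect_identical(
    sort(sel$assembly_accession), sort(sel2$assembly_accession)
  )
})

test_that("island calling applies flank geometry and e-value rules", {
  # interior hit: window is hit span +/- flank
  isl <- call_islands(pii_hit(15000, 15300), toy_contigs())
  expect_identical(nrow(isl), 1L)
  expect_identical(isl$window_start, 5000)
  expect_identical(isl$window_end, 25300)
  # hit 4 kb from the contig start: window truncated, discarded
  edge <- call_islands(pii_hit(4000, 4300), toy_contigs())
  expect_identical(nrow(edge), 0L)
  expect_identical(
    attr(edge, "discarded")$reason, "window_truncated_by_contig_edge"
  )
  # a contig too short to hold 20 kb can never yield an island
  short <- call_islands(
    pii_hit(7000, 7300, contig = "c15"), toy_contigs()
  )
  expect_identical(nrow(short), 0L)
  # e-value exactly at the threshold is retained; above it discarded
  at <- call_islands(pii_hit(15000, 15300, evalue = 1e-5), toy_contigs())
  expect_identical(nrow(at), 1L)
  above <- call_islands(
    pii_hit(15000, 15300, evalue = 1.0000001e-5), toy_contigs()
  )
  expect_identical(nrow(above), 0L)
  expect_identical(
    attr(above, "discarded")$reason, "evalue_above_threshold"
  )
  # unknown contig is a referential error
  expect_error(
    call_islands(pii_hit(1, 300, contig = "missing"), toy_contigs()),
    "unknown contig"
  )
})

test_that("pairing enforces the strict 2000-bp midpoint rule", {
  contigs <- data.frame(genome = "G1", contig_id = "c", length = 60000)
  isl <- call_islands(pii_hit(19900, 20100, contig = "c"), contigs)
  expect_identical(isl$pii_midpoint, 20000)
  nade <- function(mid, id = "n1", evalue = 1e-20) {
    data.frame(
      query_id = "NadE2", genome = "G1", contig_id = "c",
      start = mid - 100, end = mid + 100, strand = "+",
      evalue = evalue, subject_protein_id = id
    )
  }
  # distance 1999: kept
  expect_identical(
    pair_nade_with_pii(nade(21999), isl)$midpoint_distance, 1999
  )
  # distance 2000: discarded (strict inequality)
  expect_identical(nrow(pair_nade_with_pii(nade(22000), isl)), 0L)
  # overlapping midpoints: distance 0, kept
  expect_identical(
    pair_nade_with_pii(nade(20000), isl)$midpoint_distance, 0
  )
  # weak nadE hit next to the island fails the e-value filter
  expect_identical(
    nrow(pair_nade_with_pii(nade(20500, evalue = 1e-3), isl)), 0L
  )
  # equidistant between two islands: ties to the lower-coordinate one
  isl2 <- call_islands(
    rbind(
      pii_hit(19900, 20100, contig = "c", id = "pA"),
      pii_hit(22900, 23100, contig = "c", id = "pB")
    ),
    contigs
  )
  tie <- pair_nade_with_pii(nade(21500), isl2)
  expect_identical(tie$midpoint_distance, 1500)
  expect_identical(tie$pii_midpoint, 20000)
  # island-midpoint reference flag changes the measured distance
  gene_ref <- pair_nade_with_pii(nade(21000), isl, reference = "gene")
  isl_ref <- pair_nade_with_pii(nade(21000), isl, reference = "island")
  expect_identical(gene_ref$midpoint_distance, 1000)
  expect_identical(
    isl_ref$midpoint_distance,
    abs(21000 - floor((isl$window_start + isl$window_end) / 2))
  )
})

test_that("pair dereplication keeps first occurrence under canonical order", {
  pairs <- tibble::tibble(
    genome = c("G2", "G1", "G3"), contig_id = "c",
    subject_protein_id = c("W1", "W1", "W2"),
    start = c(10, 5, 7), end = c(20, 15, 17),
    midpoint_distance = c(100, 200, 300)
  )
  out <- dereplicate_pairs(pairs)
  expect_identical(nrow(out), 2L)
  # canonical order is by genome: G1's W1 survives
  expect_identical(out$genome[out$subject_protein_id == "W1"], "G1")
  expect_identical(nrow(attr(out, "removed")), 1L)
  # identical sequences under different ids collapse when sequences given
  seqs <- c(W1 = "MSEQA", W2 = "MSEQA")
  out2 <- dereplicate_pairs(pairs, sequences = seqs)
  expect_identical(nrow(out2), 1L)
  # all-unique input is identity
  expect_identical(nrow(dereplicate_pairs(out)), nrow(out))
})

test_that("taxonomy rollup buckets by rank and totals the pairs", {
  pairs <- tibble::tibble(genome = c("A", "B", "C", "D"))
  metas <- data.frame(
    assembly_accession = c("A", "B", "C", "D"), taxid = c(1, 2, 3, 99)
  )
  lineages <- data.frame(
    taxid = 1:3, phylum = "Proteobacteria",
    class = c("Beta", "Beta", "Gamma")
  )
  ru <- taxonomy_rollup(pairs, metas, lineages, rank = "class")
  expect_identical(sum(ru$n), 4L)
  expect_identical(ru$n[ru$rank_value == "Beta"], 2L)
  # missing taxid lands in the unclassified bucket
  expect_identical(ru$n[ru$rank_value == "unclassified"], 1L)
  expect_error(taxonomy_rollup(pairs, metas, lineages, rank = "order"))
})

test_that("pipeline achieves perfect recall and precision on planted truth", {
  gs <- sim_genome_set(n_genomes = 50, p_pair = 0.6, seed = 7)
  res <- islands_pipeline(
    gs$metas, gs$contigs, gs$pii_hits, gs$nade_hits, gs$lineages
  )
  truth <- gs$truth$pairs
  found <- res$pairs
  expect_identical(
    sort(found$subject_protein_id), sort(truth$subject_protein_id)
  )
  expect_true(all(found$midpoint_distance < 2000))
  # distances agree with the generator truth
  j <- dplyr::inner_join(
    found, truth,
    by = c("genome", "subject_protein_id"),
    suffix = c("", "_truth")
  )
  expect_equal(j$midpoint_distance, j$midpoint_distance_truth)
  # roll-up counts match the generator truth table
  expect_identical(res$rollup$n, gs$truth$rollup$n)
  expect_identical(res$rollup$rank_value, gs$truth$rollup$class)
  # boundary scenarios: all genomes paired / none paired
  gs_all <- sim_genome_set(
    n_genomes = 10, p_pair = 1, decoys_per_genome = 0, seed = 3
  )
  res_all <- islands_pipeline(
    gs_all$metas, gs_all$contigs, gs_all$pii_hits, gs_all$nade_hits
  )
  expect_identical(nrow(res_all$pairs), 10L)
  gs_none <- sim_genome_set(n_genomes = 10, p_pair = 0, seed = 3)
  res_none <- islands_pipeline(
    gs_none$metas, gs_none$contigs, gs_none$pii_hits, gs_none$nade_hits
  )
  expect_identical(nrow(res_none$pairs), 0L)
})

test_that("shrinking the flank can only shrink the island set", {
  gs <- sim_genome_set(n_genomes = 30, p_pair = 0.5, seed = 11)
  isl_full <- call_islands(gs$pii_hits, gs$contigs, flank = 10000)
  isl_small <- call_islands(gs$pii_hits, gs$contigs, flank = 5000)
  key <- function(x) paste(x$genome, x$pii_start)
  expect_true(all(key(isl_full) %in% key(isl_small)) ||
    nrow(isl_full) <= nrow(isl_small))
  # larger flank discards more edge hits, so monotone in the other
  # direction: every island kept at the big flank is kept at the small
  expect_true(all(key(isl_full) %in% key(isl_small)))
})
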
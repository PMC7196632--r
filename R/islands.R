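#' Select one genome assembly per species
#'
#' Keeps exactly one assembly per `species_taxid`, preferring type-strain
#' assemblies, then the most complete assembly level
#' (complete > chromosome > scaffold > contig), with remaining ties
#' broken by lexicographic `assembly_accession` so the selection is
#' deterministic and order-independent.
#'
#' @param metas Data frame of assembly metadata with columns
#'   `assembly_accession`, `species_taxid`, `assembly_level`, and
#'   `refseq_category` (anything containing "type" marks a type strain).
#' @return Tibble of the selected rows, one per species.
#' @export
dedupe_genomes <- function(metas) {
  level_rank <- c(complete = 1, chromosome = 2, scaffold = 3, contig = 4)
  metas |>
    tibble::as_tibble() |>
    dplyr::mutate(
      .type = !grepl("type", tolower(.data$refseq_category %||% "")),
      .level = level_rank[tolower(.data$assembly_level)]
    ) |>
    dplyr::arrange(
      .data$species_taxid, .data$.type, .data$.level,
      .data$assembly_accession
    ) |>
    dplyr::distinct(.data$species_taxid, .keep_all = TRUE) |>
    dplyr::select(-".type", -".level")
}

#' Call PII islands from homology hits
#'
#' A PII island is the locus of a PII-homolog hit extended by `flank`
#' base pairs on each side. Hits are dropped when their e-value exceeds
#' `evalue_max` (the threshold itself is retained) or when the flanked
#' window would run off the contig (contigs too short to hold the full
#' window are not searchable on equal footing and are discarded).
#'
#' @param pii_hits Data frame of hits: `genome`, `contig_id`, `start`,
#'   `end` (1-based inclusive bp), `strand`, `evalue`, plus optional
#'   identifier columns.
#' @param contigs Data frame of contig lengths: `genome`, `contig_id`,
#'   `length`.
#' @param flank Flank size in bp (default 10000).
#' @param evalue_max Inclusive e-value threshold (default 1e-5).
#' @return Tibble of islands with `genome`, `contig_id`, `pii_start`,
#'   `pii_end`, `pii_midpoint`, `window_start`, `window_end`; discarded
#'   hits are attached as the `"discarded"` attribute with a `reason`
#'   column.
#' @export
call_islands <- function(pii_hits, contigs, flank = 10000,
                         evalue_max = 1e-5) {
  h <- tibble::as_tibble(pii_hits) |>
    dplyr::left_join(
      dplyr::select(
        tibble::as_tibble(contigs),
        "genome", "contig_id", "length"
      ),
      by = c("genome", "contig_id")
    )
  if (any(is.na(h$length))) {
    bad <- h[is.na(h$length), ]
    stop(
      "hit(s) reference unknown contig(s): ",
      paste(unique(paste0(bad$genome, "/", bad$contig_id)), collapse = ", ")
    )
  }
  h <- h |>
    dplyr::mutate(
      window_start = .data$start - flank,
      window_end = .data$end + flank,
      reason = dplyr::case_when(
        .data$evalue > evalue_max ~ "evalue_above_threshold",
        .data$window_start < 1 | .data$window_end > .data$length ~
          "window_truncated_by_contig_edge",
        TRUE ~ NA_character_
      )
    )
  discarded <- h |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select(-"length")
  kept <- h |>
    dplyr::filter(is.na(.data$reason)) |>
    dplyr::mutate(
      pii_start = .data$start, pii_end = .data$end,
      pii_midpoint = floor((.data$start + .data$end) / 2)
    ) |>
    dplyr::select(
      dplyr::any_of(c("genome", "contig_id", "query_id", "subject_protein_id")),
      "pii_start", "pii_end", "pii_midpoint", "window_start", "window_end"
    ) |>
    dplyr::arrange(.data$genome, .data$contig_id, .data$window_start)
  attr(kept, "discarded") <- discarded
  kept
}

#' Pair nadE homologs with their closest PII island
#'
#' For each nadE-homolog hit located inside a PII island, computes the
#' distance between gene midpoints (`floor((start + end) / 2)`, strand
#' ignored) to the closest PII locus on the same contig, and keeps pairs
#' strictly closer than `max_distance`. A nadE hit equidistant between
#' two islands ties to the lower-coordinate island.
#'
#' @param nade_hits Data frame of nadE hits (same layout as
#'   [call_islands()] input, with a `subject_protein_id` column naming
#'   the encoded protein).
#' @param islands Output of [call_islands()].
#' @param evalue_max Inclusive e-value threshold for nadE hits.
#' @param max_distance Strict upper bound on midpoint distance, bp.
#' @param reference `"gene"` measures to the PII gene midpoint (default);
#'   `"island"` to the island window midpoint.
#' @return Tibble of pairs: genome/contig, nadE coordinates and protein
#'   id, PII midpoint, `midpoint_distance`.
#' @export
pair_nade_with_pii <- function(nade_hits, islands, evalue_max = 1e-5,
                               max_distance = 2000,
                               reference = c("gene", "island")) {
  reference <- match.arg(reference)
  isl <- tibble::as_tibble(islands) |>
    dplyr::mutate(
      ref_midpoint = if (reference == "gene") {
        .data$pii_midpoint
      } else {
        floor((.data$window_start + .data$window_end) / 2)
      }
    )
  nh <- tibble::as_tibble(nade_hits) |>
    dplyr::filter(.data$evalue <= evalue_max) |>
    dplyr::mutate(nade_midpoint = floor((.data$start + .data$end) / 2))
  # restrict to hits encoded within an island window, then closest PII
  joined <- nh |>
    dplyr::inner_join(
      dplyr::select(
        isl, "genome", "contig_id", "pii_midpoint", "ref_midpoint",
        "window_start", "window_end"
      ),
      by = c("genome", "contig_id"), relationship = "many-to-many"
    ) |>
    dplyr::filter(
      .data$nade_midpoint >= .data$window_start,
      .data$nade_midpoint <= .data$window_end
    ) |>
    dplyr::mutate(
      midpoint_distance = abs(.data$nade_midpoint - .data$ref_midpoint)
    ) |>
    dplyr::arrange(
      .data$genome, .data$contig_id, .data$start,
      .data$midpoint_distance, .data$ref_midpoint
    ) |>
    dplyr::distinct(
      .data$genome, .data$contig_id, .data$start, .data$end,
      .keep_all = TRUE
    ) |>
    dplyr::filter(.data$midpoint_distance < max_distance)
  joined |>
    dplyr::select(dplyr::any_of(c(
      "genome", "contig_id", "subject_protein_id", "start", "end",
      "nade_midpoint", "pii_midpoint", "ref_midpoint", "midpoint_distance"
    )))
}

#' Dereplicate island pairs
#'
#' Removes duplicated nadE entries: by identical protein sequence when a
#' named `sequences` vector is supplied, otherwise by protein id. The
#' first occurrence under a canonical ordering (genome, contig,
#' coordinate) is kept.
#'
#' @param pairs Output of [pair_nade_with_pii()].
#' @param sequences Optional named character vector,
#'   `subject_protein_id -> protein sequence`.
#' @return Tibble of unique pairs; removed rows attached as the
#'   `"removed"` attribute.
#' @export
dereplicate_pairs <- function(pairs, sequences = NULL) {
  p <- tibble::as_tibble(pairs) |>
    dplyr::arrange(.data$genome, .data$contig_id, .data$start)
  key <- if (!is.null(sequences)) {
    unname(sequences[p$subject_protein_id])
  } else {
    p$subject_protein_id
  }
  keep <- !duplicated(key)
  out <- p[keep, ]
  attr(out, "removed") <- p[!keep, ]
  out
}

#' Taxonomic roll-up of island pairs
#'
#' Counts dereplicated pairs per taxonomic rank value using a
#' pre-converted lineage table. Genomes whose taxid is missing from the
#' lineage table are counted as `"unclassified"`.
#'
#' @param pairs Island pairs with a `genome` column.
#' @param metas Assembly metadata linking `genome` (accession) to
#'   `taxid`.
#' @param lineages Data frame with `taxid` plus rank columns (`phylum`,
#'   `class`, ...).
#' @param rank Rank column to roll up on (default `"class"`).
#' @return Tibble of `rank_value`, `n`, sorted by decreasing count; the
#'   counts total the number of input pairs.
#' @export
taxonomy_rollup <- function(pairs, metas, lineages, rank = "class") {
  if (!rank %in% names(lineages)) {
    stop("rank column '", rank, "' not present in lineages")
  }
  tibble::as_tibble(pairs) |>
    dplyr::left_join(
      dplyr::select(
        tibble::as_tibble(metas), genome = "assembly_accession", "taxid"
      ),
      by = "genome"
    ) |>
    dplyr::left_join(tibble::as_tibble(lineages), by = "taxid") |>
    dplyr::mutate(
      rank_value = dplyr::coalesce(.data[[rank]], "unclassified")
    ) |>
    dplyr::count(.data$rank_value, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$rank_value)
}

#' Run the full island-detection pipeline
#'
#' Convenience wrapper: genome dereplication, island calling, nadE
#' pairing, pair dereplication, and taxonomy roll-up in one call.
#'
#' @param metas,contigs,pii_hits,nade_hits,lineages Input tables as for
#'   the individual steps.
#' @param flank,evalue_max,max_distance,reference Pipeline thresholds;
#'   see the individual steps.
#' @param rank Rank for the taxonomy roll-up.
#' @return List with `genomes`, `islands`, `pairs`, `rollup`.
#' @export
islands_pipeline <- function(metas, contigs, pii_hits, nade_hits,
                             lineages = NULL, flank = 10000,
                             evalue_max = 1e-5, max_distance = 2000,
                             reference = "gene", rank = "class") {
  sel <- dedupe_genomes(metas)
  keep_genome <- function(df) {
    dplyr::semi_join(
      tibble::as_tibble(df),
      dplyr::select(sel, genome = "assembly_accession"),
      by = "genome"
    )
  }
  islands <- call_islands(
    keep_genome(pii_hits), keep_genome(contigs),
    flank = flank, evalue_max = evalue_max
  )
  pairs <- pair_nade_with_pii(
    keep_genome(nade_hits), islands,
    evalue_max = evalue_max, max_distance = max_distance,
    reference = reference
  )
  pairs <- dereplicate_pairs(pairs)
  rollup <- if (!is.null(lineages)) {
    taxonomy_rollup(pairs, sel, lineages, rank = rank)
  }
  list(genomes = sel, islands = islands, pairs = pairs, rollup = rollup)
}
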
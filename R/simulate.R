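#' Derive a reproducible substream seed
#'
#' Fans one global seed out into per-dataset substreams so that adding a
#' scenario never shifts an existing one. The derivation is a simple
#' multiplicative hash folded into the 32-bit signed range.
#'
#' @param seed Global integer seed.
#' @param stream Small non-negative integer identifying the substream.
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %%
    2147483647)
}

#' Simulate a dose-response dataset with known truth
#'
#' Draws replicate responses from any [rate_model()] with multiplicative
#' Gaussian noise: `response = model * (1 + e)`, `e ~ N(0, noise_cv)`.
#' The ground truth (model, parameters, seed) is attached as the
#' `"truth"` attribute so recovery tests can compare against it.
#'
#' @param model Model id or [rate_model()] spec.
#' @param params True parameter values (named).
#' @param concentrations Vector of doses for the model's (single)
#'   predictor.
#' @param noise_cv Coefficient of variation of the noise (>= 0).
#' @param replicates Replicates per dose (>= 1).
#' @param seed Integer seed.
#' @param predictor Predictor column name; defaults to the model's own.
#' @return Tibble with the predictor column, `replicate`, `response`.
#' @export
sim_dose_response <- function(model, params, concentrations, noise_cv = 0.03,
                              replicates = 3, seed = 1, predictor = NULL) {
  stopifnot(noise_cv >= 0, replicates >= 1)
  spec <- if (is.character(model)) rate_model(model) else model
  if (is.null(predictor)) predictor <- spec$predictor_names[1]
  d <- tidyr::expand_grid(
    conc = concentrations, replicate = seq_len(replicates)
  )
  mean_resp <- evaluate_model(
    spec, params, stats::setNames(list(d$conc), predictor)
  )
  old <- .Random.seed_exists()
  set.seed(seed)
  eps <- stats::rnorm(nrow(d), 0, noise_cv)
  old()
  out <- tibble::tibble(
    !!predictor := d$conc,
    replicate = d$replicate,
    response = mean_resp * (1 + eps)
  )
  attr(out, "truth") <- list(
    model_id = spec$model_id, params = params, noise_cv = noise_cv,
    replicates = replicates, seed = seed
  )
  out
}

#' Simulate a multi-concentration sensorgram set
#'
#' Wraps [simulate_sensorgram()] over a concentration series with one
#' fanned-out seed stream; the design mirrors a Kd-determination series
#' (analyte titrated across the Kd).
#'
#' @param params [binding_params()] (or a 2-site list).
#' @param concentrations Analyte concentrations in nM.
#' @param noise_sd,drift,phase_times,dt As in [simulate_sensorgram()].
#' @param seed Integer seed.
#' @return Tibble of all sensorgrams (rows stacked), `"truth"`
#'   attribute carrying the generating parameters.
#' @export
sim_sensorgrams <- function(params, concentrations = c(30, 100, 300, 1000, 2000),
                            noise_sd = 0.02, drift = 0,
                            phase_times = c(
                              baseline = 30, association = 150,
                              dissociation = 300
                            ),
                            seed = 1, dt = 1) {
  out <- purrr::imap(concentrations, function(conc, i) {
    simulate_sensorgram(params, conc,
      phase_times = phase_times, noise_sd = noise_sd, drift = drift,
      seed = substream_seed(seed, i), dt = dt
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "truth") <- list(
    params = params, noise_sd = noise_sd, drift = drift, seed = seed
  )
  out
}

#' Simulate a genome set with planted PII-nadE islands
#'
#' Emits all the tables the island pipeline consumes — assembly
#' metadata, contig lengths, PII and nadE hit tables, and a lineage
#' table — with a known truth list of planted pairs. Each genome carries
#' a PII locus with probability `p_pair` placed so its flanked window
#' fits the contig, plus a nadE gene at a sampled midpoint distance
#' within `pair_distance_range`. Decoys exercise every discard rule:
#' nadE-like hits farther than `decoy_distance_min`, PII hits too close
#' to a contig edge (window truncated), and hits with e-values above the
#' pipeline threshold. Genomes are assigned taxonomy classes from
#' `taxonomy_mix`, and a fraction of species get a second, lower-priority
#' assembly to exercise genome dereplication.
#'
#' @param n_genomes Number of species.
#' @param p_pair Probability a genome carries a true PII-nadE pair.
#' @param pair_distance_range Midpoint-distance range (bp) for planted
#'   pairs; max must stay below 2000.
#' @param decoy_distance_min Minimum midpoint distance (bp) for decoy
#'   nadE genes (>= 2000).
#' @param contig_length Contig length in bp.
#' @param decoys_per_genome Number of far-away decoy nadE genes per
#'   genome.
#' @param taxonomy_mix Named probability vector over class names.
#' @param seed Integer seed.
#' @return List of tibbles `metas`, `contigs`, `pii_hits`, `nade_hits`,
#'   `lineages`, plus `truth` (planted pairs and the expected roll-up).
#' @export
sim_genome_set <- function(n_genomes = 50, p_pair = 0.6,
                           pair_distance_range = c(200, 1900),
                           decoy_distance_min = 3000,
                           contig_length = 100000,
                           decoys_per_genome = 2,
                           taxonomy_mix = c(
                             Betaproteobacteria = 0.45,
                             Gammaproteobacteria = 0.3,
                             Alphaproteobacteria = 0.25
                           ),
                           seed = 1) {
  stopifnot(
    pair_distance_range[2] < 2000, decoy_distance_min >= 2000,
    contig_length > 2 * 10000 + 2 * decoy_distance_min + 4000
  )
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)

  gene_len <- 350
  flank <- 10000
  metas <- list()
  contigs <- list()
  pii <- list()
  nade <- list()
  truth_pairs <- list()
  classes <- sample(
    names(taxonomy_mix), n_genomes,
    replace = TRUE, prob = taxonomy_mix
  )
  for (g in seq_len(n_genomes)) {
    acc <- sprintf("GCF_%06d.1", g)
    taxid <- 1000 + g
    metas[[g]] <- tibble::tibble(
      assembly_accession = acc, taxid = taxid, species_taxid = 500 + g,
      assembly_level = "complete",
      refseq_category = if (g %% 3 == 0) "type strain" else "na",
      organism_name = paste0("Synthetica species", g)
    )
    contigs[[g]] <- tibble::tibble(
      genome = acc, contig_id = "c1", length = contig_length
    )
    has_pair <- stats::runif(1) < p_pair
    # PII locus placed so the 10-kb window always fits
    pii_start <- round(stats::runif(
      1, flank + decoy_distance_min + 1000,
      contig_length - flank - decoy_distance_min - 1000 - gene_len
    ))
    pii_end <- pii_start + gene_len - 1
    pii_mid <- floor((pii_start + pii_end) / 2)
    pii[[g]] <- tibble::tibble(
      query_id = "PII", genome = acc, contig_id = "c1",
      start = pii_start, end = pii_end, strand = "+",
      evalue = 10^stats::runif(1, -40, -10),
      subject_protein_id = paste0("WP_PII_", g)
    )
    # decoy PII whose window is truncated by the contig edge
    edge_start <- round(stats::runif(1, 500, 4000))
    pii[[n_genomes + g]] <- tibble::tibble(
      query_id = "PII", genome = acc, contig_id = "c1",
      start = edge_start, end = edge_start + gene_len - 1, strand = "-",
      evalue = 1e-20, subject_protein_id = paste0("WP_PIIedge_", g)
    )
    rows <- list()
    if (has_pair) {
      d <- round(stats::runif(
        1, pair_distance_range[1], pair_distance_range[2]
      ))
      nade_mid <- pii_mid + sample(c(-1, 1), 1) * d
      ns <- nade_mid - floor(gene_len / 2)
      rows$planted <- tibble::tibble(
        query_id = "NadE2", genome = acc, contig_id = "c1",
        start = ns, end = ns + gene_len - 1, strand = "+",
        evalue = 10^stats::runif(1, -60, -20),
        subject_protein_id = paste0("WP_NADE_", g)
      )
      truth_pairs[[length(truth_pairs) + 1]] <- tibble::tibble(
        genome = acc, subject_protein_id = paste0("WP_NADE_", g),
        midpoint_distance = abs(
          floor((ns + ns + gene_len - 1) / 2) - pii_mid
        ),
        class = classes[g]
      )
    }
    for (k in seq_len(decoys_per_genome)) {
      # far decoy: inside the window only if flank allows, but >= decoy_distance_min
      side <- if (k %% 2 == 0) 1 else -1
      dd <- round(stats::runif(1, decoy_distance_min, flank - 1000))
      dmid <- pii_mid + side * dd
      ds <- dmid - floor(gene_len / 2)
      rows[[paste0("far", k)]] <- tibble::tibble(
        query_id = "NadE2", genome = acc, contig_id = "c1",
        start = ds, end = ds + gene_len - 1, strand = "-",
        evalue = 1e-15, subject_protein_id = paste0("WP_FAR_", g, "_", k)
      )
    }
    # high-evalue decoy right next to PII: must fail the e-value filter
    hs <- pii_mid + 600
    rows$weak <- tibble::tibble(
      query_id = "NadE2", genome = acc, contig_id = "c1",
      start = hs, end = hs + gene_len - 1, strand = "+",
      evalue = 1e-3, subject_protein_id = paste0("WP_WEAK_", g)
    )
    nade[[g]] <- dplyr::bind_rows(rows)
  }
  # duplicate assemblies for a third of species: lower priority, must be
  # removed by genome dereplication
  dup <- purrr::map(seq_len(max(n_genomes %/% 3, 1)), function(g) {
    tibble::tibble(
      assembly_accession = sprintf("GCF_9%05d.1", g),
      taxid = 2000 + g, species_taxid = 500 + g,
      assembly_level = "scaffold", refseq_category = "na",
      organism_name = paste0("Synthetica species", g, " alt")
    )
  })
  metas <- dplyr::bind_rows(c(metas, dup))
  empty_truth <- tibble::tibble(
    genome = character(), subject_protein_id = character(),
    midpoint_distance = numeric(), class = character()
  )
  truth_pairs <- dplyr::bind_rows(c(list(empty_truth), truth_pairs))
  lineages <- tibble::tibble(
    taxid = 1000 + seq_len(n_genomes),
    phylum = "Proteobacteria", class = classes
  )
  list(
    metas = metas,
    contigs = dplyr::bind_rows(contigs),
    pii_hits = dplyr::bind_rows(pii),
    nade_hits = dplyr::bind_rows(nade),
    lineages = lineages,
    truth = list(
      pairs = truth_pairs,
      rollup = truth_pairs |>
        dplyr::count(.data$class, name = "n") |>
        dplyr::arrange(dplyr::desc(.data$n), .data$class),
      seed = seed
    )
  )
}

#' Simulate protein families with controlled divergence
#'
#' Draws `k` random ancestor sequences and derives `n_per_family` point
#' mutants from each; within-family identity is about
#' `1 - within_mutation_rate` while unrelated ancestors share only
#' random (~6%) identity, so family structure is controlled. No indels
#' or selection are modelled.
#'
#' @param k Number of families.
#' @param n_per_family Sequences per family.
#' @param ancestor_length Sequence length, residues.
#' @param within_mutation_rate Per-site substitution probability within
#'   a family, in `(0, 1)`.
#' @param seed Integer seed.
#' @return Named character vector of sequences (`famX_seqY`), with a
#'   `"truth"` attribute carrying the family labels.
#' @export
sim_protein_families <- function(k = 3, n_per_family = 6,
                                 ancestor_length = 120,
                                 within_mutation_rate = 0.1, seed = 1) {
  stopifnot(within_mutation_rate > 0, within_mutation_rate < 1)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  seqs <- character(0)
  labels <- integer(0)
  for (f in seq_len(k)) {
    anc <- sample(aa, ancestor_length, replace = TRUE)
    for (s in seq_len(n_per_family)) {
      child <- anc
      mut <- stats::runif(ancestor_length) < within_mutation_rate
      child[mut] <- sample(aa, sum(mut), replace = TRUE)
      seqs[paste0("fam", f, "_seq", s)] <- paste(child, collapse = "")
      labels <- c(labels, f)
    }
  }
  attr(seqs, "truth") <- list(
    family = stats::setNames(labels, names(seqs)), seed = seed
  )
  seqs
}

#' Simulate a ligand-fishing intensity table
#'
#' Log-normal background intensities for `n_proteins`, with
#' `n_enriched` planted bait-specific proteins whose bait-column
#' intensities are multiplied by `fold`.
#'
#' @param n_proteins Total proteins.
#' @param n_enriched Planted enriched proteins.
#' @param fold Bait-over-control fold change of planted proteins.
#' @param seed Integer seed.
#' @return Wide tibble as consumed by [enrichment_ranking()], with the
#'   enriched ids in the `"truth"` attribute.
#' @export
sim_lfq_table <- function(n_proteins = 200, n_enriched = 5, fold = 50,
                          seed = 1) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  ids <- sprintf("P%04d", seq_len(n_proteins))
  base1 <- stats::rlnorm(n_proteins, log(1e5), 1)
  base2 <- stats::rlnorm(n_proteins, log(1e5), 1)
  noise <- function() stats::rlnorm(n_proteins, 0, 0.2)
  enriched <- sample(ids, n_enriched)
  mult <- ifelse(ids %in% enriched, fold, 1)
  out <- tibble::tibble(
    protein_id = ids,
    bait_f1 = base1 * mult * noise(),
    bait_f2 = base2 * mult * noise(),
    control_f1 = base1 * noise(),
    control_f2 = base2 * noise()
  )
  attr(out, "truth") <- list(enriched = sort(enriched), seed = seed)
  out
}
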
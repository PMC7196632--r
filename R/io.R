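#' Read a dose-response CSV
#'
#' Expected columns: `concentration`, `conc_unit`, `replicate`,
#' `response`, `response_unit`. All rows must share one concentration
#' unit; concentrations must be non-negative with at least two distinct
#' values.
#'
#' @param path CSV file path.
#' @return Validated tibble.
#' @export
read_dose_response <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("concentration", "conc_unit", "replicate", "response")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (length(unique(d$conc_unit)) != 1) {
    stop("all rows must share one concentration unit")
  }
  if (any(d$concentration < 0)) stop("negative concentration")
  if (length(unique(d$concentration)) < 2) {
    stop("need at least 2 distinct concentrations")
  }
  d
}

#' Read an assay time-course CSV
#'
#' Expected columns: `time_s`, `signal`, `assay_kind`. Time must be
#' strictly increasing.
#'
#' @param path CSV file path.
#' @return Tibble with columns `time`, `signal`, `assay_kind`.
#' @export
read_time_course <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "signal", "assay_kind")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(diff(d$time_s) <= 0)) stop("time must be strictly increasing")
  tibble::tibble(
    time = d$time_s, signal = d$signal, assay_kind = d$assay_kind
  )
}

#' Read a sensorgram CSV
#'
#' Expected columns: `time_s`, `response_nm`, `phase`,
#' `analyte_conc_nM`.
#'
#' @param path CSV file path.
#' @return Sensorgram tibble (`time`, `response`, `phase`,
#'   `analyte_conc`).
#' @export
read_sensorgram <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "response_nm", "phase", "analyte_conc_nM")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  ok <- c("baseline", "loading", "association", "dissociation")
  if (!all(d$phase %in% ok)) stop("unknown phase label")
  tibble::tibble(
    time = d$time_s, response = d$response_nm, phase = d$phase,
    analyte_conc = d$analyte_conc_nM
  )
}

#' Read a homology hit table in BLAST outfmt-6 layout
#'
#' Tab-separated, no header, standard 12 columns (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`),
#' plus a required mapping from `sseqid` to genome/contig supplied in
#' `contig_map` (columns `sseqid`, `genome`, `contig_id`). Subject
#' coordinates become the gene locus (`start <= end` regardless of
#' strand; strand inferred from coordinate orientation).
#'
#' @param path TSV file path.
#' @param contig_map Data frame mapping `sseqid` to `genome` and
#'   `contig_id`.
#' @return Hit tibble as consumed by [call_islands()] /
#'   [pair_nade_with_pii()].
#' @export
read_hits_outfmt6 <- function(path, contig_map) {
  cols <- c(
    "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"
  )
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 12) stop("expected 12 tab-separated columns (outfmt 6)")
  names(d)[1:12] <- cols
  d <- tibble::as_tibble(d) |>
    dplyr::left_join(tibble::as_tibble(contig_map), by = "sseqid")
  if (any(is.na(d$genome))) {
    stop("sseqid(s) missing from contig_map")
  }
  d |>
    dplyr::transmute(
      query_id = .data$qseqid,
      genome = .data$genome,
      contig_id = .data$contig_id,
      start = pmin(.data$sstart, .data$send),
      end = pmax(.data$sstart, .data$send),
      strand = ifelse(.data$sstart <= .data$send, "+", "-"),
      evalue = .data$evalue,
      bitscore = .data$bitscore,
      subject_protein_id = .data$sseqid
    )
}
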
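#' Ligand-fishing enrichment ranking
#'
#' Scores each protein in a label-free quantification table by its log10
#' bait-over-control intensity ratio, per elution fraction, and ranks
#' proteins by decreasing enrichment. A pseudocount keeps zero
#' intensities finite; by default it is the smallest nonzero intensity
#' in the table, which is scale-free.
#'
#' @param table Wide data frame: `protein_id`, `bait_f1`, `bait_f2`,
#'   `control_f1`, `control_f2` (intensities >= 0; missing proteins in
#'   one column are zeros).
#' @param pseudocount Strictly positive; default the smallest nonzero
#'   intensity.
#' @param top If not `NULL`, return only the top `top` rows per
#'   fraction.
#' @return Tibble `protein_id`, `fraction` (1 or 2), `log_ratio`,
#'   `rank` (dense rank within fraction, 1 = most enriched), sorted by
#'   fraction then rank.
#' @examples
#' t <- data.frame(
#'   protein_id = c("a", "b"), bait_f1 = c(1000, 10),
#'   bait_f2 = c(500, 10), control_f1 = c(10, 10), control_f2 = c(5, 10)
#' )
#' enrichment_ranking(t)
#' @export
enrichment_ranking <- function(table, pseudocount = NULL, top = NULL) {
  need <- c("protein_id", "bait_f1", "bait_f2", "control_f1", "control_f2")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  vals <- unlist(table[setdiff(need, "protein_id")])
  if (any(vals < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  if (is.null(pseudocount)) {
    nz <- vals[!is.na(vals) & vals > 0]
    if (length(nz) == 0) stop("all intensities are zero")
    pseudocount <- min(nz)
  }
  if (pseudocount <= 0) stop("pseudocount must be strictly positive")
  long <- tibble::as_tibble(table) |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(setdiff(need, "protein_id")),
      names_to = c("column", "fraction"), names_sep = "_f",
      values_to = "intensity"
    ) |>
    dplyr::mutate(
      fraction = as.integer(.data$fraction),
      intensity = dplyr::coalesce(.data$intensity, 0)
    ) |>
    tidyr::pivot_wider(
      names_from = "column", values_from = "intensity"
    ) |>
    dplyr::mutate(
      log_ratio = log10(
        (.data$bait + pseudocount) / (.data$control + pseudocount)
      )
    ) |>
    dplyr::group_by(.data$fraction) |>
    dplyr::arrange(
      dplyr::desc(.data$log_ratio), .data$protein_id,
      .by_group = TRUE
    ) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("protein_id", "fraction", "log_ratio", "rank") |>
    dplyr::arrange(.data$fraction, .data$rank)
  if (!is.null(top)) {
    long <- dplyr::filter(long, .data$rank <= top)
  }
  long
}
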
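#' Build an all-vs-all similarity graph
#'
#' Constructs the symmetric similarity graph used for force-directed
#' clustering of protein homologs, either by ingesting a precomputed hit
#' table (BLAST outfmt-6 layout: `qseqid`, `sseqid`, `evalue` at least)
#' or by aligning sequences pairwise (Smith-Waterman local alignment
#' with BLOSUM62 and affine gaps, via Biostrings) with a
#' Karlin-Altschul-style E-value approximation
#' `E = K m n exp(-lambda * S)` using the standard gapped BLOSUM62
#' parameters (lambda = 0.267, K = 0.041). The built-in aligner's
#' E-values are approximate; ingest a real search tool's hit table for
#' exact compatibility.
#'
#' Edge attraction is `min(-log10(evalue), cap) / cap`, in `[0, 1]`.
#'
#' @param x Either a data frame hit table with columns `qseqid`,
#'   `sseqid`, `evalue`, or a named character vector / `AAStringSet` of
#'   protein sequences.
#' @param evalue_cutoff Edges with larger e-values are dropped.
#' @param cap Attraction saturates at `-log10(evalue) = cap`.
#' @return A `similarity_graph`: list with `nodes` (character vector)
#'   and `edges` (tibble `from`, `to`, `evalue`, `attraction`; each
#'   undirected edge stored once with `from < to`).
#' @export
build_similarity_graph <- function(x, evalue_cutoff = 1e-5, cap = 200) {
  if (is.data.frame(x)) {
    edges <- tibble::as_tibble(x) |>
      dplyr::transmute(
        from = pmin(.data$qseqid, .data$sseqid),
        to = pmax(.data$qseqid, .data$sseqid),
        evalue = .data$evalue
      ) |>
      dplyr::filter(.data$from != .data$to) |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(evalue = min(.data$evalue), .groups = "drop")
    nodes <- sort(unique(c(x$qseqid, x$sseqid)))
  } else {
    seqs <- if (is.character(x)) x else as.character(x)
    if (length(seqs) < 2) stop("need at least 2 sequences")
    if (is.null(names(seqs))) {
      stop("sequences must be named")
    }
    nodes <- sort(names(seqs))
    edges <- .align_all_pairs(seqs[nodes])
  }
  edges <- edges |>
    dplyr::filter(.data$evalue <= evalue_cutoff) |>
    dplyr::mutate(
      attraction = pmin(-log10(pmax(.data$evalue, 1e-300)), cap) / cap
    ) |>
    dplyr::arrange(.data$from, .data$to)
  structure(
    list(nodes = nodes, edges = edges, cap = cap),
    class = "similarity_graph"
  )
}

# pairwise local alignment scores -> approximate Karlin-Altschul E-values
.align_all_pairs <- function(seqs, lambda = 0.267, K = 0.041) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required to align sequences directly")
  }
  ids <- names(seqs)
  n <- length(ids)
  res <- list()
  data(list = "BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      s <- Biostrings::pairwiseAlignment(
        seqs[[i]], seqs[[j]],
        type = "local", substitutionMatrix = mat,
        gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
      )
      m <- nchar(seqs[[i]])
      nn <- nchar(seqs[[j]])
      e <- K * m * nn * exp(-lambda * s)
      res[[length(res) + 1]] <- tibble::tibble(
        from = ids[i], to = ids[j], evalue = e
      )
    }
  }
  dplyr::bind_rows(res)
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("<similarity_graph> ", length(x$nodes), " nodes, ",
    nrow(x$edges), " edges\n",
    sep = ""
  )
  invisible(x)
}

#' Force-directed 2D layout of a similarity graph
#'
#' Seeded random initial coordinates, then iterative relaxation: each
#' node moves by `damping * clip(attraction - repulsion, max_step)`
#' where attraction pulls along each edge proportionally to its weight
#' (`k_att`) and every node pair repels with an inverse-square kernel
#' (`k_rep`), regularized by a small epsilon offset so coincident points
#' do not blow up. Deterministic given `seed`; nodes are processed in
#' canonical (sorted) order so the layout is invariant to input order.
#'
#' @param graph A [build_similarity_graph()] result.
#' @param iterations Maximum iterations (default 500).
#' @param seed Integer seed for the initial coordinates.
#' @param k_att,k_rep Attraction / repulsion gains.
#' @param damping Step damping in `(0, 1]`.
#' @param max_step Per-axis displacement clip per iteration.
#' @param tol Stop when mean displacement falls below this.
#' @return A tibble `id`, `x`, `y` with attributes `iterations` (run)
#'   and `mean_displacement` (final).
#' @export
force_layout <- function(graph, iterations = 500, seed = 1, k_att = 0.2,
                         k_rep = 0.05, damping = 0.7, max_step = 1,
                         tol = 1e-4) {
  nodes <- graph$nodes
  n <- length(nodes)
  old <- .Random.seed_exists()
  set.seed(seed)
  pos <- matrix(stats::runif(2 * n, -1, 1), ncol = 2)
  old()
  idx <- stats::setNames(seq_len(n), nodes)
  ei <- idx[graph$edges$from]
  ej <- idx[graph$edges$to]
  w <- graph$edges$attraction
  eps <- 1e-6
  mean_disp <- NA_real_
  it_run <- 0L
  for (it in seq_len(iterations)) {
    force <- matrix(0, n, 2)
    if (length(ei) > 0) {
      d <- pos[ej, , drop = FALSE] - pos[ei, , drop = FALSE]
      att <- d * (w * k_att)
      for (ax in 1:2) {
        force[, ax] <- force[, ax] +
          tapply_sum(att[, ax], ei, n) - tapply_sum(att[, ax], ej, n)
      }
    }
    # pairwise inverse-square repulsion
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    d2 <- dx^2 + dy^2 + eps
    inv <- k_rep / d2
    diag(inv) <- 0
    force[, 1] <- force[, 1] + rowSums(dx * inv / sqrt(d2))
    force[, 2] <- force[, 2] + rowSums(dy * inv / sqrt(d2))
    step <- damping * pmin(pmax(force, -max_step), max_step)
    pos <- pos + step
    mean_disp <- mean(sqrt(rowSums(step^2)))
    it_run <- it
    if (mean_disp < tol) break
  }
  out <- tibble::tibble(id = nodes, x = pos[, 1], y = pos[, 2])
  attr(out, "iterations") <- it_run
  attr(out, "mean_displacement") <- mean_disp
  attr(out, "seed") <- seed
  out
}

# grouped sum into a length-n vector (base tapply returns ragged output)
tapply_sum <- function(v, g, n) {
  out <- numeric(n)
  s <- rowsum(v, g)
  out[as.integer(rownames(s))] <- s
  out
}

#' Extract clusters as connected components
#'
#' Clusters are the connected components of the similarity graph after
#' dropping edges above the e-value cutoff. Labels are integers ordered
#' by decreasing component size, ties broken by the smallest member id,
#' so the labelling is deterministic and invariant to edge order.
#'
#' @param graph A [build_similarity_graph()] result.
#' @param evalue_cutoff Optional stricter cutoff applied to the stored
#'   edges (default: keep all stored edges).
#' @return Tibble `id`, `cluster` (integer, 1 = largest).
#' @export
extract_clusters <- function(graph, evalue_cutoff = NULL) {
  edges <- graph$edges
  if (!is.null(evalue_cutoff)) {
    edges <- edges[edges$evalue <= evalue_cutoff, ]
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes)
  )
  comp <- igraph::components(g)
  member <- comp$membership[graph$nodes]
  # order component labels: size desc, then smallest member id
  info <- tibble::tibble(id = graph$nodes, raw = as.integer(member)) |>
    dplyr::group_by(.data$raw) |>
    dplyr::mutate(size = dplyr::n(), first_id = min(.data$id)) |>
    dplyr::ungroup()
  key <- info |>
    dplyr::distinct(.data$raw, .data$size, .data$first_id) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$first_id) |>
    dplyr::mutate(cluster = dplyr::row_number())
  info |>
    dplyr::left_join(key[, c("raw", "cluster")], by = "raw") |>
    dplyr::select("id", "cluster") |>
    dplyr::arrange(.data$id)
}

#' Rand index between two labelings
#'
#' Agreement between two partitions of the same items: the fraction of
#' item pairs on which the labelings agree (same/different cluster).
#'
#' @param labels_a,labels_b Vectors of cluster labels in the same item
#'   order.
#' @return Scalar in `[0, 1]`; 1 means identical partitions.
#' @export
rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  if (n < 2) {
    return(1)
  }
  same_a <- outer(labels_a, labels_a, "==")
  same_b <- outer(labels_b, labels_b, "==")
  agree <- same_a == same_b
  (sum(agree) - n) / (n * (n - 1))
}
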
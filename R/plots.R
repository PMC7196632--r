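#' Plot a dose-response fit
#'
#' Observed points and the fitted curve on a linear dose axis.
#'
#' @param object A `nadreg_fit` from [fit_model()].
#' @param n_curve Points used to draw the curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nadreg_fit <- function(object, n_curve = 200, ...) {
  pred <- object$spec$predictor_names[1]
  d <- object$data
  grid <- seq(min(d[[pred]]), max(d[[pred]]), length.out = n_curve)
  curve <- tibble::tibble(
    x = grid,
    y = evaluate_model(
      object$spec, object$estimates, stats::setNames(list(grid), pred)
    )
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[pred]], y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(
      data = curve, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "steelblue"
    ) +
    ggplot2::labs(
      x = pred, y = "response",
      title = paste0("Fit: ", object$model_id)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a global binding-kinetics fit
#'
#' Overlays the fitted association/dissociation curves on the measured
#' sensorgrams, one colour per analyte concentration.
#'
#' @param object A `bli_fit` from [fit_binding_global()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bli_fit <- function(object, ...) {
  d <- object$data
  sites <- .as_sites(object$params)
  fitted <- d |>
    dplyr::filter(.data$phase %in% c("association", "dissociation")) |>
    dplyr::group_by(.data$analyte_conc) |>
    dplyr::group_modify(function(df, key) {
      a <- df[df$phase == "association", ]
      dd <- df[df$phase == "dissociation", ]
      z <- a$response[1]
      cur <- .bli_curve(
        sites, key$analyte_conc * 1e-9,
        a$time - a$time[1], dd$time - a$time[nrow(a)]
      )
      tibble::tibble(
        time = c(a$time, dd$time), fit = z + c(cur$assoc, cur$diss)
      )
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(
    d, ggplot2::aes(
      x = .data$time, y = .data$response,
      colour = factor(.data$analyte_conc)
    )
  ) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_line(
      data = fitted,
      ggplot2::aes(y = .data$fit), linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "time (s)", y = "response (nm)", colour = "analyte (nM)",
      title = paste0("Global ", object$model, " fit")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a hysteresis scan
#'
#' Activity versus 2-oxoglutarate for the ascending (pre-formed complex)
#' and descending (de novo formation) branches; the gap between them is
#' the memory effect.
#'
#' @param scan Output of [hysteresis_scan()].
#' @return A ggplot object.
#' @export
plot_hysteresis <- function(scan) {
  ggplot2::ggplot(
    scan[scan$OG > 0, ],
    ggplot2::aes(
      x = .data$OG, y = .data$activity, colour = .data$branch
    )
  ) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "2-oxoglutarate (uM)", y = "NadE2 activity (%)",
      title = "Complex-history hysteresis"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a force-directed similarity layout
#'
#' @param layout Output of [force_layout()].
#' @param clusters Optional output of [extract_clusters()] to colour by.
#' @return A ggplot object.
#' @export
plot_layout <- function(layout, clusters = NULL) {
  d <- layout
  if (!is.null(clusters)) {
    d <- dplyr::left_join(d, clusters, by = "id")
    p <- ggplot2::ggplot(
      d, ggplot2::aes(
        x = .data$x, y = .data$y, colour = factor(.data$cluster)
      )
    ) +
      ggplot2::labs(colour = "cluster")
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Similarity layout") +
    ggplot2::theme_minimal()
}
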
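# ggplot2 visualisations for the main result types.

#' Risk-quotient heatmap
#'
#' Tile map of monthly risk quotients per compound and matrix, coloured by
#' risk band; compounds below the `min_rq` cut are dropped, mirroring the
#' usual presentation where insignificant cells are blanked.
#'
#' @param risk tibble from [risk_table()].
#' @param min_rq smallest RQ to display (default 0.1).
#' @return a ggplot object.
#' @export
plot_risk_heatmap <- function(risk, min_rq = 0.1) {
  df <- dplyr::filter(risk, .data$metric == "RQ", .data$value >= min_rq)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$compound_id,
                                   fill = .data$category)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_wrap(~matrix) +
    ggplot2::scale_fill_manual(values = c(
      insignificant = "grey90", low = "#ffe08a",
      medium = "#f58a53", high = "#c62828"
    ), drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "risk band") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Toxic/effect unit strip plot
#'
#' Monthly log10 toxic or effect units per compound with the -3.0 toxic-unit
#' threshold drawn for TU panels.
#'
#' @param risk tibble from [risk_table()].
#' @param metric `"TU"` or `"EU"`.
#' @param thresholds a [risk_thresholds()] object (for the TU reference
#'   line).
#' @return a ggplot object.
#' @export
plot_units <- function(risk, metric = c("TU", "EU"),
                       thresholds = risk_thresholds()) {
  metric <- match.arg(metric)
  df <- dplyr::filter(risk, .data$metric == !!metric)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$compound_id,
                                        y = .data$value,
                                        colour = .data$month)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.15,
                                                            height = 0)) +
    ggplot2::facet_wrap(~matrix) +
    ggplot2::labs(x = NULL, colour = "month",
                  y = paste0("log10 ", metric, " (internal)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (metric == "TU") {
    p <- p + ggplot2::geom_hline(yintercept = thresholds$tu_log_threshold,
                                 linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Score plot for a profile PCA
#'
#' Replicate scores on the first two retained components, coloured by matrix
#' when that metadata is present.
#'
#' @param object a `profile_pca` from [pca_profiles()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot profile_pca
#' @export
autoplot.profile_pca <- function(object, ...) {
  sc <- object$scores
  aes <- if ("matrix" %in% names(sc)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$matrix)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(sc, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$explained_var_pct[1]),
      y = sprintf("PC2 (%.1f%%)", object$explained_var_pct[2])
    ) +
    ggplot2::theme_minimal()
}

#' Calibration scatter for a sampler-vs-biota effect-unit fit
#'
#' Observed pairs, the fitted line and the 1:1 line.
#'
#' @param object a `calibration_fit` from [eu_calibration()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot calibration_fit
#' @export
autoplot.calibration_fit <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$eu_psd, y = .data$eu_biota)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70",
                         linetype = "dashed") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#2166ac") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "log10 EU (sampler-as-organism)",
      y = "log10 EU (invertebrate tissue)",
      subtitle = sprintf("slope %.2f, R^2 %.3f, n = %d",
                         object$slope, object$r2, object$n)
    ) +
    ggplot2::theme_minimal()
}
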
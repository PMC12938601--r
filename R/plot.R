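#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.tf_long <- function(m, freqs, times) {
  tibble::tibble(time = rep(times, each = length(freqs)),
                 freq = rep(freqs, length(times)),
                 value = as.vector(m))
}

#' Plot a time-frequency percent-change map
#'
#' @param object An [erd_percent()] result.
#' @param ... Unused.
#' @return A ggplot: time x frequency map of ERD/ERS%, blue = power
#'   decrease (ERD), red = increase (ERS).
#' @method autoplot erd_series
#' @export
autoplot.erd_series <- function(object, ...) {
  d <- .tf_long(object$percent, object$freqs, object$times)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$freq,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  na.value = "grey90",
                                  name = "ERD/ERS %") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Time (s, prompt at 0)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a significance map
#'
#' @param object A [pseudo_t_significance()] result.
#' @param ... Unused.
#' @return A ggplot of the pseudo-T map with the significant resels
#'   outlined.
#' @method autoplot significance_map
#' @export
autoplot.significance_map <- function(object, ...) {
  d <- .tf_long(object$pseudo_t, object$freqs, object$times)
  d$sig <- as.vector(object$sig_mask)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$freq)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = d[d$sig, ], size = 0.3, alpha = 0.6) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  na.value = "grey90", name = "pseudo-T") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)",
                  subtitle = sprintf("dots: q <= %.2f (FDR)", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted power spectrum model
#'
#' @param object A [fit_spectral_model()] result.
#' @param psd The PSD that was fitted (for the observed curve).
#' @param ... Unused.
#' @return A ggplot of observed log-power, the aperiodic fit and the
#'   full model.
#' @method autoplot spectral_model
#' @export
autoplot.spectral_model <- function(object, psd = NULL, ...) {
  f <- seq(object$range_hz[1], object$range_hz[2], length.out = 200)
  ap <- .aperiodic_eval(object$aperiodic, f)
  d <- tibble::tibble(freq = f, aperiodic = ap,
                      model = ap + .gaussian_eval(object$peaks, f))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$freq)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$aperiodic), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$model), linewidth = 0.8,
                       color = "#b2182b") +
    ggplot2::labs(x = "Frequency (Hz)", y = "log10 power") +
    ggplot2::theme_minimal()
  if (!is.null(psd)) {
    sel <- psd$freqs >= object$range_hz[1] & psd$freqs <= object$range_hz[2]
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(freq = psd$freqs[sel],
                            obs = log10(psd$power[sel])),
      ggplot2::aes(.data$freq, .data$obs), size = 0.7, alpha = 0.5)
  }
  p
}

#' Plot a component topography
#'
#' Interpolates the topography weights over a schematic head outline
#' (top view, nose up).
#'
#' @param topography Channel weight vector.
#' @param hm A [head_model()] providing electrode positions.
#' @return A ggplot.
#' @export
plot_topography <- function(topography, hm = head_model()) {
  el <- hm$electrodes
  r <- hm$radii[length(hm$radii)]
  d <- tibble::tibble(x = el[, 1], y = el[, 2], w = as.numeric(topography),
                      label = rownames(el))
  circ <- tibble::tibble(x = r * cos(seq(0, 2 * pi, length.out = 100)),
                         y = r * sin(seq(0, 2 * pi, length.out = 100)))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(data = circ, ggplot2::aes(.data$x, .data$y),
                       inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(color = .data$w), size = 6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2) +
    ggplot2::scale_color_gradient2(low = "#2166ac", mid = "white",
                                   high = "#b2182b", name = "weight") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot cohort features by proficiency group
#'
#' @param features Feature tibble with a `group` column (e.g. the
#'   [run_cohort()] features joined with its stratification).
#' @return A faceted ggplot of the four headline features by group.
#' @export
plot_group_features <- function(features) {
  cols <- c("erd_pct_lh", "erd_pct_rh", "rel_ers_power_lh",
            "rel_ers_power_rh")
  d <- tidyr::pivot_longer(features[, c("group", cols)],
                           dplyr::all_of(cols),
                           names_to = "feature")
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$value,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::facet_wrap(~ .data$feature, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
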
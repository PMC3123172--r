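# Profile and insertion plotting.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a residue profile
#'
#' Faceted line plot of the aggregated per-residue descriptors: helicity
#' percentage (with the calling threshold), smoothed ASAr, smoothed mean
#' insertion depth and environment percentage.
#'
#' @param object A `residue_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.residue_profile <- function(object, ...) {
  cfg <- attr(object, "config")
  thr <- if (!is.null(cfg)) cfg$helicity_threshold else 75
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("pos", "helicity_pct", "asar_smooth",
                                  "z_smooth", "mfp_pct")],
    -"pos", names_to = "descriptor", values_to = "value")
  long$descriptor <- factor(long$descriptor,
    levels = c("helicity_pct", "asar_smooth", "z_smooth", "mfp_pct"),
    labels = c("helicity (%)", "ASAr (smoothed)",
               "insertion depth z (A)", "environment (%)"))
  hline <- tibble::tibble(descriptor = factor("helicity (%)",
    levels = levels(long$descriptor)), value = thr)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(data = hline,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~descriptor, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "residue", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.residue_profile
#' @export
plot_profile <- function(object, ...) autoplot.residue_profile(object, ...)

#' Plot a membrane-insertion energy profile
#'
#' Best membrane potential per z position of an [insertion_scan()].
#'
#' @param object An `insertion_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.insertion_result <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$z, y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_z, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "centroid z (A)", y = "best E_pot_mem (kJ/mol)") +
    ggplot2::theme_minimal()
}

#' Plot a scan result
#'
#' The residue profile with the called center and limits overlaid.
#'
#' @param object A `tmd_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmd_scan <- function(object, ...) {
  p <- autoplot.residue_profile(object$profile)
  call <- object$call
  if (length(call$center_residues))
    p <- p + ggplot2::geom_vline(xintercept = call$center_residues,
                                 colour = "firebrick", linetype = "dotted")
  if (!any(is.na(call$limits)))
    p <- p + ggplot2::geom_vline(xintercept = call$limits,
                                 colour = "steelblue", linetype = "dashed")
  p
}
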
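# Figure exports: per-condition violin plot of the visual metrics and
# FROC curves on a log FP axis. ggplot2 is suggested, not required; both
# functions error informatively when it is absent.

#' Violin plot of per-case image-quality metrics across conditions
#'
#' @param imagqm data.frame with `condition`, `ssim` (and optionally
#'   `psnr`), as produced by [run_experiment()].
#' @param metric column to plot.
#' @return a ggplot object.
#' @export
plot_imagqm_violin <- function(imagqm, metric = "ssim") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_imagqm_violin requires the ggplot2 package")
  }
  df <- imagqm[is.finite(imagqm[[metric]]), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data[[metric]])) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme_minimal()
}

#' FROC curves per condition (log FP axis for display only)
#'
#' The pAUC is always integrated on the linear FP axis; the logarithmic
#' x-axis here is purely for display, as is conventional for FROC figures.
#'
#' @param froc_list named list of `froc_result`s.
#' @param pauc_values optional named pAUC vector for the legend.
#' @return a ggplot object.
#' @export
plot_froc <- function(froc_list, pauc_values = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_froc requires the ggplot2 package")
  }
  df <- do.call(rbind, lapply(names(froc_list), function(cond) {
    pts <- froc_list[[cond]]$points
    lab <- if (!is.null(pauc_values) && cond %in% names(pauc_values)) {
      sprintf("%s (pAUC %.2f)", cond, pauc_values[[cond]])
    } else cond
    data.frame(condition = lab, fp = pts$fp_per_patient,
               sens = pts$sensitivity)
  }))
  df <- df[df$fp > 0, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fp, y = .data$sens,
                                   colour = .data$condition)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "False positives per patient (log scale)",
                  y = "Lesion sensitivity", colour = NULL) +
    ggplot2::theme_minimal()
}
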
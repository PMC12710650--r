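#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot combined co-occurrence results
#'
#' Observed co-occurrence proportion against evidence strength
#' (-log10 combined p), with the significance call mapped to color.
#'
#' @param result Tibble from [run_cooccurrence()].
#' @param label_top Number of top pairs to label (default 5).
#' @return A ggplot object.
#' @export
plot_cooccurrence <- function(result, label_top = 5) {
  df <- dplyr::mutate(tibble::as_tibble(result),
                      neglog_p = -log10(pmax(.data$edgington_p, 1e-300)))
  top <- head(dplyr::arrange(df, .data$q), label_top)
  ggplot2::ggplot(df, ggplot2::aes(.data$observed_proportion,
                                   .data$neglog_p,
                                   color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_text(data = top,
                       ggplot2::aes(label = paste(.data$gene,
                                                  .data$cancer_type)),
                       vjust = -0.6, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "observed co-occurrence proportion",
                  y = expression(-log[10] ~ "combined p"),
                  color = "significant") +
    ggplot2::theme_minimal()
}

#' Plot allelic-imbalance calls against the matched background
#'
#' Each point is one tested mutation: observed VAF against its matched
#' background rate, colored by the imbalance call; the diagonal marks
#' balance.
#'
#' @param results Tibble from [run_binoculars()].
#' @return A ggplot object.
#' @export
plot_imbalance <- function(results) {
  ggplot2::ggplot(tibble::as_tibble(results),
                  ggplot2::aes(.data$p0, .data$vaf, color = .data$call)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(increased = "#c0392b",
                                           decreased = "#2980b9",
                                           no_change = "grey60")) +
    ggplot2::labs(x = "matched background VAF",
                  y = "observed VAF", color = "call") +
    ggplot2::theme_minimal()
}

#' Plot VAF against CNV dosage for one gene-cancer pair
#'
#' @param ds Rows from [build_vaf_dataset()] (one pair).
#' @return A ggplot object with the per-GISTIC-unit trend line.
#' @export
plot_vaf_dosage <- function(ds) {
  ggplot2::ggplot(ds, ggplot2::aes(.data$gistic, .data$vaf)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "#c0392b") +
    ggplot2::labs(x = "GISTIC copy-number code", y = "VAF") +
    ggplot2::theme_minimal()
}
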
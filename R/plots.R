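#' Plot connectivity scores by drug
#'
#' Dot plot of drug-level connectivity scores, FDR-passing hits
#' highlighted — the per-approach view of which drugs reverse (left
#' tail) or mimic (right tail) the query signature.
#'
#' @param results A [score_database()] tibble.
#' @param fdr_cut Highlight threshold (default 0.05).
#' @return A ggplot object.
#' @export
plot_connectivity_scores <- function(results, fdr_cut = 0.05) {
  df <- dplyr::mutate(results, hit = .data$fdr < fdr_cut)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                   y = stats::reorder(.data$drug_id,
                                                      .data$score),
                                   colour = .data$hit)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "connectivity score (negative = reversal)",
                  y = NULL, colour = paste("FDR <", fdr_cut),
                  title = unique(df$approach)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @describeIn fit_median_effect Diagnostic plot: observed points and
#'   the fitted median-effect curve on a log-dose axis.
#' @param object A `median_effect_fit`.
#' @param ... Unused.
#' @export
autoplot.median_effect_fit <- function(object, ...) {
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$fa)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "fraction affected") +
    ggplot2::theme_minimal()
  if (object$ic50_censored == "none") {
    grid <- exp(seq(log(min(df$dose)), log(max(df$dose)), length.out = 100))
    curve <- tibble::tibble(dose = grid,
                            fa = median_effect_fa(grid, object$Dm, object$m))
    p <- p + ggplot2::geom_line(data = curve, colour = "steelblue") +
      ggplot2::geom_vline(xintercept = object$Dm, linetype = 2,
                          colour = "steelblue")
  }
  p
}

#' @describeIn analyze_dose_matrix Heatmap of combination-index
#'   classes over the dose checkerboard.
#' @param object A `dose_matrix_result`.
#' @param ... Unused.
#' @export
autoplot.dose_matrix_result <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = factor(.data$dose1_nmol_l),
                               y = factor(.data$dose2_nmol_l),
                               fill = .data$ci)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$ci)),
                       size = 2.5, na.rm = TRUE) +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "firebrick",
                                  mid = "white", high = "navy",
                                  na.value = "grey85") +
    ggplot2::labs(x = paste(unique(object$cells$drug1), "(nmol/L)"),
                  y = paste(unique(object$cells$drug2), "(nmol/L)"),
                  fill = "CI") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' Step curves of the product-limit estimate per arm, with censoring
#' marks.
#'
#' @param km A [km_estimate()] tibble.
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  start <- km |>
    dplyr::distinct(.data$arm) |>
    dplyr::mutate(time = 0, survival = 1, n_censor = 0)
  df <- dplyr::bind_rows(start, km) |>
    dplyr::arrange(.data$arm, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$n_censor > 0),
                        shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival S(t)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a concentration-time profile
#'
#' @param profile Tibble `time_hr`, `conc_ug_per_ml`.
#' @param log_y Log-scale the concentration axis (default TRUE; the
#'   terminal phase is linear on this scale).
#' @return A ggplot object.
#' @export
plot_pk_profile <- function(profile, log_y = TRUE) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$time_hr,
                                             y = .data$conc_ug_per_ml)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (hr)", y = "concentration (ug/mL)") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
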
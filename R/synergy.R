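#' Chou-Talalay combination index
#'
#' For a combination cell with doses `(d1, d2)` and observed fraction
#' affected `fa`, the mutually exclusive (Loewe-type) combination index
#' is `CI = d1/Dx1(fa) + d2/Dx2(fa)`, where `Dx_i` is the single-agent
#' dose of drug `i` producing the same effect under its median-effect
#' fit. `CI < 1` indicates synergy, `CI = 1` additivity, `CI > 1`
#' antagonism.
#'
#' Cells with negative inhibition (`fa <= 0`) or complete effect
#' (`fa >= 1`) are undefined (`NA`) — negative inhibition values cannot
#' be used to calculate CI — as is everything when either single-agent
#' fit is censored.
#'
#' @param d1,d2 Doses of the two drugs (same units as their fits).
#' @param fa Observed fraction affected at each combination cell.
#' @param fit1,fit2 Uncensored [fit_median_effect()] objects for the
#'   two single agents.
#' @return Numeric vector of CI values (`NA` where undefined).
#' @examples
#' f1 <- list(Dm = 1, m = 1, ic50_censored = "none")
#' f2 <- list(Dm = 2, m = 1, ic50_censored = "none")
#' combination_index(0.25, 0.5, fa = 0.5, f1, f2)  # 0.5
#' @export
combination_index <- function(d1, d2, fa, fit1, fit2) {
  for (f in list(fit1, fit2)) {
    if (!is.null(f$ic50_censored) && f$ic50_censored != "none") {
      warn("single-agent fit is censored; CI undefined everywhere")
      return(rep(NA_real_, length(fa)))
    }
  }
  dx1 <- dose_for_effect(fa, fit1$Dm, fit1$m)
  dx2 <- dose_for_effect(fa, fit2$Dm, fit2$m)
  d1 / dx1 + d2 / dx2
}

#' Classify a combination index into effect bands
#'
#' Bands follow the usual reporting convention: `CI < 0.5` strong
#' synergy, `0.5 <= CI < 0.9` synergy, `CI` within the additive band
#' (default `[0.9, 1.1]`) additive, larger antagonism; `NA` maps to
#' `"undefined"`. The upper edge of the additive band is a pinned,
#' configurable choice — the convention leaves the region just below 1
#' and the exact boundaries open.
#'
#' @param ci Numeric CI values (may contain `NA`).
#' @param strong,synergy Upper edges of the strong-synergy and synergy
#'   bands (defaults 0.5 and 0.9).
#' @param additive_hi Upper edge of the additive band (default 1.1).
#' @return Factor with levels `strong_synergy`, `synergy`, `additive`,
#'   `antagonism`, `undefined`.
#' @examples
#' classify_ci(c(0.3, 1.0, 2.0, NA))
#' @export
classify_ci <- function(ci, strong = 0.5, synergy = 0.9,
                        additive_hi = 1.1) {
  lab <- dplyr::case_when(
    is.na(ci) ~ "undefined",
    ci < strong ~ "strong_synergy",
    ci < synergy ~ "synergy",
    ci <= additive_hi ~ "additive",
    TRUE ~ "antagonism"
  )
  factor(lab, levels = c("strong_synergy", "synergy", "additive",
                         "antagonism", "undefined"))
}

#' Analyze a 9x9 dose-matrix block
#'
#' Takes the long form of a two-drug checkerboard (eight two-fold
#' dilutions per drug plus the zero row/column), averages replicates,
#' fits each drug's median-effect curve from its single-agent axis
#' (the cells where the other drug's dose is zero), computes the
#' combination index on every interior cell, and classifies it.
#'
#' @param data Long tibble with columns `drug1`, `drug2`,
#'   `dose1_nmol_l`, `dose2_nmol_l`, `replicate` (optional) and either
#'   `fraction_affected` or `percent_inhibition`.
#' @param ... Passed to [fit_median_effect()].
#' @return A list of class `dose_matrix_result`: `fit1`, `fit2`
#'   (single-agent fits), `cells` (tibble of interior cells with `fa`,
#'   `ci`, `ci_class`) and `summary` (median interior CI and class
#'   counts).
#' @export
analyze_dose_matrix <- function(data, ...) {
  tbl <- tibble::as_tibble(data)
  if (!"fraction_affected" %in% names(tbl)) {
    if (!"percent_inhibition" %in% names(tbl)) {
      abort("need fraction_affected or percent_inhibition")
    }
    tbl$fraction_affected <- tbl$percent_inhibition / 100
  }
  cells <- tbl |>
    dplyr::group_by(.data$drug1, .data$drug2, .data$dose1_nmol_l,
                    .data$dose2_nmol_l) |>
    dplyr::summarise(fa = mean(.data$fraction_affected), .groups = "drop")

  axis1 <- dplyr::filter(cells, .data$dose2_nmol_l == 0,
                         .data$dose1_nmol_l > 0)
  axis2 <- dplyr::filter(cells, .data$dose1_nmol_l == 0,
                         .data$dose2_nmol_l > 0)
  if (nrow(axis1) == 0 || nrow(axis2) == 0) {
    abort("dose matrix must include the zero row and column (single-agent axes)")
  }
  fit1 <- fit_median_effect(axis1, dose = dose1_nmol_l, fa = fa, ...)
  fit2 <- fit_median_effect(axis2, dose = dose2_nmol_l, fa = fa, ...)

  interior <- cells |>
    dplyr::filter(.data$dose1_nmol_l > 0, .data$dose2_nmol_l > 0) |>
    dplyr::mutate(
      ci = combination_index(.data$dose1_nmol_l, .data$dose2_nmol_l,
                             .data$fa, fit1, fit2),
      ci_class = classify_ci(.data$ci)
    )
  structure(
    list(fit1 = fit1, fit2 = fit2, cells = interior,
         summary = tibble::tibble(
           median_ci = median(interior$ci, na.rm = TRUE),
           n_defined = sum(!is.na(interior$ci)),
           n_undefined = sum(is.na(interior$ci)),
           modal_class = names(which.max(table(interior$ci_class)))
         )),
    class = "dose_matrix_result"
  )
}

#' @export
print.dose_matrix_result <- function(x, ...) {
  cat("<dose_matrix_result> ", nrow(x$cells), " interior cells; median CI ",
      format(x$summary$median_ci), " (", x$summary$modal_class, ")\n",
      sep = "")
  invisible(x)
}
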
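#' Tidy a median-effect fit
#'
#' @param x A [fit_median_effect()] object.
#' @param ... Unused.
#' @return One-row tibble with `Dm`, `m`, `sse`, `n_used`,
#'   `ic50_censored`, `ic50_label`.
#' @export
tidy.median_effect_fit <- function(x, ...) {
  tibble::tibble(Dm = x$Dm, m = x$m, sse = x$sse, n_used = x$n_used,
                 ic50_censored = x$ic50_censored,
                 ic50_label = x$ic50_label)
}

#' @rdname tidy.median_effect_fit
#' @export
glance.median_effect_fit <- function(x, ...) {
  tibble::tibble(n_used = x$n_used, sse = x$sse,
                 censored = x$ic50_censored != "none")
}

#' Tidy an NCA result into a parameter table
#'
#' One row per pharmacokinetic parameter, mirroring the conventional
#' PK summary-table layout.
#'
#' @param x An [nca()] result.
#' @param ... Unused.
#' @return Tibble with `parameter`, `value`, `unit`.
#' @export
tidy.nca_result <- function(x, ...) {
  tibble::tibble(
    parameter = c("Cmax", "Cmax_molar", "Tmax", "AUC_0_t", "AUC_0_inf",
                  "Kel", "T_half", "Cl_F", "dose"),
    value = c(x$Cmax, x$Cmax_molar, x$Tmax, x$AUC_0_t, x$AUC_0_inf,
              x$Kel, x$T_half, x$Cl_F, x$dose_ug_kg),
    unit = c("ug/mL", "umol/L", "hr", "ug*hr/mL", "ug*hr/mL",
             "1/hr", "hr", "mL/hr/kg", "ug/kg")
  )
}

#' @rdname tidy.nca_result
#' @export
glance.nca_result <- function(x, ...) {
  tibble::tibble(terminal_points_used = x$terminal_points_used,
                 terminal_r2 = x$terminal_r2,
                 extrapolated = x$extrapolated,
                 flag = x$flag)
}

#' Tidy a dose-matrix synergy result
#'
#' @param x An [analyze_dose_matrix()] result.
#' @param ... Unused.
#' @return The interior-cell tibble with CI values and classes.
#' @export
tidy.dose_matrix_result <- function(x, ...) x$cells

#' @rdname tidy.dose_matrix_result
#' @export
glance.dose_matrix_result <- function(x, ...) x$summary
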
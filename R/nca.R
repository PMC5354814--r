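GOLD_MW <- 196.97        # g/mol, elemental gold
AURANOFIN_MW <- 678.48   # g/mol, gold triethylphosphine thioglucose tetraacetate

#' Auranofin / gold unit conversions
#'
#' Auranofin is dosed as the parent complex but assayed as blood gold,
#' so doses and concentrations move between the two scales via fixed
#' molecular masses (gold 196.97 g/mol, auranofin 678.48 g/mol):
#' gold is 196.97/678.48 = 29% of auranofin by weight.
#'
#' @return `gold_mass_fraction()`: the mass fraction (~0.2903).
#' @examples
#' gold_dose(12)      # 3.48 mg/kg gold from 12 mg/kg auranofin
#' to_molar(12.43)    # 63.10 umol/L from 12.43 ug/mL gold
#' @export
gold_mass_fraction <- function() GOLD_MW / AURANOFIN_MW

#' @rdname gold_mass_fraction
#' @param auranofin_dose Auranofin dose (mg/kg, >= 0).
#' @return `gold_dose()`: the contained gold dose (mg/kg).
#' @export
gold_dose <- function(auranofin_dose) {
  if (any(auranofin_dose < 0)) abort("dose must be non-negative")
  auranofin_dose * gold_mass_fraction()
}

#' @rdname gold_mass_fraction
#' @param conc_ug_per_ml Mass concentration (ug/mL, >= 0).
#' @param mw Molar mass (g/mol); defaults to gold.
#' @return `to_molar()`: molar concentration (umol/L).
#' @export
to_molar <- function(conc_ug_per_ml, mw = GOLD_MW) {
  if (any(conc_ug_per_ml < 0)) abort("concentration must be non-negative")
  conc_ug_per_ml / mw * 1000
}

#' Linear trapezoidal AUC
#'
#' Area under a concentration-time profile by the linear trapezoid
#' rule; additive over contiguous time partitions.
#'
#' @param time Strictly increasing times (hr).
#' @param conc Concentrations (>= 0), same length.
#' @return AUC in conc x time units.
#' @export
auc_linear <- function(time, conc) {
  if (length(time) != length(conc) || length(time) < 2) {
    abort("need matched time/conc vectors of length >= 2")
  }
  if (any(diff(time) <= 0)) abort("times must be strictly increasing")
  sum(diff(time) * (head(conc, -1) + conc[-1]) / 2)
}

#' Non-compartmental analysis of a concentration-time profile
#'
#' Model-free pharmacokinetic summary: `Cmax`/`Tmax` are the observed
#' maximum and its time; `AUC(0-t)` comes from the linear trapezoid
#' over the observed points; the terminal elimination constant `Kel`
#' is minus the least-squares slope of `ln C` on `t` over a terminal
#' window chosen by `terminal_rule`; then
#' `AUC(0-inf) = AUC(0-t) + C_last/Kel`, `T1/2 = ln2/Kel`, and
#' apparent clearance `Cl/F = dose / AUC(0-inf)` (mL/hr/kg for a dose
#' in ug/kg and concentrations in ug/mL).
#'
#' The default terminal rule scans windows of the last 3..6 positive
#' concentrations (excluding `Tmax` itself) and keeps the best
#' adjusted R-squared; `"last3"` always uses the final three. A
#' non-positive terminal slope (no elimination phase) refuses
#' extrapolation: the result carries `AUC(0-t)` only and a flag.
#'
#' @param profile Tibble with columns `time_hr` (strictly increasing,
#'   including 0) and `conc_ug_per_ml` (>= 0); at least 3 points.
#' @param dose_ug_kg Analyte dose per kg (e.g. `gold_dose(12) * 1000`
#'   for blood gold after 12 mg/kg auranofin); optional — without it
#'   `Cl_F` is `NA`.
#' @param terminal_rule `"best_fit"` (default) or `"last3"`.
#' @return An `nca_result` object; see [tidy.nca_result()].
#' @examples
#' prof <- gen_pk_profile(list(ka = 1, ke = 0.029, V_F = 250,
#'                             dose_ug_kg = 3480))
#' nca(prof, dose_ug_kg = 3480)
#' @export
nca <- function(profile, dose_ug_kg = NULL,
                terminal_rule = c("best_fit", "last3")) {
  terminal_rule <- match.arg(terminal_rule)
  profile <- tibble::as_tibble(profile)
  if (!all(c("time_hr", "conc_ug_per_ml") %in% names(profile))) {
    abort("profile needs columns time_hr, conc_ug_per_ml")
  }
  t <- profile$time_hr
  cc <- profile$conc_ug_per_ml
  if (length(t) < 3) abort("need >= 3 time points")
  if (any(diff(t) <= 0)) abort("times must be strictly increasing")
  if (any(cc < 0)) abort("concentrations must be non-negative")

  i_max <- which.max(cc)
  cmax <- cc[i_max]
  tmax <- t[i_max]
  auc_t <- auc_linear(t, cc)

  # terminal candidates: positive concentrations after (not at) Tmax
  cand <- which(t > tmax & cc > 0)
  fit_window <- function(idx) {
    f <- lm(log(cc[idx]) ~ t[idx])
    r2 <- suppressWarnings(summary(f)$adj.r.squared)
    list(idx = idx, slope = unname(coef(f)[2]), r2 = r2)
  }
  pick <- NULL
  if (length(cand) >= 3) {
    if (terminal_rule == "last3") {
      pick <- fit_window(utils::tail(cand, 3))
    } else {
      sizes <- 3:min(6, length(cand))
      fits <- lapply(sizes, function(k) fit_window(utils::tail(cand, k)))
      ok <- vapply(fits, function(f) is.finite(f$r2), logical(1))
      if (any(ok)) {
        fits <- fits[ok]
        pick <- fits[[which.max(vapply(fits, function(f) f$r2, numeric(1)))]]
      }
    }
  }

  res <- list(
    Cmax = cmax, Cmax_molar = to_molar(cmax), Tmax = tmax,
    AUC_0_t = auc_t, AUC_0_inf = NA_real_,
    Kel = NA_real_, T_half = NA_real_, Cl_F = NA_real_,
    dose_ug_kg = dose_ug_kg %||% NA_real_,
    terminal_points_used = 0L, terminal_r2 = NA_real_,
    extrapolated = FALSE, flag = NA_character_
  )
  class(res) <- "nca_result"

  if (is.null(pick)) {
    res$flag <- "fewer than 3 usable terminal points; AUC(0-t) only"
    return(res)
  }
  if (pick$slope >= 0) {
    res$flag <- "non-positive terminal slope; extrapolation refused"
    return(res)
  }
  kel <- -pick$slope
  c_last <- cc[max(which(cc > 0))]
  res$Kel <- kel
  res$T_half <- log(2) / kel
  res$AUC_0_inf <- auc_t + c_last / kel
  res$terminal_points_used <- length(pick$idx)
  res$terminal_r2 <- pick$r2
  res$extrapolated <- TRUE
  if (!is.na(res$dose_ug_kg)) res$Cl_F <- res$dose_ug_kg / res$AUC_0_inf
  res
}

#' @export
print.nca_result <- function(x, ...) {
  cat("<nca_result>\n")
  cat(sprintf("  Cmax %.4g ug/mL (%.4g umol/L) at Tmax %g hr\n",
              x$Cmax, x$Cmax_molar, x$Tmax))
  cat(sprintf("  AUC(0-t) %.4g; AUC(0-inf) %.4g ug*hr/mL\n",
              x$AUC_0_t, x$AUC_0_inf))
  cat(sprintf("  Kel %.4g /hr; T1/2 %.4g hr; Cl/F %.4g mL/hr/kg\n",
              x$Kel, x$T_half, x$Cl_F))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Trough concentrations and accumulation under repeated dosing
#'
#' Reads the pre-dose (trough) concentration at each multiple of the
#' dosing interval from a multi-dose profile, and — when a single-dose
#' reference profile is supplied — the accumulation ratio
#' `trough_n / C_single(tau)`.
#'
#' @param profile Multi-dose concentration-time tibble (`time_hr`,
#'   `conc_ug_per_ml`), times measured from the first dose.
#' @param tau Dosing interval (hr, default 24).
#' @param n_doses Number of doses administered.
#' @param single_profile Optional single-dose reference profile
#'   containing time `tau`.
#' @return Tibble with one row per dosing interval: `dose_number`,
#'   `time_hr`, `trough`, `accumulation_ratio` (NA without a
#'   reference, flagged by message).
#' @export
trough_summary <- function(profile, tau = 24, n_doses = NULL,
                           single_profile = NULL) {
  profile <- tibble::as_tibble(profile)
  trough_times <- tau * seq_len(n_doses %||%
                                  floor(max(profile$time_hr) / tau))
  idx <- match(trough_times, profile$time_hr)
  if (anyNA(idx)) {
    warn(paste("trough time(s) absent from the profile:",
               paste(trough_times[is.na(idx)], collapse = ", ")))
  }
  ref <- NA_real_
  if (is.null(single_profile)) {
    inform("no single-dose reference profile; accumulation ratio unavailable")
  } else {
    j <- match(tau, single_profile$time_hr)
    if (is.na(j)) {
      warn("single-dose profile lacks the trough time; ratio unavailable")
    } else {
      ref <- single_profile$conc_ug_per_ml[j]
    }
  }
  tibble::tibble(
    dose_number = seq_along(trough_times),
    time_hr = trough_times,
    trough = profile$conc_ug_per_ml[idx],
    accumulation_ratio = .data$trough / ref
  )
}
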
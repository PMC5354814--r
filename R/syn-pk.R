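#' Default blood-sampling time grid
#'
#' Pre-dose plus 5, 15, 30 and 60 minutes and 2, 4, 8, 12, 24 and 48
#' hours — the standard rich sampling schedule for a single-dose
#' rodent PK study.
#'
#' @return Times in hours, ascending from 0.
#' @export
default_pk_times <- function() {
  c(0, 5 / 60, 0.25, 0.5, 1, 2, 4, 8, 12, 24, 48)
}

# one-compartment first-order absorption concentration at time t >= 0
one_compartment_conc <- function(t, ka, ke, V_F, dose) {
  ifelse(t <= 0, 0,
         dose * ka / (V_F * (ka - ke)) * (exp(-ke * t) - exp(-ka * t)))
}

#' Generate a concentration-time profile
#'
#' One-compartment model with first-order absorption:
#' `C(t) = (F*Dose*ka) / (V*(ka - ke)) * (exp(-ke*t) - exp(-ka*t))`,
#' extended to repeated dosing by superposition of doses at
#' `0, tau, 2*tau, ...`. `C(0) = 0` (pre-dose). Optional
#' multiplicative lognormal-free gaussian noise via `noise_cv`.
#'
#' @param pk_params List with `ka` (1/hr), `ke` (1/hr, `!= ka` — the
#'   flip-flop degenerate case is rejected), `V_F` (apparent volume,
#'   mL/kg) and `dose_ug_kg` (absorbed analyte dose, ug/kg).
#' @param times Sampling times (hr) from the first dose; default
#'   [default_pk_times()].
#' @param n_doses Number of doses (default 1).
#' @param tau Dosing interval (hr) when `n_doses > 1`.
#' @param noise_cv Multiplicative noise CV (default 0, noiseless).
#' @param seed Seed used when `noise_cv > 0`.
#' @return Tibble `time_hr`, `conc_ug_per_ml`.
#' @export
gen_pk_profile <- function(pk_params, times = default_pk_times(),
                           n_doses = 1L, tau = 24, noise_cv = 0,
                           seed = 1L) {
  ka <- pk_params$ka; ke <- pk_params$ke
  if (ka == ke) abort("ka must differ from ke (flip-flop degenerate case)")
  if (any(times < 0)) abort("times must be non-negative")
  conc <- Reduce(`+`, lapply(seq_len(n_doses) - 1L, function(k) {
    one_compartment_conc(times - k * tau, ka, ke,
                         pk_params$V_F, pk_params$dose_ug_kg)
  }))
  if (noise_cv > 0) {
    withr::with_seed(seed, {
      conc <- pmax(0, conc * (1 + rnorm(length(conc), sd = noise_cv)))
    })
  }
  tibble::tibble(time_hr = times, conc_ug_per_ml = conc)
}

#' Generate exponential survival data with administrative censoring
#'
#' Event times are exponential with the per-arm hazard; animals alive
#' at `censor_day` are censored. Kaplan-Meier comparisons downstream
#' need only the ordered event times, so exponential hazards are the
#' simplest adequate model.
#'
#' @param params Tibble with columns `arm`, `hazard` (1/day), `n`
#'   (default [default_survival_params()]).
#' @param censor_day Administrative censoring day.
#' @param seed Seed.
#' @return Tibble `subject`, `arm`, `time_days`, `event` (1 = death /
#'   sacrifice, 0 = censored).
#' @export
gen_survival <- function(params = default_survival_params(),
                         censor_day = 60, seed = 1L) {
  if (any(params$hazard <= 0) || any(params$n < 1)) {
    abort("hazards must be positive and n >= 1")
  }
  withr::with_seed(seed, {
    out <- purrr::pmap_dfr(params, function(arm, hazard, n) {
      tt <- rexp(n, rate = hazard)
      tibble::tibble(
        arm = arm,
        time_days = pmin(tt, censor_day),
        event = as.integer(tt <= censor_day)
      )
    })
  })
  out$subject <- sprintf("m%03d", seq_len(nrow(out)))
  dplyr::select(out, "subject", "arm", "time_days", "event")
}
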
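#' Generate a 384-well screening plate
#'
#' Lays out a plate the way single-concentration viability screens are
#' run: sample wells in the interior columns, vehicle (negative) and
#' kill (positive) control wells in dedicated edge columns, sized per
#' `cfg$plate_controls` so the expected Z-prime comfortably clears 0.5.
#' Signals follow `vehicle_mean * (1 - inhibition) * (1 + e)` with
#' multiplicative gaussian noise `e ~ N(0, cv)` floored at zero —
#' luminescence noise scales with signal.
#'
#' @param cfg A [syn_config()].
#' @param potency_map Named numeric vector: compound id -> fraction
#'   inhibition at 1 umol/L, in `[0, 1]`. At most 320 compounds per
#'   plate.
#' @param plate_id,cell_line Identifiers stamped on the records.
#' @param vehicle_mean Expected vehicle signal (arbitrary luminescence
#'   units).
#' @param seed Seed for this plate (default derived from the config).
#' @return A plate-record tibble (see [plate_qc()] for the columns).
#' @export
gen_plate <- function(cfg, potency_map, plate_id = "P001",
                      cell_line = "EWS1", vehicle_mean = 10000,
                      seed = cfg$seed + 401L) {
  if (any(potency_map < 0 | potency_map > 1)) {
    abort("potency values must lie in [0, 1]")
  }
  if (length(potency_map) > 320) abort("at most 320 sample wells per plate")
  cv <- cfg$plate_noise_cv
  kf <- cfg$kill_fraction
  exp_z <- 1 - 3 * cv * (2 - kf) / kf
  if (exp_z < 0) {
    warn(sprintf("plate noise so large that expected Z' = %.2f < 0", exp_z))
  }
  n_veh <- cfg$plate_controls[["vehicle"]]
  n_pos <- cfg$plate_controls[["positive"]]
  rows <- LETTERS[1:16]
  ctrl_well <- function(n, cols) {
    paste0(rep(rows, length(cols))[seq_len(n)],
           rep(cols, each = 16)[seq_len(n)])
  }
  pos_wells <- ctrl_well(n_pos, c(1, 2))
  veh_wells <- ctrl_well(n_veh, c(23, 24))
  smp_wells <- paste0(rep(rows, 20), rep(3:22, each = 16))[seq_along(potency_map)]

  tbl <- tibble::tibble(
    plate_id = plate_id,
    well = c(pos_wells, veh_wells, smp_wells),
    well_type = c(rep("positive_control", n_pos), rep("vehicle", n_veh),
                  rep("sample", length(potency_map))),
    compound_id = c(rep(NA_character_, n_pos + n_veh), names(potency_map)),
    conc_umol_l = c(rep(NA_real_, n_pos + n_veh),
                    rep(1, length(potency_map))),
    inhibition_true = c(rep(kf, n_pos), rep(0, n_veh),
                        unname(potency_map)),
    cell_line = cell_line
  )
  tbl$row <- substr(tbl$well, 1, 1)
  tbl$col <- as.integer(substring(tbl$well, 2))
  withr::with_seed(seed, {
    noise <- rnorm(nrow(tbl), sd = cv)
  })
  tbl$signal <- pmax(0, vehicle_mean * (1 - tbl$inhibition_true) * (1 + noise))
  dplyr::select(tbl, "plate_id", "well", "row", "col", "well_type",
                "compound_id", "conc_umol_l", "signal", "cell_line")
}

#' Default 12-point validation dose grid
#'
#' Twelve log-spaced concentrations from 0.001 to 50 umol/L — the
#' conventional 1 nmol/L to 50 umol/L validation range.
#'
#' @return Numeric vector of doses (umol/L), ascending.
#' @export
default_dose_grid <- function() {
  exp(seq(log(0.001), log(50), length.out = 12))
}

#' Generate a median-effect dose-response curve
#'
#' Responses follow `fa = 1/(1 + (Dm/D)^m)` with optional additive
#' gaussian noise on the fraction affected.
#'
#' @param params List with `Dm` (umol/L) and `m`, both positive.
#' @param doses Dose grid (umol/L); default [default_dose_grid()].
#' @param noise_sd Additive noise SD on `fa` (default 0, noiseless).
#' @param compound_id,cell_line,replicate Identifiers for the output.
#' @param seed Seed used when `noise_sd > 0`.
#' @return Tibble `compound_id`, `cell_line`, `replicate`,
#'   `conc_umol_l`, `fraction_affected`.
#' @export
gen_dose_response <- function(params, doses = default_dose_grid(),
                              noise_sd = 0, compound_id = "drugA",
                              cell_line = "EWS1", replicate = 1L,
                              seed = 1L) {
  if (params$Dm <= 0 || params$m <= 0) abort("Dm and m must be positive")
  if (any(doses <= 0)) abort("doses must be positive")
  fa <- median_effect_fa(doses, params$Dm, params$m)
  if (noise_sd > 0) {
    withr::with_seed(seed, fa <- fa + rnorm(length(fa), sd = noise_sd))
  }
  tibble::tibble(compound_id = compound_id, cell_line = cell_line,
                 replicate = replicate, conc_umol_l = doses,
                 fraction_affected = fa)
}

#' Default 9x9 checkerboard dose grid
#'
#' Eight serial two-fold dilutions from 1 umol/L down to 7.8 nmol/L,
#' plus the zero dose, in nmol/L.
#'
#' @return Numeric vector of nine doses (nmol/L), ascending from 0.
#' @export
default_matrix_doses <- function() {
  c(0, 1000 / 2^(7:0))
}

#' Generate a 9x9 two-drug dose matrix with a planted interaction
#'
#' Single-agent axes follow each drug's median-effect curve. Interior
#' cells follow a scaled Loewe model: the fraction affected is the
#' solution of `d1/Dx1(fa) + d2/Dx2(fa) = alpha`, so the combination
#' index recovered downstream equals `alpha` on every interior cell
#' (up to noise). `alpha = 1` is exact Loewe additivity, `alpha < 1`
#' plants synergy, `alpha > 1` antagonism.
#'
#' @param params1,params2 Lists with `Dm` (nmol/L, matching the dose
#'   grid units) and `m` for the two drugs.
#' @param interaction `"loewe_additive"`, `"synergy"` or
#'   `"antagonism"`; sets the default `alpha` (1, 0.5, 2).
#' @param alpha Optional explicit dose-scaling factor (overrides
#'   `interaction`).
#' @param doses Dose grid including 0 (default
#'   [default_matrix_doses()]).
#' @param noise_sd Additive noise SD on `fa` (default 0).
#' @param drug1,drug2 Drug ids.
#' @param seed Seed used when `noise_sd > 0`.
#' @return Long tibble `drug1`, `drug2`, `dose1_nmol_l`,
#'   `dose2_nmol_l`, `replicate`, `fraction_affected`.
#' @export
gen_dose_matrix <- function(params1, params2,
                            interaction = c("loewe_additive", "synergy",
                                            "antagonism"),
                            alpha = NULL, doses = default_matrix_doses(),
                            noise_sd = 0, drug1 = "drugA", drug2 = "drugB",
                            seed = 1L) {
  interaction <- match.arg(interaction)
  alpha <- alpha %||% c(loewe_additive = 1, synergy = 0.5,
                        antagonism = 2)[[interaction]]
  for (p in list(params1, params2)) {
    if (p$Dm <= 0 || p$m <= 0) abort("Dm and m must be positive")
  }
  grid <- tidyr::expand_grid(dose1_nmol_l = doses, dose2_nmol_l = doses)
  fa <- purrr::pmap_dbl(grid, function(dose1_nmol_l, dose2_nmol_l) {
    d1 <- dose1_nmol_l; d2 <- dose2_nmol_l
    if (d1 == 0 && d2 == 0) return(0)
    if (d2 == 0) return(median_effect_fa(d1, params1$Dm, params1$m))
    if (d1 == 0) return(median_effect_fa(d2, params2$Dm, params2$m))
    loewe_fa(d1, d2, params1, params2, alpha)
  })
  if (noise_sd > 0) {
    withr::with_seed(seed, fa <- fa + rnorm(length(fa), sd = noise_sd))
  }
  tibble::tibble(drug1 = drug1, drug2 = drug2,
                 dose1_nmol_l = grid$dose1_nmol_l,
                 dose2_nmol_l = grid$dose2_nmol_l,
                 replicate = 1L, fraction_affected = fa)
}

# fraction affected solving d1/Dx1(fa) + d2/Dx2(fa) = alpha
loewe_fa <- function(d1, d2, p1, p2, alpha) {
  if (p1$m == p2$m) {
    u <- (d1 / p1$Dm + d2 / p2$Dm) / alpha
    um <- u^p1$m
    return(um / (1 + um))
  }
  g <- function(fa) {
    d1 / dose_for_effect(fa, p1$Dm, p1$m) +
      d2 / dose_for_effect(fa, p2$Dm, p2$m) - alpha
  }
  stats::uniroot(g, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}
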
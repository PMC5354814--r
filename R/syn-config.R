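#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data module into one validated
#' object. The defaults describe the study conditions the rest of the
#' package is exercised under: a 2,000-gene universe, a 200-drug
#' perturbation library with one to five replicate instances per drug
#' (real connectivity databases hold several experimental instances per
#' compound), a handful of planted reverser and mimic drugs whose
#' profiles are anti-correlated (resp. correlated) with the query
#' signature, 384-well screening plates, median-effect dose-response
#' behaviour, one-compartment absorption pharmacokinetics and
#' exponential survival arms.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   `(config, seed)` and identical seeds give bit-identical output.
#' @param n_genes Size of the gene universe (`g1` ... `gN`).
#' @param n_drugs Number of distinct drugs in the perturbation library.
#' @param instances_per_drug Candidate replicate-instance counts; each
#'   drug draws its instance count uniformly from this set, emulating
#'   libraries where compounds were profiled in several experiments.
#' @param n_planted_reversers,n_planted_mimics Number of drugs planted
#'   as signature reversers (up-genes pushed to the bottom of the
#'   ranking, down-genes to the top) and as mimics (the opposite).
#' @param signature_size Genes per direction in generated signatures.
#' @param noise_sd Standard deviation of the latent expression noise
#'   added before rank-transforming planted profiles; 0 gives noiseless,
#'   perfectly recoverable plantings.
#' @param plant_effect Absolute latent shift applied to signature genes
#'   in planted instances, in units of the latent noise scale.
#' @param plate_format Wells per screening plate (384 only).
#' @param plate_noise_cv Multiplicative (CV) luminescence noise on plate
#'   signals; luminescence noise scales with signal.
#' @param plate_controls Vehicle / positive-control wells per plate.
#' @param kill_fraction Fraction of signal removed in positive-control
#'   (kill) wells.
#' @param hill_params Named list of median-effect parameters used by the
#'   dose-response generators: `Dm` (median-effect dose, umol/L), `m`
#'   (sigmoidicity).
#' @param pk_params Named list for the one-compartment absorption model:
#'   `ka` (1/hr), `ke` (1/hr), `V_F` (apparent volume, mL/kg),
#'   `dose_ug_kg` (absorbed dose, ug/kg). Defaults emulate blood gold
#'   kinetics after a 12 mg/kg intraperitoneal auranofin dose: gold
#'   dose 3.48 mg/kg, terminal half-life about 24 hr, peak near
#'   12.4 ug/mL around 8 hr and total exposure near 536 ug*hr/mL.
#' @param survival_params Data frame with columns `arm`, `hazard`
#'   (1/day), `n`; plus attribute-free `censor_day` handled separately.
#' @param censor_day Administrative censoring day for survival arms.
#'
#' @return An object of class `syn_config` (a named list).
#' @examples
#' cfg <- syn_config(seed = 1, n_genes = 500, n_drugs = 40)
#' cfg$n_genes
#' @export
syn_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_drugs = 200L,
                       instances_per_drug = 1:5,
                       n_planted_reversers = 5L,
                       n_planted_mimics = 5L,
                       signature_size = 50L,
                       noise_sd = 0.25,
                       plant_effect = 3,
                       plate_format = 384L,
                       plate_noise_cv = 0.05,
                       plate_controls = c(vehicle = 32L, positive = 32L),
                       kill_fraction = 0.98,
                       hill_params = list(Dm = 0.33, m = 1.5),
                       pk_params = list(ka = 0.352, ke = 0.029,
                                        V_F = 223.8, dose_ug_kg = 3480),
                       survival_params = default_survival_params(),
                       censor_day = 60) {
  counts <- c(n_genes = n_genes, n_drugs = n_drugs,
              signature_size = signature_size)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("n_genes, n_drugs and signature_size must be non-negative integers")
  }
  if (n_genes < 1 || n_drugs < 1) {
    abort("n_genes and n_drugs must be positive")
  }
  if (n_planted_reversers < 0 || n_planted_mimics < 0 ||
      n_planted_reversers + n_planted_mimics > n_drugs) {
    abort("planted reversers + mimics must be between 0 and n_drugs")
  }
  if (any(instances_per_drug < 1)) {
    abort("instances_per_drug must be positive counts")
  }
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (plate_format != 384L) abort("only 384-well plates are supported")
  if (!is.list(pk_params) || pk_params$ka == pk_params$ke) {
    abort("pk_params must be a list with ka != ke (flip-flop degenerate)")
  }
  if (hill_params$Dm <= 0 || hill_params$m <= 0) {
    abort("hill_params Dm and m must be positive")
  }
  structure(
    list(seed = as.integer(seed),
         n_genes = as.integer(n_genes),
         n_drugs = as.integer(n_drugs),
         instances_per_drug = as.integer(instances_per_drug),
         n_planted_reversers = as.integer(n_planted_reversers),
         n_planted_mimics = as.integer(n_planted_mimics),
         signature_size = as.integer(signature_size),
         noise_sd = noise_sd,
         plant_effect = plant_effect,
         plate_format = as.integer(plate_format),
         plate_noise_cv = plate_noise_cv,
         plate_controls = plate_controls,
         kill_fraction = kill_fraction,
         hill_params = hill_params,
         pk_params = pk_params,
         survival_params = survival_params,
         censor_day = censor_day),
    class = "syn_config"
  )
}

#' Default survival-arm parameters
#'
#' Four xenograft arms (vehicle, each single agent, the combination)
#' with exponential hazards; twelve animals per arm mirrors typical
#' preclinical group sizes. Vehicle median survival is about 12 days and
#' the combination roughly doubles it.
#'
#' @return A tibble with columns `arm`, `hazard` (1/day) and `n`.
#' @export
default_survival_params <- function() {
  tibble::tibble(
    arm = c("vehicle", "drugA", "drugB", "combination"),
    hazard = log(2) / c(12, 20, 20, 24),
    n = 12L
  )
}

#' @export
print.syn_config <- function(x, ...) {
  cat("<syn_config>\n")
  cat("  universe:", x$n_genes, "genes;", x$n_drugs, "drugs,",
      "instances per drug in {", paste(x$instances_per_drug, collapse = ","),
      "}\n")
  cat("  planted:", x$n_planted_reversers, "reversers,",
      x$n_planted_mimics, "mimics; signature size",
      x$signature_size, "per direction\n")
  cat("  noise_sd:", x$noise_sd, " plant_effect:", x$plant_effect, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# gene universe labels g1..gN
gene_universe <- function(cfg) paste0("g", seq_len(cfg$n_genes))
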
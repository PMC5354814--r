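#' Run the whole repurposing analysis end to end
#'
#' Orchestrates every stage on a synthetic study bundle derived from
#' one [syn_config()]: signature construction (disease, fusion-
#' silencing as the reversed disease program, chemoresistance derived
#' from a responder matrix), robustness filtering and connectivity
#' scoring of the drug library under all three approaches with
#' FDR-gated top-K selection and merging; plate-based primary
#' screening with Z-prime gating, counter-screen and blacklist hit
#' calling; median-effect validation curves for the nominated drugs;
#' a planted-synergy dose matrix; blood-gold NCA with multi-dose
#' trough accumulation; and Kaplan-Meier / log-rank comparison of the
#' four survival arms. Every stage is a pure function of
#' `(cfg, seeds derived from cfg$seed)`, so reruns are identical.
#'
#' Individual inputs can be overridden with files via `inputs` (paths
#' are validated before any computation): `signature_disease` /
#' `signature_sirna` (signature TSVs), `rank_matrix` + `instance_map`
#' (profile database TSVs).
#'
#' @param cfg A [syn_config()].
#' @param exclusion Drug ids removed from the merged in-silico table
#'   (the manually triaged / already-prescribed list).
#' @param screen_blacklist Compound ids blacklisted at screen hit
#'   calling.
#' @param n_perm Permutations for connectivity significance.
#' @param fdr_cut,top_k Hit-selection gates (defaults 0.05, 20).
#' @param min_corr Robustness-filter correlation threshold.
#' @param hit_threshold Percent-inhibition hit cutoff (strict >).
#' @param inputs Optional named list of file paths overriding
#'   synthetic inputs.
#' @param out_dir Optional directory; when given, each stage writes
#'   its table as TSV and the run parameters as `manifest.json`-style
#'   TSV.
#' @return A `repurposing_report` list with one element per stage.
#' @export
run_repurposing <- function(cfg = syn_config(),
                            exclusion = character(),
                            screen_blacklist = character(),
                            n_perm = 1000L, fdr_cut = 0.05, top_k = 20L,
                            min_corr = 0.3, hit_threshold = 50,
                            inputs = NULL, out_dir = NULL) {
  if (!is.null(inputs)) {
    missing <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(missing) > 0) {
      abort(paste("config stage: input file(s) not found:",
                  paste(missing, collapse = ", ")))
    }
  }

  # --- signatures ---------------------------------------------------
  sig_disease <- if (!is.null(inputs$signature_disease)) {
    read_signature(inputs$signature_disease, label = "disease")
  } else gen_signature(cfg, "disease")
  sig_sirna <- if (!is.null(inputs$signature_sirna)) {
    read_signature(inputs$signature_sirna, label = "sirna")
  } else {
    # silencing the driver fusion reverses the disease program
    new_sig <- gene_signature(up = sig_genes(sig_disease, "down"),
                              down = sig_genes(sig_disease, "up"),
                              label = "sirna")
    new_sig
  }
  responder <- gen_responder_matrix(cfg)
  sig_resistance <- derive_resistance_signature(responder$expr,
                                                responder$groups,
                                                fdr_cut = 0.05,
                                                top_n = cfg$signature_size)

  # --- drug profile database ----------------------------------------
  db <- if (!is.null(inputs$rank_matrix)) {
    read_profile_db(inputs$rank_matrix, inputs$instance_map)
  } else gen_drug_profiles(cfg, sig_disease)
  db <- robustness_filter(db, min_corr = min_corr)

  # --- connectivity: three approaches -------------------------------
  res_disease <- score_database(sig_disease, db, n_perm = n_perm,
                                seed = cfg$seed + 501L)
  res_sirna <- score_database(sig_sirna, db, n_perm = n_perm,
                              seed = cfg$seed + 502L, approach = "sirna")
  res_resist <- score_database(sig_resistance, db, n_perm = n_perm,
                               seed = cfg$seed + 503L,
                               approach = "resistance")
  hits <- list(
    disease = select_hits(res_disease, "negative", k = top_k,
                          fdr_cut = fdr_cut),
    sirna = select_hits(res_sirna, "positive", k = top_k,
                        fdr_cut = fdr_cut),
    resistance = suppressWarnings(
      select_hits(res_resist, "negative", k = top_k, fdr_cut = fdr_cut))
  )
  merged <- merge_hits(hits, exclusion = exclusion)

  # --- primary screen -----------------------------------------------
  roles <- db$instance_meta |>
    dplyr::distinct(.data$drug_id, .data$role)
  potency_ews <- setNames(
    dplyr::case_when(roles$role == "reverser" ~ 0.95,
                     roles$role == "mimic" ~ 0.25,
                     TRUE ~ 0.1),
    roles$drug_id)
  potency_ctrl <- setNames(rep(0.1, nrow(roles)), roles$drug_id)
  # one pan-cytotoxic background drug exercises the counter-screen
  tox <- roles$drug_id[roles$role == "background"][1]
  if (!is.na(tox)) {
    potency_ews[tox] <- 0.95
    potency_ctrl[tox] <- 0.95
  }
  lines <- c("EWS1", "EWS2", "EWS3", "CTRL1")
  plates <- purrr::imap_dfr(lines, function(ln, i) {
    pm <- if (ln == "CTRL1") potency_ctrl else potency_ews
    gen_plate(cfg, pm, plate_id = sprintf("P%03d", i), cell_line = ln,
              seed = cfg$seed + 410L + i)
  })
  inhib <- normalize_plates(plates)
  hit_calls <- call_hits(inhib, ews_lines = setdiff(lines, "CTRL1"),
                         control_lines = "CTRL1",
                         threshold = hit_threshold,
                         blacklist = screen_blacklist)

  # --- validation dose-response on nominated drugs ------------------
  nominated <- hit_calls$compound_id[hit_calls$nominated]
  dr_data <- purrr::map_dfr(nominated, function(cmp) {
    purrr::map_dfr(1:3, function(rep) {
      gen_dose_response(cfg$hill_params, compound_id = cmp,
                        cell_line = "EWS1", replicate = rep)
    })
  })
  dr_fits <- if (nrow(dr_data) > 0) fit_dose_response(dr_data) else NULL

  # --- synergy on the first nominated pair --------------------------
  synergy <- NULL
  if (length(nominated) >= 2) {
    pars <- list(Dm = cfg$hill_params$Dm * 1000, m = cfg$hill_params$m)
    mat <- gen_dose_matrix(pars, pars, interaction = "synergy",
                           drug1 = nominated[1], drug2 = nominated[2])
    synergy <- analyze_dose_matrix(mat)
  }

  # --- pharmacokinetics ---------------------------------------------
  single <- gen_pk_profile(cfg$pk_params)
  multi_times <- sort(unique(c(default_pk_times(), 24 * (1:5))))
  multi <- gen_pk_profile(cfg$pk_params, times = multi_times,
                          n_doses = 5L, tau = 24)
  nca_res <- nca(single, dose_ug_kg = cfg$pk_params$dose_ug_kg)
  troughs <- trough_summary(multi, tau = 24, n_doses = 5L,
                            single_profile = single)

  # --- survival ------------------------------------------------------
  surv <- gen_survival(cfg$survival_params, cfg$censor_day,
                       seed = cfg$seed + 601L)
  km <- km_estimate(surv)
  logrank <- pairwise_logrank(surv, ref = "vehicle")

  report <- structure(
    list(config = cfg,
         signatures = list(disease = sig_disease, sirna = sig_sirna,
                           resistance = sig_resistance),
         db_report = attr(db, "report"),
         connectivity = list(disease = res_disease, sirna = res_sirna,
                             resistance = res_resist),
         hits = hits, merged = merged,
         screen = list(qc = attr(inhib, "qc"), hit_calls = hit_calls),
         dose_response = dr_fits,
         synergy = synergy,
         pk = list(nca = nca_res, troughs = troughs),
         survival = list(data = surv, km = km, logrank = logrank),
         params = list(n_perm = n_perm, fdr_cut = fdr_cut, top_k = top_k,
                       min_corr = min_corr, hit_threshold = hit_threshold,
                       seed = cfg$seed)),
    class = "repurposing_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.repurposing_report <- function(x, ...) {
  cat("<repurposing_report>\n")
  cat("  connectivity hits:",
      paste(sprintf("%s=%d", names(x$hits),
                    vapply(x$hits, nrow, 0L)), collapse = ", "), "\n")
  cat("  merged in-silico drugs:", nrow(x$merged), "\n")
  cat("  screen nominated:", sum(x$screen$hit_calls$nominated), "of",
      nrow(x$screen$hit_calls), "compounds\n")
  if (!is.null(x$synergy)) {
    cat("  synergy median CI:", format(x$synergy$summary$median_ci), "\n")
  }
  cat(sprintf("  PK: Cmax %.3g ug/mL, T1/2 %.3g hr, Cl/F %.3g mL/hr/kg\n",
              x$pk$nca$Cmax, x$pk$nca$T_half, x$pk$nca$Cl_F))
  sig_arms <- x$survival$logrank$arm1[x$survival$logrank$significant]
  cat("  survival arms beating vehicle (p<0.05):",
      if (length(sig_arms)) paste(sig_arms, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

# serialize the per-stage tables of a report as TSVs
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, name) {
    readr::write_tsv(tbl, file.path(out_dir, paste0(name, ".tsv")))
  }
  w(report$db_report, "robustness_report")
  for (ap in names(report$connectivity)) {
    w(dplyr::select(report$connectivity[[ap]], -"instance_scores"),
      paste0("connectivity_", ap))
  }
  w(report$merged, "merged_hits")
  w(report$screen$qc, "plate_qc")
  w(report$screen$hit_calls, "screen_hit_calls")
  if (!is.null(report$dose_response)) {
    w(dplyr::select(report$dose_response, -"fits"), "dose_response_fits")
  }
  if (!is.null(report$synergy)) w(report$synergy$cells, "synergy_cells")
  w(tidy(report$pk$nca), "nca")
  w(report$pk$troughs, "troughs")
  w(report$survival$km, "km_curves")
  w(report$survival$logrank, "logrank")
  w(tibble::as_tibble(report$params), "run_params")
  invisible(out_dir)
}
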
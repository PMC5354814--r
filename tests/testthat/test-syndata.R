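test_that("signature generation is deterministic, sized, and uniform", {
  cfg <- small_cfg()
  s1 <- gen_signature(cfg, "disease")
  s2 <- gen_signature(cfg, "disease")
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))
  expect_length(sig_genes(s1, "up"), 20)
  expect_length(sig_genes(s1, "down"), 20)
  expect_length(intersect(sig_genes(s1, "up"), sig_genes(s1, "down")), 0)

  empty <- gen_signature(syn_config(seed = 1, signature_size = 0), "disease")
  expect_equal(nrow(empty), 0)

  expect_error(gen_signature(syn_config(seed = 1, n_genes = 30,
                                        signature_size = 20), "disease"),
               "signature_size")

  # overlap between independent draws matches the hypergeometric mean
  ref <- gen_signature(small_cfg(seed = 1000), "disease")
  overlaps <- vapply(1:100, function(s) {
    length(intersect(sig_genes(gen_signature(small_cfg(seed = s), "disease"),
                               "up"),
                     sig_genes(ref, "up")))
  }, numeric(1))
  # s^2/N = 20^2/400 = 1; hypergeometric SD ~0.95, 100 draws
  expect_lt(abs(mean(overlaps) - 1), 3 * 0.95 / sqrt(100) + 1e-9)
})

test_that("drug profiles plant reversers/mimics exactly at noise 0", {
  cfg <- small_cfg(noise_sd = 0)
  sig <- gen_signature(cfg, "disease")
  db <- gen_drug_profiles(cfg, sig)

  n <- cfg$n_genes
  # every instance column is a permutation
  expect_true(all(colSums(db$ranks) == n * (n + 1) / 2))

  up_idx <- match(sig_genes(sig, "up"), db$genes)
  down_idx <- match(sig_genes(sig, "down"), db$genes)
  other <- setdiff(seq_len(n), c(up_idx, down_idx))
  rev_inst <- db$instance_meta$instance_id[db$instance_meta$role == "reverser"]
  for (ins in rev_inst) {
    r <- db$ranks[, ins]
    # up-genes below every non-signature gene, down-genes above
    expect_gt(min(r[up_idx]), max(r[other]))
    expect_lt(max(r[down_idx]), min(r[other]))
  }
  mim_inst <- db$instance_meta$instance_id[db$instance_meta$role == "mimic"]
  r <- db$ranks[, mim_inst[1]]
  expect_lt(max(r[up_idx]), min(r[other]))
})

test_that("instance bookkeeping and determinism hold", {
  cfg <- small_cfg(instances_per_drug = 3L)
  sig <- gen_signature(cfg, "disease")
  db <- gen_drug_profiles(cfg, sig)
  counts <- db_instance_counts(db)
  expect_true(all(counts$n_instances == 3L))
  db2 <- gen_drug_profiles(cfg, sig)
  expect_identical(db$ranks, db2$ranks)
})

test_that("background drugs score near zero on average", {
  cfg <- small_cfg(seed = 7)
  sig <- gen_signature(cfg, "disease")
  db <- gen_drug_profiles(cfg, sig)
  bg <- db$instance_meta$instance_id[db$instance_meta$role == "background"]
  rk <- ranking_of(db, bg[1])
  withr::with_seed(11, {
    draws <- replicate(400, {
      g <- sample(db$genes, 40)
      connectivity_score(gene_signature(up = g[1:20], down = g[21:40]), rk)
    })
  })
  expect_lt(abs(mean(draws)), 3 * sd(draws) / sqrt(length(draws)))
})

test_that("responder matrices plant recoverable structure", {
  cfg <- small_cfg()
  null_mat <- gen_responder_matrix(cfg, effect = 0)
  expect_equal(nrow(null_mat$planted), 0)
  sig0 <- derive_resistance_signature(null_mat$expr, null_mat$groups)
  expect_equal(nrow(sig0), 0)

  m1 <- gen_responder_matrix(cfg)
  m2 <- gen_responder_matrix(cfg)
  expect_identical(m1$expr, m2$expr)

  expect_error(gen_responder_matrix(cfg, n_per_group = 2), ">= 3")
})

test_that("plate signals follow the multiplicative noise model", {
  cfg <- small_cfg(plate_noise_cv = 0)
  pm <- c(a = 0, b = 1, c = 0.5)
  pl <- gen_plate(cfg, pm, vehicle_mean = 8000)
  smp <- pl[pl$well_type == "sample", ]
  expect_equal(smp$signal[smp$compound_id == "a"], 8000)
  expect_equal(smp$signal[smp$compound_id == "b"], 0)
  expect_equal(smp$signal[smp$compound_id == "c"], 4000)
  expect_error(gen_plate(cfg, c(a = 1.2)), "\\[0, 1\\]")
})

test_that("seeded plates clear the Z-prime gate almost surely", {
  cfg <- small_cfg(plate_noise_cv = 0.05)
  pm <- stats::setNames(runif(100, 0, 1), paste0("c", 1:100))
  zs <- vapply(1:200, function(s) {
    pl <- gen_plate(cfg, pm, seed = 5000 + s)
    plate_qc(pl)$z_prime
  }, numeric(1))
  expect_gte(mean(zs >= 0.5), 0.95)
})

test_that("extreme plate noise warns about a negative expected Z-prime", {
  cfg <- small_cfg(plate_noise_cv = 0.4)
  expect_warning(gen_plate(cfg, c(a = 0.5)), "Z'")
})

test_that("dose-response generators hit the median effect by definition", {
  d <- gen_dose_response(list(Dm = 2, m = 3), doses = c(0.5, 2, 8))
  expect_equal(d$fraction_affected[d$conc_umol_l == 2], 0.5)
  expect_error(gen_dose_response(list(Dm = -1, m = 1)), "positive")
})

test_that("PK profiles start at zero and decay at ke in the terminal phase", {
  pk <- list(ka = 1, ke = 0.029, V_F = 250, dose_ug_kg = 3480)
  prof <- gen_pk_profile(pk)
  expect_equal(prof$conc_ug_per_ml[prof$time_hr == 0], 0)

  late <- gen_pk_profile(pk, times = c(24, 36, 48, 72, 96))
  slope <- unname(coef(lm(log(conc_ug_per_ml) ~ time_hr, late))[2])
  expect_equal(slope, -0.029, tolerance = 1e-6)

  expect_error(gen_pk_profile(list(ka = 0.1, ke = 0.1, V_F = 1,
                                   dose_ug_kg = 1)),
               "flip-flop")
})

test_that("null survival arms show no systematic log-rank signal", {
  pars <- tibble::tibble(arm = c("a", "b"), hazard = 0.05, n = 12L)
  stats_null <- vapply(1:40, function(s) {
    d <- gen_survival(pars, censor_day = 60, seed = s)
    res <- logrank_test(d, c("a", "b"))
    c(res$observed1 - res$expected1, res$p_value)
  }, numeric(2))
  expect_lt(abs(mean(stats_null[1, ])),
            3 * sd(stats_null[1, ]) / sqrt(40) + 1e-9)
  expect_lte(mean(stats_null[2, ] < 0.05), 0.15)
})
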
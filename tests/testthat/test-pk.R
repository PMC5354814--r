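test_that("gold/auranofin conversions reproduce the fixed-mass arithmetic", {
  expect_equal(round(100 * gold_mass_fraction()), 29)
  expect_equal(gold_dose(12), 12 * 196.97 / 678.48)
  expect_equal(to_molar(12.43), 12.43 / 196.97 * 1000)
  expect_error(gold_dose(-1), "non-negative")
  expect_error(to_molar(-1), "non-negative")
})

test_that("trapezoid AUC matches hand arithmetic and is additive", {
  expect_equal(auc_linear(c(0, 1, 2), c(0, 10, 5)), 12.5)
  t <- c(0, 0.5, 1, 2, 4, 8)
  cc <- c(0, 3, 5, 4, 2, 0.5)
  expect_equal(auc_linear(t, cc),
               auc_linear(t[1:4], cc[1:4]) + auc_linear(t[4:6], cc[4:6]))
  expect_error(auc_linear(c(0, 0), c(1, 2)), "increasing")
})

test_that("NCA recovers a mono-exponential profile exactly", {
  t <- c(0, 1, 2, 4, 8, 12, 24)
  cc <- 10 * exp(-0.1 * t)
  res <- nca(tibble::tibble(time_hr = t, conc_ug_per_ml = cc),
             dose_ug_kg = 1000)
  expect_equal(res$Kel, 0.1, tolerance = 1e-10)
  expect_equal(res$T_half, log(2) / 0.1, tolerance = 1e-9)
  expect_equal(res$AUC_0_inf, auc_linear(t, cc) + cc[length(cc)] / 0.1)
  expect_equal(res$Cl_F, 1000 / res$AUC_0_inf)
  # with a fine grid the trapezoid converges to the closed form C0/k
  tf <- seq(0, 200, by = 0.05)
  resf <- nca(tibble::tibble(time_hr = tf,
                             conc_ug_per_ml = 10 * exp(-0.1 * tf)))
  expect_equal(resf$AUC_0_inf, 10 / 0.1, tolerance = 1e-3)
})

test_that("NCA is scale-equivariant in concentration", {
  prof <- gen_pk_profile(list(ka = 0.352, ke = 0.029, V_F = 223.8,
                              dose_ug_kg = 3480))
  a <- nca(prof, dose_ug_kg = 3480)
  prof2 <- dplyr::mutate(prof, conc_ug_per_ml = conc_ug_per_ml * 3)
  b <- nca(prof2, dose_ug_kg = 3480)
  expect_equal(b$Cmax, 3 * a$Cmax)
  expect_equal(b$AUC_0_inf, 3 * a$AUC_0_inf)
  expect_equal(b$Kel, a$Kel)
  expect_equal(b$T_half, a$T_half)
  expect_equal(b$Cl_F, a$Cl_F / 3)
})

test_that("terminal-phase selection recovers ke on the sampling grid", {
  pk <- list(ka = 1.0, ke = 0.029, V_F = 250, dose_ug_kg = 3480)
  prof <- gen_pk_profile(pk)
  for (rule in c("best_fit", "last3")) {
    res <- nca(prof, dose_ug_kg = 3480, terminal_rule = rule)
    expect_lt(abs(res$T_half - log(2) / 0.029) / (log(2) / 0.029), 0.05)
  }
})

test_that("profiles without an elimination phase refuse extrapolation", {
  rising <- tibble::tibble(time_hr = c(0, 1, 2, 4, 8, 12),
                           conc_ug_per_ml = c(0, 1, 2, 4, 8, 12))
  res <- nca(rising)
  expect_false(res$extrapolated)
  expect_match(res$flag, "refused|terminal")
  expect_true(is.na(res$AUC_0_inf))
  expect_false(is.na(res$AUC_0_t))
})

test_that("multi-dose troughs match the superposition closed form", {
  pk <- list(ka = 0.352, ke = 0.029, V_F = 223.8, dose_ug_kg = 3480)
  tau <- 24
  n_doses <- 5
  times <- sort(unique(c(default_pk_times(), tau * (1:n_doses))))
  multi <- gen_pk_profile(pk, times = times, n_doses = n_doses, tau = tau)
  single <- gen_pk_profile(pk)
  ts <- trough_summary(multi, tau = tau, n_doses = n_doses,
                       single_profile = single)

  # closed form: C1(t) = A (e^-ke t - e^-ka t); trough_n / C1(tau)
  A <- pk$dose_ug_kg * pk$ka / (pk$V_F * (pk$ka - pk$ke))
  C1 <- function(t) A * (exp(-pk$ke * t) - exp(-pk$ka * t))
  ratio5 <- sum(C1(tau * (5:1))) / C1(tau)
  expect_lt(abs(ts$accumulation_ratio[5] - ratio5) / ratio5, 0.02)
  # approaches (but after 5 doses stays below) the steady-state limit
  expect_lt(ts$accumulation_ratio[5], 1 / (1 - exp(-pk$ke * tau)))

  expect_message(
    ts0 <- trough_summary(multi, tau = tau, n_doses = n_doses),
    "reference")
  expect_true(all(is.na(ts0$accumulation_ratio)))
})

test_that("NCA results tidy into a parameter table with consistent identities", {
  prof <- gen_pk_profile(list(ka = 0.352, ke = 0.029, V_F = 223.8,
                              dose_ug_kg = 3480))
  res <- nca(prof, dose_ug_kg = 3480)
  td <- tidy(res)
  expect_setequal(td$parameter,
                  c("Cmax", "Cmax_molar", "Tmax", "AUC_0_t", "AUC_0_inf",
                    "Kel", "T_half", "Cl_F", "dose"))
  val <- function(p) td$value[td$parameter == p]
  expect_gte(val("AUC_0_inf"), val("AUC_0_t"))
  expect_equal(val("T_half"), log(2) / val("Kel"))
  expect_equal(val("Cl_F"), val("dose") / val("AUC_0_inf"))
  expect_true(val("Tmax") %in% prof$time_hr)
  expect_equal(val("Cmax_molar"), to_molar(val("Cmax")))
})
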
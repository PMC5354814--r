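#' Fit the median-effect (Chou-Talalay) dose-response model
#'
#' The median-effect equation `fa/fu = (D/Dm)^m` (with `fu = 1 - fa`)
#' linearizes to `logit(fa) = m*log(D) - m*log(Dm)`, so `Dm` (the
#' median-effect dose, identically the IC50) and the sigmoidicity `m`
#' come from an ordinary least-squares fit of the logit-transformed
#' fraction affected on log dose.
#'
#' Points with negative fraction affected (growth stimulation) are
#' excluded; responses sitting exactly on the boundary values 0 or 1
#' are moved off them by `eps` so the logit is defined (interior
#' values are used as observed). Curves whose maximum observed
#' response never
#' reaches 0.5 are reported right-censored (`"> <max dose>"`, no `Dm`);
#' curves already at or above 0.5 at the lowest dose are left-censored
#' (`"< <min dose>"`).
#'
#' @param data Data frame of one dose-response curve.
#' @param dose,fa Tidy-eval columns for dose (positive, any consistent
#'   concentration unit) and fraction affected; defaults `conc_umol_l`
#'   and `fraction_affected`.
#' @param eps Offset applied to responses sitting exactly at 0 or 1
#'   (default 0.01).
#' @param min_points Minimum usable points for regression (default 4).
#' @return A `median_effect_fit` object: fields `Dm`, `m`, `sse`,
#'   `n_used`, `ic50_censored` (`"none"`, `"above_max"`,
#'   `"below_min"`, `"failed"`), `censor_bound`, `ic50_label`.
#' @examples
#' d <- gen_dose_response(list(Dm = 1, m = 1))
#' fit <- fit_median_effect(d)
#' tidy(fit)
#' @export
fit_median_effect <- function(data, dose = conc_umol_l,
                              fa = fraction_affected,
                              eps = 0.01, min_points = 4L) {
  d <- dplyr::pull(data, {{ dose }})
  y <- dplyr::pull(data, {{ fa }})
  if (any(d <= 0)) abort("doses must be positive")
  keep <- !is.na(y) & !is.na(d)
  d <- d[keep]; y <- y[keep]
  if (length(d) == 0) abort("no usable dose-response points")

  res <- list(Dm = NA_real_, m = NA_real_, sse = NA_real_, n_used = 0L,
              ic50_censored = "none", censor_bound = NA_real_,
              ic50_label = NA_character_,
              data = tibble::tibble(dose = d, fa = y))
  class(res) <- "median_effect_fit"

  if (max(y) <= 0.5) {
    res$ic50_censored <- "above_max"
    res$censor_bound <- max(d)
    res$ic50_label <- paste(">", format(max(d)))
    return(res)
  }
  if (min(y[d == min(d)]) >= 0.5) {
    res$ic50_censored <- "below_min"
    res$censor_bound <- min(d)
    res$ic50_label <- paste("<", format(min(d)))
    return(res)
  }

  usable <- y >= 0
  yc <- y[usable]
  yc[yc == 0] <- eps        # boundary values moved off {0,1} for the logit
  yc[yc >= 1] <- 1 - eps
  dc <- d[usable]
  if (length(dc) < min_points) {
    res$ic50_censored <- "failed"
    res$ic50_label <- paste("fewer than", min_points, "usable points")
    return(res)
  }
  fit <- lm(log(yc / (1 - yc)) ~ log(dc))
  m <- unname(coef(fit)[2])
  if (!is.finite(m) || m <= 0) {
    res$ic50_censored <- "failed"
    res$ic50_label <- "non-positive slope"
    return(res)
  }
  res$m <- m
  res$Dm <- exp(-unname(coef(fit)[1]) / m)
  res$sse <- sum(fit$residuals^2)
  res$n_used <- length(dc)
  res$ic50_label <- format(res$Dm)
  res
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat("<median_effect_fit>\n")
  if (x$ic50_censored == "none") {
    cat("  Dm (IC50):", format(x$Dm), "  m:", format(x$m),
        "  n:", x$n_used, "  SSE:", format(x$sse), "\n")
  } else {
    cat("  censored (", x$ic50_censored, "): IC50 ", x$ic50_label, "\n",
        sep = "")
  }
  invisible(x)
}

#' Fit dose-response curves for many compounds and replicates
#'
#' Fits [fit_median_effect()] per compound, cell line and replicate,
#' then summarises the IC50 as mean +- SD across replicate fits (the
#' conventional presentation for >= 3 independent experiments).
#' Censored replicates propagate: a group is reported censored when
#' every replicate is censored the same way.
#'
#' @param data Long tibble with columns `compound_id`, `cell_line`,
#'   `replicate`, `conc_umol_l`, `fraction_affected`.
#' @param ... Passed to [fit_median_effect()].
#' @return Tibble with one row per compound x cell line: `n_reps`,
#'   `ic50_mean`, `ic50_sd`, `m_mean`, `ic50_censored`, `ic50_label`,
#'   and a `fits` list-column of the replicate fit objects.
#' @export
fit_dose_response <- function(data, ...) {
  data |>
    dplyr::group_by(.data$compound_id, .data$cell_line) |>
    dplyr::group_modify(function(grp, key) {
      fits <- grp |>
        dplyr::group_by(.data$replicate) |>
        dplyr::group_map(function(g, k) fit_median_effect(g, ...))
      dm <- vapply(fits, function(f) f$Dm, numeric(1))
      mm <- vapply(fits, function(f) f$m, numeric(1))
      cens <- vapply(fits, function(f) f$ic50_censored, character(1))
      all_cens <- length(unique(cens)) == 1 && cens[1] != "none"
      tibble::tibble(
        n_reps = length(fits),
        ic50_mean = if (all_cens) NA_real_ else mean(dm, na.rm = TRUE),
        ic50_sd = if (all_cens) NA_real_ else sd(dm[!is.na(dm)]),
        m_mean = mean(mm, na.rm = TRUE),
        ic50_censored = if (all_cens) cens[1] else "none",
        ic50_label = if (all_cens) fits[[1]]$ic50_label else
          sprintf("%.3g +- %.3g", mean(dm, na.rm = TRUE),
                  sd(dm[!is.na(dm)])),
        fits = list(fits)
      )
    }) |>
    dplyr::ungroup()
}

#' Fraction affected under the median-effect model
#'
#' `fa = 1 / (1 + (Dm/D)^m)`; the inverse of [dose_for_effect()].
#' `D = Dm` gives exactly 0.5.
#'
#' @param dose Dose(s), positive.
#' @param Dm Median-effect dose (> 0).
#' @param m Sigmoidicity (> 0).
#' @return Fraction affected in (0, 1).
#' @export
median_effect_fa <- function(dose, Dm, m) {
  if (Dm <= 0 || m <= 0) abort("Dm and m must be positive")
  1 / (1 + (Dm / dose)^m)
}

#' Dose producing a given effect level
#'
#' `Dx = Dm * (fa/(1-fa))^(1/m)`, the single-agent dose needed for
#' fraction affected `fa`; the building block of the combination index.
#'
#' @param fa Fraction affected, strictly inside (0, 1).
#' @inheritParams median_effect_fa
#' @return Dose(s) on the scale of `Dm`.
#' @export
dose_for_effect <- function(fa, Dm, m) {
  if (Dm <= 0 || m <= 0) abort("Dm and m must be positive")
  out <- rep(NA_real_, length(fa))
  ok <- !is.na(fa) & fa > 0 & fa < 1
  out[ok] <- Dm * (fa[ok] / (1 - fa[ok]))^(1 / m)
  out
}
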
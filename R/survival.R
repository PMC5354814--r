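#' Kaplan-Meier product-limit estimate per arm
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the distinct event
#' times `t_i`, with `d_i` events among `n_i` at risk. The curve
#' starts at `S(0) = 1`, is non-increasing and right-continuous, and
#' with no censoring equals the empirical survival function.
#'
#' @param data Survival tibble with columns `arm`, `time_days`,
#'   `event` (1 = event, 0 = censored).
#' @return Tibble with one row per distinct event/censor time and arm:
#'   `arm`, `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @examples
#' km_estimate(tibble::tibble(arm = "a", time_days = 1:3, event = 1))
#' @export
km_estimate <- function(data) {
  data <- tibble::as_tibble(data)
  if (any(data$time_days <= 0)) abort("survival times must be positive")
  data |>
    dplyr::group_by(.data$arm) |>
    dplyr::group_modify(function(grp, key) {
      tt <- sort(unique(grp$time_days))
      n_risk <- vapply(tt, function(u) sum(grp$time_days >= u), 0)
      d <- vapply(tt, function(u) sum(grp$time_days == u & grp$event == 1), 0)
      cns <- vapply(tt, function(u) sum(grp$time_days == u & grp$event == 0), 0)
      tibble::tibble(time = tt, n_risk = n_risk, n_event = d,
                     n_censor = cns,
                     survival = cumprod(1 - d / n_risk))
    }) |>
    dplyr::ungroup()
}

#' Two-sample log-rank test
#'
#' Classic (rho = 0) log-rank over the shared risk sets of two arms:
#' at each distinct event time the observed minus expected events in
#' the first arm are accumulated with hypergeometric variance, giving
#' a 1-df chi-square statistic. The statistic is invariant under
#' swapping the arm labels (the sign of O - E flips).
#'
#' @param data Survival tibble (`arm`, `time_days`, `event`).
#' @param arms Length-2 character vector naming the arms to compare;
#'   default the first two present.
#' @return Tibble with `arm1`, `arm2`, `observed1`, `expected1`,
#'   `statistic`, `p_value`, `significant` (at 0.05).
#' @export
logrank_test <- function(data, arms = NULL) {
  data <- tibble::as_tibble(data)
  arms <- arms %||% head(unique(data$arm), 2)
  if (length(arms) != 2) abort("exactly two arms are compared")
  d2 <- dplyr::filter(data, .data$arm %in% arms)
  if (dplyr::n_distinct(d2$arm) < 2) abort("both arms need observations")

  ev_times <- sort(unique(d2$time_days[d2$event == 1]))
  o_minus_e <- 0
  v <- 0
  obs1 <- 0
  exp1 <- 0
  for (u in ev_times) {
    at_risk <- d2$time_days >= u
    n <- sum(at_risk)
    n1 <- sum(at_risk & d2$arm == arms[1])
    d_tot <- sum(d2$time_days == u & d2$event == 1)
    d1 <- sum(d2$time_days == u & d2$event == 1 & d2$arm == arms[1])
    e1 <- d_tot * n1 / n
    obs1 <- obs1 + d1
    exp1 <- exp1 + e1
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) {
      v <- v + d_tot * (n1 / n) * (1 - n1 / n) * (n - d_tot) / (n - 1)
    }
  }
  stat <- if (v > 0) o_minus_e^2 / v else 0
  p <- if (v > 0) pchisq(stat, df = 1, lower.tail = FALSE) else 1
  tibble::tibble(arm1 = arms[1], arm2 = arms[2],
                 observed1 = obs1, expected1 = exp1,
                 statistic = stat, p_value = p,
                 significant = p < 0.05)
}

#' Pairwise log-rank tests against a reference arm
#'
#' Compares every treatment arm with the reference arm. P-values are
#' unadjusted by default; Holm adjustment is available for those who
#' want family-wise control over the pairwise comparisons.
#'
#' @param data Survival tibble (`arm`, `time_days`, `event`).
#' @param ref Reference arm (default `"vehicle"`).
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return Row-bound [logrank_test()] results with a `p_adjusted`
#'   column.
#' @export
pairwise_logrank <- function(data, ref = "vehicle", p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  others <- setdiff(unique(data$arm), ref)
  if (length(others) == 0) abort("no arms to compare with the reference")
  out <- purrr::map_dfr(others, function(a) logrank_test(data, c(a, ref)))
  out$p_adjusted <- p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_adjusted < 0.05
  out
}
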
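#' Percent inhibition relative to the vehicle mean
#'
#' Viability screens are normalized as
#' `100 * (1 - signal / vehicle_mean)`. Values can be negative when a
#' compound stimulates growth above vehicle.
#'
#' @param signal Raw well signal(s) (luminescence, >= 0).
#' @param vehicle_mean Mean vehicle-control signal (> 0).
#' @return Percent inhibition, same length as `signal`.
#' @examples
#' percent_inhibition(c(0, 500, 1200), vehicle_mean = 1000)
#' @export
percent_inhibition <- function(signal, vehicle_mean) {
  if (!is.numeric(vehicle_mean) || any(vehicle_mean <= 0)) {
    abort("vehicle_mean must be positive")
  }
  100 * (1 - signal / vehicle_mean)
}

#' Z-prime assay-quality factor
#'
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|` with sample
#' (n-1) standard deviations. `Z' >= 0.5` denotes an excellent assay;
#' plates below that are excluded from hit calling. The statistic is
#' symmetric in the two control groups.
#'
#' @param pos_signals,neg_signals Control well signals (>= 2 each).
#' @return The Z-prime factor (`-Inf..1`); `NA` with a warning when the
#'   control means coincide (degenerate plate).
#' @examples
#' z_prime(rnorm(32, 100, 5), rnorm(32, 1000, 10))
#' @export
z_prime <- function(pos_signals, neg_signals) {
  if (length(pos_signals) < 2 || length(neg_signals) < 2) {
    abort("need >= 2 wells per control group")
  }
  delta <- abs(mean(pos_signals) - mean(neg_signals))
  if (delta == 0) {
    warn("control means coincide; Z' undefined")
    return(NA_real_)
  }
  1 - 3 * (sd(pos_signals) + sd(neg_signals)) / delta
}

#' Per-plate quality control
#'
#' Computes the vehicle mean and Z-prime factor of every plate and
#' flags plates failing the quality gate.
#'
#' @param plates Plate-record tibble with columns `plate_id`, `well`,
#'   `row`, `col`, `well_type` (`sample` / `vehicle` /
#'   `positive_control`), `compound_id`, `conc_umol_l`, `signal`,
#'   `cell_line`.
#' @param z_cut Minimum acceptable Z-prime (default 0.5).
#' @return Tibble `plate_id`, `cell_line`, `vehicle_mean`, `z_prime`,
#'   `pass`.
#' @export
plate_qc <- function(plates, z_cut = 0.5) {
  plates |>
    dplyr::group_by(.data$plate_id, .data$cell_line) |>
    dplyr::summarise(
      vehicle_mean = mean(.data$signal[.data$well_type == "vehicle"]),
      z_prime = z_prime(.data$signal[.data$well_type == "positive_control"],
                        .data$signal[.data$well_type == "vehicle"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(pass = !is.na(.data$z_prime) & .data$z_prime >= z_cut)
}

#' Normalize plate signals to percent inhibition
#'
#' Applies [percent_inhibition()] to every sample well using its own
#' plate's vehicle mean (per-plate normalization absorbs plate
#' effects), after dropping plates that fail the Z-prime gate.
#'
#' @inheritParams plate_qc
#' @return Tibble of sample wells with an added `inhibition` column;
#'   the [plate_qc()] table is attached as attribute `qc`.
#' @export
normalize_plates <- function(plates, z_cut = 0.5) {
  qc <- plate_qc(plates, z_cut)
  bad <- qc[!qc$pass, ]
  if (nrow(bad) > 0) {
    warn(paste("excluding", nrow(bad), "plate(s) failing Z' >=", z_cut, ":",
               paste(bad$plate_id, collapse = ", ")))
  }
  out <- plates |>
    dplyr::filter(.data$well_type == "sample") |>
    dplyr::inner_join(dplyr::filter(qc, .data$pass),
                      by = c("plate_id", "cell_line")) |>
    dplyr::mutate(inhibition = percent_inhibition(.data$signal,
                                                  .data$vehicle_mean)) |>
    dplyr::select(-"vehicle_mean", -"z_prime", -"pass")
  attr(out, "qc") <- qc
  out
}

#' Read a percent-inhibition screen table
#'
#' Parses a wide TSV of screen results: a `class` and `compound_id`
#' column followed by one column per cell line, whose entries are
#' numeric percent inhibition or left-censored strings like `"< 50"`
#' (a value known only to lie below the reporting limit).
#'
#' @param path TSV path.
#' @return Long tibble with `compound_id`, `class`, `cell_line`,
#'   `inhibition` (the value, or the censor bound for censored
#'   entries) and `censored` (logical).
#' @export
read_screen_table <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  if (!all(c("class", "compound_id") %in% names(wide))) {
    abort("screen table needs columns class, compound_id")
  }
  long <- tidyr::pivot_longer(wide, -c("class", "compound_id"),
                              names_to = "cell_line", values_to = "raw")
  long |>
    dplyr::mutate(
      censored = grepl("^<", trimws(.data$raw)),
      inhibition = as.numeric(sub("^<\\s*", "", trimws(.data$raw)))
    ) |>
    dplyr::select("compound_id", "class", "cell_line", "inhibition",
                  "censored")
}

#' Call primary-screen hits with counter-screen and blacklist filters
#'
#' A compound is a *hit* when it exceeds the inhibition threshold
#' (strictly greater, so a boundary value is not a hit) in at least one
#' tumor line; it is *counter-screen cytotoxic* when it also exceeds
#' the threshold in any non-tumorigenic control line; and it is
#' *nominated* for validation iff it is a hit, not counter-screen
#' cytotoxic, and not on the blacklist of currently prescribed agents.
#' Left-censored entries (`censored = TRUE`, value known only to lie
#' below the bound) never satisfy the threshold predicate. Compounds
#' missing any control-line measurement are flagged incomplete and not
#' nominated.
#'
#' @param inhibition Long tibble as returned by [read_screen_table()]
#'   or [normalize_plates()] (needs `compound_id`, `cell_line`,
#'   `inhibition`; an absent `censored` column is taken as all
#'   uncensored).
#' @param ews_lines,control_lines Character vectors naming the tumor
#'   and non-tumorigenic cell lines.
#' @param threshold Percent-inhibition cutoff (default 50; the rule is
#'   strict `> threshold`).
#' @param blacklist Compound ids excluded as currently prescribed.
#' @return Tibble with one row per compound: `compound_id`,
#'   `is_hit_any_ews`, `control_cytotoxic`, `blacklisted`,
#'   `incomplete`, `nominated`.
#' @export
call_hits <- function(inhibition, ews_lines, control_lines,
                      threshold = 50, blacklist = character()) {
  tbl <- tibble::as_tibble(inhibition)
  if (!"censored" %in% names(tbl)) tbl$censored <- FALSE
  missing_lines <- setdiff(c(ews_lines, control_lines), tbl$cell_line)
  if (length(missing_lines) > 0) {
    abort(paste("cell lines absent from the table:",
                paste(missing_lines, collapse = ", ")))
  }
  tbl$above <- !tbl$censored & !is.na(tbl$inhibition) &
    tbl$inhibition > threshold
  tbl |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      is_hit_any_ews = any(.data$above[.data$cell_line %in% ews_lines]),
      control_cytotoxic = any(.data$above[.data$cell_line %in% control_lines]),
      incomplete = !all(control_lines %in% .data$cell_line) ||
        anyNA(.data$inhibition[.data$cell_line %in% control_lines]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      blacklisted = .data$compound_id %in% blacklist,
      nominated = .data$is_hit_any_ews & !.data$control_cytotoxic &
        !.data$blacklisted & !.data$incomplete
    )
}

#' Path to the bundled example screen table
#'
#' A 45-compound primary-screen result set (percent inhibition at
#' 1 umol/L in three Ewing sarcoma lines and one non-tumorigenic
#' control line, with `"< 50"` left-censored entries) bundled as a
#' worked example for [read_screen_table()] and [call_hits()].
#'
#' @return File path.
#' @export
example_screen_path <- function() {
  system.file("extdata", "ews_primary_screen.tsv", package = "ewsrepo",
              mustWork = TRUE)
}
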
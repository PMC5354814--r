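#' Derive a chemoresistance signature from responder-labeled expression
#'
#' Compares pre-treatment expression between chemotherapy responders
#' and non-responders gene by gene with a Wilcoxon rank-sum test
#' (mid-ranks for ties, normal approximation with tie-corrected
#' variance — rank-based, hence invariant to any monotone transform of
#' the expression values), adjusts across genes by Benjamini-Hochberg,
#' and keeps genes below `fdr_cut`, split by the sign of the median
#' difference (non-responders minus responders; "up" = higher in
#' non-responders, i.e. up in resistance). Each direction is truncated
#' to the `top_n` genes of largest absolute effect.
#'
#' @param expr Genes x samples numeric matrix with gene rownames.
#' @param groups Data frame with columns `sample`, `group`; `group`
#'   must have exactly two levels, `responder` and `nonresponder`,
#'   with at least 3 samples each.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param top_n Maximum genes per direction (default all).
#' @return A [gene_signature()] labeled `"resistance"`, weighted by
#'   absolute median difference; its `stats` attribute holds the
#'   per-gene test table.
#' @export
derive_resistance_signature <- function(expr, groups, fdr_cut = 0.05,
                                        top_n = Inf) {
  groups <- tibble::as_tibble(groups)
  if (!all(c("sample", "group") %in% names(groups))) {
    abort("groups needs columns sample, group")
  }
  expr <- as.matrix(expr)[, groups$sample, drop = FALSE]
  is_nr <- groups$group == "nonresponder"
  n1 <- sum(is_nr)
  n2 <- sum(!is_nr)
  if (n1 < 3 || n2 < 3) abort("need >= 3 samples per group")
  N <- n1 + n2

  rk <- t(apply(expr, 1, rank))  # mid-ranks
  W <- rowSums(rk[, is_nr, drop = FALSE])
  mu <- n1 * (N + 1) / 2
  tie_term <- apply(expr, 1, function(x) {
    tt <- table(x)
    sum(tt^3 - tt)
  })
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  z <- ifelse(v > 0, (W - mu) / sqrt(v), 0)
  p <- 2 * pnorm(-abs(z))
  effect <- apply(expr[, is_nr, drop = FALSE], 1, median) -
    apply(expr[, !is_nr, drop = FALSE], 1, median)

  stats <- tibble::tibble(
    gene = rownames(expr),
    statistic = W,
    z = z,
    p_value = p,
    fdr = p.adjust(p, "BH"),
    effect = effect
  )
  sig_rows <- dplyr::filter(stats, .data$fdr < fdr_cut, .data$effect != 0)
  pick <- function(rows) {
    rows <- dplyr::arrange(rows, dplyr::desc(abs(.data$effect)), .data$gene)
    head(rows$gene, top_n)
  }
  up <- pick(dplyr::filter(sig_rows, .data$effect > 0))
  down <- pick(dplyr::filter(sig_rows, .data$effect < 0))
  out <- gene_signature(
    up = up, down = down,
    weights = setNames(abs(stats$effect), rownames(expr)),
    label = "resistance"
  )
  attr(out, "stats") <- stats
  out
}
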
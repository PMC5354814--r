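#' Bidirectional KS enrichment of a gene set in a ranked list
#'
#' The running-sum Kolmogorov-Smirnov statistic of the connectivity-map
#' lineage. With `V(j)` the ascending positions of the `t` set genes in
#' a ranking of `n` genes, it returns
#' `a = max_j (j/t - V(j)/n)` if `a >= b`, else `-b` where
#' `b = max_j (V(j)/n - (j-1)/t)`. Positive values mean the set
#' concentrates at the top of the ranking (most up-regulated side),
#' negative at the bottom; the extremes are `+-(1 - t/n)`.
#'
#' @param gene_set Character vector of gene ids (nonempty, within the
#'   ranking's universe).
#' @param ranking Named integer permutation of `1..n`: names are gene
#'   ids, values their rank (1 = most up-regulated).
#' @return A single statistic in `[-1, 1]`.
#' @examples
#' rk <- setNames(1:6, paste0("g", 1:6))
#' ks_enrichment(c("g1", "g6"), rk)  # -1/2
#' @export
ks_enrichment <- function(gene_set, ranking) {
  if (length(gene_set) == 0) abort("gene_set must be nonempty")
  n <- length(ranking)
  v <- unname(ranking[match(toupper(gene_set), toupper(names(ranking)))])
  if (anyNA(v)) {
    abort(paste("genes missing from the ranking:",
                paste(gene_set[is.na(v)], collapse = ", ")))
  }
  if (length(v) == n) return(0)  # set == universe, by convention
  ks_stat_cols(matrix(sort(v), ncol = 1), n)
}

# vectorized KS statistic: Vs is a t x k matrix of column-sorted
# positions, n the universe size; returns k statistics
ks_stat_cols <- function(Vs, n) {
  t <- nrow(Vs)
  j <- seq_len(t)
  A <- j / t - Vs / n
  B <- Vs / n - (j - 1) / t
  a <- do.call(pmax, asplit(A, 1))
  b <- do.call(pmax, asplit(B, 1))
  as.vector(ifelse(a >= b, a, -b))
}

# sort every column of an integer matrix (radix order on (col, value))
sort_cols <- function(V) {
  if (nrow(V) == 1L) return(V)
  matrix(V[order(col(V), V, method = "radix")], nrow = nrow(V))
}

# instance scores for one signature given row indices into db ranks;
# returns list(up, down, score) of length ncol(ranks)
instance_scores_idx <- function(ranks, up_idx, down_idx) {
  n <- nrow(ranks)
  ku <- kd <- rep(NA_real_, ncol(ranks))
  if (length(up_idx) > 0) {
    ku <- ks_stat_cols(sort_cols(ranks[up_idx, , drop = FALSE]), n)
  }
  if (length(down_idx) > 0) {
    kd <- ks_stat_cols(sort_cols(ranks[down_idx, , drop = FALSE]), n)
  }
  combine_ks(ku, kd)
}

# same-sign zeroing and [-1,1] scaling; one-sided signatures fall back
# to the available side with the reversal sign convention kept
combine_ks <- function(ku, kd) {
  if (all(is.na(ku))) return(-kd)
  if (all(is.na(kd))) return(ku)
  ifelse(ku != 0 & kd != 0 & sign(ku) == sign(kd), 0, (ku - kd) / 2)
}

#' Connectivity score of a signature against one instance ranking
#'
#' Combines the up- and down-set KS enrichments into a signed score:
#' `s = (ks_up - ks_down)/2`, zeroed when both statistics share the
#' same (nonzero) sign. `s = -1` is perfect reversal — the signature's
#' up-genes sit at the bottom of the drug's ranking and its down-genes
#' at the top — and `s = +1` perfect mimicry. Swapping the up and down
#' sets negates the score.
#'
#' A signature with one empty side is scored on the remaining side
#' alone (keeping the reversal sign convention) and the result carries
#' attribute `one_sided = TRUE`.
#'
#' @param sig A [gene_signature()].
#' @param ranking Named integer permutation as in [ks_enrichment()].
#' @return A score in `[-1, 1]`.
#' @export
connectivity_score <- function(sig, ranking) {
  up <- sig_genes(sig, "up")
  down <- sig_genes(sig, "down")
  if (length(up) == 0 && length(down) == 0) abort("empty signature")
  one_sided <- length(up) == 0 || length(down) == 0
  ku <- if (length(up) > 0) ks_enrichment(up, ranking) else NA_real_
  kd <- if (length(down) > 0) ks_enrichment(down, ranking) else NA_real_
  s <- combine_ks(ku, kd)
  if (one_sided) attr(s, "one_sided") <- TRUE
  s
}

#' Score a whole drug database against a query signature
#'
#' Computes the connectivity score of every instance, aggregates
#' instances to one score per drug (median by default — robust to the
#' multi-instance structure of perturbation libraries), and attaches
#' permutation significance: the null is built by scoring `n_perm`
#' random signatures of identical up/down sizes against the very same
#' instances, so the per-instance ranking structure is preserved.
#' P-values are two-tailed on `|drug score|` with an add-one
#' pseudocount (smallest attainable p is `1/(n_perm+1)`), and FDR is
#' Benjamini-Hochberg across drugs.
#'
#' @param sig A [gene_signature()]; both direction sets nonempty.
#' @param db A [drug_profile_db()], typically after
#'   [robustness_filter()].
#' @param n_perm Number of permutation signatures (>= 100; smaller
#'   values give too coarse a p-value grid for FDR gating).
#' @param seed Seed for the permutation null.
#' @param aggregate `"median"` (default) or `"max"` (maximum-magnitude
#'   instance score).
#' @param approach Label stored in the result (defaults to the
#'   signature label).
#' @return A tibble with one row per drug: `drug_id`, `score`,
#'   `p_value`, `fdr`, `rank` (1 = most negative score), `n_instances`,
#'   `instance_scores` (list-column), `approach`.
#' @export
score_database <- function(sig, db, n_perm = 1000L, seed = 1L,
                           aggregate = c("median", "max"),
                           approach = sig_label(sig)) {
  aggregate <- match.arg(aggregate)
  if (n_perm < 100L) {
    warn("n_perm < 100 gives a very coarse permutation p-value grid")
  }
  up_idx <- match(sig_genes(sig, "up"), db$genes)
  down_idx <- match(sig_genes(sig, "down"), db$genes)
  if (anyNA(up_idx) || anyNA(down_idx)) {
    abort("signature genes missing from the database universe")
  }
  if (length(up_idx) == 0 || length(down_idx) == 0) {
    abort("score_database needs both direction sets nonempty")
  }

  agg_fun <- if (aggregate == "median") median else function(x) x[which.max(abs(x))]
  meta <- db$instance_meta
  drug_of <- factor(meta$drug_id, levels = unique(meta$drug_id))

  inst <- instance_scores_idx(db$ranks, up_idx, down_idx)
  obs <- vapply(split(inst, drug_of), agg_fun, numeric(1))

  t_up <- length(up_idx)
  t_down <- length(down_idx)
  n_genes <- length(db$genes)
  exceed <- rep(0L, length(obs))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n_genes, t_up + t_down)
      s0 <- instance_scores_idx(db$ranks, idx[seq_len(t_up)],
                                idx[t_up + seq_len(t_down)])
      null_b <- vapply(split(s0, drug_of), agg_fun, numeric(1))
      exceed <- exceed + (abs(null_b) >= abs(obs))
    }
  })
  p <- (1 + exceed) / (n_perm + 1)

  res <- tibble::tibble(
    drug_id = levels(drug_of),
    score = unname(obs),
    p_value = unname(p),
    fdr = p.adjust(p, method = "BH"),
    n_instances = as.integer(table(drug_of)),
    instance_scores = unname(split(inst, drug_of)),
    approach = approach
  )
  res <- dplyr::arrange(res, .data$score, .data$p_value, .data$drug_id)
  res$rank <- seq_len(nrow(res))
  dplyr::relocate(res, "rank", .after = "fdr")
}

#' Select the FDR-gated top-K hits of one approach
#'
#' Keeps drugs with `fdr < fdr_cut`, orders them by score (ascending
#' for the negative/reversal tail, descending for the positive/mimicry
#' tail), and truncates to the top `k`. Ties are broken by p-value and
#' then lexicographic drug id, so runs are reproducible. `multiplicity`
#' counts the drug's instances whose individual score lies in the
#' selected tail.
#'
#' @param results Output of [score_database()].
#' @param direction `"negative"` (reversers) or `"positive"` (mimics).
#' @param k Maximum hits retained (default 20).
#' @param fdr_cut FDR gate (default 0.05).
#' @return A tibble of at most `k` hits with attributes `direction` and
#'   `approach`; empty (with a warning) when nothing passes the gate.
#' @export
select_hits <- function(results, direction = c("negative", "positive"),
                        k = 20L, fdr_cut = 0.05) {
  direction <- match.arg(direction)
  pass <- dplyr::filter(results, .data$fdr < fdr_cut)
  if (direction == "negative") {
    pass <- dplyr::filter(pass, .data$score < 0)
    pass <- dplyr::arrange(pass, .data$score, .data$p_value, .data$drug_id)
    tail_sign <- -1
  } else {
    pass <- dplyr::filter(pass, .data$score > 0)
    pass <- dplyr::arrange(pass, dplyr::desc(.data$score), .data$p_value,
                           .data$drug_id)
    tail_sign <- 1
  }
  if (nrow(pass) == 0) {
    warn(paste0("no drugs pass fdr < ", fdr_cut, " in the ", direction,
                " tail"))
  }
  out <- head(pass, k)
  out$multiplicity <- vapply(out$instance_scores,
                             function(s) sum(sign(s) == tail_sign),
                             integer(1))
  attr(out, "direction") <- direction
  attr(out, "approach") <- if (nrow(results)) results$approach[1] else NA
  out
}

#' Merge hit lists across approaches
#'
#' Combines the hit lists of the three computational approaches into a
#' table of distinct drugs with per-approach membership flags and
#' instance multiplicities, drops drugs on a user-supplied exclusion
#' list (e.g. agents already prescribed for the disease, or triaged
#' away manually), and orders rows by the best (largest-magnitude)
#' score across approaches.
#'
#' @param lists A list of [select_hits()] outputs (at least one
#'   nonempty).
#' @param exclusion Character vector of drug ids to remove.
#' @return A tibble with `drug_id`, one `in_<approach>` flag and
#'   `mult_<approach>` count per approach, `best_score`, and an
#'   `excluded` attribute listing removed drugs.
#' @export
merge_hits <- function(lists, exclusion = character()) {
  lists <- purrr::compact(lists)
  if (length(lists) == 0 || all(vapply(lists, nrow, 0L) == 0)) {
    abort("need at least one nonempty hit list")
  }
  long <- purrr::map_dfr(lists, function(h) {
    tibble::tibble(drug_id = h$drug_id, approach = h$approach,
                   score = h$score, multiplicity = h$multiplicity)
  })
  wide <- tidyr::pivot_wider(
    long,
    id_cols = "drug_id",
    names_from = "approach",
    values_from = c("score", "multiplicity"),
    names_glue = "{.value}_{approach}"
  )
  flags <- tidyr::pivot_wider(
    dplyr::mutate(long, flag = TRUE),
    id_cols = "drug_id", names_from = "approach",
    values_from = "flag", values_fill = FALSE,
    names_glue = "in_{approach}"
  )
  merged <- dplyr::left_join(flags, wide, by = "drug_id")
  merged$best_score <- purrr::pmap_dbl(
    dplyr::select(merged, dplyr::starts_with("score_")),
    function(...) {
      s <- c(...)
      s <- s[!is.na(s)]
      s[which.max(abs(s))]
    }
  )
  dropped <- intersect(merged$drug_id, exclusion)
  if (length(dropped) > 0) {
    inform(paste("excluded from the merged hit table:",
                 paste(dropped, collapse = ", ")))
  }
  merged <- dplyr::filter(merged, !.data$drug_id %in% exclusion)
  merged <- dplyr::arrange(merged, dplyr::desc(abs(.data$best_score)),
                           .data$drug_id)
  attr(merged, "excluded") <- dropped
  merged
}
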
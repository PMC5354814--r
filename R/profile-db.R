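#' Drug perturbation rank-profile database
#'
#' Holds rank-transformed expression profiles for a library of drug
#' perturbation instances, in the style of connectivity-map databases:
#' a genes x instances matrix of ranks (1 = most up-regulated gene of
#' that instance) plus an instance-to-drug map. One drug may own several
#' instances from repeated experiments.
#'
#' @param ranks Integer matrix, genes in rows (rownames = gene ids),
#'   instances in columns (colnames = instance ids). Every column must
#'   be a permutation of `1..nrow(ranks)`; break ties before storage.
#' @param instance_meta Data frame with columns `instance_id`,
#'   `drug_id` and optionally `experiment`; every column of `ranks`
#'   must appear exactly once.
#'
#' @return An object of class `drug_profile_db`.
#' @export
drug_profile_db <- function(ranks, instance_meta) {
  ranks <- as.matrix(ranks)
  storage.mode(ranks) <- "integer"
  if (is.null(rownames(ranks)) || is.null(colnames(ranks))) {
    abort("ranks needs gene rownames and instance colnames")
  }
  rownames(ranks) <- toupper(rownames(ranks))
  instance_meta <- tibble::as_tibble(instance_meta)
  if (!all(c("instance_id", "drug_id") %in% names(instance_meta))) {
    abort("instance_meta needs columns instance_id, drug_id")
  }
  if (!"experiment" %in% names(instance_meta)) {
    instance_meta$experiment <- NA_character_
  }
  if (!setequal(colnames(ranks), instance_meta$instance_id) ||
      anyDuplicated(instance_meta$instance_id)) {
    abort("instance_meta must map every instance column exactly once")
  }
  n <- nrow(ranks)
  ok <- vapply(seq_len(ncol(ranks)),
               function(j) identical(sort(unname(ranks[, j])), seq_len(n)),
               logical(1))
  if (!all(ok)) {
    abort(paste("instance columns are not permutations of 1..n:",
                paste(colnames(ranks)[!ok], collapse = ", ")))
  }
  instance_meta <- instance_meta[match(colnames(ranks),
                                       instance_meta$instance_id), ]
  structure(list(genes = rownames(ranks),
                 ranks = ranks,
                 instance_meta = instance_meta),
            class = "drug_profile_db")
}

#' @export
print.drug_profile_db <- function(x, ...) {
  cat("<drug_profile_db> ", length(x$genes), " genes x ",
      ncol(x$ranks), " instances (",
      dplyr::n_distinct(x$instance_meta$drug_id), " drugs)\n", sep = "")
  invisible(x)
}

#' Number of instances per drug
#' @param db A [drug_profile_db()].
#' @return Tibble with `drug_id`, `n_instances`.
#' @export
db_instance_counts <- function(db) {
  dplyr::count(db$instance_meta, .data$drug_id, name = "n_instances")
}

#' Read / write a rank-profile database
#'
#' The rank matrix travels as TSV with a leading `gene` column and one
#' column per instance; the instance map as TSV with columns
#' `instance_id`, `drug_id`, `experiment`.
#'
#' @param matrix_path,map_path File paths.
#' @return A [drug_profile_db()].
#' @export
read_profile_db <- function(matrix_path, map_path) {
  tbl <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  if (names(tbl)[1] != "gene") abort("rank matrix must start with a gene column")
  ranks <- as.matrix(tbl[, -1])
  rownames(ranks) <- tbl$gene
  map <- readr::read_tsv(map_path, show_col_types = FALSE)
  drug_profile_db(ranks, map)
}

#' @rdname read_profile_db
#' @param db A [drug_profile_db()] to serialize.
#' @export
write_profile_db <- function(db, matrix_path, map_path) {
  tbl <- tibble::as_tibble(db$ranks)
  tbl <- dplyr::bind_cols(tibble::tibble(gene = db$genes), tbl)
  readr::write_tsv(tbl, matrix_path)
  readr::write_tsv(db$instance_meta, map_path)
  invisible(c(matrix_path, map_path))
}

#' Remove drugs whose replicate instances disagree
#'
#' Drug profiles that are not robust across repeated experiments carry
#' little signal for connectivity scoring. For every drug with at least
#' `min_instances` instances the median pairwise Spearman correlation
#' among its instance rankings is computed; drugs below `min_corr` are
#' dropped (all their instances). Drugs with a single instance cannot be
#' assessed: they are retained and flagged.
#'
#' Filtering is idempotent and never increases the instance count.
#'
#' @param db A [drug_profile_db()].
#' @param min_corr Minimum median pairwise Spearman correlation
#'   (default 0.3).
#' @param min_instances Minimum instances needed to assess robustness
#'   (default 2).
#' @return The filtered [drug_profile_db()], with a `report` attribute:
#'   a tibble of `drug_id`, `n_instances`, `median_cor`, `status`
#'   (`retained` / `dropped` / `unassessed`).
#' @export
robustness_filter <- function(db, min_corr = 0.3, min_instances = 2) {
  meta <- db$instance_meta
  per_drug <- split(meta$instance_id, meta$drug_id)
  # columns are ranks, so Pearson on the stored values IS Spearman
  med_cor <- vapply(per_drug, function(ids) {
    if (length(ids) < min_instances) return(NA_real_)
    cm <- cor(db$ranks[, ids, drop = FALSE])
    median(cm[lower.tri(cm)])
  }, numeric(1))
  report <- tibble::tibble(
    drug_id = names(per_drug),
    n_instances = lengths(per_drug),
    median_cor = unname(med_cor),
    status = dplyr::case_when(
      is.na(med_cor) ~ "unassessed",
      med_cor >= min_corr ~ "retained",
      TRUE ~ "dropped"
    )
  )
  keep_drugs <- report$drug_id[report$status != "dropped"]
  keep <- meta$instance_id[meta$drug_id %in% keep_drugs]
  out <- drug_profile_db(db$ranks[, keep, drop = FALSE],
                         meta[meta$instance_id %in% keep, ])
  attr(out, "report") <- report
  out
}
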
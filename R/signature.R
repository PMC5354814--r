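#' Directional gene signatures
#'
#' A gene signature is the query object of every connectivity approach:
#' an up-regulated and a down-regulated gene set, optionally weighted by
#' effect magnitude. It is stored as a tibble with columns `gene`,
#' `direction` (`"up"`/`"down"`) and `weight`, carrying a `label`
#' attribute naming the approach it feeds (`disease`, `sirna`,
#' `resistance`).
#'
#' Gene identifiers are matched as exact strings after upper-casing; no
#' alias or ortholog resolution is attempted.
#'
#' @param up,down Character vectors of gene identifiers. Must be
#'   disjoint and free of within-set duplicates; either may be empty.
#' @param weights Optional named numeric vector of per-gene magnitudes
#'   (e.g. absolute fold-change ranks); unmatched genes get `NA`.
#' @param label Signature label, one of `"disease"`, `"sirna"`,
#'   `"resistance"` or any free-form tag.
#'
#' @return A `gene_signature` tibble.
#' @examples
#' sig <- gene_signature(up = c("G1", "G2"), down = c("G3"), label = "disease")
#' sig_genes(sig, "up")
#' @export
gene_signature <- function(up = character(), down = character(),
                           weights = NULL, label = "disease") {
  up <- toupper(as.character(up))
  down <- toupper(as.character(down))
  if (anyDuplicated(up) || anyDuplicated(down)) {
    abort("duplicate gene ids within a direction set")
  }
  if (length(intersect(up, down)) > 0) {
    abort(paste("genes appear in both directions:",
                paste(intersect(up, down), collapse = ", ")))
  }
  if (any(!nzchar(c(up, down)))) abort("gene ids must be nonempty strings")
  tbl <- tibble::tibble(
    gene = c(up, down),
    direction = c(rep("up", length(up)), rep("down", length(down)))
  )
  if (!is.null(weights)) {
    tbl$weight <- unname(weights[toupper(names(weights))][tbl$gene])
  } else {
    tbl$weight <- NA_real_
  }
  new_gene_signature(tbl, label)
}

new_gene_signature <- function(tbl, label) {
  structure(tbl,
            label = label,
            class = c("gene_signature", class(tibble::as_tibble(tbl))))
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature:", attr(x, "label"), "> ",
      sum(x$direction == "up"), "up / ",
      sum(x$direction == "down"), "down genes\n", sep = " ")
  NextMethod()
}

#' Extract one direction of a signature
#'
#' @param sig A [gene_signature()].
#' @param direction `"up"` or `"down"`.
#' @return Character vector of gene ids.
#' @export
sig_genes <- function(sig, direction = c("up", "down")) {
  direction <- match.arg(direction)
  sig$gene[sig$direction == direction]
}

#' Signature label
#' @param sig A [gene_signature()].
#' @return The label string.
#' @export
sig_label <- function(sig) attr(sig, "label")

#' Read / write signature TSV files
#'
#' The on-disk dialect has columns `gene`, `direction` (up/down) and an
#' optional `weight`.
#'
#' @param path File path.
#' @param label Label to attach on read (defaults to the file stem).
#' @return `read_signature()` returns a [gene_signature()];
#'   `write_signature()` returns `path` invisibly.
#' @export
read_signature <- function(path, label = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene", "direction") %in% names(tbl))) {
    abort("signature file needs columns gene, direction")
  }
  w <- if ("weight" %in% names(tbl)) setNames(tbl$weight, tbl$gene)
  gene_signature(up = tbl$gene[tbl$direction == "up"],
                 down = tbl$gene[tbl$direction == "down"],
                 weights = w,
                 label = label %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_signature
#' @param sig A [gene_signature()] to serialize.
#' @export
write_signature <- function(sig, path) {
  readr::write_tsv(tibble::as_tibble(sig), path)
  invisible(path)
}

#' Overlap two signatures direction-wise
#'
#' The consensus of two independently derived signatures (e.g. two
#' meta-analysis disease signatures) is their direction-wise
#' intersection: `up = a.up n b.up`, `down = a.down n b.down`. Genes
#' that appear with opposite directions in the two inputs are dropped
#' entirely — a conservative reading of "overlap" — and reported in the
#' `conflicts` attribute.
#'
#' The operation is commutative and idempotent.
#'
#' @param a,b [gene_signature()] objects; both must be nonempty.
#' @param label Label for the result (default: label of `a`).
#' @return A [gene_signature()] with attribute `conflicts` (character
#'   vector of direction-conflicted genes).
#' @examples
#' a <- gene_signature(up = c("G1", "G2", "G3"), label = "disease")
#' b <- gene_signature(up = c("G2", "G3", "G4"), label = "disease")
#' sig_genes(overlap_signatures(a, b), "up")
#' @export
overlap_signatures <- function(a, b, label = sig_label(a)) {
  if (nrow(a) == 0 || nrow(b) == 0) abort("both signatures must be nonempty")
  up <- intersect(sig_genes(a, "up"), sig_genes(b, "up"))
  down <- intersect(sig_genes(a, "down"), sig_genes(b, "down"))
  conflicts <- union(intersect(sig_genes(a, "up"), sig_genes(b, "down")),
                     intersect(sig_genes(a, "down"), sig_genes(b, "up")))
  if (length(up) == 0 && length(down) == 0) {
    abort("signature overlap is empty in both directions; the query would be undefined")
  }
  if (length(conflicts) > 0) {
    inform(paste("dropped", length(conflicts),
                 "direction-conflicted gene(s):",
                 paste(conflicts, collapse = ", ")))
  }
  out <- gene_signature(up = up, down = down, label = label)
  attr(out, "conflicts") <- conflicts
  out
}
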
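test_that("gene signatures validate their direction sets", {
  expect_error(gene_signature(up = c("g1", "g1")), "duplicate")
  expect_error(gene_signature(up = "g1", down = "g1"), "both directions")
  sig <- gene_signature(up = c("a", "b"), down = "c", label = "sirna")
  expect_identical(sig_label(sig), "sirna")
  expect_identical(sig_genes(sig, "up"), c("A", "B"))
})

test_that("signature overlap intersects direction-wise and drops conflicts", {
  a <- gene_signature(up = c("g1", "g2", "g3"), down = "g9")
  b <- gene_signature(up = c("g2", "g3", "g4"), down = "g9")
  ov <- overlap_signatures(a, b)
  expect_setequal(sig_genes(ov, "up"), c("G2", "G3"))
  expect_setequal(sig_genes(ov, "down"), "G9")

  # idempotence and commutativity
  expect_equal(tibble::as_tibble(overlap_signatures(a, a)),
               tibble::as_tibble(a), ignore_attr = TRUE)
  ba <- overlap_signatures(b, a)
  expect_setequal(sig_genes(ba, "up"), sig_genes(ov, "up"))

  # direction conflicts are dropped and reported
  x <- gene_signature(up = c("g1", "g5"), down = "g6")
  y <- gene_signature(up = "g5", down = c("g1", "g6"))
  expect_message(ovc <- overlap_signatures(x, y), "G1")
  expect_identical(attr(ovc, "conflicts"), "G1")
  expect_false("G1" %in% ovc$gene)

  z <- gene_signature(up = "g7", down = "g8")
  expect_error(overlap_signatures(a, z), "empty")
})

test_that("signature TSV round-trips", {
  sig <- gene_signature(up = c("G1", "G2"), down = "G3",
                        weights = c(G1 = 2, G2 = 1.5, G3 = 3),
                        label = "disease")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path, label = "disease")
  expect_identical(tibble::as_tibble(back), tibble::as_tibble(sig))
})

test_that("resistance derivation is null-safe, monotone-invariant and truncates", {
  cfg <- small_cfg()
  # exact null: the two groups carry identical values gene by gene
  base <- matrix(rnorm(200 * 6), 200,
                 dimnames = list(paste0("g", 1:200), NULL))
  expr <- cbind(base, base)
  colnames(expr) <- c(paste0("R", 1:6), paste0("NR", 1:6))
  groups <- tibble::tibble(sample = colnames(expr),
                           group = rep(c("responder", "nonresponder"),
                                       each = 6))
  expect_equal(nrow(derive_resistance_signature(expr, groups)), 0)

  # planted recovery at a separating effect size
  mat <- gen_responder_matrix(cfg, effect = 3)
  sig <- derive_resistance_signature(mat$expr, mat$groups)
  recovered <- intersect(sig$gene, mat$planted$gene)
  expect_gte(length(recovered) / nrow(mat$planted), 0.9)

  # invariance under a monotone transform of expression
  sig_exp <- derive_resistance_signature(exp(mat$expr), mat$groups)
  expect_setequal(sig_genes(sig_exp, "up"), sig_genes(sig, "up"))
  expect_setequal(sig_genes(sig_exp, "down"), sig_genes(sig, "down"))

  # truncation keeps the largest effects first
  sig5 <- derive_resistance_signature(mat$expr, mat$groups, top_n = 5)
  expect_lte(sum(sig5$direction == "up"), 5)
  stats <- attr(sig, "stats")
  top_up <- stats[stats$gene %in% sig_genes(sig5, "up"), ]
  other_up <- stats[stats$gene %in% setdiff(sig_genes(sig, "up"),
                                            sig_genes(sig5, "up")), ]
  if (nrow(other_up) > 0) {
    expect_gte(min(abs(top_up$effect)), max(abs(other_up$effect)))
  }
})

test_that("per-gene rank-sum p-values match the classical test", {
  cfg <- small_cfg()
  mat <- gen_responder_matrix(cfg, effect = 1)
  sig <- derive_resistance_signature(mat$expr, mat$groups, fdr_cut = 1)
  stats <- attr(sig, "stats")
  is_nr <- mat$groups$group == "nonresponder"
  for (g in stats$gene[c(1, 50, 200, 399)]) {
    ref <- stats::wilcox.test(mat$expr[g, is_nr], mat$expr[g, !is_nr],
                              exact = FALSE, correct = FALSE)$p.value
    expect_equal(unname(stats$p_value[stats$gene == g]), ref,
                 tolerance = 1e-10)
  }
})

test_that("robustness filter drops irreproducible drugs per the median rule", {
  n <- 50
  base <- seq_len(n)
  genes <- paste0("g", 1:n)
  ranks <- cbind(i1 = base, i2 = base,            # identical replicates
                 i3 = base, i4 = rev(base),       # exactly reversed
                 i5 = base, i6 = base, i7 = sample(base))
  rownames(ranks) <- genes
  meta <- tibble::tibble(
    instance_id = paste0("i", 1:7),
    drug_id = c("good", "good", "bad", "bad", "mixed", "mixed", "mixed"))
  db <- drug_profile_db(ranks, meta)
  filtered <- robustness_filter(db, min_corr = 0.3)
  rep <- attr(filtered, "report")

  expect_equal(rep$median_cor[rep$drug_id == "good"], 1)
  expect_equal(rep$median_cor[rep$drug_id == "bad"], -1)
  expect_identical(rep$status[rep$drug_id == "bad"], "dropped")
  # three-instance drug: median of the three pairwise correlations
  cm <- cor(ranks[, c("i5", "i6", "i7")])
  expect_equal(rep$median_cor[rep$drug_id == "mixed"],
               median(cm[lower.tri(cm)]))

  # idempotence; never increases instances
  twice <- robustness_filter(filtered, min_corr = 0.3)
  expect_identical(colnames(twice$ranks), colnames(filtered$ranks))
  expect_lte(ncol(filtered$ranks), ncol(db$ranks))
})

test_that("singleton drugs are retained but flagged unassessed", {
  n <- 30
  ranks <- cbind(s1 = sample(n), s2 = sample(n))
  rownames(ranks) <- paste0("g", 1:n)
  meta <- tibble::tibble(instance_id = c("s1", "s2"),
                         drug_id = c("solo1", "solo2"))
  db <- robustness_filter(drug_profile_db(ranks, meta))
  expect_equal(ncol(db$ranks), 2)
  expect_true(all(attr(db, "report")$status == "unassessed"))
})

test_that("profile database round-trips through TSV and validates", {
  cfg <- small_cfg(n_genes = 60L, n_drugs = 8L)
  sig <- gen_signature(cfg, "disease")
  db <- gen_drug_profiles(cfg, sig)
  mpath <- withr::local_tempfile(fileext = ".tsv")
  ipath <- withr::local_tempfile(fileext = ".tsv")
  write_profile_db(db, mpath, ipath)
  back <- read_profile_db(mpath, ipath)
  expect_identical(unname(back$ranks), unname(db$ranks))
  expect_identical(back$instance_meta$drug_id, db$instance_meta$drug_id)

  bad <- db$ranks
  bad[1, 1] <- bad[2, 1]
  expect_error(drug_profile_db(bad, db$instance_meta), "not permutations")
})
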
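test_that("ks_enrichment matches direct evaluation on canonical cases", {
  n <- 100
  rk <- stats::setNames(seq_len(n), paste0("g", seq_len(n)))
  # set occupying the very top / bottom of the ranking
  expect_equal(ks_enrichment(paste0("g", 1:5), rk), 1 - 5 / n)
  # the bottom-tail branch uses (j-1)/t, so the extreme is -(1-(t-1)/n)
  expect_equal(ks_enrichment(paste0("g", 96:100), rk), -(1 - 4 / n))

  rk6 <- stats::setNames(1:6, paste0("g", 1:6))
  expect_equal(ks_enrichment(c("g1", "g6"), rk6), -1 / 2)

  expect_equal(ks_enrichment(paste0("g", 1:6), rk6), 0)  # set == universe
  expect_error(ks_enrichment(character(), rk6), "nonempty")
  expect_error(ks_enrichment("gX", rk6), "missing")
})

test_that("ks_enrichment agrees with the exhaustive oracle for small universes", {
  for (n in 4:8) {
    rk <- stats::setNames(seq_len(n), paste0("g", seq_len(n)))
    for (t in 1:3) {
      combos <- utils::combn(n, t)
      for (j in seq_len(ncol(combos))) {
        pos <- combos[, j]
        expect_equal(ks_enrichment(paste0("g", pos), rk),
                     ks_oracle(pos, n),
                     info = sprintf("n=%d positions=%s", n,
                                    paste(pos, collapse = ",")))
      }
    }
  }
})

test_that("connectivity score obeys the sign conventions", {
  n <- 40
  rk <- stats::setNames(seq_len(n), paste0("g", seq_len(n)))
  # up-genes at the bottom, down-genes at the top: perfect reversal
  rev_sig <- gene_signature(up = paste0("g", 37:40), down = paste0("g", 1:4))
  expect_equal(connectivity_score(rev_sig, rk),
               -((1 - 4 / n) + (1 - 3 / n)) / 2)
  # swapping up and down negates
  mim_sig <- gene_signature(up = paste0("g", 1:4), down = paste0("g", 37:40))
  expect_equal(connectivity_score(mim_sig, rk),
               -connectivity_score(rev_sig, rk))
  # both sets at the top: same sign, zeroed
  same <- gene_signature(up = paste0("g", 1:4), down = paste0("g", 5:8))
  expect_equal(connectivity_score(same, rk), 0)
  # one-sided signature is flagged
  half <- gene_signature(up = paste0("g", 1:4))
  s <- connectivity_score(half, rk)
  expect_true(attr(s, "one_sided"))
  expect_equal(as.numeric(s), 1 - 4 / n)
})

test_that("antisymmetry holds across random signatures and rankings", {
  withr::with_seed(9, {
    for (i in 1:20) {
      n <- sample(30:80, 1)
      rk <- stats::setNames(sample(n), paste0("g", seq_len(n)))
      g <- sample(paste0("g", seq_len(n)), 10)
      a <- gene_signature(up = g[1:5], down = g[6:10])
      b <- gene_signature(up = g[6:10], down = g[1:5])
      expect_equal(connectivity_score(a, rk), -connectivity_score(b, rk))
    }
  })
})

test_that("database scoring floors p at the pseudocount and ignores instance order", {
  cfg <- small_cfg(noise_sd = 0)
  sig <- gen_signature(cfg, "disease")
  db <- gen_drug_profiles(cfg, sig)
  res <- score_database(sig, db, n_perm = 100, seed = 3)

  planted <- res[grepl("^REV", res$drug_id), ]
  expect_equal(planted$p_value, rep(1 / 101, 3))
  expect_true(all(res$score >= -1 & res$score <= 1))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_identical(sort(res$rank), seq_len(nrow(res)))

  shuffled <- drug_profile_db(db$ranks[, rev(colnames(db$ranks))],
                              db$instance_meta)
  res2 <- score_database(sig, shuffled, n_perm = 100, seed = 3)
  expect_equal(dplyr::select(res, -"instance_scores"),
               dplyr::select(res2, -"instance_scores"))
})

test_that("hit selection gates, sorts, truncates and breaks ties deterministically", {
  fake <- tibble::tibble(
    drug_id = sprintf("d%02d", 1:40),
    score = -seq(0.99, 0.21, length.out = 40),
    p_value = rep(0.001, 40),
    fdr = c(rep(0.01, 30), rep(0.5, 10)),
    rank = 1:40,
    n_instances = 1L,
    instance_scores = as.list(-seq(0.99, 0.21, length.out = 40)),
    approach = "disease"
  )
  hits <- select_hits(fake, "negative")
  expect_equal(nrow(hits), 20)
  expect_equal(hits$drug_id[1], "d01")  # most negative first
  expect_true(all(hits$fdr < 0.05))

  # ties on (score, p): lexicographic drug id decides
  tied <- fake[1:3, ]
  tied$score <- -0.5
  tied$drug_id <- c("zeta", "alpha", "mid")
  expect_identical(select_hits(tied, "negative")$drug_id,
                   c("alpha", "mid", "zeta"))

  none <- fake
  none$fdr <- 0.9
  expect_warning(empty <- select_hits(none, "negative"), "no drugs")
  expect_equal(nrow(empty), 0)
})

test_that("merging hit lists dedups, flags approaches and applies exclusions", {
  mk <- function(ids, approach, scores) {
    tibble::tibble(drug_id = ids, approach = approach, score = scores,
                   multiplicity = 1L)
  }
  l1 <- mk(sprintf("a%02d", 1:13), "disease", -seq(0.9, 0.5, length.out = 13))
  l2 <- mk(sprintf("b%02d", 1:18), "sirna", seq(0.9, 0.5, length.out = 18))
  l3 <- mk(sprintf("c%02d", 1:14), "resistance",
           -seq(0.9, 0.5, length.out = 14))
  merged <- merge_hits(list(l1, l2, l3))
  expect_equal(nrow(merged), 45)  # disjoint union

  shared <- mk("a01", "sirna", 0.8)
  m2 <- merge_hits(list(l1, shared))
  expect_equal(sum(m2$drug_id == "a01"), 1)
  row <- m2[m2$drug_id == "a01", ]
  expect_true(row$in_disease && row$in_sirna)

  expect_message(m3 <- merge_hits(list(l1), exclusion = c("a01", "a05")),
                 "a01")
  expect_false(any(c("a01", "a05") %in% m3$drug_id))
  expect_setequal(attr(m3, "excluded"), c("a01", "a05"))
})
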
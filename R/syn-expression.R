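#' Generate a synthetic query signature
#'
#' Draws disjoint up- and down-regulated gene sets of
#' `cfg$signature_size` genes each from the universe `g1..gN`,
#' uniformly at random under the config seed. The `kind` only sets the
#' signature label; all three query types (disease, fusion-silencing,
#' chemoresistance) are structurally identical gene sets.
#'
#' @param cfg A [syn_config()].
#' @param kind Signature label: `"disease"`, `"sirna"` or `"resistance"`.
#' @return A [gene_signature()].
#' @export
gen_signature <- function(cfg, kind = c("disease", "sirna", "resistance")) {
  kind <- match.arg(kind)
  size <- cfg$signature_size
  if (2L * size > cfg$n_genes) {
    abort("signature_size too large: need 2*signature_size <= n_genes")
  }
  offset <- c(disease = 101L, sirna = 102L, resistance = 103L)[[kind]]
  withr::with_seed(cfg$seed + offset, {
    picked <- sample(gene_universe(cfg), 2L * size)
  })
  gene_signature(up = picked[seq_len(size)],
                 down = picked[size + seq_len(size)],
                 label = kind)
}

#' Generate a drug perturbation rank-profile database with planted hits
#'
#' Emulates a connectivity-map style library: `cfg$n_drugs` drugs, each
#' with a number of replicate instances drawn from
#' `cfg$instances_per_drug`. Profiles arise the way real rank profiles
#' do — from a latent differential-expression vector that is then
#' rank-transformed (rank 1 = most up-regulated gene):
#'
#' * planted *reversers* (`REV..`): signature up-genes are shifted down
#'   by `plant_effect` and down-genes up, so after ranking the up-genes
#'   concentrate at the bottom and the down-genes at the top;
#' * planted *mimics* (`MIM..`): the opposite shifts;
#' * background drugs (`D...`): a drug-specific random latent profile,
#'   exchangeable with respect to any query signature.
#'
#' The latent profile is shared by all instances of a drug and
#' perturbed per instance by gaussian noise of SD `noise_sd`, so
#' replicate instances are mutually consistent (as the robustness
#' filter expects of real libraries); at `noise_sd = 0` the planting
#' is noiseless and exactly recoverable.
#'
#' @param cfg A [syn_config()].
#' @param sig The [gene_signature()] to plant against.
#' @return A [drug_profile_db()] whose `instance_meta` gains a `role`
#'   column (`reverser` / `mimic` / `background`).
#' @export
gen_drug_profiles <- function(cfg, sig) {
  if (!all(sig$gene %in% toupper(gene_universe(cfg)))) {
    abort("signature genes outside the configured universe")
  }
  n <- cfg$n_genes
  roles <- c(rep("reverser", cfg$n_planted_reversers),
             rep("mimic", cfg$n_planted_mimics),
             rep("background",
                 cfg$n_drugs - cfg$n_planted_reversers - cfg$n_planted_mimics))
  drug_ids <- character(cfg$n_drugs)
  drug_ids[roles == "reverser"] <- sprintf("REV%02d", seq_len(sum(roles == "reverser")))
  drug_ids[roles == "mimic"] <- sprintf("MIM%02d", seq_len(sum(roles == "mimic")))
  drug_ids[roles == "background"] <- sprintf("D%03d", seq_len(sum(roles == "background")))

  up_idx <- match(sig_genes(sig, "up"), toupper(gene_universe(cfg)))
  down_idx <- match(sig_genes(sig, "down"), toupper(gene_universe(cfg)))

  withr::with_seed(cfg$seed + 211L, {
    n_inst <- if (length(cfg$instances_per_drug) == 1L) {
      rep(cfg$instances_per_drug, cfg$n_drugs)
    } else {
      sample(cfg$instances_per_drug, cfg$n_drugs, replace = TRUE)
    }
    cols <- vector("list", sum(n_inst))
    meta <- tibble::tibble(
      instance_id = character(sum(n_inst)),
      drug_id = rep(drug_ids, n_inst),
      experiment = character(sum(n_inst)),
      role = rep(roles, n_inst)
    )
    k <- 0L
    for (d in seq_len(cfg$n_drugs)) {
      # drug-level latent effect shared by all instances, so replicate
      # profiles of the same drug are reproducible (and survive the
      # robustness filter); instance noise scales with noise_sd
      if (roles[d] == "background") {
        mu <- rnorm(n)
      } else {
        # planted drugs keep a drug-specific background component as
        # well, scaled by noise_sd so noise 0 plants exactly; the tiny
        # floor keeps replicate rankings reproducible (no mass ties)
        mu <- max(cfg$noise_sd, 1e-9) * rnorm(n)
        s <- if (roles[d] == "reverser") -1 else 1
        mu[up_idx] <- s * cfg$plant_effect
        mu[down_idx] <- -s * cfg$plant_effect
      }
      for (i in seq_len(n_inst[d])) {
        k <- k + 1L
        meta$instance_id[k] <- sprintf("%s_i%d", drug_ids[d], i)
        meta$experiment[k] <- sprintf("exp%d", i)
        x <- mu + rnorm(n, sd = cfg$noise_sd)
        cols[[k]] <- rank(-x, ties.method = "random")
      }
    }
    ranks <- matrix(unlist(cols), nrow = n,
                    dimnames = list(gene_universe(cfg), meta$instance_id))
  })
  db <- drug_profile_db(ranks, meta)
  db
}

#' Generate a responder / non-responder expression matrix
#'
#' Emulates pre-treatment expression profiles of chemotherapy
#' responders and non-responders, from which a chemoresistance
#' signature is derived downstream. Expression is standard normal noise
#' with a planted set of differential genes shifted in the
#' non-responder group by `effect` standard deviations (half up, half
#' down in non-responders).
#'
#' @param cfg A [syn_config()].
#' @param n_per_group Samples per group (>= 3; rank tests are
#'   degenerate below that).
#' @param effect Shift applied to planted genes in non-responders, in
#'   noise-SD units; 0 plants nothing.
#' @param n_de Number of planted differential genes (default twice the
#'   configured signature size, split evenly up/down).
#' @return A list with elements `expr` (genes x samples matrix),
#'   `groups` (tibble `sample`, `group` in
#'   `{responder, nonresponder}`) and `planted` (a [gene_signature()]
#'   of the planted truth; empty when `effect = 0`).
#' @export
gen_responder_matrix <- function(cfg, n_per_group = 10L, effect = 2,
                                 n_de = 2L * cfg$signature_size) {
  if (n_per_group < 3L) abort("need >= 3 samples per group")
  if (n_de > cfg$n_genes) abort("n_de exceeds the gene universe")
  genes <- gene_universe(cfg)
  samples <- c(sprintf("R%02d", seq_len(n_per_group)),
               sprintf("NR%02d", seq_len(n_per_group)))
  groups <- tibble::tibble(
    sample = samples,
    group = rep(c("responder", "nonresponder"), each = n_per_group)
  )
  withr::with_seed(cfg$seed + 307L, {
    expr <- matrix(rnorm(cfg$n_genes * 2L * n_per_group),
                   nrow = cfg$n_genes,
                   dimnames = list(genes, samples))
    de_idx <- sample(cfg$n_genes, n_de)
  })
  half <- n_de %/% 2L
  up_idx <- de_idx[seq_len(half)]          # higher in non-responders
  down_idx <- de_idx[setdiff(seq_len(n_de), seq_len(half))]
  nr <- groups$group == "nonresponder"
  if (effect != 0 && n_de > 0) {
    expr[up_idx, nr] <- expr[up_idx, nr] + effect
    expr[down_idx, nr] <- expr[down_idx, nr] - effect
    planted <- gene_signature(up = genes[up_idx], down = genes[down_idx],
                              label = "resistance")
  } else {
    planted <- gene_signature(label = "resistance")
  }
  list(expr = expr, groups = groups, planted = planted)
}
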
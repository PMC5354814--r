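# shared small study configuration: keeps simulation-backed tests fast
# while preserving the structure of the default conditions
small_cfg <- function(seed = 42L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 400L, n_drugs = 24L,
         instances_per_drug = 1:3, n_planted_reversers = 3L,
         n_planted_mimics = 3L, signature_size = 20L),
    list(...))
  do.call(syn_config, args)
}

# named rank vector for one instance of a profile database
ranking_of <- function(db, instance) {
  stats::setNames(db$ranks[, instance], db$genes)
}

# independent scalar evaluation of the bidirectional KS statistic,
# looping the two branch maxima explicitly over j
ks_oracle <- function(positions, n) {
  v <- sort(positions)
  t <- length(v)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - v[j] / n)
    b <- max(b, v[j] / n - (j - 1) / t)
  }
  if (a >= b) a else -b
}
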
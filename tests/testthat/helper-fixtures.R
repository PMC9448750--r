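# Shared in-code fixtures for the test suite. Everything is generated at
# test time; nothing binary is stored.

# A random non-negative NMF instance (V, W with unit columns, H).
rand_nmf_instance <- function(seed, n = 24L) {
  set.seed(seed)
  W <- matrix(rgamma(2L * n, shape = 1), n, 2L)
  W <- sweep(W, 2, colSums(W), "/")
  H <- rgamma(2L, shape = 2, rate = 1 / 50)
  V <- rpois(n, as.numeric(W %*% H) + 1)
  list(V = as.numeric(V), W = W, H = H)
}

# Cohort of noisy copies of the two bundled artefact signatures
# (Dirichlet jitter, concentration `conc`), for derivation tests.
make_two_cluster_set <- function(n_per = 8L, conc = 500, seed = 42L) {
  targets <- list(unrepaired = bundled_signatures("unrepaired")$probabilities,
                  repaired = bundled_signatures("repaired")$probabilities)
  set.seed(seed)
  rows <- lapply(rep(names(targets), each = n_per), function(proto) {
    g <- rgamma(96, shape = conc * pmax(targets[[proto]], 1e-8))
    g[channel_mask("TC")] <- 0
    g / sum(g)
  })
  sample_set(do.call(rbind, rows),
             labels = rep(names(targets), each = n_per))
}

# Small mutation table helper.
mut_table <- function(sample_id, pos, ref = "C", alt = "T", chrom = "chr1",
                      reads = NULL) {
  df <- data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
                   ref = ref, alt = alt, stringsAsFactors = FALSE)
  if (!is.null(reads)) df$supporting_reads <- reads
  df
}

# The bundled three-signature mixture basis used in recovery tests.
mixture_basis <- function() {
  reference_signatures()[, c("SBS1like", "SBS5like", "SBS18like")]
}

# Evaluate expr after seeding (lazy promise evaluation).
with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}
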
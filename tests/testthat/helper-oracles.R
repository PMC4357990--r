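# Independent oracles and small fixture builders used across test files.

# Closed-form log marginal likelihood of an HWE-graph genotype table under a
# uniform Beta prior on the allele frequency: every genotype decomposes into
# path pairs with identical transition counts, so the evidence is the
# Beta-binomial normalizer times 2^(number of heterozygotes) (ordered-pair
# likelihood convention).
hwe_closed_form_log_ml <- function(t, a1 = 1, a2 = 1) {
  nH <- sum(t$counts[, 1])
  nR <- sum(t$counts[, 2])
  n_het <- sum(t$counts[, 1] == 1)
  n_het * log(2) + lbeta(a1 + nH, a2 + nR) - lbeta(a1, a2)
}

# Sequential-predictive oracle for the naive enumeration model: multiply
# the Dirichlet-multinomial predictive probabilities of the observations one
# at a time (category counts updated after each draw).
nem_predictive_chain <- function(multiplicity, alpha = 0.5) {
  J <- length(multiplicity) + 1L   # observed categories + unobserved pool
  seq_obs <- rep(seq_along(multiplicity), multiplicity)
  n <- rep(0, J)
  log_p <- 0
  for (j in seq_obs) {
    log_p <- log_p + log((alpha + n[j]) / (J * alpha + sum(n)))
    n[j] <- n[j] + 1
  }
  log_p
}

# Single-allele gene with deletion branch and duplication loop: the smallest
# graph with genuinely ambiguous latent decompositions and exactly two free
# parameters (loss, gain).
single_gene_cnav_graph <- function(sym = "A") {
  cnav_graph(
    states = data.frame(
      id = c("start", "loss_branch", paste0("emit_", sym), "copy_exit", "end"),
      kind = c("start", "silent", "emit", "silent", "end"),
      emit = c(NA, NA, sym, NA, NA)),
    edges = data.frame(
      from = c("start", "loss_branch", "loss_branch", paste0("emit_", sym),
               "copy_exit", "copy_exit"),
      to = c("loss_branch", "end", paste0("emit_", sym), "copy_exit",
             paste0("emit_", sym), "end")))
}

# Haplotype copy-number pmf of the single-gene graph: P(0) = loss,
# P(k) = (1 - loss) * (1 - gain) * gain^(k-1) for k >= 1.
single_gene_hap_pmf <- function(loss, gain, kmax) {
  c(loss, (1 - loss) * (1 - gain) * gain^(seq_len(kmax) - 1))
}

# Genotype pmf by self-convolution of the haplotype pmf (exact, untruncated
# for totals up to kmax).
single_gene_geno_pmf <- function(loss, gain, nmax) {
  hap <- single_gene_hap_pmf(loss, gain, nmax)
  vapply(0:nmax, function(n) {
    sum(hap[(0:n) + 1] * hap[(n - 0:n) + 1])
  }, 0)
}

# small genotype table literal
toy_table <- function(m, alphabet = colnames(m)) {
  genotype_table(m, alphabet = alphabet)
}

hwe_graph <- function(a = "H", b = "R") cnav_model("hwe_biallelic", alleles = c(a, b))

expect_z_within <- function(est, truth, se, z = 3) {
  expect_lt(abs(est - truth), z * se + 1e-12)
}
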
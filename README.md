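# cnavhmm

Bayesian inference for population genotype distributions at loci with
joint **c**opy-**n**umber and **a**llelic **v**ariation (CNAV), for
geneticists analysing MLPA-style integer allele-count data — the kind of
table produced for the low-affinity Fc-gamma-receptor (FcγR) gene region,
where genes vary both in how many copies a chromosome carries and in which
alleles those copies bear.

## The model

A diploid genotype is modelled as the output of a stochastic finite-state
machine.  The user defines a directed graph with one start state, one
absorbing end state, silent states and emitting states; a **haplotype** is
the emission tally of one random start-to-end walk under a row-stochastic
transition matrix *A*, and a **genotype** is the element-wise sum of two
independent walks:

    f(y | A) = prod_i  sum_{(h,h'): e(h)+e(h') = y_i}  P(h|A) P(h'|A)

summed over ordered path pairs.  The classical Hardy-Weinberg model is the
single-bifurcation graph (the bifurcation probability is the allele
frequency, giving p², 2pq, q² exactly); deletions and duplications enter
as loss branches and gain recursion loops, extending the equilibrium with
independence between gene copies and between copy-number events (geometric
copy-number law).  Rewiring the graph expresses loss of heterozygosity,
first-order allele dependency, tandem alleles, shared (ambiguous) promoter
emissions, or a fully connected gene block whose highest-probability path
orders the genes.

The machinery around the graphs:

* **`cnav_fit()`** — data-augmented Metropolis-within-Gibbs sampler for the
  posterior of *A*: rejection-pool refreshes of latent path pairs
  (acceptance 1, identity fallback), a symmetric bounded tree-search
  ("squirrel") backup kernel with Metropolis correction, and conjugate
  MatrixDirichlet row updates.  Returns a classed fit with `print`,
  `summary`, `coef`, `plot`, `simulate`, `logLik` methods.
* **`chib_marginal()` / `nem_marginal()` / `bayes_factor()`** — two-block
  Chib–Jeliazkov marginal likelihood (exact or simulation-approximated
  likelihood ordinate) against a closed-form Dirichlet-multinomial
  "naive enumeration model" baseline with a Jeffreys prior.
* **`translate_genotypes()`** — haplotype-phase translation through an
  alternative emission set.
* **`cnav_restarts()` / `cluster_modes()` / `rank_modes()`** — multimodal
  posterior dissection by restarts, k-means on transition draws, and
  per-mode evidence ranking with highest-probability-path gene orders.
* **`make_scenario()` / `simulate_genotypes()`** — reproducible synthetic
  MLPA-style data sets, including independent-gene and linked-block
  copy-number scenarios.

## Worked example

A three-allele gene (the FcγR IIIb HNA-1 system) with a deletion branch,
a duplication loop and true allele frequencies 0.55 / 0.35 / 0.10; 387
simulated individuals:

```r
library(cnavhmm)

g <- cnav_model("cnav_multiallele", alleles = c("Na1", "Na2", "SH"))
A <- transition_matrix(g, c("loss_branch->end"         = 0.15,
                            "allele_choice->emit_Na1"  = 0.55,
                            "allele_choice->emit_Na2"  = 0.35,
                            "copy_exit->allele_choice" = 0.08))
t   <- simulate_genotypes(g, A, n = 387, seed = 20)
fit <- cnav_fit(g, t, cycles = 1000, pool_size = 500, seed = 21)
summary(fit)
```

    Posterior summary (95% credible intervals):
                           edge   mean median  lower  upper
             start->loss_branch 1.0000 1.0000 1.0000 1.0000
               loss_branch->end 0.1574 0.1578 0.1310 0.1845
     loss_branch->allele_choice 0.8426 0.8422 0.8155 0.8690
        allele_choice->emit_Na1 0.5464 0.5460 0.5064 0.5833
        allele_choice->emit_Na2 0.3495 0.3483 0.3188 0.3861
         allele_choice->emit_SH 0.1042 0.1037 0.0825 0.1265
        emit_Na1->copy_exit     1.0000 1.0000 1.0000 1.0000
        ...
       copy_exit->allele_choice 0.0751 0.0744 0.0556 0.0987
                 copy_exit->end 0.9249 0.9256 0.9013 0.9444

Every 95% interval covers its true value: the deletion probability
(truth 0.15), the three allele frequencies (0.55 / 0.35 / 0.10) and the
duplication probability (0.08) are recovered from counts alone, even
though each genotype's decomposition into two haplotypes is latent.
Model comparison against the naive enumeration baseline:

```r
cj  <- chib_marginal(fit)      # exact likelihood ordinate
nem <- nem_marginal(t)
bayes_factor(cj, nem)
```

    log marginal likelihood (chib_jeliazkov): -928.6541  (MC s.e. 0.0095)
      components: log-lik -915.6944 + log-prior 0.6931 - log-posterior 13.6528
    log marginal likelihood (nem_closed_form): -943.3121
    Bayes factor (chib_jeliazkov over nem_closed_form): 2.322e+06

The HMM, with 4 free parameters, beats the 17-category enumeration model
by a Bayes factor of about 2×10⁶ — the graph both compresses the genotype
distribution and assigns positive probability to genotypes never observed.

A command-line front end over the same functions ships at
`inst/cli/cnav.R` (subcommands `validate`, `simulate`, `fit`, `evidence`,
`phase`, `modes`, `compare`; every run writes a JSON manifest).

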
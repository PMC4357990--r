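test_that("exact log likelihood matches hand values", {
  g <- hwe_graph()
  # deterministic matrix, data all equal to the single reachable genotype
  A1 <- transition_matrix(g, c("allele_choice->emit_H" = 1))
  t1 <- toy_table(matrix(rep(c(2L, 0L), 10), ncol = 2, byrow = TRUE,
                         dimnames = list(NULL, c("H", "R"))))
  expect_equal(cnav_loglik(g, A1, t1, copy_cap = 1)$value, 0)

  # one heterozygote at p = 0.5: 2pq = 0.5
  A2 <- transition_matrix(g, c("allele_choice->emit_H" = 0.5))
  t2 <- toy_table(matrix(c(1L, 1L), 1, dimnames = list(NULL, c("H", "R"))))
  expect_equal(cnav_loglik(g, A2, t2, copy_cap = 1)$value, log(0.5),
               tolerance = 1e-12)
})

test_that("simulated likelihood agrees with the exact one within MC error", {
  g <- cnav_model("cnav_multiallele", alleles = c("A", "B"))
  A <- transition_matrix(g, c("loss_branch->end" = 0.2,
                              "allele_choice->emit_A" = 0.6,
                              "copy_exit->allele_choice" = 0.1))
  t <- simulate_genotypes(g, A, 100, seed = 1)
  exact <- cnav_loglik(g, A, t, method = "exact", copy_cap = 6)
  sim <- cnav_loglik(g, A, t, method = "simulated", m = 2e5, seed = 2)
  expect_equal(sim$smoothing, 1 / (2 * 2e5))
  expect_z_within(sim$value, exact$value, sim$se)
})

test_that("NEM closed form equals the sequential-predictive oracle", {
  # single observation: predictive probability 1/2 by prior symmetry
  t1 <- toy_table(matrix(c(1L, 1L), 1, dimnames = list(NULL, c("H", "R"))))
  expect_equal(nem_marginal(t1)$log_ml, log(0.5), tolerance = 1e-12)
  expect_equal(nem_marginal(t1)$categories, 2)

  # counts (1, 1): direct gamma-function expression
  m2 <- rbind(c(1L, 1L), c(2L, 0L))
  colnames(m2) <- c("H", "R")
  val <- nem_marginal(toy_table(m2))$log_ml
  hand <- log(gamma(1.5)^3 * gamma(0.5) / (gamma(0.5)^3 * gamma(3.5)))
  expect_equal(val, hand, tolerance = 1e-12)
  expect_equal(val, nem_predictive_chain(c(1, 1)), tolerance = 1e-10)

  # random small multisets: agreement to 1e-10
  set.seed(3)
  for (r in 1:10) {
    k <- sample(1:5, 1)
    mult <- sample(1:6, k, replace = TRUE)
    geno <- matrix(sample(0:3, 2 * k, replace = TRUE), k)
    while (anyDuplicated(geno)) geno <- matrix(sample(0:3, 2 * k, replace = TRUE), k)
    colnames(geno) <- c("H", "R")
    tt <- toy_table(geno[rep(seq_len(k), mult), , drop = FALSE])
    expect_equal(nem_marginal(tt)$log_ml, nem_predictive_chain(mult),
                 tolerance = 1e-10)
  }

  # multiplicity invariance under individual order
  m3 <- rbind(c(0L, 2L), c(1L, 1L), c(0L, 2L), c(2L, 0L))
  colnames(m3) <- c("H", "R")
  expect_equal(nem_marginal(toy_table(m3))$log_ml,
               nem_marginal(toy_table(m3[c(3, 1, 4, 2), ]))$log_ml)
})

test_that("Chib-Jeliazkov estimate matches the conjugate closed form", {
  g <- hwe_graph()
  A <- transition_matrix(g, c("allele_choice->emit_H" = 0.3))
  t <- simulate_genotypes(g, A, 80, seed = 4)
  fit <- cnav_fit(g, t, cycles = 600, pool_size = 150, seed = 5)
  ev <- chib_marginal(fit, copy_cap = 1)
  # the component identity holds exactly
  expect_equal(ev$log_ml,
               ev$components[["log_likelihood"]] +
                 ev$components[["log_prior_ordinate"]] -
                 ev$components[["log_posterior_ordinate"]])
  closed <- hwe_closed_form_log_ml(t)
  expect_z_within(ev$log_ml, closed, max(ev$se, 1e-4))

  # invariant (within MC error) to the interior evaluation point
  A_alt <- interior_project(g, transition_matrix(
    g, c("allele_choice->emit_H" = 0.45)))
  ev2 <- chib_marginal(fit, A_star = A_alt, copy_cap = 1)
  expect_z_within(ev2$log_ml, closed, max(3 * ev2$se, 0.05))

  # boundary evaluation points are refused
  expect_error(chib_marginal(fit, A_star = transition_matrix(
    g, c("allele_choice->emit_H" = 1))), "boundary")
})

test_that("two independent estimator runs agree within their error bands", {
  g <- hwe_graph()
  A <- transition_matrix(g, c("allele_choice->emit_H" = 0.4))
  t <- simulate_genotypes(g, A, 60, seed = 6)
  f1 <- cnav_fit(g, t, cycles = 500, pool_size = 100, seed = 7)
  f2 <- cnav_fit(g, t, cycles = 500, pool_size = 100, seed = 8)
  e1 <- chib_marginal(f1, copy_cap = 1)
  e2 <- chib_marginal(f2, copy_cap = 1)
  expect_z_within(e1$log_ml, e2$log_ml,
                  max(sqrt(e1$se^2 + e2$se^2), 1e-3))
})

test_that("an empty data set has marginal likelihood 1", {
  g <- hwe_graph()
  t0 <- genotype_table(matrix(0L, 0, 2, dimnames = list(NULL, c("H", "R"))))
  expect_equal(cnav_loglik(g, transition_matrix(g), t0)$value, 0)
})

test_that("Bayes factors are oriented, anti-symmetric, and data-guarded", {
  g <- hwe_graph()
  A <- transition_matrix(g, c("allele_choice->emit_H" = 0.3))
  t <- simulate_genotypes(g, A, 60, seed = 9)
  fit <- cnav_fit(g, t, cycles = 400, pool_size = 100, seed = 10)
  cj <- chib_marginal(fit, copy_cap = 1)
  nem <- nem_marginal(t)

  bf <- bayes_factor(cj, nem)
  expect_equal(bf$bf, exp(cj$log_ml - nem$log_ml))
  expect_equal(bf$log10_bf, (cj$log_ml - nem$log_ml) / log(10))
  # identical inputs: BF exactly 1; anti-symmetry
  expect_equal(bayes_factor(nem, nem)$bf, 1)
  expect_equal(bayes_factor(cj, nem)$bf * bayes_factor(nem, cj)$bf, 1,
               tolerance = 1e-12)
  # a log-ML advantage of 4.2 corresponds to a Bayes factor of about 66.7
  shifted <- nem
  shifted$log_ml <- nem$log_ml + 4.2
  expect_equal(bayes_factor(shifted, nem)$bf, 66.7, tolerance = 1e-3)

  t_other <- simulate_genotypes(g, A, 61, seed = 11)
  expect_error(bayes_factor(cj, nem_marginal(t_other)), "different data")
})
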
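test_that("conjugate row sampling follows the MatrixDirichlet posterior", {
  g <- cnav_model("cnav_multiallele", alleles = c("A", "B"))
  prior <- cnav_prior(g, 1)

  # single-edge rows are exactly 1
  set.seed(1)
  A <- sample_transition_matrix(g, prior)
  expect_equal(unname(A["start->loss_branch"]), 1)
  expect_equal(unname(A["emit_A->copy_exit"]), 1)

  # zero counts, uniform prior: mean 1/out_degree over 1e4 draws
  set.seed(2)
  draws <- replicate(1e4, sample_transition_matrix(g, prior)["allele_choice->emit_A"])
  expect_z_within(mean(draws), 0.5, stats::sd(draws) / sqrt(1e4))

  # Beta(999, 1) mean under counts (998, 0)
  set.seed(3)
  draws <- replicate(1e4, sample_transition_matrix(
    g, prior, c("allele_choice->emit_A" = 998))["allele_choice->emit_A"])
  mu <- 999 / 1000
  se <- sqrt(mu * (1 - mu) / 1001) / sqrt(1e4)
  expect_z_within(mean(draws), mu, se)

  expect_error(sample_transition_matrix(g, prior, c("emit_A->emit_B" = 3)),
               "non-edge")
  expect_error(cnav_prior(g, 0), "> 0")
})

test_that("latent initialization finds compatible pairs or a named error", {
  g <- hwe_graph()
  t <- toy_table(matrix(c(1, 1), 1, dimnames = list(NULL, c("H", "R"))))
  set.seed(4)
  latent <- initialize_latent(g, t)
  # the unique decomposition: one H path and one R path
  expect_equal(unname(latent[1, "allele_choice->emit_H"]), 1L)
  expect_equal(unname(latent[1, "allele_choice->emit_R"]), 1L)

  t_bad <- toy_table(matrix(c(3, 0), 1, dimnames = list(NULL, c("H", "R"))))
  expect_error(initialize_latent(g, t_bad), "S1.*no compatible")

  g2 <- cnav_model("cnav_multiallele", alleles = c("A", "B"))
  t2 <- toy_table(matrix(c(2, 0), 1, dimnames = list(NULL, c("A", "B"))))
  set.seed(5)
  latent2 <- initialize_latent(g2, t2)
  inc <- cnavhmm:::emission_incidence(g2)
  expect_equal(unname((latent2 %*% inc)[1, ]), c(2L, 0L))
})

test_that("pool refresh is exact conditional sampling with identity fallback", {
  g <- hwe_graph()
  A <- transition_matrix(g, c("allele_choice->emit_H" = 1))
  t <- toy_table(matrix(c(2, 0, 2, 0), 2, byrow = TRUE,
                        dimnames = list(NULL, c("H", "R"))))
  set.seed(6)
  latent <- initialize_latent(g, t)
  upd <- pool_path_update(g, A, t, latent, pool_size = 10)
  expect_true(all(upd$matched))

  # match probability per genotype ~ 1 - (1 - q_g)^n with q_g from the oracle
  A2 <- transition_matrix(g, c("allele_choice->emit_H" = 0.5))
  m3 <- rbind(matrix(rep(c(2, 0), 40), ncol = 2, byrow = TRUE),
              matrix(rep(c(1, 1), 40), ncol = 2, byrow = TRUE),
              matrix(rep(c(0, 2), 40), ncol = 2, byrow = TRUE))
  colnames(m3) <- c("H", "R")
  t3 <- toy_table(m3)
  set.seed(7)
  latent3 <- initialize_latent(g, t3)
  n_pool <- 5
  reps <- 200
  hit <- matrix(NA, reps, 3)
  for (r in seq_len(reps)) {
    u <- pool_path_update(g, A2, t3, latent3, pool_size = n_pool)
    hit[r, ] <- c(mean(u$matched[1:40]), mean(u$matched[41:80]),
                  mean(u$matched[81:120]))
  }
  q <- c(0.25, 0.5, 0.25)
  expected <- 1 - (1 - q)^n_pool
  for (j in 1:3) {
    se <- sqrt(expected[j] * (1 - expected[j]) / (40 * reps))
    expect_z_within(mean(hit[, j]), expected[j], se)
  }

  expect_error(cnav_fit(g, t, pool_size = 0), "pool_size")
})

test_that("tree-search proposals depend only on the genotype (symmetry)", {
  g <- cnav_model("cnav_multiallele", alleles = c("A", "B"))
  geno <- c(A = 2L, B = 0L)
  cp1 <- compatible_pairs(g, geno)
  cp2 <- compatible_pairs(g, geno)
  expect_identical(cp1$counts, cp2$counts)   # deterministic, genotype-only
  expect_equal(length(cp1$first), 3)         # (AA,null), (null,AA), (A,A)

  # same seed, different current pair: identical proposal choice
  A <- transition_matrix(g, c("loss_branch->end" = 0.2,
                              "allele_choice->emit_A" = 0.6,
                              "copy_exit->allele_choice" = 0.1))
  for (s in 1:10) {
    set.seed(100 + s)
    r1 <- squirrel_update(g, A, geno, cp1$counts[1, ])
    set.seed(100 + s)
    r2 <- squirrel_update(g, A, geno, cp1$counts[3, ])
    # both runs proposed the same pair; acceptance may differ, but a move,
    # when it happens, lands on that same proposal
    if (!identical(r1, cp1$counts[1, ]) && !identical(r2, cp1$counts[3, ])) {
      expect_identical(r1, r2)
    }
  }
})

test_that("tree-search kernel leaves the exact conditional invariant", {
  g <- cnav_model("cnav_multiallele", alleles = c("A", "B"))
  A <- transition_matrix(g, c("loss_branch->end" = 0.2,
                              "allele_choice->emit_A" = 0.6,
                              "copy_exit->allele_choice" = 0.1))
  geno <- c(A = 2L, B = 0L)
  cp <- compatible_pairs(g, geno)
  key <- apply(cp$counts, 1, paste, collapse = ",")
  pp <- path_prob(cp$paths, A)
  w <- pp[cp$first] * pp[cp$second]
  cond <- tapply(w, key, sum)
  cond <- cond / sum(cond)

  set.seed(8)
  cache <- new.env(parent = emptyenv())
  cur <- cp$counts[1, ]
  n_updates <- 20000
  trace <- character(n_updates)
  for (i in seq_len(n_updates)) {
    cur <- squirrel_update(g, A, geno, cur, cache = cache)
    trace[i] <- paste(cur, collapse = ",")
  }
  # batch-means z per decomposition class (the chain is autocorrelated)
  batches <- rep(seq_len(50), each = n_updates / 50)
  for (k in names(cond)) {
    bm <- tapply(trace == k, batches, mean)
    z <- (mean(bm) - cond[[k]]) / (stats::sd(bm) / sqrt(50))
    expect_lt(abs(z), 4)
  }

  # a genotype with a unique pair, or a zero budget, leaves the chain alone
  gh <- hwe_graph()
  Ah <- transition_matrix(gh, c("allele_choice->emit_H" = 0.4))
  cph <- compatible_pairs(gh, c(H = 2L, R = 0L))
  expect_equal(length(unique(apply(cph$counts, 1, paste, collapse = ","))), 1)
  set.seed(9)
  expect_identical(squirrel_update(gh, Ah, c(H = 2L, R = 0L), cph$counts[1, ]),
                   cph$counts[1, ])
  expect_identical(squirrel_update(g, A, geno, cp$counts[1, ], budget = 0),
                   cp$counts[1, ])
})

test_that("sampler collapses to the closed-form Beta posterior on unambiguous data", {
  g <- hwe_graph()
  A <- transition_matrix(g, c("allele_choice->emit_H" = 0.3))
  t <- simulate_genotypes(g, A, 60, seed = 10)
  fit <- cnav_fit(g, t, cycles = 500, pool_size = 100, seed = 11)
  expect_equal(nrow(fit$draws), 500)

  nH <- sum(t$counts[, "H"]); nR <- sum(t$counts[, "R"])
  a <- 1 + nH; b <- 1 + nR
  keep <- as.matrix(fit)[, "allele_choice->emit_H"]
  ess <- length(keep) / cnavhmm:::iact_geyer(keep)
  expect_z_within(mean(keep), a / (a + b),
                  sqrt(a * b / ((a + b)^2 * (a + b + 1))) / sqrt(ess))
  expect_z_within(stats::sd(keep), sqrt(a * b / ((a + b)^2 * (a + b + 1))),
                  stats::sd(keep) / sqrt(2 * ess))

  # same seed, bit-identical chains
  fit2 <- cnav_fit(g, t, cycles = 500, pool_size = 100, seed = 11)
  expect_identical(fit$draws, fit2$draws)

  # latent pairs always reproduce the observed genotypes
  inc <- cnavhmm:::emission_incidence(g)
  expect_equal(unname(fit$latent %*% inc), unname(t$counts))
})

test_that("posterior summaries respect row stochasticity and Beta quantiles", {
  g <- hwe_graph()
  A <- transition_matrix(g, c("allele_choice->emit_H" = 0.3))
  t <- simulate_genotypes(g, A, 80, seed = 12)
  fit <- cnav_fit(g, t, cycles = 600, pool_size = 100, seed = 13)
  s <- posterior_summary(fit)
  for (r in cnavhmm:::edge_rows(g)) {
    expect_equal(sum(s$mean[r]), 1, tolerance = 1e-9)
  }
  nH <- sum(t$counts[, "H"]); nR <- sum(t$counts[, "R"])
  i <- match("allele_choice->emit_H", s$edge)
  ess <- nrow(as.matrix(fit)) / cnavhmm:::iact_geyer(as.matrix(fit)[, i])
  mc <- 3 * stats::sd(as.matrix(fit)[, i]) / sqrt(ess)
  expect_lt(abs(s$lower[i] - stats::qbeta(0.025, 1 + nH, 1 + nR)), 4 * mc + 0.02)
  expect_lt(abs(s$upper[i] - stats::qbeta(0.975, 1 + nH, 1 + nR)), 4 * mc + 0.02)

  # degenerate draws give zero-width intervals
  fit0 <- fit
  fit0$draws[] <- rep(colMeans(fit$draws), each = nrow(fit$draws))
  s0 <- posterior_summary(fit0)
  expect_equal(s0$lower, s0$upper)
})

test_that("diagnostics behave on iid draws, identical chains, and dispersed starts", {
  g <- hwe_graph()
  A <- transition_matrix(g, c("allele_choice->emit_H" = 0.3))
  t <- simulate_genotypes(g, A, 50, seed = 14)
  fit <- cnav_fit(g, t, cycles = 400, pool_size = 100, seed = 15)

  # iid draws injected: autocorrelation time ~ 1
  fit_iid <- fit
  set.seed(16)
  p <- stats::rbeta(400, 5, 5)
  fit_iid$draws[, "allele_choice->emit_H"] <- p
  fit_iid$draws[, "allele_choice->emit_R"] <- 1 - p
  d <- cnav_diagnostics(fit_iid)
  expect_lt(max(d$iact), 1.5)

  # identical chains: PSRF ~ 1
  d2 <- cnav_diagnostics(fit, list(fit))
  expect_lt(max(abs(d2$psrf - 1)), 0.05)

  # chains from different simplex corners on a unimodal target converge
  t2 <- simulate_genotypes(g, A, 80, seed = 17)
  f1 <- cnav_fit(g, t2, cycles = 400, pool_size = 100, seed = 18)
  f2 <- cnav_fit(g, t2, cycles = 400, pool_size = 100, seed = 19)
  d3 <- cnav_diagnostics(f1, list(f2))
  expect_lt(max(d3$psrf), 1.1)

  short <- cnav_fit(g, t, cycles = 12, pool_size = 50, seed = 20)
  expect_error(cnav_diagnostics(short), "fewer than 10")
})

test_that("fit methods expose the model idiomatically", {
  g <- hwe_graph()
  A <- transition_matrix(g, c("allele_choice->emit_H" = 0.3))
  t <- simulate_genotypes(g, A, 60, seed = 21)
  fit <- cnav_fit(g, t, cycles = 200, pool_size = 100, seed = 22)
  expect_s3_class(coef(fit), "cnav_tmat")
  expect_equal(length(coef(fit)), nrow(g$edges))
  sim <- simulate(fit, seed = 23)
  expect_s3_class(sim, "cnav_genotypes")
  expect_equal(nrow(sim$counts), nrow(t$counts))
  ll <- logLik(fit)
  expect_true(is.finite(as.numeric(ll)))
  expect_equal(attr(ll, "df"), 1)
  expect_output(print(fit), "CNAV hidden Markov model fit")
  expect_output(print(summary(fit)), "credible")
})
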
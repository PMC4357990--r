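#' Initialize latent path pairs
#'
#' Assigns every individual one haplotype path pair compatible with its
#' observed genotype, drawn uniformly at random from the set discovered by
#' the deterministic bounded tree search ([compatible_pairs()]).  A genotype
#' with no compatible decomposition within the cap is a model/data mismatch
#' and raises an error naming the individual.
#'
#' @param g a valid [cnav_graph()].
#' @param t a [genotype_table()] aligned to `g`.
#' @param copy_cap per-haplotype per-symbol cap (default 5).
#' @param budget tree-search expansion budget per distinct genotype.
#' @param cache optional environment memoizing compatible-pair sets by
#'   genotype key (shared with the sampler).
#' @return Integer matrix (individuals x edges) of combined pair transition
#'   counts, with the cache attached as attribute `"cache"`.
#' @export
initialize_latent <- function(g, t, copy_cap = 5, budget = 1e5, cache = NULL) {
  stopifnot(inherits(g, "cnav_graph"), inherits(t, "cnav_genotypes"))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  N <- nrow(t$counts)
  E <- nrow(g$edges)
  latent <- matrix(0L, N, E, dimnames = list(t$sample_id, edge_labels(g)))
  for (i in seq_len(N)) {
    cp <- compat_cached(cache, g, t$counts[i, ], copy_cap, budget)
    if (length(cp$first) == 0) {
      stop("individual '", t$sample_id[i], "' (genotype ",
           paste(t$counts[i, ], collapse = ","),
           ") has no compatible path pair within copy_cap = ",
           paste(copy_cap, collapse = ","),
           "; the graph cannot produce this genotype", call. = FALSE)
    }
    pick <- sample.int(length(cp$first), 1L)
    latent[i, ] <- cp$counts[pick, ]
  }
  attr(latent, "cache") <- cache
  latent
}

compat_cached <- function(cache, g, genotype, copy_cap, budget) {
  key <- paste(genotype, collapse = ",")
  if (is.null(cache[[key]])) {
    cache[[key]] <- compatible_pairs(g, genotype, copy_cap, budget)
  }
  cache[[key]]
}

#' Incomplete-Gibbs pool refresh of latent path pairs
#'
#' For each individual, up to `pool_size` random path pairs are simulated at
#' the current transition matrix; the first pair whose summed emissions
#' match the observed genotype replaces the individual's latent pair.  This
#' is exact sampling from the full conditional by rejection, so the
#' acceptance probability is 1.  Individuals for which no pair matches keep
#' their current pair (identity kernel) and are flagged unmatched.
#'
#' @inheritParams initialize_latent
#' @param A a [transition_matrix()].
#' @param latent current latent counts (individuals x edges).
#' @param pool_size number of attempted pairs per individual (>= 1).
#' @param step_guard maximum transitions per walk.
#' @return List with `latent` (updated counts) and `matched` (logical per
#'   individual).
#' @export
pool_path_update <- function(g, A, t, latent, pool_size = 1000,
                             step_guard = 10000) {
  stopifnot(pool_size >= 1)
  enc <- graph_encoding(g)
  res <- cpp_pool_update(enc$ptr, enc$out_idx, enc$edge_to, as.numeric(A),
                         enc$emit, enc$start, enc$fin, enc$K, enc$E,
                         t$counts, as.integer(pool_size),
                         as.integer(step_guard))
  matched <- as.logical(res$matched)
  latent[matched, ] <- res$counts[matched, , drop = FALSE]
  list(latent = latent, matched = matched)
}

#' Symmetric tree-search ("squirrel") update of one latent pair
#'
#' Backup kernel for individuals the pool refresh missed.  A proposal pair
#' is drawn uniformly from the genotype's compatible-pair set discovered by
#' the deterministic bounded tree search; because that set depends only on
#' the genotype — never on the current pair — the proposal distribution is
#' symmetric, and a Metropolis acceptance
#' `min(1, P(proposal | A) / P(current | A))` leaves the full conditional
#' invariant.  On rejection, or when the search finds nothing within
#' budget, the current pair is kept.
#'
#' @inheritParams pool_path_update
#' @param genotype observed count vector for the individual.
#' @param current combined edge-count vector of the current pair.
#' @param budget tree-search expansion budget (0 gives the identity kernel).
#' @param copy_cap per-haplotype cap.
#' @param cache optional memoization environment (see [initialize_latent()]).
#' @return Updated combined edge-count vector.
#' @export
squirrel_update <- function(g, A, genotype, current, budget = 1e5,
                            copy_cap = 5, cache = NULL) {
  if (budget <= 0) return(current)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  cp <- compat_cached(cache, g, genotype, copy_cap, budget)
  S <- length(cp$first)
  if (S == 0) return(current)
  pick <- sample.int(S, 1L)
  la <- log(as.numeric(A))
  la[!is.finite(la)] <- -1e308
  lr <- sum((cp$counts[pick, ] - as.numeric(current)) * la)
  if (lr >= 0 || log(stats::runif(1)) < lr) cp$counts[pick, ] else current
}

#' Fit a CNAV hidden Markov model
#'
#' Data-augmented Metropolis-within-Gibbs sampler for the posterior
#' distribution of transition probabilities given observed genotypes.  Each
#' cycle (1) refreshes latent path pairs by the rejection pool
#' ([pool_path_update()]), (2) applies the symmetric tree-search kernel
#' ([squirrel_update()]) to every unmatched individual, and (3) draws the
#' transition matrix from its conjugate MatrixDirichlet full conditional
#' given the current pair transition counts.  All transition draws, the
#' per-cycle transition-count totals (needed for the Chib-Jeliazkov
#' posterior ordinate) and the pool match-fraction trace are recorded.
#'
#' @param g a valid [cnav_graph()].
#' @param t a [genotype_table()] aligned to `g` (see [read_genotypes()]).
#' @param prior a [cnav_prior()]; default uniform (`alpha = 1`).
#' @param cycles number of sampling cycles (>= 1), each yielding one draw.
#' @param pool_size path pairs attempted per individual and cycle.
#' @param burn_in fraction of initial cycles discarded by summaries, in
#'   `[0, 1)` (default 0.5).
#' @param squirrel_budget tree-search expansion budget (0 disables the
#'   backup kernel).
#' @param copy_cap per-haplotype per-symbol emission cap.
#' @param seed optional integer seed; two runs with the same seed are
#'   bit-identical.
#' @param step_guard maximum transitions per random walk.
#' @param cache optional environment memoizing compatible-pair sets by
#'   genotype (reused across restarts on the same graph and data).
#' @return Object of class `cnav_fit` with elements `draws` (cycles x edges
#'   matrix of transition probabilities), `path_counts` (cycles x edges
#'   transition-count totals), `match_fraction`, `graph`, `data`, `prior`,
#'   `latent` (final state) and `config`.  Methods: `print`, `summary`,
#'   `coef`, `plot`, `simulate`, `as.matrix`, `logLik`.
#' @examples
#' g <- cnav_model("hwe_biallelic", alleles = c("H", "R"))
#' A <- transition_matrix(g, c("allele_choice->emit_H" = 0.7))
#' t <- simulate_genotypes(g, A, n = 100, seed = 1)
#' fit <- cnav_fit(g, t, cycles = 200, pool_size = 200, seed = 1)
#' coef(fit)["allele_choice->emit_H"]
#' @export
cnav_fit <- function(g, t, prior = cnav_prior(g), cycles = 1000,
                     pool_size = 1000, burn_in = 0.5,
                     squirrel_budget = 1e5, copy_cap = 5, seed = NULL,
                     step_guard = 10000, cache = NULL) {
  stopifnot(inherits(g, "cnav_graph"), inherits(t, "cnav_genotypes"))
  if (cycles < 1) stop("cycles must be >= 1", call. = FALSE)
  if (pool_size < 1) stop("pool_size must be >= 1", call. = FALSE)
  if (burn_in < 0 || burn_in >= 1) stop("burn_in must be in [0, 1)", call. = FALSE)
  if (!identical(t$alphabet, g$alphabet)) {
    stop("genotype table alphabet does not match the graph", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  latent <- initialize_latent(g, t, copy_cap,
                              budget = max(squirrel_budget, 1e4), cache = cache)
  N <- nrow(t$counts)
  E <- nrow(g$edges)
  draws <- matrix(NA_real_, cycles, E, dimnames = list(NULL, edge_labels(g)))
  path_counts <- matrix(NA_integer_, cycles, E,
                        dimnames = list(NULL, edge_labels(g)))
  match_fraction <- numeric(cycles)
  A <- sample_transition_matrix(g, prior, colSums(latent))
  for (cy in seq_len(cycles)) {
    upd <- pool_path_update(g, A, t, latent, pool_size, step_guard)
    latent <- upd$latent
    if (squirrel_budget > 0 && any(!upd$matched)) {
      for (i in which(!upd$matched)) {
        latent[i, ] <- squirrel_update(g, A, t$counts[i, ], latent[i, ],
                                       squirrel_budget, copy_cap, cache)
      }
    }
    totals <- colSums(latent)
    A <- sample_transition_matrix(g, prior, totals)
    draws[cy, ] <- as.numeric(A)
    path_counts[cy, ] <- as.integer(totals)
    match_fraction[cy] <- mean(upd$matched)
  }
  structure(list(draws = draws, path_counts = path_counts,
                 match_fraction = match_fraction,
                 graph = g, data = t, prior = prior, latent = latent,
                 config = list(cycles = cycles, pool_size = pool_size,
                               burn_in = burn_in,
                               squirrel_budget = squirrel_budget,
                               copy_cap = copy_cap, seed = seed,
                               step_guard = step_guard),
                 fingerprint = data_fingerprint(t)),
            class = "cnav_fit")
}

# post-burn-in draw indices
keep_index <- function(fit, burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- fit$config$burn_in
  n <- nrow(fit$draws)
  seq.int(floor(burn_in * n) + 1L, n)
}

#' Posterior summary of transition probabilities
#'
#' Per-edge posterior mean, median and central credible interval from the
#' post-burn-in draws.  The mean rows are renormalized to be row-stochastic
#' (the largest renormalization deviation is reported as attribute
#' `"renorm_deviation"`).
#'
#' @param fit a [cnav_fit()].
#' @param level credible level (default 0.95).
#' @param burn_in override of the fit's burn-in fraction.
#' @return Data frame with columns `edge`, `mean`, `median`, `lower`,
#'   `upper`.
#' @export
posterior_summary <- function(fit, level = 0.95, burn_in = NULL) {
  stopifnot(inherits(fit, "cnav_fit"))
  keep <- keep_index(fit, burn_in)
  if (length(keep) < 1) stop("no post-burn-in draws", call. = FALSE)
  d <- fit$draws[keep, , drop = FALSE]
  mu <- colMeans(d)
  dev <- 0
  for (r in edge_rows(fit$graph)) {
    s <- sum(mu[r])
    dev <- max(dev, abs(s - 1))
    mu[r] <- mu[r] / s
  }
  a <- (1 - level) / 2
  qs <- apply(d, 2, stats::quantile, probs = c(a, 0.5, 1 - a), names = FALSE)
  out <- data.frame(edge = colnames(d), mean = unname(mu),
                    median = qs[2, ], lower = qs[1, ], upper = qs[3, ],
                    row.names = NULL)
  attr(out, "renorm_deviation") <- dev
  attr(out, "level") <- level
  out
}

#' Convergence diagnostics for posterior samples
#'
#' For every free transition parameter: the integrated autocorrelation time
#' (Geyer initial-positive-sequence estimator), the effective sample size,
#' and — when several chains are supplied — the Gelman-Rubin potential
#' scale reduction factor.
#'
#' @param fit a [cnav_fit()].
#' @param others optional list of further `cnav_fit` chains on the same
#'   model (for PSRF).
#' @param burn_in override of the fit's burn-in fraction.
#' @return Data frame with columns `edge`, `iact`, `ess` and (multi-chain)
#'   `psrf`.
#' @export
cnav_diagnostics <- function(fit, others = NULL, burn_in = NULL) {
  stopifnot(inherits(fit, "cnav_fit"))
  chains <- c(list(fit), others)
  keeps <- lapply(chains, keep_index, burn_in = burn_in)
  if (any(vapply(keeps, length, 1L) < 10L)) {
    stop("fewer than 10 post-burn-in draws; run more cycles", call. = FALSE)
  }
  idx <- free_coordinate_index(fit$graph)
  labs <- edge_labels(fit$graph)[idx]
  d1 <- fit$draws[keeps[[1]], idx, drop = FALSE]
  iact <- vapply(seq_along(idx), function(j) iact_geyer(d1[, j]), 0)
  out <- data.frame(edge = labs, iact = iact,
                    ess = nrow(d1) / pmax(iact, 1e-12), row.names = NULL)
  if (length(chains) >= 2) {
    mats <- Map(function(ch, k) ch$draws[k, idx, drop = FALSE], chains, keeps)
    out$psrf <- vapply(seq_along(idx), function(j) {
      psrf(lapply(mats, function(m) m[, j]))
    }, 0)
  }
  out
}

# Geyer initial positive sequence estimator of the integrated
# autocorrelation time tau = 1 + 2 * sum_k rho_k
iact_geyer <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(1)
  rho <- stats::acf(x, lag.max = min(n - 1L, 500L), plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
  # pair sums rho_{2m} + rho_{2m+1}, truncate at first negative pair
  tau <- -rho[1]   # rho_0 = 1 counted twice below
  m <- 0L
  while (2L * m + 2L <= length(rho)) {
    gam <- rho[2L * m + 1L] + rho[2L * m + 2L]
    if (gam <= 0) break
    tau <- tau + 2 * gam
    m <- m + 1L
  }
  max(tau, 1e-12)
}

# Gelman-Rubin PSRF over a list of numeric chains (equal length)
psrf <- function(chains) {
  m <- length(chains)
  n <- min(lengths(chains))
  x <- vapply(chains, function(v) v[seq_len(n)], numeric(n))
  mu <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(mu)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
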
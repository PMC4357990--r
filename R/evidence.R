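#' HMM log likelihood of a genotype table
#'
#' The likelihood of an individual is the probability of its genotype under
#' two independent graph walks.  `method = "exact"` computes it from the
#' enumerated, cap-renormalized genotype distribution;
#' `method = "simulated"` approximates genotype frequencies from `m`
#' simulated genotypes, with additive smoothing `1/(2m)` on the observed
#' genotype cells to avert zero frequencies, and a delta-method Monte Carlo
#' standard error.  Ordered-pair (ordered-sample) conventions are used
#' throughout, so values are directly comparable with the enumeration
#' model's evidence.
#'
#' @param g a valid [cnav_graph()].
#' @param A a [transition_matrix()].
#' @param t a [genotype_table()] or [aggregate_genotypes()] multiset.
#' @param method `"exact"` or `"simulated"`.
#' @param m simulated genotypes for `method = "simulated"`.
#' @param copy_cap enumeration cap for `method = "exact"`.
#' @param seed optional seed (simulated method).
#' @param smooth disable to get raw frequencies (a zero then yields
#'   `-Inf`, flagged with advice to raise `m`).
#' @return List with `value`, `se` (0 for exact), `method` and bookkeeping
#'   fields.
#' @export
cnav_loglik <- function(g, A, t, method = c("exact", "simulated"),
                        m = 1e5, copy_cap = 5, seed = NULL, smooth = TRUE) {
  method <- match.arg(method)
  ms <- if (inherits(t, "cnav_multiset")) t else {
    if (nrow(t$counts) == 0) {
      return(list(value = 0, se = 0, method = method, n = 0L))
    }
    aggregate_genotypes(t)
  }
  key <- apply(ms$genotypes, 1, paste, collapse = ",")
  w <- ms$multiplicity
  if (method == "exact") {
    d <- exact_genotype_distribution(g, A, copy_cap)
    p <- unname(dist_lookup(d)[key])
    if (anyNA(p) || any(p == 0)) {
      warning("observed genotype(s) outside the capped support have probability 0; ",
              "raise copy_cap", call. = FALSE)
      p[is.na(p)] <- 0
    }
    list(value = sum(w * log(p)), se = 0, method = "exact",
         renorm = d$renorm, n = ms$n)
  } else {
    if (m < 1) stop("m must be >= 1", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    enc <- graph_encoding(g)
    geno <- cpp_sample_genotypes(enc$ptr, enc$out_idx, enc$edge_to,
                                 as.numeric(A), enc$emit, enc$start, enc$fin,
                                 enc$K, as.integer(m),
                                 as.integer(10000))
    sim_key <- apply(geno, 1, paste, collapse = ",")
    hits <- as.numeric(table(factor(sim_key, levels = key)))
    p <- if (smooth) (hits + 0.5) / m else hits / m
    if (any(p == 0)) {
      warning("simulated frequency 0 for observed genotype(s); ",
              "raise m or enable smoothing", call. = FALSE)
      return(list(value = -Inf, se = NA_real_, method = "simulated",
                  m = m, smoothing = smooth, n = ms$n))
    }
    # delta method under multinomial sampling of the m draws
    v <- (sum(w^2 * (1 - p) / p) - (sum(w)^2 - sum(w^2))) / m
    list(value = sum(w * log(p)), se = sqrt(max(v, 0)),
         method = "simulated", m = m, smoothing = if (smooth) 1 / (2 * m) else 0,
         n = ms$n)
  }
}

#' Chib-Jeliazkov marginal likelihood
#'
#' Two-block marginal-likelihood estimator at a fixed evaluation point
#' `A*`:
#' `log m(y) = log f(y | A*) + log pi(A*) - log pihat(A* | y)`,
#' where the posterior ordinate `pihat(A* | y)` is the Rao-Blackwellized
#' average, over the recorded latent path draws, of the conjugate
#' MatrixDirichlet full-conditional density at `A*`.  `A*` defaults to the
#' interior-projected, renormalized posterior mean.  The identity between
#' the reported components holds exactly by construction; the Monte Carlo
#' standard error combines the batch-means error of the posterior ordinate
#' with the likelihood error (simulated method).
#'
#' @param fit a [cnav_fit()] (path transition counts are recorded by
#'   default).
#' @param A_star evaluation point; must be strictly inside every multi-edge
#'   row simplex (see [interior_project()]).
#' @param method likelihood method, `"exact"` or `"simulated"`.
#' @param m,copy_cap,seed passed to [cnav_loglik()].
#' @param burn_in override of the fit's burn-in fraction.
#' @return Object of class `cnav_evidence`: `log_ml`, `se`, `method`
#'   (`"chib_jeliazkov"`), `components` (likelihood, prior and posterior
#'   ordinates), `A_star`.
#' @export
chib_marginal <- function(fit, A_star = NULL, method = c("exact", "simulated"),
                          m = 1e5, copy_cap = NULL, seed = NULL,
                          burn_in = NULL) {
  stopifnot(inherits(fit, "cnav_fit"))
  method <- match.arg(method)
  g <- fit$graph
  if (is.null(copy_cap)) {
    # smallest per-symbol cap covering every observed genotype: keeps the
    # exact-likelihood enumeration as cheap as the data allow
    copy_cap <- if (nrow(fit$data$counts)) {
      pmax(apply(fit$data$counts, 2, max), 1L)
    } else {
      fit$config$copy_cap
    }
  }
  if (is.null(A_star)) {
    A_star <- interior_project(g, coef(fit))
  } else {
    p <- as.numeric(A_star)
    for (r in edge_rows(g)) {
      if (length(r) > 1L && (any(p[r] <= 0) || any(p[r] >= 1))) {
        stop("A_star lies on the boundary of row '", g$edges$from[r[1]],
             "'; pass interior_project(g, A_star)", call. = FALSE)
      }
    }
  }
  ll <- cnav_loglik(g, A_star, fit$data, method = method, m = m,
                    copy_cap = copy_cap, seed = seed)
  lprior <- ldirichlet_matrix(g, A_star, fit$prior)
  keep <- keep_index(fit, burn_in)
  lt <- vapply(keep, function(cy) {
    ldirichlet_matrix(g, A_star, as.numeric(fit$prior) + fit$path_counts[cy, ])
  }, 0)
  mx <- max(lt)
  wts <- exp(lt - mx)
  lpost <- mx + log(mean(wts))
  # batch-means MC error of the log posterior ordinate
  B <- max(2L, min(30L, floor(length(wts) / 4)))
  bm <- vapply(split(wts, cut(seq_along(wts), B, labels = FALSE)), mean, 0)
  se_post <- stats::sd(bm) / sqrt(B) / mean(wts)
  se <- sqrt(ll$se^2 + se_post^2)
  structure(list(log_ml = ll$value + lprior - lpost,
                 method = "chib_jeliazkov", se = se,
                 components = c(log_likelihood = ll$value,
                                log_prior_ordinate = lprior,
                                log_posterior_ordinate = lpost),
                 A_star = A_star, n = nrow(fit$data$counts),
                 likelihood_method = method,
                 fingerprint = fit$fingerprint),
            class = "cnav_evidence")
}

#' Naive enumeration model evidence
#'
#' Closed-form Dirichlet-multinomial marginal likelihood of the ordered
#' sample under the naive enumeration model (NEM): one category per
#' genotype observed at least once, plus one pooled category for unobserved
#' genotypes, with a Jeffreys `Dirichlet(1/2, ..., 1/2)` prior:
#' `log m = log G(sum a) - log G(sum a + N) + sum_j [log G(a_j + n_j) - log G(a_j)]`.
#' No multinomial coefficient is included, so the value is directly
#' comparable with the HMM evidence for the same individuals.
#'
#' @param t a [genotype_table()] or [aggregate_genotypes()] multiset.
#' @param alpha per-category concentration (default Jeffreys 0.5).
#' @return A `cnav_evidence` object with `method = "nem_closed_form"` and
#'   `se = 0`.
#' @export
nem_marginal <- function(t, alpha = 0.5) {
  ms <- if (inherits(t, "cnav_multiset")) t else aggregate_genotypes(t)
  J <- nrow(ms$genotypes) + 1L    # observed categories + unobserved pool
  n <- c(ms$multiplicity, 0L)
  a <- rep(alpha, J)
  log_ml <- lgamma(sum(a)) - lgamma(sum(a) + ms$n) +
    sum(lgamma(a + n) - lgamma(a))
  structure(list(log_ml = log_ml, method = "nem_closed_form", se = 0,
                 categories = J, n = ms$n, alpha = alpha,
                 fingerprint = data_fingerprint(ms)),
            class = "cnav_evidence")
}

#' @export
print.cnav_evidence <- function(x, ...) {
  cat(sprintf("log marginal likelihood (%s): %.4f", x$method, x$log_ml))
  if (x$se > 0) cat(sprintf("  (MC s.e. %.4f)", x$se))
  cat("\n")
  if (!is.null(x$components)) {
    cat(sprintf("  components: log-lik %.4f + log-prior %.4f - log-posterior %.4f\n",
                x$components[1], x$components[2], x$components[3]))
  }
  invisible(x)
}

#' Bayes factor between two evidence results
#'
#' `BF(a over b) = exp(logML_a - logML_b)`, with the Monte Carlo standard
#' errors of the two log marginal likelihoods propagated in quadrature.
#' Results computed on different data sets are refused.
#'
#' @param a,b `cnav_evidence` objects for the same data.
#' @return Object of class `cnav_bf`: `bf`, `log_bf` (natural), `log10_bf`,
#'   `se_log_bf`, and the orientation label.
#' @export
bayes_factor <- function(a, b) {
  stopifnot(inherits(a, "cnav_evidence"), inherits(b, "cnav_evidence"))
  if (!is.null(a$fingerprint) && !is.null(b$fingerprint) &&
      !identical(a$fingerprint, b$fingerprint)) {
    stop("evidence results were computed on different data sets", call. = FALSE)
  }
  lb <- a$log_ml - b$log_ml
  structure(list(bf = exp(lb), log_bf = lb, log10_bf = lb / log(10),
                 se_log_bf = sqrt(a$se^2 + b$se^2),
                 orientation = sprintf("%s over %s", a$method, b$method)),
            class = "cnav_bf")
}

#' @export
print.cnav_bf <- function(x, ...) {
  cat(sprintf("Bayes factor (%s): %.4g  (log %.4f, log10 %.4f, s.e.(log) %.4f)\n",
              x$orientation, x$bf, x$log_bf, x$log10_bf, x$se_log_bf))
  invisible(x)
}
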
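#' Repeated sampler restarts
#'
#' Runs the sampler several times with independent random latent
#' initializations.  On multimodal posteriors — e.g. fully connected gene
#' blocks, where the gene order along the highest-probability path is only
#' identified up to symmetry — each chain converges to one local optimum,
#' and the pooled draws can be dissected with [cluster_modes()].
#'
#' @inheritParams cnav_fit
#' @param runs number of restarts (>= 1).
#' @param seeds integer vector of per-run seeds (default `seq_len(runs)`
#'   offset by 1000); must be distinct.
#' @param ... further arguments to [cnav_fit()].
#' @return List of [cnav_fit()] objects, class `cnav_restarts`.
#' @export
cnav_restarts <- function(g, t, runs, seeds = NULL, ...) {
  if (runs < 1) stop("runs must be >= 1", call. = FALSE)
  if (is.null(seeds)) seeds <- 1000L + seq_len(runs)
  if (length(seeds) != runs || anyDuplicated(seeds)) {
    stop("seeds must be one distinct integer per run", call. = FALSE)
  }
  cache <- new.env(parent = emptyenv())   # compatible-pair sets shared across runs
  out <- lapply(seeds, function(s) cnav_fit(g, t, seed = s, cache = cache, ...))
  class(out) <- "cnav_restarts"
  out
}

#' k-means dissection of a multimodal posterior
#'
#' Pools the post-burn-in transition draws of all runs, clusters them by
#' k-means on the flattened free-parameter coordinates (fixed edge order,
#' 10 random starts, deterministic given `seed`), renormalizes each cluster
#' mean into a row-stochastic transition matrix, and assigns every run to
#' the cluster holding the majority of its draws.
#'
#' @param fits a list of [cnav_fit()] objects (or a `cnav_restarts`).
#' @param k number of clusters (<= pooled draw count).
#' @param burn_in override of each fit's burn-in fraction.
#' @param seed seed for the k-means starts.
#' @return Object of class `cnav_modes`: `means` (list of `cnav_tmat`
#'   cluster means), `sizes` (member draw counts), `draw_cluster`,
#'   `run_cluster`, `k`, and the pooled coordinates bookkeeping.
#' @export
cluster_modes <- function(fits, k, burn_in = NULL, seed = 1) {
  fits <- unclass(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "cnav_fit")))
  g <- fits[[1]]$graph
  idx <- free_coordinate_index(g)
  pooled <- lapply(fits, function(f) f$draws[keep_index(f, burn_in), idx, drop = FALSE])
  run_of <- rep(seq_along(fits), vapply(pooled, nrow, 1L))
  X <- do.call(rbind, pooled)
  if (k > nrow(X)) stop("k exceeds the pooled draw count", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = 10, iter.max = 100)
  labs <- edge_labels(g)
  means <- lapply(seq_len(k), function(j) {
    p <- rep(1, nrow(g$edges))
    p[idx] <- km$centers[j, ]
    for (r in edge_rows(g)) p[r] <- p[r] / sum(p[r])
    structure(stats::setNames(p, labs), class = "cnav_tmat")
  })
  run_cluster <- vapply(seq_along(fits), function(i) {
    cl <- km$cluster[run_of == i]
    as.integer(names(which.max(table(cl))))
  }, 1L)
  structure(list(means = means, sizes = as.integer(km$size),
                 draw_cluster = km$cluster, run_cluster = run_cluster,
                 k = k, graph = g, inertia = km$tot.withinss),
            class = "cnav_modes")
}

#' Rank posterior modes by marginal likelihood
#'
#' Evaluates the Chib-Jeliazkov marginal likelihood of every run at its
#' cluster's interior-projected mean transition matrix, aggregates
#' mean +/- s.d. of the log marginal likelihood per cluster, and ranks
#' clusters by decreasing mean.  Each cluster is annotated with its
#' highest-probability haplotype path and the gene (symbol) order emitted
#' along it.
#'
#' @param fits the list of [cnav_fit()] runs passed to [cluster_modes()].
#' @param clusters a [cluster_modes()] result.
#' @param method,m,copy_cap likelihood options for [chib_marginal()].
#' @param best_path_cap cap for the highest-probability path search.
#' @param seed optional seed for the simulated likelihood.
#' @return Object of class `cnav_mode_report`: data frame `report` (one row
#'   per cluster, ranked) with columns `cluster`, `size`, `runs`,
#'   `log_ml_mean`, `log_ml_sd`, `order` (emitted symbol order of the
#'   highest-probability path), plus `run_log_ml` and `run_cluster`.
#' @export
rank_modes <- function(fits, clusters, method = c("simulated", "exact"),
                       m = 1e5, copy_cap = 5, best_path_cap = 3, seed = NULL) {
  fits <- unclass(fits)
  method <- match.arg(method)
  stopifnot(inherits(clusters, "cnav_modes"))
  g <- clusters$graph
  if (!is.null(seed)) set.seed(seed)
  run_log_ml <- vapply(seq_along(fits), function(i) {
    A_star <- interior_project(g, clusters$means[[clusters$run_cluster[i]]])
    chib_marginal(fits[[i]], A_star = A_star, method = method, m = m,
                  copy_cap = copy_cap)$log_ml
  }, 0)
  per <- lapply(seq_len(clusters$k), function(j) {
    members <- which(clusters$run_cluster == j)
    bp <- best_path(g, clusters$means[[j]], copy_cap = best_path_cap)
    data.frame(cluster = j, size = clusters$sizes[j], runs = length(members),
               log_ml_mean = if (length(members)) mean(run_log_ml[members]) else NA_real_,
               log_ml_sd = if (length(members) > 1) stats::sd(run_log_ml[members]) else 0,
               order = paste(bp$emitted, collapse = ">"),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, per)
  report <- report[order(-report$log_ml_mean), ]
  rownames(report) <- NULL
  structure(list(report = report, run_log_ml = run_log_ml,
                 run_cluster = clusters$run_cluster),
            class = "cnav_mode_report")
}

#' @export
print.cnav_mode_report <- function(x, ...) {
  cat("Posterior modes ranked by Chib-Jeliazkov log marginal likelihood:\n")
  print(transform(x$report, log_ml_mean = round(log_ml_mean, 3),
                  log_ml_sd = round(log_ml_sd, 3)), row.names = FALSE)
  invisible(x)
}
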
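#' @export
print.cnav_fit <- function(x, ...) {
  cfg <- x$config
  cat("CNAV hidden Markov model fit\n")
  cat(sprintf("  %d individuals, %d-symbol alphabet, %d edges (%d free parameters)\n",
              nrow(x$data$counts), length(x$graph$alphabet),
              nrow(x$graph$edges), free_parameters(x$graph)))
  cat(sprintf("  %d cycles (burn-in %.0f%%), pool size %d, mean match fraction %.3f\n",
              cfg$cycles, 100 * cfg$burn_in, cfg$pool_size,
              mean(x$match_fraction)))
  cat("Posterior mean transition probabilities:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.cnav_fit <- function(object, ...) {
  s <- posterior_summary(object)
  structure(stats::setNames(s$mean, s$edge), class = "cnav_tmat")
}

#' @export
summary.cnav_fit <- function(object, level = 0.95, ...) {
  out <- list(summary = posterior_summary(object, level = level),
              diagnostics = tryCatch(cnav_diagnostics(object),
                                     error = function(e) NULL),
              config = object$config)
  class(out) <- "summary.cnav_fit"
  out
}

#' @export
print.summary.cnav_fit <- function(x, ...) {
  cat(sprintf("Posterior summary (%d%% credible intervals):\n",
              round(100 * attr(x$summary, "level"))))
  print(transform(x$summary, mean = round(mean, 4), median = round(median, 4),
                  lower = round(lower, 4), upper = round(upper, 4)),
        row.names = FALSE)
  if (!is.null(x$diagnostics)) {
    cat("\nDiagnostics (free parameters):\n")
    print(transform(x$diagnostics, iact = round(iact, 2), ess = round(ess, 1)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.matrix.cnav_fit <- function(x, burn_in = NULL, ...) {
  x$draws[keep_index(x, burn_in), , drop = FALSE]
}

#' Simulate genotype tables from a fitted model
#'
#' Draws new MLPA-style data sets of the same size as the training data
#' (or `n`) at the renormalized posterior-mean transition matrix.
#'
#' @param object a [cnav_fit()].
#' @param nsim number of tables.
#' @param seed optional seed.
#' @param n individuals per table (default: as in the data).
#' @param ... unused.
#' @return A list of [genotype_table()]s (length `nsim`), or a single table
#'   when `nsim = 1`.
#' @export
simulate.cnav_fit <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- nrow(object$data$counts)
  A <- coef(object)
  out <- lapply(seq_len(nsim), function(i) {
    simulate_genotypes(object$graph, A, n)
  })
  if (nsim == 1) out[[1]] else out
}

#' @export
logLik.cnav_fit <- function(object, copy_cap = NULL, ...) {
  if (is.null(copy_cap)) {
    copy_cap <- pmax(apply(object$data$counts, 2, max), 1L)
  }
  ll <- cnav_loglik(object$graph, coef(object), object$data,
                    method = "exact", copy_cap = copy_cap)
  structure(ll$value, df = free_parameters(object$graph), class = "logLik")
}

#' Trace plots of transition-probability draws
#'
#' One panel per free parameter row, drawn with base graphics.
#'
#' @param x a [cnav_fit()].
#' @param edges which edge labels to plot (default: all free parameters).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cnav_fit <- function(x, edges = NULL, ...) {
  idx <- free_coordinate_index(x$graph)
  labs <- edge_labels(x$graph)[idx]
  if (!is.null(edges)) labs <- intersect(labs, edges)
  if (!length(labs)) stop("nothing to plot", call. = FALSE)
  graphics::matplot(x$draws[, labs, drop = FALSE], type = "l", lty = 1,
                    xlab = "cycle", ylab = "transition probability", ...)
  graphics::legend("topright", legend = labs, col = seq_along(labs), lty = 1,
                   cex = 0.7, bg = "white")
  invisible(x)
}

#' Export posterior draws as TSV
#'
#' One row per sampling cycle, one column per graph edge, plus a JSON
#' metadata sidecar (`<path>.meta.json`) echoing the run configuration.
#'
#' @param fit a [cnav_fit()].
#' @param path output TSV path.
#' @export
write_posterior <- function(fit, path) {
  utils::write.table(data.frame(cycle = seq_len(nrow(fit$draws)), fit$draws,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(fit$config, list(match_fraction_mean = mean(fit$match_fraction))),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
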
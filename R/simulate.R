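#' Random haplotype and genotype walks
#'
#' `sample_path()` draws one random start-to-end walk of the graph under a
#' transition matrix and tallies its counting events (one haplotype).
#' `sample_genotype()` walks the graph twice and returns the pair together
#' with the element-wise emission sum (one diploid genotype).  Both use R's
#' global RNG; seed with [set.seed()].
#'
#' @param g a valid [cnav_graph()].
#' @param A a [transition_matrix()].
#' @param step_guard maximum transitions per walk (default 10000); a
#'   runaway recursion loop beyond it raises an error.
#' @return `sample_path()`: list with `states` (visited id sequence) and
#'   `emissions` (named count vector).  `sample_genotype()`: list with
#'   `first`, `second` (the two path records) and `genotype`.
#' @export
sample_path <- function(g, A, step_guard = 10000) {
  stopifnot(inherits(g, "cnav_graph"))
  s <- g$states
  E <- nrow(g$edges)
  out <- split(seq_len(E), factor(g$edges$from, levels = s$id))
  emit_of <- stats::setNames(match(s$emit, g$alphabet), s$id)
  p <- as.numeric(A)
  state <- s$id[s$kind == "start"]
  end_id <- s$id[s$kind == "end"]
  path <- state
  em <- stats::setNames(integer(length(g$alphabet)), g$alphabet)
  steps <- 0L
  while (state != end_id) {
    steps <- steps + 1L
    if (steps > step_guard) {
      stop("random walk exceeded the step guard (", step_guard,
           " steps) around state '", state,
           "'; a recursion loop has runaway probability", call. = FALSE)
    }
    es <- out[[state]]
    e <- if (length(es) == 1L) es else es[sample.int(length(es), 1L, prob = p[es])]
    state <- g$edges$to[e]
    path <- c(path, state)
    k <- emit_of[[state]]
    if (!is.na(k)) em[k] <- em[k] + 1L
  }
  list(states = path, emissions = em)
}

#' @rdname sample_path
#' @export
sample_genotype <- function(g, A, step_guard = 10000) {
  h1 <- sample_path(g, A, step_guard)
  h2 <- sample_path(g, A, step_guard)
  list(first = h1, second = h2, genotype = h1$emissions + h2$emissions)
}

#' Simulate a genotype data set
#'
#' Draws `n` independent diploid genotypes (two independent haplotype walks
#' each) and returns them as a [genotype_table()].  Fully reproducible from
#' `seed`.
#'
#' @inheritParams sample_path
#' @param n number of individuals (>= 1).
#' @param seed optional integer seed applied via [set.seed()].
#' @return A [genotype_table()] with `n` rows.
#' @export
simulate_genotypes <- function(g, A, n, seed = NULL, step_guard = 10000) {
  stopifnot(inherits(g, "cnav_graph"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  enc <- graph_encoding(g)
  m <- cpp_sample_genotypes(enc$ptr, enc$out_idx, enc$edge_to, as.numeric(A),
                            enc$emit, enc$start, enc$fin, enc$K,
                            as.integer(n), as.integer(step_guard))
  colnames(m) <- g$alphabet
  genotype_table(m)
}

#' Exact and empirical genotype distributions
#'
#' `exact_genotype_distribution()` enumerates all haplotype paths within
#' the per-symbol cap, renormalizes their probabilities over the capped set
#' (the renormalization factor — the probability mass captured by the cap —
#' is reported), and convolves the haplotype distribution with itself to
#' obtain the diploid genotype distribution.  `empirical_genotype_distribution()`
#' instead simulates `m` genotypes and reports relative frequencies — the
#' simulation approximation used for the HMM likelihood.
#'
#' @inheritParams enumerate_paths
#' @param A a [transition_matrix()].
#' @return Object of class `cnav_dist`: list with `genotypes` (count
#'   matrix), `prob`, `flag` (`"exact"` or `"empirical"`), `renorm`
#'   (captured haplotype mass, exact only), `m`/`seed` (empirical only) and
#'   `haplotypes`/`hap_prob` (exact only).
#' @export
exact_genotype_distribution <- function(g, A, copy_cap = 5, max_paths = 5e5,
                                        max_expansions = 2e7) {
  paths <- enumerate_paths(g, copy_cap, max_paths, max_expansions)
  if (length(paths$states) == 0) stop("no paths within the cap", call. = FALSE)
  pr <- path_prob(paths, A)
  renorm <- sum(pr)
  pr <- pr / renorm
  key <- apply(paths$emissions, 1, paste, collapse = ",")
  hap_prob <- vapply(split(pr, key), sum, 0)
  hap <- do.call(rbind, lapply(strsplit(names(hap_prob), ","), as.integer))
  H <- nrow(hap)
  # ordered self-convolution: P(genotype) = sum over ordered haplotype pairs
  gp <- new.env(parent = emptyenv())
  for (i in seq_len(H)) {
    for (j in seq_len(H)) {
      k <- paste(hap[i, ] + hap[j, ], collapse = ",")
      gp[[k]] <- (if (is.null(gp[[k]])) 0 else gp[[k]]) + hap_prob[i] * hap_prob[j]
    }
  }
  ks <- sort(ls(gp))
  prob <- vapply(ks, function(k) gp[[k]], 0)
  geno <- do.call(rbind, lapply(strsplit(ks, ","), as.integer))
  colnames(geno) <- g$alphabet
  colnames(hap) <- g$alphabet
  structure(list(genotypes = geno, prob = unname(prob), key = ks,
                 flag = "exact", renorm = renorm,
                 haplotypes = hap, hap_prob = unname(hap_prob)),
            class = "cnav_dist")
}

#' @rdname exact_genotype_distribution
#' @param m number of simulated genotypes (>= 1).
#' @param seed optional integer seed.
#' @param step_guard maximum transitions per walk.
#' @export
empirical_genotype_distribution <- function(g, A, m, seed = NULL,
                                            step_guard = 10000) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  enc <- graph_encoding(g)
  geno <- cpp_sample_genotypes(enc$ptr, enc$out_idx, enc$edge_to, as.numeric(A),
                               enc$emit, enc$start, enc$fin, enc$K,
                               as.integer(m), as.integer(step_guard))
  key <- apply(geno, 1, paste, collapse = ",")
  tab <- table(key)
  ord <- order(names(tab))
  ks <- names(tab)[ord]
  gm <- do.call(rbind, lapply(strsplit(ks, ","), as.integer))
  colnames(gm) <- g$alphabet
  structure(list(genotypes = gm, prob = as.numeric(tab[ord]) / m, key = ks,
                 flag = "empirical", m = m, seed = seed),
            class = "cnav_dist")
}

#' @export
print.cnav_dist <- function(x, n = 10, ...) {
  cat(sprintf("%s genotype distribution over %d genotypes\n",
              x$flag, length(x$prob)))
  ord <- order(x$prob, decreasing = TRUE)
  show <- utils::head(ord, n)
  df <- data.frame(genotype = x$key[show], probability = x$prob[show])
  print(df, row.names = FALSE)
  if (length(ord) > n) cat("...\n")
  invisible(x)
}

# probability lookup: named vector key -> prob
dist_lookup <- function(d) stats::setNames(d$prob, d$key)

#' Export a genotype distribution as TSV
#'
#' One row per genotype: the count columns followed by `probability`.
#'
#' @param d a `cnav_dist`.
#' @param path output file.
#' @export
write_distribution <- function(d, path) {
  df <- data.frame(d$genotypes, probability = d$prob, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
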
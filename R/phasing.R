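#' Translate non-phased genotypes into phased genotypes
#'
#' A graph may carry an alternative emission set in which homologous states
#' that emit the same raw counting event emit distinct, locus-resolved
#' ("phased") symbols.  Given a point transition matrix — typically the
#' posterior mean from a fit on the non-phased emissions — a large set of
#' path pairs is simulated; pairs are grouped by their non-phased genotype,
#' and within each observed genotype's group the alternative emissions are
#' re-tallied to give the conditional distribution of phased genotypes.
#'
#' Every sampled pair's phased genotype marginalizes back to its non-phased
#' genotype by construction (each alternative symbol maps to one primary
#' symbol); this is asserted for all matching pairs.
#'
#' @param g a valid [cnav_graph()] with alternative emissions.
#' @param A a [transition_matrix()], e.g. `coef(fit)`.
#' @param t a [genotype_table()] of observed non-phased genotypes.
#' @param m number of simulated path pairs (default `1e6`).
#' @param seed optional seed.
#' @param min_hits observed genotypes matched by fewer than this many
#'   simulated pairs are reported as unmatched rather than given noisy
#'   probabilities (default 100).
#' @param step_guard maximum transitions per walk.
#' @return Object of class `cnav_translation`: data frame `table` with
#'   columns `original`, `translation`, `probability`, `hits`; character
#'   vector `unmatched`; `m`; `seed`.
#' @export
translate_genotypes <- function(g, A, t, m = 1e6, seed = NULL,
                                min_hits = 100, step_guard = 10000) {
  stopifnot(inherits(g, "cnav_graph"), inherits(t, "cnav_genotypes"))
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (length(g$alt_alphabet) == 0) {
    stop("graph has no alternative emission set", call. = FALSE)
  }
  check_alt_config(g, t)
  map <- alt_incidence(g)
  if (!is.null(seed)) set.seed(seed)
  enc <- graph_encoding(g)
  sim <- cpp_walk_pairs_alt(enc$ptr, enc$out_idx, enc$edge_to, as.numeric(A),
                            enc$emit, enc$alt, enc$start, enc$fin,
                            enc$K, enc$Kalt, as.integer(m),
                            as.integer(step_guard))
  ms <- aggregate_genotypes(t)
  obs_key <- apply(ms$genotypes, 1, paste, collapse = ",")
  prim_key <- apply(sim$primary, 1, paste, collapse = ",")
  rows <- list()
  unmatched <- character(0)
  for (jj in seq_along(obs_key)) {
    hit <- which(prim_key == obs_key[jj])
    if (length(hit) < min_hits) {
      unmatched <- c(unmatched, obs_key[jj])
      next
    }
    back <- sim$phased[hit, , drop = FALSE] %*% map
    if (any(back != sim$primary[hit, , drop = FALSE])) {
      stop("internal error: phased emissions do not marginalize to the original genotype",
           call. = FALSE)
    }
    alt_key <- apply(sim$phased[hit, , drop = FALSE], 1, paste, collapse = ",")
    tab <- sort(table(alt_key), decreasing = TRUE)
    rows[[jj]] <- data.frame(original = obs_key[jj],
                             translation = names(tab),
                             probability = as.numeric(tab) / length(hit),
                             hits = as.integer(tab),
                             stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), unmatched = unmatched,
                 m = m, seed = seed, alphabet = g$alphabet,
                 alt_alphabet = g$alt_alphabet),
            class = "cnav_translation")
}

# every emit state that can contribute to an observed genotype must carry
# an alternative symbol
check_alt_config <- function(g, t) {
  no_alt <- g$states$id[g$states$kind == "emit" & is.na(g$states$alt_emit)]
  if (!length(no_alt)) return(invisible())
  ms <- aggregate_genotypes(t)
  for (i in seq_len(nrow(ms$genotypes))) {
    cp <- compatible_pairs(g, ms$genotypes[i, ],
                           copy_cap = max(ms$genotypes[i, ], 1))
    used <- unique(unlist(cp$paths$states[unique(c(cp$first, cp$second))]))
    bad <- intersect(no_alt, used)
    if (length(bad)) {
      stop("emit state(s) without alternative symbol contribute to observed genotypes: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible()
}

# alt symbol -> primary symbol incidence (Kalt x K); errors if an alt
# symbol is attached to states with different primary symbols
alt_incidence <- function(g) {
  s <- g$states[g$states$kind == "emit" & !is.na(g$states$alt_emit), ]
  M <- matrix(0L, length(g$alt_alphabet), length(g$alphabet),
              dimnames = list(g$alt_alphabet, g$alphabet))
  for (i in seq_len(nrow(s))) {
    ka <- match(s$alt_emit[i], g$alt_alphabet)
    k <- match(s$emit[i], g$alphabet)
    if (sum(M[ka, ]) && M[ka, k] == 0) {
      stop("alternative symbol '", s$alt_emit[i],
           "' is attached to states with different primary symbols",
           call. = FALSE)
    }
    M[ka, k] <- 1L
  }
  M
}

#' @export
print.cnav_translation <- function(x, ...) {
  cat(sprintf("Phase translation from %d simulated path pairs\n", x$m))
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  if (length(x$unmatched)) {
    cat("unmatched genotypes (raise m):",
        paste(x$unmatched, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Export a translation table as TSV
#'
#' One row per (original genotype, phased genotype) with its conditional
#' probability.
#'
#' @param x a [translate_genotypes()] result.
#' @param path output file.
#' @export
write_translation <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
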
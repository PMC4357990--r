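#' Enumerate all bounded haplotype paths
#'
#' Exhaustively lists every start-to-end path of the graph whose per-symbol
#' emission counts stay within `copy_cap`.  Because every directed cycle
#' contains an emitting state, the cap makes the path set finite.  Paths are
#' returned in deterministic lexicographic order of their state-id
#' sequences.  This is the brute-force oracle behind the exact genotype
#' distribution, the latent-path initializer and the symmetric tree-search
#' kernel.
#'
#' @param g a valid [cnav_graph()].
#' @param copy_cap maximum emissions per symbol per haplotype; either a
#'   scalar (default 5, the working range of MLPA copy calling) or a vector
#'   over the alphabet.
#' @param max_paths enumeration limit; exceeding it raises an overflow
#'   error (or truncates when `on_budget = "truncate"`).
#' @param max_expansions bound on tree-search node expansions.
#' @param on_budget `"error"` (default) or `"truncate"`: what to do when a
#'   limit is hit.
#' @return Object of class `cnav_paths`: list with `states` (list of
#'   state-id vectors), `emissions` (paths x alphabet count matrix),
#'   `alt_emissions` (paths x alt alphabet), `edge_counts` (paths x edges),
#'   and `truncated` flag.
#' @examples
#' g <- cnav_model("hwe_biallelic", alleles = c("H", "R"))
#' enumerate_paths(g, copy_cap = 1)$emissions
#' @export
enumerate_paths <- function(g, copy_cap = 5, max_paths = 1e5,
                            max_expansions = 1e6,
                            on_budget = c("error", "truncate")) {
  on_budget <- match.arg(on_budget)
  stopifnot(inherits(g, "cnav_graph"))
  K <- length(g$alphabet)
  cap <- rep_len(as.numeric(copy_cap), max(K, 1L))
  enc <- graph_encoding(g)
  # re-sort within-state adjacency by target id for lexicographic output
  ids <- g$states$id
  for (s in seq_len(length(enc$ptr) - 1L)) {
    rng <- if (enc$ptr[s] < enc$ptr[s + 1]) (enc$ptr[s] + 1L):enc$ptr[s + 1] else integer(0)
    if (length(rng) > 1L) {
      tgt <- ids[enc$edge_to[enc$out_idx[rng] + 1L] + 1L]
      enc$out_idx[rng] <- enc$out_idx[rng][order(tgt)]
    }
  }
  res <- cpp_enumerate_paths(enc$ptr, enc$out_idx, enc$edge_to, enc$emit,
                             enc$alt, enc$start, enc$fin, enc$K,
                             enc$Kalt, enc$E,
                             as.integer(pmin(cap, .Machine$integer.max)),
                             as.integer(min(max_paths, .Machine$integer.max)),
                             as.double(max_expansions))
  if (res$truncated && on_budget == "error") {
    stop("path enumeration overflow (more than ", max_paths, " paths or ",
         max_expansions, " node expansions); lower copy_cap or raise the limit",
         call. = FALSE)
  }
  em <- res$emissions; colnames(em) <- g$alphabet
  al <- res$alt_emissions; colnames(al) <- g$alt_alphabet
  ec <- res$edge_counts; colnames(ec) <- edge_labels(g)
  structure(list(states = lapply(res$states, function(ix) ids[ix + 1L]),
                 emissions = em, alt_emissions = al, edge_counts = ec,
                 truncated = res$truncated, copy_cap = cap),
            class = "cnav_paths")
}

#' @export
print.cnav_paths <- function(x, ...) {
  cat(sprintf("%d enumerated haplotype paths%s\n", length(x$states),
              if (x$truncated) " (truncated at the search budget)" else ""))
  invisible(x)
}

#' Path probabilities under a transition matrix
#'
#' The probability of a path is the product of its edge probabilities;
#' computed from the path's edge-visit counts.
#'
#' @param paths a [enumerate_paths()] result.
#' @param A a [transition_matrix()].
#' @return Numeric vector of probabilities, one per path.
#' @export
path_prob <- function(paths, A) {
  la <- log(as.numeric(A))
  la[!is.finite(la)] <- -1e308   # zero-probability edge; 0^0 = 1 convention
  exp(as.numeric(paths$edge_counts %*% la))
}

# edge -> emission symbol incidence (E x K): 1 iff the edge's target emits k.
# Emission tallies are then edge_counts %*% incidence, which is how latent
# pair invariants are checked without storing state sequences.
emission_incidence <- function(g) {
  K <- length(g$alphabet)
  M <- matrix(0L, nrow(g$edges), K, dimnames = list(edge_labels(g), g$alphabet))
  tgt <- match(g$edges$to, g$states$id)
  sym <- match(g$states$emit[tgt], g$alphabet)
  ok <- !is.na(sym)
  M[cbind(which(ok), sym[ok])] <- 1L
  M
}

#' Highest-probability haplotype path
#'
#' Best-first search over partial paths, expanding in order of decreasing
#' path probability (admissible: extending a path never increases its
#' probability), within the per-symbol emission cap.  Ties are broken
#' lexicographically by state-id sequence.  The first complete path popped
#' is the global argmax; a test obligation is agreement with the
#' brute-force [enumerate_paths()] argmax.
#'
#' @inheritParams enumerate_paths
#' @param A a [transition_matrix()].
#' @return A list with `states`, `emissions`, `log_prob` and the emitted
#'   symbol order `emitted` (sequence of counting events along the path).
#' @export
best_path <- function(g, A, copy_cap = 5, max_expansions = 1e6) {
  stopifnot(inherits(g, "cnav_graph"))
  K <- length(g$alphabet)
  cap <- rep_len(as.numeric(copy_cap), max(K, 1L))
  s <- g$states
  start_id <- s$id[s$kind == "start"]
  end_id <- s$id[s$kind == "end"]
  E <- nrow(g$edges)
  out <- split(seq_len(E), factor(g$edges$from, levels = s$id))
  emit_of <- stats::setNames(match(s$emit, g$alphabet), s$id)
  la <- log(as.numeric(A))
  to_of <- g$edges$to

  frontier <- list(list(path = start_id, em = integer(K), lp = 0,
                        emitted = character(0)))
  lps <- 0
  expansions <- 0L
  while (length(frontier)) {
    best <- which(lps == max(lps))
    if (length(best) > 1L) {   # lexicographic tie-break on state sequence
      keys <- vapply(frontier[best], function(x) paste(x$path, collapse = "\r"),
                     "")
      best <- best[order(keys)[1L]]
    }
    node <- frontier[[best]]
    frontier <- frontier[-best]
    lps <- lps[-best]
    st <- node$path[length(node$path)]
    if (st == end_id) {
      return(list(states = node$path,
                  emissions = stats::setNames(node$em, g$alphabet),
                  log_prob = node$lp, emitted = node$emitted))
    }
    for (e in out[[st]]) {
      expansions <- expansions + 1L
      if (expansions > max_expansions) {
        stop("best-first search exceeded ", max_expansions,
             " expansions; lower copy_cap", call. = FALSE)
      }
      if (!is.finite(la[e])) next
      nxt <- to_of[e]
      em2 <- node$em
      emitted2 <- node$emitted
      k <- emit_of[[nxt]]
      if (!is.na(k)) {
        if (em2[k] + 1 > cap[k]) next
        em2[k] <- em2[k] + 1L
        emitted2 <- c(emitted2, g$alphabet[k])
      }
      frontier[[length(frontier) + 1L]] <-
        list(path = c(node$path, nxt), em = em2, lp = node$lp + la[e],
             emitted = emitted2)
      lps <- c(lps, node$lp + la[e])
    }
  }
  stop("no start-to-end path within the cap", call. = FALSE)
}

#' Compatible path pairs for a genotype
#'
#' Deterministic bounded tree search for the set of ordered haplotype-path
#' pairs whose summed emissions equal the genotype.  The search depends only
#' on the genotype (never on any current latent state), which is what makes
#' the tree-search proposal kernel symmetric.
#'
#' @param g a valid [cnav_graph()].
#' @param genotype non-negative integer vector over the graph alphabet.
#' @param copy_cap per-haplotype cap, as in [enumerate_paths()]; the
#'   effective per-symbol cap is `pmin(genotype, copy_cap)`.
#' @param budget maximum tree-search node expansions.
#' @return List with `first`, `second` (path indices into `paths`),
#'   `counts` (pairs x edges combined transition counts), `log_weight`
#'   (placeholder, filled at evaluation), `paths` (the underlying
#'   [enumerate_paths()] object) and `truncated`.
#' @export
compatible_pairs <- function(g, genotype, copy_cap = 5, budget = 1e5) {
  K <- length(g$alphabet)
  genotype <- as.integer(round(genotype))
  stopifnot(length(genotype) == K, all(genotype >= 0))
  cap <- pmin(genotype, rep_len(as.numeric(copy_cap), K))
  paths <- enumerate_paths(g, copy_cap = cap, max_paths = budget,
                           max_expansions = budget, on_budget = "truncate")
  P <- length(paths$states)
  if (P == 0) {
    return(list(first = integer(0), second = integer(0),
                counts = matrix(0L, 0, nrow(g$edges)),
                paths = paths, truncated = paths$truncated))
  }
  key <- apply(paths$emissions, 1, paste, collapse = ",")
  lookup <- split(seq_len(P), key)
  comp_key <- apply(sweep(-paths$emissions, 2, genotype, "+"), 1,
                    function(v) if (any(v < 0)) NA_character_ else paste(v, collapse = ","))
  js_list <- lookup[comp_key]
  lens <- vapply(js_list, length, 1L)
  first <- rep.int(seq_len(P), lens)
  second <- unlist(js_list, use.names = FALSE)
  if (is.null(second)) second <- integer(0)
  counts <- paths$edge_counts[first, , drop = FALSE] +
    paths$edge_counts[second, , drop = FALSE]
  list(first = first, second = second, counts = counts,
       paths = paths, truncated = paths$truncated)
}
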
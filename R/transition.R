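#' Transition matrices on a CNAV graph
#'
#' A transition matrix assigns a probability to every edge of the graph such
#' that the outgoing probabilities of each non-end state sum to 1.  It is
#' represented as a numeric vector aligned to the graph's edge order, with
#' names `"from->to"`.
#'
#' `probs` may be `NULL` (every row uniform), a full unnamed vector of
#' length `nrow(g$edges)` in edge order, or a named vector setting selected
#' edges by their `"from->to"` label; in the latter case the unspecified
#' edges of a partially specified row share the remaining mass equally, and
#' untouched rows stay uniform.
#'
#' @param g a [cnav_graph()].
#' @param probs edge probabilities, see Details.
#' @param tol tolerance on row sums (default `1e-12`).
#' @return Named numeric vector of class `cnav_tmat`.
#' @examples
#' g <- cnav_model("hwe_biallelic", alleles = c("H", "R"))
#' A <- transition_matrix(g, c("allele_choice->emit_H" = 0.7))
#' @export
transition_matrix <- function(g, probs = NULL, tol = 1e-12) {
  stopifnot(inherits(g, "cnav_graph"))
  labs <- edge_labels(g)
  rows <- edge_rows(g)
  E <- nrow(g$edges)
  if (is.null(probs)) {
    p <- numeric(E)
    for (r in rows) p[r] <- 1 / length(r)
  } else if (is.null(names(probs))) {
    if (length(probs) != E) {
      stop("unnamed probability vector must have one entry per edge (",
           E, ")", call. = FALSE)
    }
    p <- as.numeric(probs)
  } else {
    unknown <- setdiff(names(probs), labs)
    if (length(unknown)) {
      stop("unknown edge(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    p <- rep(NA_real_, E)
    p[match(names(probs), labs)] <- as.numeric(probs)
    for (r in rows) {
      set <- !is.na(p[r])
      if (!any(set)) {
        p[r] <- 1 / length(r)
      } else if (all(set)) {
        # fully specified row: validated below
      } else {
        used <- sum(p[r][set])
        if (used > 1 + 1e-9) {
          stop("specified probabilities in row '", g$edges$from[r[1]],
               "' exceed 1", call. = FALSE)
        }
        p[r][!set] <- (1 - used) / sum(!set)
      }
    }
  }
  if (any(p < -tol) || any(p > 1 + 1e-9)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  p <- pmin(pmax(p, 0), 1)
  for (r in rows) {
    if (abs(sum(p[r]) - 1) > max(tol, 1e-9)) {
      stop("outgoing probabilities of state '", g$edges$from[r[1]],
           "' sum to ", format(sum(p[r])), ", not 1", call. = FALSE)
    }
  }
  structure(stats::setNames(p, labs), class = "cnav_tmat")
}

#' @export
print.cnav_tmat <- function(x, digits = 4, ...) {
  cat("Transition probabilities (", length(x), " edges):\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Dirichlet prior on transition rows
#'
#' The conjugate prior for a transition matrix is an independent Dirichlet
#' distribution per state row ("MatrixDirichlet").  The default `alpha = 1`
#' is uniform on each row simplex; `alpha = 0.5` gives the Jeffreys prior.
#'
#' @param g a [cnav_graph()].
#' @param alpha scalar or per-edge concentration parameters (all > 0).
#' @return Named numeric vector of concentrations aligned to edges, class
#'   `cnav_prior`.
#' @export
cnav_prior <- function(g, alpha = 1) {
  stopifnot(inherits(g, "cnav_graph"))
  E <- nrow(g$edges)
  a <- rep_len(as.numeric(alpha), E)
  if (any(a <= 0)) stop("all concentrations must be > 0", call. = FALSE)
  structure(stats::setNames(a, edge_labels(g)), class = "cnav_prior")
}

#' Draw a transition matrix from its full conditional
#'
#' Given path-pair transition counts on the graph edges, draws each row of
#' the transition matrix from `Dirichlet(prior_row + counts_row)` — the
#' conjugate MatrixDirichlet update.  Rows with a single outgoing edge get
#' probability exactly 1.
#'
#' @param g a [cnav_graph()].
#' @param prior a [cnav_prior()] (default uniform).
#' @param counts non-negative integer edge counts; either a full vector in
#'   edge order or a named vector over `"from->to"` labels (missing edges
#'   count 0).  Counts on non-edges are an error.
#' @return A [transition_matrix()] draw.  Uses R's global RNG; seed with
#'   [set.seed()].
#' @export
sample_transition_matrix <- function(g, prior = cnav_prior(g), counts = NULL) {
  labs <- edge_labels(g)
  E <- nrow(g$edges)
  if (is.null(counts)) {
    n <- numeric(E)
  } else if (is.null(names(counts))) {
    if (length(counts) != E) stop("counts must have one entry per edge", call. = FALSE)
    n <- as.numeric(counts)
  } else {
    unknown <- setdiff(names(counts), labs)
    if (length(unknown)) {
      stop("count on non-edge(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    n <- numeric(E)
    n[match(names(counts), labs)] <- as.numeric(counts)
  }
  if (any(n < 0)) stop("counts must be non-negative", call. = FALSE)
  a <- as.numeric(prior) + n
  p <- numeric(E)
  for (r in edge_rows(g)) {
    if (length(r) == 1L) {
      p[r] <- 1
    } else {
      x <- stats::rgamma(length(r), shape = a[r], rate = 1)
      while (sum(x) == 0) x <- stats::rgamma(length(r), shape = a[r], rate = 1)
      p[r] <- x / sum(x)
    }
  }
  structure(stats::setNames(p, labs), class = "cnav_tmat")
}

#' Project a transition matrix into the simplex interior
#'
#' Density ordinates (prior and posterior) are undefined on the boundary of
#' a row simplex.  This replaces any probability below `eps` on a multi-edge
#' row by `eps` and renormalizes the row.
#'
#' @param g a [cnav_graph()].
#' @param A a [transition_matrix()].
#' @param eps interior margin (default `1e-6`).
#' @return A `cnav_tmat` strictly inside every row simplex.
#' @export
interior_project <- function(g, A, eps = 1e-6) {
  p <- as.numeric(A)
  for (r in edge_rows(g)) {
    if (length(r) > 1L) {
      x <- pmax(p[r], eps)
      p[r] <- x / sum(x)
    } else {
      p[r] <- 1
    }
  }
  structure(stats::setNames(p, edge_labels(g)), class = "cnav_tmat")
}

# log MatrixDirichlet density of A under per-edge concentrations a,
# summed over multi-edge rows (single-edge rows are degenerate, density 1)
ldirichlet_matrix <- function(g, A, a) {
  p <- as.numeric(A)
  a <- as.numeric(a)
  total <- 0
  for (r in edge_rows(g)) {
    if (length(r) > 1L) {
      if (any(p[r] <= 0) || any(p[r] >= 1)) {
        stop("ordinate undefined: probability on the simplex boundary in row '",
             g$edges$from[r[1]],
             "'; use interior_project() first", call. = FALSE)
      }
      total <- total + lgamma(sum(a[r])) - sum(lgamma(a[r])) +
        sum((a[r] - 1) * log(p[r]))
    }
  }
  total
}

# free coordinates of A: probabilities of all edges in multi-edge rows
free_coordinates <- function(g, A) {
  keep <- unlist(lapply(edge_rows(g), function(r) if (length(r) > 1L) r else NULL))
  keep <- sort(keep)
  as.numeric(A)[keep]
}

free_coordinate_index <- function(g) {
  keep <- unlist(lapply(edge_rows(g), function(r) if (length(r) > 1L) r else NULL))
  sort(keep)
}
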
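#' Directed HMM graphs for copy-number and allelic variation
#'
#' A `cnav_graph` is the fixed skeleton of a CNAV model: a directed graph
#' with exactly one start state, one absorbing end state, and in between
#' silent states (emitting nothing) and emitting states, each of which
#' increments one counting-event symbol per visit.  A haplotype is one
#' random start-to-end walk; a diploid genotype is the element-wise sum of
#' the emission tallies of two independent walks.  Recursion loops through
#' emitting states model gene duplication; bypass edges model deletion.
#'
#' @param states data frame (or list coercible to one) with columns
#'   `id` (unique state labels), `kind` (one of `"start"`, `"silent"`,
#'   `"emit"`, `"end"`), `emit` (counting-event symbol, required exactly for
#'   emit states, `NA` otherwise) and optionally `alt_emit` (alternative
#'   "phased" symbol, only on emit states).
#' @param edges data frame with columns `from`, `to` holding state ids.
#'   Edge order is meaningful: transition matrices, Dirichlet priors and
#'   flattened parameter vectors all follow it.
#' @param validate if `TRUE` (default), invariant violations raise an error.
#'
#' @return An object of class `cnav_graph` with elements `states`, `edges`,
#'   `alphabet` (ordered distinct emission symbols) and `alt_alphabet`.
#' @seealso [cnav_model()] for canonical builders, [validate_cnav_graph()],
#'   [enumerate_paths()], [transition_matrix()].
#' @export
cnav_graph <- function(states, edges, validate = TRUE) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0) ||
      (is.list(edges) && length(edges) == 0)) {
    edges <- data.frame(from = character(0), to = character(0))
  }
  states <- as.data.frame(states, stringsAsFactors = FALSE)
  if (!"alt_emit" %in% names(states)) states$alt_emit <- NA_character_
  states$emit <- as.character(states$emit)
  states$alt_emit <- as.character(states$alt_emit)
  states <- states[, c("id", "kind", "emit", "alt_emit")]
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)[, c("from", "to")]
  rownames(states) <- NULL
  rownames(edges) <- NULL
  alphabet <- unique(states$emit[states$kind == "emit" & !is.na(states$emit)])
  alt_alphabet <- unique(states$alt_emit[!is.na(states$alt_emit)])
  g <- structure(
    list(states = states, edges = edges,
         alphabet = alphabet, alt_alphabet = alt_alphabet),
    class = "cnav_graph")
  if (validate) {
    bad <- validate_cnav_graph(g)
    if (length(bad)) {
      stop("invalid CNAV graph:\n  - ", paste(bad, collapse = "\n  - "),
           call. = FALSE)
    }
  }
  g
}

#' Validate a CNAV graph
#'
#' Checks every structural invariant a graph must satisfy before any other
#' operation may use it, and reports *all* violations rather than the first:
#' unique ids, legal state kinds, emission symbols exactly on emit states,
#' one start (no incoming edges) and one absorbing end, duplicate-free edges
#' over known states, reachability of every state on some start-to-end path,
#' and the absence of silent-only directed cycles (every cycle must emit, so
#' walks terminate almost surely).
#'
#' @param g a [cnav_graph()] (built with `validate = FALSE` if you expect
#'   violations).
#' @return Character vector of violation messages; `character(0)` means the
#'   graph is usable by every other function in the package.
#' @export
validate_cnav_graph <- function(g) {
  s <- g$states; e <- g$edges
  bad <- character(0)
  if (anyDuplicated(s$id)) {
    bad <- c(bad, paste0("duplicate state id(s): ",
                         paste(unique(s$id[duplicated(s$id)]), collapse = ", ")))
  }
  unknown_kind <- setdiff(unique(s$kind), c("start", "silent", "emit", "end"))
  if (length(unknown_kind)) {
    bad <- c(bad, paste0("unknown state kind(s): ",
                         paste(unknown_kind, collapse = ", ")))
  }
  no_sym <- s$id[s$kind == "emit" & is.na(s$emit)]
  if (length(no_sym)) {
    bad <- c(bad, paste0("emit state(s) without emission symbol: ",
                         paste(no_sym, collapse = ", ")))
  }
  stray_sym <- s$id[s$kind != "emit" & !is.na(s$emit)]
  if (length(stray_sym)) {
    bad <- c(bad, paste0("non-emit state(s) carrying an emission symbol: ",
                         paste(stray_sym, collapse = ", ")))
  }
  stray_alt <- s$id[s$kind != "emit" & !is.na(s$alt_emit)]
  if (length(stray_alt)) {
    bad <- c(bad, paste0("alt_emit on non-emit state(s): ",
                         paste(stray_alt, collapse = ", ")))
  }
  bad_ep <- c(setdiff(e$from, s$id), setdiff(e$to, s$id))
  if (length(bad_ep)) {
    bad <- c(bad, paste0("edge endpoint(s) not among states: ",
                         paste(unique(bad_ep), collapse = ", ")))
  }
  dup_e <- duplicated(paste(e$from, e$to, sep = "\r"))
  if (any(dup_e)) {
    bad <- c(bad, paste0("duplicate edge(s): ",
                         paste(unique(paste0(e$from[dup_e], " -> ", e$to[dup_e])),
                               collapse = ", ")))
  }
  n_start <- sum(s$kind == "start")
  n_end <- sum(s$kind == "end")
  if (n_start != 1) bad <- c(bad, sprintf("exactly one start state required (found %d)", n_start))
  if (n_end != 1) bad <- c(bad, sprintf("exactly one end state required (found %d)", n_end))
  if (length(bad_ep) || anyDuplicated(s$id)) return(bad)

  start_in <- intersect(s$id[s$kind == "start"], e$to)
  if (length(start_in)) {
    bad <- c(bad, paste0("start state must have no incoming edges: ",
                         paste(start_in, collapse = ", ")))
  }
  end_out <- intersect(s$id[s$kind == "end"], e$from)
  if (length(end_out)) {
    bad <- c(bad, paste0("end state must be absorbing (no outgoing edges): ",
                         paste(end_out, collapse = ", ")))
  }
  if (n_start == 1 && n_end == 1 && nrow(e) > 0) {
    ig <- igraph::graph_from_data_frame(e, directed = TRUE, vertices = s$id)
    start_id <- s$id[s$kind == "start"]
    end_id <- s$id[s$kind == "end"]
    fwd <- names(igraph::subcomponent(ig, start_id, mode = "out"))
    bwd <- names(igraph::subcomponent(ig, end_id, mode = "in"))
    off_path <- setdiff(s$id, intersect(fwd, bwd))
    if (length(off_path)) {
      bad <- c(bad, paste0("state(s) not on any start-to-end path: ",
                           paste(off_path, collapse = ", ")))
    }
    # a directed cycle with no emitting state would allow an infinite
    # silent walk; the induced subgraph on non-emitting states must be a DAG
    silent_ids <- s$id[s$kind != "emit"]
    sub <- igraph::induced_subgraph(ig, silent_ids)
    if (!igraph::is_dag(sub)) {
      bad <- c(bad, "silent-only directed cycle found (every cycle must contain an emitting state)")
    }
  } else if (n_start == 1 && nrow(e) == 0 && nrow(s) > 1) {
    bad <- c(bad, "graph has no edges but more than one state")
  }
  bad
}

#' Number of free transition-probability parameters
#'
#' Each non-end state with `d` outgoing edges contributes `max(d - 1, 0)`
#' free parameters (its transition row lives on a `d-1` simplex).  The count
#' is invariant under state relabelling and is the dimension of the
#' flattened parameter vectors used for posterior clustering.
#'
#' @param g a valid [cnav_graph()].
#' @return Non-negative integer.
#' @export
free_parameters <- function(g) {
  stopifnot(inherits(g, "cnav_graph"))
  bad <- validate_cnav_graph(g)
  if (length(bad)) stop("invalid graph: ", paste(bad, collapse = "; "), call. = FALSE)
  out_deg <- table(factor(g$edges$from, levels = g$states$id))
  sum(pmax(as.integer(out_deg) - 1L, 0L))
}

#' @export
print.cnav_graph <- function(x, ...) {
  cat(sprintf("CNAV model graph: %d states (%d emitting), %d edges, %d free parameters\n",
              nrow(x$states), sum(x$states$kind == "emit"), nrow(x$edges),
              tryCatch(free_parameters(x), error = function(e) NA_integer_)))
  cat("  alphabet:    ", paste(x$alphabet, collapse = ", "), "\n")
  if (length(x$alt_alphabet)) {
    cat("  alt alphabet:", paste(x$alt_alphabet, collapse = ", "), "\n")
  }
  invisible(x)
}

# --- serialization -----------------------------------------------------------

#' Read and write CNAV graphs
#'
#' Graphs serialize to a small JSON dialect with top-level keys `states`
#' (objects with `id`, `kind`, and for emitting states `emit` and optionally
#' `alt_emit`) and `edges` (objects with `from`, `to`).  Unknown keys are
#' rejected.  `write_cnav_graph()` followed by `read_cnav_graph()` restores
#' the graph exactly, including edge order.
#'
#' @param path file path (or connection for reading).
#' @param g a [cnav_graph()].
#' @return `read_cnav_graph()` returns a validated `cnav_graph`;
#'   `write_cnav_graph()` returns `path` invisibly.
#' @export
read_cnav_graph <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("graph document syntax error: ",
                                           conditionMessage(e), call. = FALSE))
  extra <- setdiff(names(doc), c("states", "edges"))
  if (length(extra)) {
    stop("unknown top-level key(s) in graph document: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (is.null(doc$states) || is.null(doc$edges)) {
    stop("graph document must have 'states' and 'edges' keys", call. = FALSE)
  }
  st <- lapply(doc$states, function(x) {
    extra <- setdiff(names(x), c("id", "kind", "emit", "alt_emit"))
    if (length(extra)) {
      stop("unknown state key(s): ", paste(extra, collapse = ", "), call. = FALSE)
    }
    data.frame(id = as.character(x$id), kind = as.character(x$kind),
               emit = if (is.null(x$emit)) NA_character_ else as.character(x$emit),
               alt_emit = if (is.null(x$alt_emit)) NA_character_ else as.character(x$alt_emit),
               stringsAsFactors = FALSE)
  })
  ed <- lapply(doc$edges, function(x) {
    extra <- setdiff(names(x), c("from", "to"))
    if (length(extra)) {
      stop("unknown edge key(s): ", paste(extra, collapse = ", "), call. = FALSE)
    }
    data.frame(from = as.character(x$from), to = as.character(x$to),
               stringsAsFactors = FALSE)
  })
  cnav_graph(do.call(rbind, st),
             if (length(ed)) do.call(rbind, ed) else NULL)
}

#' @rdname read_cnav_graph
#' @export
write_cnav_graph <- function(g, path) {
  stopifnot(inherits(g, "cnav_graph"))
  states <- lapply(seq_len(nrow(g$states)), function(i) {
    x <- list(id = g$states$id[i], kind = g$states$kind[i])
    if (!is.na(g$states$emit[i])) x$emit <- g$states$emit[i]
    if (!is.na(g$states$alt_emit[i])) x$alt_emit <- g$states$alt_emit[i]
    x
  })
  edges <- lapply(seq_len(nrow(g$edges)), function(i) {
    list(from = g$edges$from[i], to = g$edges$to[i])
  })
  jsonlite::write_json(list(states = states, edges = edges), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# --- internal helpers --------------------------------------------------------

# edge labels "from->to", the canonical parameter names
edge_labels <- function(g) paste0(g$edges$from, "->", g$edges$to)

# indices of edges grouped by origin state, in graph edge order;
# names are state ids of all non-end states with outgoing edges
edge_rows <- function(g) {
  from <- factor(g$edges$from, levels = g$states$id[g$states$kind != "end"])
  rows <- split(seq_len(nrow(g$edges)), from)
  rows[vapply(rows, length, 1L) > 0L]
}

# 0-based CSR encoding consumed by the C++ walkers
graph_encoding <- function(g) {
  s <- g$states
  n <- nrow(s)
  idx <- stats::setNames(seq_len(n) - 1L, s$id)
  efrom <- idx[g$edges$from]
  eto <- idx[g$edges$to]
  ord <- order(efrom, seq_along(efrom))   # stable: edge order within state
  out_idx <- (seq_len(nrow(g$edges)) - 1L)[ord]
  cnt <- tabulate(efrom + 1L, nbins = n)
  ptr <- c(0L, cumsum(cnt))
  emit <- ifelse(s$kind == "emit", match(s$emit, g$alphabet) - 1L, -1L)
  emit[is.na(emit)] <- -1L
  alt <- match(s$alt_emit, g$alt_alphabet) - 1L
  alt[is.na(alt)] <- -1L
  list(ptr = as.integer(ptr), out_idx = as.integer(out_idx),
       edge_to = as.integer(unname(eto)),
       emit = as.integer(emit), alt = as.integer(alt),
       start = unname(idx[s$id[s$kind == "start"]]),
       fin = unname(idx[s$id[s$kind == "end"]]),
       K = length(g$alphabet), Kalt = length(g$alt_alphabet),
       E = nrow(g$edges))
}
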
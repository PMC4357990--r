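#' Emission alphabet of the FcgR MLPA panel
#'
#' The counting-event symbols measured by the multiplex ligation-dependent
#' probe amplification (MLPA) assay for the low-affinity Fc-gamma-receptor
#' gene region: allele-specific copy numbers for 7 genes (FCGR2A, FCGR2B,
#' FCGR2C, FCGR3A, FCGR3B, HSPA6, HSPA7) distinguishing the allelic
#' variants of 9 polymorphisms.  The two promoter polymorphisms are shared
#' (not separable) between FCGR2B and FCGR2C — the ambiguity the phasing
#' translation resolves.
#'
#' @return Ordered character vector of emission symbols with attributes
#'   `genes` (7 gene labels) and `snps` (9 polymorphism labels).
#' @export
fcgr_alphabet <- function() {
  structure(
    c("2A_H131", "2A_R131",
      "2B_I232", "2B_T232",
      "2C_ORF", "2C_Stop",
      "3A_F158", "3A_V158",
      "3B_Na1", "3B_Na2", "3B_SH",
      "prom_-386C", "prom_-386G", "prom_-120A", "prom_-120T",
      "HSPA6", "HSPA7"),
    genes = c("FCGR2A", "FCGR2B", "FCGR2C", "FCGR3A", "FCGR3B",
              "HSPA6", "HSPA7"),
    snps = c("H131R", "I232T", "ORF/Stop", "F158V",
             "HNA1a", "HNA1b", "HNA1c", "C-386G", "A-120T"))
}

#' Ready-made synthetic scenarios
#'
#' Bundles a model graph, a ground-truth transition matrix and a simulated
#' MLPA-style genotype table into a reproducible test scenario.  Besides
#' the canonical [cnav_model()] builders, two multi-gene series scenarios
#' are available for copy-number-linkage studies:
#' \describe{
#'   \item{`independent_genes`}{three genes in series, each with its own
#'     deletion bypass and duplication loop — copy numbers are mutually
#'     independent, so a fully connected fit has six symmetric optima.}
#'   \item{`linked_block`}{as above, but the second and third gene form a
#'     single block that is deleted or duplicated as one, breaking the
#'     order symmetry toward arrangements keeping them adjacent.}
#' }
#'
#' @param name a [cnav_model()] scenario name or one of the series
#'   scenarios above.
#' @param overrides named edge probabilities (`"from->to"`) fixing the true
#'   transition matrix; unspecified rows/edges as in [transition_matrix()].
#'   Overriding a non-existent edge is an error.
#' @param n individuals to simulate (default 387, the scale of an MLPA
#'   association cohort).
#' @param seed scenario seed; part of the fixture contract — the same call
#'   reproduces the same scenario exactly.
#' @param ... options passed to the graph builder.
#' @return Object of class `cnav_scenario`: `name`, `graph`, `A` (true
#'   transition matrix), `table`, `n`, `seed`, `description`.
#' @examples
#' sc <- make_scenario("hwe_biallelic", alleles = c("H", "R"),
#'                     overrides = c("allele_choice->emit_H" = 0.3),
#'                     n = 387, seed = 1)
#' mean(sc$table$counts[, "H"]) / 2   # close to 0.3
#' @export
make_scenario <- function(name, overrides = NULL, n = 387, seed = 1, ...) {
  g <- switch(name,
              independent_genes = gene_series_graph(blocks = list("3A", "2C", "3B"), ...),
              linked_block = gene_series_graph(blocks = list("3A", c("2C", "3B")), ...),
              cnav_model(name, ...))
  A <- transition_matrix(g, overrides)
  table <- simulate_genotypes(g, A, n = n, seed = seed)
  structure(list(name = name, graph = g, A = A, table = table,
                 n = n, seed = seed,
                 description = sprintf("scenario '%s': %d simulated individuals (seed %d)",
                                       name, n, seed)),
            class = "cnav_scenario")
}

#' @export
print.cnav_scenario <- function(x, ...) {
  cat(x$description, "\n")
  print(x$graph)
  invisible(x)
}

#' Series graph of gene blocks with per-block loss and gain
#'
#' Builds a chain of gene blocks walked left to right: each block has a
#' silent loss branch bypassing it entirely, its genes emitted in order,
#' and a duplication loop re-emitting the whole block.  With singleton
#' blocks the per-gene copy numbers are mutually independent; multi-gene
#' blocks gain and lose as one unit (complete copy-number linkage).
#'
#' State naming per block `i` (genes `g`): `loss_b<i>`, `emit_<g>`,
#' `exit_b<i>`.
#'
#' @param blocks list of character vectors of gene names, in chromosomal
#'   order; the concatenation must be duplicate-free.
#' @param loss,gain default loss and gain probabilities are set by the
#'   caller through [transition_matrix()] overrides; this builder only
#'   fixes the topology.
#' @return A validated [cnav_graph()].
#' @export
gene_series_graph <- function(blocks = list("3A", "2C", "3B")) {
  genes <- unlist(blocks)
  if (anyDuplicated(genes)) stop("duplicate gene names", call. = FALSE)
  states <- state_row("start", "start")
  edges <- NULL
  entries <- paste0("loss_b", seq_along(blocks))
  nxt <- c(entries[-1], "end")
  for (i in seq_along(blocks)) {
    gs <- blocks[[i]]
    em <- paste0("emit_", gs)
    states <- rbind(states,
                    state_row(entries[i], "silent"),
                    do.call(rbind, mapply(state_row, em, "emit", gs,
                                          SIMPLIFY = FALSE)),
                    state_row(paste0("exit_b", i), "silent"))
    edges <- rbind(edges,
                   data.frame(from = entries[i], to = c(nxt[i], em[1])),
                   if (length(em) > 1) data.frame(from = em[-length(em)], to = em[-1]),
                   data.frame(from = em[length(em)],
                              to = paste0("exit_b", i)),
                   data.frame(from = paste0("exit_b", i),
                              to = c(em[1], nxt[i])))
  }
  states <- rbind(states, state_row("end", "end"))
  edges <- rbind(data.frame(from = "start", to = entries[1]), edges)
  cnav_graph(states, edges)
}
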
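#' Canonical CNAV model graphs
#'
#' Builders for the model-graph families used throughout the package, from
#' the plain Hardy-Weinberg bifurcation to fully connected gene blocks.
#' State naming is fixed and documented so that tests and transition-matrix
#' overrides can address states by id.
#'
#' Available scenarios and their state naming:
#' \describe{
#'   \item{`hwe_biallelic`}{Hardy-Weinberg model for a gene without copy
#'     number variation: `start` -> `allele_choice` -> one `emit_<sym>`
#'     state per allele -> `end`.  The single bifurcation probability is the
#'     allele (haplotype) frequency.  Options: `alleles` (>= 2 symbols).}
#'   \item{`cnav_multiallele`}{One gene with k alleles, a deletion bypass
#'     and a duplication loop: `start` -> `loss_branch` (-> `end` directly
#'     on loss) -> `allele_choice` -> `emit_<sym>` -> `copy_exit` -> `end`,
#'     with the gain loop `copy_exit` -> `allele_choice` re-drawing an
#'     allele per extra copy (independence between gene copies).  Options:
#'     `alleles`, `loss` (default `TRUE`), `gain` (default `TRUE`).}
#'   \item{`cnav_loh`}{Biallelic variant whose duplication loop returns to
#'     the *same* allele state (`copy_exit_<sym>` -> `emit_<sym>`), the
#'     loss-of-heterozygosity signature of microhomology-mediated repair.
#'     Options: `alleles` (exactly 2).}
#'   \item{`first_order_dependency`}{k-allele model where every allele
#'     state connects to every allele state (including itself, a repeat
#'     loop), relaxing the independence between consecutive gene copies:
#'     `start` -> `loss_branch` -> `allele_choice` -> `emit_<sym>` states
#'     (fully interconnected) -> `copy_exit` with gain loop back to
#'     `allele_choice`.  13 free parameters for k = 3.}
#'   \item{`tandem_allele`}{Three-allele model with an extra composite
#'     allele branch emitting `tandem[1]` then `tandem[2]` in one copy
#'     (`tandem_first`, `tandem_second` states) and irregular-repeat loops
#'     on both states emitting the first tandem symbol.  7 free parameters
#'     in the default configuration.  Options: `alleles` (3 symbols),
#'     `tandem` (2 symbols drawn from `alleles`).}
#'   \item{`two_locus_phasing`}{Two tandem loci ("B", constant copy number;
#'     "C", with loss and gain) whose promoter states emit the *same*
#'     non-phased symbols (`prom_C`, `prom_G`) but distinct alternative
#'     phased symbols (`B:prom_C`, ..., `C:prom_G`); coding polymorphisms
#'     (`2B_I232`/`2B_T232`, `2C_ORF`/`2C_Stop`) are emitted by downstream
#'     states, with promoter-to-coding edges carrying the linkage.}
#'   \item{`fully_connected_block`}{One emitting state per gene
#'     (`gene_<name>`), all connected in both directions including self
#'     loops, plus `start`/`end` edges and a `start` -> `end` bypass (null
#'     haplotype).  The highest-probability path orders the genes; with m
#'     genes there are m! candidate orders.  Options: `genes`.}
#' }
#'
#' @param name scenario label, see Details.
#' @param ... scenario options (see Details).
#' @return A validated [cnav_graph()].
#' @examples
#' g <- cnav_model("hwe_biallelic", alleles = c("2A_H131", "2A_R131"))
#' free_parameters(g)   # 1: the allele frequency
#' @export
cnav_model <- function(name, ...) {
  opts <- list(...)
  builders <- list(
    hwe_biallelic = build_hwe,
    cnav_multiallele = build_cnav_multiallele,
    cnav_loh = build_cnav_loh,
    first_order_dependency = build_first_order,
    tandem_allele = build_tandem,
    two_locus_phasing = build_two_locus,
    fully_connected_block = build_fully_connected)
  if (!name %in% names(builders)) {
    stop("unknown canonical model '", name, "'; available: ",
         paste(names(builders), collapse = ", "), call. = FALSE)
  }
  do.call(builders[[name]], opts)
}

state_row <- function(id, kind, emit = NA_character_, alt = NA_character_) {
  data.frame(id = id, kind = kind, emit = emit, alt_emit = alt,
             stringsAsFactors = FALSE)
}

build_hwe <- function(alleles = c("A", "B")) {
  alleles <- as.character(alleles)
  if (length(alleles) < 2) stop("hwe_biallelic needs at least 2 alleles", call. = FALSE)
  states <- rbind(
    state_row("start", "start"),
    state_row("allele_choice", "silent"),
    do.call(rbind, lapply(alleles, function(a) state_row(paste0("emit_", a), "emit", a))),
    state_row("end", "end"))
  edges <- rbind(
    data.frame(from = "start", to = "allele_choice"),
    data.frame(from = "allele_choice", to = paste0("emit_", alleles)),
    data.frame(from = paste0("emit_", alleles), to = "end"))
  cnav_graph(states, edges)
}

build_cnav_multiallele <- function(alleles = c("A", "B"), loss = TRUE, gain = TRUE) {
  alleles <- as.character(alleles)
  if (length(alleles) < 2) stop("cnav_multiallele needs at least 2 alleles", call. = FALSE)
  states <- rbind(
    state_row("start", "start"),
    if (loss) state_row("loss_branch", "silent"),
    state_row("allele_choice", "silent"),
    do.call(rbind, lapply(alleles, function(a) state_row(paste0("emit_", a), "emit", a))),
    state_row("copy_exit", "silent"),
    state_row("end", "end"))
  entry <- if (loss) "loss_branch" else "allele_choice"
  edges <- rbind(
    data.frame(from = "start", to = entry),
    if (loss) data.frame(from = "loss_branch", to = c("end", "allele_choice")),
    data.frame(from = "allele_choice", to = paste0("emit_", alleles)),
    data.frame(from = paste0("emit_", alleles), to = "copy_exit"),
    if (gain) data.frame(from = "copy_exit", to = "allele_choice"),
    data.frame(from = "copy_exit", to = "end"))
  cnav_graph(states, edges)
}

build_cnav_loh <- function(alleles = c("A", "B")) {
  alleles <- as.character(alleles)
  if (length(alleles) != 2) stop("cnav_loh is biallelic (exactly 2 alleles)", call. = FALSE)
  states <- rbind(
    state_row("start", "start"),
    state_row("loss_branch", "silent"),
    state_row("allele_choice", "silent"),
    do.call(rbind, lapply(alleles, function(a) rbind(
      state_row(paste0("emit_", a), "emit", a),
      state_row(paste0("copy_exit_", a), "silent")))),
    state_row("end", "end"))
  edges <- rbind(
    data.frame(from = "start", to = "loss_branch"),
    data.frame(from = "loss_branch", to = c("end", "allele_choice")),
    data.frame(from = "allele_choice", to = paste0("emit_", alleles)),
    do.call(rbind, lapply(alleles, function(a) data.frame(
      from = c(paste0("emit_", a), paste0("copy_exit_", a), paste0("copy_exit_", a)),
      to = c(paste0("copy_exit_", a), paste0("emit_", a), "end")))))
  cnav_graph(states, edges)
}

build_first_order <- function(alleles = c("Na1", "Na2", "SH")) {
  alleles <- as.character(alleles)
  if (length(alleles) < 2) stop("first_order_dependency needs at least 2 alleles", call. = FALSE)
  em <- paste0("emit_", alleles)
  states <- rbind(
    state_row("start", "start"),
    state_row("loss_branch", "silent"),
    state_row("allele_choice", "silent"),
    do.call(rbind, lapply(alleles, function(a) state_row(paste0("emit_", a), "emit", a))),
    state_row("copy_exit", "silent"),
    state_row("end", "end"))
  edges <- rbind(
    data.frame(from = "start", to = "loss_branch"),
    data.frame(from = "loss_branch", to = c("end", "allele_choice")),
    data.frame(from = "allele_choice", to = em),
    expand.grid(from = em, to = em, stringsAsFactors = FALSE)[, c("from", "to")],
    data.frame(from = em, to = "copy_exit"),
    data.frame(from = "copy_exit", to = c("allele_choice", "end")))
  cnav_graph(states, edges)
}

build_tandem <- function(alleles = c("Na1", "Na2", "SH"), tandem = c("SH", "Na1")) {
  alleles <- as.character(alleles)
  tandem <- as.character(tandem)
  if (length(alleles) != 3) stop("tandem_allele expects 3 base alleles", call. = FALSE)
  if (length(tandem) != 2 || !all(tandem %in% alleles)) {
    stop("tandem must name 2 of the base alleles", call. = FALSE)
  }
  repeat_sym <- tandem[1]     # the irregularly repeating allele
  states <- rbind(
    state_row("start", "start"),
    state_row("loss_branch", "silent"),
    state_row("allele_choice", "silent"),
    do.call(rbind, lapply(alleles, function(a) state_row(paste0("emit_", a), "emit", a))),
    state_row("tandem_first", "emit", tandem[1]),
    state_row("tandem_second", "emit", tandem[2]),
    state_row("copy_exit", "silent"),
    state_row("end", "end"))
  single_exit <- data.frame(from = paste0("emit_", alleles), to = "copy_exit")
  edges <- rbind(
    data.frame(from = "start", to = "loss_branch"),
    data.frame(from = "loss_branch", to = c("end", "allele_choice")),
    data.frame(from = "allele_choice", to = c(paste0("emit_", alleles), "tandem_first")),
    data.frame(from = paste0("emit_", repeat_sym), to = paste0("emit_", repeat_sym)),
    single_exit,
    data.frame(from = "tandem_first", to = c("tandem_first", "tandem_second")),
    data.frame(from = "tandem_second", to = "copy_exit"),
    data.frame(from = "copy_exit", to = c("allele_choice", "end")))
  cnav_graph(states, edges)
}

build_two_locus <- function() {
  states <- rbind(
    state_row("start", "start"),
    state_row("B_prom_choice", "silent"),
    state_row("B_prom_C", "emit", "prom_C", "B:prom_C"),
    state_row("B_prom_G", "emit", "prom_G", "B:prom_G"),
    state_row("B_orf_choice", "silent"),
    state_row("B_I232", "emit", "2B_I232", "2B_I232"),
    state_row("B_T232", "emit", "2B_T232", "2B_T232"),
    state_row("C_loss", "silent"),
    state_row("C_prom_choice", "silent"),
    state_row("C_prom_C", "emit", "prom_C", "C:prom_C"),
    state_row("C_prom_G", "emit", "prom_G", "C:prom_G"),
    state_row("C_ORF", "emit", "2C_ORF", "2C_ORF"),
    state_row("C_Stop", "emit", "2C_Stop", "2C_Stop"),
    state_row("C_exit", "silent"),
    state_row("end", "end"))
  edges <- rbind(
    data.frame(from = "start", to = "B_prom_choice"),
    data.frame(from = "B_prom_choice", to = c("B_prom_C", "B_prom_G")),
    data.frame(from = c("B_prom_C", "B_prom_G"), to = "B_orf_choice"),
    data.frame(from = "B_orf_choice", to = c("B_I232", "B_T232")),
    data.frame(from = c("B_I232", "B_T232"), to = "C_loss"),
    data.frame(from = "C_loss", to = c("end", "C_prom_choice")),
    data.frame(from = "C_prom_choice", to = c("C_prom_C", "C_prom_G")),
    data.frame(from = "C_prom_C", to = c("C_ORF", "C_Stop")),
    data.frame(from = "C_prom_G", to = c("C_ORF", "C_Stop")),
    data.frame(from = c("C_ORF", "C_Stop"), to = "C_exit"),
    data.frame(from = "C_exit", to = c("C_prom_choice", "end")))
  cnav_graph(states, edges)
}

build_fully_connected <- function(genes = c("3A", "2C", "3B")) {
  genes <- as.character(genes)
  if (length(genes) < 2) stop("fully_connected_block needs at least 2 genes", call. = FALSE)
  gs <- paste0("gene_", genes)
  states <- rbind(
    state_row("start", "start"),
    do.call(rbind, mapply(state_row, gs, "emit", genes, SIMPLIFY = FALSE)),
    state_row("end", "end"))
  edges <- rbind(
    data.frame(from = "start", to = c(gs, "end")),
    expand.grid(from = gs, to = gs, stringsAsFactors = FALSE)[, c("from", "to")],
    data.frame(from = gs, to = "end"))
  cnav_graph(states, edges)
}
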
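#' Genotype count tables
#'
#' A genotype table holds one non-negative integer count vector per
#' individual over the emission alphabet of a model graph — the layout of an
#' exported MLPA copy-number spreadsheet.  On disk it is a TSV with a first
#' column `sample_id` and one integer column per counting-event symbol.
#'
#' @param counts integer matrix (individuals x symbols) with column names
#'   from the alphabet, or a data frame.
#' @param sample_id character vector of individual ids (default `S1..Sn`).
#' @param alphabet symbol order; defaults to the matrix column names.
#' @return Object of class `cnav_genotypes`: list with `sample_id`,
#'   `counts` (integer matrix) and `alphabet`.
#' @export
genotype_table <- function(counts, sample_id = NULL, alphabet = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(alphabet)) stop("counts must have column names (the alphabet)", call. = FALSE)
  if (anyDuplicated(alphabet)) stop("alphabet symbols must be unique", call. = FALSE)
  storage <- suppressWarnings(as.integer(counts))
  if (any(is.na(storage)) || any(abs(counts - storage) > 0)) {
    bad <- which(is.na(storage) | abs(counts - round(counts)) > 0)[1]
    stop(sprintf("non-integer count at row %d, column '%s'",
                 (bad - 1) %% nrow(counts) + 1,
                 colnames(counts)[(bad - 1) %/% nrow(counts) + 1]), call. = FALSE)
  }
  m <- matrix(storage, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row %d, column '%s'",
                 bad[1], colnames(m)[bad[2]]), call. = FALSE)
  }
  m <- m[, alphabet, drop = FALSE]
  if (is.null(sample_id)) {
    sample_id <- if (nrow(m)) paste0("S", seq_len(nrow(m))) else character(0)
  }
  stopifnot(length(sample_id) == nrow(m))
  structure(list(sample_id = as.character(sample_id), counts = m,
                 alphabet = alphabet),
            class = "cnav_genotypes")
}

#' @export
print.cnav_genotypes <- function(x, ...) {
  cat(sprintf("Genotype table: %d individuals x %d symbols\n",
              nrow(x$counts), ncol(x$counts)))
  print(utils::head(data.frame(sample_id = x$sample_id, x$counts,
                               check.names = FALSE), 6))
  if (nrow(x$counts) > 6) cat("...\n")
  invisible(x)
}

#' @export
dim.cnav_genotypes <- function(x) dim(x$counts)

#' Read a genotype TSV aligned to a graph alphabet
#'
#' The file must have a header with `sample_id` plus exactly the emission
#' symbols of the graph (order free; the table is reordered to the graph's
#' alphabet).  Missing or extra symbol columns, non-integer and negative
#' cells are errors that name the offending row/column.
#'
#' @param path TSV file path or connection.
#' @param g a [cnav_graph()] fixing the alphabet.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, g) {
  stopifnot(inherits(g, "cnav_graph"))
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (!"sample_id" %in% names(df)) {
    stop("first column must be 'sample_id'", call. = FALSE)
  }
  cols <- setdiff(names(df), "sample_id")
  missing <- setdiff(g$alphabet, cols)
  if (length(missing)) {
    stop("missing symbol column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(cols, g$alphabet)
  if (length(extra)) {
    stop("column(s) not in the graph alphabet: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  m <- matrix(NA_integer_, nrow(df), length(g$alphabet),
              dimnames = list(NULL, g$alphabet))
  for (col in g$alphabet) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v != round(v) | v < 0)
    if (length(bad)) {
      stop(sprintf("invalid count '%s' at row %d, column '%s' (non-negative integer required)",
                   df[[col]][bad[1]], bad[1], col), call. = FALSE)
    }
    m[, col] <- as.integer(v)
  }
  genotype_table(m, sample_id = df$sample_id, alphabet = g$alphabet)
}

#' @rdname read_genotypes
#' @param t a [genotype_table()].
#' @export
write_genotypes <- function(t, path) {
  stopifnot(inherits(t, "cnav_genotypes"))
  df <- data.frame(sample_id = t$sample_id, t$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate a genotype table into a multiset
#'
#' Collapses identical count vectors into distinct genotype categories with
#' multiplicities (the categories of the naive enumeration model).  Distinct
#' genotypes are ordered lexicographically, so the result is invariant under
#' row permutation.
#'
#' @param t a [genotype_table()].
#' @return Object of class `cnav_multiset`: list with `genotypes` (distinct
#'   count matrix), `multiplicity` and `n` (total individuals).
#' @export
aggregate_genotypes <- function(t) {
  stopifnot(inherits(t, "cnav_genotypes"))
  if (nrow(t$counts) == 0) stop("empty genotype table", call. = FALSE)
  key <- apply(t$counts, 1, paste, collapse = ",")
  tab <- table(key)
  ord <- order(names(tab))   # lexicographic on the key string
  ks <- names(tab)[ord]
  geno <- do.call(rbind, lapply(strsplit(ks, ","), as.integer))
  colnames(geno) <- t$alphabet
  structure(list(genotypes = geno,
                 multiplicity = as.integer(tab[ord]),
                 n = nrow(t$counts), alphabet = t$alphabet),
            class = "cnav_multiset")
}

#' @export
print.cnav_multiset <- function(x, ...) {
  cat(sprintf("Genotype multiset: %d distinct genotypes, N = %d\n",
              nrow(x$genotypes), x$n))
  invisible(x)
}

# stable identifier of the observed data, used to refuse Bayes factors
# across different data sets
data_fingerprint <- function(t) {
  if (!inherits(t, "cnav_multiset") && nrow(t$counts) == 0) {
    return(paste0("empty|", ncol(t$counts)))
  }
  m <- if (inherits(t, "cnav_multiset")) {
    cbind(t$genotypes, t$multiplicity)
  } else {
    agg <- aggregate_genotypes(t)
    cbind(agg$genotypes, agg$multiplicity)
  }
  paste(c(dim(m), as.integer(m)), collapse = "|")
}
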
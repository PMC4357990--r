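test_that("canonical builders produce valid graphs that round-trip through the writer", {
  built <- list(
    hwe_biallelic = cnav_model("hwe_biallelic", alleles = c("2A_H131", "2A_R131")),
    cnav_multiallele = cnav_model("cnav_multiallele", alleles = c("Na1", "Na2", "SH")),
    cnav_loh = cnav_model("cnav_loh"),
    first_order_dependency = cnav_model("first_order_dependency"),
    tandem_allele = cnav_model("tandem_allele"),
    two_locus_phasing = cnav_model("two_locus_phasing"),
    fully_connected_block = cnav_model("fully_connected_block", genes = c("3A", "2C", "3B")))
  for (nm in names(built)) {
    g <- built[[nm]]
    expect_length(validate_cnav_graph(g), 0)
    f <- tempfile(fileext = ".json")
    write_cnav_graph(g, f)
    expect_identical(read_cnav_graph(f), g)
  }
  # biallelic HWE: a start, a silent bifurcation, two emitting states, an end
  g <- built$hwe_biallelic
  expect_equal(nrow(g$states), 5)
  expect_equal(length(g$alphabet), 2)
})

test_that("builder option errors are caught", {
  expect_error(cnav_model("no_such_model"), "unknown canonical model")
  expect_error(cnav_model("hwe_biallelic", alleles = "only_one"), "at least 2")
  expect_error(cnav_model("cnav_multiallele", alleles = "A"), "at least 2")
  expect_error(cnav_model("cnav_loh", alleles = c("A", "B", "C")), "exactly 2")
  expect_error(cnav_model("tandem_allele", tandem = c("SH", "nope")), "tandem")
})

test_that("graph invariant violations are all reported", {
  # two start states
  s <- data.frame(id = c("s1", "s2", "e", "f"),
                  kind = c("start", "start", "emit", "end"),
                  emit = c(NA, NA, "A", NA))
  e <- data.frame(from = c("s1", "s2", "e"), to = c("e", "e", "f"))
  expect_error(cnav_graph(s, e), "exactly one start")
  rep <- validate_cnav_graph(cnav_graph(s, e, validate = FALSE))
  expect_true(any(grepl("exactly one start", rep)))

  # silent-only cycle
  s <- data.frame(id = c("s", "a", "b", "e", "f"),
                  kind = c("start", "silent", "silent", "emit", "end"),
                  emit = c(NA, NA, NA, "A", NA))
  e <- data.frame(from = c("s", "a", "b", "a", "e"),
                  to = c("a", "b", "a", "e", "f"))
  rep <- validate_cnav_graph(cnav_graph(s, e, validate = FALSE))
  expect_true(any(grepl("silent-only directed cycle", rep)))

  # end state with an outgoing edge
  s <- data.frame(id = c("s", "e", "f"), kind = c("start", "emit", "end"),
                  emit = c(NA, "A", NA))
  e <- data.frame(from = c("s", "e", "f"), to = c("e", "f", "e"))
  rep <- validate_cnav_graph(cnav_graph(s, e, validate = FALSE))
  expect_true(any(grepl("absorbing", rep)))

  # unreachable state named in the report
  s <- data.frame(id = c("s", "e", "orphan", "f"),
                  kind = c("start", "emit", "silent", "end"),
                  emit = c(NA, "A", NA, NA))
  e <- data.frame(from = c("s", "e"), to = c("e", "f"))
  rep <- validate_cnav_graph(cnav_graph(s, e, validate = FALSE))
  expect_true(any(grepl("orphan", rep)))

  # duplicate ids and edges
  s <- data.frame(id = c("s", "e", "e", "f"),
                  kind = c("start", "emit", "emit", "end"),
                  emit = c(NA, "A", "A", NA))
  e <- data.frame(from = c("s", "s", "e"), to = c("e", "e", "f"))
  rep <- validate_cnav_graph(cnav_graph(s, e, validate = FALSE))
  expect_true(any(grepl("duplicate state", rep)))
})

test_that("graph documents with syntax or schema problems are rejected", {
  f <- tempfile(fileext = ".json")
  writeLines("{not json", f)
  expect_error(read_cnav_graph(f), "syntax")
  writeLines('{"states": [], "edges": [], "bogus": 1}', f)
  expect_error(read_cnav_graph(f), "unknown top-level key")
  writeLines('{"states": [{"id": "s", "kind": "start", "colour": "red"}], "edges": []}', f)
  expect_error(read_cnav_graph(f), "unknown state key")
})

test_that("free parameter count is the sum of per-state simplex dimensions", {
  expect_equal(free_parameters(hwe_graph()), 1)
  # single chain start -> emit -> end
  chain <- cnav_graph(
    data.frame(id = c("s", "e", "f"), kind = c("start", "emit", "end"),
               emit = c(NA, "A", NA)),
    data.frame(from = c("s", "e"), to = c("e", "f")))
  expect_equal(free_parameters(chain), 0)
  # loss branch + allele bifurcation + gain loop: three degree-2 states
  expect_equal(free_parameters(cnav_model("cnav_multiallele")), 3)
  # caption-level reconstructions: 13 and 7 free parameters
  expect_equal(free_parameters(cnav_model("first_order_dependency")), 13)
  expect_equal(free_parameters(cnav_model("tandem_allele")), 7)
})

test_that("free parameter count is invariant under state relabeling", {
  g <- cnav_model("cnav_multiallele", alleles = c("A", "B"))
  relabel <- stats::setNames(paste0("z", seq_len(nrow(g$states))), g$states$id)
  g2 <- cnav_graph(
    transform(g$states, id = unname(relabel[id])),
    data.frame(from = unname(relabel[g$edges$from]),
               to = unname(relabel[g$edges$to])))
  expect_equal(free_parameters(g2), free_parameters(g))
})

test_that("path enumeration respects caps, order and limits", {
  g <- hwe_graph()
  expect_equal(nrow(enumerate_paths(g, copy_cap = 1)$emissions), 2)
  expect_equal(nrow(enumerate_paths(g, copy_cap = 0)$emissions), 0)

  g2 <- cnav_model("cnav_multiallele", alleles = c("A", "B"))
  # all words over {A, B} with each symbol used at most twice, plus the
  # null haplotype: sum over (a <= 2, b <= 2) of (a+b)!/(a!b!) = 19
  p2 <- enumerate_paths(g2, copy_cap = 2)
  expect_equal(nrow(p2$emissions), 19)
  expect_true(all(p2$emissions <= 2))
  # count vectors present: null, single, and mixed copies
  keys <- apply(p2$emissions, 1, paste, collapse = ",")
  expect_true(all(c("0,0", "1,0", "0,1", "2,0", "1,1", "0,2", "2,2") %in% keys))

  # monotone non-decreasing in the cap
  sizes <- vapply(0:3, function(cc) nrow(enumerate_paths(g2, copy_cap = cc)$emissions), 1L)
  expect_true(all(diff(sizes) >= 0))

  # deterministic lexicographic order
  pA <- enumerate_paths(g2, copy_cap = 2)
  pB <- enumerate_paths(g2, copy_cap = 2)
  expect_identical(pA$states, pB$states)
  seqs <- vapply(pA$states, paste, "", collapse = "\r")
  expect_identical(seqs, sort(seqs))

  expect_error(enumerate_paths(g2, copy_cap = 5, max_paths = 3), "overflow")
})

test_that("emissions equal the tally of emitting-state visits along each path", {
  g <- cnav_model("tandem_allele")
  p <- enumerate_paths(g, copy_cap = 2, max_paths = 1e4)
  emit_of <- stats::setNames(g$states$emit, g$states$id)
  for (i in seq_along(p$states)) {
    visited <- emit_of[p$states[[i]]]
    tallied <- table(factor(visited[!is.na(visited)], levels = g$alphabet))
    expect_equal(unname(p$emissions[i, ]), as.integer(tallied))
  }
})
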
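test_that("Wang similarity matches hand-computed S-values on chains", {
  g <- toy_graph()    # A -> B -> C, D -> C
  expect_equal(wang_similarity(g, "T:A", "T:A"), 1)
  # chain child/parent: (0.8 + 1) / (1.8 + 1)
  expect_equal(wang_similarity(g, "T:B", "T:C"), 1.8 / 2.8, tolerance = 1e-9)
  # A vs C: common ancestor C only; S_A = {A:1, B:.8, C:.64}
  expect_equal(wang_similarity(g, "T:A", "T:C"), (0.64 + 1) / (2.44 + 1),
               tolerance = 1e-9)
  # siblings via C: common {C}; (0.64 + 0.8) / (2.44 + 1.8)
  expect_equal(wang_similarity(g, "T:A", "T:D"), (0.64 + 0.8) / (2.44 + 1.8),
               tolerance = 1e-9)
})

test_that("Wang similarity decreases along chains and is symmetric", {
  g <- toy_graph()
  expect_gt(wang_similarity(g, "T:A", "T:B"), wang_similarity(g, "T:A", "T:C"))
  expect_equal(wang_similarity(g, "T:A", "T:D"),
               wang_similarity(g, "T:D", "T:A"))
  sims <- wang_sim_table(g, expand.grid(t1 = g$terms$id, t2 = g$terms$id,
                                        stringsAsFactors = FALSE))
  expect_true(all(sims$sim >= 0 & sims$sim <= 1))
})

test_that("terms in disjoint components have similarity zero", {
  g <- ontology_graph(terms = data.frame(
    id = c("X:1", "X:2"), name = c("one", "two"),
    namespace = "other", obsolete = FALSE))
  expect_equal(wang_similarity(g, "X:1", "X:2"), 0)
})

test_that("unknown or obsolete terms are lookup errors", {
  g <- ontology_graph(terms = data.frame(
    id = c("X:1", "X:2"), name = c("one", "two"),
    namespace = "other", obsolete = c(FALSE, TRUE)))
  expect_error(wang_similarity(g, "X:1", "X:9"), "unknown")
  expect_error(wang_similarity(g, "X:1", "X:2"), "obsolete")
})

ann_fixture <- function() {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("A:1\tg1", "A:1\tg2", "A:2\tg2", "A:2\tg3",
               "A:3\tg1", "A:3\tg2", "A:4\tg4"), f)
  load_annotations(f)
}

test_that("gene similarity follows the cosine and Jaccard formulas", {
  at <- ann_fixture()
  expect_equal(gene_similarity(at, "A:1", "A:3"), 1)          # identical sets
  expect_equal(gene_similarity(at, "A:1", "A:4"), 0)          # disjoint
  expect_equal(gene_similarity(at, "A:1", "A:2"), 1 / sqrt(4))
  expect_equal(gene_similarity(at, "A:1", "A:2", "jaccard"), 1 / 3)
  expect_true(is.na(gene_similarity(at, "A:1", "A:9")))       # unannotated
})

test_that("Jaccard never exceeds cosine", {
  at <- ann_fixture()
  pairs <- t(combn(c("A:1", "A:2", "A:3", "A:4"), 2))
  cosine <- gene_similarity(at, pairs[, 1], pairs[, 2], "cosine")
  jaccard <- gene_similarity(at, pairs[, 1], pairs[, 2], "jaccard")
  expect_true(all(jaccard <= cosine + 1e-12))
})

test_that("correlate reproduces the hand-computed Pearson value", {
  sc <- scores_fixture(sprintf("a%d", 1:4), sprintf("b%d", 1:4), c(1, 2, 3, 4))
  st <- structure(data.table::data.table(
    t1 = sprintf("a%d", 1:4), t2 = sprintf("b%d", 1:4),
    sim = c(0.2, 0.1, 0.4, 0.3)), class = c("similarity_table", "data.table",
                                            "data.frame"))
  data.table::setattr(st, "method", "WANG")
  rep <- correlate(sc, st)
  expect_equal(rep$pearson_r, 0.6, tolerance = 1e-12)
  expect_equal(rep$n_pairs, 4)
  expect_equal(rep$p_value,
               cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3))$p.value)
})

test_that("perfectly linear relations give r = 1", {
  sc <- scores_fixture(sprintf("a%d", 1:10), sprintf("b%d", 1:10), 1:10)
  st <- structure(data.table::data.table(
    t1 = sprintf("a%d", 1:10), t2 = sprintf("b%d", 1:10),
    sim = (1:10) / 20 + 0.1), class = c("similarity_table", "data.table",
                                        "data.frame"))
  data.table::setattr(st, "method", "WANG")
  expect_equal(correlate(sc, st)$pearson_r, 1, tolerance = 1e-12)
})

test_that("degenerate correlation inputs raise errors", {
  sc <- scores_fixture(c("a", "b"), c("x", "y"), c(1, 2))
  st <- structure(data.table::data.table(t1 = c("a", "b"), t2 = c("x", "y"),
                                         sim = c(0.1, 0.2)),
                  class = c("similarity_table", "data.table", "data.frame"))
  data.table::setattr(st, "method", "WANG")
  expect_error(correlate(sc, st), "insufficient")
  sc3 <- scores_fixture(c("a", "b", "c"), c("x", "y", "z"), c(1, 2, 3))
  st3 <- structure(data.table::data.table(t1 = c("a", "b", "c"),
                                          t2 = c("x", "y", "z"),
                                          sim = c(0.5, 0.5, 0.5)),
                   class = c("similarity_table", "data.table", "data.frame"))
  data.table::setattr(st3, "method", "WANG")
  expect_error(correlate(sc3, st3), "zero variance")
})

test_that("scatter_export writes exactly the shared pairs", {
  sc <- scores_fixture(c("a", "b", "c", "d"), c("w", "x", "y", "z"), 1:4)
  st <- structure(data.table::data.table(t1 = c("a", "b", "c"),
                                         t2 = c("w", "x", "y"),
                                         sim = c(0.1, 0.2, 0.3)),
                  class = c("similarity_table", "data.table", "data.frame"))
  data.table::setattr(st, "method", "WANG")
  f <- withr::local_tempfile(fileext = ".tsv")
  scatter_export(sc, st, f)
  out <- read.delim(f)
  expect_equal(nrow(out), 3)
  expect_equal(names(out), c("term1", "term2", "score", "similarity"))
})
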
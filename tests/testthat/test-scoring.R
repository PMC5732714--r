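test_that("raw RSS reproduces hand-computed values", {
  idx <- rss_fixture_index()
  expect_equal(rss(idx, "a", "b"), -4, tolerance = 1e-12)
  expect_equal(rss(idx, "c", "d"), -3, tolerance = 1e-12)
  expect_equal(rss(idx, "e", "f"), -2, tolerance = 1e-12)
  # self pair: log10(COV / COV^2)
  expect_equal(rss(idx, "a", "a"), -2, tolerance = 1e-12)
  expect_equal(rss(idx, "a", "b"), rss(idx, "b", "a"))
  expect_true(is.na(rss(idx, "a", "c")))   # never co-occurs: not scorable
})

test_that("RSS normalization maps the observed range onto [1, 100]", {
  idx <- rss_fixture_index()
  raw <- score_all(idx, "rss")
  expect_equal(sort(raw$score), c(-4, -3, -2))
  norm <- normalize_rss(raw)
  expect_equal(sort(norm$score), c(1, 50.5, 100), tolerance = 1e-12)
  expect_equal(attr(norm, "rss_min"), -4)
  expect_equal(attr(norm, "rss_max"), -2)
  # endpoint pairs land exactly on the bounds
  expect_equal(norm$score[norm$t1 == "e"], 100)
  expect_equal(norm$score[norm$t1 == "a"], 1)
})

test_that("degenerate single-value tables normalize to 100 with a warning", {
  idx <- cooc_index(M = 100, S = 100, sent_count = c(a = 10, b = 10),
                    pair_sent = data.frame(t1 = "a", t2 = "b", cov = 5L))
  raw <- score_all(idx, "rss")
  expect_warning(norm <- normalize_rss(raw), "identical")
  expect_equal(norm$score, 100)
})

test_that("NMD reproduces the hand-computed distance and identities", {
  idx <- cooc_index(M = 1000, S = 1000,
                    sent_count = c(x = 100, y = 100),
                    pair_sent = data.frame(t1 = "x", t2 = "y", cov = 50L),
                    doc_count = c(x = 100, y = 100),
                    pair_doc = data.frame(t1 = "x", t2 = "y", cov = 50L))
  # (log 100 - log 50) / (log 1000 - log 100) in any base
  expect_equal(nmd(idx, "x", "y"), log10(2), tolerance = 1e-9)
  expect_equal(nmd(idx, "x", "y"), 0.30103, tolerance = 1e-5)
  expect_equal(nmd(idx, "x", "x"), 0)
  expect_equal(nmd(idx, "x", "y"), nmd(idx, "y", "x"))
})

test_that("perfect containment with equal marginals gives NMD 0", {
  idx <- cooc_index(M = 500, S = 500,
                    sent_count = c(x = 40, y = 40),
                    pair_sent = data.frame(t1 = "x", t2 = "y", cov = 40L),
                    doc_count = c(x = 40, y = 40),
                    pair_doc = data.frame(t1 = "x", t2 = "y", cov = 40L))
  expect_equal(nmd(idx, "x", "y"), 0)
})

test_that("a corpus no larger than a term's document count is degenerate", {
  idx <- cooc_index(M = 50, S = 500,
                    sent_count = c(x = 50, y = 40),
                    pair_sent = data.frame(t1 = "x", t2 = "y", cov = 10L),
                    doc_count = c(x = 50, y = 40),
                    pair_doc = data.frame(t1 = "x", t2 = "y", cov = 10L))
  expect_error(nmd(idx, "x", "y"), "degenerate")
})

test_that("sim_nmd is the clamped 1 - d transform", {
  expect_equal(sim_nmd(0), 1)
  expect_equal(sim_nmd(0.30103), 0.69897, tolerance = 1e-12)
  expect_equal(sim_nmd(1.7), 0)
  expect_error(sim_nmd(-0.1), "negative")
})

test_that("score_all covers all qualifying pairs per method", {
  idx <- rss_fixture_index()
  norm <- score_all(idx, "rss_n")
  expect_equal(nrow(norm), 3)
  expect_equal(max(norm$score), 100)
  expect_equal(min(norm$score), 1)
  sim <- score_all(idx, "sim_nmd")
  expect_true(all(sim$score >= 0 & sim$score <= 1))
  expect_warning(empty <- score_all(idx, "rss", min_cov = 1000), "no pairs")
  expect_equal(nrow(empty), 0)
})

test_that("min_cov leaves NMD scores unchanged but rescales RSS_N", {
  set.seed(23)
  fx <- random_mentions(n_docs = 12, sent_per_doc = 5, n_terms = 6,
                        n_mentions = 120)
  idx <- build_index(fx$documents, fx$sentences, fx$mentions)
  n_all <- score_all(idx, "nmd", min_cov = 1)
  n_hi <- score_all(idx, "nmd", min_cov = 3)
  j <- merge(as.data.frame(n_all), as.data.frame(n_hi), by = c("t1", "t2"))
  expect_true(nrow(j) >= 1)
  expect_equal(j$score.x, j$score.y)
  r_all <- score_all(idx, "rss_n", min_cov = 1)
  r_hi <- score_all(idx, "rss_n", min_cov = 3)
  # renormalization over the surviving pairs changes values but keeps order
  j2 <- merge(as.data.frame(r_all), as.data.frame(r_hi), by = c("t1", "t2"))
  expect_equal(order(j2$score.x), order(j2$score.y))
  expect_equal(max(r_hi$score), 100)
})

test_that("RSS grows with the joint count; NMD falls with it", {
  base <- function(cov12, covd) cooc_index(
    M = 1000, S = 2000, sent_count = c(a = 50, b = 80),
    pair_sent = data.frame(t1 = "a", t2 = "b", cov = cov12),
    doc_count = c(a = 50, b = 80),
    pair_doc = data.frame(t1 = "a", t2 = "b", cov = covd))
  r <- vapply(1:10, function(c12) rss(base(c12, 1L), "a", "b"), 0)
  expect_true(all(diff(r) > 0))
  d <- vapply(1:10, function(cd) nmd(base(1L, cd), "a", "b"), 0)
  expect_true(all(diff(d) < 0))
})

test_that("growing the corpus with irrelevant documents shrinks NMD", {
  mk <- function(M) cooc_index(
    M = M, S = M, sent_count = c(a = 50, b = 80),
    pair_sent = data.frame(t1 = "a", t2 = "b", cov = 10L),
    doc_count = c(a = 50, b = 80),
    pair_doc = data.frame(t1 = "a", t2 = "b", cov = 10L))
  d <- vapply(c(200, 500, 2000, 10000), function(M) nmd(mk(M), "a", "b"), 0)
  expect_true(all(diff(d) < 0))
})

test_that("RSS and SimNMD rank pairs identically under equal marginals", {
  idx <- cooc_index(
    M = 1000, S = 1000,
    sent_count = c(a = 50, b = 50, c = 50, d = 50, e = 50, f = 50),
    pair_sent = data.frame(t1 = c("a", "c", "e"), t2 = c("b", "d", "f"),
                           cov = c(5L, 20L, 45L)),
    doc_count = c(a = 50, b = 50, c = 50, d = 50, e = 50, f = 50),
    pair_doc = data.frame(t1 = c("a", "c", "e"), t2 = c("b", "d", "f"),
                          cov = c(5L, 20L, 45L)))
  r <- score_all(idx, "rss")
  s <- score_all(idx, "sim_nmd")
  j <- merge(as.data.frame(r), as.data.frame(s), by = c("t1", "t2"))
  expect_equal(order(j$score.x), order(j$score.y))
})

test_that("score tables round-trip through TSV", {
  idx <- rss_fixture_index()
  norm <- score_all(idx, "rss_n")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scores(norm, f)
  back <- read_scores(f)
  expect_equal(as.data.frame(back), as.data.frame(norm))
  expect_equal(attr(back, "method"), "RSS_N")
  expect_equal(attr(back, "rss_min"), attr(norm, "rss_min"))
})
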
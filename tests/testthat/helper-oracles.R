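# Shared fixtures and independent oracles.

extdata <- function(f) system.file("extdata", f, package = "cooclink")

# small hand-built ontology: chain A -> B -> C plus sibling D under C
toy_graph <- function() {
  ontology_graph(
    terms = data.frame(
      id = c("T:A", "T:B", "T:C", "T:D"),
      name = c("alpha", "beta", "gamma", "delta"),
      namespace = "other", obsolete = FALSE),
    edges = data.frame(child = c("T:A", "T:B", "T:D"),
                       parent = c("T:B", "T:C", "T:C"))
  )
}

# dictionary over explicit surface -> id pairs, via a throwaway ontology
dict_from_surfaces <- function(surfaces, ids, min_token_length = 3L) {
  g <- ontology_graph(terms = data.frame(
    id = ids, name = surfaces, namespace = "other", obsolete = FALSE))
  build_dictionary(g, min_token_length = min_token_length)
}

# brute-force matcher oracle: enumerate every token window that matches the
# dictionary, then greedily select leftmost-longest non-overlapping windows
oracle_match <- function(text, dictionary) {
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1L) return(data.frame(term_id = character(), start = integer(),
                                     end = integer()))
  tok_start <- as.integer(m)
  tok_len <- attr(m, "match.length")
  toks <- tolower(regmatches(text, list(m))[[1]])
  n <- length(toks)
  cand <- list()
  for (i in seq_len(n)) for (L in seq_len(min(dictionary$max_len, n - i + 1L))) {
    k <- paste(toks[i:(i + L - 1L)], collapse = " ")
    if (exists(k, envir = dictionary$entries, inherits = FALSE))
      cand[[length(cand) + 1L]] <- list(i = i, L = L,
                                        ids = get(k, envir = dictionary$entries))
  }
  if (!length(cand)) return(data.frame(term_id = character(),
                                       start = integer(), end = integer()))
  ord <- order(vapply(cand, `[[`, 0L, "i"), -vapply(cand, `[[`, 0L, "L"))
  cand <- cand[ord]
  chosen <- list()
  blocked_until <- 0L
  for (c0 in cand) {
    if (c0$i <= blocked_until) next
    chosen[[length(chosen) + 1L]] <- c0
    blocked_until <- c0$i + c0$L - 1L
  }
  do.call(rbind, lapply(chosen, function(c0) data.frame(
    term_id = c0$ids,
    start = tok_start[c0$i] - 1L,
    end = tok_start[c0$i + c0$L - 1L] + tok_len[c0$i + c0$L - 1L] - 1L)))
}

# O(T^2 * S) nested-loop recount of a co-occurrence index
oracle_index <- function(documents, sentences, mentions) {
  terms <- sort(unique(mentions$term_id))
  skey <- paste(sentences$doc_id, sentences$index)
  present_s <- lapply(terms, function(t) {
    unique(paste(mentions$doc_id[mentions$term_id == t],
                 mentions$sentence_index[mentions$term_id == t]))
  })
  present_d <- lapply(terms, function(t)
    unique(mentions$doc_id[mentions$term_id == t]))
  names(present_s) <- names(present_d) <- terms
  sent_count <- vapply(present_s, length, 0L)
  doc_count <- vapply(present_d, length, 0L)
  ps <- list(); pd <- list()
  if (length(terms) >= 2) for (i in seq_len(length(terms) - 1L))
    for (j in (i + 1L):length(terms)) {
      cs <- length(intersect(present_s[[i]], present_s[[j]]))
      cd <- length(intersect(present_d[[i]], present_d[[j]]))
      if (cs > 0)
        ps[[length(ps) + 1L]] <- data.frame(t1 = terms[i], t2 = terms[j], cov = cs)
      if (cd > 0)
        pd[[length(pd) + 1L]] <- data.frame(t1 = terms[i], t2 = terms[j], cov = cd)
    }
  list(M = nrow(documents), S = nrow(sentences),
       sent_count = sent_count, doc_count = doc_count,
       pair_sent = do.call(rbind, ps), pair_doc = do.call(rbind, pd))
}

# random mention table over a toy corpus (for brute-force comparisons)
random_mentions <- function(n_docs = 10, sent_per_doc = 5, n_terms = 6,
                            n_mentions = 40) {
  docs <- data.frame(doc_id = sprintf("d%02d", seq_len(n_docs)),
                     text = "unused")
  sentences <- do.call(rbind, lapply(docs$doc_id, function(d)
    data.frame(doc_id = d, index = seq_len(sent_per_doc) - 1L, text = "unused")))
  pick <- sample(nrow(sentences), n_mentions, replace = TRUE)
  mentions <- data.frame(
    doc_id = sentences$doc_id[pick],
    sentence_index = sentences$index[pick],
    term_id = sample(sprintf("T:%03d", seq_len(n_terms)), n_mentions,
                     replace = TRUE),
    start = 0L, end = 1L, text = "x")
  list(documents = docs, sentences = sentences, mentions = mentions)
}

# score-table constructor for network tests
scores_fixture <- function(t1, t2, score) {
  idx_like <- data.table::data.table(t1 = t1, t2 = t2, score = score)
  data.table::setattr(idx_like, "method", "RSS_N")
  data.table::setattr(idx_like, "class",
                      c("pair_scores", class(idx_like)))
  idx_like
}

# fixture index with raw RSS values {-4, -3, -2}
rss_fixture_index <- function() {
  cooc_index(
    M = 3000, S = 6000,
    sent_count = c(a = 100, b = 1000, c = 100, d = 100, e = 100, f = 100),
    pair_sent = data.frame(t1 = c("a", "c", "e"), t2 = c("b", "d", "f"),
                           cov = c(10L, 10L, 100L)))
}
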
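# Sentence- and document-level occurrence / co-occurrence counting.
#
# The occurrence value OV(t, s) is a binary indicator (a term counted once
# per sentence however often it is mentioned); the co-occurrence value
# COV(t1, t2) is the number of sentences containing both terms, summed over
# the corpus. COV(t, t) equals the term's sentence count. Document-level
# analogues feed the NMD distance.

#' Keep only sentences mentioning at least two distinct terms
#'
#' Sentences with fewer than two distinct term ids carry no pair information
#' and are dropped before indexing.
#'
#' @param mentions Mention table from [match_terms()].
#' @return Filtered mention table (same columns).
#' @export
filter_sentences <- function(mentions) {
  mentions <- as.data.table(mentions)
  if (!nrow(mentions)) return(mentions[])
  mentions[, if (uniqueN(term_id) >= 2L) .SD, by = .(doc_id, sentence_index)][]
}

#' Construct a co-occurrence index from counts
#'
#' Low-level constructor, used by [build_index()] and directly when the
#' counts are already known (fixtures, serialized indexes). Marginal counts
#' are named integer vectors; pair counts are tables with canonically
#' ordered (`t1 < t2`) unordered pairs.
#'
#' @param M Total number of documents in the corpus (including documents
#'   contributing no mentions).
#' @param S Total number of sentences.
#' @param sent_count Named integer vector: sentences containing each term
#'   (`COV(t, t)`).
#' @param pair_sent data.frame `t1`, `t2`, `cov`: sentences containing both
#'   terms.
#' @param doc_count Named integer vector: documents containing each term;
#'   defaults to `sent_count` capped at `M` only when absent (supply real
#'   counts for NMD work).
#' @param pair_doc data.frame `t1`, `t2`, `cov` at document granularity;
#'   defaults to `pair_sent`.
#' @return An object of class `cooc_index`.
#' @export
cooc_index <- function(M, S, sent_count, pair_sent,
                       doc_count = NULL, pair_doc = NULL) {
  pair_sent <- .canonical_pairs(as.data.table(pair_sent))
  if (is.null(doc_count)) doc_count <- pmin(sent_count, M)
  pair_doc <- if (is.null(pair_doc)) copy(pair_sent)
              else .canonical_pairs(as.data.table(pair_doc))
  idx <- structure(
    list(M = as.integer(M), S = as.integer(S),
         sent_count = sent_count, doc_count = doc_count,
         pair_sent = pair_sent, pair_doc = pair_doc),
    class = "cooc_index"
  )
  .validate_index(idx)
  idx
}

.canonical_pairs <- function(pairs) {
  stopifnot(all(c("t1", "t2") %in% names(pairs)))
  if (!"cov" %in% names(pairs)) setnames(pairs, "n", "cov", skip_absent = TRUE)
  swap <- pairs$t1 > pairs$t2
  if (any(swap)) {
    lo <- pairs$t2[swap]; hi <- pairs$t1[swap]
    pairs$t1[swap] <- lo; pairs$t2[swap] <- hi
  }
  pairs <- pairs[t1 != t2]
  pairs <- pairs[, .(cov = as.integer(sum(cov))), by = .(t1, t2)]
  setkeyv(pairs, c("t1", "t2"))
  pairs[]
}

.validate_index <- function(idx) {
  stopifnot(idx$M >= 0L, idx$S >= 0L,
            all(idx$sent_count >= 0L), all(idx$doc_count >= 0L))
  p <- idx$pair_sent
  if (nrow(p)) {
    cap <- pmin(idx$sent_count[p$t1], idx$sent_count[p$t2])
    if (any(is.na(cap)) || any(p$cov > cap))
      stop("pair sentence count exceeds a marginal sentence count")
  }
  p <- idx$pair_doc
  if (nrow(p)) {
    cap <- pmin(idx$doc_count[p$t1], idx$doc_count[p$t2])
    if (any(is.na(cap)) || any(p$cov > cap))
      stop("pair document count exceeds a marginal document count")
  }
  invisible(idx)
}

#' Build a co-occurrence index from mentions
#'
#' Counts, per term, the sentences and documents containing it, and, per
#' unordered term pair, the sentences and documents containing both.
#' Repeated mentions within one sentence (or document) count once. `M`
#' counts every document read, including those contributing no mentions.
#'
#' @param documents Document table (as from [read_corpus()]).
#' @param sentences Sentence table (as from [segment_sentences()]).
#' @param mentions Mention table, normally [filter_sentences()] output.
#' @return A [cooc_index()].
#' @export
build_index <- function(documents, sentences, mentions) {
  documents <- as.data.table(documents)
  sentences <- as.data.table(sentences)
  mentions <- as.data.table(mentions)
  if (nrow(mentions)) {
    known <- sentences[, .(doc_id, sentence_index = index)]
    orphan <- mentions[!known, on = c("doc_id", "sentence_index")]
    if (nrow(orphan))
      stop("mentions reference unknown sentences, e.g. doc ",
           orphan$doc_id[1], " sentence ", orphan$sentence_index[1])
  }
  usent <- unique(mentions[, .(doc_id, sentence_index, term_id)])
  udoc <- unique(mentions[, .(doc_id, term_id)])
  sent_count <- if (nrow(usent)) {
    sc <- usent[, .N, by = term_id]
    setNames(sc$N, sc$term_id)
  } else integer()
  doc_count <- if (nrow(udoc)) {
    dc <- udoc[, .N, by = term_id]
    setNames(dc$N, dc$term_id)
  } else integer()
  pair_sent <- .count_pairs(usent, c("doc_id", "sentence_index"))
  pair_doc <- .count_pairs(udoc, "doc_id")
  cooc_index(M = nrow(documents), S = nrow(sentences),
             sent_count = sent_count, pair_sent = pair_sent,
             doc_count = doc_count, pair_doc = pair_doc)
}

.count_pairs <- function(utab, by_cols) {
  if (!nrow(utab))
    return(data.table(t1 = character(), t2 = character(), cov = integer()))
  j <- merge(utab, utab, by = by_cols, allow.cartesian = TRUE,
             suffixes = c("", ".y"))
  j <- j[term_id < term_id.y]
  if (!nrow(j))
    return(data.table(t1 = character(), t2 = character(), cov = integer()))
  j[, .(cov = .N), by = .(t1 = term_id, t2 = term_id.y)]
}

#' @export
print.cooc_index <- function(x, ...) {
  cat(sprintf(
    "<cooc_index> M=%d documents, S=%d sentences, %d terms, %d sentence-level pairs\n",
    x$M, x$S, length(x$sent_count), nrow(x$pair_sent)))
  invisible(x)
}

#' Sentence-level co-occurrence value of a pair
#'
#' `cov_sent(index, t, t)` returns the term's sentence count; order of the
#' two terms is irrelevant. Pairs never co-mentioned return 0.
#'
#' @param index A [cooc_index()].
#' @param t1,t2 Term ids.
#' @return Integer count.
#' @export
cov_sent <- function(index, t1, t2) .pair_lookup(index, t1, t2, "sent")

#' Document-level co-occurrence value of a pair
#' @inheritParams cov_sent
#' @return Integer count.
#' @export
cov_doc <- function(index, t1, t2) .pair_lookup(index, t1, t2, "doc")

.pair_lookup <- function(index, t1, t2, level) {
  stopifnot(inherits(index, "cooc_index"))
  marg <- if (level == "sent") index$sent_count else index$doc_count
  if (t1 == t2) {
    v <- marg[t1]
    return(if (length(v) == 0L || is.na(v)) 0L else as.integer(v))
  }
  tab <- if (level == "sent") index$pair_sent else index$pair_doc
  a <- min(t1, t2); b <- max(t1, t2)
  v <- tab[.(a, b), cov]
  if (is.na(v)) 0L else as.integer(v)
}

#' List co-occurring pairs above a count threshold
#'
#' @param index A [cooc_index()].
#' @param min_cov Minimum sentence-level co-occurrence count (>= 1).
#' @return data.table `t1`, `t2`, `cov` with `t1 < t2`, sorted
#'   lexicographically; deterministic.
#' @export
pair_list <- function(index, min_cov = 1L) {
  stopifnot(inherits(index, "cooc_index"), min_cov >= 1L)
  out <- index$pair_sent[cov >= min_cov]
  setorderv(out, c("t1", "t2"))
  out[]
}

#' Serialize a co-occurrence index
#'
#' Writes each granularity as TSV triples `(term, term, count)` where self
#' pairs `(t, t, count)` carry the marginal counts, preceded by a one-line
#' `# M=<docs> S=<sentences>` header. Two files are produced in `dir`:
#' `index_sentence.tsv` and `index_document.tsv`.
#'
#' @param index A [cooc_index()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_index <- function(index, dir) {
  stopifnot(inherits(index, "cooc_index"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_level <- function(marg, pairs, path) {
    self <- data.table(t1 = names(marg), t2 = names(marg),
                       cov = as.integer(marg))
    tab <- rbind(self, pairs[, .(t1, t2, cov)])
    setorderv(tab, c("t1", "t2"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# M=%d S=%d", index$M, index$S), con)
    write.table(tab, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  .write_level(index$sent_count, index$pair_sent,
               file.path(dir, "index_sentence.tsv"))
  .write_level(index$doc_count, index$pair_doc,
               file.path(dir, "index_document.tsv"))
  invisible(dir)
}

#' Read a serialized co-occurrence index
#' @param dir Directory written by [write_index()].
#' @return A [cooc_index()].
#' @export
read_index <- function(dir) {
  .read_level <- function(path) {
    hdr <- readLines(path, n = 1L)
    m <- as.integer(sub(".*M=(\\d+).*", "\\1", hdr))
    s <- as.integer(sub(".*S=(\\d+).*", "\\1", hdr))
    tab <- fread(path, skip = 1L, header = FALSE,
                 col.names = c("t1", "t2", "cov"),
                 colClasses = list(character = 1:2, integer = 3))
    list(M = m, S = s,
         marg = setNames(tab[t1 == t2, cov], tab[t1 == t2, t1]),
         pairs = tab[t1 != t2])
  }
  sl <- .read_level(file.path(dir, "index_sentence.tsv"))
  dl <- .read_level(file.path(dir, "index_document.tsv"))
  cooc_index(M = sl$M, S = sl$S,
             sent_count = sl$marg, pair_sent = sl$pairs,
             doc_count = dl$marg, pair_doc = dl$pairs)
}
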
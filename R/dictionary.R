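# Dictionary construction and leftmost-longest term matching.
#
# Surface forms are normalized aggressively but conservatively: lowercase,
# split on any non-alphanumeric run, no stemming, no plural folding. The
# matcher scans token-by-token and at each position takes the longest
# dictionary entry (leftmost-longest, non-overlapping), the behaviour of
# radix-tree concept recognizers; here entries live in a hashed environment
# keyed by the normalized token sequence.

#' Normalize a surface form into matching tokens
#'
#' @param x Character vector of surface strings.
#' @return List of character vectors: lowercased alphanumeric tokens, empty
#'   tokens dropped.
#' @export
normalize_tokens <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

#' Build a term dictionary from ontologies
#'
#' Inserts the name and every synonym of each non-obsolete term, normalized
#' with [normalize_tokens()]. Single-token entries shorter than
#' `min_token_length` characters are excluded (they match too promiscuously).
#' One normalized surface form may map to several term ids, possibly from
#' different ontologies.
#'
#' @param ontologies An [ontology_graph()] or list of them.
#' @param min_token_length Minimum character length for single-token
#'   entries. Default 3.
#' @param synonym_scopes Optional character vector restricting which synonym
#'   scopes are inserted (e.g. `"EXACT"`); default all scopes.
#' @return An object of class `term_dictionary`.
#' @export
build_dictionary <- function(ontologies, min_token_length = 3L,
                             synonym_scopes = NULL) {
  if (inherits(ontologies, "ontology_graph")) ontologies <- list(ontologies)
  stopifnot(length(ontologies) >= 1,
            all(vapply(ontologies, inherits, TRUE, "ontology_graph")))
  env <- new.env(parent = emptyenv(), size = 4096L)
  max_len <- 0L
  insert <- function(surface, ids) {
    toks <- normalize_tokens(surface)[[1]]
    if (!length(toks)) return()
    if (length(toks) == 1L && nchar(toks) < min_token_length) return()
    key <- paste(toks, collapse = " ")
    cur <- if (exists(key, envir = env, inherits = FALSE)) get(key, envir = env)
           else character()
    assign(key, sort(unique(c(cur, ids))), envir = env)
    max_len <<- max(max_len, length(toks))
  }
  for (g in ontologies) {
    live <- g$terms[obsolete == FALSE]
    for (i in seq_len(nrow(live))) insert(live$name[i], live$id[i])
    syns <- g$synonyms[id %chin% live$id]
    if (!is.null(synonym_scopes)) syns <- syns[scope %chin% synonym_scopes]
    for (i in seq_len(nrow(syns))) insert(syns$synonym[i], syns$id[i])
  }
  if (!length(ls(env)))
    stop("dictionary is empty: no term surface forms survived normalization")
  structure(
    list(entries = env, max_len = max_len,
         min_token_length = as.integer(min_token_length)),
    class = "term_dictionary"
  )
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat(sprintf("<term_dictionary> %d entries, longest %d tokens\n",
              length(ls(x$entries)), x$max_len))
  invisible(x)
}

#' Dictionary entries as a table
#' @param dictionary A `term_dictionary`.
#' @return data.table with columns `key` (normalized surface) and `term_id`.
#' @export
dictionary_entries <- function(dictionary) {
  keys <- sort(ls(dictionary$entries))
  out <- rbindlist(lapply(keys, function(k)
    data.table(k = k, term_id = get(k, envir = dictionary$entries))))
  setnames(out, "k", "key")
  out[]
}

#' Match ontology terms in sentences
#'
#' Tokenizes each sentence with the dictionary's normalization, keeping
#' character offsets, then scans left to right: at each token position the
#' longest dictionary token-sequence match wins, one mention is emitted per
#' term id of that entry, and the scan resumes after the match. Matches
#' respect token boundaries, so no intra-word hits occur. Spans are 0-based,
#' half-open, within the sentence text.
#'
#' @param sentences data.table with columns `doc_id`, `index`, `text` (as
#'   from [segment_sentences()]); a single character string is also
#'   accepted and treated as one sentence of document `"<text>"`.
#' @param dictionary A `term_dictionary` from [build_dictionary()].
#' @return data.table with columns `doc_id`, `sentence_index`, `term_id`,
#'   `start`, `end`, `text` (the matched surface), sorted by `start` within
#'   each sentence.
#' @export
match_terms <- function(sentences, dictionary) {
  stopifnot(inherits(dictionary, "term_dictionary"))
  if (is.character(sentences))
    sentences <- data.table(doc_id = "<text>",
                            index = seq_along(sentences) - 1L,
                            text = sentences)
  sentences <- as.data.table(sentences)
  stopifnot(all(c("doc_id", "index", "text") %in% names(sentences)))
  env <- dictionary$entries
  max_len <- dictionary$max_len
  rows <- lapply(seq_len(nrow(sentences)), function(r) {
    txt <- sentences$text[r]
    m <- gregexpr("[A-Za-z0-9]+", txt)[[1]]
    if (m[1] == -1L) return(NULL)
    tok_start <- as.integer(m)
    tok_len <- attr(m, "match.length")
    toks <- tolower(regmatches(txt, list(m))[[1]])
    ntok <- length(toks)
    out <- list()
    i <- 1L
    while (i <= ntok) {
      hit_len <- 0L; hit_ids <- NULL
      for (L in seq(min(max_len, ntok - i + 1L), 1L)) {
        key <- paste(toks[i:(i + L - 1L)], collapse = " ")
        if (exists(key, envir = env, inherits = FALSE)) {
          hit_len <- L
          hit_ids <- get(key, envir = env)
          break
        }
      }
      if (hit_len > 0L) {
        s0 <- tok_start[i] - 1L                                  # 0-based
        e0 <- tok_start[i + hit_len - 1L] + tok_len[i + hit_len - 1L] - 1L
        out[[length(out) + 1L]] <- data.table(
          doc_id = sentences$doc_id[r],
          sentence_index = sentences$index[r],
          term_id = hit_ids, start = s0, end = e0,
          text = substr(txt, s0 + 1L, e0)
        )
        i <- i + hit_len
      } else i <- i + 1L
    }
    if (length(out)) rbindlist(out) else NULL
  })
  out <- rbindlist(rows)
  if (!nrow(out))
    out <- data.table(doc_id = character(), sentence_index = integer(),
                      term_id = character(), start = integer(),
                      end = integer(), text = character())
  out[]
}
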
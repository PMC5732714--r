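# Abstract readers and the rule-based sentence segmenter.

#' Read an abstract corpus
#'
#' Reads MEDLINE XML (`PubmedArticleSet`) or JSONL (one
#' `{"doc_id": ..., "text": ...}` object per line) into a document table.
#' For MEDLINE XML the abstract is the concatenation of all `AbstractText`
#' sections in order, space-joined, with structured-abstract labels dropped;
#' articles without an abstract yield an empty text. Records without a PMID
#' are skipped with a warning.
#'
#' @param path Input file.
#' @param format `"jsonl"` or `"medline_xml"`.
#' @param include_title For MEDLINE XML, prepend the article title to the
#'   text (default `FALSE`: abstracts only).
#' @return data.table with columns `doc_id`, `text`, one row per article in
#'   file order.
#' @export
read_corpus <- function(path, format = c("jsonl", "medline_xml"),
                        include_title = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    ids <- vapply(recs, function(r) as.character(r$doc_id %||% NA_character_), "")
    if (anyNA(ids)) {
      warning(sum(is.na(ids)), " record(s) without doc_id skipped")
      recs <- recs[!is.na(ids)]; ids <- ids[!is.na(ids)]
    }
    docs <- data.table(
      doc_id = ids,
      text = vapply(recs, function(r) as.character(r$text %||% ""), "")
    )
  } else {
    xml <- xml2::read_xml(path)
    arts <- xml2::xml_find_all(xml, ".//PubmedArticle")
    rows <- lapply(seq_along(arts), function(i) {
      a <- arts[[i]]
      pmid <- xml2::xml_find_first(a, ".//MedlineCitation/PMID")
      if (inherits(pmid, "xml_missing"))
        pmid <- xml2::xml_find_first(a, ".//PMID")
      if (inherits(pmid, "xml_missing")) {
        warning("article ", i, " has no PMID; skipped")
        return(NULL)
      }
      abst <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
      text <- paste(trimws(xml2::xml_text(abst)), collapse = " ")
      if (include_title) {
        ttl <- xml2::xml_find_first(a, ".//ArticleTitle")
        if (!inherits(ttl, "xml_missing"))
          text <- trimws(paste(xml2::xml_text(ttl), text))
      }
      data.table(doc_id = trimws(xml2::xml_text(pmid)), text = trimws(text))
    })
    docs <- rbindlist(rows)
    if (!nrow(docs)) docs <- data.table(doc_id = character(), text = character())
  }
  if (anyDuplicated(docs$doc_id)) stop("duplicate doc_id in corpus")
  docs[]
}

#' Default sentence-terminator abbreviation list
#'
#' Abbreviations whose trailing period never ends a sentence. Extend or
#' replace via `file`, one abbreviation per line.
#'
#' @param file Optional path to a plain-text abbreviation list.
#' @return Character vector of abbreviations (each ends with `.`).
#' @export
default_abbreviations <- function(file = NULL) {
  ab <- c("e.g.", "i.e.", "et al.", "al.", "Fig.", "Figs.", "Dr.",
          "vs.", "approx.", "No.", "cf.")
  if (!is.null(file)) ab <- union(ab, trimws(readLines(file, warn = FALSE)))
  ab
}

#' Segment text into sentences
#'
#' Deterministic rule-based segmentation: a sentence is the longest
#' whitespace-trimmed span between terminators. The text splits after `.`,
#' `!` or `?` when followed by whitespace and then an uppercase letter or a
#' digit, or at end of text. A period does not split when it closes a listed
#' abbreviation or a single-uppercase-letter token (protecting, e.g.,
#' "E. coli"); a decimal point is never followed by whitespace and so never
#' splits. Runs of whitespace are collapsed to single spaces, so joining the
#' returned sentences with single spaces reproduces the whitespace-collapsed
#' input.
#'
#' @param x A character string (one document's text).
#' @param abbreviations Character vector of protected abbreviations; see
#'   [default_abbreviations()].
#' @return Character vector of sentences (possibly empty).
#' @examples
#' segment_text("E. coli causes sepsis in 3.5 days. Treatment helps.")
#' @export
segment_text <- function(x, abbreviations = default_abbreviations()) {
  x <- gsub("\\s+", " ", trimws(x))
  if (!nzchar(x)) return(character())
  nc <- nchar(x)
  cand <- gregexpr("[.!?]", x)[[1]]
  if (cand[1] == -1L) return(x)
  ab_low <- tolower(abbreviations)
  cuts <- integer()
  for (p in cand) {
    if (p < nc) {
      if (substr(x, p + 1L, p + 1L) != " ") next
      nxt <- substr(x, p + 2L, p + 2L)
      if (!grepl("^[A-Z0-9]$", nxt)) next
    }
    ch <- substr(x, p, p)
    if (ch == ".") {
      prefix <- substr(x, 1L, p)
      tok <- regmatches(prefix, regexpr("[^ ]+$", prefix))
      if (length(tok) && grepl("^[A-Z]\\.$", tok)) next
      pl <- tolower(prefix)
      protected <- any(vapply(ab_low, function(ab) {
        endsWith(pl, ab) &&
          (nchar(pl) == nchar(ab) ||
             substr(pl, nchar(pl) - nchar(ab), nchar(pl) - nchar(ab)) == " ")
      }, logical(1)))
      if (protected) next
    }
    cuts <- c(cuts, p)
  }
  starts <- c(1L, cuts[cuts < nc] + 1L)
  ends <- c(cuts[cuts < nc], nc)
  out <- trimws(substring(x, starts, ends))
  out[nzchar(out)]
}

#' Segment a corpus into sentences
#'
#' Applies [segment_text()] to every document and returns one row per
#' sentence with its 0-based ordinal within the document. Documents with
#' empty text contribute no rows.
#'
#' @param documents data.table/data.frame with columns `doc_id`, `text`
#'   (as from [read_corpus()]).
#' @param abbreviations Passed to [segment_text()].
#' @return data.table with columns `doc_id`, `index`, `text`.
#' @export
segment_sentences <- function(documents, abbreviations = default_abbreviations()) {
  documents <- as.data.table(documents)
  stopifnot(all(c("doc_id", "text") %in% names(documents)))
  rows <- lapply(seq_len(nrow(documents)), function(i) {
    s <- segment_text(documents$text[i], abbreviations)
    if (!length(s)) return(NULL)
    data.table(doc_id = documents$doc_id[i], index = seq_along(s) - 1L, text = s)
  })
  out <- rbindlist(rows)
  if (!nrow(out))
    out <- data.table(doc_id = character(), index = integer(), text = character())
  out[]
}
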
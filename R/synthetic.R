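# Seeded generator of toy ontologies, annotations and corpora with planted
# co-occurrence structure.
#
# Design: per namespace a random is_a DAG is grown; term surface forms are
# 1-3 pseudo-word tokens drawn without replacement from a fixed pool (so
# names never collide and the matcher faces multi-token cases). Every
# within-namespace pair is co-mentioned per document with probability
# proportional to the square of its Wang similarity, so the co-occurrence
# signal is coupled to DAG proximity throughout; planted pairs are a
# term-disjoint subset with an elevated floor on that weight. Solo mentions
# top every term up to the busiest term's expected frequency, so marginal
# counts are comparable and score differences reflect joint counts, not
# marginal imbalance. Gene sets are inherited along the DAG (children keep
# a fraction of a parent's genes), so gene overlap also tracks proximity,
# and planted pairs share additional genes in proportion to the coupling
# strength.

#' Generate a synthetic world
#'
#' Builds seeded toy ontologies, a gene-annotation table and an abstract
#' corpus with planted term-pair associations, standing in for the
#' PubMed/GO/DO inputs of the full-scale pipeline.
#'
#' @param n_terms Terms per namespace. Default 20.
#' @param namespaces Character vector of namespace tags; `"DO"` produces
#'   `DOID:` identifiers, anything else `GO:` identifiers. Default
#'   `c("DO", "BP")`.
#' @param branching Maximum children per DAG node before a new parent is
#'   preferred. Default 3.
#' @param n_docs Number of documents. Default 500.
#' @param sentences_per_doc Sentences per document. Default 5.
#' @param background_rate Per-sentence probability that any given term is
#'   mentioned as background noise. Default 0.02.
#' @param planted_prob Per-document probability scale of pair co-mention:
#'   each within-namespace pair is co-mentioned in one of a document's
#'   sentences with probability `planted_prob * weight^2`, where `weight`
#'   is the pair's Wang similarity, floored at 0.6 for planted pairs.
#'   Default 0.3.
#' @param n_planted Planted pairs per namespace (term-disjoint). Default 8.
#' @param gene_pool Size of the gene universe. Default 100.
#' @param genes_per_term Genes annotated to each term. Default 8.
#' @param coupling Annotation-coupling strength in `[0, 1]`: the fraction
#'   (scaled by the pair weight) of a planted pair's genes that are shared.
#'   Default 0.8.
#' @param seed Integer seed; identical parameters and seed give a
#'   byte-identical world. The session RNG state is left untouched.
#' @return An object of class `synthetic_world`: list with `ontologies`
#'   (named list of [ontology_graph()]), `annotations`
#'   (`annotation_table`), `corpus` (document table), `planted_pairs`
#'   (data.table `t1`, `t2`, `namespace`, `sim`, `weight`, `prob`),
#'   `pair_weights` (the same fields for every within-namespace pair, with
#'   a `planted` flag) and `params`.
#' @export
generate_world <- function(n_terms = 20L, namespaces = c("DO", "BP"),
                           branching = 3L, n_docs = 500L,
                           sentences_per_doc = 5L,
                           background_rate = 0.02, planted_prob = 0.3,
                           n_planted = 8L, gene_pool = 100L,
                           genes_per_term = 8L, coupling = 0.8,
                           seed = 1L) {
  stopifnot(n_terms >= 3L, length(namespaces) >= 1L, branching >= 1L,
            n_docs >= 1L, sentences_per_doc >= 1L,
            gene_pool >= genes_per_term, genes_per_term >= 1L,
            n_planted >= 0L, 2L * n_planted <= n_terms)
  if (background_rate <= 0 || background_rate >= 1)
    stop("background_rate must be in (0, 1)")
  if (planted_prob < background_rate || planted_prob > 1)
    stop("planted_prob must be in [background_rate, 1]")
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  params <- list(n_terms = n_terms, namespaces = namespaces,
                 branching = branching, n_docs = n_docs,
                 sentences_per_doc = sentences_per_doc,
                 background_rate = background_rate,
                 planted_prob = planted_prob, n_planted = n_planted,
                 gene_pool = gene_pool, genes_per_term = genes_per_term,
                 coupling = coupling, seed = seed)
  with_seed(seed, .generate_world_impl(params))
}

.word_pool <- function() {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))
  as.vector(outer(syl, syl, paste0))          # 4900 four-letter pseudo-words
}

# English fillers; none are four-letter consonant-vowel pairs, so they can
# never collide with pool-generated term tokens
.filler_pool <- function() {
  c("the", "study", "of", "results", "in", "patients", "we", "observed",
    "with", "analysis", "showed", "levels", "during", "treatment", "cases",
    "clinical", "between", "association", "increased", "reported")
}

.generate_world_impl <- function(p) {
  pool <- sample(.word_pool())
  pool_pos <- 0L
  take_tokens <- function(k) {
    stopifnot(pool_pos + k <= length(pool))
    out <- pool[(pool_pos + 1L):(pool_pos + k)]
    pool_pos <<- pool_pos + k
    out
  }
  ontologies <- list()
  planted <- list()
  all_terms <- list()
  for (ni in seq_along(p$namespaces)) {
    ns <- p$namespaces[ni]
    prefix <- if (ns == "DO") "DOID" else "GO"
    ids <- sprintf("%s:%07d", prefix, (ni - 1L) * p$n_terms + seq_len(p$n_terms))
    # surface forms: 1-3 tokens, drawn without replacement from the pool
    nm <- vapply(seq_len(p$n_terms), function(i)
      paste(take_tokens(sample(1:3, 1, prob = c(0.4, 0.4, 0.2))),
            collapse = " "), "")
    has_syn <- runif(p$n_terms) < 0.3
    syn <- ifelse(has_syn,
                  vapply(seq_len(p$n_terms), function(i)
                    if (has_syn[i]) paste(take_tokens(sample(1:2, 1)),
                                          collapse = " ") else "", ""),
                  NA_character_)
    # random is_a DAG: each later term attaches below an earlier one,
    # preferring parents with spare child capacity; occasional second parent
    child_n <- integer(p$n_terms)
    edges <- list()
    for (i in 2:p$n_terms) {
      open <- which(child_n[seq_len(i - 1L)] < p$branching)
      par1 <- if (length(open)) open[sample.int(length(open), 1L)]
              else sample.int(i - 1L, 1L)
      child_n[par1] <- child_n[par1] + 1L
      parents <- par1
      if (i > 2L && runif(1) < 0.15) {
        par2 <- sample.int(i - 1L, 1L)
        if (par2 != par1) parents <- c(parents, par2)
      }
      edges[[i]] <- data.table(child = ids[i], parent = ids[parents])
    }
    terms <- data.table(id = ids, name = nm, namespace = ns, obsolete = FALSE)
    syns <- data.table(id = ids[has_syn], synonym = syn[has_syn],
                       scope = "EXACT")
    g <- ontology_graph(terms, rbindlist(edges), syns)
    ontologies[[ns]] <- g
    all_terms[[ns]] <- data.table(term_id = ids, namespace = ns,
                                  name = nm, synonym = syn)
    cand <- as.data.table(t(combn(ids, 2L)))
    setnames(cand, c("t1", "t2"))
    cand[, sim := wang_sim_table(g, cand)$sim]
    cand[, namespace := ns]
    cand[, planted := FALSE]
    if (p$n_planted > 0L) {
      # term-disjoint planted pairs, favouring DAG-close candidates
      used <- character()
      picked <- integer()
      for (k in seq_len(p$n_planted)) {
        ok <- which(!(cand$t1 %chin% used) & !(cand$t2 %chin% used))
        if (!length(ok)) break
        pick <- ok[sample.int(length(ok), 1L,
                              prob = (cand$sim[ok] + 0.05)^2)]
        picked <- c(picked, pick)
        used <- c(used, cand$t1[pick], cand$t2[pick])
      }
      cand[picked, planted := TRUE]
    }
    planted[[ns]] <- cand
  }
  # every within-namespace pair is co-mentioned at a rate tied to its DAG
  # proximity (weight ~ Wang similarity, squared to sharpen contrast);
  # planted pairs carry an elevated floor, background pairs a damped slope,
  # so the planted signal stays clearly above the proximity background
  pairs_all <- rbindlist(planted)
  pairs_all[, weight := ifelse(planted, pmax(0.6, sim), 0.5 * sim)]
  pairs_all[, prob := p$planted_prob * weight^2]
  terms_dt <- rbindlist(all_terms)
  n_all <- nrow(terms_dt)

  # balance marginal frequencies: solo-mention probability tops every term
  # up to the busiest term's expected pair activity per document
  pair_load <- setNames(numeric(n_all), terms_dt$term_id)
  for (k in seq_len(nrow(pairs_all))) {
    pair_load[pairs_all$t1[k]] <- pair_load[pairs_all$t1[k]] + pairs_all$prob[k]
    pair_load[pairs_all$t2[k]] <- pair_load[pairs_all$t2[k]] + pairs_all$prob[k]
  }
  solo_prob <- max(pair_load, 0) - pair_load

  # corpus: per document, planted pair events land in one random sentence;
  # solo top-ups likewise; background mentions are i.i.d. per sentence
  fillers <- .filler_pool()
  surface <- function(i) {
    s <- terms_dt$synonym[i]
    if (!is.na(s) && runif(1) < 0.2) s else terms_dt$name[i]
  }
  doc_ids <- sprintf("%d", 100000L + seq_len(p$n_docs))
  texts <- character(p$n_docs)
  spd <- p$sentences_per_doc
  i1 <- match(pairs_all$t1, terms_dt$term_id)
  i2 <- match(pairs_all$t2, terms_dt$term_id)
  for (d in seq_len(p$n_docs)) {
    sent_terms <- replicate(spd, integer(), simplify = FALSE)
    hits <- which(runif(nrow(pairs_all)) < pairs_all$prob)
    for (k in hits) {
      s <- sample.int(spd, 1L)
      sent_terms[[s]] <- c(sent_terms[[s]], i1[k], i2[k])
    }
    solo_hits <- which(runif(n_all) < solo_prob)
    for (i in solo_hits) {
      s <- sample.int(spd, 1L)
      sent_terms[[s]] <- c(sent_terms[[s]], i)
    }
    bg <- matrix(runif(spd * n_all) < p$background_rate, spd, n_all)
    sents <- vapply(seq_len(spd), function(s) {
      idx <- unique(c(sent_terms[[s]], which(bg[s, ])))
      .render_sentence(idx, surface, fillers)
    }, "")
    texts[d] <- paste(sents, collapse = " ")
  }
  corpus <- data.table(doc_id = doc_ids, text = texts)

  # annotations: gene sets of fixed size are inherited along the DAG (a
  # child keeps each parental gene with probability 0.6 and fills up with
  # fresh genes), so annotation overlap decays with DAG distance; planted
  # pairs are then forced to share at least
  # round(coupling * weight * genes_per_term) genes
  genes <- sprintf("G%04d", seq_len(p$gene_pool))
  gene_sets <- setNames(replicate(n_all, character(), simplify = FALSE),
                        terms_dt$term_id)
  for (ns in p$namespaces) {
    g <- ontologies[[ns]]
    for (tid in g$terms$id) {           # generation order: parents precede
      par <- g$edges[child == tid, parent]
      keep <- if (length(par)) {
        ps <- gene_sets[[par[1]]]
        ps[runif(length(ps)) < 0.6]
      } else character()
      fill <- sample(setdiff(genes, keep), p$genes_per_term - length(keep))
      gene_sets[[tid]] <- c(keep, fill)
    }
  }
  for (k in which(pairs_all$planted)) {
    n_sh <- round(p$coupling * pairs_all$weight[k] * p$genes_per_term)
    s1 <- gene_sets[[pairs_all$t1[k]]]
    s2 <- gene_sets[[pairs_all$t2[k]]]
    need <- n_sh - length(intersect(s1, s2))
    if (need > 0L) {
      add <- sample(setdiff(s1, s2), min(need, length(setdiff(s1, s2))))
      drop <- sample(setdiff(s2, s1), length(add))
      gene_sets[[pairs_all$t2[k]]] <- c(setdiff(s2, drop), add)
    }
  }
  records <- rbindlist(lapply(terms_dt$term_id, function(tid)
    data.table(term_id = tid, gene_id = gene_sets[[tid]], evidence = "EXP")))
  structure(
    list(ontologies = ontologies,
         annotations = .annotation_table(records),
         corpus = corpus,
         planted_pairs = .canonical_planted(
           pairs_all[planted == TRUE, .(t1, t2, namespace, sim, weight, prob)]),
         pair_weights = .canonical_planted(
           pairs_all[, .(t1, t2, namespace, sim, weight, prob, planted)]),
         params = p),
    class = "synthetic_world"
  )
}

.canonical_planted <- function(planted) {
  if (!nrow(planted)) return(planted[])
  swap <- planted$t1 > planted$t2
  if (any(swap)) {
    lo <- planted$t2[swap]; hi <- planted$t1[swap]
    planted$t1[swap] <- lo; planted$t2[swap] <- hi
  }
  setorderv(planted, c("t1", "t2"))
  planted[]
}

.render_sentence <- function(term_idx, surface, fillers) {
  words <- character()
  for (i in term_idx) {
    words <- c(words, sample(fillers, sample(1:2, 1)), surface(i))
  }
  words <- c(words, sample(fillers, sample(2:4, 1)))
  s <- paste(words, collapse = " ")
  paste0(toupper(substr(s, 1, 1)), substring(s, 2), ".")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d namespaces x %d terms, %d documents, %d planted pairs (seed %d)\n",
    length(x$ontologies), x$params$n_terms, nrow(x$corpus),
    nrow(x$planted_pairs), x$params$seed))
  invisible(x)
}

#' Write a synthetic world to files
#'
#' Emits one OBO file per namespace, the annotation TSV, the corpus in both
#' JSONL and MEDLINE-XML dialects, and a manifest of the planted pairs
#' (ground truth). Reloading the files through [load_obo()],
#' [load_annotations()] and [read_corpus()] reproduces the in-memory
#' structures.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
world_to_files <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (ns in names(world$ontologies)) {
    f <- file.path(dir, paste0(tolower(ns), ".obo"))
    write_obo(world$ontologies[[ns]], f)
    files[paste0("obo_", ns)] <- f
  }
  f <- file.path(dir, "annotations.tsv")
  fwrite(world$annotations$records, f, sep = "\t")
  files["annotations"] <- f
  f <- file.path(dir, "corpus.jsonl")
  con <- file(f, "w")
  for (i in seq_len(nrow(world$corpus)))
    writeLines(jsonlite::toJSON(
      list(doc_id = world$corpus$doc_id[i], text = world$corpus$text[i]),
      auto_unbox = TRUE), con)
  close(con)
  files["corpus_jsonl"] <- f
  f <- file.path(dir, "corpus.xml")
  .write_medline_xml(world$corpus, f)
  files["corpus_xml"] <- f
  f <- file.path(dir, "planted_pairs.tsv")
  fwrite(world$planted_pairs, f, sep = "\t")
  files["manifest"] <- f
  invisible(files)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.write_medline_xml <- function(corpus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('<?xml version="1.0" encoding="UTF-8"?>', con)
  writeLines("<PubmedArticleSet>", con)
  for (i in seq_len(nrow(corpus))) {
    abstract <- if (nzchar(corpus$text[i]))
      sprintf("<Abstract><AbstractText>%s</AbstractText></Abstract>",
              .xml_escape(corpus$text[i])) else ""
    writeLines(sprintf(paste0(
      "<PubmedArticle><MedlineCitation><PMID>%s</PMID>",
      "<Article>%s</Article></MedlineCitation></PubmedArticle>"),
      .xml_escape(corpus$doc_id[i]), abstract), con)
  }
  writeLines("</PubmedArticleSet>", con)
}
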
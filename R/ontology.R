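# OBO ontology and gene-annotation readers.
#
# Only [Term] stanzas and `is_a` edges are used: the subsumption DAG is what
# both the dictionary and the Wang similarity need. `part_of` and other typed
# relationships are ignored on load.

NAMESPACE_TAGS <- c(
  biological_process = "BP",
  molecular_function = "MF",
  cellular_component = "CC",
  disease_ontology   = "DO"
)

#' Construct an ontology graph
#'
#' Low-level constructor used by [load_obo()] and the synthetic generator.
#' Validates that edge endpoints exist, that obsolete terms carry no edges,
#' and that the `is_a` graph is acyclic.
#'
#' @param terms `data.frame` with columns `id`, `name`, `namespace`
#'   (`"BP"`, `"MF"`, `"CC"`, `"DO"` or `"other"`) and logical `obsolete`.
#' @param edges `data.frame` with columns `child`, `parent` (`is_a` edges,
#'   child subsumed by parent).
#' @param synonyms `data.frame` with columns `id`, `synonym`, `scope`
#'   (e.g. `"EXACT"`, `"RELATED"`).
#' @param alt_ids `data.frame` with columns `alt`, `id` mapping secondary
#'   identifiers to the primary one.
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms,
                           edges = data.frame(child = character(), parent = character()),
                           synonyms = data.frame(id = character(), synonym = character(),
                                                 scope = character()),
                           alt_ids = data.frame(alt = character(), id = character())) {
  terms <- as.data.table(terms)
  edges <- as.data.table(edges)
  synonyms <- as.data.table(synonyms)
  alt_ids <- as.data.table(alt_ids)
  if (anyDuplicated(terms$id))
    stop("duplicate term ids: ", paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "))
  bad_name <- terms[!obsolete & (is.na(name) | !nzchar(name))]
  if (nrow(bad_name))
    stop("non-obsolete terms with empty names: ", paste(bad_name$id, collapse = ", "))
  if (nrow(edges)) {
    missing <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
    if (length(missing))
      stop("is_a edge endpoints not among terms: ", paste(missing, collapse = ", "))
    obs <- terms$id[terms$obsolete]
    if (any(edges$child %chin% obs | edges$parent %chin% obs))
      stop("obsolete terms must not carry is_a edges")
    edges <- unique(edges)
  }
  g <- igraph::graph_from_data_frame(
    edges[, .(child, parent)], directed = TRUE,
    vertices = data.frame(name = terms$id)
  )
  if (!igraph::is_dag(g)) {
    cyc <- .find_cycle(edges)
    stop("is_a graph is cyclic; one cycle: ", paste(cyc, collapse = " -> "))
  }
  structure(
    list(terms = terms, edges = edges, synonyms = synonyms,
         alt_ids = alt_ids, graph = g),
    class = "ontology_graph"
  )
}

# DFS cycle finder, only called on graphs known to contain one
.find_cycle <- function(edges) {
  adj <- split(edges$parent, edges$child)
  state <- new.env(parent = emptyenv())
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- mget(v, envir = state, ifnotfound = 0L)[[1]]
    if (st == 1L) {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    if (st == 2L) return()
    assign(v, 1L, envir = state)
    path <<- c(path, v)
    for (p in adj[[v]]) visit(p)
    path <<- path[-length(path)]
    assign(v, 2L, envir = state)
  }
  for (v in unique(edges$child)) {
    visit(v)
    if (!is.null(found)) break
  }
  found
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf(
    "<ontology_graph> %d terms (%d obsolete), %d is_a edges, %d synonyms\n",
    nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges), nrow(x$synonyms)
  ))
  ns <- table(x$terms$namespace)
  cat("  namespaces:", paste(sprintf("%s=%d", names(ns), ns), collapse = ", "), "\n")
  invisible(x)
}

#' Parse an OBO ontology file
#'
#' Reads an OBO 1.2/1.4 flat file, keeping `[Term]` stanzas only. `is_a`
#' lines become edges of the subsumption DAG; synonyms of all scopes are
#' captured; obsolete terms are loaded, flagged, and stripped of edges;
#' `alt_id` lines populate the alternate-identifier map.
#'
#' @param path Path to an OBO file.
#' @param namespace_filter Optional namespace tag (`"BP"`, `"MF"`, `"CC"`,
#'   `"DO"`); if given, terms are restricted to that namespace and edges to
#'   the retained terms.
#' @return An [ontology_graph()].
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: GO:0000001", "name: alpha",
#'              "is_a: GO:0000002 ! beta",
#'              "", "[Term]", "id: GO:0000002", "name: beta"), obo)
#' g <- load_obo(obo)
#' nrow(g$terms)
#' @export
load_obo <- function(path, namespace_filter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  terms <- list(); syns <- list(); edges <- list(); alts <- list()
  if (length(starts)) {
    ends <- c(starts[-1] - 1L, length(lines))
    for (k in seq_along(starts)) {
      if (trimws(lines[starts[k]]) != "[Term]") next
      body_idx <- seq(starts[k] + 1L, length.out = max(0L, ends[k] - starts[k]))
      rec <- .parse_term_stanza(lines, body_idx)
      if (is.null(rec$id))
        stop("malformed stanza at line ", starts[k], ": missing id")
      terms[[length(terms) + 1L]] <- data.table(
        id = rec$id, name = rec$name %||% "",
        namespace = rec$namespace, obsolete = rec$obsolete
      )
      if (length(rec$is_a) && !rec$obsolete)
        edges[[length(edges) + 1L]] <- data.table(child = rec$id, parent = rec$is_a)
      if (length(rec$synonyms))
        syns[[length(syns) + 1L]] <- data.table(
          id = rec$id, synonym = rec$synonyms, scope = rec$scopes)
      if (length(rec$alt_id))
        alts[[length(alts) + 1L]] <- data.table(alt = rec$alt_id, id = rec$id)
    }
  }
  terms <- rbindlist(terms)
  if (!nrow(terms)) stop("no [Term] stanzas found in ", path)
  edges <- if (length(edges)) rbindlist(edges) else
    data.table(child = character(), parent = character())
  syns <- if (length(syns)) rbindlist(syns) else
    data.table(id = character(), synonym = character(), scope = character())
  alts <- if (length(alts)) rbindlist(alts) else
    data.table(alt = character(), id = character())
  if (!is.null(namespace_filter)) {
    keep <- terms$id[terms$namespace == namespace_filter]
    terms <- terms[id %chin% keep]
    edges <- edges[child %chin% keep & parent %chin% keep]
    syns <- syns[id %chin% keep]
    alts <- alts[id %chin% keep]
  } else {
    # edges may point at terms pruned from the file (e.g. other namespaces)
    missing <- !(edges$parent %chin% terms$id)
    if (any(missing)) {
      warning(sum(missing), " is_a edge(s) with unknown parent dropped")
      edges <- edges[!missing]
    }
  }
  ontology_graph(terms, edges, syns, alts)
}

.parse_term_stanza <- function(lines, idx) {
  rec <- list(id = NULL, name = NULL, namespace = "other", obsolete = FALSE,
              is_a = character(), synonyms = character(), scopes = character(),
              alt_id = character())
  for (i in idx) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(ln, "!")) next
    m <- regexpr(": ", ln, fixed = TRUE)
    if (m < 0) {
      m2 <- regexpr(":", ln, fixed = TRUE)
      if (m2 < 0) stop("malformed stanza line ", i, ": ", ln)
      tag <- substr(ln, 1, m2 - 1L); val <- substring(ln, m2 + 1L)
    } else {
      tag <- substr(ln, 1, m - 1L); val <- substring(ln, m + 2L)
    }
    val <- sub("\\s+!.*$", "", val)  # trailing comments
    val <- trimws(val)
    switch(tag,
      id = { rec$id <- val },
      name = { rec$name <- val },
      namespace = {
        rec$namespace <- if (val %in% names(NAMESPACE_TAGS)) NAMESPACE_TAGS[[val]]
                         else if (val %in% NAMESPACE_TAGS) val else "other"
      },
      is_a = { rec$is_a <- c(rec$is_a, sub("\\s.*$", "", val)) },
      alt_id = { rec$alt_id <- c(rec$alt_id, val) },
      is_obsolete = { rec$obsolete <- identical(tolower(val), "true") },
      synonym = {
        sm <- regmatches(val, regexec('^"(.*)"\\s*([A-Z]*)', val))[[1]]
        if (length(sm) >= 2 && nzchar(sm[2])) {
          rec$synonyms <- c(rec$synonyms, sm[2])
          rec$scopes <- c(rec$scopes,
                          if (length(sm) >= 3 && nzchar(sm[3])) sm[3] else "RELATED")
        }
      }
    )
  }
  # DO files often omit the namespace line; infer from the id prefix
  if (identical(rec$namespace, "other") && !is.null(rec$id) &&
      startsWith(rec$id, "DOID:"))
    rec$namespace <- "DO"
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an ontology graph back to OBO
#'
#' Round-trip companion to [load_obo()]: term count, edge count and the
#' synonym multiset survive a write/load cycle.
#'
#' @param graph An [ontology_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  ns_rev <- setNames(names(NAMESPACE_TAGS), NAMESPACE_TAGS)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(graph$terms))) {
    tm <- graph$terms[i]
    out <- c("", "[Term]", paste0("id: ", tm$id), paste0("name: ", tm$name))
    if (tm$namespace %in% names(ns_rev))
      out <- c(out, paste0("namespace: ", ns_rev[[tm$namespace]]))
    s <- graph$synonyms[id == tm$id]
    if (nrow(s))
      out <- c(out, sprintf('synonym: "%s" %s []', s$synonym, s$scope))
    a <- graph$alt_ids[id == tm$id]
    if (nrow(a)) out <- c(out, paste0("alt_id: ", a$alt))
    e <- graph$edges[child == tm$id]
    if (nrow(e)) out <- c(out, paste0("is_a: ", e$parent))
    if (tm$obsolete) out <- c(out, "is_obsolete: true")
    writeLines(out, con)
  }
  invisible(path)
}

#' Ancestors of a term under is_a
#'
#' @param graph An [ontology_graph()].
#' @param id Term identifier.
#' @param inclusive Include the term itself (default `TRUE`).
#' @return Character vector of ancestor ids.
#' @export
term_ancestors <- function(graph, id, inclusive = TRUE) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (!id %in% graph$terms$id) stop("unknown term: ", id)
  anc <- igraph::subcomponent(graph$graph, id, mode = "out")$name
  if (!inclusive) anc <- setdiff(anc, id)
  anc
}

#' Resolve a possibly-alternate term id to its primary id
#' @param graph An [ontology_graph()].
#' @param ids Character vector of term ids.
#' @return Character vector with alternate ids replaced by primary ones;
#'   ids unknown to the graph pass through unchanged.
#' @export
resolve_term_ids <- function(graph, ids) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (!nrow(graph$alt_ids)) return(ids)
  m <- match(ids, graph$alt_ids$alt)
  hit <- !is.na(m)
  ids[hit] <- graph$alt_ids$id[m[hit]]
  ids
}

#' Load a term-to-gene annotation table
#'
#' Accepts GAF 2.x (17 tab-separated columns, `!` comment lines; the term id
#' is column 5, the gene is the DB Object ID in column 2, the evidence code
#' column 7) or a minimal 2-3 column TSV `(term id, gene id[, evidence])`
#' with an optional `term` header line.
#'
#' @param path Path to the annotation file.
#' @param drop_iea Drop records with evidence code `"IEA"` (inferred from
#'   electronic annotation), the conventional filter for high-confidence
#'   sets. Default `TRUE`.
#' @param dedupe Collapse duplicate `(term, gene)` pairs to one record.
#'   Default `TRUE`.
#' @param ontology Optional [ontology_graph()]; if given, alternate term ids
#'   are resolved to primary ids before deduplication.
#' @return An object of class `annotation_table`: list with `records`
#'   (data.table `term_id`, `gene_id`, `evidence`) and `by_term` (named list
#'   of gene-id vectors).
#' @export
load_annotations <- function(path, drop_iea = TRUE, dedupe = TRUE,
                             ontology = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  data_lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "!")]
  if (!length(data_lines)) {
    warning("empty annotation file: ", path)
    return(.annotation_table(data.table(
      term_id = character(), gene_id = character(), evidence = character())))
  }
  nfield <- length(strsplit(data_lines[1], "\t", fixed = TRUE)[[1]])
  if (nfield >= 15) {            # GAF 2.x
    parts <- strsplit(data_lines, "\t", fixed = TRUE)
    rec <- data.table(
      term_id = vapply(parts, `[`, "", 5L),
      gene_id = vapply(parts, `[`, "", 2L),
      evidence = vapply(parts, `[`, "", 7L)
    )
  } else if (nfield %in% c(2L, 3L)) {
    if (grepl("^term", data_lines[1], ignore.case = TRUE))
      data_lines <- data_lines[-1]
    parts <- strsplit(data_lines, "\t", fixed = TRUE)
    rec <- data.table(
      term_id = vapply(parts, `[`, "", 1L),
      gene_id = vapply(parts, `[`, "", 2L),
      evidence = vapply(parts, function(p) if (length(p) >= 3) p[3] else "", "")
    )
  } else {
    stop("unknown annotation file dialect (", nfield, " columns): ", path)
  }
  ok <- grepl("^[A-Za-z_]+:[A-Za-z0-9_.:-]+$", rec$term_id)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with malformed term ids dropped")
    rec <- rec[ok]
  }
  if (!is.null(ontology)) rec[, term_id := resolve_term_ids(ontology, term_id)]
  if (drop_iea) rec <- rec[evidence != "IEA"]
  if (dedupe) rec <- unique(rec, by = c("term_id", "gene_id"))
  .annotation_table(rec)
}

.annotation_table <- function(records) {
  by_term <- if (nrow(records))
    lapply(split(records$gene_id, records$term_id), unique)
  else list()
  structure(list(records = records, by_term = by_term),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("<annotation_table> %d records, %d terms, %d genes\n",
              nrow(x$records), length(x$by_term),
              uniqueN(x$records$gene_id)))
  invisible(x)
}

#' Gene set annotated to a term
#' @param annotations An `annotation_table`.
#' @param id Term identifier.
#' @return Character vector of gene ids (may be empty).
#' @export
term_genes <- function(annotations, id) {
  stopifnot(inherits(annotations, "annotation_table"))
  annotations$by_term[[id]] %||% character()
}
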
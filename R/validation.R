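# Reference similarities and correlation analysis.
#
# Wang's DAG-based semantic similarity: each ancestor a of a term A carries
# a semantic contribution S_A(a), 1 for A itself and decaying by the is_a
# contribution factor w along each edge, taking the best (maximal) path:
# with a single edge type this is S_A(a) = w^d(A, a), d the shortest is_a
# path length. The similarity of A and B is the sum of both terms'
# contributions over their common ancestors, normalized by the two total
# semantic values SV(A) + SV(B).
#
# The gene-based reference similarity is set overlap of the annotated gene
# sets (cosine by default, Jaccard as an alternative), standing in for
# annotation-derived term similarity: the claim under test is that
# co-mentioned terms share genes.

#' Wang semantic similarity of two terms
#'
#' @param graph An [ontology_graph()].
#' @param t1,t2 Term ids; must be present and non-obsolete.
#' @param w_isa is_a edge contribution factor in (0, 1); default 0.8.
#' @return Similarity in `[0, 1]`; 0 when the terms share no ancestor.
#' @examples
#' g <- ontology_graph(
#'   terms = data.frame(id = c("A", "B"), name = c("a", "b"),
#'                      namespace = "other", obsolete = FALSE),
#'   edges = data.frame(child = "A", parent = "B"))
#' wang_similarity(g, "A", "B")  # (0.8 + 1) / (1.8 + 1)
#' @export
wang_similarity <- function(graph, t1, t2, w_isa = 0.8) {
  tab <- wang_sim_table(graph, data.frame(t1 = t1, t2 = t2), w_isa)
  tab$sim
}

#' Wang similarity for a table of pairs
#'
#' Vectorized version of [wang_similarity()] computing shortest-path
#' distances once per distinct term.
#'
#' @param graph An [ontology_graph()].
#' @param pairs data.frame with columns `t1`, `t2`.
#' @param w_isa is_a contribution factor in (0, 1).
#' @return A `similarity_table`: data.table `t1`, `t2`, `sim` with attribute
#'   `method = "WANG"`.
#' @export
wang_sim_table <- function(graph, pairs, w_isa = 0.8) {
  stopifnot(inherits(graph, "ontology_graph"), w_isa > 0, w_isa < 1)
  pairs <- as.data.table(pairs)[, .(t1, t2)]
  ids <- unique(c(pairs$t1, pairs$t2))
  missing <- setdiff(ids, graph$terms$id)
  if (length(missing)) stop("unknown term(s): ", paste(missing, collapse = ", "))
  obs <- intersect(ids, graph$terms$id[graph$terms$obsolete])
  if (length(obs)) stop("obsolete term(s): ", paste(obs, collapse = ", "))
  # d[i, ] = shortest is_a path lengths from term i to every node (Inf if
  # not an ancestor); semantic contribution S_i = w^d
  d <- igraph::distances(graph$graph, v = ids, mode = "out")
  S <- w_isa^d                      # Inf -> 0
  S[!is.finite(d)] <- 0
  sv <- rowSums(S)
  sim <- vapply(seq_len(nrow(pairs)), function(k) {
    s1 <- S[pairs$t1[k], ]; s2 <- S[pairs$t2[k], ]
    common <- s1 > 0 & s2 > 0
    if (!any(common)) return(0)
    sum(s1[common] + s2[common]) / (sv[pairs$t1[k]] + sv[pairs$t2[k]])
  }, numeric(1))
  .similarity_table(pairs[, .(t1, t2, sim = sim)], "WANG")
}

#' Gene-annotation similarity of two terms
#'
#' Overlap of the two annotated gene sets: cosine
#' `|G1 n G2| / sqrt(|G1| |G2|)` (default) or Jaccard
#' `|G1 n G2| / |G1 u G2|`. Terms without annotations are not scorable and
#' return `NA`.
#'
#' @param annotations An `annotation_table` from [load_annotations()].
#' @param t1,t2 Term ids (vectorized in parallel).
#' @param measure `"cosine"` or `"jaccard"`.
#' @return Similarity in `[0, 1]`, or `NA`.
#' @export
gene_similarity <- function(annotations, t1, t2,
                            measure = c("cosine", "jaccard")) {
  measure <- match.arg(measure)
  stopifnot(inherits(annotations, "annotation_table"),
            length(t1) == length(t2))
  mapply(function(a, b) {
    g1 <- term_genes(annotations, a); g2 <- term_genes(annotations, b)
    if (!length(g1) || !length(g2)) return(NA_real_)
    i <- length(intersect(g1, g2))
    if (measure == "cosine") i / sqrt(length(g1) * length(g2))
    else i / length(union(g1, g2))
  }, t1, t2, USE.NAMES = FALSE)
}

#' Gene similarity for a table of pairs
#' @inheritParams gene_similarity
#' @param pairs data.frame with columns `t1`, `t2`.
#' @return A `similarity_table` with method `"GENE_COSINE"` or
#'   `"GENE_JACCARD"`; unscorable pairs are dropped.
#' @export
gene_sim_table <- function(annotations, pairs,
                           measure = c("cosine", "jaccard")) {
  measure <- match.arg(measure)
  pairs <- as.data.table(pairs)[, .(t1, t2)]
  pairs[, sim := gene_similarity(annotations, t1, t2, measure)]
  .similarity_table(pairs[!is.na(sim)],
                    paste0("GENE_", toupper(measure)))
}

.similarity_table <- function(tab, method) {
  if (nrow(tab) && (any(tab$sim < 0) || any(tab$sim > 1)))
    stop("similarity outside [0, 1]")
  setattr(tab, "method", method)
  setattr(tab, "class", c("similarity_table", class(tab)))
  tab
}

#' @export
print.similarity_table <- function(x, ...) {
  cat(sprintf("<similarity_table> method=%s, %d pairs\n",
              attr(x, "method"), nrow(x)))
  invisible(x)
}

#' Pearson correlation between a score table and a similarity table
#'
#' Joins the two tables on the canonically ordered pair key and reports the
#' Pearson correlation with a two-sided p-value (t transform on
#' `n_pairs - 2` degrees of freedom, as in [stats::cor.test()]).
#'
#' @param score_table A `pair_scores` table.
#' @param sim_table A `similarity_table`.
#' @return An object of class `correlation_report`: list with `n_pairs`,
#'   `pearson_r`, `p_value`, `method_pair`.
#' @export
correlate <- function(score_table, sim_table) {
  stopifnot(inherits(score_table, "pair_scores"),
            inherits(sim_table, "similarity_table"))
  a <- .canonical_keyed(as.data.table(score_table)[, .(t1, t2, score)])
  b <- .canonical_keyed(as.data.table(sim_table)[, .(t1, t2, sim)])
  j <- merge(a, b, by = c("t1", "t2"))
  setorderv(j, c("t1", "t2"))
  if (nrow(j) < 3L)
    stop("insufficient data: only ", nrow(j), " shared pair(s); need >= 3")
  if (stats::sd(j$score) == 0 || stats::sd(j$sim) == 0)
    stop("undefined correlation: zero variance in one of the vectors")
  ct <- cor.test(j$score, j$sim, method = "pearson",
                 alternative = "two.sided")
  structure(
    list(n_pairs = nrow(j),
         pearson_r = unname(ct$estimate),
         p_value = ct$p.value,
         method_pair = c(attr(score_table, "method"),
                         attr(sim_table, "method"))),
    class = "correlation_report"
  )
}

.canonical_keyed <- function(tab) {
  swap <- tab$t1 > tab$t2
  if (any(swap)) {
    lo <- tab$t2[swap]; hi <- tab$t1[swap]
    tab$t1[swap] <- lo; tab$t2[swap] <- hi
  }
  unique(tab, by = c("t1", "t2"))
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %s vs %s: r = %.4f (p = %.3g, n = %d)\n",
              x$method_pair[1], x$method_pair[2],
              x$pearson_r, x$p_value, x$n_pairs))
  invisible(x)
}

#' Export paired score/similarity values for plotting
#'
#' Writes a TSV of `(term1, term2, score, similarity)` over the pairs shared
#' by the two tables — the data behind a score-versus-similarity scatter
#' plot.
#'
#' @param score_table A `pair_scores` table.
#' @param sim_table A `similarity_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly; warns when the intersection is empty.
#' @export
scatter_export <- function(score_table, sim_table, path) {
  a <- .canonical_keyed(as.data.table(score_table)[, .(t1, t2, score)])
  b <- .canonical_keyed(as.data.table(sim_table)[, .(t1, t2, sim)])
  j <- merge(a, b, by = c("t1", "t2"))
  setorderv(j, c("t1", "t2"))
  if (!nrow(j)) warning("no shared pairs; writing header only")
  setnames(j, c("term1", "term2", "score", "similarity"))
  fwrite(j, path, sep = "\t")
  invisible(path)
}
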
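# Relationship-degree scores over a co-occurrence index.
#
# RSS (relationship-scaled score), a mutual-information-style statistic over
# sentence-level counts:
#
#   RSS(t1, t2) = log10( COV(t1,t2) / (COV(t1,t1) * COV(t2,t2)) )
#
# linearly rescaled to [1, 100] over the score table at hand:
#
#   RSS_N = 1 + 99 * (RSS - RSS_min) / (RSS_max - RSS_min)
#
# NMD (Normalized MEDLINE Distance), the NGD-style distance over
# document-level counts D1, D2, D12 in a corpus of M documents:
#
#   NMD = (max(log D1, log D2) - log D12) / (log M - min(log D1, log D2))
#
# The log base cancels in the ratio; natural logs are used internally.
# The similarity transform is Sim = max(0, 1 - NMD), keeping the raw
# distance available for any alternative transform.

#' Raw relationship-scaled score of a pair
#'
#' `log10(COV(t1,t2) / (COV(t1,t1) * COV(t2,t2)))` over sentence-level
#' counts. Pairs with zero co-occurrence are not scorable and return `NA`
#' (they are excluded from tables, not assigned `-Inf`).
#'
#' @param index A [cooc_index()].
#' @param t1,t2 Term ids (vectorized in parallel).
#' @return Numeric score(s); `NA` where the pair never co-occurs.
#' @examples
#' idx <- cooc_index(M = 100, S = 2000,
#'                   sent_count = c(a = 100, b = 1000),
#'                   pair_sent = data.frame(t1 = "a", t2 = "b", cov = 10))
#' rss(idx, "a", "b")  # log10(10 / (100 * 1000)) = -4
#' @export
rss <- function(index, t1, t2) {
  stopifnot(inherits(index, "cooc_index"), length(t1) == length(t2))
  mapply(function(a, b) {
    c12 <- cov_sent(index, a, b)
    if (c12 == 0L) return(NA_real_)
    c1 <- cov_sent(index, a, a); c2 <- cov_sent(index, b, b)
    if (c1 == 0L || c2 == 0L) return(NA_real_)
    log10(c12 / (c1 * c2))
  }, t1, t2, USE.NAMES = FALSE)
}

#' Normalized MEDLINE Distance of a pair
#'
#' NGD-style distance over document-level counts; 0 for a pair with
#' identical document profiles (and for `t1 == t2`), growing as the
#' association weakens. Requires more documents in the corpus than either
#' term occurs in.
#'
#' @inheritParams rss
#' @return Numeric distance(s); `NA` where the pair shares no document.
#' @export
nmd <- function(index, t1, t2) {
  stopifnot(inherits(index, "cooc_index"), length(t1) == length(t2))
  M <- index$M
  mapply(function(a, b) {
    if (a == b) return(0)
    d1 <- cov_doc(index, a, a); d2 <- cov_doc(index, b, b)
    d12 <- cov_doc(index, a, b)
    if (d12 == 0L) return(NA_real_)
    if (d1 == 0L || d2 == 0L) return(NA_real_)
    if (M <= max(d1, d2))
      stop("degenerate corpus: M (", M, ") must exceed every document count")
    denom <- log(M) - min(log(d1), log(d2))
    (max(log(d1), log(d2)) - log(d12)) / denom
  }, t1, t2, USE.NAMES = FALSE)
}

#' Similarity transform of an NMD distance
#'
#' Relationship degree is inversely related to the distance; the bounded
#' transform `max(0, 1 - d)` maps distance 0 to similarity 1 and clamps
#' distances beyond 1 to 0.
#'
#' @param distance Non-negative numeric distance(s); `NA` passes through.
#' @return Similarity in `[0, 1]`.
#' @export
sim_nmd <- function(distance) {
  if (any(distance < 0, na.rm = TRUE)) stop("negative distance")
  pmax(0, 1 - distance)
}

#' Construct a pair-score table
#' @noRd
.pair_scores <- function(tab, method, index = NULL,
                         rss_min = NA_real_, rss_max = NA_real_) {
  setattr(tab, "method", method)
  setattr(tab, "rss_min", rss_min)
  setattr(tab, "rss_max", rss_max)
  if (!is.null(index)) {
    setattr(tab, "M", index$M)
    setattr(tab, "S", index$S)
  }
  setattr(tab, "class", c("pair_scores", class(tab)))
  tab
}

#' @export
print.pair_scores <- function(x, ...) {
  cat(sprintf("<pair_scores> method=%s, %d pairs\n",
              attr(x, "method"), nrow(x)))
  if (nrow(x)) print(as.data.table(head(x, 5)))
  invisible(x)
}

#' Rescale raw RSS scores to [1, 100]
#'
#' Applies the linear normalization `1 + 99 * (RSS - RSS_min) /
#' (RSS_max - RSS_min)` over exactly the pairs of the given table; the
#' observed bounds are recorded in the result's `rss_min` / `rss_max`
#' attributes. A table with a single distinct raw value maps entirely to
#' 100, with a warning.
#'
#' @param raw_table A `pair_scores` table with method `"RSS"`.
#' @return A `pair_scores` table with method `"RSS_N"`, scores in
#'   `[1, 100]`.
#' @export
normalize_rss <- function(raw_table) {
  stopifnot(inherits(raw_table, "pair_scores"),
            identical(attr(raw_table, "method"), "RSS"))
  if (!nrow(raw_table)) stop("empty raw RSS table")
  tab <- copy(as.data.table(raw_table))
  lo <- min(tab$score); hi <- max(tab$score)
  if (hi == lo) {
    warning("all raw RSS values identical; every pair assigned 100")
    tab[, score := 100]
  } else {
    tab[, score := 1 + 99 * (score - lo) / (hi - lo)]
  }
  out <- .pair_scores(tab, "RSS_N", rss_min = lo, rss_max = hi)
  setattr(out, "M", attr(raw_table, "M"))
  setattr(out, "S", attr(raw_table, "S"))
  out
}

#' Score every co-occurring pair of an index
#'
#' Applies the chosen scorer to every pair from [pair_list()]; for
#' `"rss_n"` the normalization bounds are taken over exactly this pair set.
#'
#' @param index A [cooc_index()].
#' @param method `"rss"`, `"rss_n"`, `"nmd"` or `"sim_nmd"`.
#' @param min_cov Minimum sentence co-occurrence count for a pair to be
#'   scored (default 1).
#' @return A `pair_scores` data.table (`t1`, `t2`, `score`) with attributes
#'   `method`, `rss_min`, `rss_max`, `M`, `S`.
#' @export
score_all <- function(index, method = c("rss", "rss_n", "nmd", "sim_nmd"),
                      min_cov = 1L) {
  method <- match.arg(method)
  pairs <- pair_list(index, min_cov)
  if (!nrow(pairs)) {
    warning("no pairs at min_cov=", min_cov, "; empty score table")
    tab <- data.table(t1 = character(), t2 = character(), score = numeric())
    return(.pair_scores(tab, toupper(method), index))
  }
  tab <- pairs[, .(t1, t2)]
  raw <- switch(method,
    rss = , rss_n = rss(index, tab$t1, tab$t2),
    nmd = , sim_nmd = nmd(index, tab$t1, tab$t2)
  )
  tab[, score := raw]
  tab <- tab[!is.na(score)]
  out <- .pair_scores(tab, toupper(method), index)
  switch(method,
    rss = out,
    rss_n = {
      attr(out, "method") <- "RSS"
      normalize_rss(out)
    },
    nmd = out,
    sim_nmd = {
      tab[, score := sim_nmd(score)]
      .pair_scores(tab, "SIM_NMD", index)
    }
  )
}

#' Write a score table as TSV
#'
#' Columns `term1`, `term2`, `score` preceded by a `#` metadata header
#' recording the method, corpus sizes and RSS normalization bounds.
#'
#' @param scores A `pair_scores` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "pair_scores"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# method=%s M=%s S=%s rss_min=%s rss_max=%s",
    attr(scores, "method"),
    attr(scores, "M") %||% NA, attr(scores, "S") %||% NA,
    format(attr(scores, "rss_min")), format(attr(scores, "rss_max"))
  ), con)
  writeLines("term1\tterm2\tscore", con)
  if (nrow(scores))
    write.table(as.data.table(scores)[, .(t1, t2, score)], con, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_scores()]
#' @param path TSV path.
#' @return A `pair_scores` table.
#' @export
read_scores <- function(path) {
  hdr <- readLines(path, n = 1L)
  field <- function(k) {
    m <- regmatches(hdr, regexpr(paste0(k, "=[^ ]+"), hdr))
    if (!length(m)) return(NA)
    sub(paste0(k, "="), "", m)
  }
  tab <- if (length(readLines(path, warn = FALSE)) > 2L)
    fread(path, skip = 2L, header = FALSE,
          col.names = c("t1", "t2", "score"),
          colClasses = list(character = 1:2, numeric = 3))
  else data.table(t1 = character(), t2 = character(), score = numeric())
  out <- .pair_scores(tab, field("method"),
                      rss_min = as.numeric(field("rss_min")),
                      rss_max = as.numeric(field("rss_max")))
  setattr(out, "M", suppressWarnings(as.integer(field("M"))))
  setattr(out, "S", suppressWarnings(as.integer(field("S"))))
  out
}
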
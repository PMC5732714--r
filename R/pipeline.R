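# End-to-end pipeline: segment -> annotate -> filter -> index -> score
# (-> validate) (-> network), with plain-text intermediates so any stage can
# be inspected, replaced, or resumed.

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and `#`
#' comments ignored. Unknown keys are rejected against the set understood
#' by [run_pipeline()].
#'
#' @param path Config file path.
#' @return Named list of character values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 0L) != 3L]
  if (length(bad)) stop("malformed config line: ", bad[1])
  cfg <- setNames(lapply(kv, function(m) trimws(m[3])),
                  vapply(kv, `[`, "", 2L))
  unknown <- setdiff(names(cfg), .pipeline_keys())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}

.pipeline_keys <- function() {
  c("corpus", "corpus_format", "obo", "namespace", "annotations", "out",
    "min_cov", "method", "min_token_length", "threshold", "replicates",
    "seed", "validate", "network", "resume", "include_title")
}

#' Run the full term-association pipeline
#'
#' Executes segment, annotate (term matching), sentence filter, index and
#' score stages in order, then optionally the validation (Wang and gene
#' similarity correlations) and network stages. Each stage writes a
#' plain-text intermediate under `out`; with `resume = TRUE` a stage whose
#' output file already exists is reused rather than recomputed. Stage
#' counts (documents, sentences, mentions, kept sentences, scored pairs)
#' are logged, and a provenance manifest (parameters, input digests,
#' package version, timestamp) is written as `manifest.json`.
#'
#' @param config Named list or path to a key = value file (see
#'   [read_config()]). Recognized keys: `corpus`, `corpus_format`
#'   (`jsonl`/`medline_xml`), `obo` (comma-separated OBO paths),
#'   `namespace` (optional filter), `annotations` (optional, enables the
#'   gene-similarity validation), `out` (output directory), `min_cov`,
#'   `method` (`rss`/`rss_n`/`nmd`/`sim_nmd`), `min_token_length`,
#'   `threshold` (enables the network stage), `replicates`, `seed`,
#'   `validate` (`true`/`false`), `network` (`true`/`false`), `resume`,
#'   `include_title`.
#' @return Invisibly, a named list of stage outputs (paths and in-memory
#'   results).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  stopifnot(is.list(config), !is.null(config$corpus), !is.null(config$obo),
            !is.null(config$out))
  unknown <- setdiff(names(config), .pipeline_keys())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  fmt <- config$corpus_format %||% "jsonl"
  method <- config$method %||% "rss_n"
  min_cov <- as.integer(config$min_cov %||% 1L)
  mtl <- as.integer(config$min_token_length %||% 3L)
  seed <- as.integer(config$seed %||% 1L)
  resume <- isTRUE(as.logical(config$resume %||% FALSE))
  .stage <- function(path, compute, read, write) {
    if (resume && file.exists(path)) {
      message("[cooclink] reusing ", path)
      return(read(path))
    }
    x <- compute()
    tmp <- paste0(path, ".partial")
    ok <- FALSE
    on.exit(if (!ok && file.exists(tmp)) invisible(NULL), add = TRUE)
    write(x, tmp)
    file.rename(tmp, path)
    ok <- TRUE
    x
  }

  obo_paths <- trimws(strsplit(config$obo, ",")[[1]])
  ontologies <- lapply(obo_paths, load_obo,
                       namespace_filter = config$namespace)
  docs <- read_corpus(config$corpus, format = fmt,
                      include_title = isTRUE(as.logical(config$include_title %||% FALSE)))
  message("[cooclink] documents: ", nrow(docs))

  sentences <- .stage(file.path(out, "sentences.tsv"),
    compute = function() segment_sentences(docs),
    read = function(p) fread(p, colClasses = list(character = c(1, 3))),
    write = function(x, p) fwrite(x, p, sep = "\t"))
  message("[cooclink] sentences: ", nrow(sentences))

  dict <- build_dictionary(ontologies, min_token_length = mtl)
  mentions <- .stage(file.path(out, "mentions.tsv"),
    compute = function() match_terms(sentences, dict),
    read = function(p) fread(p, colClasses = list(character = c(1, 3, 6))),
    write = function(x, p) fwrite(x, p, sep = "\t"))
  message("[cooclink] mentions: ", nrow(mentions))

  kept <- filter_sentences(mentions)
  message("[cooclink] kept sentences (>= 2 distinct terms): ",
          uniqueN(kept[, .(doc_id, sentence_index)]))

  index_dir <- file.path(out, "index")
  if (resume && dir.exists(index_dir) &&
      file.exists(file.path(index_dir, "index_sentence.tsv"))) {
    message("[cooclink] reusing ", index_dir)
    index <- read_index(index_dir)
  } else {
    index <- build_index(docs, sentences, kept)
    write_index(index, index_dir)
  }

  scores <- .stage(file.path(out, "scores.tsv"),
    compute = function() score_all(index, method = method, min_cov = min_cov),
    read = read_scores,
    write = function(x, p) write_scores(x, p))
  message("[cooclink] scored pairs: ", nrow(scores))

  results <- list(sentences = file.path(out, "sentences.tsv"),
                  mentions = file.path(out, "mentions.tsv"),
                  index = index_dir, scores = file.path(out, "scores.tsv"),
                  score_table = scores)

  if (isTRUE(as.logical(config$validate %||% FALSE))) {
    pairs <- as.data.table(scores)[, .(t1, t2)]
    reports <- list()
    for (g in ontologies) {
      inside <- pairs[t1 %chin% g$terms$id & t2 %chin% g$terms$id]
      if (nrow(inside) >= 3L) {
        wt <- wang_sim_table(g, inside)
        sub <- .pair_scores(as.data.table(scores)[inside, on = c("t1", "t2")],
                            attr(scores, "method"))
        rep <- tryCatch(correlate(sub, wt), error = function(e) NULL)
        if (!is.null(rep)) reports[[length(reports) + 1L]] <- rep
      }
    }
    if (!is.null(config$annotations)) {
      ann <- load_annotations(config$annotations)
      gt <- gene_sim_table(ann, pairs)
      rep <- tryCatch(correlate(scores, gt), error = function(e) NULL)
      if (!is.null(rep)) reports[[length(reports) + 1L]] <- rep
    }
    vfile <- file.path(out, "validation.json")
    jsonlite::write_json(lapply(reports, function(r)
      list(methods = r$method_pair, n_pairs = r$n_pairs,
           pearson_r = r$pearson_r, p_value = r$p_value)),
      vfile, auto_unbox = TRUE, digits = NA)
    message("[cooclink] validation reports: ", length(reports))
    results$validation <- vfile
  }

  if (!is.null(config$threshold) || isTRUE(as.logical(config$network %||% FALSE))) {
    th <- as.numeric(config$threshold %||% 60)
    net <- build_network(scores, th)
    fwrite(net$edges, file.path(out, "network_edges.tsv"), sep = "\t")
    rep <- network_report(net,
                          n_replicates = as.integer(config$replicates %||% 1000L),
                          seed = seed)
    jsonlite::write_json(rep, file.path(out, "network_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    message("[cooclink] network: ", rep$n_nodes, " nodes, ",
            rep$n_edges, " edges")
    results$network <- file.path(out, "network_stats.json")
  }

  inputs <- c(config$corpus, obo_paths,
              if (!is.null(config$annotations)) config$annotations)
  manifest <- list(
    tool = "cooclink",
    version = as.character(utils::packageVersion("cooclink")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[order(names(config))],
    input_digests = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- file.path(out, "manifest.json")
  invisible(results)
}
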
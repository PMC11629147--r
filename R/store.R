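# Named-graph triple store behind a minimal contract: load batches, run
# SPARQL SELECTs over the union of graphs, expose the merged dataset schema.

#' Create an empty triple store
#'
#' An in-memory store organised as named graphs (one per integrated file by
#' convention); the default graph for querying is the union of all named
#' graphs.
#'
#' @return an object of class `triplestore`.
#' @export
triplestore <- function() {
  env <- new.env(parent = emptyenv())
  env$triples <- cbind(data.frame(g = character(), stringsAsFactors = FALSE),
                       triple_df())
  env$graphs <- data.frame(name = character(), source = character(),
                           triple_count = integer(), stringsAsFactors = FALSE)
  env$schema <- list()
  structure(env, class = "triplestore")
}

#' @export
print.triplestore <- function(x, ...) {
  cat("<triplestore> ", nrow(x$triples), " triple(s) in ", nrow(x$graphs),
      " graph(s), ", length(x$schema), " class(es)\n", sep = "")
  invisible(x)
}

#' Load a triple batch into its named graph
#'
#' Loading is idempotent (set semantics): reloading an identical batch leaves
#' the graph unchanged.
#'
#' @param store a [triplestore()].
#' @param batch a [triple_batch()].
#' @param schema optional list of [entity_class_def()] to register alongside
#'   (unioned into the store's merged schema).
#' @param source free-text label of the batch's origin (file path etc.).
#' @return a named-graph reference: list with `name`, `triple_count` (distinct
#'   triples now in the graph), `added` (new triples this load) and `source`.
#' @export
load_graph <- function(store, batch, schema = NULL, source = NA_character_) {
  stopifnot(inherits(store, "triplestore"), inherits(batch, "triple_batch"))
  g <- batch$graph_name
  incoming <- cbind(data.frame(g = rep(g, nrow(batch$triples)),
                               stringsAsFactors = FALSE), batch$triples)
  before <- sum(store$triples$g == g)
  all_g <- rbind(store$triples[store$triples$g == g, , drop = FALSE], incoming)
  key <- paste(all_g$s, all_g$p, all_g$o, all_g$ot, sep = "\r")
  all_g <- all_g[!duplicated(key), , drop = FALSE]
  store$triples <- rbind(store$triples[store$triples$g != g, , drop = FALSE], all_g)
  rownames(store$triples) <- NULL
  count <- nrow(all_g)
  gi <- which(store$graphs$name == g)
  if (length(gi)) {
    store$graphs$triple_count[gi] <- count
    if (!is.na(source)) store$graphs$source[gi] <- source
  } else {
    store$graphs <- rbind(store$graphs,
                          data.frame(name = g, source = source,
                                     triple_count = count, stringsAsFactors = FALSE))
  }
  if (!is.null(schema)) store$schema <- merge_schemas(c(store$schema, schema))
  list(name = g, triple_count = count, added = count - before, source = source)
}

#' List the named graphs of a store
#' @param store a [triplestore()].
#' @return data.frame with `name`, `source`, `triple_count`.
#' @export
list_graphs <- function(store) store$graphs

#' Run a SPARQL SELECT over the store
#'
#' The query is evaluated against the union of all named graphs
#' (default-graph-as-union). An empty store yields an empty result, not an
#' error.
#'
#' @param store a [triplestore()].
#' @param sparql SPARQL 1.1 SELECT string (the supported fragment covers
#'   basic graph patterns, FILTER expressions, DISTINCT, COUNT(DISTINCT),
#'   ORDER BY and LIMIT).
#' @return data.frame of bindings, one column per projected variable, with a
#'   `"kinds"` attribute naming each column's term kind.
#' @export
run_select <- function(store, sparql) {
  stopifnot(inherits(store, "triplestore"), is.character(sparql))
  q <- sparql_parse(sparql)
  eval_sparql(store$triples, q)
}

#' Merged dataset schema of everything loaded
#' @param store a [triplestore()].
#' @return list of [entity_class_def()] (set-union of all loaded schemas).
#' @export
merged_schema <- function(store) store$schema

# --- serialization ---------------------------------------------------------

escape_nt <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

format_nt_object <- function(o, ot) {
  out <- character(length(o))
  iri <- ot == "iri"
  out[iri] <- paste0("<", o[iri], ">")
  if (any(!iri))
    out[!iri] <- paste0("\"", escape_nt(o[!iri]), "\"^^<",
                        vapply(ot[!iri], xsd_for, character(1)), ">")
  out
}

#' Export triples as N-Triples
#'
#' @param store a [triplestore()].
#' @param path output file; when `NULL` the lines are returned invisibly.
#' @param graph restrict to one named graph (IRI); default exports the union.
#' @return character vector of N-Triples lines, invisibly.
#' @export
export_ntriples <- function(store, path = NULL, graph = NULL) {
  df <- store$triples
  if (!is.null(graph)) df <- df[df$g == graph, , drop = FALSE]
  lines <- if (nrow(df) == 0L) character()
           else paste0("<", df$s, "> <", df$p, "> ", format_nt_object(df$o, df$ot), " .")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Export triples as Turtle
#'
#' A plain serialization: prefix header plus one triple per line.
#'
#' @inheritParams export_ntriples
#' @return character vector of Turtle lines, invisibly.
#' @export
export_turtle <- function(store, path = NULL, graph = NULL) {
  df <- store$triples
  if (!is.null(graph)) df <- df[df$g == graph, , drop = FALSE]
  header <- c(paste0("@prefix rdf: <", RDF_NS, "> ."),
              paste0("@prefix rdfs: <", RDFS_NS, "> ."),
              paste0("@prefix xsd: <", XSD_NS, "> ."),
              paste0("@prefix faldo: <", FALDO_NS, "> ."), "")
  body <- if (nrow(df) == 0L) character()
          else paste0("<", df$s, "> <", df$p, "> ", format_nt_object(df$o, df$ot), " .")
  lines <- c(header, body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

unescape_nt <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  x <- gsub("\\\\", "\\", x, fixed = TRUE)
  x
}

#' Parse N-Triples into a triple batch
#'
#' @param lines character vector of N-Triples lines, or a path to a file.
#' @param graph_name named graph for the parsed batch.
#' @return a [triple_batch()].
#' @export
parse_ntriples <- function(lines, graph_name = paste0(default_namespace(), "/graph/imported")) {
  if (length(lines) == 1L && !grepl("\n", lines) && file.exists(lines))
    lines <- readLines(lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  n <- length(lines)
  s <- character(n); p <- character(n); o <- character(n); ot <- character(n)
  re <- paste0("^<([^>]*)>\\s+<([^>]*)>\\s+(.*)\\s*\\.\\s*$")
  for (i in seq_len(n)) {
    m <- regmatches(lines[i], regexec(re, lines[i]))[[1]]
    if (length(m) != 4L) stop("N-Triples parse error at line ", i, ": ", lines[i])
    s[i] <- m[2]; p[i] <- m[3]
    obj <- trimws(m[4])
    if (startsWith(obj, "<")) {
      o[i] <- sub("^<(.*)>$", "\\1", obj); ot[i] <- "iri"
    } else if (startsWith(obj, "\"")) {
      lm <- regmatches(obj, regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^<([^>]*)>)?$',
                                    obj, perl = TRUE))[[1]]
      if (length(lm) < 2L) stop("N-Triples literal parse error at line ", i)
      o[i] <- unescape_nt(lm[2])
      dt <- if (length(lm) >= 3L && nzchar(lm[3])) sub(".*#", "", lm[3]) else "string"
      ot[i] <- switch(dt, integer = "integer", int = "integer",
                      decimal = "decimal", double = "decimal", float = "decimal",
                      "string")
    } else stop("N-Triples parse error at line ", i, ": unsupported object ", obj)
  }
  triple_batch(triple_df(s, p, o, ot), graph_name)
}

# --- persistence -----------------------------------------------------------

#' Save a store to a directory
#'
#' Writes one N-Triples file per named graph, a graph manifest, and the
#' merged schema (JSON), so a CLI session can resume it.
#'
#' @param store a [triplestore()].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gs <- store$graphs
  gs$file <- paste0("graph-", seq_len(nrow(gs)), ".nt")
  for (i in seq_len(nrow(gs)))
    export_ntriples(store, file.path(dir, gs$file[i]), graph = gs$name[i])
  jsonlite::write_json(gs, file.path(dir, "graphs.json"), auto_unbox = TRUE)
  schema <- lapply(store$schema, function(cl)
    list(label = cl$label, namespace = cl$namespace, is_located = cl$is_located,
         properties = cl$properties))
  jsonlite::write_json(schema, file.path(dir, "schema.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Open a store saved with [save_store()]
#' @param dir directory written by [save_store()].
#' @return a [triplestore()].
#' @export
open_store <- function(dir) {
  store <- triplestore()
  gpath <- file.path(dir, "graphs.json")
  if (!file.exists(gpath)) stop("not a saved store (missing graphs.json): ", dir)
  gs <- jsonlite::read_json(gpath, simplifyVector = TRUE)
  for (i in seq_len(nrow(gs))) {
    batch <- parse_ntriples(file.path(dir, gs$file[i]), graph_name = gs$name[i])
    load_graph(store, batch, source = gs$source[i])
  }
  spath <- file.path(dir, "schema.json")
  if (file.exists(spath)) {
    raw <- jsonlite::read_json(spath, simplifyVector = FALSE)
    store$schema <- merge_schemas(lapply(raw, function(cl) {
      props <- if (length(cl$properties))
        do.call(rbind, lapply(cl$properties, function(p)
          data.frame(label = p$label, kind = p$kind, range = p$range,
                     stringsAsFactors = FALSE)))
      else NULL
      entity_class_def(cl$label, cl$namespace, isTRUE(cl$is_located), props)
    }))
  }
  store
}
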
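# Abstract query graphs: entity nodes with filters, edges that are either
# declared relations or genomic-overlap constraints. Compiles to SPARQL.

#' Define a query node
#'
#' @param var SPARQL variable name (without `?`), unique within the graph.
#' @param entity_class class the node ranges over (must exist in the merged
#'   schema at compile time).
#' @param filters list of `list(property, op, value)` constraints; `op` is one
#'   of `=`, `!=`, `<`, `<=`, `>`, `>=`, `contains`. The built-in properties
#'   `label`, `chromosome`, `start`, `end`, `strand` are always available.
#' @param select property labels to project alongside the node variable.
#' @return list of class `query_node`.
#' @export
query_node <- function(var, entity_class, filters = list(), select = character()) {
  stopifnot(is.character(var), length(var) == 1L, nzchar(var),
            is.character(entity_class), length(entity_class) == 1L)
  for (f in filters) {
    stopifnot(length(f) >= 3L)
    if (!f[[2]] %in% c("=", "!=", "<", "<=", ">", ">=", "contains"))
      stop("unsupported filter comparator: ", f[[2]])
  }
  structure(list(var = var, entity_class = entity_class,
                 filters = filters, select = as.character(select)),
            class = "query_node")
}

#' Define a query edge
#'
#' @param from_var,to_var node variables the edge connects.
#' @param kind `"relation"` (a declared `label@Target` / parent relation) or
#'   `"overlap"` (a genomic-interval join through the FALDO nodes).
#' @param relation_label relation property label (kind = relation).
#' @param overlap_mode `"any_overlap"` (closed 1-based intervals intersect),
#'   `"a_within_b"` or `"b_within_a"` (containment).
#' @param strand_policy `"ignore"` or `"same_strand"`.
#' @return list of class `query_edge`.
#' @export
query_edge <- function(from_var, to_var, kind = c("relation", "overlap"),
                       relation_label = NULL,
                       overlap_mode = c("any_overlap", "a_within_b", "b_within_a"),
                       strand_policy = c("ignore", "same_strand")) {
  kind <- match.arg(kind)
  if (kind == "relation" && (is.null(relation_label) || !nzchar(relation_label)))
    stop("relation edges need a relation_label")
  structure(list(from_var = from_var, to_var = to_var, kind = kind,
                 relation_label = relation_label,
                 overlap_mode = match.arg(overlap_mode),
                 strand_policy = match.arg(strand_policy)),
            class = "query_edge")
}

#' Assemble a query graph
#'
#' @param nodes list of [query_node()] (at least one).
#' @param edges list of [query_edge()]; the graph must be connected.
#' @param count_distinct optional node variable: compile to
#'   `COUNT(DISTINCT ?var)` instead of projecting bindings.
#' @return list of class `query_graph`.
#' @export
query_graph <- function(nodes, edges = list(), count_distinct = NULL) {
  if (inherits(nodes, "query_node")) nodes <- list(nodes)
  if (inherits(edges, "query_edge")) edges <- list(edges)
  stopifnot(length(nodes) >= 1L)
  vars <- vapply(nodes, `[[`, character(1), "var")
  if (anyDuplicated(vars)) stop("duplicate node variables")
  for (e in edges) {
    if (!all(c(e$from_var, e$to_var) %in% vars))
      stop("edge endpoint not a node variable: ", e$from_var, " / ", e$to_var)
  }
  # connectivity check
  if (length(nodes) > 1L) {
    reach <- vars[1]
    repeat {
      grew <- FALSE
      for (e in edges) {
        if (e$from_var %in% reach && !(e$to_var %in% reach)) { reach <- c(reach, e$to_var); grew <- TRUE }
        if (e$to_var %in% reach && !(e$from_var %in% reach)) { reach <- c(reach, e$from_var); grew <- TRUE }
      }
      if (!grew) break
    }
    if (!setequal(reach, vars)) stop("query graph is not connected")
  }
  if (!is.null(count_distinct) && !count_distinct %in% vars)
    stop("count_distinct must name a node variable")
  structure(list(nodes = nodes, edges = edges, count_distinct = count_distinct),
            class = "query_graph")
}

#' @export
print.query_graph <- function(x, ...) {
  cat("<query_graph> ", length(x$nodes), " node(s), ", length(x$edges),
      " edge(s)", if (!is.null(x$count_distinct))
        paste0(", COUNT(DISTINCT ?", x$count_distinct, ")"), "\n", sep = "")
  invisible(x)
}

# --- JSON (de)serialization so saved queries are shareable ------------------

#' Serialize a query graph to JSON
#' @param q a [query_graph()].
#' @param path optional file to write.
#' @return JSON string, invisibly when `path` is given.
#' @export
write_query_graph <- function(q, path = NULL) {
  doc <- list(
    nodes = lapply(q$nodes, function(n) list(
      var = n$var, entity_class = n$entity_class,
      filters = lapply(n$filters, function(f)
        list(property = f[[1]], op = f[[2]], value = f[[3]])),
      select = as.list(n$select))),
    edges = lapply(q$edges, function(e) list(
      from_var = e$from_var, to_var = e$to_var, kind = e$kind,
      relation_label = e$relation_label, overlap_mode = e$overlap_mode,
      strand_policy = e$strand_policy)),
    count_distinct = q$count_distinct)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read a query graph from JSON
#' @param json JSON string or file path.
#' @return a [query_graph()].
#' @export
read_query_graph <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  nodes <- lapply(doc$nodes, function(n)
    query_node(n$var, n$entity_class,
               filters = lapply(n$filters, function(f) list(f$property, f$op, f$value)),
               select = unlist(n$select) %||% character()))
  edges <- lapply(doc$edges, function(e)
    query_edge(e$from_var, e$to_var, e$kind,
               relation_label = e$relation_label,
               overlap_mode = e$overlap_mode %||% "any_overlap",
               strand_policy = e$strand_policy %||% "ignore"))
  query_graph(nodes, edges, count_distinct = doc$count_distinct)
}
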
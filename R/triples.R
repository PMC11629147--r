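# Triple batches: the unit of data exchange between converters and the store.
#
# A batch is a data.frame of triples with set semantics plus the named graph
# it is destined for. Objects are either IRIs or typed literals; the `ot`
# column records which ("iri", "string", "integer", "decimal").

triple_df <- function(s = character(), p = character(), o = character(),
                      ot = character()) {
  data.frame(s = as.character(s), p = as.character(p), o = as.character(o),
             ot = as.character(ot), stringsAsFactors = FALSE)
}

dedupe_triples <- function(df) {
  if (nrow(df) == 0L) return(df)
  key <- paste(df$s, df$p, df$o, df$ot, sep = "\r")
  out <- df[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Create a triple batch
#'
#' @param df data.frame with columns `s`, `p`, `o`, `ot` (`ot` is one of
#'   `"iri"`, `"string"`, `"integer"`, `"decimal"`). Duplicate triples are
#'   dropped (RDF set semantics).
#' @param graph_name IRI of the named graph the batch belongs to.
#' @return an object of class `triple_batch`.
#' @export
triple_batch <- function(df = triple_df(), graph_name = paste0(default_namespace(), "/graph/default")) {
  stopifnot(is.data.frame(df), all(c("s", "p", "o", "ot") %in% names(df)))
  bad <- !df$ot %in% c("iri", "string", "integer", "decimal")
  if (any(bad)) stop("unknown object type(s): ", paste(unique(df$ot[bad]), collapse = ", "))
  structure(list(triples = dedupe_triples(df[c("s", "p", "o", "ot")]),
                 graph_name = graph_name),
            class = "triple_batch")
}

#' @export
print.triple_batch <- function(x, ...) {
  cat("<triple_batch> ", nrow(x$triples), " triple(s) in graph <",
      x$graph_name, ">\n", sep = "")
  invisible(x)
}

#' Number of triples in a batch
#' @param batch a `triple_batch`.
#' @return integer count of distinct triples.
#' @export
n_triples <- function(batch) nrow(batch$triples)

#' Merge triple batches (set union)
#' @param ... `triple_batch` objects.
#' @param graph_name graph for the merged batch; defaults to the first input's.
#' @return a `triple_batch`.
#' @export
merge_batches <- function(..., graph_name = NULL) {
  batches <- list(...)
  if (length(batches) == 1L && is.list(batches[[1]]) && !inherits(batches[[1]], "triple_batch"))
    batches <- batches[[1]]
  stopifnot(length(batches) >= 1L)
  if (is.null(graph_name)) graph_name <- batches[[1]]$graph_name
  df <- do.call(rbind, lapply(batches, function(b) b$triples))
  triple_batch(df, graph_name)
}

# Literal constructors ------------------------------------------------------

lit_string  <- function(x) list(o = as.character(x), ot = "string")
lit_integer <- function(x) list(o = format(as.integer(x), scientific = FALSE), ot = "integer")
lit_decimal <- function(x) {
  list(o = vapply(as.numeric(x), function(v) format(v, scientific = FALSE, digits = 15),
                  character(1)),
       ot = "decimal")
}

xsd_for <- function(ot) {
  switch(ot,
    string  = paste0(XSD_NS, "string"),
    integer = paste0(XSD_NS, "integer"),
    decimal = paste0(XSD_NS, "decimal"),
    stop("no xsd type for ", ot))
}
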
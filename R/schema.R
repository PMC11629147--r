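# Dataset schemas: self-describing class/property definitions that travel
# with every converted dataset and drive query validation.

#' Define an entity class
#'
#' @param label class name (unique within a dataset schema).
#' @param namespace project namespace the class IRI is minted under.
#' @param is_located whether instances carry a genomic region.
#' @param properties data.frame with columns `label`, `kind`
#'   (`"attribute"`/`"relation"`) and `range` (a literal type
#'   `string`/`integer`/`decimal` for attributes, a class label for
#'   relations). May be empty.
#' @return a list of class `entity_class_def`.
#' @export
entity_class_def <- function(label, namespace = default_namespace(),
                             is_located = FALSE, properties = NULL) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (is.null(properties))
    properties <- data.frame(label = character(), kind = character(),
                             range = character(), stringsAsFactors = FALSE)
  stopifnot(all(c("label", "kind", "range") %in% names(properties)))
  bad <- !properties$kind %in% c("attribute", "relation")
  if (any(bad)) stop("property kind must be attribute or relation")
  properties <- properties[!duplicated(properties[c("label", "kind", "range")]), ,
                           drop = FALSE]
  rownames(properties) <- NULL
  structure(list(label = label,
                 uri = class_uri(namespace, label),
                 namespace = namespace,
                 is_located = isTRUE(is_located),
                 properties = properties[c("label", "kind", "range")]),
            class = "entity_class_def")
}

#' @export
print.entity_class_def <- function(x, ...) {
  cat("<class> ", x$label, if (x$is_located) " [located]" else "", "  (",
      nrow(x$properties), " propert", if (nrow(x$properties) == 1) "y" else "ies",
      ")\n", sep = "")
  invisible(x)
}

#' Merge dataset schemas
#'
#' Classes sharing a label are collapsed to one definition: located if any
#' contributor is located, properties unioned as a set.
#'
#' @param ... `entity_class_def` objects or lists of them.
#' @return list of `entity_class_def`, one per distinct label.
#' @export
merge_schemas <- function(...) {
  defs <- list(...)
  flat <- list()
  for (d in defs) {
    if (inherits(d, "entity_class_def")) flat[[length(flat) + 1L]] <- d
    else flat <- c(flat, d)
  }
  out <- list()
  for (d in flat) {
    stopifnot(inherits(d, "entity_class_def"))
    if (is.null(out[[d$label]])) {
      out[[d$label]] <- d
    } else {
      cur <- out[[d$label]]
      props <- rbind(cur$properties, d$properties)
      out[[d$label]] <- entity_class_def(cur$label, cur$namespace,
                                         cur$is_located || d$is_located, props)
    }
  }
  unname(out)
}

#' Serialize a dataset schema as RDFS triples
#'
#' Declares each class (`rdfs:Class` + label), each property
#' (`rdf:Property` + kind marker via its `rdfs:range`: an XSD datatype for
#' attributes, the target class IRI for relations, with `rdfs:domain` the
#' declaring class), and links located classes to the FALDO `Region`
#' abstraction.
#'
#' @param classes list of [entity_class_def()] (labels must be unique).
#' @param graph_name named graph for the schema triples.
#' @return a [triple_batch()].
#' @export
schema_triples <- function(classes, graph_name = paste0(default_namespace(), "/graph/schema")) {
  labels <- vapply(classes, `[[`, character(1), "label")
  dup <- unique(labels[duplicated(labels)])
  if (length(dup))
    stop("duplicate class label(s) in schema: ", paste(dup, collapse = ", "))
  df <- triple_df()
  for (cl in classes) {
    rows <- triple_df(
      s = c(cl$uri, cl$uri),
      p = c(RDF_TYPE, RDFS_LABEL),
      o = c(RDFS_CLASS, cl$label),
      ot = c("iri", "string"))
    if (cl$is_located)
      rows <- rbind(rows, triple_df(cl$uri, OMI_LOCATED, FALDO_REGION, "iri"))
    if (nrow(cl$properties)) {
      for (i in seq_len(nrow(cl$properties))) {
        pr <- cl$properties[i, ]
        puri <- property_uri(cl$namespace, cl$label, pr$label)
        rng <- if (pr$kind == "attribute") xsd_for(pr$range)
               else class_uri(cl$namespace, pr$range)
        rows <- rbind(rows, triple_df(
          s = c(puri, puri, puri, puri),
          p = c(RDF_TYPE, RDFS_LABEL, RDFS_DOMAIN, RDFS_RANGE),
          o = c(RDF_PROP, pr$label, cl$uri, rng),
          ot = c("iri", "string", "iri", "iri")))
      }
    }
    df <- rbind(df, rows)
  }
  triple_batch(df, graph_name)
}

# (class label, property label) -> predicate IRI + kind, honoring built-ins.
resolve_property <- function(schema, class_label, property) {
  b <- builtin_predicate(property)
  if (!is.null(b)) return(list(uri = b, kind = "attribute",
                               range = BUILTIN_ATTRS$range[BUILTIN_ATTRS$label == property]))
  for (cl in schema) {
    if (cl$label != class_label) next
    hit <- cl$properties[cl$properties$label == property, , drop = FALSE]
    if (nrow(hit)) {
      return(list(uri = property_uri(cl$namespace, class_label, property),
                  kind = hit$kind[1], range = hit$range[1]))
    }
  }
  NULL
}

schema_class <- function(schema, label) {
  for (cl in schema) if (cl$label == label) return(cl)
  NULL
}
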
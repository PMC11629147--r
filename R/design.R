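# Experimental-design vocabulary: Condition, Context (aggregates Conditions),
# Contrast (compares two Contexts). Differential results attach to Contrasts;
# peak-type results attach to Conditions.

#' Assemble experimental-design tables
#'
#' @param conditions data.frame with first column `Condition` (ids) and any
#'   further attribute columns.
#' @param contexts data.frame with columns `Context` and `condition` (comma
#'   separated member Condition ids).
#' @param contrasts data.frame with columns `Contrast`, `context_a`,
#'   `context_b`.
#' @return list of class `design_tables`.
#' @export
design_tables <- function(conditions = NULL, contexts = NULL, contrasts = NULL) {
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  conditions <- conditions %||% empty(Condition = character())
  contexts   <- contexts   %||% empty(Context = character(), condition = character())
  contrasts  <- contrasts  %||% empty(Contrast = character(), context_a = character(),
                                      context_b = character())
  stopifnot(names(conditions)[1] == "Condition",
            all(c("Context", "condition") %in% names(contexts)),
            all(c("Contrast", "context_a", "context_b") %in% names(contrasts)))
  members <- unlist(strsplit(contexts$condition, ",", fixed = TRUE))
  members <- trimws(members[!is.na(members)])
  unknown <- setdiff(members, conditions$Condition)
  if (length(unknown))
    stop("context member condition(s) not declared: ", paste(unknown, collapse = ", "))
  refs <- c(contrasts$context_a, contrasts$context_b)
  unknown <- setdiff(refs[!is.na(refs)], contexts$Context)
  if (length(unknown))
    stop("contrast references undeclared context(s): ", paste(unknown, collapse = ", "))
  structure(list(conditions = conditions, contexts = contexts, contrasts = contrasts),
            class = "design_tables")
}

#' Build the design block of the graph
#'
#' Emits Condition/Context/Contrast entities, `hasCondition` membership
#' triples from contexts, and `compares` triples from contrasts to their two
#' contexts.
#'
#' @param design a [design_tables()].
#' @param namespace project namespace.
#' @param graph_name named graph IRI.
#' @return list with `batch` and `schema` as in [convert_table()].
#' @export
build_design_graph <- function(design, namespace = default_namespace(),
                               graph_name = NULL) {
  stopifnot(inherits(design, "design_tables"))
  if (is.null(graph_name))
    graph_name <- paste0(sub("/+$", "", namespace), "/graph/design")
  df <- triple_df()
  decl <- function(cls, id) {
    u <- mint_entity_uri(namespace, cls, id)
    triple_df(c(u, u), c(RDF_TYPE, RDFS_LABEL),
              c(class_uri(namespace, cls), id), c("iri", "string"))
  }
  for (i in seq_len(nrow(design$conditions)))
    df <- rbind(df, decl("Condition", design$conditions$Condition[i]))
  for (i in seq_len(nrow(design$contexts))) {
    id <- design$contexts$Context[i]
    df <- rbind(df, decl("Context", id))
    u <- mint_entity_uri(namespace, "Context", id)
    members <- trimws(strsplit(design$contexts$condition[i], ",", fixed = TRUE)[[1]])
    members <- members[nzchar(members)]
    for (m in members)
      df <- rbind(df, triple_df(u, property_uri(namespace, "Context", "hasCondition"),
                                mint_entity_uri(namespace, "Condition", m), "iri"))
  }
  for (i in seq_len(nrow(design$contrasts))) {
    id <- design$contrasts$Contrast[i]
    df <- rbind(df, decl("Contrast", id))
    u <- mint_entity_uri(namespace, "Contrast", id)
    for (ctx in c(design$contrasts$context_a[i], design$contrasts$context_b[i]))
      df <- rbind(df, triple_df(u, property_uri(namespace, "Contrast", "compares"),
                                mint_entity_uri(namespace, "Context", ctx), "iri"))
  }
  schema <- list(
    entity_class_def("Condition", namespace),
    entity_class_def("Context", namespace, properties = data.frame(
      label = "hasCondition", kind = "relation", range = "Condition")),
    entity_class_def("Contrast", namespace, properties = data.frame(
      label = "compares", kind = "relation", range = "Context")))
  if (nrow(df)) {
    sb <- schema_triples(schema, graph_name)
    df <- rbind(df, sb$triples)
  } else schema <- list()
  list(batch = triple_batch(df, graph_name), schema = schema,
       n_entities = nrow(design$conditions) + nrow(design$contexts) +
         nrow(design$contrasts))
}

#' Detect cross-links between dataset schemas
#'
#' Relation links come from `label@TargetClass` columns (and GFF3 `parent`
#' relations); a location link is declared between every pair of located
#' classes, both being joinable through the FALDO Region abstraction.
#'
#' @param schemas list of [entity_class_def()] (possibly from several
#'   datasets; merged internally).
#' @return data.frame with columns `source`, `kind` (`relation`/`location`),
#'   `target`, `label` and `resolved` (FALSE when a relation names a class
#'   absent from every schema — reported, not fatal).
#' @export
infer_links <- function(schemas) {
  stopifnot(length(schemas) >= 1L)
  merged <- merge_schemas(schemas)
  labels <- vapply(merged, `[[`, character(1), "label")
  out <- data.frame(source = character(), kind = character(), target = character(),
                    label = character(), resolved = logical(),
                    stringsAsFactors = FALSE)
  for (cl in merged) {
    rels <- cl$properties[cl$properties$kind == "relation", , drop = FALSE]
    for (i in seq_len(nrow(rels))) {
      out <- rbind(out, data.frame(source = cl$label, kind = "relation",
                                   target = rels$range[i], label = rels$label[i],
                                   resolved = rels$range[i] %in% labels))
    }
  }
  located <- labels[vapply(merged, `[[`, logical(1), "is_located")]
  if (length(located) >= 2L) {
    pairs <- utils::combn(located, 2L)
    for (j in seq_len(ncol(pairs)))
      out <- rbind(out, data.frame(source = pairs[1, j], kind = "location",
                                   target = pairs[2, j], label = "overlaps",
                                   resolved = TRUE))
  }
  unresolved <- out[out$kind == "relation" & !out$resolved, , drop = FALSE]
  if (nrow(unresolved))
    warning("unresolved relation target class(es): ",
            paste(unique(unresolved$target), collapse = ", "), call. = FALSE)
  rownames(out) <- NULL
  out
}
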
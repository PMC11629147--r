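# Query-graph -> SPARQL compilation, including the genomic-overlap join
# fragment, plus the all-pairs brute-force oracle with identical semantics.

#' SPARQL fragment joining two located variables by genomic overlap
#'
#' Walks the FALDO nodes of both variables (shared `faldo:reference`, begin
#' and end `faldo:position` values) and emits the interval constraint on
#' 1-based inclusive coordinates: for `any_overlap`,
#' `start(a) <= end(b) && start(b) <= end(a)` — abutting closed intervals that
#' share a single base DO overlap. Containment modes tighten to
#' `start/end` inequalities; `same_strand` adds equality of the flat strand
#' attributes.
#'
#' @param a_var,b_var node variable names (no `?`).
#' @param mode `"any_overlap"`, `"a_within_b"` or `"b_within_a"`.
#' @param strand_policy `"ignore"` or `"same_strand"`.
#' @return character vector of SPARQL lines.
#' @export
overlap_pattern <- function(a_var, b_var, mode = "any_overlap",
                            strand_policy = "ignore") {
  stopifnot(mode %in% c("any_overlap", "a_within_b", "b_within_a"),
            strand_policy %in% c("ignore", "same_strand"))
  pair <- paste0(a_var, "_", b_var)
  faldo_walk <- function(v) c(
    sprintf("?%s faldo:location ?%s_loc .", v, v),
    sprintf("?%s_loc faldo:reference ?ref_%s .", v, pair),
    sprintf("?%s_loc faldo:begin ?%s_begnode .", v, v),
    sprintf("?%s_begnode faldo:position ?%s_start .", v, v),
    sprintf("?%s_loc faldo:end ?%s_endnode .", v, v),
    sprintf("?%s_endnode faldo:position ?%s_end .", v, v))
  lines <- c(faldo_walk(a_var), faldo_walk(b_var))
  cond <- switch(mode,
    any_overlap = sprintf("?%s_start <= ?%s_end && ?%s_start <= ?%s_end",
                          a_var, b_var, b_var, a_var),
    a_within_b  = sprintf("?%s_start >= ?%s_start && ?%s_end <= ?%s_end",
                          a_var, b_var, a_var, b_var),
    b_within_a  = sprintf("?%s_start >= ?%s_start && ?%s_end <= ?%s_end",
                          b_var, a_var, b_var, a_var))
  lines <- c(lines, sprintf("FILTER(%s)", cond))
  if (strand_policy == "same_strand") {
    lines <- c(lines,
      sprintf("?%s omi:strand ?%s_strand .", a_var, a_var),
      sprintf("?%s omi:strand ?%s_strand .", b_var, b_var),
      sprintf("FILTER(?%s_strand = ?%s_strand)", a_var, b_var))
  }
  lines
}

sparql_quote_literal <- function(value, range) {
  if (range %in% c("integer", "decimal")) as.character(value)
  else paste0('"', gsub('"', '\\"', as.character(value), fixed = TRUE), '"')
}

#' Compile a query graph into SPARQL
#'
#' Validates every node class and filtered/selected property against the
#' merged schema first; relation edges become triple patterns on the declared
#' predicates, overlap edges become [overlap_pattern()] fragments, and a
#' `count_distinct` target becomes `COUNT(DISTINCT ?var)`. Without an
#' aggregate, results are `DISTINCT` and ordered by the first projected
#' variable so output is deterministic.
#'
#' @param q a [query_graph()].
#' @param schema merged schema (list of [entity_class_def()]), e.g.
#'   [merged_schema()].
#' @param namespace project namespace the data was minted under.
#' @return a single SPARQL SELECT string.
#' @export
compile_sparql <- function(q, schema, namespace = default_namespace()) {
  stopifnot(inherits(q, "query_graph"))
  classes <- vapply(schema, `[[`, character(1), "label")
  for (n in q$nodes) {
    if (!n$entity_class %in% classes)
      stop("unknown entity class in query: ", n$entity_class)
    for (f in n$filters)
      if (is.null(resolve_property(schema, n$entity_class, f[[1]])))
        stop("property '", f[[1]], "' is not declared for class ", n$entity_class)
    for (s in n$select)
      if (is.null(resolve_property(schema, n$entity_class, s)))
        stop("property '", s, "' is not declared for class ", n$entity_class)
  }
  node_class <- stats::setNames(vapply(q$nodes, `[[`, character(1), "entity_class"),
                                vapply(q$nodes, `[[`, character(1), "var"))
  for (e in q$edges) {
    if (e$kind == "relation") {
      r <- resolve_property(schema, node_class[[e$from_var]], e$relation_label)
      if (is.null(r) || r$kind != "relation")
        stop("relation '", e$relation_label, "' is not declared from class ",
             node_class[[e$from_var]])
    } else {
      for (v in c(e$from_var, e$to_var)) {
        cl <- schema_class(schema, node_class[[v]])
        if (!isTRUE(cl$is_located))
          stop("overlap edge touches non-located class ", node_class[[v]])
      }
    }
  }

  body <- character(); proj <- character()
  for (n in q$nodes) {
    cls <- schema_class(schema, n$entity_class)
    body <- c(body, sprintf("?%s a <%s> .", n$var, cls$uri))
    proj <- c(proj, paste0("?", n$var))
    for (f in n$filters) {
      r <- resolve_property(schema, n$entity_class, f[[1]])
      fv <- paste0(n$var, "_", gsub("[^A-Za-z0-9_]", "_", f[[1]]))
      body <- c(body, sprintf("?%s <%s> ?%s .", n$var, r$uri, fv))
      if (f[[2]] == "contains") {
        body <- c(body, sprintf('FILTER(CONTAINS(STR(?%s), %s))', fv,
                                sparql_quote_literal(f[[3]], "string")))
      } else if (r$kind == "relation") {
        tgt <- mint_entity_uri(namespace, r$range, f[[3]])
        if (f[[2]] != "=") stop("relation filters support '=' only")
        body <- c(body, sprintf("FILTER(?%s = <%s>)", fv, tgt))
      } else {
        body <- c(body, sprintf("FILTER(?%s %s %s)", fv, f[[2]],
                                sparql_quote_literal(f[[3]], r$range)))
      }
    }
    for (s in n$select) {
      r <- resolve_property(schema, n$entity_class, s)
      sv <- paste0(n$var, "_", gsub("[^A-Za-z0-9_]", "_", s))
      body <- c(body, sprintf("?%s <%s> ?%s .", n$var, r$uri, sv))
      proj <- c(proj, paste0("?", sv))
    }
  }
  for (e in q$edges) {
    if (e$kind == "relation") {
      r <- resolve_property(schema, node_class[[e$from_var]], e$relation_label)
      body <- c(body, sprintf("?%s <%s> ?%s .", e$from_var, r$uri, e$to_var))
    } else {
      body <- c(body, overlap_pattern(e$from_var, e$to_var,
                                      e$overlap_mode, e$strand_policy))
    }
  }

  prologue <- c(sprintf("PREFIX faldo: <%s>", FALDO_NS),
                sprintf("PREFIX omi: <%s>", OMI_VOCAB))
  if (!is.null(q$count_distinct)) {
    head_ <- sprintf("SELECT (COUNT(DISTINCT ?%s) AS ?n)", q$count_distinct)
    tail_ <- character()
  } else {
    head_ <- paste("SELECT DISTINCT", paste(proj, collapse = " "))
    tail_ <- sprintf("ORDER BY %s", proj[1])
  }
  paste(c(prologue, head_, "WHERE {", paste(" ", body), "}", tail_),
        collapse = "\n")
}

#' Compile and run a counting query
#'
#' @param store a [triplestore()].
#' @param q a [query_graph()].
#' @param var node variable to count; defaults to the graph's
#'   `count_distinct`, or the first node.
#' @param namespace project namespace.
#' @return integer count of distinct bindings of `var`.
#' @export
count_distinct <- function(store, q, var = NULL, namespace = default_namespace()) {
  if (is.null(var)) var <- q$count_distinct %||% q$nodes[[1]]$var
  q2 <- query_graph(q$nodes, q$edges, count_distinct = var)
  res <- run_select(store, compile_sparql(q2, merged_schema(store), namespace))
  as.integer(res$n[1])
}

#' Brute-force interval-overlap oracle
#'
#' All-pairs evaluation over plain coordinate tables, with semantics
#' identical (by construction and by test) to the SPARQL generated by
#' [overlap_pattern()]: same reference required; closed 1-based intervals;
#' `same_strand` compares normalized strand labels (unknown == unknown
#' matches). Used as the independent oracle for the compiled queries.
#'
#' @param features_a,features_b data.frames with columns `id`, `reference`,
#'   `start`, `end` and optionally `strand`.
#' @param mode overlap mode as in [overlap_pattern()].
#' @param strand_policy `"ignore"` or `"same_strand"`.
#' @return data.frame of matched pairs with columns `a`, `b` (ids).
#' @export
brute_force_overlap <- function(features_a, features_b, mode = "any_overlap",
                                strand_policy = "ignore") {
  stopifnot(all(c("id", "reference", "start", "end") %in% names(features_a)),
            all(c("id", "reference", "start", "end") %in% names(features_b)),
            mode %in% c("any_overlap", "a_within_b", "b_within_a"),
            strand_policy %in% c("ignore", "same_strand"))
  empty <- data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  if (nrow(features_a) == 0L || nrow(features_b) == 0L) return(empty)
  g <- expand.grid(i = seq_len(nrow(features_a)), j = seq_len(nrow(features_b)))
  A <- features_a[g$i, ]; B <- features_b[g$j, ]
  keep <- A$reference == B$reference
  keep <- keep & switch(mode,
    any_overlap = A$start <= B$end & B$start <= A$end,
    a_within_b  = A$start >= B$start & A$end <= B$end,
    b_within_a  = B$start >= A$start & B$end <= A$end)
  if (strand_policy == "same_strand") {
    sa <- vapply(as.character(A$strand %||% rep("unknown", nrow(A))),
                 normalize_strand, character(1))
    sb <- vapply(as.character(B$strand %||% rep("unknown", nrow(B))),
                 normalize_strand, character(1))
    keep <- keep & sa == sb
  }
  out <- data.frame(a = as.character(A$id[keep]), b = as.character(B$id[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}
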
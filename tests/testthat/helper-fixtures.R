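# Shared test helpers: random located feature tables, stores built from them,
# and an rdflib-backed SPARQL oracle (python) for engine cross-checks.

random_features <- function(prefix, n, n_refs = 3L, max_pos = 5000L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(id = paste0(prefix, seq_len(n)),
             reference = paste0("chr", sample.int(n_refs, n, replace = TRUE)),
             start = start,
             end = start + sample(0:400, n, replace = TRUE),
             strand = sample(c("forward", "reverse", "unknown"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

as_located_table <- function(features, class_name) {
  df <- features
  names(df)[names(df) == "id"] <- class_name
  names(df)[names(df) == "reference"] <- "chromosome"
  tabular_dataset(df[, c(class_name, "chromosome", "start", "end", "strand")])
}

store_with_features <- function(a, b, class_a = "feat_a", class_b = "feat_b") {
  store <- triplestore()
  for (x in list(list(a, class_a), list(b, class_b))) {
    cv <- convert_table(as_located_table(x[[1]], x[[2]]),
                        graph_name = paste0(default_namespace(), "/graph/", x[[2]]))
    load_graph(store, cv$batch, cv$schema, source = x[[2]])
  }
  store
}

overlap_query <- function(mode, strand_policy, class_a = "feat_a", class_b = "feat_b") {
  query_graph(list(query_node("x", class_a), query_node("y", class_b)),
              list(query_edge("x", "y", "overlap", overlap_mode = mode,
                              strand_policy = strand_policy)))
}

sorted_pairs <- function(a, b) sort(paste(a, b))

# pairs of local ids from a compiled overlap SELECT
sparql_overlap_pairs <- function(store, q) {
  res <- run_select(store, compile_sparql(q, merged_schema(store)))
  if (nrow(res) == 0L) return(character())
  decode <- function(u) utils::URLdecode(sub(".*/", "", u))
  sorted_pairs(vapply(res$x, decode, character(1)),
               vapply(res$y, decode, character(1)))
}

# --- rdflib oracle (python, pre-installed) ----------------------------------

rdflib_script <- function() {
  f <- file.path(tempdir(), "rdflib_oracle.py")
  if (!file.exists(f))
    writeLines(c("import rdflib, sys",
                 "g = rdflib.Graph()",
                 "g.parse(sys.argv[1], format='nt')",
                 "res = g.query(open(sys.argv[2]).read())",
                 "for row in res:",
                 "    print('\\t'.join('' if v is None else str(v) for v in row))"),
               f)
  f
}

rdflib_select <- function(store, sparql) {
  nt <- tempfile(fileext = ".nt"); export_ntriples(store, nt)
  rq <- tempfile(fileext = ".rq"); writeLines(sparql, rq)
  on.exit(unlink(c(nt, rq)))
  out <- system2("python", c(rdflib_script(), nt, rq), stdout = TRUE, stderr = "")
  out
}
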
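# Named-graph storage, idempotent loading, union semantics, serialization
# round-trips, merged schema.

simple_batch <- function(n, graph = paste0(default_namespace(), "/graph/t")) {
  triple_batch(data.frame(s = paste0("https://ex.org/s", seq_len(n)),
                          p = "https://ex.org/p", o = "v", ot = "string",
                          stringsAsFactors = FALSE), graph)
}

test_that("loading is idempotent and counts distinct triples per graph", {
  store <- triplestore()
  b <- simple_batch(10)
  ref <- load_graph(store, b)
  expect_equal(ref$triple_count, 10L)
  ref2 <- load_graph(store, b)
  expect_equal(ref2$triple_count, 10L)
  expect_equal(ref2$added, 0L)
  # two batches sharing 3 triples -> union size
  b1 <- triple_batch(data.frame(s = paste0("https://ex.org/x", 1:5),
                                p = "https://ex.org/p", o = "v", ot = "string"),
                     paste0(default_namespace(), "/graph/u"))
  b2 <- triple_batch(data.frame(s = paste0("https://ex.org/x", 3:8),
                                p = "https://ex.org/p", o = "v", ot = "string"),
                     paste0(default_namespace(), "/graph/u"))
  load_graph(store, b1)
  ref3 <- load_graph(store, b2)
  expect_equal(ref3$triple_count, 8L)
})

test_that("SELECT evaluates over the union of named graphs", {
  store <- triplestore()
  expect_equal(nrow(run_select(store, "SELECT ?s WHERE { ?s ?p ?o }")), 0L)
  load_graph(store, simple_batch(4, paste0(default_namespace(), "/graph/a")))
  b <- triple_batch(data.frame(s = "https://ex.org/s9", p = "https://ex.org/p",
                               o = "v", ot = "string"),
                    paste0(default_namespace(), "/graph/b"))
  load_graph(store, b)
  res <- run_select(store, "SELECT ?s ?o WHERE { ?s <https://ex.org/p> ?o }")
  expect_equal(nrow(res), 5L)
  # same rows as loading everything into one graph
  one <- triplestore()
  load_graph(one, merge_batches(simple_batch(4), b,
                                graph_name = paste0(default_namespace(), "/graph/all")))
  res_one <- run_select(one, "SELECT ?s ?o WHERE { ?s <https://ex.org/p> ?o }")
  expect_setequal(res$s, res_one$s)
})

test_that("N-Triples export/reload round-trips counts and query answers", {
  truth <- generate_toy_annotation(12, 2, seed = 4)
  store <- triplestore()
  cv <- convert_gff3(truth$gff)
  load_graph(store, cv$batch, cv$schema)
  nt <- tempfile(fileext = ".nt")
  export_ntriples(store, nt, graph = cv$batch$graph_name)
  store2 <- triplestore()
  load_graph(store2, parse_ntriples(nt, graph_name = cv$batch$graph_name))
  expect_equal(nrow(store2$triples), nrow(store$triples))
  q <- "SELECT (COUNT(DISTINCT ?g) AS ?n) WHERE { ?g <https://omigraph.example.org/vocab#strand> ?s }"
  expect_equal(run_select(store2, q)$n, run_select(store, q)$n)
  unlink(nt)
})

test_that("literals with quotes, newlines and tabs survive the N-Triples round-trip", {
  b <- triple_batch(data.frame(
    s = "https://ex.org/s", p = "https://ex.org/p",
    o = c("say \"hi\"", "two\nlines", "tab\there", "back\\slash"),
    ot = "string", stringsAsFactors = FALSE))
  store <- triplestore(); load_graph(store, b)
  nt <- tempfile(); export_ntriples(store, nt)
  back <- parse_ntriples(nt)
  expect_setequal(back$triples$o, b$triples$o)
  unlink(nt)
})

test_that("turtle export is parseable by an independent RDF library", {
  store <- triplestore()
  cv <- convert_table(tabular_dataset(data.frame(
    g = c("a", "b"), v = c("1.5", "2"), stringsAsFactors = FALSE)))
  load_graph(store, cv$batch, cv$schema)
  ttl <- tempfile(fileext = ".ttl")
  export_turtle(store, ttl)
  py <- tempfile(fileext = ".py")
  writeLines(c("import rdflib, sys",
               "g = rdflib.Graph(); g.parse(sys.argv[1], format='turtle')",
               "print(len(g))"), py)
  n <- system2("python", c(py, ttl), stdout = TRUE, stderr = "")
  expect_equal(as.integer(n), nrow(store$triples))
  unlink(c(ttl, py))
})

test_that("stores persist to a directory and reopen with schema intact", {
  truth <- generate_toy_annotation(6, 1, seed = 9)
  store <- triplestore()
  cv <- convert_gff3(truth$gff)
  load_graph(store, cv$batch, cv$schema, source = "toy")
  d <- file.path(tempdir(), "storetest")
  save_store(store, d)
  store2 <- open_store(d)
  expect_equal(nrow(store2$triples), nrow(store$triples))
  expect_setequal(vapply(merged_schema(store2), `[[`, character(1), "label"),
                  vapply(merged_schema(store), `[[`, character(1), "label"))
  unlink(d, recursive = TRUE)
})

test_that("merged schema is the union of loaded dataset schemas", {
  store <- triplestore()
  expect_length(merged_schema(store), 0L)
  cv1 <- convert_table(tabular_dataset(data.frame(
    DEG = "d", `differentiallyExpressedIn@Contrast` = "c",
    check.names = FALSE, stringsAsFactors = FALSE)))
  cv2 <- convert_table(tabular_dataset(data.frame(
    DEG = "d", FDR = "0.1", check.names = FALSE, stringsAsFactors = FALSE)))
  load_graph(store, cv1$batch, cv1$schema)
  load_graph(store, cv2$batch, cv2$schema)
  m <- merged_schema(store)
  expect_length(m, 1L)
  expect_setequal(m[[1]]$properties$label, c("differentiallyExpressedIn", "FDR"))
})
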
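# Query-graph construction, compilation, overlap semantics, oracle
# equivalence, monotonicity and symmetry.

test_that("overlap fragments implement closed-interval semantics", {
  mk <- function(s1, e1, s2, e2, mode = "any_overlap", sp = "ignore") {
    a <- data.frame(id = "a1", reference = "chr1", start = s1, end = e1,
                    strand = "forward", stringsAsFactors = FALSE)
    b <- data.frame(id = "b1", reference = "chr1", start = s2, end = e2,
                    strand = "reverse", stringsAsFactors = FALSE)
    nrow(brute_force_overlap(a, b, mode, sp)) == 1L
  }
  expect_true(mk(100, 200, 150, 300))
  # abutting closed intervals share base 200 -> they DO overlap
  expect_true(mk(100, 200, 200, 300))
  expect_false(mk(100, 200, 201, 300))
  expect_true(mk(120, 180, 100, 200, mode = "a_within_b"))
  expect_false(mk(120, 180, 100, 200, mode = "b_within_a"))
  expect_false(mk(100, 200, 150, 300, sp = "same_strand"))
  # disjoint chromosomes never match
  a <- data.frame(id = "a1", reference = "chr1", start = 1, end = 10)
  b <- data.frame(id = "b1", reference = "chr2", start = 1, end = 10)
  expect_equal(nrow(brute_force_overlap(a, b)), 0L)
  # identical single features on one list used twice -> one self-pair
  expect_equal(brute_force_overlap(a, a),
               data.frame(a = "a1", b = "a1", stringsAsFactors = FALSE))
  # the SPARQL fragment carries the same boundary condition
  frag <- paste(overlap_pattern("x", "y"), collapse = "\n")
  expect_match(frag, "\\?x_start <= \\?y_end && \\?y_start <= \\?x_end")
})

test_that("compiled SPARQL overlap joins equal the brute-force oracle", {
  # randomized equivalence across all modes and strand policies
  set.seed(303)
  for (rep in 1:3) {
    A <- random_features("a", 60)
    B <- random_features("b", 60)
    store <- store_with_features(A, B)
    for (mode in c("any_overlap", "a_within_b", "b_within_a")) {
      for (sp in c("ignore", "same_strand")) {
        q <- overlap_query(mode, sp)
        got <- sparql_overlap_pairs(store, q)
        want <- brute_force_overlap(A, B, mode, sp)
        expect_equal(got, sorted_pairs(want$a, want$b),
                     label = paste("pairs for", mode, sp, "rep", rep))
      }
    }
  }
})

test_that("overlap is symmetric and edges/filters are monotone for counts", {
  set.seed(77)
  A <- random_features("a", 50)
  B <- random_features("b", 50)
  bf_ab <- brute_force_overlap(A, B, "any_overlap", "ignore")
  bf_ba <- brute_force_overlap(B, A, "any_overlap", "ignore")
  expect_equal(sorted_pairs(bf_ab$a, bf_ab$b), sorted_pairs(bf_ba$b, bf_ba$a))

  truth <- generate_toy_annotation(80, 3, seed = 15)
  truth <- generate_omics_tables(truth, seed = 15)
  store <- integrate_fixtures(truth)
  base <- query_graph(list(query_node("g", "gene")), count_distinct = "g")
  n0 <- count_distinct(store, base)
  with_edge <- query_graph(
    list(query_node("g", "gene"), query_node("p", "atac_peak")),
    list(query_edge("g", "p", "overlap")), count_distinct = "g")
  n1 <- count_distinct(store, with_edge)
  with_filter <- query_graph(
    list(query_node("g", "gene",
                    filters = list(list("regulation_sense", "=", "UP"))),
         query_node("p", "atac_peak")),
    list(query_edge("g", "p", "overlap")), count_distinct = "g")
  n2 <- count_distinct(store, with_filter)
  expect_lte(n1, n0)
  expect_lte(n2, n1)
})

test_that("query graphs validate classes, properties and connectivity", {
  truth <- generate_toy_annotation(80, 3, seed = 2)
  truth <- generate_omics_tables(truth, seed = 2)
  store <- integrate_fixtures(truth)
  schema <- merged_schema(store)

  expect_error(compile_sparql(query_graph(list(query_node("x", "NoSuchClass"))),
                              schema), "unknown entity class")
  expect_error(compile_sparql(query_graph(list(
    query_node("g", "gene", filters = list(list("no_such_prop", "=", 1))))),
    schema), "not declared")
  expect_error(query_graph(list(query_node("a", "gene"), query_node("b", "dmr"))),
               "not connected")
  expect_error(compile_sparql(query_graph(
    list(query_node("a", "gene"), query_node("c", "Contrast")),
    list(query_edge("a", "c", "overlap"))), schema), "non-located")
  # single unfiltered node selects all instances of the class
  res <- run_select(store, compile_sparql(
    query_graph(list(query_node("c", "Contrast"))), schema))
  expect_equal(nrow(res), 2L)
})

test_that("a 3-node chain count matches independent evaluation over the tables", {
  truth <- generate_toy_annotation(80, 3, seed = 31)
  truth <- generate_omics_tables(truth, seed = 31)
  store <- integrate_fixtures(truth)
  q <- fixture_queries(truth)[["deg_atac_4Qvs4W"]]
  got <- count_distinct(store, q)
  # brute-force evaluation straight off the source tables
  deg <- truth$tables$deg
  de_genes <- deg$gene[deg[["differentiallyExpressedIn@Contrast"]] == "4Qvs4W"]
  genes <- truth$genes[truth$genes$id %in% de_genes, ]
  peaks <- truth$tables$atac_peak
  peaks_f <- data.frame(id = peaks$atac_peak, reference = peaks$chromosome,
                        start = as.integer(peaks$start), end = as.integer(peaks$end),
                        stringsAsFactors = FALSE)
  genes_f <- data.frame(id = genes$id, reference = genes$reference,
                        start = genes$start, end = genes$end,
                        stringsAsFactors = FALSE)
  want <- length(unique(brute_force_overlap(genes_f, peaks_f)$a))
  expect_equal(got, want)
  expect_equal(got, unname(truth$expected[["deg_atac_4Qvs4W"]]))
})

test_that("query graphs round-trip through their JSON serialization", {
  q <- query_graph(
    list(query_node("g", "gene", filters = list(list("label", "=", "MYH7")),
                    select = c("biotype")),
         query_node("d", "dmr",
                    filters = list(list("methylation_sense", "=", "hyper")))),
    list(query_edge("d", "g", "relation", relation_label = "associatedGene")),
    count_distinct = "d")
  f <- tempfile(fileext = ".json")
  write_query_graph(q, f)
  q2 <- read_query_graph(f)
  expect_equal(q2$nodes[[1]]$filters, q$nodes[[1]]$filters)
  expect_equal(q2$edges[[1]]$relation_label, "associatedGene")
  expect_equal(q2$count_distinct, "d")
  unlink(f)
})

test_that("count_distinct returns 0 on an empty store's classes", {
  store <- triplestore()
  cv <- convert_table(tabular_dataset(
    data.frame(dmr = character(), methylation_sense = character(),
               stringsAsFactors = FALSE)))
  load_graph(store, cv$batch, cv$schema)
  q <- query_graph(list(query_node("d", "dmr")), count_distinct = "d")
  expect_equal(count_distinct(store, q), 0L)
})
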
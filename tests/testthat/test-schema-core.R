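# URI minting, FALDO region serialization, RDFS schema triples.

test_that("entity IRIs are deterministic concatenations with RFC 3986 encoding", {
  expect_equal(mint_entity_uri("https://ex.org", "gene", "MYH7"),
               "https://ex.org/gene/MYH7")
  # expected value computed independently by percent-encoding " " -> %20,
  # "/" -> %2F per RFC 3986 (unreserved set passes through)
  expect_equal(mint_entity_uri("https://ex.org", "gene", "a b/c"),
               "https://ex.org/gene/a%20b%2Fc")
  u <- replicate(1000, mint_entity_uri("https://ex.org", "DMR", "chr1:100-200"))
  expect_length(unique(u), 1L)
  expect_error(mint_entity_uri("https://ex.org", "gene", ""), "empty entity id")
  expect_error(mint_entity_uri("not-an-iri", "gene", "x"), "absolute IRI")
  # distinct ids that would collide without encoding stay distinct
  expect_false(mint_entity_uri("https://ex.org", "g", "a/b") ==
                 mint_entity_uri("https://ex.org", "g", "a%2Fb"))
})

test_that("region triples carry FALDO begin/end positions and strand classes", {
  u <- "https://ex.org/gene/g1"
  b <- region_triples(u, region("chr1", 100, 200, "forward"))
  df <- b$triples
  faldo <- "http://biohackathon.org/resource/faldo#"
  loc <- df$o[df$s == u & df$p == paste0(faldo, "location")]
  expect_length(loc, 1L)
  beg <- df$o[df$s == loc & df$p == paste0(faldo, "begin")]
  expect_equal(df$o[df$s == beg & df$p == paste0(faldo, "position")], "100")
  endn <- df$o[df$s == loc & df$p == paste0(faldo, "end")]
  expect_equal(df$o[df$s == endn & df$p == paste0(faldo, "position")], "200")
  rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  expect_true(paste0(faldo, "ForwardStrandPosition") %in%
                df$o[df$s == beg & df$p == rdf_type])
  # flat attribute encoding present alongside
  expect_true(any(df$s == u & df$o == "chr1"))
  expect_true(any(df$s == u & df$o == "forward"))

  # degenerate single-base region
  b2 <- region_triples(u, region("chr1", 5, 5, "unknown"))
  pos <- b2$triples[b2$triples$p == paste0(faldo, "position"), ]
  expect_equal(sort(pos$o), c("5", "5"))
  # unknown strand: no strand position class anywhere
  expect_false(any(grepl("StrandPosition", b2$triples$o)))

  expect_error(region("chr1", 200, 100), "start 200 > end 100")
  expect_error(region("chr1", 0, 10), "start must be >= 1")
  expect_error(region("", 1, 10), "non-empty")
  expect_error(region("chr1", 1, 10, "5"), "strand")
})

test_that("regions round-trip exactly through their FALDO triples", {
  set.seed(11)
  for (i in 1:25) {
    ref <- sample(c("chr1", "scaffold_2", "MT"), 1)
    st <- sample.int(1e6, 1)
    reg <- region(ref, st, st + sample(0:5000, 1),
                  sample(c("forward", "reverse", "unknown"), 1))
    u <- mint_entity_uri("https://ex.org", "feat", paste0("f", i))
    back <- parse_region(region_triples(u, reg), u)
    expect_equal(back, reg)
  }
})

test_that("schema triples declare classes, properties, and Region links", {
  deg <- entity_class_def("DEG", properties = data.frame(
    label = c("FDR", "differentiallyExpressedIn"),
    kind = c("attribute", "relation"),
    range = c("decimal", "Contrast")))
  b <- schema_triples(list(deg))
  df <- b$triples
  rdfs <- "http://www.w3.org/2000/01/rdf-schema#"
  expect_true(any(df$s == deg$uri & df$o == paste0(rdfs, "Class")))
  # one domain declaration per property, both pointing at DEG
  expect_equal(sum(df$p == paste0(rdfs, "domain") & df$o == deg$uri), 2L)
  # attribute range is an XSD datatype, relation range a class IRI
  ranges <- df$o[df$p == paste0(rdfs, "range")]
  expect_true(any(grepl("XMLSchema#decimal", ranges)))
  expect_true(any(grepl("/Contrast$", ranges)))

  expect_equal(n_triples(schema_triples(list())), 0L)
  expect_error(schema_triples(list(deg, deg)), "duplicate class label")
})

test_that("merging schemas unions properties and located flags per class", {
  a <- entity_class_def("gene", is_located = TRUE, properties = data.frame(
    label = "biotype", kind = "attribute", range = "string"))
  b <- entity_class_def("gene", is_located = FALSE, properties = data.frame(
    label = c("biotype", "FDR"), kind = "attribute", range = c("string", "decimal")))
  m <- merge_schemas(a, b)
  expect_length(m, 1L)
  expect_true(m[[1]]$is_located)
  expect_setequal(m[[1]]$properties$label, c("biotype", "FDR"))
  # located classes are linked to the FALDO Region abstraction
  st <- schema_triples(m)
  expect_true(any(st$triples$o == "http://biohackathon.org/resource/faldo#Region"))
})

test_that("triple batches have set semantics", {
  df <- data.frame(s = c("a", "a"), p = c("b", "b"), o = c("c", "c"),
                   ot = "iri", stringsAsFactors = FALSE)
  expect_equal(n_triples(triple_batch(df)), 1L)
  b1 <- triple_batch(data.frame(s = letters[1:3], p = "p", o = "x", ot = "iri"))
  b2 <- triple_batch(data.frame(s = letters[2:5], p = "p", o = "x", ot = "iri"))
  expect_equal(n_triples(merge_batches(b1, b2)), 5L)
})
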
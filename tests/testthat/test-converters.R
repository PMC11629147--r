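# Header classification, table -> RDF, GFF3 -> RDF, design graph, link
# inference.

test_that("headers classify into entity/relation/position/attribute roles", {
  r <- classify_headers(c("DEG", "differentiallyExpressedIn@Contrast", "FDR"))
  expect_equal(r$role, c("entity_id", "relation", "attribute"))
  expect_equal(r$relation_label[2], "differentiallyExpressedIn")
  expect_equal(r$target_class[2], "Contrast")

  r <- classify_headers(c("DMR", "chromosome", "start", "end", "strand"))
  expect_equal(r$role, c("entity_id", "position_reference", "position_start",
                         "position_end", "position_strand"))
  # synonyms, case-insensitive
  r <- classify_headers(c("peak", "Chrom", "BEGIN", "Stop"))
  expect_equal(r$role, c("entity_id", "position_reference", "position_start",
                         "position_end"))

  expect_equal(classify_headers("X")$role, "entity_id")
  expect_error(classify_headers(c("a", "b", "a")), "duplicate")
  # split happens at the LAST @
  r <- classify_headers(c("x", "a@b@C"))
  expect_equal(r$relation_label[2], "a@b")
  expect_equal(r$target_class[2], "C")
})

test_that("tables convert to one entity per row with typed literals and relations", {
  df <- data.frame(
    DEG = c("d1", "d2", "d3"),
    `differentiallyExpressedIn@Contrast` = "HCMvsControl",
    FDR = c("0.01", "0.002", "0.03"),
    note = c("a", NA, "c"),
    check.names = FALSE, stringsAsFactors = FALSE)
  cv <- convert_table(tabular_dataset(df))
  expect_equal(cv$n_entities, 3L)
  t <- cv$batch$triples
  # 3 DEG entities each linked to the same minted Contrast entity
  contrast_uri <- mint_entity_uri(default_namespace(), "Contrast", "HCMvsControl")
  expect_equal(sum(t$o == contrast_uri & t$ot == "iri"), 3L)
  # FDR literals are decimal-typed
  expect_true(all(t$ot[grepl("#FDR$", t$p)] == "decimal"))
  # missing cells emit no triple
  expect_equal(sum(grepl("#note$", t$p)), 2L)
  # schema reflects the columns
  props <- cv$schema[[1]]$properties
  expect_setequal(props$label, c("differentiallyExpressedIn", "FDR", "note"))
  expect_equal(props$range[props$label == "differentiallyExpressedIn"], "Contrast")
})

test_that("duplicate entity ids union their triples; counts track distinct ids", {
  df <- data.frame(g = c("g1", "g1"), v = c("a", "b"), stringsAsFactors = FALSE)
  cv <- convert_table(tabular_dataset(df))
  t <- cv$batch$triples
  g1 <- mint_entity_uri(default_namespace(), "g", "g1")
  # one entity URI, two attribute values
  expect_equal(cv$n_entities, 1L)
  expect_equal(sum(t$s == g1 & grepl("#v$", t$p)), 2L)

  set.seed(5)
  n <- 100L
  df <- data.frame(item = paste0("i", sample.int(40, n, replace = TRUE)),
                   val = as.character(seq_len(n)), stringsAsFactors = FALSE)
  cv <- convert_table(tabular_dataset(df))
  # brute-force distinct count over the source column
  expect_equal(cv$n_entities, length(unique(df$item)))
  ents <- unique(cv$batch$triples$s[grepl("/item/", cv$batch$triples$s)])
  expect_length(ents, length(unique(df$item)))
})

test_that("multi-valued relation cells split on comma; numeric typing is all-or-none", {
  df <- data.frame(x = "x1", `rel@T` = "a,b , c", mixed = "12",
                   check.names = FALSE, stringsAsFactors = FALSE)
  df2 <- data.frame(x = "x2", `rel@T` = NA, mixed = "12abc",
                    check.names = FALSE, stringsAsFactors = FALSE)
  cv <- convert_table(tabular_dataset(rbind(df, df2)))
  t <- cv$batch$triples
  expect_equal(sum(grepl("#rel$", t$p)), 3L)
  # one non-numeric cell makes the whole column string-typed
  expect_true(all(t$ot[grepl("#mixed$", t$p)] == "string"))
})

test_that("rows with invalid coordinates are skipped with a warning, not fatal", {
  df <- data.frame(peak = c("p1", "p2"), chromosome = "chr1",
                   start = c("100", "300"), end = c("200", "250"),
                   stringsAsFactors = FALSE)
  expect_warning(cv <- convert_table(tabular_dataset(df)), "p2")
  expect_equal(cv$skipped, 2L)
  expect_equal(cv$n_entities, 1L)
  expect_error(convert_table(tabular_dataset(
    data.frame(peak = "", v = "1", stringsAsFactors = FALSE))), "empty entity id")
})

test_that("GFF3 conversion builds the gene/mRNA/exon hierarchy with FALDO locations", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t100\t900\t.\t+\t.\tID=g1;Name=GENE1;biotype=protein_coding",
           "chr1\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=t1;Parent=g1",
           "chr1\tsrc\texon\t100\t400\t.\t+\t.\tID=e1;Parent=t1")
  cv <- convert_gff3(gff)
  expect_equal(cv$n_entities, 3L)
  t <- cv$batch$triples
  # 2 parent triples (mRNA->gene, exon->mRNA)
  expect_equal(sum(grepl("#parent$", t$p)), 2L)
  # 3 FALDO locations, one per record
  expect_equal(sum(t$p == "http://biohackathon.org/resource/faldo#location"), 3L)
  expect_setequal(vapply(cv$schema, `[[`, character(1), "label"),
                  c("gene", "mRNA", "exon"))
  # biotype carried as attribute
  expect_true(any(grepl("#biotype$", t$p) & t$o == "protein_coding"))
})

test_that("GFF3 multi-parent, missing-ID, filtering and error cases behave", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t1\t50\t.\t+\t.\tID=g1",
           "chr1\tsrc\tgene\t60\t100\t.\t-\t.\tID=g2",
           "chr1\tsrc\tmRNA\t1\t50\t.\t+\t.\tID=t1;Parent=g1,g2",
           "chr1\tsrc\texon\t1\t50\t.\t+\t.\tParent=t1",
           "chr1\tsrc\tregion\t1\t1000\t.\t.\t.\tID=r1")
  cv <- convert_gff3(gff)
  t <- cv$batch$triples
  # GFF3-spec multi-parent: two parent triples from t1
  t1 <- mint_entity_uri(default_namespace(), "mRNA", "t1")
  expect_equal(sum(t$s == t1 & grepl("#parent$", t$p)), 2L)
  # 'region' type is not whitelisted
  expect_equal(cv$n_entities, 4L)
  # ID-less exon got the deterministic synthetic id
  expect_true(any(grepl("/exon/exon%3Achr1%3A1-50%3A1$", t$s)))

  expect_equal(convert_gff3(c("##gff-version 3"))$n_entities, 0L)
  expect_error(convert_gff3("chr1\tsrc\tgene\t100"), "line 1")
  expect_error(convert_gff3("chr1\tsrc\tgene\t5\t2\t.\t+\t.\tID=x"),
               "start 5 > end 2")
  expect_warning(convert_gff3(c("chr1\tsrc\tmRNA\t1\t9\t.\t+\t.\tID=t;Parent=ghost")),
                 "ghost")
})

test_that("design tables become Condition/Context/Contrast entities with links", {
  d <- design_tables(
    conditions = data.frame(Condition = c("2Q", "2W", "4Q", "4W")),
    contexts = data.frame(Context = c("2Q", "2W", "4Q", "4W"),
                          condition = c("2Q", "2W", "4Q", "4W")),
    contrasts = data.frame(Contrast = c("2Qvs2W", "4Qvs4W"),
                           context_a = c("2Q", "4Q"), context_b = c("2W", "4W")))
  dg <- build_design_graph(d)
  expect_equal(dg$n_entities, 4L + 4L + 2L)
  t <- dg$batch$triples
  expect_equal(sum(grepl("#compares$", t$p)), 4L)  # 2 per contrast
  # a context aggregating two conditions emits two membership triples
  d2 <- design_tables(
    conditions = data.frame(Condition = c("a", "b")),
    contexts = data.frame(Context = "ab", condition = "a,b"),
    contrasts = data.frame(Contrast = character(), context_a = character(),
                           context_b = character()))
  t2 <- build_design_graph(d2)$batch$triples
  expect_equal(sum(grepl("#hasCondition$", t2$p)), 2L)

  expect_equal(n_triples(build_design_graph(design_tables())$batch), 0L)
  expect_error(design_tables(
    conditions = data.frame(Condition = "a"),
    contexts = data.frame(Context = "x", condition = "a"),
    contrasts = data.frame(Contrast = "bad", context_a = "x", context_b = "nope")),
    "undeclared context")
})

test_that("cross-links are inferred from @ columns and shared locatedness", {
  deg <- entity_class_def("DEG", properties = data.frame(
    label = "differentiallyExpressedIn", kind = "relation", range = "Contrast"))
  contrast <- entity_class_def("Contrast")
  links <- infer_links(list(deg, contrast))
  expect_equal(nrow(links), 1L)
  expect_true(links$resolved[1])

  g <- entity_class_def("gene", is_located = TRUE)
  p <- entity_class_def("ATACpeak", is_located = TRUE)
  links <- infer_links(list(g, p))
  expect_equal(links$kind, "location")
  expect_setequal(c(links$source, links$target), c("gene", "ATACpeak"))

  lone <- entity_class_def("Reference")
  expect_equal(nrow(infer_links(list(lone))), 0L)
  expect_warning(infer_links(list(deg)), "unresolved")
})
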
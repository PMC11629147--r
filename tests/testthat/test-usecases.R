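# Sheet concatenation and the use-case reproduction machinery, exercised on
# synthetic stand-in directories shaped like the published supplements.

test_that("concat_sheets conserves rows, order and per-sheet constants", {
  s1 <- data.frame(gene_id = c("a", "b"), fc = c("1", "2"), stringsAsFactors = FALSE)
  s2 <- data.frame(gene_id = c("c", "d", "e"), fc = c("3", "4", "5"),
                   stringsAsFactors = FALSE)
  ds <- concat_sheets(list(up = s1, down = s2),
                      added_columns = list(
                        "differentiallyExpressedIn@Contrast" = c(up = "X", down = "X"),
                        regulation_sense = c(up = "UP", down = "DOWN")),
                      output_entity = "DEG")
  expect_equal(nrow(ds$rows), 5L)
  expect_equal(ds$rows$gene_id, c("a", "b", "c", "d", "e"))  # never reordered
  expect_equal(ds$rows$regulation_sense, c("UP", "UP", "DOWN", "DOWN", "DOWN"))
  expect_equal(ds$entity_class, "DEG")

  # four sheets (type x sense): per-tag row counts preserved
  mk <- function(ids, type) data.frame(gene_id = ids, gene_type = type,
                                       stringsAsFactors = FALSE)
  ds4 <- concat_sheets(
    list(cu = mk(c("a", "b"), "protein_coding"), cd = mk("c", "protein_coding"),
         lu = mk(c("d", "e", "f"), "lncRNA"), ld = mk("g", "lncRNA")),
    added_columns = list(regulation_sense = c(cu = "UP", cd = "DOWN",
                                              lu = "UP", ld = "DOWN")),
    output_entity = "DEG")
  tab <- table(ds4$rows$gene_type, ds4$rows$regulation_sense)
  expect_equal(unname(tab["protein_coding", "UP"]), 2L)
  expect_equal(unname(tab["lncRNA", "UP"]), 3L)

  # empty sheet contributes zero rows, no error
  ds0 <- concat_sheets(list(a = s1, b = s1[0, ]),
                       added_columns = list(tag = c(a = "1", b = "2")),
                       output_entity = "X")
  expect_equal(nrow(ds0$rows), 2L)

  expect_error(concat_sheets(
    list(a = s1, b = data.frame(other = "x")), output_entity = "X"),
    "irreconcilable headers")
  expect_error(concat_sheets(list(a = s1), added_columns = list(tag = c(z = "1")),
                             output_entity = "X"),
               "no value for sheet")
})

test_that("HCM stand-in pipeline reproduces its planted counts end to end", {
  d <- file.path(tempdir(), "hcm_standin")
  counts <- write_hcm_standin(d)
  prepared <- prepare_hcm_inputs(d)
  # merged DEG table carries contrast + sense for every row
  deg <- prepared$datasets$DEG
  expect_equal(nrow(deg$rows), 10L)
  expect_setequal(unique(deg$rows$regulation_sense), c("UP", "DOWN"))
  # S4 two sheets -> one DMR table with methylation_sense in {hyper, hypo}
  dmr <- prepared$datasets$DMR
  expect_setequal(unique(dmr$rows$methylation_sense), c("hyper", "hypo"))
  expect_true("associatedGene@gene" %in% names(dmr$rows))
  # S6 six sheets -> one TF table with condition and proximal/distal columns
  tf <- prepared$datasets$TFmotif
  expect_equal(nrow(tf$rows), 6L)
  expect_setequal(unique(tf$rows$regulation_type), c("proximal", "distal"))

  store <- integrate_usecase(prepared)
  report <- run_reproduction(store, hcm_reproduction_suite(expected = counts))
  expect_true(all(report$pass))
  expect_equal(attr(report, "status"), 0L)
  unlink(d, recursive = TRUE)
})

test_that("honeybee stand-in pipeline reproduces its planted counts end to end", {
  d <- file.path(tempdir(), "bee_standin")
  counts <- write_honeybee_standin(d, seed = 3)
  store <- integrate_honeybee_dir(d)
  report <- run_reproduction(store, honeybee_reproduction_suite(expected = counts))
  expect_true(all(report$pass), info = paste(capture.output(print(report)), collapse = "\n"))
  unlink(d, recursive = TRUE)
})

test_that("missing supplements raise errors naming the expected file", {
  d <- file.path(tempdir(), "empty_supp")
  dir.create(d, showWarnings = FALSE)
  expect_error(prepare_hcm_inputs(d), "s3_coding_up.csv")
  expect_error(prepare_honeybee_inputs(d), "deg_2Qvs2W_up.csv")
  unlink(d, recursive = TRUE)
})

test_that("an empty reproduction suite reports success", {
  report <- run_reproduction(triplestore(), list())
  expect_equal(nrow(report), 0L)
  expect_equal(attr(report, "status"), 0L)
})

test_that("published expected counts are write-once constants", {
  hcm <- hcm_reproduction_suite()
  exp_hcm <- stats::setNames(vapply(hcm, `[[`, integer(1), "expected"),
                             vapply(hcm, `[[`, character(1), "name"))
  expect_equal(unname(exp_hcm[c("hcm_deg_up", "hcm_deg_down")]), c(691L, 835L))
  expect_equal(unname(exp_hcm[c("hcm_lncrna_up", "hcm_lncrna_down")]), c(264L, 207L))
  expect_equal(unname(exp_hcm[c("hcm_co_up", "hcm_co_down")]), c(297L, 523L))
  expect_equal(unname(exp_hcm[c("hcm_dmr_hyper", "hcm_dmr_hypo")]), c(1453L, 3600L))
  bee <- honeybee_reproduction_suite()
  exp_bee <- stats::setNames(vapply(bee, `[[`, integer(1), "expected"),
                             vapply(bee, `[[`, character(1), "name"))
  expect_equal(unname(exp_bee[c("bee_genes_switch_4Qvs4W", "bee_genes_switch_2Qvs2W")]),
               c(325L, 247L))
  expect_equal(unname(exp_bee[paste0("bee_atac_", c("2Q", "2W", "4Q", "4W"))]),
               c(253L, 382L, 4618L, 448L))
  expect_equal(unname(exp_bee[paste0("bee_chip_", c("2Q", "2W", "4Q", "4W"))]),
               c(37L, 181L, 703L, 578L))
  # every entry carries a citation and a compilable query shape
  expect_true(all(vapply(c(hcm, bee), function(e) nzchar(e$citation), logical(1))))
})

test_that("the CLI script is syntactically valid R", {
  cli <- system.file("scripts", "omigraph.R", package = "omigraph")
  expect_true(nzchar(cli))
  expect_silent(parse(file = cli))
})
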
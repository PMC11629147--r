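# Synthetic fixtures: a toy genome annotation plus omics tables with planted
# overlap/contrast structure and exact expected answers, so the whole
# pipeline is testable without external downloads.
#
# Genes are laid out sequentially per chromosome with generous gaps, so no
# two genes overlap; planted peaks/switch regions are *constructed* inside
# (or, for decoys, between) specific genes rather than sampled-and-checked,
# which makes every expected count exact by construction.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy GFF3 annotation with known ground truth
#'
#' Emits a valid GFF3 with gene -> mRNA -> exon/CDS hierarchies on
#' `n_refs` chromosomes, mixed strands, non-degenerate intervals, and
#' sequential non-overlapping gene layout. Deterministic per seed
#' (regeneration is byte-identical).
#'
#' @param n_genes number of genes (>= 1).
#' @param n_refs number of chromosomes (>= 1).
#' @param seed integer RNG seed.
#' @return list of class `truth_model` with elements `seed`, `genes`
#'   (data.frame id/name/reference/start/end/strand), `features`
#'   (data.frame type/id), `gff` (character lines), `gaps` (data.frame of
#'   intergenic intervals usable for decoys), `expected` (named integer map,
#'   filled by [generate_omics_tables()]), `tables` (list of data.frames).
#' @export
generate_toy_annotation <- function(n_genes, n_refs = 3L, seed = 1L) {
  stopifnot(n_genes >= 1L, n_refs >= 1L)
  with_seed(seed, {
    refs <- paste0("chr", seq_len(n_refs))
    gene_ref <- refs[((seq_len(n_genes) - 1L) %% n_refs) + 1L]
    lines <- "##gff-version 3"
    genes <- data.frame(id = character(), name = character(), reference = character(),
                        start = integer(), end = integer(), strand = character(),
                        stringsAsFactors = FALSE)
    feats <- data.frame(type = character(), id = character(), stringsAsFactors = FALSE)
    gaps <- data.frame(reference = character(), start = integer(), end = integer(),
                       stringsAsFactors = FALSE)
    cursor <- stats::setNames(rep(1000L, n_refs), refs)
    for (i in seq_len(n_genes)) {
      ref <- gene_ref[i]
      gap <- sample(400:900, 1L)
      len <- sample(800:3000, 1L)
      gstart <- cursor[[ref]] + gap
      gend <- gstart + len - 1L
      gaps <- rbind(gaps, data.frame(reference = ref, start = cursor[[ref]] + 1L,
                                     end = gstart - 1L))
      cursor[[ref]] <- gend
      strand <- sample(c("+", "-"), 1L)
      gid <- paste0("g", i)
      gname <- paste0("GENE", i)
      genes <- rbind(genes, data.frame(id = gid, name = gname, reference = ref,
                                       start = gstart, end = gend, strand = strand))
      lines <- c(lines, paste(ref, "toy", "gene", gstart, gend, ".", strand, ".",
                              paste0("ID=", gid, ";Name=", gname, ";biotype=protein_coding"),
                              sep = "\t"))
      feats <- rbind(feats, data.frame(type = "gene", id = gid))
      n_mrna <- sample(1:2, 1L)
      for (j in seq_len(n_mrna)) {
        tid <- paste0(gid, ".t", j)
        lines <- c(lines, paste(ref, "toy", "mRNA", gstart, gend, ".", strand, ".",
                                paste0("ID=", tid, ";Parent=", gid), sep = "\t"))
        feats <- rbind(feats, data.frame(type = "mRNA", id = tid))
        n_exon <- sample(1:3, 1L)
        width <- (gend - gstart + 1L) %/% n_exon
        for (k in seq_len(n_exon)) {
          es <- gstart + (k - 1L) * width
          ee <- if (k == n_exon) gend else es + width - 11L
          eid <- paste0(tid, ".e", k)
          lines <- c(lines, paste(ref, "toy", "exon", es, ee, ".", strand, ".",
                                  paste0("ID=", eid, ";Parent=", tid), sep = "\t"))
          feats <- rbind(feats, data.frame(type = "exon", id = eid))
          if (j == 1L) {
            cid <- paste0(tid, ".c", k)
            lines <- c(lines, paste(ref, "toy", "CDS", es, ee, ".", strand, "0",
                                    paste0("ID=", cid, ";Parent=", tid), sep = "\t"))
            feats <- rbind(feats, data.frame(type = "CDS", id = cid))
          }
        }
      }
    }
    # trailing gap per chromosome for decoys beyond the last gene
    for (ref in refs)
      gaps <- rbind(gaps, data.frame(reference = ref, start = cursor[[ref]] + 200L,
                                     end = cursor[[ref]] + 5000L))
    structure(list(seed = seed, genes = genes, features = feats, gff = lines,
                   gaps = gaps, expected = integer(), tables = list()),
              class = "truth_model")
  })
}

#' @export
print.truth_model <- function(x, ...) {
  cat("<truth_model> seed ", x$seed, ": ", nrow(x$genes), " genes, ",
      nrow(x$features), " features, ", length(x$tables), " table(s), ",
      length(x$expected), " expected count(s)\n", sep = "")
  invisible(x)
}

#' Default planted-structure specification for the fixture generator
#'
#' The shipped defaults emulate a two-contrast (2Qvs2W / 4Qvs4W), four
#' condition design with per-contrast DEG sets, ATAC peaks planted inside
#' chosen DE genes, conformation-switch regions planted over chosen genes,
#' a caste-annotation list intersecting the DEG/peak overlap set, and a focal
#' gene with associated DMRs.
#'
#' @return a named list of plant counts, editable before passing to
#'   [generate_omics_tables()].
#' @export
default_fixture_spec <- function() {
  list(
    contrasts = c("2Qvs2W", "4Qvs4W"),
    conditions = c("2Q", "2W", "4Q", "4W"),
    deg = list("2Qvs2W" = c(UP = 8L, DOWN = 12L),
               "4Qvs4W" = c(UP = 18L, DOWN = 12L)),
    deg_peak_overlaps = c("2Qvs2W" = 4L, "4Qvs4W" = 7L),
    gene_switch_overlaps = c("2Qvs2W" = 6L, "4Qvs4W" = 10L),
    atac_decoys = 12L,
    switch_decoys = 8L,
    caste_in_overlap = 3L,
    caste_extra = 5L,
    focal_hyper_dmrs = 2L,
    focal_hypo_dmrs = 1L
  )
}

#' Generate omics result tables with planted ground truth
#'
#' Builds, on top of a [generate_toy_annotation()] truth model, the table
#' battery the integration schema consumes: a DEG table (first column `gene`,
#' `differentiallyExpressedIn@Contrast` + regulation sense), ATAC peaks per
#' Condition (planted inside chosen DE genes, decoys in intergenic gaps),
#' Hi-C-style conformation switch regions per Contrast, a DMR table tied to a
#' focal gene by an `associatedGene@gene` relation, a caste-annotation gene
#' list, and the Condition/Context/Contrast design tables. Fills
#' `truth$expected` with the exact planted answers.
#'
#' @param truth a `truth_model`.
#' @param spec plant structure; see `default_fixture_spec()` in the sources.
#'   Counts exceeding geometric feasibility raise an error.
#' @param seed integer RNG seed for the planting choices.
#' @return the updated `truth_model` (tables under `$tables`, answers under
#'   `$expected`, focal gene id under `$focal_gene`).
#' @export
generate_omics_tables <- function(truth, spec = default_fixture_spec(), seed = 1L) {
  stopifnot(inherits(truth, "truth_model"))
  genes <- truth$genes
  need <- sum(vapply(spec$deg, sum, integer(1))) +
    sum(spec$gene_switch_overlaps) + spec$caste_extra
  if (need > nrow(genes))
    stop("planted structure needs ", need, " genes but annotation has only ",
         nrow(genes), "; raise n_genes")
  for (ct in names(spec$deg_peak_overlaps))
    if (spec$deg_peak_overlaps[[ct]] > sum(spec$deg[[ct]]))
      stop("cannot plant ", spec$deg_peak_overlaps[[ct]], " DEG/peak overlaps in ",
           ct, ": only ", sum(spec$deg[[ct]]), " DEGs requested")
  if (spec$caste_in_overlap > spec$deg_peak_overlaps[["4Qvs4W"]])
    stop("caste_in_overlap exceeds planted 4Qvs4W DEG/peak overlaps")

  with_seed(seed + 1L, {
    pool <- sample(genes$id)
    take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }

    # --- DEG table ---------------------------------------------------------
    deg_rows <- list()
    deg_sets <- list()
    for (ct in names(spec$deg)) {
      ids <- take(sum(spec$deg[[ct]]))
      deg_sets[[ct]] <- ids
      sense <- rep(c("UP", "DOWN"), times = spec$deg[[ct]][c("UP", "DOWN")])
      deg_rows[[ct]] <- data.frame(
        gene = ids,
        `differentiallyExpressedIn@Contrast` = ct,
        regulation_sense = sense,
        log2FC = round(ifelse(sense == "UP", 1, -1) * stats::runif(length(ids), 0.8, 4), 3),
        pvalue = signif(stats::runif(length(ids), 1e-8, 1e-3), 3),
        FDR = signif(stats::runif(length(ids), 1e-6, 0.05), 3),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    deg <- do.call(rbind, deg_rows); rownames(deg) <- NULL

    # --- ATAC peaks --------------------------------------------------------
    peak_condition <- c("2Qvs2W" = "2Q", "4Qvs4W" = "4Q")
    peaks <- list(); pn <- 0L
    overlap_sets <- list()
    for (ct in names(spec$deg_peak_overlaps)) {
      k <- spec$deg_peak_overlaps[[ct]]
      host <- deg_sets[[ct]][seq_len(k)]
      overlap_sets[[ct]] <- host
      for (gid in host) {
        g <- genes[genes$id == gid, ]
        ps <- g$start + (g$end - g$start) %/% 4L
        pe <- min(g$end, ps + 120L)
        pn <- pn + 1L
        peaks[[pn]] <- data.frame(atac_peak = paste0("P", pn),
                                  chromosome = g$reference, start = ps, end = pe,
                                  strand = ".", `measuredIn@Condition` = peak_condition[[ct]],
                                  fold_change = round(stats::runif(1, 2, 20), 2),
                                  check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
    gaps <- truth$gaps[truth$gaps$end - truth$gaps$start >= 160L, , drop = FALSE]
    if (spec$atac_decoys + spec$switch_decoys > nrow(gaps))
      stop("not enough intergenic gaps for the requested decoys")
    gap_idx <- sample(nrow(gaps), spec$atac_decoys + spec$switch_decoys)
    for (d in seq_len(spec$atac_decoys)) {
      gp <- gaps[gap_idx[d], ]
      ps <- gp$start + 20L; pe <- min(gp$end - 20L, ps + 100L)
      pn <- pn + 1L
      peaks[[pn]] <- data.frame(atac_peak = paste0("P", pn),
                                chromosome = gp$reference, start = ps, end = pe,
                                strand = ".",
                                `measuredIn@Condition` = spec$conditions[((d - 1L) %% 4L) + 1L],
                                fold_change = round(stats::runif(1, 2, 20), 2),
                                check.names = FALSE, stringsAsFactors = FALSE)
    }
    atac <- do.call(rbind, peaks); rownames(atac) <- NULL

    # --- Hi-C style switch regions ----------------------------------------
    sw <- list(); sn <- 0L
    switch_sets <- list()
    for (ct in names(spec$gene_switch_overlaps)) {
      ids <- take(spec$gene_switch_overlaps[[ct]])
      switch_sets[[ct]] <- ids
      for (gid in ids) {
        g <- genes[genes$id == gid, ]
        sn <- sn + 1L
        sw[[sn]] <- data.frame(switch_region = paste0("S", sn),
                               chromosome = g$reference,
                               start = max(1L, g$start - 10L), end = g$end + 10L,
                               `switchedIn@Contrast` = ct,
                               switch_direction = if (sn %% 2L) "AtoB" else "BtoA",
                               score = round(stats::runif(1, 0.1, 1), 3),
                               check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
    for (d in seq_len(spec$switch_decoys)) {
      gp <- gaps[gap_idx[spec$atac_decoys + d], ]
      ss <- gp$start + 30L; se <- min(gp$end - 30L, ss + 80L)
      sn <- sn + 1L
      sw[[sn]] <- data.frame(switch_region = paste0("S", sn),
                             chromosome = gp$reference, start = ss, end = se,
                             `switchedIn@Contrast` = spec$contrasts[((d - 1L) %% 2L) + 1L],
                             switch_direction = if (d %% 2L) "AtoB" else "BtoA",
                             score = round(stats::runif(1, 0.1, 1), 3),
                             check.names = FALSE, stringsAsFactors = FALSE)
    }
    switch_tab <- do.call(rbind, sw); rownames(switch_tab) <- NULL

    # --- caste annotation list --------------------------------------------
    caste_ids <- c(overlap_sets[["4Qvs4W"]][seq_len(spec$caste_in_overlap)],
                   take(spec$caste_extra))
    caste <- data.frame(gene = caste_ids, annotation = "caste_differentiation",
                        stringsAsFactors = FALSE)

    # --- DMRs tied to a focal gene ----------------------------------------
    focal <- deg_sets[["4Qvs4W"]][1]
    fg <- genes[genes$id == focal, ]
    n_dmr <- spec$focal_hyper_dmrs + spec$focal_hypo_dmrs
    dmr <- data.frame(
      dmr = paste0("D", seq_len(n_dmr)),
      chromosome = fg$reference,
      start = fg$start + (seq_len(n_dmr) - 1L) * 150L,
      end = fg$start + (seq_len(n_dmr) - 1L) * 150L + 99L,
      `associatedGene@gene` = focal,
      `differentiallyMethylatedIn@Contrast` = "4Qvs4W",
      methylation_sense = rep(c("hyper", "hypo"),
                              c(spec$focal_hyper_dmrs, spec$focal_hypo_dmrs)),
      check.names = FALSE, stringsAsFactors = FALSE)

    # --- design tables -----------------------------------------------------
    conditions <- data.frame(Condition = spec$conditions,
                             description = paste("condition", spec$conditions),
                             stringsAsFactors = FALSE)
    contexts <- data.frame(Context = spec$conditions, condition = spec$conditions,
                           stringsAsFactors = FALSE)
    contrasts <- data.frame(Contrast = spec$contrasts,
                            context_a = c("2Q", "4Q"), context_b = c("2W", "4W"),
                            stringsAsFactors = FALSE)

    expected <- c(
      stats::setNames(vapply(names(spec$deg), function(ct) sum(spec$deg[[ct]]), integer(1)),
                      paste0("deg_", names(spec$deg))),
      stats::setNames(vapply(names(spec$deg), function(ct) spec$deg[[ct]][["UP"]], integer(1)),
                      paste0("deg_up_", names(spec$deg))),
      stats::setNames(vapply(names(spec$deg), function(ct) spec$deg[[ct]][["DOWN"]], integer(1)),
                      paste0("deg_down_", names(spec$deg))),
      stats::setNames(vapply(spec$conditions, function(cd)
        sum(atac[["measuredIn@Condition"]] == cd), integer(1)),
        paste0("atac_", spec$conditions)),
      stats::setNames(as.integer(spec$deg_peak_overlaps),
                      paste0("deg_atac_", names(spec$deg_peak_overlaps))),
      stats::setNames(as.integer(spec$gene_switch_overlaps),
                      paste0("genes_switch_", names(spec$gene_switch_overlaps))),
      deg_atac_caste_4Qvs4W = spec$caste_in_overlap,
      focal_hyper_dmr = spec$focal_hyper_dmrs,
      n_genes = nrow(genes)
    )

    truth$tables <- list(deg = deg, atac_peak = atac, switch_region = switch_tab,
                         caste_gene = caste, dmr = dmr,
                         conditions = conditions, contexts = contexts,
                         contrasts = contrasts)
    truth$expected <- expected
    truth$focal_gene <- focal
    truth
  })
}

#' Query graphs answering every planted fixture question
#'
#' @param truth a `truth_model` with tables generated.
#' @return named list of [query_graph()], keyed like `truth$expected`.
#' @export
fixture_queries <- function(truth) {
  ct_node <- function(ct) query_node("c", "Contrast", filters = list(list("label", "=", ct)))
  qs <- list()
  for (ct in c("2Qvs2W", "4Qvs4W")) {
    qs[[paste0("deg_", ct)]] <- query_graph(
      list(query_node("g", "gene"), ct_node(ct)),
      list(query_edge("g", "c", "relation", relation_label = "differentiallyExpressedIn")),
      count_distinct = "g")
    for (sense in c("UP", "DOWN")) {
      qs[[paste0("deg_", tolower(sense), "_", ct)]] <- query_graph(
        list(query_node("g", "gene",
                        filters = list(list("regulation_sense", "=", sense))),
             ct_node(ct)),
        list(query_edge("g", "c", "relation", relation_label = "differentiallyExpressedIn")),
        count_distinct = "g")
    }
    qs[[paste0("deg_atac_", ct)]] <- query_graph(
      list(query_node("g", "gene"), ct_node(ct), query_node("p", "atac_peak")),
      list(query_edge("g", "c", "relation", relation_label = "differentiallyExpressedIn"),
           query_edge("g", "p", "overlap")),
      count_distinct = "g")
    qs[[paste0("genes_switch_", ct)]] <- query_graph(
      list(query_node("g", "gene"), query_node("s", "switch_region"), ct_node(ct)),
      list(query_edge("g", "s", "overlap"),
           query_edge("s", "c", "relation", relation_label = "switchedIn")),
      count_distinct = "g")
  }
  for (cd in c("2Q", "2W", "4Q", "4W")) {
    qs[[paste0("atac_", cd)]] <- query_graph(
      list(query_node("p", "atac_peak"),
           query_node("k", "Condition", filters = list(list("label", "=", cd)))),
      list(query_edge("p", "k", "relation", relation_label = "measuredIn")),
      count_distinct = "p")
  }
  qs[["deg_atac_caste_4Qvs4W"]] <- query_graph(
    list(query_node("g", "gene",
                    filters = list(list("annotation", "=", "caste_differentiation"))),
         ct_node("4Qvs4W"), query_node("p", "atac_peak")),
    list(query_edge("g", "c", "relation", relation_label = "differentiallyExpressedIn"),
         query_edge("g", "p", "overlap")),
    count_distinct = "g")
  qs[["focal_hyper_dmr"]] <- query_graph(
    list(query_node("d", "dmr", filters = list(list("methylation_sense", "=", "hyper"))),
         query_node("g", "gene", filters = list(list("label", "=", truth$focal_gene)))),
    list(query_edge("d", "g", "relation", relation_label = "associatedGene")),
    count_distinct = "d")
  qs[["n_genes"]] <- query_graph(list(query_node("g", "gene")), count_distinct = "g")
  qs
}

#' Write a complete fixture set to a directory
#'
#' Writes the GFF3, one CSV per omics table, the design CSVs and a
#' `truth.json` with the expected answers.
#'
#' @param dir output directory (created).
#' @param n_genes,n_refs,seed,spec forwarded to the generators.
#' @return the `truth_model`, invisibly.
#' @export
write_fixture_set <- function(dir, n_genes = 80L, n_refs = 3L, seed = 1L,
                              spec = default_fixture_spec()) {
  truth <- generate_toy_annotation(n_genes, n_refs, seed)
  truth <- generate_omics_tables(truth, spec, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(truth$gff, file.path(dir, "annotation.gff3"))
  for (nm in c("deg", "atac_peak", "switch_region", "caste_gene", "dmr",
               "conditions", "contexts", "contrasts"))
    utils::write.csv(truth$tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(
    list(seed = truth$seed, focal_gene = truth$focal_gene,
         expected = as.list(truth$expected)),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(truth)
}

#' Integrate a truth model (or a fixture directory) into a fresh store
#'
#' @param x a `truth_model`, or a directory written by [write_fixture_set()].
#' @param namespace project namespace.
#' @return a [triplestore()] with one named graph per source.
#' @export
integrate_fixtures <- function(x, namespace = default_namespace()) {
  store <- triplestore()
  if (is.character(x)) {
    gff <- convert_gff3(file.path(x, "annotation.gff3"), namespace)
    load_graph(store, gff$batch, gff$schema, source = "annotation.gff3")
    for (nm in c("deg", "atac_peak", "switch_region", "caste_gene", "dmr")) {
      ds <- read_table_dataset(file.path(x, paste0(nm, ".csv")))
      cv <- convert_table(ds, namespace,
                          graph_name = paste0(sub("/+$", "", namespace), "/graph/", nm))
      load_graph(store, cv$batch, cv$schema, source = paste0(nm, ".csv"))
    }
    design <- design_tables(
      utils::read.csv(file.path(x, "conditions.csv"), colClasses = "character"),
      utils::read.csv(file.path(x, "contexts.csv"), colClasses = "character"),
      utils::read.csv(file.path(x, "contrasts.csv"), colClasses = "character"))
    dg <- build_design_graph(design, namespace)
    load_graph(store, dg$batch, dg$schema, source = "design")
    return(store)
  }
  stopifnot(inherits(x, "truth_model"))
  gff <- convert_gff3(x$gff, namespace)
  load_graph(store, gff$batch, gff$schema, source = "annotation")
  for (nm in c("deg", "atac_peak", "switch_region", "caste_gene", "dmr")) {
    cv <- convert_table(tabular_dataset(x$tables[[nm]]), namespace,
                        graph_name = paste0(sub("/+$", "", namespace), "/graph/", nm))
    load_graph(store, cv$batch, cv$schema, source = nm)
  }
  design <- design_tables(x$tables$conditions, x$tables$contexts, x$tables$contrasts)
  dg <- build_design_graph(design, namespace)
  load_graph(store, dg$batch, dg$schema, source = "design")
  store
}

#' Run the end-to-end fixture demo
#'
#' Generates fixtures, integrates them, compiles and executes every planted
#' query, and compares observed with expected counts.
#'
#' @param outdir directory the fixture files are written to; `NULL` keeps
#'   everything in memory.
#' @param seed integer seed.
#' @param n_genes,n_refs annotation size.
#' @param spec plant structure.
#' @return data.frame report: `name`, `expected`, `observed`, `pass`.
#' @export
run_demo <- function(outdir = NULL, seed = 1L, n_genes = 80L, n_refs = 3L,
                     spec = default_fixture_spec()) {
  if (!is.null(outdir)) {
    truth <- write_fixture_set(outdir, n_genes, n_refs, seed, spec)
    store <- integrate_fixtures(outdir)
  } else {
    truth <- generate_toy_annotation(n_genes, n_refs, seed)
    truth <- generate_omics_tables(truth, spec, seed)
    store <- integrate_fixtures(truth)
  }
  qs <- fixture_queries(truth)
  out <- data.frame(name = names(truth$expected),
                    expected = as.integer(truth$expected),
                    observed = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out)))
    out$observed[i] <- count_distinct(store, qs[[out$name[i]]])
  out$pass <- out$expected == out$observed
  out
}
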
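# Use-case preprocessing and reproduction suites.
#
# Two published multi-omics studies are reproduced on top of the schema:
# a hypertrophic-cardiomyopathy (HCM) study (human, hg19) combining DEGs,
# lncRNAs, co-regulated genes, DMRs and TF motifs, and a honeybee
# caste-differentiation study (Amel_HAv3.1) combining DEGs, Hi-C A/B
# compartment switches, ATAC-seq and ChIP-seq peaks plus curated gene lists.
# Their supplementary tables arrive split per contrast / regulation sense /
# condition; the prepare functions concatenate them back and add the
# Contrast / sense / Condition columns the schema expects. The supplements
# themselves are NOT redistributed: callers download them (see README) or use
# the synthetic stand-in writers, which produce directories of the same shape
# with known counts.

#' Concatenate spreadsheet tables into one dataset
#'
#' Rows are conserved and never reordered within a sheet; per-sheet constant
#' columns (typically the Contrast and the regulation sense) are appended.
#'
#' @param sheets named list of data.frames; names label the sheets.
#' @param added_columns named list: column name -> named character vector
#'   giving that column's constant value per sheet label.
#' @param output_entity entity class of the combined table.
#' @param id_prefix when given, a synthetic first column `<output_entity>` is
#'   prepended with ids `<id_prefix><row>` (for tables, like DMRs, that have
#'   no natural id column).
#' @return a [tabular_dataset()].
#' @export
concat_sheets <- function(sheets, added_columns = list(), output_entity,
                          id_prefix = NULL) {
  stopifnot(is.list(sheets), length(sheets) >= 1L, !is.null(names(sheets)))
  ref_names <- names(sheets[[1]])
  for (lab in names(sheets)) {
    if (!identical(names(sheets[[lab]]), ref_names))
      stop("irreconcilable headers in sheet '", lab, "': got [",
           paste(names(sheets[[lab]]), collapse = ", "), "], expected [",
           paste(ref_names, collapse = ", "), "]")
  }
  for (col in names(added_columns)) {
    missing <- setdiff(names(sheets), names(added_columns[[col]]))
    if (length(missing))
      stop("added column '", col, "' has no value for sheet(s): ",
           paste(missing, collapse = ", "))
  }
  parts <- lapply(names(sheets), function(lab) {
    df <- sheets[[lab]]
    df <- as.data.frame(lapply(df, as.character), stringsAsFactors = FALSE,
                        check.names = FALSE)
    names(df) <- ref_names
    for (col in names(added_columns))
      df[[col]] <- rep(added_columns[[col]][[lab]], max(nrow(df), 0L))
    df
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  if (!is.null(id_prefix)) {
    ids <- paste0(id_prefix, seq_len(nrow(out)))
    out <- cbind(stats::setNames(data.frame(ids, stringsAsFactors = FALSE),
                                 output_entity), out)
  }
  tabular_dataset(out, entity_class = output_entity)
}

require_supplement <- function(dir, file, what) {
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop("missing expected supplement file '", file, "' (", what, ") in ", dir,
         "; download the study supplements or generate a stand-in directory")
  path
}

read_sheet <- function(path) {
  utils::read.csv(path, colClasses = "character", check.names = FALSE)
}

# --- use-case 1: hypertrophic cardiomyopathy -------------------------------

#' Prepare the HCM study inputs from a supplement directory
#'
#' Expects CSV conversions of the study's supplementary tables:
#' `s3_coding_up.csv`, `s3_coding_down.csv`, `s3_lncrna_up.csv`,
#' `s3_lncrna_down.csv` (DEG sheets), `s5_co_up.csv`, `s5_co_down.csv`
#' (co-regulated genes), `s4_hyper.csv`, `s4_hypo.csv` (DMRs, with columns
#' chromosome/start/end/associated_gene), and six TF-motif sheets
#' `s6_<condition>_<proximal|distal>.csv`. Produces the merged DEG table
#' (Contrast + regulation sense), the co-regulated table, the DMR table
#' (Contrast + hyper/hypo, gene association as a relation), the TF table
#' (Condition + proximal/distal) and the Control/HCM/Fetus design tables.
#'
#' @param supp_dir directory of supplement CSVs.
#' @return list with `datasets` (named list of [tabular_dataset()]) and
#'   `design` (a [design_tables()]).
#' @export
prepare_hcm_inputs <- function(supp_dir) {
  deg_sheets <- list(
    coding_up   = read_sheet(require_supplement(supp_dir, "s3_coding_up.csv",   "Table S3 protein-coding up-regulated")),
    coding_down = read_sheet(require_supplement(supp_dir, "s3_coding_down.csv", "Table S3 protein-coding down-regulated")),
    lncrna_up   = read_sheet(require_supplement(supp_dir, "s3_lncrna_up.csv",   "Table S3 lncRNA up-regulated")),
    lncrna_down = read_sheet(require_supplement(supp_dir, "s3_lncrna_down.csv", "Table S3 lncRNA down-regulated")))
  deg <- concat_sheets(deg_sheets,
    added_columns = list(
      "differentiallyExpressedIn@Contrast" = c(coding_up = "HCMvsControl",
        coding_down = "HCMvsControl", lncrna_up = "HCMvsControl",
        lncrna_down = "HCMvsControl"),
      regulation_sense = c(coding_up = "UP", coding_down = "DOWN",
                           lncrna_up = "UP", lncrna_down = "DOWN")),
    output_entity = "DEG")

  co_sheets <- list(
    co_up   = read_sheet(require_supplement(supp_dir, "s5_co_up.csv",   "Table S5 co-up-regulated genes")),
    co_down = read_sheet(require_supplement(supp_dir, "s5_co_down.csv", "Table S5 co-down-regulated genes")))
  co <- concat_sheets(co_sheets,
    added_columns = list(regulation_sense = c(co_up = "UP", co_down = "DOWN")),
    output_entity = "CoRegulated")

  dmr_sheets <- list(
    hyper = read_sheet(require_supplement(supp_dir, "s4_hyper.csv", "Table S4 hyper-methylated DMRs")),
    hypo  = read_sheet(require_supplement(supp_dir, "s4_hypo.csv",  "Table S4 hypo-methylated DMRs")))
  dmr_sheets <- lapply(dmr_sheets, function(df) {
    names(df)[names(df) == "associated_gene"] <- "associatedGene@gene"
    df
  })
  dmr <- concat_sheets(dmr_sheets,
    added_columns = list(
      methylation_sense = c(hyper = "hyper", hypo = "hypo"),
      "differentiallyMethylatedIn@Contrast" = c(hyper = "HCMvsControl",
                                                hypo = "HCMvsControl")),
    output_entity = "DMR", id_prefix = "DMR_")

  tf_sheets <- list()
  for (cond in c("Control", "HCM", "Fetus")) {
    for (kind in c("proximal", "distal")) {
      lab <- paste0(tolower(cond), "_", kind)
      tf_sheets[[lab]] <- read_sheet(require_supplement(
        supp_dir, paste0("s6_", lab, ".csv"),
        paste("Table S6", cond, kind, "TF motifs")))
    }
  }
  added_cond <- stats::setNames(rep(c("Control", "HCM", "Fetus"), each = 2L),
                                names(tf_sheets))
  added_kind <- stats::setNames(rep(c("proximal", "distal"), times = 3L),
                                names(tf_sheets))
  tf_sheets <- lapply(tf_sheets, function(df) {
    names(df)[names(df) == "target_gene"] <- "targetGene@gene"
    df
  })
  tf <- concat_sheets(tf_sheets,
    added_columns = list("relatedCondition@Condition" = added_cond,
                         regulation_type = added_kind),
    output_entity = "TFmotif", id_prefix = "TF_")

  design <- design_tables(
    conditions = data.frame(Condition = c("Control", "HCM", "Fetus"),
                            stringsAsFactors = FALSE),
    contexts = data.frame(Context = c("Control", "HCM", "Fetus"),
                          condition = c("Control", "HCM", "Fetus"),
                          stringsAsFactors = FALSE),
    contrasts = data.frame(Contrast = c("HCMvsControl", "FetusvsControl"),
                           context_a = c("HCM", "Fetus"),
                           context_b = c("Control", "Control"),
                           stringsAsFactors = FALSE))
  list(datasets = list(DEG = deg, CoRegulated = co, DMR = dmr, TFmotif = tf),
       design = design)
}

# --- use-case 2: honeybee caste differentiation ----------------------------

#' Prepare the honeybee study inputs from a supplement directory
#'
#' Expects CSV conversions of the study's supplements: four DEG sheets
#' `deg_<contrast>_<up|down>.csv` (first column the gene id, matching the
#' genome annotation's gene ids), four Hi-C sheets `hic_<contrast>_<AtoB|BtoA>.csv`
#' (100-kb regions: chromosome/start/end/score), four ATAC sheets
#' `atac_<condition>.csv` and four ChIP sheets `chip_<condition>.csv`
#' (chromosome/start/end plus statistics), and the curated lists
#' `caste_genes.csv` and `aft1_targets.csv` (included as-is).
#'
#' @param supp_dir directory of supplement CSVs.
#' @return list with `datasets` and `design` as in [prepare_hcm_inputs()].
#' @export
prepare_honeybee_inputs <- function(supp_dir) {
  contrasts <- c("2Qvs2W", "4Qvs4W")
  conditions <- c("2Q", "2W", "4Q", "4W")

  deg_sheets <- list()
  for (ct in contrasts) for (sense in c("up", "down"))
    deg_sheets[[paste0(ct, "_", sense)]] <- read_sheet(require_supplement(
      supp_dir, paste0("deg_", ct, "_", sense, ".csv"),
      paste("DEG sheet", ct, toupper(sense))))
  deg <- concat_sheets(deg_sheets,
    added_columns = list(
      "differentiallyExpressedIn@Contrast" = stats::setNames(
        rep(contrasts, each = 2L), names(deg_sheets)),
      regulation_sense = stats::setNames(rep(c("UP", "DOWN"), times = 2L),
                                         names(deg_sheets))),
    output_entity = "gene")

  hic_sheets <- list()
  for (ct in contrasts) for (dir_ in c("AtoB", "BtoA"))
    hic_sheets[[paste0(ct, "_", dir_)]] <- read_sheet(require_supplement(
      supp_dir, paste0("hic_", ct, "_", dir_, ".csv"),
      paste("Hi-C switch sheet", ct, dir_)))
  hic <- concat_sheets(hic_sheets,
    added_columns = list(
      "switchedIn@Contrast" = stats::setNames(rep(contrasts, each = 2L),
                                              names(hic_sheets)),
      switch_direction = stats::setNames(rep(c("AtoB", "BtoA"), times = 2L),
                                         names(hic_sheets))),
    output_entity = "switch_region", id_prefix = "SW_")

  peak_table <- function(prefix, entity, idp) {
    sheets <- list()
    for (cd in conditions)
      sheets[[cd]] <- read_sheet(require_supplement(
        supp_dir, paste0(prefix, "_", cd, ".csv"),
        paste(toupper(prefix), "peaks, condition", cd)))
    concat_sheets(sheets,
      added_columns = list("measuredIn@Condition" = stats::setNames(conditions, conditions)),
      output_entity = entity, id_prefix = idp)
  }
  atac <- peak_table("atac", "atac_peak", "AP_")
  chip <- peak_table("chip", "chip_peak", "CP_")

  caste <- tabular_dataset(read_sheet(require_supplement(
    supp_dir, "caste_genes.csv", "curated caste-differentiation gene list")),
    entity_class = "gene")
  aft1 <- tabular_dataset(read_sheet(require_supplement(
    supp_dir, "aft1_targets.csv", "curated Aft1 target list")),
    entity_class = "gene")

  design <- design_tables(
    conditions = data.frame(Condition = conditions, stringsAsFactors = FALSE),
    contexts = data.frame(Context = conditions, condition = conditions,
                          stringsAsFactors = FALSE),
    contrasts = data.frame(Contrast = contrasts,
                           context_a = c("2Q", "4Q"), context_b = c("2W", "4W"),
                           stringsAsFactors = FALSE))
  list(datasets = list(gene_deg = deg, switch_region = hic, atac_peak = atac,
                       chip_peak = chip, caste = caste, aft1 = aft1),
       design = design)
}

#' Integrate prepared use-case inputs into a store
#'
#' @param prepared output of [prepare_hcm_inputs()] or
#'   [prepare_honeybee_inputs()].
#' @param store optionally, an existing [triplestore()] (e.g. already holding
#'   the genome annotation); a fresh one is created otherwise.
#' @param namespace project namespace.
#' @return the [triplestore()].
#' @export
integrate_usecase <- function(prepared, store = NULL,
                              namespace = default_namespace()) {
  if (is.null(store)) store <- triplestore()
  for (nm in names(prepared$datasets)) {
    cv <- convert_table(prepared$datasets[[nm]], namespace,
                        graph_name = paste0(sub("/+$", "", namespace), "/graph/", nm))
    load_graph(store, cv$batch, cv$schema, source = nm)
  }
  dg <- build_design_graph(prepared$design, namespace)
  load_graph(store, dg$batch, dg$schema, source = "design")
  store
}
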
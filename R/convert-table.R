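# Lifting tabular omics results into triples.
#
# Conventions (AskOmics-style): the first column names the entity class and
# holds entity ids; a header of the form `relation@TargetClass` declares a
# relation column; headers matching chromosome/start/end/strand synonyms are
# positional; everything else is an attribute.

POSITION_SYNONYMS <- list(
  position_reference = c("chromosome", "chrom", "chr", "ref", "reference", "seqid"),
  position_start     = c("start", "begin"),
  position_end       = c("end", "stop"),
  position_strand    = c("strand")
)

#' Classify table headers into column roles
#'
#' @param headers character vector of column headers; the first is always the
#'   entity-id column (its text names the entity class).
#' @return data.frame with one row per header: `source_header`, `role`
#'   (`entity_id`, `attribute`, `relation`, `position_reference`,
#'   `position_start`, `position_end`, `position_strand`), and for relation
#'   columns `relation_label` / `target_class` (split at the last `"@"`).
#' @examples
#' classify_headers(c("DEG", "differentiallyExpressedIn@Contrast", "FDR"))
#' @export
classify_headers <- function(headers) {
  stopifnot(length(headers) >= 1L)
  headers <- as.character(headers)
  dup <- unique(headers[duplicated(headers)])
  if (length(dup))
    stop("duplicate column header(s): ", paste(dup, collapse = ", "))
  out <- data.frame(source_header = headers, role = "attribute",
                    relation_label = NA_character_, target_class = NA_character_,
                    stringsAsFactors = FALSE)
  out$role[1] <- "entity_id"
  for (i in seq_along(headers)[-1]) {
    h <- headers[i]
    if (grepl("@", h, fixed = TRUE)) {
      at <- regexpr("@[^@]*$", h)
      out$role[i] <- "relation"
      out$relation_label[i] <- substr(h, 1L, at - 1L)
      out$target_class[i] <- substr(h, at + 1L, nchar(h))
      if (!nzchar(out$relation_label[i]) || !nzchar(out$target_class[i]))
        stop("malformed relation header '", h, "' (expected label@TargetClass)")
      next
    }
    lh <- tolower(h)
    for (role in names(POSITION_SYNONYMS)) {
      if (lh %in% POSITION_SYNONYMS[[role]]) { out$role[i] <- role; break }
    }
  }
  for (role in c("position_reference", "position_start", "position_end", "position_strand")) {
    k <- sum(out$role == role)
    if (k > 1L) stop("multiple columns classified as ", role)
  }
  out
}

#' Assemble a tabular dataset
#'
#' @param df data.frame as read from a CSV/TSV (header row preserved in
#'   `names(df)`); all cells are treated as text until typed.
#' @param entity_class optional class-name override; defaults to the first
#'   column's header.
#' @return list of class `tabular_dataset` with `entity_class`, `columns`
#'   (role table from [classify_headers()]) and `rows` (character data.frame).
#' @export
tabular_dataset <- function(df, entity_class = NULL) {
  stopifnot(is.data.frame(df), ncol(df) >= 1L)
  cols <- classify_headers(names(df))
  pos <- cols$role %in% c("position_reference", "position_start", "position_end")
  have <- sort(unique(cols$role[pos]))
  if (length(have) > 0L && !identical(have, c("position_end", "position_reference", "position_start")))
    stop("position columns are all-or-none: need chromosome, start and end together")
  rows <- as.data.frame(lapply(df, as.character), stringsAsFactors = FALSE,
                        check.names = FALSE)
  structure(list(entity_class = entity_class %||% names(df)[1],
                 columns = cols, rows = rows),
            class = "tabular_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a delimited file as a tabular dataset
#'
#' The delimiter is sniffed from the header line (tab wins over comma over
#' semicolon) unless given.
#'
#' @param path CSV/TSV file with a header row.
#' @param delim optional delimiter override.
#' @param entity_class optional class-name override.
#' @return a [tabular_dataset()].
#' @export
read_table_dataset <- function(path, delim = NULL, entity_class = NULL) {
  if (!file.exists(path)) stop("no such table file: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(delim)) {
    delim <- if (grepl("\t", header)) "\t"
             else if (grepl(",", header)) ","
             else if (grepl(";", header)) ";" else ","
  }
  df <- utils::read.delim(path, sep = delim, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""), quote = "\"",
                          comment.char = "")
  tabular_dataset(df, entity_class = entity_class)
}

# TRUE iff every non-empty cell parses as a number; integer kept integral.
detect_literal_type <- function(cells) {
  v <- cells[!is.na(cells) & nzchar(cells)]
  if (length(v) == 0L) return("string")
  suppressWarnings(num <- as.numeric(v))
  if (anyNA(num)) return("string")
  if (all(grepl("^[+-]?[0-9]+$", v)) &&
      all(num >= -.Machine$integer.max & num <= .Machine$integer.max))
    return("integer")
  "decimal"
}

#' Convert a tabular dataset into triples plus its dataset schema
#'
#' One entity per distinct first-column id. Attribute cells become typed
#' literals (a column is numeric iff every non-empty cell parses as a number;
#' all-integral columns stay integers). Relation cells become object triples
#' to entities minted in the target class's namespace; multi-valued cells are
#' split on `","`. Complete position cells yield [region_triples()]. Missing
#' cells emit nothing. Every entity gets an `rdfs:label` equal to its id.
#'
#' @param dataset a [tabular_dataset()].
#' @param namespace project namespace.
#' @param graph_name named graph IRI; defaults to one minted from the class.
#' @return list with elements `batch` (a [triple_batch()]), `schema` (list of
#'   [entity_class_def()]), `n_entities`, and `skipped` (row numbers dropped
#'   for invalid coordinates, reported via warning).
#' @export
convert_table <- function(dataset, namespace = default_namespace(),
                          graph_name = NULL) {
  stopifnot(inherits(dataset, "tabular_dataset"))
  cls <- dataset$entity_class
  cols <- dataset$columns
  rows <- dataset$rows
  if (is.null(graph_name))
    graph_name <- paste0(sub("/+$", "", namespace), "/graph/", pct_encode(cls))

  ids <- rows[[1]]
  if (nrow(rows) > 0L && any(is.na(ids) | !nzchar(ids)))
    stop("empty entity id in class '", cls, "' at row(s) ",
         paste(which(is.na(ids) | !nzchar(ids)), collapse = ", "))

  ref_i <- which(cols$role == "position_reference")
  start_i <- which(cols$role == "position_start")
  end_i <- which(cols$role == "position_end")
  strand_i <- which(cols$role == "position_strand")
  located <- length(ref_i) == 1L

  # literal types per attribute column
  attr_i <- which(cols$role == "attribute")
  attr_types <- vapply(attr_i, function(i) detect_literal_type(rows[[i]]), character(1))
  names(attr_types) <- cols$source_header[attr_i]

  parts <- list(); skipped <- integer()
  for (r in seq_len(nrow(rows))) {
    subject <- mint_entity_uri(namespace, cls, ids[r],
                               context = paste0(cls, " row ", r))
    reg <- NULL
    if (located && !is.na(rows[[ref_i]][r]) && nzchar(rows[[ref_i]][r])) {
      st <- suppressWarnings(as.integer(rows[[start_i]][r]))
      en <- suppressWarnings(as.integer(rows[[end_i]][r]))
      sd <- if (length(strand_i)) rows[[strand_i]][r] else "unknown"
      if (is.na(sd)) sd <- "unknown"
      if (is.na(st) || is.na(en) || st < 1L || st > en) {
        warning("skipping ", cls, " row ", r, " ('", ids[r],
                "'): invalid coordinates ", rows[[start_i]][r], "..",
                rows[[end_i]][r], call. = FALSE)
        skipped <- c(skipped, r)
        next
      }
      reg <- region(rows[[ref_i]][r], st, en, sd)
    }
    rws <- triple_df(
      s = c(subject, subject),
      p = c(RDF_TYPE, RDFS_LABEL),
      o = c(class_uri(namespace, cls), ids[r]),
      ot = c("iri", "string"))
    for (i in seq_len(nrow(cols))) {
      cell <- rows[[i]][r]
      if (is.na(cell) || !nzchar(cell)) next
      role <- cols$role[i]
      if (role == "attribute") {
        ty <- attr_types[[cols$source_header[i]]]
        puri <- property_uri(namespace, cls, cols$source_header[i])
        lit <- switch(ty, integer = lit_integer(cell),
                      decimal = lit_decimal(as.numeric(cell)),
                      lit_string(cell))
        rws <- rbind(rws, triple_df(subject, puri, lit$o, lit$ot))
      } else if (role == "relation") {
        puri <- property_uri(namespace, cls, cols$relation_label[i])
        vals <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
        vals <- vals[nzchar(vals)]
        tgt <- mint_entity_uri(namespace, cols$target_class[i], vals)
        rws <- rbind(rws, triple_df(rep(subject, length(tgt)), puri, tgt, "iri"))
      }
    }
    if (!is.null(reg)) {
      rb <- region_triples(subject, reg, namespace, graph_name)
      rws <- rbind(rws, rb$triples)
    }
    parts[[length(parts) + 1L]] <- rws
  }

  df <- if (length(parts)) do.call(rbind, parts) else triple_df()

  props <- data.frame(label = character(), kind = character(), range = character(),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cols))) {
    if (cols$role[i] == "attribute")
      props <- rbind(props, data.frame(label = cols$source_header[i],
                                       kind = "attribute",
                                       range = attr_types[[cols$source_header[i]]]))
    else if (cols$role[i] == "relation")
      props <- rbind(props, data.frame(label = cols$relation_label[i],
                                       kind = "relation",
                                       range = cols$target_class[i]))
  }
  schema <- list(entity_class_def(cls, namespace, is_located = located,
                                  properties = props))
  sb <- schema_triples(schema, graph_name)
  list(batch = triple_batch(rbind(df, sb$triples), graph_name),
       schema = schema,
       n_entities = length(unique(ids[setdiff(seq_along(ids), skipped)])),
       skipped = skipped)
}
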
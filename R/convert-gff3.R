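# GFF3 -> RDF conversion.
#
# GFF3 v3 dialect: 9 tab-separated columns, 1-based inclusive coordinates,
# `;`-separated key=value attributes with %XX escapes, multi-valued Parent.
# Each retained record becomes an entity classed by its GFF type; Parent
# attributes become relation triples (forward references are legal).

DEFAULT_FEATURE_WHITELIST <- c(
  "gene", "mRNA", "transcript", "exon", "CDS",
  "five_prime_UTR", "three_prime_UTR",
  "ncRNA", "lncRNA", "lnc_RNA", "miRNA", "tRNA", "rRNA", "snoRNA", "snRNA",
  "pseudogene"
)

gff3_unescape <- function(x) {
  # %XX escapes per the GFF3 spec; applied to attribute values.
  vapply(x, function(s) utils::URLdecode(s), character(1), USE.NAMES = FALSE)
}

parse_gff3_attributes <- function(raw, line_no) {
  if (is.na(raw) || raw == "." || !nzchar(raw)) return(list())
  parts <- strsplit(raw, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 1L)
      stop("GFF3 line ", line_no, ": malformed attribute '", p, "'")
    key <- substr(p, 1L, eq - 1L)
    val <- substr(p, eq + 1L, nchar(p))
    out[[key]] <- gff3_unescape(strsplit(val, ",", fixed = TRUE)[[1]])
  }
  out
}

#' Parse GFF3 text into records
#'
#' @param lines character vector of GFF3 lines (or a file path of length 1
#'   pointing to an existing file).
#' @return data.frame with one row per feature line: seqid, source, type,
#'   start, end, score, strand, phase, id, name, parents (comma-joined),
#'   attributes (list column), line (source line number).
#' @export
parse_gff3 <- function(lines) {
  if (length(lines) == 1L && !grepl("\n", lines) && file.exists(lines))
    lines <- readLines(lines)
  recs <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("GFF3 line ", i, ": expected 9 tab-separated fields, got ", length(f))
    start <- suppressWarnings(as.integer(f[4])); end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end))
      stop("GFF3 line ", i, ": non-integer coordinates '", f[4], "', '", f[5], "'")
    if (start > end)
      stop("GFF3 line ", i, ": start ", start, " > end ", end)
    at <- parse_gff3_attributes(f[9], i)
    recs[[length(recs) + 1L]] <- list(
      seqid = f[1], source = f[2], type = f[3], start = start, end = end,
      score = f[6], strand = f[7], phase = f[8],
      id = if (!is.null(at$ID)) at$ID[1] else NA_character_,
      name = if (!is.null(at$Name)) at$Name[1] else NA_character_,
      parents = if (!is.null(at$Parent)) paste(at$Parent, collapse = ",") else NA_character_,
      attributes = at, line = i)
  }
  if (!length(recs)) {
    return(data.frame(seqid = character(), source = character(), type = character(),
                      start = integer(), end = integer(), score = character(),
                      strand = character(), phase = character(), id = character(),
                      name = character(), parents = character(), line = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(recs, function(r)
    data.frame(seqid = r$seqid, source = r$source, type = r$type,
               start = r$start, end = r$end, score = r$score,
               strand = r$strand, phase = r$phase, id = r$id, name = r$name,
               parents = r$parents, line = r$line, stringsAsFactors = FALSE)))
  df$attributes <- lapply(recs, `[[`, "attributes")
  df
}

#' Convert a GFF3 annotation into triples plus its dataset schema
#'
#' Each record whose type is in the whitelist becomes an entity of a class
#' named after its GFF type ("transcript" and "mRNA" stay distinct classes).
#' `Parent` attributes yield one `parent` relation triple per parent; `ID`,
#' `Name` and `biotype`-like attributes become attributes; every record gets
#' FALDO location triples. Records lacking an `ID` get the deterministic
#' synthetic id `<type>:<seqid>:<start>-<end>:<ordinal>`.
#'
#' @param gff3 path to a GFF3 file, or a character vector of GFF3 lines.
#' @param namespace project namespace.
#' @param feature_whitelist GFF types to retain.
#' @param graph_name named graph IRI (defaults to one minted from the source).
#' @param type_alias optional named character vector remapping GFF types to
#'   class labels (e.g. `c(transcript = "mRNA")`).
#' @return list with `batch`, `schema`, `n_entities`, `unresolved_parents`
#'   (ids referenced by Parent but never declared; triples are still emitted,
#'   with a warning).
#' @export
convert_gff3 <- function(gff3, namespace = default_namespace(),
                         feature_whitelist = DEFAULT_FEATURE_WHITELIST,
                         graph_name = NULL, type_alias = NULL) {
  df <- parse_gff3(gff3)
  if (is.null(graph_name))
    graph_name <- paste0(sub("/+$", "", namespace), "/graph/gff3")
  keep <- df[df$type %in% feature_whitelist, , drop = FALSE]

  cls_of <- function(ty) {
    if (!is.null(type_alias) && ty %in% names(type_alias)) unname(type_alias[[ty]]) else ty
  }

  # synthetic ids for ID-less features, deterministic in file order
  ord <- 0L
  ids <- character(nrow(keep))
  if (nrow(keep)) for (r in seq_len(nrow(keep))) {
    if (is.na(keep$id[r])) {
      ord <- ord + 1L
      ids[r] <- paste0(keep$type[r], ":", keep$seqid[r], ":",
                       keep$start[r], "-", keep$end[r], ":", ord)
    } else ids[r] <- keep$id[r]
  }

  id2class <- stats::setNames(vapply(keep$type, cls_of, character(1)), ids)

  parts <- list()
  attr_props <- list()  # class -> set of attribute labels seen
  rel_classes <- list() # class -> set of parent target classes
  for (r in seq_len(nrow(keep))) {
    cls <- cls_of(keep$type[r])
    subject <- mint_entity_uri(namespace, cls, ids[r],
                               context = paste0("GFF3 line ", keep$line[r]))
    rws <- triple_df(
      s = c(subject, subject),
      p = c(RDF_TYPE, RDFS_LABEL),
      o = c(class_uri(namespace, cls),
            if (!is.na(keep$name[r])) keep$name[r] else ids[r]),
      ot = c("iri", "string"))
    seen <- attr_props[[cls]] %||% character()
    for (key in names(keep$attributes[[r]])) {
      if (key %in% c("ID", "Parent", "Name")) next
      vals <- keep$attributes[[r]][[key]]
      puri <- property_uri(namespace, cls, key)
      rws <- rbind(rws, triple_df(rep(subject, length(vals)), puri, vals, "string"))
      seen <- union(seen, key)
    }
    if (!is.na(keep$name[r])) {
      rws <- rbind(rws, triple_df(subject, property_uri(namespace, cls, "name"),
                                  keep$name[r], "string"))
      seen <- union(seen, "name")
    }
    attr_props[[cls]] <- seen
    if (!is.na(keep$parents[r])) {
      pids <- strsplit(keep$parents[r], ",", fixed = TRUE)[[1]]
      for (pid in pids) {
        pcls <- if (pid %in% names(id2class)) id2class[[pid]] else NA_character_
        tgt_cls <- if (!is.na(pcls)) pcls else "gene"
        tgt <- mint_entity_uri(namespace, tgt_cls, pid)
        rws <- rbind(rws, triple_df(subject, property_uri(namespace, cls, "parent"),
                                    tgt, "iri"))
        rel_classes[[cls]] <- union(rel_classes[[cls]] %||% character(), tgt_cls)
      }
    }
    reg <- region(keep$seqid[r], keep$start[r], keep$end[r], keep$strand[r],
                  context = paste0("GFF3 line ", keep$line[r]))
    rb <- region_triples(subject, reg, namespace, graph_name)
    parts[[length(parts) + 1L]] <- rbind(rws, rb$triples)
  }

  unresolved <- character()
  if (nrow(keep)) {
    all_parents <- unique(unlist(strsplit(keep$parents[!is.na(keep$parents)], ",", fixed = TRUE)))
    unresolved <- setdiff(all_parents, ids)
    if (length(unresolved))
      warning("GFF3 Parent id(s) never declared: ",
              paste(utils::head(unresolved, 5), collapse = ", "),
              if (length(unresolved) > 5) " ..." else "", call. = FALSE)
  }

  classes <- unique(unname(vapply(keep$type, cls_of, character(1))))
  schema <- lapply(classes, function(cl) {
    props <- data.frame(label = character(), kind = character(), range = character(),
                        stringsAsFactors = FALSE)
    for (a in attr_props[[cl]] %||% character())
      props <- rbind(props, data.frame(label = a, kind = "attribute", range = "string"))
    for (tc in rel_classes[[cl]] %||% character())
      props <- rbind(props, data.frame(label = "parent", kind = "relation", range = tc))
    entity_class_def(cl, namespace, is_located = TRUE, properties = props)
  })

  df_out <- if (length(parts)) do.call(rbind, parts) else triple_df()
  if (length(schema)) {
    sb <- schema_triples(schema, graph_name)
    df_out <- rbind(df_out, sb$triples)
  }
  list(batch = triple_batch(df_out, graph_name), schema = schema,
       n_entities = nrow(keep), unresolved_parents = unresolved)
}
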
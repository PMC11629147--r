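# Genomic regions and their FALDO serialization.
#
# Coordinates are 1-based inclusive throughout (GFF3 convention; FALDO
# positions are stored unchanged). Every located entity is emitted twice
# over: as a FALDO region node (used by overlap joins) and as four flat
# attribute triples (chromosome/start/end/strand, used by plain filters).

#' Construct a genomic region
#'
#' @param reference chromosome / scaffold label (kept verbatim).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"forward"`, `"reverse"` or `"unknown"`; the GFF3 symbols
#'   `"+"`, `"-"`, `"."` and `"?"` are accepted and normalized.
#' @param context optional source description used in error messages.
#' @return a list of class `region`.
#' @export
region <- function(reference, start, end, strand = "unknown", context = NULL) {
  where <- if (is.null(context)) "" else paste0(" (", context, ")")
  if (length(reference) != 1L || is.na(reference) || !nzchar(reference))
    stop("region reference must be non-empty", where)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end))
    stop("region coordinates must be integers", where)
  if (start < 1L) stop("region start must be >= 1, got ", start, where)
  if (start > end)
    stop("invalid region: start ", start, " > end ", end, where)
  strand <- normalize_strand(strand)
  structure(list(reference = as.character(reference), start = start,
                 end = end, strand = strand),
            class = "region")
}

normalize_strand <- function(strand) {
  s <- as.character(strand)
  if (length(s) != 1L || is.na(s)) return("unknown")
  out <- switch(s,
    "+" = "forward", "-" = "reverse", "." = "unknown", "?" = "unknown",
    forward = "forward", reverse = "reverse", unknown = "unknown",
    NULL)
  if (is.null(out))
    stop("unrecognized strand symbol: '", s, "' (use +/-/. or forward/reverse/unknown)")
  out
}

strand_position_class <- function(strand) {
  switch(strand, forward = FALDO_FWD, reverse = FALDO_REV, NULL)
}

#' Emit FALDO triples (plus flat positional attributes) for a located entity
#'
#' Produces, for `subject`, a `faldo:location` link to a region node carrying
#' `faldo:begin` / `faldo:end` exact-position nodes (1-based inclusive
#' `faldo:position` values), a `faldo:reference` link to a chromosome entity,
#' and strand expressed through the FALDO position classes
#' (`ForwardStrandPosition` / `ReverseStrandPosition`; plain `ExactPosition`
#' only, when the strand is unknown). Four plain attribute triples
#' (chromosome, start, end, strand) are emitted as well so that simple
#' tabular-style filters do not need to walk the FALDO nodes.
#'
#' @param subject entity IRI.
#' @param reg a [region()].
#' @param namespace project namespace used to mint the chromosome entity IRI.
#' @param graph_name named graph for the batch.
#' @return a [triple_batch()].
#' @export
region_triples <- function(subject, reg, namespace = default_namespace(),
                           graph_name = paste0(default_namespace(), "/graph/default")) {
  stopifnot(inherits(reg, "region"))
  loc <- paste0(subject, "/region")
  beg <- paste0(loc, "/begin")
  end <- paste0(loc, "/end")
  ref <- mint_entity_uri(namespace, "reference", reg$reference)

  s <- c(subject, loc, loc, loc, loc,
         beg, beg, end, end)
  p <- c(FALDO_LOCATION, RDF_TYPE, FALDO_BEGIN, FALDO_END, FALDO_REFERENCE,
         RDF_TYPE, FALDO_POSITION, RDF_TYPE, FALDO_POSITION)
  o <- c(loc, FALDO_REGION, beg, end, ref,
         FALDO_EXACT, format(reg$start, scientific = FALSE),
         FALDO_EXACT, format(reg$end, scientific = FALSE))
  ot <- c("iri", "iri", "iri", "iri", "iri",
          "iri", "integer", "iri", "integer")

  sp <- strand_position_class(reg$strand)
  if (!is.null(sp)) {
    s <- c(s, beg, end); p <- c(p, RDF_TYPE, RDF_TYPE)
    o <- c(o, sp, sp);   ot <- c(ot, "iri", "iri")
  }

  # flat attribute encoding
  s <- c(s, subject, subject, subject, subject)
  p <- c(p, OMI_CHROM, OMI_START, OMI_END, OMI_STRAND)
  o <- c(o, reg$reference, format(reg$start, scientific = FALSE),
         format(reg$end, scientific = FALSE), reg$strand)
  ot <- c(ot, "string", "integer", "integer", "string")

  triple_batch(triple_df(s, p, o, ot), graph_name)
}

#' Recover a region from its FALDO triples
#'
#' Inverse of [region_triples()]: given a batch (or a raw triple data.frame)
#' and a subject IRI, reconstructs `(reference, start, end, strand)` from the
#' FALDO nodes alone (the flat attributes are ignored, so this doubles as a
#' consistency check on the FALDO encoding).
#'
#' @param batch a `triple_batch` or triple data.frame.
#' @param subject entity IRI whose location to read back.
#' @return a [region()], or `NULL` when the subject has no FALDO location.
#' @export
parse_region <- function(batch, subject) {
  df <- if (inherits(batch, "triple_batch")) batch$triples else batch
  loc <- df$o[df$s == subject & df$p == FALDO_LOCATION]
  if (length(loc) == 0L) return(NULL)
  loc <- loc[[1]]
  beg <- df$o[df$s == loc & df$p == FALDO_BEGIN][1]
  end <- df$o[df$s == loc & df$p == FALDO_END][1]
  ref_uri <- df$o[df$s == loc & df$p == FALDO_REFERENCE][1]
  start <- as.integer(df$o[df$s == beg & df$p == FALDO_POSITION][1])
  stop_ <- as.integer(df$o[df$s == end & df$p == FALDO_POSITION][1])
  types <- df$o[df$s == beg & df$p == RDF_TYPE]
  strand <- if (FALDO_FWD %in% types) "forward"
            else if (FALDO_REV %in% types) "reverse" else "unknown"
  reference <- utils::URLdecode(sub(".*/", "", ref_uri))
  region(reference, start, stop_, strand)
}
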
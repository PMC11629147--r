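# Namespace constants and term helpers shared by all modules.

RDF_NS   <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS  <- "http://www.w3.org/2000/01/rdf-schema#"
XSD_NS   <- "http://www.w3.org/2001/XMLSchema#"
FALDO_NS <- "http://biohackathon.org/resource/faldo#"

RDF_TYPE    <- paste0(RDF_NS, "type")
RDF_PROP    <- paste0(RDF_NS, "Property")
RDFS_CLASS  <- paste0(RDFS_NS, "Class")
RDFS_LABEL  <- paste0(RDFS_NS, "label")
RDFS_DOMAIN <- paste0(RDFS_NS, "domain")
RDFS_RANGE  <- paste0(RDFS_NS, "range")

FALDO_LOCATION  <- paste0(FALDO_NS, "location")
FALDO_REGION    <- paste0(FALDO_NS, "Region")
FALDO_BEGIN     <- paste0(FALDO_NS, "begin")
FALDO_END       <- paste0(FALDO_NS, "end")
FALDO_REFERENCE <- paste0(FALDO_NS, "reference")
FALDO_POSITION  <- paste0(FALDO_NS, "position")
FALDO_EXACT     <- paste0(FALDO_NS, "ExactPosition")
FALDO_FWD       <- paste0(FALDO_NS, "ForwardStrandPosition")
FALDO_REV       <- paste0(FALDO_NS, "ReverseStrandPosition")

#' Default project namespace
#'
#' All entity, class and property IRIs are minted under a single project
#' namespace unless the caller supplies another one.
#'
#' @return An absolute IRI prefix (no trailing slash).
#' @export
default_namespace <- function() "https://omigraph.example.org/data"

# Internal vocabulary for the flat positional attributes that are emitted
# alongside FALDO nodes (dual encoding: region nodes for overlap joins,
# plain attributes for tabular-style filtering).
OMI_VOCAB <- "https://omigraph.example.org/vocab#"
OMI_CHROM  <- paste0(OMI_VOCAB, "chromosome")
OMI_START  <- paste0(OMI_VOCAB, "start")
OMI_END    <- paste0(OMI_VOCAB, "end")
OMI_STRAND <- paste0(OMI_VOCAB, "strand")
OMI_LOCATED <- paste0(OMI_VOCAB, "isLocatedOn")

# Pseudo-properties every entity carries and every class implicitly declares.
BUILTIN_ATTRS <- data.frame(
  label = c("label", "chromosome", "start", "end", "strand"),
  kind  = "attribute",
  range = c("string", "string", "integer", "integer", "string"),
  stringsAsFactors = FALSE
)

builtin_predicate <- function(label) {
  switch(label,
    label      = RDFS_LABEL,
    chromosome = OMI_CHROM,
    start      = OMI_START,
    end        = OMI_END,
    strand     = OMI_STRAND,
    NULL
  )
}
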
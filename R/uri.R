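# Deterministic IRI minting.

#' Percent-encode a string for use as an IRI path segment
#'
#' RFC 3986 encoding: unreserved characters (alphanumerics and `-._~`) pass
#' through, everything else (including `/`, space, `@`) is percent-encoded,
#' so minted IRIs never collide across distinct local ids.
#'
#' @param x character vector to encode.
#' @return character vector of the same length.
#' @export
pct_encode <- function(x) {
  vapply(as.character(x), function(s) {
    bytes <- charToRaw(enc2utf8(s))
    enc <- vapply(as.integer(bytes), function(b) {
      ch <- rawToChar(as.raw(b))
      if (grepl("^[A-Za-z0-9._~-]$", ch, useBytes = TRUE)) ch
      else sprintf("%%%02X", b)
    }, character(1))
    paste(enc, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Mint a deterministic entity IRI
#'
#' Entities are identified as `<namespace>/<class_label>/<encoded local id>`.
#' Minting is pure: identical inputs always yield the identical IRI, which is
#' what lets independently converted datasets merge on shared entities.
#'
#' @param namespace absolute IRI prefix (no trailing slash needed).
#' @param class_label entity class name, e.g. `"gene"`.
#' @param local_id vector of entity identifiers (first-column values of a
#'   table, GFF3 `ID`s, ...).
#' @param context optional string naming the source row/file, used in error
#'   messages for empty ids.
#' @return character vector of absolute IRIs.
#' @examples
#' mint_entity_uri("https://ex.org", "gene", "MYH7")
#' @export
mint_entity_uri <- function(namespace, class_label, local_id, context = NULL) {
  stopifnot(is.character(namespace), length(namespace) == 1L, nzchar(namespace))
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", namespace))
    stop("namespace must be an absolute IRI, got: ", namespace)
  if (length(class_label) != 1L || is.na(class_label) || !nzchar(class_label))
    stop("class_label must be a non-empty string")
  local_id <- as.character(local_id)
  bad <- is.na(local_id) | !nzchar(local_id)
  if (any(bad)) {
    where <- if (is.null(context)) paste0("row(s) ", paste(which(bad), collapse = ", "))
             else context
    stop("empty entity id for class '", class_label, "' at ", where)
  }
  ns <- sub("/+$", "", namespace)
  paste0(ns, "/", pct_encode(class_label), "/", pct_encode(local_id))
}

#' Mint the IRI of an entity class
#' @inheritParams mint_entity_uri
#' @return absolute IRI `<namespace>/<encoded class label>`.
#' @export
class_uri <- function(namespace, class_label) {
  paste0(sub("/+$", "", namespace), "/", pct_encode(class_label))
}

#' Mint the IRI of a class-scoped property
#'
#' Properties (both attributes and relations) are scoped to the class that
#' declares them: `<namespace>/<Class>#<property>`. Two tables that both have
#' an `FDR` column therefore do not share a predicate, but two loads of the
#' same table do.
#'
#' @inheritParams mint_entity_uri
#' @param property property label.
#' @return absolute IRI.
#' @export
property_uri <- function(namespace, class_label, property) {
  paste0(class_uri(namespace, class_label), "#", pct_encode(property))
}
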
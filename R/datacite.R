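# DataCite metadata crosswalk. Internal entry metadata is mapped onto the
# DataCite Metadata Schema 3.0 kernel -- the version that introduced the
# HasMetadata relation type used to expose METS and OAI-ORE manifest
# locations as machine-actionable related identifiers. Chemical identifiers
# (InChI, InChIKey, CAS, NCI, SMILES) become alternate identifiers and
# contributor ORCID iDs become name identifiers. All network operations
# (minting, media registration, search) stay behind value objects; nothing
# here performs HTTP.

DATACITE_NS <- "http://datacite.org/schema/kernel-3"
METS_SCHEME_URI <- "http://www.loc.gov/METS/"
ORE_SCHEME_URI <- "http://www.openarchives.org/ore/terms/"

#' Construct a DataCite record
#'
#' @param doi DataCite DOI.
#' @param creators data.frame with columns `name` and `orcid` (NA for
#'   creators without one).
#' @param title entry title.
#' @param publisher publisher string.
#' @param publication_year four-digit year string.
#' @param alternate_identifiers data.frame with columns `scheme` (one of
#'   InChI, InChIKey, CAS, NCI, SMILES) and `value`.
#' @param related_identifiers data.frame with columns `value`, `id_type`,
#'   `relation_type`, `metadata_scheme`, `scheme_uri`. Every HasMetadata
#'   relation must carry a metadata scheme and scheme URI.
#' @param media data.frame with columns `mime` and `url` (DataCite Media
#'   API registrations; not part of the kernel XML).
#' @return object of class `datacite_record`.
#' @export
datacite_record <- function(doi, creators, title, publisher,
                            publication_year,
                            alternate_identifiers = NULL,
                            related_identifiers = NULL,
                            media = NULL) {
  .check_doi(doi)
  stopifnot(is.data.frame(creators), nrow(creators) >= 1,
            all(c("name", "orcid") %in% names(creators)))
  if (!grepl("^[0-9]{4}$", as.character(publication_year))) {
    stop("publicationYear must be a four-digit year")
  }
  empty_alt <- data.frame(scheme = character(0), value = character(0),
                          stringsAsFactors = FALSE)
  empty_rel <- data.frame(value = character(0), id_type = character(0),
                          relation_type = character(0),
                          metadata_scheme = character(0),
                          scheme_uri = character(0), stringsAsFactors = FALSE)
  if (is.null(alternate_identifiers)) alternate_identifiers <- empty_alt
  if (is.null(related_identifiers)) related_identifiers <- empty_rel
  bad_scheme <- setdiff(alternate_identifiers$scheme,
                        c("InChI", "InChIKey", "CAS", "NCI", "SMILES"))
  if (length(bad_scheme)) {
    stop("unsupported alternate identifier scheme(s): ",
         paste(bad_scheme, collapse = ", "))
  }
  hm <- related_identifiers$relation_type == "HasMetadata"
  if (any(hm & (is.na(related_identifiers$metadata_scheme) |
                is.na(related_identifiers$scheme_uri)))) {
    stop("HasMetadata related identifiers require metadata_scheme and scheme_uri")
  }
  if (is.null(media)) {
    media <- data.frame(mime = character(0), url = character(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(doi = doi, creators = creators, title = as.character(title),
                 publisher = as.character(publisher),
                 publication_year = as.character(publication_year),
                 alternate_identifiers = alternate_identifiers,
                 related_identifiers = related_identifiers,
                 media = media),
            class = "datacite_record")
}

#' Crosswalk entry metadata to a DataCite record
#'
#' Maps the per-entry descriptive metadata and bundle identifiers onto the
#' DataCite 3.0 kernel: the METS and ORE manifest URLs become HasMetadata
#' related identifiers (relatedIdentifierType URL, schemes METS and OAI-ORE
#' with their scheme URIs), every chemical identifier present becomes an
#' alternate identifier, and every contributor ORCID becomes a name
#' identifier on a creator.
#'
#' @param metadata an [entry_metadata()].
#' @param bundle the corresponding [entry_bundle()].
#' @param mets_url,ore_url manifest retrieval URLs.
#' @param creators optional data.frame (`name`, `orcid`); defaults to one
#'   creator per ORCID iD with the iD as the name placeholder.
#' @param publisher publisher string.
#' @param publication_year four-digit year string.
#' @return a [datacite_record()].
#' @export
crosswalk <- function(metadata, bundle, mets_url, ore_url,
                      creators = NULL, publisher = "Molecular Curation",
                      publication_year = format(Sys.Date(), "%Y")) {
  stopifnot(inherits(metadata, "entry_metadata"),
            inherits(bundle, "entry_bundle"))
  if (is.null(creators)) {
    creators <- if (length(metadata$orcids)) {
      data.frame(name = metadata$orcids, orcid = metadata$orcids,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(name = "Unknown contributor", orcid = NA_character_,
                 stringsAsFactors = FALSE)
    }
  }
  alt <- data.frame(scheme = character(0), value = character(0),
                    stringsAsFactors = FALSE)
  add_alt <- function(scheme, value) {
    if (length(value) == 1 && !is.na(value)) {
      alt <<- rbind(alt, data.frame(scheme = scheme,
                                    value = as.character(value),
                                    stringsAsFactors = FALSE))
    }
  }
  add_alt("InChI", metadata$inchi)
  add_alt("InChIKey", metadata$inchikey)
  add_alt("CAS", metadata$cas_id)
  add_alt("NCI", metadata$nsc_id)
  add_alt("SMILES", metadata$smiles)
  rel <- data.frame(
    value = c(mets_url, ore_url),
    id_type = "URL",
    relation_type = "HasMetadata",
    metadata_scheme = c("METS", "OAI-ORE"),
    scheme_uri = c(METS_SCHEME_URI, ORE_SCHEME_URI),
    stringsAsFactors = FALSE)
  if (!is.na(metadata$back_link)) {
    rel <- rbind(rel, data.frame(value = metadata$back_link,
                                 id_type = "URL",
                                 relation_type = "IsDerivedFrom",
                                 metadata_scheme = NA_character_,
                                 scheme_uri = NA_character_,
                                 stringsAsFactors = FALSE))
  }
  datacite_record(doi = bundle$doi, creators = creators,
                  title = metadata$name, publisher = publisher,
                  publication_year = publication_year,
                  alternate_identifiers = alt, related_identifiers = rel)
}

#' Add a media-type registration to a record
#'
#' Mirrors the DataCite Media API: a (media type, URL) pair is associated
#' with the DOI so the content resolver can retrieve the file by type.
#' Idempotent for identical pairs.
#'
#' @param record a [datacite_record()].
#' @param mime registered media type.
#' @param url retrieval URL.
#' @return updated record.
#' @export
register_media <- function(record, mime, url) {
  stopifnot(inherits(record, "datacite_record"))
  if (!mime %in% c(.media_type_table, "application/octet-stream")) {
    stop("media type not in the registered table: ", mime)
  }
  dup <- record$media$mime == mime & record$media$url == url
  if (!any(dup)) {
    record$media <- rbind(record$media,
                          data.frame(mime = mime, url = url,
                                     stringsAsFactors = FALSE))
  }
  record
}

#' Serialize a record as DataCite kernel-3 XML
#'
#' @param record a [datacite_record()].
#' @return XML text.
#' @export
datacite_xml <- function(record) {
  stopifnot(inherits(record, "datacite_record"))
  doc <- xml2::xml_new_root("resource", xmlns = DATACITE_NS)
  xml2::xml_add_child(doc, "identifier", record$doi,
                      identifierType = "DOI")
  crs <- xml2::xml_add_child(doc, "creators")
  for (i in seq_len(nrow(record$creators))) {
    cr <- xml2::xml_add_child(crs, "creator")
    xml2::xml_add_child(cr, "creatorName", record$creators$name[i])
    if (!is.na(record$creators$orcid[i])) {
      xml2::xml_add_child(cr, "nameIdentifier", record$creators$orcid[i],
                          nameIdentifierScheme = "ORCID",
                          schemeURI = "http://orcid.org/")
    }
  }
  tts <- xml2::xml_add_child(doc, "titles")
  xml2::xml_add_child(tts, "title", record$title)
  xml2::xml_add_child(doc, "publisher", record$publisher)
  xml2::xml_add_child(doc, "publicationYear", record$publication_year)
  if (nrow(record$alternate_identifiers)) {
    alts <- xml2::xml_add_child(doc, "alternateIdentifiers")
    for (i in seq_len(nrow(record$alternate_identifiers))) {
      xml2::xml_add_child(
        alts, "alternateIdentifier",
        record$alternate_identifiers$value[i],
        alternateIdentifierType = record$alternate_identifiers$scheme[i])
    }
  }
  if (nrow(record$related_identifiers)) {
    rels <- xml2::xml_add_child(doc, "relatedIdentifiers")
    for (i in seq_len(nrow(record$related_identifiers))) {
      r <- record$related_identifiers[i, ]
      node <- xml2::xml_add_child(rels, "relatedIdentifier", r$value,
                                  relatedIdentifierType = r$id_type,
                                  relationType = r$relation_type)
      if (!is.na(r$metadata_scheme)) {
        xml2::xml_set_attr(node, "relatedMetadataScheme", r$metadata_scheme)
      }
      if (!is.na(r$scheme_uri)) {
        xml2::xml_set_attr(node, "schemeURI", r$scheme_uri)
      }
    }
  }
  as.character(doc)
}

#' Validate DataCite XML against the bundled kernel-3 subset schema
#'
#' @param x XML text or document.
#' @return TRUE when valid; otherwise an error carrying the validator
#'   output.
#' @export
validate_datacite <- function(x) {
  doc <- .read_xml_input(x)
  xsd_path <- system.file("extdata", "datacite-kernel3-subset.xsd",
                          package = "molcurate")
  if (!nzchar(xsd_path)) stop("bundled DataCite schema not found")
  schema <- xml2::read_xml(xsd_path)
  ok <- xml2::xml_validate(doc, schema)
  if (!ok) {
    stop("DataCite schema validation failed: ",
         paste(attr(ok, "errors"), collapse = "; "))
  }
  TRUE
}

# ---- machine-actionable URL builders ------------------------------------

#' Handle-resolver URL with a requested media type (10320/loc pattern)
#'
#' @param handle assigned handle identifier (e.g. `"10042/31117"`).
#' @param mime requested media type.
#' @param resolver resolver base URL ending in `/`; either
#'   `"http://doi.org/"` (default) or `"http://hdl.handle.net/"`.
#' @return URL of the exact form
#'   `<resolver><handle>?locatt=mimetype:<mime>`.
#' @export
build_locatt_url <- function(handle, mime, resolver = "http://doi.org/") {
  .check_handle(handle)
  sprintf("%s%s?locatt=mimetype:%s", resolver, handle, mime)
}

#' Content-resolver URL for a DOI and media type
#'
#' @param doi DataCite DOI (e.g. `"10.14469/ch/153690"`).
#' @param mime requested media type (subtype punctuation passed verbatim).
#' @param resolver content resolver base URL ending in `/`.
#' @return URL of the exact form `<resolver><mime>/<doi>`.
#' @export
build_media_url <- function(doi, mime,
                            resolver = "http://data.datacite.org/") {
  .check_doi(doi)
  sprintf("%s%s/%s", resolver, mime, doi)
}

# ---- search queries ------------------------------------------------------

#' A fielded search-API term
#'
#' @param field metadata field name (e.g. `"prefix"`,
#'   `"alternateIdentifier"`, `"ORCID"`).
#' @param value field value; `*` wildcards are preserved and `:` inside the
#'   value is backslash-escaped at serialization.
#' @param equals use `field=value` instead of the default `field:value`.
#' @return list of class `search_term`.
#' @export
search_term <- function(field, value, equals = FALSE) {
  structure(list(field = field, value = as.character(value),
                 equals = equals), class = "search_term")
}

#' Build a metadata search-API query URL
#'
#' Serializes terms in the fielded grammar of the search API: `+`-joined
#' `field:value` terms with `:` inside values backslash-escaped and `*`
#' wildcards preserved. The `api` formats append `fl` (field list), `wt`
#' (output format) and `rows` parameters; the `ui` format emits only the
#' query.
#'
#' @param terms list of [search_term()] objects (at least one).
#' @param format one of `"ui"`, `"xml"`, `"csv"`, `"json"`.
#' @param rows row limit (API formats only).
#' @param fl field list for API formats.
#' @param base search service base URL.
#' @return query URL string.
#' @export
build_search_query <- function(terms, format = c("ui", "xml", "csv", "json"),
                               rows = NULL,
                               fl = c("doi", "title", "relatedIdentifier"),
                               base = "http://search.datacite.org") {
  format <- match.arg(format)
  if (inherits(terms, "search_term")) terms <- list(terms)
  if (!length(terms)) stop("at least one search term required")
  ser <- vapply(terms, function(t) {
    stopifnot(inherits(t, "search_term"))
    value <- gsub(":", "\\\\:", t$value)
    paste0(t$field, if (t$equals) "=" else ":", value)
  }, "")
  q <- paste(ser, collapse = "+")
  if (format == "ui") {
    return(sprintf("%s/ui?q=%s", base, q))
  }
  sprintf("%s/api?&q=%s&fl=%s&wt=%s%s", base, q,
          paste(fl, collapse = ","), format,
          if (!is.null(rows)) sprintf("&rows=%d", as.integer(rows)) else "")
}

#' Parse a search-API response into records
#'
#' Understands the csv form (`doi,title,relatedIdentifier` header, the
#' related-identifier column holding comma-separated
#' `Relation:Type:value` entries) and the xml form. Each related identifier
#' is split into its relation, identifier type and value, so HasMetadata
#' children yield (scheme, URL) pairs directly usable for re-curation.
#'
#' @param payload response text.
#' @param format `"csv"` or `"xml"`.
#' @return data.frame with columns `doi`, `title` and a list-column
#'   `related` of data.frames (`relation`, `type`, `value`).
#' @export
parse_search_response <- function(payload, format = c("csv", "xml")) {
  format <- match.arg(format)
  if (format == "xml") {
    doc <- .read_xml_input(payload)
    docs <- xml2::xml_find_all(doc, "//doc")
    rows <- lapply(docs, function(d) {
      get1 <- function(f) xml2::xml_text(
        xml2::xml_find_first(d, sprintf(".//str[@name='%s']", f)))
      rel <- xml2::xml_text(xml2::xml_find_all(
        d, ".//arr[@name='relatedIdentifier']/str"))
      list(doi = get1("doi"), title = get1("title"), rel = rel)
    })
  } else {
    lines <- strsplit(paste(payload, collapse = "\n"), "\n")[[1]]
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      return(data.frame(doi = character(0), title = character(0),
                        related = I(list()), stringsAsFactors = FALSE))
    }
    if (grepl("^doi\\s*,", lines[1])) lines <- lines[-1]
    if (!length(lines)) {
      return(data.frame(doi = character(0), title = character(0),
                        related = I(list()), stringsAsFactors = FALSE))
    }
    con <- textConnection(lines)
    on.exit(close(con), add = TRUE)
    df <- tryCatch(
      utils::read.csv(con, header = FALSE, stringsAsFactors = FALSE,
                      strip.white = TRUE, col.names = c("doi", "title", "rel"),
                      fill = TRUE),
      error = function(e) stop("malformed search response: ",
                               conditionMessage(e)))
    rows <- lapply(seq_len(nrow(df)), function(i) {
      rel_raw <- df$rel[i]
      rel <- if (is.na(rel_raw) || !is.character(rel_raw)) character(0) else
        trimws(strsplit(rel_raw, ",")[[1]])
      list(doi = df$doi[i], title = df$title[i], rel = rel)
    })
  }
  related <- lapply(rows, function(r) {
    rel <- r$rel[nzchar(r$rel)]
    if (!length(rel)) {
      return(data.frame(relation = character(0), type = character(0),
                        value = character(0), stringsAsFactors = FALSE))
    }
    parts <- regmatches(rel, regexec("^([^:]+):([^:]+):(.*)$", rel))
    keep <- lengths(parts) == 4
    data.frame(relation = vapply(parts[keep], `[[`, "", 2),
               type = vapply(parts[keep], `[[`, "", 3),
               value = vapply(parts[keep], `[[`, "", 4),
               stringsAsFactors = FALSE)
  })
  data.frame(doi = vapply(rows, `[[`, "", "doi"),
             title = vapply(rows, `[[`, "", "title"),
             related = I(related), stringsAsFactors = FALSE)
}
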
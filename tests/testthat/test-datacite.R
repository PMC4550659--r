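fixture_metadata <- function() {
  entry_metadata("NSC5396", inchi = "InChI=1S/H2O/h1H2",
                 inchikey = "XLYOFNOQVPJJNP-UHFFFAOYSA-N", smiles = "O",
                 cas_id = "7732-18-5", nsc_id = 5396L,
                 back_link = "http://hdl.handle.net/1810/724",
                 orcids = "0000-0002-8635-8390")
}

fixture_bundle <- function() {
  entry_bundle("10042/159060", "10.14469/ch/159060", fixture_metadata(),
               list(bundle_file("PM7.xml", "<molecule/>", 3L)))
}

test_that("crosswalk emits HasMetadata related identifiers with schemes", {
  rec <- crosswalk(fixture_metadata(), fixture_bundle(),
                   "https://repo/metadata/handle/10042/159060/mets.xml",
                   "https://repo/metadata/handle/10042/159060/ore.xml")
  x <- datacite_xml(rec)
  expect_true(validate_datacite(x))
  doc <- xml2::read_xml(x)
  ns <- c(d = "http://datacite.org/schema/kernel-3")
  rel <- xml2::xml_find_all(doc, "//d:relatedIdentifier", ns)
  mets_rel <- rel[[which(xml2::xml_attr(rel, "relatedMetadataScheme") ==
                           "METS")[1]]]
  expect_identical(xml2::xml_attr(mets_rel, "relatedIdentifierType"), "URL")
  expect_identical(xml2::xml_attr(mets_rel, "relationType"), "HasMetadata")
  expect_identical(xml2::xml_attr(mets_rel, "schemeURI"),
                   "http://www.loc.gov/METS/")
  expect_match(xml2::xml_text(mets_rel), "mets.xml$")

  alt <- xml2::xml_find_all(doc, "//d:alternateIdentifier", ns)
  schemes <- xml2::xml_attr(alt, "alternateIdentifierType")
  expect_setequal(schemes, c("InChI", "InChIKey", "CAS", "NCI", "SMILES"))
  expect_identical(
    xml2::xml_text(alt[[which(schemes == "InChIKey")]]),
    "XLYOFNOQVPJJNP-UHFFFAOYSA-N")
  nid <- xml2::xml_find_first(doc, "//d:nameIdentifier", ns)
  expect_identical(xml2::xml_attr(nid, "nameIdentifierScheme"), "ORCID")
})

test_that("a minimal record validates and an invalid one does not", {
  minimal <- datacite_record(
    "10.14469/ch/1",
    creators = data.frame(name = "A Person", orcid = NA_character_),
    title = "t", publisher = "p", publication_year = "2015")
  expect_true(validate_datacite(datacite_xml(minimal)))
  expect_error(datacite_record("not-a-doi",
                               data.frame(name = "x", orcid = NA),
                               "t", "p", "2015"), "malformed DOI")
  expect_error(datacite_record("10.1/x", data.frame(name = "x", orcid = NA),
                               "t", "p", "15"), "four-digit")
  bad_xml <- '<resource xmlns="http://datacite.org/schema/kernel-3"><identifier identifierType="DOI">10.1/x</identifier></resource>'
  expect_error(validate_datacite(bad_xml), "validation failed")
})

test_that("media registration is idempotent and type-checked", {
  rec <- crosswalk(fixture_metadata(), fixture_bundle(), "https://m",
                   "https://o")
  r1 <- register_media(rec, "chemical/x-cml", "http://x/file.cml")
  r2 <- register_media(r1, "chemical/x-cml", "http://x/file.cml")
  expect_identical(nrow(r2$media), 1L)
  r3 <- register_media(r2, "chemical/x-mopac-input", "http://x/file.mop")
  expect_identical(nrow(r3$media), 2L)
  expect_error(register_media(rec, "text/weird", "http://x"), "not in the")
})

test_that("resolver URL builders reproduce the printed patterns exactly", {
  expect_identical(build_locatt_url("10042/31117", "chemical/x-cml"),
                   "http://doi.org/10042/31117?locatt=mimetype:chemical/x-cml")
  expect_identical(
    build_locatt_url("10042/31117", "chemical/x-cml",
                     resolver = "http://hdl.handle.net/"),
    "http://hdl.handle.net/10042/31117?locatt=mimetype:chemical/x-cml")
  expect_identical(
    build_media_url("10.14469/ch/153690", "chemical/x-cml"),
    "http://data.datacite.org/chemical/x-cml/10.14469/ch/153690")
  expect_error(build_locatt_url("", "chemical/x-cml"), "malformed")
  expect_error(build_media_url("", "chemical/x-cml"), "malformed")
})

test_that("search queries serialize the fielded grammar with escaping", {
  q1 <- build_search_query(
    list(search_term("prefix", "10.14469"),
         search_term("alternateIdentifier", "NCI:*")),
    format = "xml", rows = 3)
  expect_match(q1, "prefix:10.14469", fixed = TRUE)
  expect_match(q1, "alternateIdentifier:NCI\\:*", fixed = TRUE)
  expect_match(q1, "rows=3", fixed = TRUE)
  expect_match(q1, "wt=xml", fixed = TRUE)

  q4 <- build_search_query(list(search_term("ORCID", "*"),
                                search_term("prefix", "10.14469")))
  expect_identical(q4, "http://search.datacite.org/ui?q=ORCID:*+prefix:10.14469")

  q7 <- build_search_query(list(
    search_term("InChIKey", "LQPOSWKBQVCBKS-PGMHMLKASA-N", equals = TRUE)))
  expect_identical(
    q7,
    "http://search.datacite.org/ui?q=InChIKey=LQPOSWKBQVCBKS-PGMHMLKASA-N")
  expect_error(build_search_query(list()), "at least one")
})

test_that("search responses parse into doi/title/related triples", {
  csv <- paste0(
    "doi,title,relatedIdentifier\n",
    '10.14469/CH/123315,NSC5396, "HasMetadata:URL:https://spectradspace.lib.imperial.ac.uk:8443/metadata/handle/10042/130536/mets.xml, ',
    "HasMetadata:URL:https://spectradspace.lib.imperial.ac.uk:8443/metadata/handle/10042/130536/ore.xml, ",
    'IsPartOf:Handle:10042/31117"')
  r <- parse_search_response(csv, "csv")
  expect_identical(r$doi, "10.14469/CH/123315")
  expect_identical(r$title, "NSC5396")
  rel <- r$related[[1]]
  expect_identical(nrow(rel), 3L)
  expect_identical(sum(rel$relation == "HasMetadata"), 2L)
  expect_match(rel$value[1], "mets.xml$")
  expect_identical(rel$value[rel$relation == "IsPartOf"], "10042/31117")

  empty <- parse_search_response("", "csv")
  expect_identical(nrow(empty), 0L)
  norel <- parse_search_response("doi,title,relatedIdentifier\n10.1/x,t,",
                                 "csv")
  expect_identical(nrow(norel$related[[1]]), 0L)
})

test_that("crosswalk then response-parse recovers dois and manifest URLs", {
  rec <- crosswalk(fixture_metadata(), fixture_bundle(),
                   "https://repo/mets.xml", "https://repo/ore.xml")
  fake_row <- sprintf('%s,%s,"HasMetadata:URL:%s, HasMetadata:URL:%s"',
                      rec$doi, rec$title,
                      rec$related_identifiers$value[1],
                      rec$related_identifiers$value[2])
  parsed <- parse_search_response(paste0("doi,title,relatedIdentifier\n",
                                         fake_row), "csv")
  expect_identical(parsed$doi, rec$doi)
  expect_setequal(parsed$related[[1]]$value,
                  rec$related_identifiers$value[1:2])
})
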
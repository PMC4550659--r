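test_that("payload digests match an independent MD5 oracle", {
  cases <- list(raw(0), charToRaw("abc"), as.raw(sample(0:255, 500,
                                                        replace = TRUE)))
  for (payload in cases) {
    ck <- checksum_payload(payload)
    expect_identical(ck$size, length(payload))
    tf <- tempfile(); writeBin(payload, tf)
    expect_identical(ck$md5, unname(tools::md5sum(tf)))  # oracle
    unlink(tf)
  }
  expect_identical(checksum_payload(raw(0))$md5,
                   "d41d8cd98f00b204e9800998ecf8427e")
  expect_identical(checksum_payload("abc")$md5,
                   "900150983cd24fb0d6963f7d28e17f72")
  expect_identical(checksum_payload("abc")$size, 3L)
  # determinism
  expect_identical(checksum_payload("abc"), checksum_payload("abc"))
})

test_that("media types follow the registered table with graceful fallback", {
  expect_identical(assign_mime("PM7.xml"), "chemical/x-cml")
  expect_identical(assign_mime("nsc1_original.cml"), "chemical/x-cml")
  expect_identical(assign_mime("entry.mop"), "chemical/x-mopac-input")
  expect_identical(assign_mime("entry.out"), "chemical/x-mopac-out")
  expect_warning(m <- assign_mime("notes.txt"), "no registered media type")
  expect_identical(m, "application/octet-stream")
})

test_that("ORCID iDs are validated with their checksum digit", {
  expect_silent(entry_metadata("x", orcids = "0000-0002-8635-8390"))
  expect_error(entry_metadata("x", orcids = "0000-0002-8635-839"),
               "malformed")
  expect_error(entry_metadata("x", orcids = "0000-0002-8635-8391"),
               "checksum")
})

make_bundle <- function() {
  md <- entry_metadata("NSC5396", inchi = "InChI=1S/H2O/h1H2",
                       inchikey = "XLYOFNOQVPJJNP-UHFFFAOYSA-N",
                       smiles = "O", cas_id = "7732-18-5", nsc_id = 5396L,
                       back_link = "http://hdl.handle.net/1810/724",
                       article_doi = "https://doi.org/10.1000/example",
                       orcids = "0000-0002-8635-8390",
                       license_url = "https://creativecommons.org/publicdomain/zero/1.0/")
  files <- list(
    bundle_file("nsc5396_original.cml", "<molecule/>", 1L),
    bundle_file("nsc5396_post-mopac.cml", "<molecule charge='0'/>", 2L),
    bundle_file("PM7.xml", "<molecule name='pm7'/>", 3L),
    bundle_file("nsc5396.mop", "PM7 CHARGE=0 SINGLET\n", 4L))
  entry_bundle("10042/159060", "10.14469/ch/159060", md, files)
}

test_that("the manifest carries checksums, sizes and bitstream locators", {
  b <- make_bundle()
  m <- build_mets(b)
  expect_identical(nrow(validate_mets(m)), 0L)
  doc <- xml2::read_xml(m)
  ns <- c(mets = "http://www.loc.gov/METS/",
          xlink = "http://www.w3.org/1999/xlink")
  files <- xml2::xml_find_all(doc, "//mets:file", ns)
  expect_identical(length(files), 4L)
  for (i in seq_along(b$files)) {
    f <- files[[i]]
    expect_identical(xml2::xml_attr(f, "CHECKSUMTYPE"), "MD5")
    expect_identical(xml2::xml_attr(f, "CHECKSUM"), b$files[[i]]$md5)
    expect_identical(xml2::xml_attr(f, "SIZE"),
                     as.character(b$files[[i]]$size))
    expect_identical(xml2::xml_attr(f, "MIMETYPE"), b$files[[i]]$mime)
  }
  href <- xml2::xml_attr(xml2::xml_find_all(doc, "//mets:FLocat", ns),
                         "href")
  expect_true("/bitstream/handle/10042/159060/PM7.xml?sequence=3" %in% href)
  expect_error(entry_bundle("10042/1", "10.14469/ch/1",
                            make_bundle()$metadata, list()), "no files")
  expect_error(entry_bundle("not a handle", "10.14469/ch/1",
                            make_bundle()$metadata, make_bundle()$files),
               "malformed handle")
})

test_that("METS and ORE describe identical file sets and URLs", {
  b <- make_bundle()
  mets <- xml2::read_xml(build_mets(b))
  ore <- xml2::read_xml(build_ore_map(b))
  ns_m <- c(mets = "http://www.loc.gov/METS/",
            xlink = "http://www.w3.org/1999/xlink")
  ns_o <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
            ore = "http://www.openarchives.org/ore/terms/")
  mets_paths <- xml2::xml_attr(
    xml2::xml_find_all(mets, "//mets:FLocat", ns_m), "href")
  agg <- xml2::xml_attr(
    xml2::xml_find_all(ore, "//ore:aggregates", ns_o), "resource")
  expect_identical(length(agg), length(mets_paths))
  for (p in mets_paths) expect_true(any(endsWith(agg, p)))
  expect_match(build_ore_map(b), "metadata/handle/10042/159060/ore.xml",
               fixed = TRUE)
})

test_that("the SWORD archive round-trips every payload byte-identically", {
  b <- make_bundle()
  zp <- build_sword_bundle(b)
  rb <- read_sword_bundle(zp)
  expect_identical(length(rb$members), length(b$files) + 1L)  # + mets.xml
  expect_true("mets.xml" %in% rb$members)
  for (f in b$files) {
    got <- readBin(file.path(rb$dir, f$filename), "raw",
                   n = f$size + 10)
    expect_identical(digest::digest(got, algo = "md5", serialize = FALSE),
                     f$md5)
  }
  req <- sword_deposit_request(zp, "https://repo.example.org/sword/deposit/1")
  expect_identical(unname(req$headers["X-Packaging"]),
                   "http://purl.org/net/sword-types/METSDSpaceSIP")
})
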
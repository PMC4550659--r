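test_that("both charge dialects are captured independently, absence is not zero", {
  legacy <- parse_cml(legacy_dialect_cml)
  expect_identical(legacy$legacy_charge, 1L)
  expect_identical(legacy$formal_charge_attr, NA_integer_)
  expect_identical(legacy$nsc_id, 138467L)
  expect_match(legacy$legacy_basic, "^C13H21N2O")

  modern <- parse_cml(attr_dialect_cml)
  expect_identical(modern$formal_charge_attr, 1L)
  expect_identical(modern$legacy_charge, NA_integer_)
  expect_identical(modern$name, "mol1")

  neither <- parse_cml(
    '<molecule id="NSC1" name="m"><atomArray><atom id="a1" elementType="C"/></atomArray></molecule>')
  expect_identical(neither$formal_charge_attr, NA_integer_)
  expect_identical(neither$legacy_charge, NA_integer_)
})

test_that("parse errors and element validation are reported by atom", {
  expect_error(parse_cml("this is not xml"))
  expect_error(parse_cml(
    '<molecule id="NSC2" name="m"><atomArray><atom id="a1" elementType="Xx"/></atomArray></molecule>'),
    "unknown element")
})

test_that("write/parse round trip reproduces every field exactly", {
  set.seed(11)
  for (k in 1:10) {
    n <- sample(2:8, 1)
    at <- random_atoms(n)
    rec <- molecule_record(
      name = sprintf("NSC%d", 100 + k), atoms = at,
      bonds = data.frame(i = 1L, j = 2L, order = "1"),
      nsc_id = 100L + k,
      cas_id = if (k %% 2) "50-00-0" else NA_character_,
      formal_charge_attr = sample(c(NA_integer_, -1L, 0L, 1L), 1),
      legacy_charge = sample(c(NA_integer_, 0L, 1L), 1),
      legacy_basic = if (k %% 3) "C2H6O" else NA_character_,
      provenance = sample(c("NCI", "PM5", "PM7"), 1),
      smiles = "CCO")
    back <- parse_cml(write_cml(rec))
    expect_identical(back$formal_charge_attr, rec$formal_charge_attr)
    expect_identical(back$legacy_charge, rec$legacy_charge)
    expect_identical(back$legacy_basic, rec$legacy_basic)
    expect_identical(back$provenance, rec$provenance)
    expect_identical(back$nsc_id, rec$nsc_id)
    expect_identical(back$cas_id, rec$cas_id)
    expect_identical(back$atoms$element, rec$atoms$element)
    expect_equal(back$atoms$x, rec$atoms$x, tolerance = 0)
    expect_equal(back$atoms$y, rec$atoms$y, tolerance = 0)
    expect_equal(back$atoms$z, rec$atoms$z, tolerance = 0)
    expect_identical(back$bonds$i, rec$bonds$i)
  }
})

test_that("conflated profile embeds three provenance-tagged geometry blocks", {
  at <- water_atoms()
  recs <- lapply(c("NCI", "PM5", "PM7"), function(p)
    molecule_record("NSC9", at, nsc_id = 9L, provenance = p))
  doc <- write_cml(recs, profile = "conflated")
  back <- parse_cml_set(doc)
  expect_setequal(names(back), c("NCI", "PM5", "PM7"))
  expect_equal(back$PM7$atoms$x, at$x)
  # missing coordinates refuse conflation, naming the atoms
  nc <- molecule_record("NSC9", atoms("C"), provenance = "PM7")
  expect_error(write_cml(list(nc), profile = "conflated"), "coordinates")
  expect_error(write_cml(molecule_record("empty", atoms(character(0)))),
               "no atoms")
})

test_that("profile validation flags missing bond arrays and bad references", {
  ok <- validate_cml(attr_dialect_cml, cml_schema())
  expect_identical(nrow(ok), 0L)
  v <- validate_cml(attr_dialect_cml, cml_schema(require_bonds = TRUE))
  expect_identical(nrow(v), 1L)
  expect_match(v$location, "bondArray")
  v2 <- validate_cml(
    '<molecule id="m" name="m"><atomArray><atom id="a1" elementType="C"/></atomArray><bondArray><bond atomRefs2="a1 a9" order="1"/></bondArray></molecule>')
  expect_match(v2$message, "undeclared atom id")
  expect_error(validate_cml("not xml at all <"))
  expect_error(validate_cml(attr_dialect_cml, schema = "cml24"),
               "descriptor")
})

test_that("deduplication keeps the first record per accession and balances", {
  mk <- function(id, name) molecule_record(name, atoms("C"), nsc_id = id)
  dd <- deduplicate(list(mk(1, "A"), mk(2, "B"), mk(1, "A2")))
  expect_identical(length(dd$records), 2L)
  expect_identical(dd$records[[1]]$name, "A")
  expect_identical(dd$report$duplicates_removed, 1L)

  empty <- deduplicate(list())
  expect_identical(empty$report$total_read, 0L)

  # independent set-based oracle on a 100-record corpus with 7 duplicates
  set.seed(3)
  ids <- sample(1000:9999, 93)
  ids <- c(ids, sample(ids, 7))          # 7 injected duplicates
  recs <- lapply(seq_along(ids), function(i) mk(ids[i], paste0("r", i)))
  dd <- deduplicate(recs)
  expect_identical(length(dd$records), length(unique(ids)))
  expect_identical(dd$report$unique_kept, 93L)
  # idempotence
  dd2 <- deduplicate(dd$records)
  expect_identical(dd2$report$duplicates_removed, 0L)
  expect_identical(length(dd2$records), length(dd$records))

  no_id <- list(mk(1, "A"), molecule_record("x", atoms("C")))
  expect_error(deduplicate(no_id), "position\\(s\\) 2")
})

test_that("entries without a computed annotation are excluded and counted", {
  p <- function(with) list(nci = molecule_record("n", atoms("C")),
                           computed = if (with)
                             molecule_record("c", atoms("C")) else NULL)
  fa <- filter_annotated(list(p(TRUE), p(FALSE), p(TRUE), p(FALSE), p(TRUE)))
  expect_identical(length(fa$kept), 3L)
  expect_identical(fa$excluded, 2L)
  expect_identical(filter_annotated(list(p(TRUE)))$excluded, 0L)
  all_absent <- filter_annotated(list(p(FALSE), p(FALSE)))
  expect_identical(length(all_absent$kept), 0L)
})

test_that("largest-component selection removes counter-ions deterministically", {
  lib <- base_molecule_library()
  salt <- lib$molecules$tma_chloride
  rec <- molecule_record("salt", salt$atoms, formal_charge_attr = 1L)
  g <- perceive_connectivity(salt$atoms)
  sel <- select_largest_component(rec, g)
  expect_identical(sel$removed, "Cl")
  expect_false(sel$tie)
  expect_false(sel$charge_suspect)
  expect_lt(nrow(sel$record$atoms), nrow(salt$atoms))
  # atom order preserved
  keep_el <- salt$atoms$element[salt$atoms$element != "Cl"]
  expect_identical(sel$record$atoms$element, keep_el)

  # single component is the identity
  w <- molecule_record("w", water_atoms())
  sw <- select_largest_component(w, perceive_connectivity(w$atoms))
  expect_identical(sw$removed, character(0))
  expect_identical(nrow(sw$record$atoms), 3L)

  # equal-size tie breaks to the component with the lowest atom index
  two_h2 <- atoms(rep("H", 4), x = c(0, 0.74, 9, 9.74), y = 0, z = 0)
  th <- molecule_record("t", two_h2)
  st <- select_largest_component(th, perceive_connectivity(two_h2))
  expect_true(st$tie)
  expect_identical(nrow(st$record$atoms), 2L)
  expect_equal(st$record$atoms$x, c(0, 0.74))
  expect_true(st$charge_suspect)   # component removed, no declared charge

  expect_error(select_largest_component(
    molecule_record("e", atoms(character(0))),
    structure(list(n_atoms = 0L, edges = matrix(0L, 0, 2)),
              class = "connectivity_graph")), "empty")
})

test_that("XYZ round trip preserves coordinates to six decimals", {
  at <- water_atoms()
  txt <- write_xyz(at, "water")
  back <- read_xyz(txt)
  expect_identical(back$comment, "water")
  expect_equal(back$atoms$x, at$x, tolerance = 1e-6)
  expect_error(read_xyz("2\nonly a comment"), "fewer")
  expect_error(write_xyz(atoms(character(0))), "no atoms")
})
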
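test_that("decks always carry explicit CHARGE and spin keywords", {
  lib <- base_molecule_library()
  tma <- molecule_record("tma", lib$molecules$tetramethylammonium$atoms,
                         formal_charge_attr = 1L)
  deck <- build_mopac_input(tma, reconcile_charge(tma))
  expect_true("CHARGE=1" %in% deck$keywords)
  txt <- format_mopac_input(deck)
  expect_match(txt, "CHARGE=1")
  expect_no_match(txt, "PUT KEYWORDS HERE", fixed = TRUE)

  w <- molecule_record("water", water_atoms())
  dw <- build_mopac_input(w, reconcile_charge(w))
  expect_true(all(c("CHARGE=0", "SINGLET") %in% dw$keywords))

  no <- molecule_record("NO", lib$molecules$nitric_oxide$atoms)
  dn <- build_mopac_input(no, reconcile_charge(no))
  expect_true("DOUBLET" %in% dn$keywords)

  # spin consistency holds by construction for every deck
  for (d in list(deck, dw, dn)) {
    q <- as.integer(sub("CHARGE=", "", grep("CHARGE=", d$keywords,
                                            value = TRUE)))
    spin <- intersect(d$keywords, c("SINGLET", "DOUBLET"))
    expect_identical(length(spin), 1L)
  }
})

test_that("deck text parses back to identical keywords and geometry", {
  lib <- base_molecule_library()
  rec <- molecule_record("etoh", lib$molecules$ethanol$atoms)
  for (mode in c("internal", "cartesian")) {
    deck <- build_mopac_input(rec, coords = mode)
    back <- parse_mopac_input(format_mopac_input(deck))
    expect_identical(back$keywords, deck$keywords)
    if (mode == "internal") {
      expect_lt(max(abs(back$geometry$distance - deck$geometry$distance),
                    na.rm = TRUE), 1e-4)
      expect_lt(max(abs(back$geometry$angle - deck$geometry$angle),
                    na.rm = TRUE), 1e-2)
      expect_identical(back$geometry$r1, deck$geometry$r1)
    } else {
      expect_lt(max(abs(back$geometry$x - deck$geometry$x)), 1e-4)
    }
  }
  # determinism: identical inputs give byte-identical decks
  expect_identical(format_mopac_input(build_mopac_input(rec)),
                   format_mopac_input(build_mopac_input(rec)))
})

test_that("missing coordinates stop deck generation; implausible charge warns", {
  bare <- molecule_record("b", atoms("C"))
  expect_error(build_mopac_input(bare), "lacks coordinates")
  w <- molecule_record("w", water_atoms(), formal_charge_attr = 4L)
  expect_warning(deck <- build_mopac_input(w, reconcile_charge(w)),
                 "implausible")
  expect_true("CHARGE=4" %in% deck$keywords)
})

test_that("optimizer output parsing distinguishes normal and error runs", {
  w <- molecule_record("water", water_atoms())
  deck <- build_mopac_input(w)
  out <- run_optimizer(deck, "mock")
  parsed <- parse_mopac_output(out)
  expect_identical(parsed$status, "normal")
  expect_identical(nrow(parsed$atoms), 3L)
  expect_lt(max(abs(dist_matrix(parsed$atoms) - dist_matrix(water_atoms()))),
            1e-3)

  err <- parse_mopac_output("SOMETHING BAD\n CALCULATION ABANDONED ERROR")
  expect_identical(err$status, "error")
  expect_null(err$atoms)

  expect_error(parse_mopac_output("truncated with no marker"),
               "unrecognizable")
  expect_error(run_optimizer(deck, "definitely-missing-binary {input}"),
               "not found")
})
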
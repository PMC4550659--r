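test_that("the library's injection-pair layer annotations are reproducible", {
  # regenerate each pair's InChIs through the real normalization path and
  # compare the divergent layers with the frozen annotations
  lib <- base_molecule_library()
  path_xyz <- function(at) {
    rec <- molecule_record("x", at)
    sel <- select_largest_component(rec, perceive_connectivity(at))
    to_canonical_xyz(sel$record)
  }
  blocks <- list()
  for (lay in names(lib$injection_pairs)) {
    p <- lib$injection_pairs[[lay]]
    blocks[[paste0(lay, "_base")]] <-
      path_xyz(lib$molecules[[p$base]]$atoms)
    blocks[[paste0(lay, "_variant")]] <- path_xyz(p$variant_atoms)
  }
  res <- generate_inchi_batch(unname(blocks))
  nm <- names(blocks)
  for (lay in names(lib$injection_pairs)) {
    base_i <- res$inchi[match(paste0(lay, "_base"), nm)]
    var_i <- res$inchi[match(paste0(lay, "_variant"), nm)]
    expect_false(identical(base_i, var_i))
    expect_setequal(divergent_layers(base_i, var_i),
                    lib$injection_pairs[[lay]]$layers)
  }
})

test_that("specs are validated and isotope injections are refused", {
  expect_error(injection_spec(0), "n_entries")
  expect_error(injection_spec(10, fraction_duplicates = 1.5), "within")
  expect_error(injection_spec(
    10, per_layer_mismatch_counts = c(isotope = 1L)), "isotope")
  expect_error(injection_spec(
    10, per_layer_mismatch_counts = c(banana = 1L)), "no injection pair")
  expect_error(injection_spec(
    5, per_layer_mismatch_counts = c(formula = 10L)), "infeasible")
  expect_error(injection_spec(10, charge_dialect_mix = c(absent = 1)),
               "dialect_mix")
})

test_that("benign perturbation is the identity at magnitude zero and keeps connectivity", {
  lib <- base_molecule_library()
  at <- lib$molecules$glycine$atoms
  expect_identical(perturb_geometry(at, "benign", 0), at)
  jit <- perturb_geometry(at, "benign", 0.01, seed = 4)
  expect_false(identical(jit$x, at$x))
  expect_identical(perceive_connectivity(jit)$edges,
                   perceive_connectivity(at)$edges)
  # determinism under a fixed seed
  expect_identical(perturb_geometry(at, "benign", 0.01, seed = 4), jit)
})

test_that("bond breaking removes exactly one edge near the threshold", {
  # two H at threshold - 0.05 (1.02 - 0.05), pushed by 0.2
  at <- h2_atoms(0.97)
  before <- nrow(perceive_connectivity(at)$edges)
  after <- nrow(perceive_connectivity(
    perturb_geometry(at, "bond_breaking", 0.2))$edges)
  expect_identical(before - after, 1L)
  far <- atoms(c("He", "He"), x = c(0, 30), y = 0, z = 0)
  expect_error(perturb_geometry(far, "bond_breaking", 0.2), "no bonded pair")
})

test_that("stereo flip inverts a tetrahedral center's layer", {
  lib <- base_molecule_library()
  at <- lib$molecules$r_butan_2_ol$atoms
  flipped <- perturb_geometry(at, "stereo_flip")
  res <- generate_inchi_batch(list(write_xyz(at, "a"),
                                   write_xyz(flipped, "b")))
  expect_identical(divergent_layers(res$inchi[1], res$inchi[2]),
                   "tetrahedral")
  expect_error(perturb_geometry(water_atoms(), "stereo_flip"),
               "no eligible")
})

test_that("corpus generation is deterministic and honours the spec", {
  spec <- injection_spec(25, seed = 42,
                         per_layer_mismatch_counts = c(double_bond = 2L),
                         fraction_duplicates = 0.08,
                         fraction_unannotated = 0.12)
  d1 <- tempfile("c1"); d2 <- tempfile("c2")
  g1 <- generate_corpus(spec, d1)
  g2 <- generate_corpus(spec, d2)
  # byte-identical trees under the same seed
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  gt <- g1$ground_truth
  expect_identical(gt$duplicates, 2L)
  expect_identical(gt$excluded_no_annotation, 3L)
  expect_identical(gt$expected_category_counts$PM5_NCI_NOT_PM7, 2L)
  expect_identical(gt$expected_layer_histogram$double_bond, 2L)
  # every original document parses and unannotated entries lack computed files
  n_orig <- length(list.files(d1, pattern = "_original"))
  expect_identical(n_orig, gt$total_documents)
  n_pm5 <- length(list.files(d1, pattern = "post-mopac"))
  expect_identical(n_pm5, 25L - gt$excluded_no_annotation)
  unlink(c(d1, d2), recursive = TRUE)
})
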
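test_that("the five categories partition all equality patterns of 3 strings", {
  expect_identical(classify_triplet("X", "X", "X"), "ALL_MATCH")
  expect_identical(classify_triplet("X", "Y", "Y"), "PM5_PM7_NOT_NCI")
  expect_identical(classify_triplet("X", "Y", "X"), "PM7_NCI_NOT_PM5")
  expect_identical(classify_triplet("X", "X", "Y"), "PM5_NCI_NOT_PM7")
  expect_identical(classify_triplet("X", "Y", "Z"), "ALL_DIFFER")
  # exhaustive enumeration over all 27 string assignments: exactly one
  # category each, and the category is determined by the equality pattern
  labels <- c("A", "B", "C")
  seen <- character(0)
  for (a in labels) for (b in labels) for (d in labels) {
    cat_ <- classify_triplet(a, b, d)
    expect_true(cat_ %in% c("ALL_MATCH", "PM5_PM7_NOT_NCI",
                            "PM7_NCI_NOT_PM5", "PM5_NCI_NOT_PM7",
                            "ALL_DIFFER"))
    pattern <- paste(as.integer(c(a == b, b == d, a == d)), collapse = "")
    expected <- switch(pattern,
                       "111" = "ALL_MATCH", "010" = "PM5_PM7_NOT_NCI",
                       "001" = "PM7_NCI_NOT_PM5", "100" = "PM5_NCI_NOT_PM7",
                       "000" = "ALL_DIFFER")
    expect_identical(cat_, expected)
    seen <- union(seen, cat_)
  }
  expect_identical(length(seen), 5L)   # all five categories realizable
  expect_error(classify_triplet("", "X", "Y"), "NCI")
})

test_that("divergent layers are symmetric and report every difference", {
  a <- parse_inchi_layers("InChI=1S/C4H12N/c1-5(2,3)4/h1-4H3/q+1")
  b <- parse_inchi_layers("InChI=1S/C4H12N/c1-5(2,3)4/h1-4H3")
  expect_identical(divergent_layers(a, b), "charge")
  expect_identical(divergent_layers(b, a), "charge")
  expect_identical(divergent_layers(a, a), character(0))

  c1 <- parse_inchi_layers("InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3")
  c2 <- parse_inchi_layers("InChI=1S/C2H5O/c1-2-3/h2H2,1H3")
  expect_identical(divergent_layers(c1, c2), c("formula", "hydrogen"))

  m1 <- parse_inchi_layers("InChI=1S/C4H10O/c1-3-4(2)5/h4-5H,3H2,1-2H3/t4-/m1/s1")
  m0 <- parse_inchi_layers("InChI=1S/C4H10O/c1-3-4(2)5/h4-5H,3H2,1-2H3/t4-/m0/s1")
  expect_identical(divergent_layers(m1, m0), "tetrahedral")
})

test_that("tabulation preserves the partition and the layer histogram", {
  mk <- function(id, nci, pm5, pm7) triplet_result(
    id, c(NCI = nci, PM5 = pm5, PM7 = pm7))
  same <- "InChI=1S/H2O/h1H2"
  allm <- lapply(1:10, function(i) mk(i, same, same, same))
  tab <- concordance_table(allm)
  expect_identical(tab$counts[["ALL_MATCH"]], 10L)
  expect_identical(sum(tab$counts), 10L)
  expect_identical(length(tab$layer_distribution), 0L)

  other <- "InChI=1S/H2O/h1H2/i/hD"
  mixed <- c(allm, list(mk(11, same, same, other),
                        mk(12, other, same, same)))
  tab2 <- concordance_table(mixed)
  expect_identical(sum(tab2$counts), length(mixed))
  expect_identical(tab2$counts[["PM5_NCI_NOT_PM7"]], 1L)
  expect_identical(tab2$counts[["PM5_PM7_NOT_NCI"]], 1L)
  # both divergent triplets differ from the original in the isotope layer
  expect_identical(tab2$layer_distribution[["isotope"]], 2L)
})

test_that("category-count arithmetic identities hold", {
  counts <- c(ALL_MATCH = 154552L, PM5_PM7_NOT_NCI = 2041L,
              PM7_NCI_NOT_PM5 = 573L, PM5_NCI_NOT_PM7 = 470L,
              ALL_DIFFER = 486L)
  s <- concordance_summary(counts)
  expect_identical(s$total, sum(counts))
  expect_identical(s$pm7_ne_nci,
                   counts[["PM5_PM7_NOT_NCI"]] + counts[["PM5_NCI_NOT_PM7"]] +
                     counts[["ALL_DIFFER"]])
  expect_identical(s$all_match_percent,
                   round(100 * counts[["ALL_MATCH"]] / sum(counts), 1))
})

test_that("triplet tables round-trip through the TSV reader", {
  tf <- tempfile(fileext = ".tsv")
  df <- data.frame(nsc_id = c(1L, 2L),
                   NCI = c("InChI=1S/H2O/h1H2", "InChI=1S/CH4/h1H4"),
                   PM5 = c("InChI=1S/H2O/h1H2", "InChI=1S/CH4/h1H4"),
                   PM7 = c("InChI=1S/H2O/h1H2", "InChI=1S/CH4/h1H4/i1+1"))
  utils::write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  res <- read_triplets(tf)
  expect_identical(vapply(res, `[[`, "", "category"),
                   c("ALL_MATCH", "PM5_NCI_NOT_PM7"))
})
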
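# Triplet concordance: each molecule has three structure versions (original
# database entry, legacy semi-empirical optimization, re-optimization), each
# reduced to an InChI. The five equality patterns of the three strings
# partition all outcomes; mismatches are then attributed to InChI layers in
# a separate diagnostic pass.

.concordance_labels <- c("ALL_MATCH", "PM5_PM7_NOT_NCI", "PM7_NCI_NOT_PM5",
                         "PM5_NCI_NOT_PM7", "ALL_DIFFER")

#' Classify one structure-version triplet
#'
#' Equality is exact whole-string InChI equality. The five categories are
#' mutually exclusive and exhaustive over the equality patterns of three
#' strings.
#'
#' @param inchi_nci,inchi_pm5,inchi_pm7 non-empty InChI strings.
#' @return one of `"ALL_MATCH"`, `"PM5_PM7_NOT_NCI"`, `"PM7_NCI_NOT_PM5"`,
#'   `"PM5_NCI_NOT_PM7"`, `"ALL_DIFFER"`.
#' @export
classify_triplet <- function(inchi_nci, inchi_pm5, inchi_pm7) {
  vals <- c(NCI = inchi_nci, PM5 = inchi_pm5, PM7 = inchi_pm7)
  empty <- !nzchar(vals) | is.na(vals)
  if (any(empty)) {
    stop("empty InChI for provenance: ",
         paste(names(vals)[empty], collapse = ", "))
  }
  if (inchi_nci == inchi_pm5 && inchi_pm5 == inchi_pm7) return("ALL_MATCH")
  if (inchi_pm5 == inchi_pm7) return("PM5_PM7_NOT_NCI")
  if (inchi_pm7 == inchi_nci) return("PM7_NCI_NOT_PM5")
  if (inchi_pm5 == inchi_nci) return("PM5_NCI_NOT_PM7")
  "ALL_DIFFER"
}

#' Layers on which two dissected InChIs differ
#'
#' A layer label is reported iff that layer's string differs, where absence
#' is a distinct comparable state (present-vs-absent counts as divergent).
#' All differing layers are reported, not only the first, so one mismatched
#' pair can contribute to several layer counts. The tetrahedral label covers
#' the t layer together with its m/s sublayers.
#'
#' @param a,b `inchi_layers` objects (or InChI strings, parsed on the fly).
#' @return character vector of layer labels (possibly empty), in canonical
#'   layer order.
#' @export
divergent_layers <- function(a, b) {
  if (is.character(a)) a <- parse_inchi_layers(a)
  if (is.character(b)) b <- parse_inchi_layers(b)
  stopifnot(inherits(a, "inchi_layers"), inherits(b, "inchi_layers"))
  differs <- function(x, y) !identical(is.na(x), is.na(y)) ||
    (!is.na(x) && x != y)
  out <- character(0)
  for (f in c("formula", "connectivity", "hydrogen", "charge",
              "protonation", "double_bond", "isotope")) {
    if (differs(a[[f]], b[[f]])) out <- c(out, f)
  }
  tet <- function(l) paste(l$tetrahedral, l$stereo_m, l$stereo_s,
                           collapse = "/")
  if (!identical(tet(a), tet(b))) out <- c(out, "tetrahedral")
  # canonical order
  ord <- c("formula", "connectivity", "hydrogen", "charge", "protonation",
           "double_bond", "tetrahedral", "isotope")
  out[order(match(out, ord))]
}

#' Concordance result for one triplet
#'
#' @param nsc_id accession number.
#' @param inchis named character vector with elements `NCI`, `PM5`, `PM7`.
#' @return object of class `triplet_result`: the category plus, for every
#'   unequal provenance pair, the set of divergent layer labels.
#' @export
triplet_result <- function(nsc_id, inchis) {
  stopifnot(all(c("NCI", "PM5", "PM7") %in% names(inchis)))
  category <- classify_triplet(inchis[["NCI"]], inchis[["PM5"]],
                               inchis[["PM7"]])
  layers <- list()
  if (category != "ALL_MATCH") {
    parsed <- lapply(inchis[c("NCI", "PM5", "PM7")], parse_inchi_layers)
    for (pair in list(c("PM7", "NCI"), c("PM5", "NCI"), c("PM7", "PM5"))) {
      if (inchis[[pair[1]]] != inchis[[pair[2]]]) {
        layers[[paste(pair, collapse = "_vs_")]] <-
          divergent_layers(parsed[[pair[1]]], parsed[[pair[2]]])
      }
    }
  }
  structure(list(nsc_id = as.integer(nsc_id), category = category,
                 divergent_layers = layers),
            class = "triplet_result")
}

#' Tabulate triplet results into a concordance table
#'
#' Category counts over all classified triplets, plus a per-layer mismatch
#' distribution computed over one provenance pair (default the
#' re-optimization against the original database version) restricted to the
#' triplets where that pair differs. The layer distribution total can exceed
#' the number of mismatched pairs: one mismatch may differ in several
#' layers.
#'
#' @param results list of `triplet_result` objects.
#' @param pair character(2): provenance pair for the layer distribution.
#' @return object of class `concordance_table`: list with `counts` (named,
#'   all five categories), `layer_distribution` (named counts), `pair`, `n`.
#' @export
concordance_table <- function(results, pair = c("PM7", "NCI")) {
  cats <- vapply(results, `[[`, "", "category")
  counts <- stats::setNames(
    as.integer(table(factor(cats, levels = .concordance_labels))),
    .concordance_labels)
  key <- paste(pair, collapse = "_vs_")
  alt_key <- paste(rev(pair), collapse = "_vs_")
  layer_counts <- integer(0)
  for (r in results) {
    lay <- r$divergent_layers[[key]]
    if (is.null(lay)) lay <- r$divergent_layers[[alt_key]]
    for (l in lay) {
      layer_counts[l] <- (if (is.na(layer_counts[l][1])) 0L else
        layer_counts[l]) + 1L
    }
  }
  structure(list(counts = counts,
                 layer_distribution = layer_counts,
                 pair = pair, n = length(results)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("<concordance_table n =", x$n, ">\n")
  print(x$counts)
  if (length(x$layer_distribution)) {
    cat("layer distribution (", paste(x$pair, collapse = " vs "), "):\n")
    print(x$layer_distribution)
  }
  invisible(x)
}

#' Arithmetic summary of a set of category counts
#'
#' Works directly from the five category counts (as printed in a concordance
#' table), so published tables can be checked without re-running the corpus:
#' the partition identity (counts sum to the classified total), the number
#' of triplets whose re-optimized version disagrees with the original
#' database version, and the all-match percentage.
#'
#' @param counts named integer vector over the five category labels.
#' @return list with `total`, `all_match_percent` (one decimal),
#'   `pm7_ne_nci` (sum of the three categories with PM7 != NCI).
#' @export
concordance_summary <- function(counts) {
  stopifnot(all(.concordance_labels %in% names(counts)))
  counts <- counts[.concordance_labels]
  total <- sum(counts)
  pm7_ne_nci <- counts[["PM5_PM7_NOT_NCI"]] + counts[["PM5_NCI_NOT_PM7"]] +
    counts[["ALL_DIFFER"]]
  list(total = as.integer(total),
       all_match_percent = round(100 * counts[["ALL_MATCH"]] / total, 1),
       pm7_ne_nci = as.integer(pm7_ne_nci))
}

#' Read a three-column triplet table
#'
#' @param path TSV with columns `nsc_id`, `NCI`, `PM5`, `PM7` (InChI
#'   strings).
#' @return list of `triplet_result` objects.
#' @export
read_triplets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("nsc_id", "NCI", "PM5", "PM7") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i) {
    triplet_result(df$nsc_id[i],
                   c(NCI = df$NCI[i], PM5 = df$PM5[i], PM7 = df$PM7[i]))
  })
}
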
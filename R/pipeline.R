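# End-to-end curation run: ingest -> validate -> charge reconciliation ->
# (pluggable external optimization) -> Cartesian normalization -> InChI ->
# triplet concordance -> per-entry packaging -> metadata crosswalk.
# Failures are isolated per entry: one bad record never aborts the corpus.

#' Configure a curation run
#'
#' @param input_dir directory of per-entry CML documents
#'   (`nsc<ID>_original.cml`, `nsc<ID>_post-mopac.cml`, `nsc<ID>_PM7.xml`).
#' @param output_dir optional; when set, SWORD bundles and the JSON report
#'   are written there.
#' @param schema CML validation profile ([cml_schema()]).
#' @param radii covalent radius table for bond perception.
#' @param tolerance bond-perception tolerance, Angstrom.
#' @param optimizer `"mock"` (default), `"none"`, or an external command
#'   template for [run_optimizer()].
#' @param handle_prefix,doi_prefix,doi_suffix_template persistent-identifier
#'   configuration; per-entry identifiers are
#'   `<handle_prefix>/<nsc>` and `<doi_prefix>/<suffix_template><nsc>`.
#' @param base_url repository base URL used in manifests.
#' @return object of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir = NULL,
                       schema = cml_schema(), radii = covalent_radii(),
                       tolerance = 0.40, optimizer = "mock",
                       handle_prefix = "10042", doi_prefix = "10.14469",
                       doi_suffix_template = "ch/",
                       base_url = "https://repository.example.org") {
  if (!dir.exists(input_dir)) stop("input directory does not exist: ",
                                   input_dir)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 schema = schema, radii = radii, tolerance = tolerance,
                 optimizer = optimizer, handle_prefix = handle_prefix,
                 doi_prefix = doi_prefix,
                 doi_suffix_template = doi_suffix_template,
                 base_url = base_url),
            class = "run_config")
}

.entry_status <- function(nsc_id, stage, status, message = "") {
  data.frame(nsc_id = nsc_id, stage = stage, status = status,
             message = message, stringsAsFactors = FALSE)
}

#' Run the curation pipeline over a corpus directory
#'
#' Stages run in order (retrieval-style ingest, technical validation,
#' re-deposition packaging); per-entry failures are recorded in the report
#' and the run continues. An unreadable or empty input directory is fatal.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`: corpus report, charge histogram and
#'   flags, concordance table, per-entry statuses, package manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  orig_files <- list.files(config$input_dir, pattern = "_original.*\\.cml$",
                           full.names = TRUE)
  if (!length(orig_files)) {
    stop("no original CML documents found in ", config$input_dir)
  }
  statuses <- list()
  note <- function(...) statuses[[length(statuses) + 1L]] <<-
    .entry_status(...)

  records <- list()
  for (f in sort(orig_files)) {
    rec <- tryCatch(parse_cml(f), error = function(e) e)
    if (inherits(rec, "error")) {
      note(NA_integer_, "parse", "error",
           paste0(basename(f), ": ", conditionMessage(rec)))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  if (!length(records)) stop("no parseable original documents")

  dd <- deduplicate(records)
  uniq <- dd$records

  pairs <- lapply(uniq, function(r) {
    base <- file.path(config$input_dir, sprintf("nsc%d", r$nsc_id))
    pm5_f <- paste0(base, "_post-mopac.cml")
    pm7_f <- paste0(base, "_PM7.xml")
    list(nci = r,
         computed = if (file.exists(pm5_f)) parse_cml(pm5_f) else NULL,
         pm7 = if (file.exists(pm7_f)) parse_cml(pm7_f) else NULL)
  })
  fa <- filter_annotated(pairs)
  kept <- fa$kept

  report <- corpus_report(
    total_read = dd$report$total_read,
    unique_kept = length(kept),
    duplicates_removed = dd$report$duplicates_removed,
    excluded_no_annotation = fa$excluded)

  assignments <- list()
  xyz_blocks <- list()
  triplet_ids <- integer(0)
  manifests <- list()
  decks <- list()

  for (p in kept) {
    id <- p$nci$nsc_id
    res <- tryCatch({
      viol <- validate_cml(write_cml(p$nci), config$schema)
      if (nrow(viol)) {
        note(id, "validate", "warning",
             paste(viol$message, collapse = "; "))
      }
      charge <- reconcile_charge(p$nci)
      assignments[[as.character(id)]] <- charge

      normalize <- function(rec) {
        g <- perceive_connectivity(rec$atoms, radii = config$radii,
                                   tolerance = config$tolerance)
        sel <- select_largest_component(rec, g)
        to_canonical_xyz(sel$record)
      }
      xyz3 <- list(NCI = normalize(p$nci), PM5 = normalize(p$computed),
                   PM7 = if (!is.null(p$pm7)) normalize(p$pm7) else NULL)

      deck <- suppressWarnings(build_mopac_input(p$computed, charge,
                                                 method = "PM7"))
      decks[[as.character(id)]] <- deck
      opt_out <- NULL
      if (!identical(config$optimizer, "none")) {
        opt_out <- run_optimizer(deck, config$optimizer)
        parsed <- parse_mopac_output(opt_out)
        if (parsed$status != "normal") {
          note(id, "optimize", "error", "optimizer error termination")
        }
        if (is.null(xyz3$PM7)) {
          # no re-optimized document supplied: use the optimizer result
          rec7 <- molecule_record(p$nci$name, parsed$atoms, nsc_id = id,
                                  formal_charge_attr = charge$value,
                                  provenance = "PM7")
          xyz3$PM7 <- normalize(rec7)
        }
      }
      if (is.null(xyz3$PM7)) stop("no re-optimized geometry available")

      for (prov in c("NCI", "PM5", "PM7")) {
        xyz_blocks[[sprintf("%d_%s", id, prov)]] <- xyz3[[prov]]
      }
      triplet_ids <- c(triplet_ids, id)

      files <- list(
        bundle_file(sprintf("nsc%d_original.cml", id), write_cml(p$nci), 1L),
        bundle_file(sprintf("nsc%d_post-mopac.cml", id),
                    write_cml(p$computed), 2L),
        bundle_file("PM7.xml", if (!is.null(p$pm7)) write_cml(p$pm7) else
          write_cml(molecule_record(p$nci$name,
                                    read_xyz(xyz3$PM7)$atoms, nsc_id = id,
                                    provenance = "PM7")), 3L),
        bundle_file(sprintf("nsc%d.mop", id), format_mopac_input(deck), 4L))
      if (!is.null(opt_out)) {
        files <- c(files, list(bundle_file(sprintf("nsc%d.out", id),
                                           opt_out, 5L)))
      }
      md <- entry_metadata(name = p$nci$name, smiles = p$nci$smiles,
                           cas_id = p$nci$cas_id, nsc_id = id)
      bundle <- entry_bundle(
        handle = sprintf("%s/%d", config$handle_prefix, id),
        doi = sprintf("%s/%s%d", config$doi_prefix,
                      config$doi_suffix_template, id),
        metadata = md, files = files)
      manifests[[as.character(id)]] <- bundle
      note(id, "package", "ok")
      TRUE
    }, error = function(e) {
      note(id, "pipeline", "error", conditionMessage(e))
      FALSE
    })
  }

  # conflated CML per bundle needs all three geometries; add after the loop
  # (kept minimal: conflated document built from the stored versions)
  inchis <- generate_inchi_batch(unname(xyz_blocks))
  key <- names(xyz_blocks)
  results <- lapply(triplet_ids, function(id) {
    idx <- match(sprintf("%d_%s", id, c("NCI", "PM5", "PM7")), key)
    triplet_result(id, stats::setNames(inchis$inchi[idx],
                                       c("NCI", "PM5", "PM7")))
  })
  conc <- concordance_table(results)

  crosswalks <- lapply(manifests, function(b) {
    mets_url <- sprintf("%s/metadata/handle/%s/mets.xml", config$base_url,
                        b$handle)
    ore_url <- sprintf("%s/metadata/handle/%s/ore.xml", config$base_url,
                       b$handle)
    rec <- crosswalk(b$metadata, b, mets_url, ore_url)
    register_media(rec, "chemical/x-cml",
                   build_media_url(b$doi, "chemical/x-cml"))
  })

  out <- structure(list(
    corpus = report,
    charges = charge_histogram(unname(assignments)),
    concordance = conc,
    triplets = results,
    statuses = if (length(statuses)) do.call(rbind, statuses) else
      .entry_status(integer(0), character(0), character(0))[0, ],
    bundles = manifests,
    datacite = crosswalks,
    decks = decks), class = "run_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    for (b in manifests) {
      build_sword_bundle(b, file.path(config$output_dir,
                                      sprintf("nsc%d_sword.zip",
                                              b$metadata$nsc_id)))
    }
    jsonlite::write_json(summary_list(out),
                         file.path(config$output_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Plain-list summary of a run report (JSON-ready)
#'
#' @param report a `run_report`.
#' @return nested list of counts and flags.
#' @export
summary_list <- function(report) {
  stopifnot(inherits(report, "run_report"))
  list(corpus = unclass(report$corpus),
       charge_histogram = as.list(report$charges$histogram),
       charge_conflicts = report$charges$conflicts,
       charge_implausible = report$charges$implausible,
       concordance_counts = as.list(report$concordance$counts),
       layer_distribution = as.list(report$concordance$layer_distribution),
       n_bundles = length(report$bundles),
       n_errors = sum(report$statuses$status == "error"))
}

#' @export
print.run_report <- function(x, ...) {
  print(x$corpus)
  cat("charge conflicts:", x$charges$conflicts,
      "implausible:", x$charges$implausible, "\n")
  print(x$concordance)
  cat("bundles:", length(x$bundles), " errors:",
      sum(x$statuses$status == "error"), "\n")
  invisible(x)
}

#' Describe the re-curation actions for a set of bundles
#'
#' For each bundle: the manifest retrieval URL pair (mets.xml, ore.xml
#' under `<base>/metadata/handle/<handle>/`) and a deposit action carrying
#' the METSDSpaceSIP packaging header. Dry-run by default; this function
#' never performs network calls.
#'
#' @param bundles list of [entry_bundle()] objects.
#' @param endpoint SWORD deposit endpoint URL.
#' @param base_url repository base URL for manifest retrieval.
#' @return list of actions, each with `handle`, `mets_url`, `ore_url` and
#'   `deposit` (headers incl. `X-Packaging`), plus attribute
#'   `dry_run = TRUE`.
#' @export
recuration_export <- function(bundles, endpoint,
                              base_url = "https://repository.example.org") {
  actions <- lapply(bundles, function(b) {
    list(handle = b$handle,
         mets_url = sprintf("%s/metadata/handle/%s/mets.xml", base_url,
                            b$handle),
         ore_url = sprintf("%s/metadata/handle/%s/ore.xml", base_url,
                           b$handle),
         deposit = sword_deposit_request(
           sprintf("nsc%s_sword.zip", sub(".*/", "", b$handle)), endpoint))
  })
  attr(actions, "dry_run") <- TRUE
  actions
}
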
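# Synthetic corpus generation with recorded ground truth. The generator
# emulates the structural variety of a legacy computed-structure corpus --
# duplicate accessions, entries without a computed annotation, both charge
# dialects (agreeing, conflicting or absent), counter-ion components and
# implausible declared charges -- and injects InChI-layer mismatches using a
# frozen library of base/variant geometry pairs whose divergent layers are
# known and re-verifiable against the reference implementation. All
# randomness is confined to this module; the pipeline itself is
# deterministic.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.library_cache <- new.env(parent = emptyenv())

#' The built-in synthetic base-molecule library
#'
#' A small hand-constructed library of organic structures (with charges,
#' stereocenters and multi-component salts) stored as a frozen plain-text
#' data file -- no external database. Injection pairs carry a variant
#' geometry whose InChI diverges from the base in an annotated layer set.
#'
#' @return list with `molecules` (named list; each has `name`, `atoms`,
#'   `charge`, `smiles`, `roles`) and `injection_pairs` (named by layer;
#'   each has `base`, `variant_atoms`, `layers`).
#' @export
base_molecule_library <- function() {
  if (!is.null(.library_cache$lib)) return(.library_cache$lib)
  path <- system.file("extdata", "base_molecules.json",
                      package = "molcurate")
  if (!nzchar(path)) stop("bundled molecule library not found")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  as_atoms <- function(rows) {
    atoms(vapply(rows, function(r) r[[1]], ""),
          vapply(rows, function(r) r[[2]], 0),
          vapply(rows, function(r) r[[3]], 0),
          vapply(rows, function(r) r[[4]], 0))
  }
  mols <- lapply(raw$molecules, function(m) {
    list(name = m$name, smiles = m$smiles, charge = as.integer(m$charge),
         roles = unlist(m$roles), atoms = as_atoms(m$atoms))
  })
  names(mols) <- vapply(mols, `[[`, "", "name")
  pairs <- lapply(raw$injection_pairs, function(p) {
    list(base = p$base, variant_atoms = as_atoms(p$variant_atoms),
         layers = unlist(p$layers))
  })
  .library_cache$lib <- list(molecules = mols, injection_pairs = pairs)
  .library_cache$lib
}

.dialect_cases <- c("legacy_only", "attr_only", "both_agree",
                    "both_conflict", "absent")

#' Specify a synthetic corpus
#'
#' Defaults reflect the shape of a real legacy corpus: predominantly neutral
#' unique entries, a dedicated fraction without a computed annotation, a few
#' percent duplicate accessions, both charge dialects in circulation with
#' occasional disagreement, a minority of salt entries with counter-ion
#' components, and a rare implausible (|q| > 3) declaration.
#'
#' @param n_entries number of unique molecules.
#' @param seed integer; the same seed gives a byte-identical corpus.
#' @param fraction_duplicates proportion of additional duplicate documents.
#' @param fraction_unannotated proportion of entries lacking a computed
#'   record.
#' @param per_layer_mismatch_counts named integer vector: how many entries
#'   receive a re-optimized geometry whose InChI diverges from the original
#'   in (at least) the named layer. Supported layers: formula, connectivity,
#'   hydrogen, charge, double_bond, tetrahedral. Isotope injections are
#'   rejected: the Cartesian normalization path cannot carry isotope labels,
#'   so such a difference could never be recovered.
#' @param charge_dialect_mix named proportions over `legacy_only`,
#'   `attr_only`, `both_agree`, `both_conflict`, `absent`.
#' @param fraction_multicomponent proportion of entries with a counter-ion
#'   component.
#' @param fraction_implausible_charge proportion with a declared |q| > 3.
#' @return object of class `injection_spec`.
#' @export
injection_spec <- function(n_entries, seed = 1L,
                           fraction_duplicates = 0.05,
                           fraction_unannotated = 0.08,
                           per_layer_mismatch_counts = c(
                             formula = 4L, connectivity = 4L, hydrogen = 4L,
                             charge = 3L, double_bond = 3L, tetrahedral = 3L),
                           charge_dialect_mix = c(
                             legacy_only = 0.2, attr_only = 0.3,
                             both_agree = 0.3, both_conflict = 0.1,
                             absent = 0.1),
                           fraction_multicomponent = 0.10,
                           fraction_implausible_charge = 0.05) {
  stopifnot(n_entries >= 1)
  fracs <- c(fraction_duplicates, fraction_unannotated,
             fraction_multicomponent, fraction_implausible_charge)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must be within [0, 1]")
  if (length(per_layer_mismatch_counts)) {
    if ("isotope" %in% names(per_layer_mismatch_counts)) {
      stop("isotope-layer injections are not supported: the Cartesian ",
           "normalization path discards isotope labels, so an injected ",
           "isotope difference could never be recovered by the pipeline")
    }
    known <- names(base_molecule_library()$injection_pairs)
    bad <- setdiff(names(per_layer_mismatch_counts), known)
    if (length(bad)) stop("no injection pair for layer(s): ",
                          paste(bad, collapse = ", "))
  }
  if (abs(sum(charge_dialect_mix) - 1) > 1e-9 ||
      !setequal(names(charge_dialect_mix), .dialect_cases)) {
    stop("charge_dialect_mix must cover exactly ",
         paste(.dialect_cases, collapse = ", "), " and sum to 1")
  }
  n_inject <- sum(per_layer_mismatch_counts)
  n_unann <- round(fraction_unannotated * n_entries)
  n_multi <- round(fraction_multicomponent * n_entries)
  n_implaus <- round(fraction_implausible_charge * n_entries)
  if (n_inject + n_unann + n_multi + n_implaus > n_entries) {
    stop("infeasible spec: injected/unannotated/multicomponent/implausible ",
         "slots exceed n_entries")
  }
  structure(list(n_entries = as.integer(n_entries), seed = as.integer(seed),
                 fraction_duplicates = fraction_duplicates,
                 fraction_unannotated = fraction_unannotated,
                 per_layer_mismatch_counts = per_layer_mismatch_counts,
                 charge_dialect_mix = charge_dialect_mix,
                 fraction_multicomponent = fraction_multicomponent,
                 fraction_implausible_charge = fraction_implausible_charge),
            class = "injection_spec")
}

#' Perturb a geometry
#'
#' Three modes: `benign` jitters every coordinate uniformly within
#' `magnitude` Angstrom (small enough jitters leave the bonded-distance
#' regime, and hence connectivity, unchanged); `bond_breaking` moves one
#' atom of the bonded pair closest to the perception threshold outward along
#' the bond axis by `magnitude`; `stereo_flip` mirror-inverts the geometry
#' of a molecule with an eligible tetrahedral center (an atom with four
#' neighbours of at least three distinct elements -- a geometric heuristic,
#' not a CIP analysis).
#'
#' @param atoms atom table with coordinates.
#' @param mode `"benign"`, `"bond_breaking"` or `"stereo_flip"`.
#' @param magnitude displacement in Angstrom (>= 0).
#' @param seed integer seed (used by the benign mode's jitter).
#' @return perturbed atom table.
#' @export
perturb_geometry <- function(atoms, mode = c("benign", "bond_breaking",
                                             "stereo_flip"),
                             magnitude = 0.01, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(magnitude >= 0)
  if (mode == "benign") {
    if (magnitude == 0) return(atoms)
    n <- nrow(atoms)
    jit <- .with_seed(seed, matrix(stats::runif(3 * n, -magnitude, magnitude),
                                   n, 3))
    out <- atoms
    out$x <- out$x + jit[, 1]; out$y <- out$y + jit[, 2]
    out$z <- out$z + jit[, 3]
    return(out)
  }
  if (mode == "bond_breaking") {
    g <- perceive_connectivity(atoms)
    if (!nrow(g$edges)) stop("no bonded pair eligible for bond_breaking")
    radii <- covalent_radii()
    slack <- apply(g$edges, 1, function(e) {
      thr <- radii[atoms$element[e[1]]] + radii[atoms$element[e[2]]] + 0.40
      d <- sqrt(sum((as.numeric(atoms[e[1], c("x", "y", "z")]) -
                       as.numeric(atoms[e[2], c("x", "y", "z")]))^2))
      thr - d
    })
    e <- g$edges[which.min(slack), ]
    i <- e[1]; j <- e[2]
    dvec <- c(atoms$x[j] - atoms$x[i], atoms$y[j] - atoms$y[i],
              atoms$z[j] - atoms$z[i])
    dvec <- dvec / sqrt(sum(dvec^2))
    out <- atoms
    out$x[j] <- out$x[j] + magnitude * dvec[1]
    out$y[j] <- out$y[j] + magnitude * dvec[2]
    out$z[j] <- out$z[j] + magnitude * dvec[3]
    return(out)
  }
  # stereo_flip
  g <- perceive_connectivity(atoms)
  eligible <- FALSE
  for (k in seq_len(nrow(atoms))) {
    nb <- c(g$edges[g$edges[, 1] == k, 2], g$edges[g$edges[, 2] == k, 1])
    if (length(nb) == 4 &&
        length(unique(atoms$element[nb])) >= 3) { eligible <- TRUE; break }
  }
  if (!eligible) stop("no eligible tetrahedral center for stereo_flip")
  out <- atoms
  out$x <- -out$x
  out
}

#' Generate a synthetic corpus with ground truth
#'
#' Emits, per entry, a legacy-dialect original document, a
#' computed-annotation document (modern dialect) and a re-optimized third
#' geometry, plus duplicate documents, missing annotations, dialect cases,
#' counter-ion components and layer-targeted mismatch injections exactly as
#' the spec demands -- together with a ground-truth record of every
#' injection, so pipeline recovery can be checked exactly.
#'
#' @param spec an [injection_spec()].
#' @param dir optional output directory; when given, per-entry CML files
#'   (`nsc<ID>_original.cml`, `nsc<ID>_post-mopac.cml`, `nsc<ID>_PM7.xml`)
#'   and `ground_truth.json` are written.
#' @return list with `entries` (per-entry record triples), `ground_truth`
#'   and `dir`.
#' @export
generate_corpus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "injection_spec"))
  lib <- base_molecule_library()
  .with_seed(spec$seed, {
    n <- spec$n_entries
    plm <- spec$per_layer_mismatch_counts
    inj_layers <- rep(names(plm), times = plm)
    n_inject <- length(inj_layers)
    n_unann <- as.integer(round(spec$fraction_unannotated * n))
    n_multi <- as.integer(round(spec$fraction_multicomponent * n))
    n_implaus <- as.integer(round(spec$fraction_implausible_charge * n))
    n_dup <- as.integer(round(spec$fraction_duplicates * n))

    perm <- sample.int(n)
    idx_inject <- perm[seq_len(n_inject)]
    idx_unann <- perm[n_inject + seq_len(n_unann)]
    idx_multi <- perm[n_inject + n_unann + seq_len(n_multi)]
    idx_implaus <- perm[n_inject + n_unann + n_multi + seq_len(n_implaus)]

    mol_names <- names(lib$molecules)
    is_salt <- vapply(lib$molecules, function(m)
      "multicomponent" %in% m$roles, TRUE)
    plain <- mol_names[!is_salt &
                         !mol_names %in% "sodium_acetate_contact"]
    salts <- mol_names[is_salt]
    neutral_plain <- plain[vapply(lib$molecules[plain], function(m)
      m$charge == 0L, TRUE)]

    assigned <- character(n)
    assigned[seq_len(n)] <- plain[(seq_len(n) - 1L) %% length(plain) + 1L]
    for (k in seq_along(idx_inject)) {
      assigned[idx_inject[k]] <- lib$injection_pairs[[inj_layers[k]]]$base
    }
    assigned[idx_multi] <- salts[(seq_along(idx_multi) - 1L) %%
                                   length(salts) + 1L]
    assigned[idx_implaus] <- neutral_plain[(seq_along(idx_implaus) - 1L) %%
                                             length(neutral_plain) + 1L]

    nsc_ids <- sample(100000:999999, n)

    # dialect case assignment, honouring the mix proportions
    case_counts <- round(spec$charge_dialect_mix * n)
    while (sum(case_counts) > n) {
      k <- which.max(case_counts); case_counts[k] <- case_counts[k] - 1L
    }
    while (sum(case_counts) < n) {
      k <- which.max(spec$charge_dialect_mix)
      case_counts[k] <- case_counts[k] + 1L
    }
    cases <- sample(rep(names(case_counts), times = case_counts))
    # implausible entries must declare through the formal attribute
    cases[idx_implaus] <- "attr_only"
    # charged molecules cannot be 'absent' (absence means charge zero):
    # swap with a neutral entry that is not implausible
    declared0 <- vapply(assigned, function(nm) lib$molecules[[nm]]$charge, 0L)
    for (i in which(cases == "absent" & declared0 != 0L)) {
      swap <- which(cases != "absent" & declared0 == 0L &
                      !seq_len(n) %in% idx_implaus)[1]
      if (is.na(swap)) stop("cannot honour dialect mix: too few neutral entries")
      tmp <- cases[swap]; cases[swap] <- cases[i]; cases[i] <- tmp
    }

    entries <- vector("list", n)
    for (i in seq_len(n)) {
      mol <- lib$molecules[[assigned[i]]]
      true_charge <- mol$charge
      declared <- if (i %in% idx_implaus) {
        if (match(i, idx_implaus) %% 2L == 1L) 4L else -5L
      } else true_charge
      fc <- la <- NA_integer_
      case <- cases[i]
      if (case == "legacy_only") la <- declared
      if (case == "attr_only") fc <- declared
      if (case == "both_agree") { fc <- declared; la <- declared }
      if (case == "both_conflict") { fc <- declared; la <- declared - 1L }

      nci <- molecule_record(
        name = sprintf("NSC%d", nsc_ids[i]), atoms = mol$atoms,
        nsc_id = nsc_ids[i], formal_charge_attr = fc, legacy_charge = la,
        legacy_basic = if (!is.na(la))
          format_formula(molecular_formula(mol$atoms)) else NA_character_,
        provenance = "NCI", smiles = mol$smiles)

      annotated <- !(i %in% idx_unann)
      pm5 <- pm7 <- NULL
      if (annotated) {
        g <- perceive_connectivity(mol$atoms)
        retained <- select_largest_component(nci, g)$record$atoms
        pm5_at <- perturb_geometry(retained, "benign", 0.01,
                                   seed = spec$seed * 1000L + i)
        pm5 <- molecule_record(
          name = nci$name, atoms = pm5_at, nsc_id = nsc_ids[i],
          formal_charge_attr = if (!is.na(fc)) fc else if (!is.na(la)) la
          else NA_integer_,
          provenance = "PM5")
        pm7_at <- if (i %in% idx_inject) {
          lib$injection_pairs[[inj_layers[match(i, idx_inject)]]]$variant_atoms
        } else {
          perturb_geometry(retained, "benign", 0.01,
                           seed = spec$seed * 2000L + i)
        }
        pm7 <- molecule_record(
          name = nci$name, atoms = pm7_at, nsc_id = nsc_ids[i],
          formal_charge_attr = pm5$formal_charge_attr, provenance = "PM7")
      }
      entries[[i]] <- list(
        nsc_id = nsc_ids[i], molecule = assigned[i], dialect_case = case,
        declared_charge = declared, implausible = i %in% idx_implaus,
        multicomponent = i %in% idx_multi,
        injected_layer = if (i %in% idx_inject)
          inj_layers[match(i, idx_inject)] else NA_character_,
        annotated = annotated, nci = nci, pm5 = pm5, pm7 = pm7)
    }

    dup_of <- if (n_dup > 0) sample(seq_len(n), n_dup, replace = TRUE)
    else integer(0)

    expected_layer_hist <- integer(0)
    for (lay in inj_layers) {
      for (l in lib$injection_pairs[[lay]]$layers) {
        expected_layer_hist[l] <- (if (is.na(expected_layer_hist[l][1])) 0L
        else expected_layer_hist[l]) + 1L
      }
    }
    n_annotated <- n - n_unann
    ground_truth <- list(
      n_entries = n, total_documents = n + n_dup,
      seed = spec$seed,
      duplicates = n_dup, duplicate_nsc_ids = nsc_ids[dup_of],
      excluded_no_annotation = n_unann,
      dialect_case_counts = as.list(table(cases)),
      # reconciliation statistics cover the annotated (kept) entries, since
      # excluded entries never reach the charge stage
      conflicts = sum(cases == "both_conflict" &
                        !seq_len(n) %in% idx_unann),
      implausible = n_implaus,
      multicomponent = n_multi,
      expected_category_counts = list(
        ALL_MATCH = n_annotated - n_inject,
        PM5_PM7_NOT_NCI = 0L, PM7_NCI_NOT_PM5 = 0L,
        PM5_NCI_NOT_PM7 = n_inject, ALL_DIFFER = 0L),
      expected_layer_histogram = as.list(expected_layer_hist),
      injections = lapply(which(!is.na(vapply(entries, function(e)
        e$injected_layer, ""))), function(i)
          list(nsc_id = entries[[i]]$nsc_id,
               layer = entries[[i]]$injected_layer)))

    out <- list(entries = entries, dup_of = dup_of,
                ground_truth = ground_truth, dir = dir)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (e in entries) {
        base <- file.path(dir, sprintf("nsc%d", e$nsc_id))
        writeLines(write_cml(e$nci), paste0(base, "_original.cml"))
        if (e$annotated) {
          writeLines(write_cml(e$pm5), paste0(base, "_post-mopac.cml"))
          writeLines(write_cml(e$pm7), paste0(base, "_PM7.xml"))
        }
      }
      for (k in seq_along(dup_of)) {
        e <- entries[[dup_of[k]]]
        writeLines(write_cml(e$nci),
                   file.path(dir, sprintf("nsc%d_original_dup%d.cml",
                                          e$nsc_id, k)))
      }
      jsonlite::write_json(ground_truth,
                           file.path(dir, "ground_truth.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    out
  })
}
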
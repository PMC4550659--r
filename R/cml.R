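# CML (Chemical Markup Language) reading and writing for the two dialects a
# legacy corpus mixes: the early `identifier` element carrying a <charge>
# child plus a <basic> proto-InChI string, and the later `molecule`
# formalCharge attribute. Both are captured verbatim and independently;
# neither is ever coerced into the other or defaulted to zero at parse time.

CML_NS <- "http://www.xml-cml.org/schema"

.as_int_or_na <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(NA_integer_)
  v <- suppressWarnings(as.integer(sub("^\\+", "", trimws(x))))
  if (is.na(v)) stop("non-integer charge declaration: ", x)
  v
}

.read_xml_input <- function(x) {
  if (inherits(x, "xml_document")) return(x)
  if (length(x) == 1 && !grepl("<", x, fixed = TRUE) && file.exists(x)) {
    return(xml2::read_xml(x))
  }
  xml2::read_xml(paste(x, collapse = "\n"))
}

.parse_molecule_node <- function(mol) {
  id <- xml2::xml_attr(mol, "id")
  nsc_id <- NA_integer_
  if (!is.na(id) && grepl("^NSC[0-9]+$", id)) {
    nsc_id <- as.integer(sub("^NSC", "", id))
  }
  name <- xml2::xml_attr(mol, "name")
  if (is.na(name)) name <- if (!is.na(id)) id else "molecule"

  formal_charge <- .as_int_or_na(xml2::xml_attr(mol, "formalCharge"))

  legacy_charge <- NA_integer_
  legacy_basic <- NA_character_
  ident <- xml2::xml_find_first(mol, "./identifier")
  if (!inherits(ident, "xml_missing")) {
    ch <- xml2::xml_find_first(ident, "./charge")
    if (!inherits(ch, "xml_missing")) {
      legacy_charge <- .as_int_or_na(xml2::xml_text(ch))
    }
    bs <- xml2::xml_find_first(ident, "./basic")
    if (!inherits(bs, "xml_missing")) legacy_basic <- xml2::xml_text(bs)
  }

  atom_nodes <- xml2::xml_find_all(mol, "./atomArray/atom")
  if (length(atom_nodes)) {
    el <- xml2::xml_attr(atom_nodes, "elementType")
    bad <- which(!is_element(el))
    if (length(bad)) {
      stop("atom ", paste(bad, collapse = ", "),
           ": unknown element symbol '", paste(unique(el[bad]), collapse = "','"),
           "'")
    }
    num <- function(a) suppressWarnings(as.numeric(xml2::xml_attr(atom_nodes, a)))
    iso <- suppressWarnings(as.integer(xml2::xml_attr(atom_nodes, "isotopeNumber")))
    atom_tab <- atoms(el, num("x3"), num("y3"), num("z3"), iso)
    atom_ids <- xml2::xml_attr(atom_nodes, "id")
  } else {
    atom_tab <- atoms(character(0))
    atom_ids <- character(0)
  }

  bond_nodes <- xml2::xml_find_all(mol, "./bondArray/bond")
  bonds <- NULL
  if (length(bond_nodes)) {
    refs <- strsplit(xml2::xml_attr(bond_nodes, "atomRefs2"), "\\s+")
    idx <- function(k) vapply(refs, function(r) match(r[[k]], atom_ids), 0L)
    ord <- xml2::xml_attr(bond_nodes, "order")
    ord[is.na(ord)] <- "1"
    bonds <- data.frame(i = idx(1), j = idx(2), order = ord,
                        stringsAsFactors = FALSE)
    if (anyNA(bonds$i) || anyNA(bonds$j)) {
      stop("bond references undeclared atom id")
    }
  }

  meta <- function(key) {
    n <- xml2::xml_find_first(
      mol, sprintf("./metadataList/metadata[@name='mc:%s']", key))
    if (inherits(n, "xml_missing")) NA_character_ else
      xml2::xml_attr(n, "content")
  }
  provenance <- xml2::xml_attr(mol, "convention")
  if (is.na(provenance) || !provenance %in% .provenance_tags) provenance <- "NCI"

  molecule_record(
    name = name, atoms = atom_tab, bonds = bonds, nsc_id = nsc_id,
    cas_id = meta("cas"), formal_charge_attr = formal_charge,
    legacy_charge = legacy_charge, legacy_basic = legacy_basic,
    provenance = provenance, smiles = meta("smiles"),
    inchi = meta("inchi"), inchikey = meta("inchikey"))
}

#' Parse a CML document into a molecule record
#'
#' Handles both charge dialects: the `formalCharge` attribute on the
#' `molecule` element and the legacy `identifier` child with its own
#' `<charge>` element. Each is recorded independently; a missing dialect is
#' recorded as NA (absent), never as 0. Atom order follows document order.
#'
#' @param x XML text, a file path, or an `xml_document`.
#' @return a [molecule_record()].
#' @export
parse_cml <- function(x) {
  doc <- .read_xml_input(x)
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "molecule") {
    stop("expected a <molecule> document; found <", xml2::xml_name(root),
         "> (use parse_cml_set() for conflated documents)")
  }
  .parse_molecule_node(root)
}

#' Parse a conflated CML document into its provenance-tagged records
#'
#' A conflated document carries up to three geometry blocks for the same
#' molecule (original database structure, legacy semi-empirical structure,
#' re-optimized structure) as sibling `molecule` elements under a `cml` root.
#'
#' @param x XML text, file path or `xml_document`.
#' @return list of [molecule_record()] objects, named by provenance tag.
#' @export
parse_cml_set <- function(x) {
  doc <- .read_xml_input(x)
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  mols <- if (xml2::xml_name(root) == "molecule") list(root) else
    as.list(xml2::xml_find_all(root, "./molecule"))
  if (!length(mols)) stop("no <molecule> elements found")
  recs <- lapply(mols, .parse_molecule_node)
  names(recs) <- vapply(recs, `[[`, "", "provenance")
  recs
}

.fmt_num <- function(x) sprintf("%.17g", x)

.molecule_xml_node <- function(parent, record) {
  mol_id <- if (!is.na(record$nsc_id)) sprintf("NSC%d", record$nsc_id) else
    record$name
  mol <- xml2::xml_add_child(parent, "molecule", id = mol_id,
                             name = record$name,
                             convention = record$provenance)
  if (!is.na(record$formal_charge_attr)) {
    xml2::xml_set_attr(mol, "formalCharge",
                       as.character(record$formal_charge_attr))
  }
  if (!is.na(record$legacy_charge) || !is.na(record$legacy_basic)) {
    ident <- xml2::xml_add_child(mol, "identifier", version = "0.932Beta",
                                 tautomeric = "0")
    if (!is.na(record$legacy_basic)) {
      xml2::xml_add_child(ident, "basic", record$legacy_basic)
    }
    if (!is.na(record$legacy_charge)) {
      xml2::xml_add_child(ident, "charge",
                          sprintf("%+d", record$legacy_charge))
    }
  }
  meta_fields <- c(cas = record$cas_id, smiles = record$smiles,
                   inchi = record$inchi, inchikey = record$inchikey)
  meta_fields <- meta_fields[!is.na(meta_fields)]
  if (length(meta_fields)) {
    ml <- xml2::xml_add_child(mol, "metadataList")
    for (k in names(meta_fields)) {
      xml2::xml_add_child(ml, "metadata", name = paste0("mc:", k),
                          content = meta_fields[[k]])
    }
  }
  aa <- xml2::xml_add_child(mol, "atomArray")
  at <- record$atoms
  for (i in seq_len(nrow(at))) {
    an <- xml2::xml_add_child(aa, "atom", id = sprintf("a%d", i),
                              elementType = at$element[i])
    if (!is.na(at$x[i])) {
      xml2::xml_set_attr(an, "x3", .fmt_num(at$x[i]))
      xml2::xml_set_attr(an, "y3", .fmt_num(at$y[i]))
      xml2::xml_set_attr(an, "z3", .fmt_num(at$z[i]))
    }
    if (!is.na(at$isotope[i])) {
      xml2::xml_set_attr(an, "isotopeNumber", as.character(at$isotope[i]))
    }
  }
  if (!is.null(record$bonds) && nrow(record$bonds) > 0) {
    ba <- xml2::xml_add_child(mol, "bondArray")
    b <- record$bonds
    for (i in seq_len(nrow(b))) {
      xml2::xml_add_child(ba, "bond",
                          atomRefs2 = sprintf("a%d a%d", b$i[i], b$j[i]),
                          order = as.character(b$order[i]))
    }
  }
  mol
}

#' Write a molecule record (or a provenance set) as CML
#'
#' The `"legacy"` profile emits one `molecule` document reproducing whichever
#' charge dialects the record carries, so that [parse_cml()] round-trips all
#' fields exactly. The `"conflated"` profile takes a list of records of the
#' same molecule and embeds their provenance-tagged geometry blocks in a
#' single `cml` document; every atom then needs coordinates.
#'
#' @param record a [molecule_record()], or for `profile = "conflated"` a list
#'   of up to three records.
#' @param profile `"legacy"` or `"conflated"`.
#' @return XML text (single string).
#' @export
write_cml <- function(record, profile = c("legacy", "conflated")) {
  profile <- match.arg(profile)
  if (profile == "legacy") {
    if (!inherits(record, "molecule_record")) stop("record expected")
    if (nrow(record$atoms) == 0) stop("record has no atoms")
    doc <- xml2::xml_new_root("dummy")
    node <- .molecule_xml_node(doc, record)
    return(.serialize_node(node))
  }
  records <- if (inherits(record, "molecule_record")) list(record) else record
  if (!length(records)) stop("no records to conflate")
  for (r in records) {
    if (nrow(r$atoms) == 0) stop("record '", r$name, "' has no atoms")
    if (!has_coordinates(r$atoms)) {
      miss <- which(is.na(r$atoms$x))
      stop("conflated profile requires coordinates for all atoms; record '",
           r$name, "' lacks them for atom(s) ",
           paste(miss, collapse = ", "))
    }
  }
  doc <- xml2::xml_new_root("cml")
  for (r in records) .molecule_xml_node(doc, r)
  .serialize_node(xml2::xml_root(doc))
}

.serialize_node <- function(node) {
  txt <- as.character(node)
  sub("^<\\?xml[^>]*\\?>\\s*", "", txt)
}

# ---- schema-profile validation ------------------------------------------

#' Describe a CML validation profile
#'
#' The validator targets a documented subset profile of CML 2.4 covering the
#' `molecule`, `atomArray`, `bondArray` and `identifier` elements this corpus
#' uses; full CML is out of scope.
#'
#' @param name profile name; only `"cml24-subset"` is defined.
#' @param require_bonds logical; when TRUE a missing `bondArray` is a
#'   violation (legacy computed-annotation documents historically omitted
#'   bond connection terms and failed schema validation for it).
#' @return schema descriptor list.
#' @export
cml_schema <- function(name = "cml24-subset", require_bonds = FALSE) {
  if (!identical(name, "cml24-subset")) {
    stop("unknown CML schema profile: ", name)
  }
  structure(list(name = name, require_bonds = require_bonds),
            class = "cml_schema")
}

#' Validate a CML document against a subset profile
#'
#' @param x XML text, file path or `xml_document`. Non-XML input is a parse
#'   error, not a violation list.
#' @param schema a [cml_schema()] descriptor.
#' @return data.frame with columns `location` (XPath-like) and `message`;
#'   zero rows iff the document conforms to the profile.
#' @export
validate_cml <- function(x, schema = cml_schema()) {
  if (!inherits(schema, "cml_schema")) stop("schema descriptor required")
  doc <- .read_xml_input(x)   # malformed XML stops here with a parse error
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  violations <- list()
  bad <- function(location, message) {
    violations[[length(violations) + 1L]] <<-
      data.frame(location = location, message = message,
                 stringsAsFactors = FALSE)
  }

  mols <- if (xml2::xml_name(root) == "molecule") {
    list(root)
  } else if (xml2::xml_name(root) == "cml") {
    as.list(xml2::xml_find_all(root, "./molecule"))
  } else {
    bad("/", sprintf("root element <%s> is not molecule or cml",
                     xml2::xml_name(root)))
    list()
  }
  if (xml2::xml_name(root) == "cml" && !length(mols)) {
    bad("/cml", "no molecule elements")
  }

  for (k in seq_along(mols)) {
    mol <- mols[[k]]
    loc <- if (xml2::xml_name(root) == "cml")
      sprintf("/cml/molecule[%d]", k) else "/molecule"
    fc <- xml2::xml_attr(mol, "formalCharge")
    if (!is.na(fc) && !grepl("^[+-]?[0-9]+$", fc)) {
      bad(loc, sprintf("formalCharge '%s' is not an integer", fc))
    }
    atom_nodes <- xml2::xml_find_all(mol, "./atomArray/atom")
    if (!length(atom_nodes)) {
      bad(paste0(loc, "/atomArray"), "missing atomArray or it has no atoms")
    }
    ids <- xml2::xml_attr(atom_nodes, "id")
    for (i in seq_along(atom_nodes)) {
      aloc <- sprintf("%s/atomArray/atom[%d]", loc, i)
      el <- xml2::xml_attr(atom_nodes[[i]], "elementType")
      if (is.na(el)) {
        bad(aloc, "atom lacks elementType")
      } else if (!is_element(el)) {
        bad(aloc, sprintf("unknown element symbol '%s'", el))
      }
      coords <- xml2::xml_attr(atom_nodes[[i]], c("x3", "y3", "z3"))
      n_set <- sum(!is.na(coords))
      if (n_set > 0 && n_set < 3) {
        bad(aloc, "incomplete coordinate triple (x3/y3/z3)")
      }
    }
    bond_array <- xml2::xml_find_first(mol, "./bondArray")
    if (inherits(bond_array, "xml_missing")) {
      if (schema$require_bonds) {
        bad(paste0(loc, "/bondArray"),
            "profile requires a bondArray element and none is present")
      }
    } else {
      bnodes <- xml2::xml_find_all(bond_array, "./bond")
      for (i in seq_along(bnodes)) {
        bloc <- sprintf("%s/bondArray/bond[%d]", loc, i)
        refs <- xml2::xml_attr(bnodes[[i]], "atomRefs2")
        if (is.na(refs)) { bad(bloc, "bond lacks atomRefs2"); next }
        parts <- strsplit(refs, "\\s+")[[1]]
        if (length(parts) != 2) {
          bad(bloc, "atomRefs2 must reference exactly two atoms")
        } else if (!all(parts %in% ids)) {
          bad(bloc, sprintf("atomRefs2 '%s' references undeclared atom id",
                            refs))
        }
      }
    }
    ident <- xml2::xml_find_first(mol, "./identifier/charge")
    if (!inherits(ident, "xml_missing")) {
      ctxt <- trimws(xml2::xml_text(ident))
      if (!grepl("^[+-]?[0-9]+$", ctxt)) {
        bad(paste0(loc, "/identifier/charge"),
            sprintf("charge '%s' is not an integer", ctxt))
      }
    }
  }
  if (!length(violations)) {
    return(data.frame(location = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, violations)
}

# ---- corpus operations ---------------------------------------------------

#' Corpus bookkeeping record
#'
#' @param total_read,unique_kept,duplicates_removed,excluded_no_annotation
#'   non-negative counts; the constructor enforces
#'   `total_read == unique_kept + duplicates_removed + excluded_no_annotation`.
#' @return object of class `corpus_report`.
#' @export
corpus_report <- function(total_read, unique_kept, duplicates_removed,
                          excluded_no_annotation = 0L) {
  r <- list(total_read = as.integer(total_read),
            unique_kept = as.integer(unique_kept),
            duplicates_removed = as.integer(duplicates_removed),
            excluded_no_annotation = as.integer(excluded_no_annotation))
  if (r$total_read !=
      r$unique_kept + r$duplicates_removed + r$excluded_no_annotation) {
    stop("corpus report arithmetic does not balance")
  }
  structure(r, class = "corpus_report")
}

#' @export
print.corpus_report <- function(x, ...) {
  cat(sprintf(
    "<corpus_report read=%d unique=%d duplicates=%d excluded=%d>\n",
    x$total_read, x$unique_kept, x$duplicates_removed,
    x$excluded_no_annotation))
  invisible(x)
}

#' Deduplicate a corpus by accession number
#'
#' Keeps the first record encountered for each NSC accession (deterministic,
#' order-stable) and reports counts.
#'
#' @param records list of [molecule_record()] objects, each with an `nsc_id`.
#' @return list with `records` (unique, input order) and `report`
#'   (a [corpus_report()]).
#' @export
deduplicate <- function(records) {
  ids <- vapply(records, function(r) {
    if (!inherits(r, "molecule_record")) stop("non-record element in input")
    r$nsc_id
  }, 0L)
  if (anyNA(ids)) {
    stop("record(s) at position(s) ", paste(which(is.na(ids)), collapse = ", "),
         " lack an nsc_id")
  }
  keep <- !duplicated(ids)
  list(records = records[keep],
       report = corpus_report(length(records), sum(keep), sum(!keep)))
}

#' Exclude entries lacking a computed annotation
#'
#' @param pairs list of pairs, each a list with elements `nci` (the original
#'   database record) and `computed` (the computed-annotation record, or NULL
#'   when no calculation was reported).
#' @return list with `kept` (pairs unchanged) and `excluded` (count).
#' @export
filter_annotated <- function(pairs) {
  present <- vapply(pairs, function(p) !is.null(p$computed), TRUE)
  list(kept = pairs[present], excluded = sum(!present))
}

#' Retain the largest connected component of a record
#'
#' Disconnected components in legacy database entries are predominantly
#' counter-ions; only the larger component is retained. Ties are broken
#' deterministically towards the component containing the lowest original
#' atom index, and flagged. The retained record keeps the declared
#' whole-record charge fields as given; when a component is removed and
#' neither charge dialect declares a value, the result is flagged as
#' charge-suspect (a split salt with no declared fragment charge is
#' chemically implausible).
#'
#' @param record a [molecule_record()].
#' @param graph a `connectivity_graph` over the record's atoms (see
#'   [perceive_connectivity()]).
#' @return list with `record` (largest component, atom order preserved),
#'   `removed` (character vector of formula strings, one per removed
#'   component), `tie` (logical) and `charge_suspect` (logical).
#' @export
select_largest_component <- function(record, graph) {
  stopifnot(inherits(record, "molecule_record"),
            inherits(graph, "connectivity_graph"))
  n <- nrow(record$atoms)
  if (n == 0 || graph$n_atoms == 0) stop("empty connectivity graph")
  if (graph$n_atoms != n) stop("graph does not cover the record's atoms")
  comp <- connected_components(graph)
  sizes <- tabulate(comp, max(comp))
  best_size <- max(sizes)
  cand <- which(sizes == best_size)
  tie <- length(cand) > 1
  # lowest first-atom-index tie break
  first_idx <- vapply(cand, function(cc) min(which(comp == cc)), 0L)
  chosen <- cand[which.min(first_idx)]
  keep <- which(comp == chosen)          # ascending: preserves atom order
  if (length(keep) == n) {
    return(list(record = record, removed = character(0), tie = tie,
                charge_suspect = FALSE))
  }
  removed <- vapply(setdiff(sort(unique(comp)), chosen), function(cc) {
    format_formula(molecular_formula(record$atoms[comp == cc, , drop = FALSE]))
  }, "")
  new_rec <- record
  new_rec$atoms <- record$atoms[keep, , drop = FALSE]
  rownames(new_rec$atoms) <- NULL
  class(new_rec$atoms) <- c("molcurate_atoms", "data.frame")
  if (!is.null(record$bonds) && nrow(record$bonds)) {
    remap <- match(seq_len(n), keep)
    b <- record$bonds
    inside <- !is.na(remap[b$i]) & !is.na(remap[b$j])
    b <- b[inside, , drop = FALSE]
    b$i <- remap[b$i]; b$j <- remap[b$j]
    rownames(b) <- NULL
    new_rec$bonds <- b
  }
  suspect <- is.na(record$formal_charge_attr) && is.na(record$legacy_charge)
  list(record = new_rec, removed = removed, tie = tie,
       charge_suspect = suspect)
}

# ---- XYZ (XMol dialect) --------------------------------------------------

#' Read an XMol XYZ file or text
#'
#' @param x path or character text (atom count line, comment line, then
#'   `element x y z` rows, Angstrom).
#' @return list with `atoms` and `comment`.
#' @export
read_xyz <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    readLines(x) else strsplit(paste(x, collapse = "\n"), "\n")[[1]]
  if (length(lines) < 2) stop("truncated XYZ input")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ first line must be the atom count")
  if (length(lines) < 2 + n) stop("XYZ declares ", n, " atoms but has fewer rows")
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  el <- vapply(rows, `[[`, "", 1)
  coord <- function(k) vapply(rows, function(r) as.numeric(r[[k]]), 0)
  list(atoms = atoms(el, coord(2), coord(3), coord(4)),
       comment = lines[2])
}

#' Write atoms as XMol XYZ text
#'
#' @param atoms atom table with coordinates.
#' @param comment second-line comment.
#' @param digits coordinate decimals (default 6).
#' @return XYZ text.
#' @export
write_xyz <- function(atoms, comment = "", digits = 6) {
  if (nrow(atoms) == 0) stop("no atoms to write")
  if (!has_coordinates(atoms)) stop("atoms lack coordinates")
  fmt <- sprintf("%%-3s %%.%df %%.%df %%.%df", digits, digits, digits)
  paste(c(nrow(atoms), comment,
          sprintf(fmt, atoms$element, atoms$x, atoms$y, atoms$z)),
        collapse = "\n")
}
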
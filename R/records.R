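# Core record model. A molecule record holds one structure version (atoms,
# optional bonds, both charge dialects, identifiers, provenance tag). The two
# charge declarations are kept verbatim and independently: NA means the
# dialect was ABSENT from the source document, which is deliberately distinct
# from a declared 0 -- the implicit-default failure mode this tool exists to
# guard against.

.provenance_tags <- c("NCI", "PM5", "PM7")

#' Construct an atom table
#'
#' Atoms are modeled as a data.frame with columns `element`, `x`, `y`, `z`
#' (Cartesian Angstrom; NA when the source record carries no coordinates) and
#' `isotope` (mass number; NA when unlabeled).
#'
#' @param element character vector of element symbols.
#' @param x,y,z numeric coordinate vectors (Angstrom), or NA.
#' @param isotope optional integer vector of mass numbers.
#' @return data.frame of class `molcurate_atoms`.
#' @export
atoms <- function(element, x = NA_real_, y = NA_real_, z = NA_real_,
                  isotope = NA_integer_) {
  bad <- unique(element[!is_element(element)])
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  n <- length(element)
  rec <- function(v) rep_len(v, n)
  df <- data.frame(
    element = as.character(element),
    x = rec(as.numeric(x)), y = rec(as.numeric(y)), z = rec(as.numeric(z)),
    isotope = rec(as.integer(isotope)),
    stringsAsFactors = FALSE
  )
  has_pos <- !(is.na(df$x) & is.na(df$y) & is.na(df$z))
  partial <- has_pos & (is.na(df$x) | is.na(df$y) | is.na(df$z) |
                          !is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
  if (any(partial)) {
    stop("atom(s) with incomplete or non-finite coordinates at position(s): ",
         paste(which(partial), collapse = ", "))
  }
  class(df) <- c("molcurate_atoms", "data.frame")
  df
}

has_coordinates <- function(atoms) {
  nrow(atoms) > 0 && !anyNA(atoms$x) && !anyNA(atoms$y) && !anyNA(atoms$z)
}

#' Construct a molecule record
#'
#' One structure version of one molecule: ordered atoms, optional bond list,
#' both charge-declaration dialects captured independently (NA = absent, a
#' state distinct from 0), identifiers and a provenance tag.
#'
#' @param name entry name.
#' @param atoms atom table from [atoms()].
#' @param bonds optional data.frame with integer columns `i`, `j` (1-based
#'   atom indices) and `order`.
#' @param nsc_id NCI accession number (integer) or NA.
#' @param cas_id CAS registry string or NA.
#' @param formal_charge_attr integer charge from the `formalCharge`
#'   attribute dialect, or NA when absent.
#' @param legacy_charge integer charge from the legacy `identifier/charge`
#'   child dialect, or NA when absent.
#' @param legacy_basic legacy identifier string (early-InChI form) or NA.
#' @param provenance one of `"NCI"`, `"PM5"`, `"PM7"`.
#' @param smiles,inchi,inchikey optional identifier strings.
#' @return object of class `molecule_record`.
#' @export
molecule_record <- function(name, atoms, bonds = NULL,
                            nsc_id = NA_integer_, cas_id = NA_character_,
                            formal_charge_attr = NA_integer_,
                            legacy_charge = NA_integer_,
                            legacy_basic = NA_character_,
                            provenance = "NCI",
                            smiles = NA_character_, inchi = NA_character_,
                            inchikey = NA_character_) {
  stopifnot(inherits(atoms, "molcurate_atoms"))
  provenance <- match.arg(provenance, .provenance_tags)
  if (!is.null(bonds) && nrow(bonds) > 0) {
    stopifnot(all(c("i", "j", "order") %in% names(bonds)))
    n <- nrow(atoms)
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)) {
      stop("bond references atom index out of range (1..", n, ")")
    }
  }
  for (chg in list(formal_charge_attr, legacy_charge)) {
    if (!is.na(chg) && chg != as.integer(chg)) stop("charge must be integral")
  }
  structure(list(
    name = as.character(name), atoms = atoms, bonds = bonds,
    nsc_id = as.integer(nsc_id), cas_id = as.character(cas_id),
    formal_charge_attr = as.integer(formal_charge_attr),
    legacy_charge = as.integer(legacy_charge),
    legacy_basic = as.character(legacy_basic),
    provenance = provenance,
    smiles = as.character(smiles), inchi = as.character(inchi),
    inchikey = as.character(inchikey)
  ), class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  chg <- function(v) if (is.na(v)) "ABSENT" else sprintf("%+d", v)
  cat(sprintf("<molecule_record %s [%s] %d atoms%s>\n",
              x$name, x$provenance, nrow(x$atoms),
              if (!is.na(x$nsc_id)) sprintf(" NSC%d", x$nsc_id) else ""))
  cat(sprintf("  formalCharge attr: %s; legacy identifier charge: %s\n",
              chg(x$formal_charge_attr), chg(x$legacy_charge)))
  invisible(x)
}

#' Molecular formula of an atom table
#'
#' @param atoms atom table.
#' @return named integer vector, element symbol -> count, in Hill order
#'   (C first, then H, then alphabetical).
#' @export
molecular_formula <- function(atoms) {
  counts <- table(atoms$element)
  els <- names(counts)
  ord <- order(match(els, c("C", "H"), nomatch = 3L), els)
  stats::setNames(as.integer(counts[ord]), els[ord])
}

#' Render a formula map as a Hill-order string
#' @param formula named integer vector as from [molecular_formula()].
#' @return string such as `"C2H3O2"`.
#' @export
format_formula <- function(formula) {
  paste0(names(formula), ifelse(formula > 1L, formula, ""), collapse = "")
}

#' Parse a molecular formula string
#'
#' Accepts plain Hill-style formulas such as `"C13H21N2O"` (the form used in
#' legacy identifier strings).
#'
#' @param x formula string.
#' @return named integer vector, element -> count.
#' @export
parse_formula <- function(x) {
  x <- trimws(x)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  pieces <- regmatches(x, list(m))[[1]]
  if (!length(pieces) || sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse formula string: ", x)
  }
  els <- sub("[0-9]*$", "", pieces)
  cnt <- as.integer(sub("^[A-Za-z]+", "", paste0(pieces, "")))
  cnt[is.na(cnt)] <- 1L
  bad <- unique(els[!is_element(els)])
  if (length(bad)) stop("unknown element symbol(s) in formula: ",
                        paste(bad, collapse = ", "))
  out <- tapply(cnt, els, sum)
  els_u <- names(out)
  ord <- order(match(els_u, c("C", "H"), nomatch = 3L), els_u)
  stats::setNames(as.integer(out[ord]), els_u[ord])
}
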
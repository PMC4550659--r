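# Charge and spin semantics. The failure mode this module guards against is
# implicit defaulting: a quantum-chemistry code treats an undeclared charge
# as zero and silently derives the spin multiplicity from the resulting
# electron parity. Here every charge is reconciled explicitly (with its
# source and plausibility recorded) and the spin state is computed from the
# electron count so it can be written out as a checksum keyword.

#' Reconcile the two charge-declaration dialects of a record
#'
#' Precedence is `formalCharge` attribute over legacy `identifier/charge`
#' over default zero. When both dialects are present and disagree, the value
#' is taken from the attribute and the conflict is flagged (curation
#' proceeds; it does not abort). Charges with magnitude above 3 are flagged
#' implausible: manual inspection of such species in legacy corpora shows
#' them to be curation errors (misread metal centres and the like).
#'
#' @param record a [molecule_record()].
#' @param plausibility_limit flag `|value|` above this as implausible
#'   (default 3).
#' @return object of class `charge_assignment`: list with `value` (integer),
#'   `source` (`"FORMAL_ATTR"`, `"LEGACY_IDENTIFIER"` or `"DEFAULT_ZERO"`),
#'   `conflict` and `plausible` logicals.
#' @export
reconcile_charge <- function(record, plausibility_limit = 3L) {
  fa <- record$formal_charge_attr
  lc <- record$legacy_charge
  if (!is.na(fa)) {
    value <- fa
    source <- "FORMAL_ATTR"
    conflict <- !is.na(lc) && lc != fa
  } else if (!is.na(lc)) {
    value <- lc
    source <- "LEGACY_IDENTIFIER"
    conflict <- FALSE
  } else {
    value <- 0L
    source <- "DEFAULT_ZERO"
    conflict <- FALSE
  }
  structure(list(value = as.integer(value), source = source,
                 conflict = conflict,
                 plausible = abs(value) <= plausibility_limit),
            class = "charge_assignment")
}

#' @export
print.charge_assignment <- function(x, ...) {
  cat(sprintf("<charge_assignment %+d from %s%s%s>\n", x$value, x$source,
              if (x$conflict) " CONFLICT" else "",
              if (!x$plausible) " IMPLAUSIBLE" else ""))
  invisible(x)
}

#' Total electron count of a species
#'
#' Sum of atomic numbers over the formula, minus the net charge.
#'
#' @param formula named integer vector (element -> count) as from
#'   [molecular_formula()] or [parse_formula()], or a formula string.
#' @param charge integer net charge (elementary charge units).
#' @return non-negative integer; an impossible (negative) count is an error.
#' @export
electron_count <- function(formula, charge = 0L) {
  if (is.character(formula)) formula <- parse_formula(formula)
  n <- sum(atomic_number(names(formula)) * as.integer(formula)) -
    as.integer(charge)
  if (n < 0) stop("impossible species: electron count would be ", n)
  as.integer(n)
}

#' Spin state from an electron count
#'
#' Even electron counts give a singlet, odd counts a doublet; higher
#' multiplicities are outside this tool's scope.
#'
#' @param electron_count non-negative integer.
#' @return object of class `spin_state`: list with `electron_count` and
#'   `multiplicity` (`"SINGLET"` or `"DOUBLET"`).
#' @export
spin_state <- function(electron_count) {
  electron_count <- as.integer(electron_count)
  stopifnot(electron_count >= 0)
  structure(list(electron_count = electron_count,
                 multiplicity = if (electron_count %% 2L == 0L)
                   "SINGLET" else "DOUBLET"),
            class = "spin_state")
}

#' Check a declared multiplicity against the computed one
#'
#' The declared spin keyword acts as a checksum: it is consistent iff it
#' equals the multiplicity derived from the electron count at the reconciled
#' charge. Inconsistency is a reported value, not an exception.
#'
#' @param declared `"SINGLET"` or `"DOUBLET"`.
#' @param charge a [reconcile_charge()] assignment (or bare integer).
#' @param formula element -> count map or formula string.
#' @return list with `ok` (logical), `declared`, `computed`, `charge_used`
#'   and `electron_count`.
#' @export
validate_spin_consistency <- function(declared, charge, formula) {
  declared <- match.arg(declared, c("SINGLET", "DOUBLET"))
  value <- if (inherits(charge, "charge_assignment")) charge$value else
    as.integer(charge)
  ss <- spin_state(electron_count(formula, value))
  list(ok = identical(declared, ss$multiplicity),
       declared = declared, computed = ss$multiplicity,
       charge_used = value, electron_count = ss$electron_count)
}

#' Formal-charge histogram over a set of assignments
#'
#' @param assignments list of `charge_assignment` objects.
#' @return list with `histogram` (named count vector, names are signed
#'   charges in ascending order), `conflicts` and `implausible` (counts).
#' @export
charge_histogram <- function(assignments) {
  vals <- vapply(assignments, `[[`, 0L, "value")
  tab <- table(factor(vals, levels = sort(unique(vals))))
  list(histogram = stats::setNames(as.integer(tab),
                                   sprintf("%+d", as.integer(names(tab)))),
       conflicts = sum(vapply(assignments, `[[`, TRUE, "conflict")),
       implausible = sum(!vapply(assignments, `[[`, TRUE, "plausible")))
}
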
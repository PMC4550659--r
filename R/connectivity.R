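# Distance-heuristic bond perception. Two atoms are bonded when their
# separation is at most the sum of their single-bond covalent radii plus a
# tolerance; pairs closer than a lower floor are treated as corrupt
# geometry, not as bonds. Both thresholds are explicit configuration since
# connection distances are not formally standardized.

#' Perceive connectivity from Cartesian coordinates
#'
#' Edge (i,j) is present iff
#' `lower_floor < dist(i,j) <= radius(el_i) + radius(el_j) + tolerance`.
#' A pair closer than `lower_floor` raises a geometry error.
#'
#' @param atoms atom table with coordinates.
#' @param radii named numeric vector, element -> covalent radius (Angstrom);
#'   defaults to the bundled table ([covalent_radii()]).
#' @param tolerance slack added to the radius sum, Angstrom (default 0.40).
#' @param lower_floor distance below which a pair is reported as corrupt
#'   coordinates (default 0.40 Angstrom).
#' @return object of class `connectivity_graph`: list with `n_atoms` and
#'   `edges` (two-column integer matrix, i < j).
#' @export
perceive_connectivity <- function(atoms, radii = covalent_radii(),
                                  tolerance = 0.40, lower_floor = 0.40) {
  stopifnot(tolerance >= 0)
  if (!has_coordinates(atoms)) stop("atoms lack coordinates")
  missing_r <- setdiff(unique(atoms$element), names(radii))
  if (length(missing_r)) {
    stop("no covalent radius for element(s): ",
         paste(missing_r, collapse = ", "))
  }
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  r <- radii[atoms$element]
  thr <- outer(r, r, `+`) + tolerance
  too_close <- d < lower_floor & upper.tri(d)
  if (any(too_close)) {
    w <- which(too_close, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "atoms %d and %d are %.3f Angstrom apart (< %.2f floor): corrupt geometry",
      w[1], w[2], d[w[1], w[2]], lower_floor))
  }
  hit <- d <= thr & upper.tri(d)
  idx <- which(hit, arr.ind = TRUE)
  edges <- cbind(i = as.integer(pmin(idx[, 1], idx[, 2])),
                 j = as.integer(pmax(idx[, 1], idx[, 2])))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(list(n_atoms = n, edges = edges), class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph %d atoms, %d edges>\n",
              x$n_atoms, nrow(x$edges)))
  invisible(x)
}

#' Connected-component labels of a connectivity graph
#'
#' @param graph a `connectivity_graph`.
#' @return integer vector of component labels (1-based, in order of first
#'   appearance) of length `n_atoms`.
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "connectivity_graph"))
  g <- igraph::make_empty_graph(n = graph$n_atoms, directed = FALSE)
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(g, t(graph$edges))
  }
  memb <- igraph::components(g)$membership
  # relabel so components are numbered by first appearance
  as.integer(match(memb, unique(memb)))
}

#' Normalize a record to canonical Cartesian (XYZ) form
#'
#' Emits only element symbols and coordinates: any bond or connection data in
#' the source record is deliberately discarded, so that downstream InChI
#' generation is normalized against a single connection algorithm. Atom order
#' is canonicalized (element alphabetical, then original index) for
#' deterministic diffs; the InChI canonicalization makes this cosmetic.
#'
#' @param record a [molecule_record()] with coordinates for all atoms.
#' @param digits coordinate decimals (default 6).
#' @return XYZ text.
#' @export
to_canonical_xyz <- function(record, digits = 6) {
  at <- record$atoms
  if (nrow(at) == 0) stop("record has no atoms")
  if (!has_coordinates(at)) {
    stop("record '", record$name, "' lacks coordinates for atom(s) ",
         paste(which(is.na(at$x)), collapse = ", "))
  }
  ord <- order(at$element, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  class(at) <- c("molcurate_atoms", "data.frame")
  write_xyz(at, comment = record$name, digits = digits)
}
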
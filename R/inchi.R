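# InChI generation is delegated to the reference algorithm through the
# OpenBabel binding (`obabel` executable); re-implementing the
# canonicalization is explicitly out of scope. Layer dissection is done
# here: an InChI string is split into its delimiter-prefixed component
# layers so that mismatches between structure versions can be attributed to
# formula, connectivity, hydrogen, charge, stereo or isotope differences.

.obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    stop("the OpenBabel executable 'obabel' is required for InChI ",
         "generation but was not found on the PATH")
  }
  p
}

.run_obabel <- function(infile, out_format, value_pattern) {
  out <- suppressWarnings(system2(
    .obabel_path(), c("-ixyz", shQuote(infile), paste0("-o", out_format)),
    stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("obabel failed (exit ", status, "): ",
         paste(out, collapse = " / "))
  }
  out[grepl(value_pattern, out)]
}

#' Generate an InChI and InChIKey from XYZ coordinates
#'
#' Connectivity is derived by the reference binding from the Cartesian
#' coordinates alone (any upstream bond data having been discarded by
#' [to_canonical_xyz()]), and the standard InChI plus its hashed key are
#' returned. Deterministic for identical input.
#'
#' @param xyz XYZ text (or path to an XYZ file).
#' @return list with `inchi` and `inchikey` strings.
#' @export
generate_inchi <- function(xyz) {
  res <- generate_inchi_batch(list(xyz))
  list(inchi = res$inchi[[1]], inchikey = res$inchikey[[1]])
}

#' Generate InChIs for many XYZ blocks in one reference-binding call
#'
#' Concatenates the XYZ blocks into a single multi-molecule stream and runs
#' the binding once per output form, which is substantially faster than one
#' subprocess per structure for corpus-scale runs.
#'
#' @param xyzs list of XYZ texts (or paths).
#' @return data.frame with columns `inchi` and `inchikey`, one row per input
#'   in input order.
#' @export
generate_inchi_batch <- function(xyzs) {
  if (!length(xyzs)) {
    return(data.frame(inchi = character(0), inchikey = character(0),
                      stringsAsFactors = FALSE))
  }
  texts <- vapply(xyzs, function(x) {
    if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
      paste(readLines(x), collapse = "\n") else paste(x, collapse = "\n")
  }, "")
  tmp <- tempfile(fileext = ".xyz")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(paste(sub("\n+$", "", texts), collapse = "\n"), tmp)
  inchis <- .run_obabel(tmp, "inchi", "^InChI=")
  keys <- .run_obabel(tmp, "inchikey", "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
  if (length(inchis) != length(texts) || length(keys) != length(texts)) {
    stop("reference InChI implementation returned ", length(inchis),
         " identifiers for ", length(texts),
         " structures; its diagnostics indicate failed conversions")
  }
  data.frame(inchi = inchis, inchikey = keys, stringsAsFactors = FALSE)
}

# ---- layer dissection ----------------------------------------------------

.layer_fields <- c("formula", "connectivity", "hydrogen", "charge",
                   "protonation", "double_bond", "tetrahedral", "isotope")

#' Dissect an InChI string into its component layers
#'
#' Splits on the `/` delimiter and assigns each prefixed segment to its
#' layer: formula (no prefix), `c` connectivity, `h` hydrogen, `q` charge,
#' `p` protonation, `b` double-bond stereo, `t` tetrahedral stereo (with its
#' `m`/`s` sublayers), and `i` isotope (with everything after it, since
#' isotopic sublayers re-use the `h`/`b`/`t`/`m`/`s` prefixes). Absent
#' layers are recorded as NA. [serialize_inchi()] inverts this exactly.
#'
#' @param inchi an InChI string beginning with a recognized version prefix.
#' @return object of class `inchi_layers`.
#' @export
parse_inchi_layers <- function(inchi) {
  stopifnot(length(inchi) == 1)
  m <- regmatches(inchi, regexec("^InChI=([0-9]+[A-Za-z]*)/(.*)$", inchi))[[1]]
  if (!length(m)) stop("unrecognized InChI version prefix in: ", inchi)
  version <- m[2]
  body <- m[3]
  toks <- strsplit(body, "/", fixed = TRUE)[[1]]
  out <- stats::setNames(as.list(rep(NA_character_, length(.layer_fields))),
                         .layer_fields)
  out$version_prefix <- version
  out$formula <- toks[1]
  out$stereo_m <- NA_character_
  out$stereo_s <- NA_character_
  i <- 2L
  seen_i <- FALSE
  while (i <= length(toks)) {
    tok <- toks[i]
    pre <- substr(tok, 1, 1)
    val <- substr(tok, 2, nchar(tok))
    if (seen_i) {
      out$isotope <- paste(c(out$isotope[!is.na(out$isotope)], tok),
                           collapse = "/")
      # isotope group already holds its own prefixes
      i <- i + 1L
      next
    }
    switch(pre,
      c = { out$connectivity <- val },
      h = { out$hydrogen <- val },
      q = { out$charge <- val },
      p = { out$protonation <- val },
      b = { out$double_bond <- val },
      t = { out$tetrahedral <- val },
      m = { out$stereo_m <- val },
      s = { out$stereo_s <- val },
      i = { out$isotope <- val; seen_i <- TRUE },
      stop("unrecognized InChI layer prefix '", pre, "' in: ", inchi)
    )
    i <- i + 1L
  }
  structure(out, class = "inchi_layers")
}

#' Reassemble an InChI string from its layers
#'
#' Exact inverse of [parse_inchi_layers()] on its image.
#'
#' @param layers an `inchi_layers` object.
#' @return InChI string.
#' @export
serialize_inchi <- function(layers) {
  stopifnot(inherits(layers, "inchi_layers"))
  seg <- function(prefix, val) {
    if (is.na(val)) character(0) else paste0(prefix, val)
  }
  paste0("InChI=", layers$version_prefix, "/",
         paste(c(layers$formula,
                 seg("c", layers$connectivity),
                 seg("h", layers$hydrogen),
                 seg("q", layers$charge),
                 seg("p", layers$protonation),
                 seg("b", layers$double_bond),
                 seg("t", layers$tetrahedral),
                 seg("m", layers$stereo_m),
                 seg("s", layers$stereo_s),
                 seg("i", layers$isotope)),
               collapse = "/"))
}

#' @export
print.inchi_layers <- function(x, ...) {
  cat("<inchi_layers>", serialize_inchi(x), "\n")
  for (f in .layer_fields) {
    if (!is.na(x[[f]])) cat(sprintf("  %-11s %s\n", f, x[[f]]))
  }
  invisible(x)
}
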
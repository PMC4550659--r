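# Fully explicit semi-empirical input decks. Two policies are enforced by
# construction and never optional: CHARGE=<n> is always written (including
# CHARGE=0), and exactly one spin keyword (SINGLET or DOUBLET) derived from
# the electron count is always written so the program's own parity check
# acts as a checksum. The historical failure this prevents: a converter that
# emits only a placeholder keyword line, leaving the charge to default to
# zero implicitly.

MOPAC_PLACEHOLDER <- "PUT KEYWORDS HERE"

#' Build a semi-empirical input deck
#'
#' @param record a [molecule_record()] with coordinates for all atoms.
#' @param charge a [reconcile_charge()] assignment for the record.
#' @param method method keyword token (default `"PM7"`).
#' @param coords `"internal"` (default) for a Z-matrix geometry block or
#'   `"cartesian"`.
#' @return object of class `mopac_input`: list with `keywords` (ordered
#'   token vector), `title` (two comment lines) and `geometry` (a `zmatrix`
#'   or an atom table). An implausible charge proceeds with a warning
#'   attached (`attr(,"warning")`); missing coordinates are an error.
#' @export
build_mopac_input <- function(record, charge = reconcile_charge(record),
                              method = "PM7",
                              coords = c("internal", "cartesian")) {
  coords <- match.arg(coords)
  if (!has_coordinates(record$atoms)) {
    miss <- which(is.na(record$atoms$x))
    stop("record '", record$name, "' lacks coordinates for atom(s) ",
         paste(miss, collapse = ", "))
  }
  warn <- NULL
  if (!charge$plausible) {
    warn <- sprintf("implausible charge %+d (|q| > 3); proceeding",
                    charge$value)
    warning(warn, call. = FALSE)
  }
  ss <- spin_state(electron_count(molecular_formula(record$atoms),
                                  charge$value))
  keywords <- c(method,
                sprintf("CHARGE=%d", charge$value),
                ss$multiplicity)
  geometry <- if (coords == "internal") {
    cartesian_to_internal(record$atoms)
  } else {
    record$atoms
  }
  out <- structure(list(keywords = keywords,
                        title = c(record$name,
                                  sprintf("provenance: %s", record$provenance)),
                        geometry = geometry),
                   class = "mopac_input")
  if (!is.null(warn)) attr(out, "warning") <- warn
  out
}

#' Render an input deck as text
#'
#' Keyword line, two title/comment lines, then the geometry block.
#' Distances are written with 4 decimals and angles with 2, matching the
#' round-trip tolerances (1e-4 Angstrom, 1e-2 degree).
#'
#' @param input a `mopac_input`.
#' @return deck text (single string).
#' @export
format_mopac_input <- function(input) {
  stopifnot(inherits(input, "mopac_input"))
  geom <- input$geometry
  rows <- if (inherits(geom, "zmatrix")) {
    vapply(seq_len(nrow(geom)), function(k) {
      sprintf("%-3s %9.4f 1 %9.2f 1 %9.2f 1 %4d %4d %4d",
              geom$element[k],
              if (is.na(geom$distance[k])) 0 else geom$distance[k],
              if (is.na(geom$angle[k])) 0 else geom$angle[k],
              if (is.na(geom$dihedral[k])) 0 else geom$dihedral[k],
              if (is.na(geom$r1[k])) 0L else geom$r1[k],
              if (is.na(geom$r2[k])) 0L else geom$r2[k],
              if (is.na(geom$r3[k])) 0L else geom$r3[k])
    }, "")
  } else {
    sprintf("%-3s %12.4f 1 %12.4f 1 %12.4f 1",
            geom$element, geom$x, geom$y, geom$z)
  }
  paste(c(paste(input$keywords, collapse = " "),
          input$title[1], input$title[2],
          rows, ""), collapse = "\n")
}

#' Parse an input deck back into its components
#'
#' Inverse of [format_mopac_input()]; used to verify that generated decks
#' are self-describing.
#'
#' @param text deck text.
#' @return a `mopac_input`.
#' @export
parse_mopac_input <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  if (length(lines) < 4) stop("truncated input deck")
  keywords <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  title <- lines[2:3]
  geom_lines <- lines[-(1:3)]
  geom_lines <- geom_lines[nzchar(trimws(geom_lines))]
  toks <- lapply(geom_lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  ncol <- unique(vapply(toks, length, 0L))
  if (length(ncol) != 1) stop("ragged geometry block")
  el <- vapply(toks, `[[`, "", 1)
  num <- function(k) vapply(toks, function(t) as.numeric(t[[k]]), 0)
  geometry <- if (ncol == 10) {
    z <- data.frame(element = el, distance = num(2), angle = num(4),
                    dihedral = num(6),
                    r1 = as.integer(num(8)), r2 = as.integer(num(9)),
                    r3 = as.integer(num(10)), stringsAsFactors = FALSE)
    z$distance[1] <- NA; z$r1[z$r1 == 0] <- NA
    z$angle[z$r2 == 0 | is.na(z$r2)] <- NA
    z$r2[z$r2 == 0] <- NA
    z$dihedral[z$r3 == 0 | is.na(z$r3)] <- NA
    z$r3[z$r3 == 0] <- NA
    if (nrow(z) >= 1) z$angle[1] <- NA
    class(z) <- c("zmatrix", "data.frame")
    z
  } else if (ncol == 7) {
    atoms(el, num(2), num(4), num(6))
  } else {
    stop("unrecognized geometry row layout (", ncol, " fields)")
  }
  structure(list(keywords = keywords, title = title, geometry = geometry),
            class = "mopac_input")
}

#' Parse optimizer output for the final geometry and status
#'
#' Understands the output dialect written by semi-empirical optimizers (and
#' by this package's mock): a `CARTESIAN COORDINATES` block of
#' `n element x y z` rows, `PROPERTY = value` lines, and a normal/error
#' termination marker.
#'
#' @param text output or archive text.
#' @return list with `atoms` (final Cartesian geometry, or NULL after error
#'   termination), `properties` (named numeric list) and `status`
#'   (`"normal"` or `"error"`).
#' @export
parse_mopac_output <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  if (!length(lines)) stop("empty optimizer output")
  status <- if (any(grepl("JOB ENDED NORMALLY|MOPAC DONE", lines))) {
    "normal"
  } else if (any(grepl("ERROR|CALCULATION ABANDONED", lines))) {
    "error"
  } else {
    stop("unrecognizable optimizer output: no termination marker in ",
         length(lines), " lines (last line: '",
         lines[length(lines)], "')")
  }
  props <- list()
  for (l in grep("^\\s*[A-Z][A-Z ]+=\\s*-?[0-9.]+", lines, value = TRUE)) {
    kv <- strsplit(l, "=")[[1]]
    key <- gsub("\\s+", "_", trimws(kv[1]))
    val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (!is.na(val)) props[[key]] <- val
  }
  final_atoms <- NULL
  hdr <- grep("CARTESIAN COORDINATES", lines)
  if (length(hdr)) {
    start <- hdr[length(hdr)] + 1L
    rows <- list()
    for (i in seq(start, length(lines))) {
      t <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(t) == 5 && !is.na(suppressWarnings(as.integer(t[1])))) {
        rows[[length(rows) + 1L]] <- t
      } else if (length(rows)) break else next
    }
    if (length(rows)) {
      el <- vapply(rows, `[[`, "", 2)
      num <- function(k) vapply(rows, function(r) as.numeric(r[[k]]), 0)
      final_atoms <- atoms(el, num(3), num(4), num(5))
    }
  }
  if (status == "normal" && is.null(final_atoms)) {
    stop("normal termination but no CARTESIAN COORDINATES block found")
  }
  list(atoms = final_atoms, properties = props, status = status)
}

#' Run the external optimizer stage
#'
#' The optimization itself is a pluggable external command; this function
#' only captures its output and never interprets it (that is
#' [parse_mopac_output()]'s job). With `command = "mock"` a built-in stand-in
#' echoes the input geometry back as a normally terminated output, so the
#' pipeline is testable without licensed software.
#'
#' @param input a `mopac_input`.
#' @param command `"mock"`, or an external command template containing
#'   `{input}` and `{output}` placeholders, e.g.
#'   `"mopac {input} && cat {output}"`.
#' @param timeout seconds before the external command is abandoned.
#' @return captured output text.
#' @export
run_optimizer <- function(input, command = "mock", timeout = 300) {
  stopifnot(inherits(input, "mopac_input"))
  if (identical(command, "mock")) {
    return(mock_optimizer_output(input))
  }
  if (!nzchar(command)) stop("optimizer command not configured")
  deck <- tempfile(fileext = ".mop")
  outfile <- tempfile(fileext = ".out")
  on.exit(unlink(c(deck, outfile)), add = TRUE)
  writeLines(format_mopac_input(input), deck)
  cmd <- gsub("{input}", deck, gsub("{output}", outfile, command,
                                    fixed = TRUE), fixed = TRUE)
  exe <- strsplit(cmd, "\\s+")[[1]][1]
  if (!nzchar(Sys.which(exe)) && !file.exists(exe)) {
    stop("optimizer executable '", exe, "' not found: configuration error")
  }
  res <- suppressWarnings(system(cmd, intern = TRUE, timeout = timeout,
                                 ignore.stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status == 124) {
    stop("optimizer timed out after ", timeout, "s for entry '",
         input$title[1], "'")
  }
  if (file.exists(outfile) && file.size(outfile) > 0) {
    return(paste(readLines(outfile), collapse = "\n"))
  }
  paste(res, collapse = "\n")
}

#' Mock optimizer output for an input deck
#'
#' Echoes the deck's geometry (converting internal coordinates back to
#' Cartesian where needed) as a normally terminated output block. This is a
#' testing stand-in, not a physics calculation: coordinates are returned
#' unoptimized.
#'
#' @param input a `mopac_input`.
#' @return output text in the dialect [parse_mopac_output()] reads.
#' @export
mock_optimizer_output <- function(input) {
  geom <- input$geometry
  at <- if (inherits(geom, "zmatrix")) internal_to_cartesian(geom) else geom
  rows <- sprintf("  %4d %-3s %12.6f %12.6f %12.6f",
                  seq_len(nrow(at)), at$element, at$x, at$y, at$z)
  paste(c(" MOCK OPTIMIZER (echo geometry)",
          paste0(" KEYWORDS: ", paste(input$keywords, collapse = " ")),
          " FINAL HEAT OF FORMATION = 0.0",
          "",
          "          CARTESIAN COORDINATES",
          rows,
          "",
          " == MOPAC DONE ==  JOB ENDED NORMALLY"),
        collapse = "\n")
}
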
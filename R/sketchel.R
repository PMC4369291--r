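# Wire dialect for the minimalist molecule format.
#
# Line-oriented UTF-8:
#
#   SketchEl!(<natoms>,<nbonds>)
#   <element>=<x>,<y>;<charge>,<unpaired>[,h<count>][,<ext>[,<ext>...]]   x natoms
#   <from>-<to>=<order>,<stereo>[,<ext>[,<ext>...]]                      x nbonds
#   !End
#
# Coordinates are fixed 4-decimal; stereo codes are 0 flat, 1 inclined,
# 2 declined, 3 unknown. The h<count> field is present only for an explicit
# virtual-hydrogen override -- its absence means AUTO. Extension tokens are
# comma-separated and escaped (backslash escapes: `\\`, `\,`, `\n`); tokens
# with reserved prefixes are z: (z coordinate), i: (isotope mass), n:
# (mapping number), q: (query), a: (inline abbreviation, whose payload is the
# fragment serialized in this same dialect and escaped). Unknown tokens --
# reserved-prefix or otherwise -- are preserved verbatim but never
# interpreted, which is what makes the format forward- and
# backward-compatible: read/modify/write never destroys information the
# reader does not understand. The dialect is frozen by golden files under
# inst/extdata/.

esc_token <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub(",", "\\,", s, fixed = TRUE)
  gsub("\n", "\\n", s, fixed = TRUE)
}

unesc_token <- function(s) {
  out <- character(1)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  buf <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "\\" && i < length(chars)) {
      nxt <- chars[[i + 1L]]
      buf <- c(buf, switch(nxt, "n" = "\n", nxt))
      i <- i + 2L
    } else {
      buf <- c(buf, ch)
      i <- i + 1L
    }
  }
  paste(buf, collapse = "")
}

# split on commas that are not backslash-escaped
split_esc <- function(s) {
  if (!nzchar(s)) return(character())
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character()
  buf <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "\\" && i < length(chars)) {
      buf <- c(buf, ch, chars[[i + 1L]])
      i <- i + 2L
    } else if (ch == ",") {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character(0)
      i <- i + 1L
    } else {
      buf <- c(buf, ch)
      i <- i + 1L
    }
  }
  c(out, paste(buf, collapse = ""))
}

fmt_coord <- function(v) {
  v <- round(v, 4)
  if (v == 0) v <- 0  # avoid "-0.0000"
  sprintf("%.4f", v)
}

STEREO_CODE <- c(flat = 0L, inclined = 1L, declined = 2L, unknown = 3L)

parse_err <- function(lineno, msg) {
  abort(sprintf("parse error at line %d: %s", lineno, msg),
        class = "elnote_parse_error")
}

#' Parse the molecule serialization
#'
#' Reads the line-oriented dialect documented in [write_sketchel()]. Every
#' extension token, recognized or not, is preserved in order; malformed input
#' raises a parse error naming the offending line.
#'
#' @param text A single string or a character vector of lines.
#' @return A [molecule()].
#' @export
parse_sketchel <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  if (length(lines) == 0) parse_err(1L, "empty document")
  m <- regmatches(lines[[1]],
                  regexec("^SketchEl!\\((\\d+),(\\d+)\\)$", lines[[1]]))[[1]]
  if (length(m) != 3) parse_err(1L, "malformed header")
  na <- as.integer(m[[2]]); nb <- as.integer(m[[3]])
  if (length(lines) < 1L + na + nb + 1L)
    parse_err(length(lines), sprintf(
      "document truncated: header declares %d atoms and %d bonds", na, nb))
  mol <- molecule()
  for (i in seq_len(na)) {
    ln <- 1L + i
    s <- lines[[ln]]
    eq <- regexpr("=", s, fixed = TRUE)
    if (eq < 1) parse_err(ln, "atom line lacks '='")
    element <- substr(s, 1L, eq - 1L)
    rest <- substring(s, eq + 1L)
    semi <- regexpr(";", rest, fixed = TRUE)
    if (semi < 1) parse_err(ln, "atom line lacks ';'")
    coords <- strsplit(substr(rest, 1L, semi - 1L), ",", fixed = TRUE)[[1]]
    if (length(coords) != 2) parse_err(ln, "expected two coordinates")
    x <- suppressWarnings(as.numeric(coords[[1]]))
    y <- suppressWarnings(as.numeric(coords[[2]]))
    if (is.na(x) || is.na(y)) parse_err(ln, "non-numeric coordinate")
    fields <- split_esc(substring(rest, semi + 1L))
    if (length(fields) < 2) parse_err(ln, "expected charge and unpaired fields")
    charge <- suppressWarnings(as.integer(fields[[1]]))
    unpaired <- suppressWarnings(as.integer(fields[[2]]))
    if (is.na(charge) || is.na(unpaired))
      parse_err(ln, "non-integer charge or unpaired field")
    fields <- fields[-(1:2)]
    hydrogens <- NA_integer_
    if (length(fields) > 0 && grepl("^h\\d+$", fields[[1]])) {
      hydrogens <- as.integer(substring(fields[[1]], 2L))
      fields <- fields[-1]
    }
    ext <- vapply(fields, unesc_token, character(1), USE.NAMES = FALSE)
    mol <- add_atom(mol, element, x, y, charge, unpaired, hydrogens, ext)
  }
  for (j in seq_len(nb)) {
    ln <- 1L + na + j
    s <- lines[[ln]]
    m <- regmatches(s, regexec("^(\\d+)-(\\d+)=(.*)$", s))[[1]]
    if (length(m) != 4) parse_err(ln, "malformed bond line")
    fields <- split_esc(m[[4]])
    if (length(fields) < 2) parse_err(ln, "expected order and stereo fields")
    order <- suppressWarnings(as.integer(fields[[1]]))
    scode <- suppressWarnings(as.integer(fields[[2]]))
    if (is.na(order)) parse_err(ln, "non-integer bond order")
    if (is.na(scode) || !scode %in% 0:3) parse_err(ln, "stereo code outside 0..3")
    ext <- vapply(fields[-(1:2)], unesc_token, character(1), USE.NAMES = FALSE)
    mol <- add_bond(mol, as.integer(m[[2]]), as.integer(m[[3]]), order,
                    names(STEREO_CODE)[[scode + 1L]], ext)
  }
  term <- lines[[1L + na + nb + 1L]]
  if (!identical(term, "!End")) parse_err(1L + na + nb + 1L, "missing !End terminator")
  mol
}

#' Serialize a molecule
#'
#' Writes the dialect documented at the head of this file. Output is
#' byte-stable for value-equal molecules (canonical number formatting), and
#' `parse_sketchel(write_sketchel(m))` is value-equal to `m`. A molecule that
#' fails [check_graph()] is refused.
#'
#' @param mol A [molecule()].
#' @return A single string, newline-terminated.
#' @export
write_sketchel <- function(mol) {
  bad <- check_graph(mol)
  if (nrow(bad) > 0) {
    abort(paste0("refusing to write molecule with structural violations: ",
                 paste(unique(bad$rule), collapse = ", ")))
  }
  out <- sprintf("SketchEl!(%d,%d)", n_atoms(mol), n_bonds(mol))
  for (a in mol$atoms) {
    fields <- c(sprintf("%d", a$charge), sprintf("%d", a$unpaired))
    if (!is.na(a$hydrogens)) fields <- c(fields, sprintf("h%d", a$hydrogens))
    fields <- c(fields, vapply(a$extensions, esc_token, character(1),
                               USE.NAMES = FALSE))
    out <- c(out, sprintf("%s=%s,%s;%s", a$element, fmt_coord(a$x),
                          fmt_coord(a$y), paste(fields, collapse = ",")))
  }
  for (b in mol$bonds) {
    fields <- c(sprintf("%d", b$order), sprintf("%d", STEREO_CODE[[b$stereo]]))
    fields <- c(fields, vapply(b$extensions, esc_token, character(1),
                               USE.NAMES = FALSE))
    out <- c(out, sprintf("%d-%d=%s", b$from, b$to,
                          paste(fields, collapse = ",")))
  }
  paste0(paste(c(out, "!End"), collapse = "\n"), "\n")
}

#' Read or write a molecule file
#'
#' Files use the `.el` extension (MIME type `chemical/x-sketchel`).
#'
#' @param path File path.
#' @return `read_sketchel()` returns a [molecule()];
#'   `write_sketchel_file()` returns `path` invisibly.
#' @export
read_sketchel <- function(path) {
  parse_sketchel(readLines(path, warn = FALSE))
}

#' @rdname read_sketchel
#' @param mol A [molecule()].
#' @export
write_sketchel_file <- function(mol, path) {
  writeLines(sub("\n$", "", write_sketchel(mol)), path)
  invisible(path)
}
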
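# The typed tabular container. Each column is strongly typed -- molecule,
# string, integer, real or boolean -- and molecule cells embed the molecule
# serialization. The header carries extensions: opaque named payloads that
# unaware software must preserve verbatim through read/modify/write.
# Extensions following a recognized protocol are "aspects" (Solvent,
# SARTable, Reaction, Experiment); aspect-aware software gains features,
# aspect-unaware software can still edit the sheet without destroying the
# higher-order markup, and a damaged aspect repairs itself by recreating
# missing columns with defaults.

DS_TYPES <- c("molecule", "string", "integer", "real", "boolean")
ASPECT_NAMES <- c("Solvent", "SARTable", "Reaction", "Experiment")

#' Create a datasheet
#'
#' @param names Character vector of column names (unique).
#' @param types Character vector of column types, each one of `"molecule"`,
#'   `"string"`, `"integer"`, `"real"`, `"boolean"`.
#' @return An object of class `datasheet` with no rows.
#' @export
datasheet <- function(names = character(), types = character()) {
  stopifnot(length(names) == length(types))
  if (anyDuplicated(names)) abort("duplicate column names")
  if (!all(types %in% DS_TYPES))
    abort(paste0("unknown column type: ",
                 paste(setdiff(types, DS_TYPES), collapse = ", ")))
  structure(list(columns = tibble(name = as.character(names),
                                  type = as.character(types)),
                 rows = list(), extensions = list()),
            class = "datasheet")
}

#' @export
is.datasheet <- function(x) inherits(x, "datasheet")

#' Datasheet dimensions and column lookup
#'
#' @param sheet A [datasheet()].
#' @return `ds_ncol()`/`ds_nrow()` return integers; `ds_colnames()` the name
#'   vector; `ds_coltype()` one column's type.
#' @export
ds_ncol <- function(sheet) nrow(sheet$columns)

#' @rdname ds_ncol
#' @export
ds_nrow <- function(sheet) length(sheet$rows)

#' @rdname ds_ncol
#' @export
ds_colnames <- function(sheet) sheet$columns$name

#' @rdname ds_ncol
#' @param col Column name or index.
#' @export
ds_coltype <- function(sheet, col) sheet$columns$type[[ds_colindex(sheet, col)]]

ds_colindex <- function(sheet, col) {
  if (is.numeric(col)) {
    col <- as.integer(col)
    if (col < 1 || col > ds_ncol(sheet)) abort("column index out of range")
    return(col)
  }
  i <- match(col, sheet$columns$name)
  if (is.na(i)) abort(sprintf("no column named '%s'", col))
  i
}

check_cell_type <- function(value, type) {
  if (is.null(value)) return(TRUE)
  switch(type,
         molecule = is.molecule(value),
         string = is.character(value) && length(value) == 1,
         integer = is.numeric(value) && length(value) == 1 &&
           !is.na(value) && value == round(value),
         real = is.numeric(value) && length(value) == 1 && !is.na(value),
         boolean = is.logical(value) && length(value) == 1 && !is.na(value))
}

coerce_cell <- function(value, type) {
  if (is.null(value)) return(NULL)
  switch(type, molecule = value, string = as.character(value),
         integer = as.integer(value), real = as.numeric(value),
         boolean = as.logical(value))
}

#' Row and cell operations
#'
#' Generic sheet editing: these are the operations an aspect-unaware editor
#' uses, and none of them may corrupt aspect payloads.
#'
#' @param sheet A [datasheet()].
#' @param values List of cell values (length `ds_ncol`), `NULL` for empty
#'   cells. Each value must conform to its column type.
#' @return The modified sheet (or the cell value for `ds_cell()`).
#' @export
ds_append_row <- function(sheet, values = NULL) {
  nc <- ds_ncol(sheet)
  if (is.null(values)) values <- vector("list", nc)
  if (length(values) != nc) abort("row length does not match column count")
  for (k in seq_len(nc)) {
    if (!check_cell_type(values[[k]], sheet$columns$type[[k]]))
      abort(sprintf("cell in column '%s' does not conform to type %s",
                    sheet$columns$name[[k]], sheet$columns$type[[k]]))
    values[k] <- list(coerce_cell(values[[k]], sheet$columns$type[[k]]))
  }
  sheet$rows[[length(sheet$rows) + 1L]] <- values
  sheet
}

#' @rdname ds_append_row
#' @param row Row index.
#' @param col Column name or index.
#' @export
ds_cell <- function(sheet, row, col) {
  stopifnot(row >= 1, row <= ds_nrow(sheet))
  sheet$rows[[row]][[ds_colindex(sheet, col)]]
}

#' @rdname ds_append_row
#' @param value New cell value (`NULL` clears the cell).
#' @export
ds_set_cell <- function(sheet, row, col, value) {
  stopifnot(row >= 1, row <= ds_nrow(sheet))
  k <- ds_colindex(sheet, col)
  if (!check_cell_type(value, sheet$columns$type[[k]]))
    abort(sprintf("cell in column '%s' does not conform to type %s",
                  sheet$columns$name[[k]], sheet$columns$type[[k]]))
  sheet$rows[[row]][k] <- list(coerce_cell(value, sheet$columns$type[[k]]))
  sheet
}

#' @rdname ds_append_row
#' @export
ds_delete_row <- function(sheet, row) {
  stopifnot(row >= 1, row <= ds_nrow(sheet))
  sheet$rows[[row]] <- NULL
  sheet
}

#' @rdname ds_append_row
#' @param name,type New column name and type.
#' @export
ds_add_column <- function(sheet, name, type) {
  if (name %in% ds_colnames(sheet)) abort(sprintf("column '%s' already exists", name))
  if (!type %in% DS_TYPES) abort(sprintf("unknown column type '%s'", type))
  sheet$columns <- dplyr::bind_rows(sheet$columns, tibble(name = name, type = type))
  sheet$rows <- lapply(sheet$rows, function(r) c(r, list(NULL)))
  sheet
}

#' @rdname ds_append_row
#' @export
ds_delete_column <- function(sheet, col) {
  k <- ds_colindex(sheet, col)
  sheet$columns <- sheet$columns[-k, , drop = FALSE]
  sheet$rows <- lapply(sheet$rows, function(r) r[-k])
  sheet
}

#' Header extensions
#'
#' Named opaque payloads carried in the sheet header. Unrecognized names are
#' preserved byte-identically through read/modify/write; recognized names
#' (the four aspects) additionally get a parsed view via [ds_aspects()].
#'
#' @param sheet A [datasheet()].
#' @param name Extension name.
#' @param payload Payload text.
#' @return The modified sheet; `ds_extension()` returns the payload string
#'   or `NULL`.
#' @export
ds_set_extension <- function(sheet, name, payload) {
  for (i in seq_along(sheet$extensions)) {
    if (sheet$extensions[[i]]$name == name) {
      sheet$extensions[[i]]$payload <- payload
      return(sheet)
    }
  }
  sheet$extensions[[length(sheet$extensions) + 1L]] <-
    list(name = name, payload = payload)
  sheet
}

#' @rdname ds_set_extension
#' @export
ds_extension <- function(sheet, name) {
  for (e in sheet$extensions) if (e$name == name) return(e$payload)
  NULL
}

# --- aspect payload grammar --------------------------------------------------
# Line-oriented: one record per line, each a ;-separated list of key=value
# pairs. The concrete field lists are repo-specific (documented in the
# methods vignette); the behavioural contract (tolerance of unaware edits,
# self-repair) is what matters.

parse_kv_line <- function(line) {
  parts <- strsplit(line, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 1) next
    out[[substr(p, 1, eq - 1)]] <- substring(p, eq + 1)
  }
  out
}

parse_aspect_payload <- function(name, payload) {
  lines <- strsplit(payload, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, parse_kv_line)
  switch(name,
    Solvent = list(columns = purrr::map(recs, function(r) list(
      column = r$column, role = r$role %||% "property",
      units = r$units %||% "", type = r$type %||% "real"))),
    SARTable = {
      scaffold <- NULL; mol <- NULL; subst <- character(); props <- list()
      for (r in recs) {
        if (!is.null(r$scaffold)) scaffold <- r$scaffold
        if (!is.null(r$molecule)) mol <- r$molecule
        if (!is.null(r$substituent)) subst <- c(subst, r$substituent)
        if (!is.null(r$property)) props[[length(props) + 1L]] <- list(
          column = r$property, units = r$units %||% "",
          min = as.numeric(r$min %||% NA), max = as.numeric(r$max %||% NA))
      }
      list(scaffold = scaffold, substituents = subst, molecule = mol,
           properties = props)
    },
    Reaction = ,
    Experiment = list(components = purrr::map(recs, function(r) list(
      step = as.integer(r$step %||% 1), role = r$role %||% "reactant",
      column = r$column, type = r$type %||% "molecule",
      quantity = r$quantity))),
    NULL)
}

#' Parsed aspect views
#'
#' @param sheet A [datasheet()].
#' @return Named list of parsed payloads for every recognized aspect present
#'   in the header.
#' @export
ds_aspects <- function(sheet) {
  out <- list()
  for (e in sheet$extensions) {
    if (e$name %in% ASPECT_NAMES)
      out[[e$name]] <- parse_aspect_payload(e$name, e$payload)
  }
  out
}

aspect_required_columns <- function(name, parsed) {
  req <- list()
  add <- function(column, type) {
    if (!is.null(column) && nzchar(column))
      req[[length(req) + 1L]] <<- list(name = column, type = type)
  }
  if (name == "Solvent") {
    for (cdef in parsed$columns) add(cdef$column, cdef$type)
  } else if (name == "SARTable") {
    add(parsed$scaffold, "molecule")
    for (s in parsed$substituents) add(s, "molecule")
    add(parsed$molecule, "molecule")
    for (p in parsed$properties) add(p$column, "real")
  } else {
    for (comp in parsed$components) {
      add(comp$column, switch(comp$type, molecule = "molecule",
                              string = "string", "real"))
      if (!is.null(comp$quantity)) add(comp$quantity, "real")
    }
  }
  req
}

#' Repair an aspect after disruptive external edits
#'
#' An aspect must tolerate aspect-unaware editing: if one of its necessary
#' columns has been deleted, it is recreated (null-filled, with its declared
#' default type) and existing data is left untouched. Repairing an intact
#' sheet is a no-op, and repairing twice equals repairing once.
#'
#' @param sheet A [datasheet()].
#' @param aspect_name One of `"Solvent"`, `"SARTable"`, `"Reaction"`,
#'   `"Experiment"`.
#' @return The repaired sheet.
#' @export
repair_aspect <- function(sheet, aspect_name) {
  if (!aspect_name %in% ASPECT_NAMES)
    abort(sprintf("unknown aspect '%s'", aspect_name))
  payload <- ds_extension(sheet, aspect_name)
  if (is.null(payload))
    abort(sprintf("sheet does not carry the %s aspect", aspect_name))
  parsed <- parse_aspect_payload(aspect_name, payload)
  for (req in aspect_required_columns(aspect_name, parsed)) {
    if (!req$name %in% ds_colnames(sheet))
      sheet <- ds_add_column(sheet, req$name, req$type)
  }
  sheet
}

# --- XML serialization -------------------------------------------------------

#' Parse datasheet XML
#'
#' Documented schema (frozen by golden files): a `<DataSheet>` root holding a
#' `<Header>` of `<Column name type>` declarations and `<Extension name>`
#' payload blocks, followed by `<Row>` elements of `<Cell col>` elements.
#' Null cells are absent elements, so numeric columns stay type-clean.
#' Molecule cells contain the molecule serialization as escaped text. Types
#' are enforced cell by cell (the offending row/column is named); unknown
#' extensions are preserved as opaque payloads.
#'
#' @param xml_text XML text (or an `xml2` document).
#' @return A [datasheet()].
#' @export
parse_datasheet <- function(xml_text) {
  doc <- if (inherits(xml_text, "xml_document")) xml_text else
    xml2::read_xml(paste(xml_text, collapse = "\n"))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "DataSheet") abort("root element is not <DataSheet>")
  header <- xml2::xml_find_first(root, "./Header")
  if (inherits(header, "xml_missing")) abort("missing <Header> element")
  cols <- xml2::xml_find_all(header, "./Column")
  names <- xml2::xml_attr(cols, "name")
  types <- xml2::xml_attr(cols, "type")
  if (anyDuplicated(names)) abort("duplicate column names in header")
  sheet <- datasheet(names, types)
  for (ext in xml2::xml_find_all(header, "./Extension")) {
    sheet <- ds_set_extension(sheet, xml2::xml_attr(ext, "name"),
                              xml2::xml_text(ext))
  }
  for (rnode in xml2::xml_find_all(root, "./Row")) {
    values <- vector("list", ds_ncol(sheet))
    for (cnode in xml2::xml_find_all(rnode, "./Cell")) {
      k <- as.integer(xml2::xml_attr(cnode, "col"))
      if (is.na(k) || k < 1 || k > ds_ncol(sheet))
        abort("cell references a missing column")
      txt <- xml2::xml_text(cnode)
      type <- sheet$columns$type[[k]]
      rw <- ds_nrow(sheet) + 1L
      value <- switch(type,
        molecule = parse_sketchel(txt),
        string = txt,
        integer = {
          if (!grepl("^-?\\d+$", txt))
            abort(sprintf("cell (row %d, column '%s') is not an integer: '%s'",
                          rw, sheet$columns$name[[k]], txt))
          as.integer(txt)
        },
        real = {
          v <- suppressWarnings(as.numeric(txt))
          if (is.na(v))
            abort(sprintf("cell (row %d, column '%s') is not a real number: '%s'",
                          rw, sheet$columns$name[[k]], txt))
          v
        },
        boolean = {
          if (!txt %in% c("true", "false"))
            abort(sprintf("cell (row %d, column '%s') is not a boolean: '%s'",
                          rw, sheet$columns$name[[k]], txt))
          txt == "true"
        })
      values[k] <- list(value)
    }
    sheet <- ds_append_row(sheet, values)
  }
  sheet
}

cell_to_text <- function(value, type) {
  switch(type,
         molecule = write_sketchel(value),
         string = value,
         integer = sprintf("%d", value),
         real = format(value, scientific = FALSE, trim = TRUE, digits = 15),
         boolean = if (value) "true" else "false")
}

#' Write datasheet XML
#'
#' `parse_datasheet(write_datasheet(s))` is value-equal to `s`, unknown
#' header extensions included byte-identically.
#'
#' @param sheet A [datasheet()].
#' @return XML text as a single string.
#' @export
write_datasheet <- function(sheet) {
  stopifnot(is.datasheet(sheet))
  doc <- xml2::xml_new_root("DataSheet")
  header <- xml2::xml_add_child(doc, "Header",
                                ncols = as.character(ds_ncol(sheet)),
                                nrows = as.character(ds_nrow(sheet)))
  for (k in seq_len(ds_ncol(sheet))) {
    xml2::xml_add_child(header, "Column", id = as.character(k),
                        name = sheet$columns$name[[k]],
                        type = sheet$columns$type[[k]])
  }
  for (e in sheet$extensions) {
    node <- xml2::xml_add_child(header, "Extension", name = e$name)
    xml2::xml_text(node) <- e$payload
  }
  for (r in seq_len(ds_nrow(sheet))) {
    rnode <- xml2::xml_add_child(doc, "Row", id = as.character(r))
    for (k in seq_len(ds_ncol(sheet))) {
      value <- sheet$rows[[r]][[k]]
      if (is.null(value)) next
      cnode <- xml2::xml_add_child(rnode, "Cell", col = as.character(k))
      xml2::xml_text(cnode) <- cell_to_text(value, sheet$columns$type[[k]])
    }
  }
  as.character(doc)
}

#' @rdname parse_datasheet
#' @param path File path (conventional extension `.ds`).
#' @export
read_datasheet <- function(path) parse_datasheet(xml2::read_xml(path))

#' @rdname write_datasheet
#' @param path File path.
#' @export
write_datasheet_file <- function(sheet, path) {
  writeLines(write_datasheet(sheet), path)
  invisible(path)
}

#' Datasheet value equality
#'
#' @param a,b [datasheet()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
ds_equal <- function(a, b) {
  if (!identical(a$columns$name, b$columns$name)) return(FALSE)
  if (!identical(a$columns$type, b$columns$type)) return(FALSE)
  if (ds_nrow(a) != ds_nrow(b)) return(FALSE)
  if (length(a$extensions) != length(b$extensions)) return(FALSE)
  for (i in seq_along(a$extensions)) {
    if (!identical(a$extensions[[i]], b$extensions[[i]])) return(FALSE)
  }
  for (r in seq_len(ds_nrow(a))) {
    for (k in seq_len(ds_ncol(a))) {
      x <- a$rows[[r]][[k]]; y <- b$rows[[r]][[k]]
      if (is.null(x) != is.null(y)) return(FALSE)
      if (is.null(x)) next
      if (a$columns$type[[k]] == "molecule") {
        if (!mol_equal(x, y)) return(FALSE)
      } else if (!isTRUE(all.equal(x, y))) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.datasheet <- function(x, ...) {
  cat(sprintf("<datasheet: %d columns x %d rows>\n", ds_ncol(x), ds_nrow(x)))
  for (k in seq_len(ds_ncol(x)))
    cat(sprintf("  %s <%s>\n", x$columns$name[[k]], x$columns$type[[k]]))
  if (length(x$extensions))
    cat("  extensions:", paste(vapply(x$extensions, `[[`, character(1), "name"),
                               collapse = ", "), "\n")
  invisible(x)
}

# --- SAR composition ---------------------------------------------------------

placeholder_rx <- "^(X|R[0-9]*)$"

#' Compose a SAR molecule from scaffold and substituents
#'
#' Placeholder atoms in the scaffold (tokens `X`, `R`, `R1`, `R2`, ...) are
#' replaced by the named substituent fragments, grafted with the same splice
#' semantics as abbreviation expansion. Matching is by exact label;
#' substituent entries with no matching placeholder are ignored with a
#' warning. Each fragment needs exactly one `"*"` attachment atom; a bare-H
#' fragment restores a hydrogen at the placeholder position.
#'
#' @param scaffold A [molecule()] containing placeholder atoms.
#' @param substituents Named list: placeholder label -> fragment [molecule()].
#' @return The composite [molecule()].
#' @export
compose_sar_molecule <- function(scaffold, substituents) {
  labels <- vapply(scaffold$atoms, `[[`, character(1), "element")
  todo <- which(grepl(placeholder_rx, labels) &
                  !vapply(seq_along(labels), has_abbrev, logical(1), mol = scaffold))
  missing <- setdiff(labels[todo], names(substituents))
  if (length(missing) > 0)
    abort(paste0("missing substituent for placeholder(s): ",
                 paste(unique(missing), collapse = ", ")))
  unused <- setdiff(names(substituents), labels[todo])
  if (length(unused) > 0)
    warning("unmatched substituent entries ignored: ",
            paste(unused, collapse = ", "), call. = FALSE)
  mol <- scaffold
  repeat {
    labels <- vapply(mol$atoms, `[[`, character(1), "element")
    todo <- which(grepl(placeholder_rx, labels) &
                    !vapply(seq_along(labels), has_abbrev, logical(1), mol = mol))
    if (length(todo) == 0) break
    p <- todo[[1]]
    mol <- splice_fragment(mol, p, substituents[[labels[[p]]]])
  }
  mol
}

# --- SDfile ------------------------------------------------------------------

#' Export a datasheet as an MDL SDfile
#'
#' One record per row: the designated molecule column becomes the connection
#' table, every other column becomes a `> <name>` data field. Column typing
#' and all header extensions/aspects cannot be represented in an SDfile;
#' each such downgrade is recorded in the loss attribute.
#'
#' @param sheet A [datasheet()].
#' @param molecule_column Name (or index) of a molecule-typed column.
#' @return SDfile text, with a `loss` attribute (tibble: locator, code,
#'   note) recording dropped typing, aspects and per-molecule downgrades.
#' @export
export_sdfile <- function(sheet, molecule_column) {
  k <- ds_colindex(sheet, molecule_column)
  if (sheet$columns$type[[k]] != "molecule")
    abort(sprintf("column '%s' is not molecule-typed", sheet$columns$name[[k]]))
  loss <- list()
  note_loss <- function(locator, code, note) {
    loss[[length(loss) + 1L]] <- tibble(locator = locator, code = code, note = note)
    loss <<- loss
  }
  for (e in sheet$extensions) {
    note_loss(paste0("extension:", e$name), "aspect_dropped",
              sprintf("header extension '%s' has no SDfile representation", e$name))
  }
  for (j in setdiff(seq_len(ds_ncol(sheet)), k)) {
    if (sheet$columns$type[[j]] != "string")
      note_loss(paste0("column:", sheet$columns$name[[j]]), "column_type_dropped",
                sprintf("%s column serialized as text data field",
                        sheet$columns$type[[j]]))
  }
  records <- character()
  for (r in seq_len(ds_nrow(sheet))) {
    mol <- sheet$rows[[r]][[k]] %||% molecule()
    mf <- write_molfile(mol)
    if (nrow(mf$loss) > 0) {
      mf$loss$locator <- paste0("row:", r, "/", mf$loss$locator)
      loss[[length(loss) + 1L]] <- mf$loss
    }
    rec <- mf$text
    for (j in setdiff(seq_len(ds_ncol(sheet)), k)) {
      value <- sheet$rows[[r]][[j]]
      if (is.null(value)) next
      rec <- paste0(rec, sprintf("> <%s>\n%s\n\n", sheet$columns$name[[j]],
                                 cell_to_text(value, sheet$columns$type[[j]])))
    }
    records <- c(records, paste0(rec, "$$$$\n"))
  }
  out <- paste(records, collapse = "")
  attr(out, "loss") <- if (length(loss)) dplyr::bind_rows(loss) else empty_loss()
  out
}

#' Import an MDL SDfile as a datasheet
#'
#' Data fields become columns typed by best-effort sniffing (integer, then
#' real, then boolean, falling back to string); structures land in a
#' molecule column named `Molecule`, with hydrogens frozen under
#' `hydrogen_mode` (see [parse_molfile()]).
#'
#' @param text SDfile text.
#' @param hydrogen_mode `"legacy"` or `"strict"`.
#' @return A [datasheet()].
#' @export
parse_sdfile <- function(text, hydrogen_mode = c("legacy", "strict")) {
  hydrogen_mode <- match.arg(hydrogen_mode)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  # split records on $$$$
  recs <- list(); cur <- character()
  for (ln in lines) {
    if (trimws(ln) == "$$$$") { recs[[length(recs) + 1L]] <- cur; cur <- character() }
    else cur <- c(cur, ln)
  }
  if (length(cur) > 0 && any(nzchar(trimws(cur)))) recs[[length(recs) + 1L]] <- cur
  mols <- list(); fields <- list()
  for (rec in recs) {
    endct <- which(substr(rec, 1, 6) == "M  END")
    split_at <- if (length(endct)) endct[[1]] else length(rec)
    mols[[length(mols) + 1L]] <- parse_molfile(rec[seq_len(split_at)],
                                               hydrogen_mode)$molecule
    fv <- list()
    i <- split_at + 1L
    while (i <= length(rec)) {
      m <- regmatches(rec[[i]], regexec("^>\\s*<(.+)>", rec[[i]]))[[1]]
      if (length(m) == 2) {
        vals <- character()
        i <- i + 1L
        while (i <= length(rec) && nzchar(trimws(rec[[i]]))) {
          vals <- c(vals, rec[[i]]); i <- i + 1L
        }
        fv[[m[[2]]]] <- paste(vals, collapse = "\n")
      }
      i <- i + 1L
    }
    fields[[length(fields) + 1L]] <- fv
  }
  fnames <- unique(unlist(lapply(fields, names)))
  sniff_type <- function(vals) {
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return("string")
    if (all(grepl("^-?\\d+$", vals))) return("integer")
    if (!anyNA(suppressWarnings(as.numeric(vals)))) return("real")
    if (all(vals %in% c("true", "false"))) return("boolean")
    "string"
  }
  ftypes <- vapply(fnames, function(nm) {
    sniff_type(unlist(lapply(fields, function(fv) fv[[nm]] %||% NA_character_)))
  }, character(1))
  sheet <- datasheet(c("Molecule", fnames), c("molecule", unname(ftypes)))
  for (ri in seq_along(mols)) {
    values <- vector("list", ds_ncol(sheet))
    values[[1]] <- mols[[ri]]
    for (ci in seq_along(fnames)) {
      raw <- fields[[ri]][[fnames[[ci]]]]
      if (is.null(raw)) next
      values[[ci + 1L]] <- switch(ftypes[[ci]],
                                  integer = as.integer(raw),
                                  real = as.numeric(raw),
                                  boolean = raw == "true",
                                  raw)
    }
    sheet <- ds_append_row(sheet, values)
  }
  sheet
}

# --- reaction schemes --------------------------------------------------------

#' Assemble the reaction scheme encoded by a Reaction/Experiment aspect
#'
#' Groups the aspect's molecule/text/number columns of one row into ordered
#' reaction steps with component roles (reactant, reagent, product), ready
#' for rendering as a single graphical object.
#'
#' @param sheet A [datasheet()] carrying a `Reaction` or `Experiment` aspect.
#' @param row Row index.
#' @return A tibble with columns `step`, `role`, `column`, `type`, `value`
#'   (list column) and `quantity`, ordered by step then by declaration order.
#' @export
assemble_reaction_scheme <- function(sheet, row) {
  aspects <- ds_aspects(sheet)
  asp <- aspects$Experiment %||% aspects$Reaction
  if (is.null(asp))
    abort("sheet carries neither a Reaction nor an Experiment aspect")
  stopifnot(row >= 1, row <= ds_nrow(sheet))
  rows <- list()
  for (comp in asp$components) {
    if (!comp$column %in% ds_colnames(sheet)) next  # survivable damage; repair restores
    value <- ds_cell(sheet, row, comp$column)
    quantity <- NA_real_
    if (!is.null(comp$quantity) && comp$quantity %in% ds_colnames(sheet)) {
      q <- ds_cell(sheet, row, comp$quantity)
      if (!is.null(q)) quantity <- as.numeric(q)
    }
    rows[[length(rows) + 1L]] <- tibble(
      step = comp$step, role = comp$role, column = comp$column,
      type = comp$type, value = list(value), quantity = quantity)
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$step), , drop = FALSE]
}
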
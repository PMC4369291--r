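#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort %||%
NULL

STEREO_TYPES <- c("flat", "inclined", "declined", "unknown")

#' Create an empty molecule
#'
#' A molecule is an ordered list of atoms and an ordered list of bonds -- a
#' deliberately minimal 2D sketch graph. Each atom carries an element token
#' (any non-empty string; usually a periodic-table symbol), 2D coordinates in
#' quasi-Angstrom units (idealized bond length 1.5, y increasing upward), an
#' integer formal charge, an unpaired-electron count, a virtual-hydrogen
#' field (`NA` = automatic, or an explicit count >= 0), and an ordered list
#' of opaque extension tokens. Extension tokens with reserved prefixes encode
#' the z coordinate (`z:`), isotope mass (`i:`), atom mapping number (`n:`),
#' query properties (`q:`) and inline abbreviations (`a:`); unknown tokens are
#' preserved verbatim through read/modify/write. Each bond records two 1-based
#' atom indices, an integer order in 0..5 (zero-order bonds carry no valence),
#' a stereo type (flat, inclined, declined, unknown) and its own extensions.
#'
#' The graph may be disconnected: mixtures and salts are legitimate records.
#'
#' @return An object of class `molecule` with no atoms and no bonds.
#' @seealso [add_atom()], [add_bond()], [check_graph()]
#' @export
#' @examples
#' mol <- molecule() |>
#'   add_atom("C", 0, 0) |>
#'   add_atom("O", 1.5, 0) |>
#'   add_bond(1, 2, order = 2)
#' n_atoms(mol)
molecule <- function() {
  structure(list(atoms = list(), bonds = list()), class = "molecule")
}

#' @export
is.molecule <- function(x) inherits(x, "molecule")

new_atom <- function(element, x = 0, y = 0, charge = 0L, unpaired = 0L,
                     hydrogens = NA_integer_, extensions = character()) {
  list(element = as.character(element), x = as.numeric(x), y = as.numeric(y),
       charge = as.integer(charge), unpaired = as.integer(unpaired),
       hydrogens = as.integer(hydrogens), extensions = as.character(extensions))
}

new_bond <- function(from, to, order = 1L, stereo = "flat",
                     extensions = character()) {
  list(from = as.integer(from), to = as.integer(to), order = as.integer(order),
       stereo = as.character(stereo), extensions = as.character(extensions))
}

#' Add an atom to a molecule
#'
#' @param mol A [molecule()].
#' @param element Element token (any non-empty string).
#' @param x,y 2D coordinates, quasi-Angstrom units.
#' @param charge Integer formal charge.
#' @param unpaired Unpaired-electron count (>= 0).
#' @param hydrogens Virtual hydrogens: `NA` for automatic calculation, or an
#'   explicit count >= 0 that overrides the decision table.
#' @param extensions Character vector of extension tokens.
#' @return The molecule with the atom appended.
#' @export
add_atom <- function(mol, element, x = 0, y = 0, charge = 0L, unpaired = 0L,
                     hydrogens = NA_integer_, extensions = character()) {
  stopifnot(is.molecule(mol))
  mol$atoms[[length(mol$atoms) + 1L]] <-
    new_atom(element, x, y, charge, unpaired, hydrogens, extensions)
  mol
}

#' Add a bond to a molecule
#'
#' @param mol A [molecule()].
#' @param from,to 1-based atom indices.
#' @param order Bond order, an integer in 0..5. Zero-order bonds mark dative
#'   or multicentre attachments and never consume valence.
#' @param stereo One of `"flat"`, `"inclined"`, `"declined"`, `"unknown"`.
#' @param extensions Character vector of extension tokens.
#' @return The molecule with the bond appended.
#' @export
add_bond <- function(mol, from, to, order = 1L, stereo = "flat",
                     extensions = character()) {
  stopifnot(is.molecule(mol))
  mol$bonds[[length(mol$bonds) + 1L]] <-
    new_bond(from, to, order, stereo, extensions)
  mol
}

#' @rdname add_atom
#' @export
n_atoms <- function(mol) length(mol$atoms)

#' @rdname add_bond
#' @export
n_bonds <- function(mol) length(mol$bonds)

#' Delete an atom (and its incident bonds)
#'
#' Remaining bond indices are renumbered so they keep pointing at the same
#' atoms. Adding an atom and deleting it again restores a value-equal
#' molecule.
#'
#' @param mol A [molecule()].
#' @param idx 1-based atom index.
#' @return The molecule without the atom.
#' @export
delete_atom <- function(mol, idx) {
  stopifnot(is.molecule(mol), idx >= 1L, idx <= n_atoms(mol))
  mol$atoms[[idx]] <- NULL
  keep <- vapply(mol$bonds, function(b) b$from != idx && b$to != idx, logical(1))
  mol$bonds <- mol$bonds[keep]
  mol$bonds <- lapply(mol$bonds, function(b) {
    if (b$from > idx) b$from <- b$from - 1L
    if (b$to > idx) b$to <- b$to - 1L
    b
  })
  mol
}

#' Modify fields of an existing atom or bond
#'
#' Only the supplied fields change; everything else, including extension
#' tokens, is untouched.
#'
#' @param mol A [molecule()].
#' @param idx 1-based atom (or bond) index.
#' @param ... Named fields to replace (`element`, `x`, `y`, `charge`,
#'   `unpaired`, `hydrogens`, `extensions` for atoms; `from`, `to`, `order`,
#'   `stereo`, `extensions` for bonds).
#' @return The modified molecule.
#' @export
set_atom <- function(mol, idx, ...) {
  stopifnot(is.molecule(mol), idx >= 1L, idx <= n_atoms(mol))
  fields <- list(...)
  a <- mol$atoms[[idx]]
  for (nm in names(fields)) {
    if (!nm %in% names(a)) abort(paste0("unknown atom field: ", nm))
    a[[nm]] <- fields[[nm]]
  }
  mol$atoms[[idx]] <- new_atom(a$element, a$x, a$y, a$charge, a$unpaired,
                               a$hydrogens, a$extensions)
  mol
}

#' @rdname set_atom
#' @export
set_bond <- function(mol, idx, ...) {
  stopifnot(is.molecule(mol), idx >= 1L, idx <= n_bonds(mol))
  fields <- list(...)
  b <- mol$bonds[[idx]]
  for (nm in names(fields)) {
    if (!nm %in% names(b)) abort(paste0("unknown bond field: ", nm))
    b[[nm]] <- fields[[nm]]
  }
  mol$bonds[[idx]] <- new_bond(b$from, b$to, b$order, b$stereo, b$extensions)
  mol
}

#' Atom and bond accessors
#'
#' @param mol A [molecule()].
#' @param idx 1-based index.
#' @return `get_atom()`/`get_bond()` return the full record as a named list;
#'   the scalar accessors return single fields.
#' @export
get_atom <- function(mol, idx) {
  stopifnot(idx >= 1L, idx <= n_atoms(mol))
  mol$atoms[[idx]]
}

#' @rdname get_atom
#' @export
get_bond <- function(mol, idx) {
  stopifnot(idx >= 1L, idx <= n_bonds(mol))
  mol$bonds[[idx]]
}

#' @rdname get_atom
#' @export
atom_element <- function(mol, idx) get_atom(mol, idx)$element

# --- extension token helpers -------------------------------------------------

ext_with_prefix <- function(tokens, prefix) {
  tokens[startsWith(tokens, prefix)]
}

get_atom_ext <- function(mol, idx, prefix) {
  hits <- ext_with_prefix(get_atom(mol, idx)$extensions, prefix)
  if (length(hits) == 0) NULL else substring(hits[[1]], nchar(prefix) + 1L)
}

set_atom_ext <- function(mol, idx, prefix, payload) {
  a <- get_atom(mol, idx)
  ext <- a$extensions
  keep <- !startsWith(ext, prefix)
  slot <- which(!keep)
  token <- if (is.null(payload)) character() else paste0(prefix, payload)
  if (length(slot) > 0) {
    # replace in place to preserve extension order
    if (length(token) > 0) {
      ext[slot[[1]]] <- token
      ext <- ext[keep | seq_along(ext) == slot[[1]]]
    } else {
      ext <- ext[keep]
    }
  } else {
    ext <- c(ext, token)
  }
  set_atom(mol, idx, extensions = ext)
}

#' Isotope mass of an atom
#'
#' The isotope extension stores an integer mass number; 0 (or an absent
#' extension) means natural abundance.
#'
#' @inheritParams get_atom
#' @return Integer mass number; 0 for natural abundance.
#' @export
atom_isotope <- function(mol, idx) {
  v <- get_atom_ext(mol, idx, "i:")
  if (is.null(v)) 0L else as.integer(v)
}

#' @rdname atom_isotope
#' @param mass Integer mass number, or 0 to clear back to natural abundance.
#' @export
set_isotope <- function(mol, idx, mass) {
  set_atom_ext(mol, idx, "i:", if (mass == 0) NULL else as.character(as.integer(mass)))
}

#' Atom mapping number
#'
#' @inheritParams get_atom
#' @return Integer mapping number, 0 when unset.
#' @export
atom_mapnum <- function(mol, idx) {
  v <- get_atom_ext(mol, idx, "n:")
  if (is.null(v)) 0L else as.integer(v)
}

has_query_ext <- function(rec) length(ext_with_prefix(rec$extensions, "q:")) > 0

# --- derived quantities ------------------------------------------------------

#' Count heavy (non-hydrogen) atoms
#'
#' Counts atom nodes whose element token is not `"H"`. Abbreviation
#' placeholder nodes count as one node each; no expansion is performed, so a
#' Ph--Br drawing with an inline phenyl abbreviation counts 2.
#'
#' @param mol A [molecule()].
#' @return Non-negative integer.
#' @export
heavy_atom_count <- function(mol) {
  sum(vapply(mol$atoms, function(a) a$element != "H", logical(1)))
}

#' Net formal charge
#'
#' Sum of atom formal charges over the whole record, disconnected components
#' included (salts are stored as one record).
#'
#' @param mol A [molecule()].
#' @return Integer.
#' @export
net_formal_charge <- function(mol) {
  if (n_atoms(mol) == 0) return(0L)
  sum(vapply(mol$atoms, function(a) a$charge, integer(1)))
}

#' Occupied valence of an atom
#'
#' Sum of incident bond orders (zero-order bonds contribute nothing) plus the
#' unpaired-electron count. This is the quantity the implicit-hydrogen
#' decision tables compare against the allowed valences.
#'
#' @inheritParams get_atom
#' @return Non-negative integer.
#' @export
atom_occupied <- function(mol, idx) {
  occ <- get_atom(mol, idx)$unpaired
  for (b in mol$bonds) {
    if (b$from == idx || b$to == idx) occ <- occ + b$order
  }
  as.integer(occ)
}

atom_degree <- function(mol, idx) {
  sum(vapply(mol$bonds, function(b) b$from == idx || b$to == idx, logical(1)))
}

atom_neighbours <- function(mol, idx) {
  out <- integer()
  for (b in mol$bonds) {
    if (b$from == idx) out <- c(out, b$to)
    if (b$to == idx) out <- c(out, b$from)
  }
  out
}

connected_components <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0) return(integer())
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in atom_neighbours(mol, v)) {
        if (is.na(comp[w])) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

#' Check the structural invariants of a molecule graph
#'
#' Violations are data, not exceptions: the result is a tibble with one row
#' per broken rule (empty for a well-formed molecule). Checked rules: element
#' tokens non-empty; unpaired and explicit virtual-hydrogen counts
#' non-negative; at most one isotope and one abbreviation extension per atom;
#' bond endpoints distinct and within range; bond order in 0..5; stereo type
#' recognized; no duplicate bond between the same unordered atom pair.
#'
#' @param mol Any molecule-shaped object.
#' @return A tibble with columns `kind` ("atom"/"bond"), `index`, `rule`,
#'   `message`.
#' @export
check_graph <- function(mol) {
  rows <- list()
  note <- function(kind, index, rule, message) {
    rows[[length(rows) + 1L]] <<- tibble(
      kind = kind, index = as.integer(index), rule = rule, message = message)
  }
  n <- n_atoms(mol)
  for (i in seq_len(n)) {
    a <- mol$atoms[[i]]
    if (!nzchar(a$element)) note("atom", i, "element_empty", "element token is empty")
    if (is.na(a$unpaired) || a$unpaired < 0)
      note("atom", i, "unpaired_negative", "unpaired electron count must be >= 0")
    if (!is.na(a$hydrogens) && a$hydrogens < 0)
      note("atom", i, "hydrogens_negative", "explicit virtual hydrogens must be >= 0")
    if (length(ext_with_prefix(a$extensions, "a:")) > 1)
      note("atom", i, "multiple_abbreviations", "more than one abbreviation extension")
    if (length(ext_with_prefix(a$extensions, "i:")) > 1)
      note("atom", i, "multiple_isotopes", "more than one isotope extension")
  }
  seen_pairs <- character()
  for (j in seq_len(n_bonds(mol))) {
    b <- mol$bonds[[j]]
    if (b$from < 1 || b$from > n || b$to < 1 || b$to > n) {
      note("bond", j, "index_out_of_range",
           sprintf("bond references atom outside 1..%d", n))
      next
    }
    if (b$from == b$to)
      note("bond", j, "self_bond", "bond connects an atom to itself")
    if (!b$order %in% 0:5)
      note("bond", j, "order_out_of_range",
           sprintf("bond order %d outside 0..5", b$order))
    if (!b$stereo %in% STEREO_TYPES)
      note("bond", j, "stereo_unknown_type",
           sprintf("unrecognized stereo type '%s'", b$stereo))
    key <- paste(sort(c(b$from, b$to)), collapse = "-")
    if (key %in% seen_pairs)
      note("bond", j, "duplicate_bond",
           sprintf("duplicate bond between atoms %s", key))
    seen_pairs <- c(seen_pairs, key)
  }
  if (length(rows) == 0) {
    tibble(kind = character(), index = integer(), rule = character(),
           message = character())
  } else {
    dplyr::bind_rows(rows)
  }
}

#' Structural molecule equality
#'
#' Field-by-field value equality, order-sensitive for atom and bond lists and
#' for extension-token lists. This is the equality the round-trip guarantees
#' are stated in; the default coordinate tolerance is half the last digit of
#' the serialization's fixed 4-decimal precision, so a molecule is equal to
#' its parsed-back serialization.
#'
#' @param a,b Molecules.
#' @param tol Coordinate tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
mol_equal <- function(a, b, tol = 5e-5) {
  if (n_atoms(a) != n_atoms(b) || n_bonds(a) != n_bonds(b)) return(FALSE)
  for (i in seq_len(n_atoms(a))) {
    x <- a$atoms[[i]]; y <- b$atoms[[i]]
    if (!identical(x$element, y$element)) return(FALSE)
    if (abs(x$x - y$x) > tol || abs(x$y - y$y) > tol) return(FALSE)
    if (x$charge != y$charge || x$unpaired != y$unpaired) return(FALSE)
    if (!identical(is.na(x$hydrogens), is.na(y$hydrogens))) return(FALSE)
    if (!is.na(x$hydrogens) && x$hydrogens != y$hydrogens) return(FALSE)
    if (!identical(x$extensions, y$extensions)) return(FALSE)
  }
  for (j in seq_len(n_bonds(a))) {
    x <- a$bonds[[j]]; y <- b$bonds[[j]]
    if (x$from != y$from || x$to != y$to || x$order != y$order) return(FALSE)
    if (!identical(x$stereo, y$stereo)) return(FALSE)
    if (!identical(x$extensions, y$extensions)) return(FALSE)
  }
  TRUE
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms, %d bonds>\n", n_atoms(x), n_bonds(x)))
  for (i in seq_len(n_atoms(x))) {
    a <- x$atoms[[i]]
    h <- if (is.na(a$hydrogens)) "auto" else as.character(a$hydrogens)
    ext <- if (length(a$extensions)) paste0(" [", paste(a$extensions, collapse = ","), "]") else ""
    cat(sprintf("  %2d %-3s (%.3f, %.3f) q=%+d u=%d H=%s%s\n",
                i, a$element, a$x, a$y, a$charge, a$unpaired, h, ext))
  }
  for (b in x$bonds) {
    cat(sprintf("  %d-%d order=%d stereo=%s\n", b$from, b$to, b$order, b$stereo))
  }
  invisible(x)
}

#' Atoms and bonds as tibbles
#'
#' Tabular views for inspection and tidy workflows; the list form remains the
#' source of truth.
#'
#' @param mol A [molecule()].
#' @return A tibble with one row per atom (or bond).
#' @export
atoms_tbl <- function(mol) {
  tibble(
    index = seq_len(n_atoms(mol)),
    element = vapply(mol$atoms, `[[`, character(1), "element"),
    x = vapply(mol$atoms, `[[`, numeric(1), "x"),
    y = vapply(mol$atoms, `[[`, numeric(1), "y"),
    charge = vapply(mol$atoms, `[[`, integer(1), "charge"),
    unpaired = vapply(mol$atoms, `[[`, integer(1), "unpaired"),
    hydrogens = vapply(mol$atoms, `[[`, integer(1), "hydrogens"),
    extensions = lapply(mol$atoms, `[[`, "extensions")
  )
}

#' @rdname atoms_tbl
#' @export
bonds_tbl <- function(mol) {
  tibble(
    index = seq_len(n_bonds(mol)),
    from = vapply(mol$bonds, `[[`, integer(1), "from"),
    to = vapply(mol$bonds, `[[`, integer(1), "to"),
    order = vapply(mol$bonds, `[[`, integer(1), "order"),
    stereo = vapply(mol$bonds, `[[`, character(1), "stereo"),
    extensions = lapply(mol$bonds, `[[`, "extensions")
  )
}
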
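# MDL Molfile V2000 interop: the deliberate "lowest common denominator"
# downstream conversion. Import freezes implicit hydrogens as explicit
# per-atom overrides (computed under a caller-chosen decision table), so the
# formula perceived at import time can never drift under later
# re-interpretation. Export downgrades everything the CTfile subset cannot
# carry and records each downgrade in a machine-readable loss report --
# irreversibility is made explicit instead of silent.

CHG_CODES <- c(`3` = 1L, `2` = 2L, `1` = 3L, `-1` = 5L, `-2` = 6L, `-3` = 7L)

molfile_err <- function(msg) abort(msg, class = "elnote_molfile_error")

numfield <- function(line, from, to, what, default = NA_real_) {
  s <- trimws(substr(line, from, to))
  if (!nzchar(s)) return(default)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) molfile_err(sprintf("non-numeric %s field: '%s'", what, s))
  v
}

new_finding <- function(severity, code, locator, message) {
  tibble(severity = severity, code = code, locator = locator, message = message)
}

empty_findings <- function() {
  tibble(severity = character(), code = character(), locator = character(),
         message = character())
}

#' Parse an MDL Molfile (V2000)
#'
#' Atoms, bonds, charges, isotopes, radicals and wedge codes are mapped onto
#' the core model; wedges are stored pictorially, never interpreted. Atom
#' labels that are not periodic-table symbols are kept as tokens and
#' flagged. Implicit hydrogens are materialized as explicit virtual-hydrogen
#' overrides computed under `hydrogen_mode` (or taken from an explicit
#' valence field), freezing the molecular formula at import time.
#'
#' @param text Molfile text (single string or lines).
#' @param hydrogen_mode `"legacy"` (default: emulate what permissive Molfile
#'   software perceives, e.g. H2SnCl2 from a bare SnCl2 sketch) or
#'   `"strict"`.
#' @return A list with elements `molecule` and `findings` (a tibble with
#'   columns severity, code, locator, message).
#' @export
parse_molfile <- function(text, hydrogen_mode = c("legacy", "strict")) {
  hydrogen_mode <- match.arg(hydrogen_mode)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  if (length(lines) < 4) molfile_err("truncated header block")
  counts <- lines[[4]]
  na <- suppressWarnings(as.integer(trimws(substr(counts, 1, 3))))
  nb <- suppressWarnings(as.integer(trimws(substr(counts, 4, 6))))
  if (is.na(na) || is.na(nb)) molfile_err("malformed counts line")
  if (length(lines) < 4 + na + nb) molfile_err("truncated connection table")

  mol <- molecule()
  findings <- list()
  valence_field <- rep(0L, na)
  for (i in seq_len(na)) {
    ln <- lines[[4 + i]]
    x <- numfield(ln, 1, 10, "x coordinate", 0)
    y <- numfield(ln, 11, 20, "y coordinate", 0)
    z <- numfield(ln, 21, 30, "z coordinate", 0)
    sym <- trimws(substr(ln, 32, 34))
    if (!nzchar(sym)) molfile_err(sprintf("atom %d has an empty symbol", i))
    chg_code <- as.integer(numfield(ln, 37, 39, "charge", 0))
    charge <- 0L
    unpaired <- 0L
    if (chg_code %in% c(1L, 2L, 3L, 5L, 6L, 7L)) {
      charge <- as.integer(names(CHG_CODES)[match(chg_code, CHG_CODES)])
    } else if (chg_code == 4L) {
      unpaired <- 1L
    }
    valence_field[i] <- as.integer(numfield(ln, 49, 51, "valence", 0))
    ext <- character()
    if (abs(z) > 1e-9) ext <- c(ext, paste0("z:", fmt_coord(z)))
    mol <- add_atom(mol, sym, x, y, charge, unpaired, NA_integer_, ext)
    if (!is_element(sym)) {
      findings[[length(findings) + 1L]] <- new_finding(
        "WARNING", "non_element_label", paste0("atom:", i),
        sprintf("atom label '%s' is not an element symbol", sym))
    }
  }
  for (j in seq_len(nb)) {
    ln <- lines[[4 + na + j]]
    from <- as.integer(numfield(ln, 1, 3, "bond from"))
    to <- as.integer(numfield(ln, 4, 6, "bond to"))
    order <- as.integer(numfield(ln, 7, 9, "bond order", 1))
    scode <- as.integer(numfield(ln, 10, 12, "bond stereo", 0))
    if (is.na(from) || is.na(to)) molfile_err(sprintf("bond %d lacks atom indices", j))
    stereo <- switch(as.character(scode), `1` = "inclined", `6` = "declined",
                     `4` = "unknown", "flat")
    mol <- add_bond(mol, from, to, order, stereo)
  }

  # properties block: M CHG / M ISO / M RAD supersede atom-line codes
  prop_lines <- lines[seq(4 + na + nb + 1, length.out = max(0, length(lines) - 4 - na - nb))]
  saw_chg <- FALSE
  saw_rad <- FALSE
  pending_chg <- list(); pending_rad <- list()
  for (ln in prop_lines) {
    tag <- substr(ln, 1, 6)
    if (tag == "M  END") break
    if (!tag %in% c("M  CHG", "M  ISO", "M  RAD")) next
    body <- substring(ln, 7)
    toks <- suppressWarnings(as.integer(strsplit(trimws(body), "\\s+")[[1]]))
    if (length(toks) < 1 || anyNA(toks)) molfile_err(sprintf("malformed property line '%s'", ln))
    k <- toks[[1]]
    pairs <- toks[-1]
    if (length(pairs) != 2 * k) molfile_err(sprintf("property count mismatch in '%s'", ln))
    for (p in seq_len(k)) {
      ai <- pairs[[2 * p - 1L]]; val <- pairs[[2 * p]]
      if (ai < 1 || ai > na) molfile_err("property references missing atom")
      if (tag == "M  CHG") { saw_chg <- TRUE; pending_chg[[length(pending_chg) + 1L]] <- c(ai, val) }
      if (tag == "M  ISO") mol <- set_isotope(mol, ai, val)
      if (tag == "M  RAD") { saw_rad <- TRUE; pending_rad[[length(pending_rad) + 1L]] <- c(ai, val) }
    }
  }
  if (saw_chg) {
    for (i in seq_len(na)) mol <- set_atom(mol, i, charge = 0L)
    for (pc in pending_chg) mol <- set_atom(mol, pc[[1]], charge = pc[[2]])
  }
  if (saw_rad) {
    for (i in seq_len(na)) mol <- set_atom(mol, i, unpaired = 0L)
    for (pr in pending_rad) {
      mol <- set_atom(mol, pr[[1]],
                      unpaired = switch(as.character(pr[[2]]), `2` = 1L, `3` = 2L, 0L))
    }
  }

  # freeze hydrogens: valence field wins, otherwise the chosen decision table
  for (i in seq_len(na)) {
    occ <- atom_occupied(mol, i)
    h <- if (valence_field[i] > 0L) {
      total <- if (valence_field[i] == 15L) 0L else valence_field[i]
      max(0L, total - occ)
    } else {
      implicit_hydrogen_count(mol, i, hydrogen_mode)
    }
    mol <- set_atom(mol, i, hydrogens = as.integer(h))
  }

  findings <- if (length(findings)) dplyr::bind_rows(findings) else empty_findings()
  list(molecule = mol, findings = findings)
}

empty_loss <- function() {
  tibble(locator = character(), code = character(), note = character())
}

#' Write an MDL Molfile (V2000) with a loss report
#'
#' Abbreviations are expanded fully first. Charges are emitted via `M  CHG`,
#' isotopes via `M  ISO`, radicals via `M  RAD`; explicit virtual-hydrogen
#' counts that disagree with the legacy valence model are emitted through the
#' atom valence field (15 encodes zero), computed against the bond orders as
#' *written*, so a legacy re-import reproduces the frozen hydrogen counts.
#' Everything the CTfile lowest-common-denominator subset cannot carry is
#' downgraded and recorded: zero-order bonds are written as single bonds,
#' bond orders 4-5 as single bonds, query extensions, mapping numbers,
#' abbreviation expansions and unknown extensions are noted. The loss report
#' is empty exactly when the conversion is invertible for that molecule.
#'
#' @param mol A [molecule()].
#' @param title Optional title for line 1 of the header.
#' @return A list with elements `text` (the Molfile) and `loss` (a tibble
#'   with columns locator, code, note).
#' @export
write_molfile <- function(mol, title = "") {
  loss <- list()
  note_loss <- function(locator, code, note) {
    loss[[length(loss) + 1L]] <<- tibble(locator = locator, code = code, note = note)
  }
  for (i in seq_len(n_atoms(mol))) {
    if (has_abbrev(mol, i))
      note_loss(paste0("atom:", i), "abbreviation_expanded",
                sprintf("inline abbreviation '%s' expanded; definition not exported",
                        atom_element(mol, i)))
  }
  mol <- expand_fully(mol)
  na <- n_atoms(mol); nb <- n_bonds(mol)
  for (i in seq_len(na)) {
    a <- mol$atoms[[i]]
    if (!is_element(a$element))
      molfile_err(sprintf(
        "cannot export atom %d: token '%s' is neither an element nor an abbreviation",
        i, a$element))
    for (e in a$extensions) {
      if (startsWith(e, "q:"))
        note_loss(paste0("atom:", i), "query_extension", e)
      else if (startsWith(e, "n:"))
        note_loss(paste0("atom:", i), "mapping_number", e)
      else if (!startsWith(e, "z:") && !startsWith(e, "i:"))
        note_loss(paste0("atom:", i), "unknown_extension", e)
    }
    if (a$unpaired > 2L)
      note_loss(paste0("atom:", i), "unpaired_electrons",
                sprintf("unpaired count %d exceeds the radical codes", a$unpaired))
  }

  written_order <- integer(nb)
  for (j in seq_len(nb)) {
    b <- mol$bonds[[j]]
    written_order[j] <- b$order
    if (b$order == 0L) {
      written_order[j] <- 1L
      note_loss(paste0("bond:", j), "zero_order_bond",
                "zero-order bond written as single bond")
    } else if (b$order %in% c(4L, 5L)) {
      written_order[j] <- 1L
      note_loss(paste0("bond:", j), "high_order_bond",
                sprintf("bond order %d written as single bond", b$order))
    }
    for (e in b$extensions) {
      if (startsWith(e, "q:"))
        note_loss(paste0("bond:", j), "query_extension", e)
      else
        note_loss(paste0("bond:", j), "unknown_extension", e)
    }
  }

  # occupied valence under the orders as written (plus surviving radicals)
  occ_written <- integer(na)
  for (j in seq_len(nb)) {
    b <- mol$bonds[[j]]
    occ_written[b$from] <- occ_written[b$from] + written_order[j]
    occ_written[b$to] <- occ_written[b$to] + written_order[j]
  }

  out <- c(title, "  elnote  2D", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  chg <- list(); iso <- list(); rad <- list()
  for (i in seq_len(na)) {
    a <- mol$atoms[[i]]
    zc <- get_atom_ext(mol, i, "z:")
    z <- if (is.null(zc)) 0 else as.numeric(zc)
    unp <- min(a$unpaired, 2L)
    occ <- occ_written[i] + unp
    h_eff <- implicit_hydrogen_count(mol, i, "strict")
    legacy_here <- {
      allowed <- adjusted_valences(a$element, a$charge, LEGACY_VALENCES)
      fits <- allowed[allowed >= occ]
      if (length(fits) == 0) 0L else as.integer(min(fits) - occ)
    }
    val <- 0L
    if (h_eff != legacy_here) {
      total <- occ + h_eff
      val <- if (total == 0L) 15L else total
    }
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0%3d  0  0  0  0  0  0",
                          a$x, a$y, z, a$element, val))
    if (a$charge != 0L) chg[[length(chg) + 1L]] <- c(i, a$charge)
    if (atom_isotope(mol, i) != 0L) iso[[length(iso) + 1L]] <- c(i, atom_isotope(mol, i))
    if (unp > 0L) rad[[length(rad) + 1L]] <- c(i, if (unp == 1L) 2L else 3L)
  }
  scode <- c(flat = 0L, inclined = 1L, declined = 6L, unknown = 4L)
  for (j in seq_len(nb)) {
    b <- mol$bonds[[j]]
    out <- c(out, sprintf("%3d%3d%3d%3d  0  0  0", b$from, b$to,
                          written_order[j], scode[[b$stereo]]))
  }
  prop_block <- function(tag, entries) {
    res <- character()
    while (length(entries) > 0) {
      take <- utils::head(entries, 8)
      entries <- entries[-seq_along(take)]
      res <- c(res, paste0(tag, sprintf("%3d", length(take)),
                           paste(vapply(take, function(e)
                             sprintf("%4d%4d", e[[1]], e[[2]]), character(1)),
                             collapse = "")))
    }
    res
  }
  out <- c(out, prop_block("M  CHG", chg), prop_block("M  ISO", iso),
           prop_block("M  RAD", rad), "M  END")
  loss <- if (length(loss)) dplyr::bind_rows(loss) else empty_loss()
  list(text = paste0(paste(out, collapse = "\n"), "\n"), loss = loss)
}
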
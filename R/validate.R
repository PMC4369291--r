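# The machine-first gate: parse, detect entries with zero or more than one
# possible interpretation, report, and reject. Hard errors block; everything
# else is advisory -- the originating scientist is always the final arbiter,
# so chemically suspicious but representable structures (pentavalent carbon,
# covalent Na-Cl) warn rather than block, and the gate never mutates its
# input: proactive "fixing" of structures does more harm than good.

#' Classify a record as molecule, template or query
#'
#' A record whose atom tokens include a placeholder (`X`, `R`, or `R` plus
#' digits, case-sensitive) without an inline abbreviation encodes a family
#' of molecules -- a template. A record carrying query extensions is a
#' query. Everything else is a molecule.
#'
#' @param mol A [molecule()].
#' @return `"MOLECULE"`, `"TEMPLATE"` or `"QUERY"`.
#' @export
classify_entry <- function(mol) {
  for (i in seq_len(n_atoms(mol))) {
    if (grepl(placeholder_rx, atom_element(mol, i)) && !has_abbrev(mol, i))
      return("TEMPLATE")
  }
  for (a in mol$atoms) if (has_query_ext(a)) return("QUERY")
  for (b in mol$bonds) if (has_query_ext(b)) return("QUERY")
  "MOLECULE"
}

#' Validate a molecule entry
#'
#' Produces findings, never exceptions, in a stable order (by rule class,
#' then atom/bond index). ERROR findings mean the entry has no sound
#' machine interpretation and will be rejected by [gate_entry()]:
#' uninterpretable non-element labels, or placeholder templates submitted
#' where a single species is required. WARNING findings flag likely mistakes
#' with legitimate exceptions (hypervalent atoms -- carboranes are real;
#' covalent alkali-halide bonds; pentavalent neutral nitro groups; bare
#' metals whose open valence admits divergent readings unless pinned by an
#' explicit hydrogen count, unpaired-electron count or charge). INFO notes a
#' non-zero net charge on a single-component entry.
#'
#' @param mol A [molecule()].
#' @param mode Hydrogen decision table used for valence advice
#'   (`"strict"` default).
#' @return A tibble with columns `severity`, `code`, `locator`, `message`.
#' @export
validate_molecule <- function(mol, mode = "strict") {
  rows <- list()
  note <- function(severity, code, locator, message) {
    rows[[length(rows) + 1L]] <<- new_finding(severity, code, locator, message)
  }
  n <- n_atoms(mol)

  for (i in seq_len(n)) {
    el <- atom_element(mol, i)
    if (is_element(el) || has_abbrev(mol, i)) next
    if (grepl(placeholder_rx, el)) {
      note("ERROR", "template_requires_enumeration", paste0("atom:", i),
           sprintf(paste0("placeholder '%s' encodes a family of molecules; ",
                          "supply an enumeration recipe before submission"), el))
    } else {
      note("ERROR", "uninterpretable_label", paste0("atom:", i),
           sprintf("'%s' is not an element and has no inline abbreviation", el))
    }
  }

  nitro_flagged <- integer()
  for (i in seq_len(n)) {
    a <- mol$atoms[[i]]
    if (a$element == "N" && a$charge == 0L && is.na(a$hydrogens)) {
      occ <- atom_occupied(mol, i)
      nbrs <- atom_neighbours(mol, i)
      n_ox <- sum(vapply(nbrs, function(w) atom_element(mol, w) == "O", logical(1)))
      if (occ >= 5L && n_ox >= 2L) {
        nitro_flagged <- c(nitro_flagged, i)
        note("WARNING", "pentavalent_nitro", paste0("atom:", i),
             "neutral pentavalent nitro group; the charge-separated form is the machine-readable one")
      }
    }
  }

  for (i in seq_len(n)) {
    a <- mol$atoms[[i]]
    if (i %in% nitro_flagged) next
    allowed <- adjusted_valences(a$element, a$charge,
                                 if (identical(mode, "legacy")) LEGACY_VALENCES else STRICT_VALENCES)
    if (length(allowed) == 0) next
    occ <- atom_occupied(mol, i)
    if (occ > max(allowed)) {
      note("WARNING", "hypervalent_atom", paste0("atom:", i),
           sprintf("occupied valence %d exceeds the maximum %d allowed for %s (real exceptions exist: verify, do not auto-fix)",
                   occ, max(allowed), a$element))
    }
  }

  for (j in seq_len(n_bonds(mol))) {
    b <- mol$bonds[[j]]
    if (b$order < 1L) next
    e1 <- atom_element(mol, b$from); e2 <- atom_element(mol, b$to)
    if ((e1 %in% ALKALI_METALS && e2 %in% HALOGENS) ||
        (e2 %in% ALKALI_METALS && e1 %in% HALOGENS)) {
      note("WARNING", "covalent_alkali_halide", paste0("bond:", j),
           sprintf("covalently bound salt %s-%s; ionic components are usually intended", e1, e2))
    }
  }

  for (i in seq_len(n)) {
    a <- mol$atoms[[i]]
    if (a$element %in% c("H", names(STRICT_VALENCES))) next
    if (!is.null(LEGACY_VALENCES[[a$element]]) && is.na(a$hydrogens) &&
        a$unpaired == 0L && a$charge == 0L &&
        atom_occupied(mol, i) < min(LEGACY_VALENCES[[a$element]])) {
      note("WARNING", "ambiguous_metal_valence", paste0("atom:", i),
           sprintf(paste0("%s with open valence admits more than one reading; pin it down ",
                          "with an explicit hydrogen count, unpaired electrons or a charge"),
                   a$element))
    }
  }

  if (n > 0 && length(unique(connected_components(mol))) == 1L &&
      net_formal_charge(mol) != 0L) {
    note("INFO", "net_charge_nonzero", "molecule",
         sprintf("single-component entry with net charge %+d", net_formal_charge(mol)))
  }

  if (length(rows) == 0) empty_findings() else dplyr::bind_rows(rows)
}

#' Accept or reject an entry
#'
#' The workflow gate: an entry with zero sound interpretations (any ERROR
#' finding across all molecules or cells) is rejected with the findings that
#' say why; otherwise it is accepted, carrying residual warnings for display
#' alongside the computed formula -- the real-time feedback loop for the
#' person entering the data.
#'
#' @param payload A [molecule()] or a [datasheet()].
#' @param mode Hydrogen decision table for valence advice.
#' @return A list of class `gate_result` with elements `status` (`"ACCEPT"`
#'   or `"REJECT"`), `findings` (tibble) and, on acceptance, `formulas`
#'   (character vector of formula strings, one per molecule checked).
#' @export
gate_entry <- function(payload, mode = "strict") {
  findings <- list()
  mols <- list()
  if (is.molecule(payload)) {
    f <- validate_molecule(payload, mode)
    if (nrow(f) > 0) findings[[1]] <- f
    mols[["molecule"]] <- payload
  } else if (is.datasheet(payload)) {
    for (r in seq_len(ds_nrow(payload))) {
      for (k in seq_len(ds_ncol(payload))) {
        if (payload$columns$type[[k]] != "molecule") next
        cellmol <- payload$rows[[r]][[k]]
        if (is.null(cellmol)) next
        f <- validate_molecule(cellmol, mode)
        if (nrow(f) > 0) {
          f$locator <- sprintf("row:%d/col:%s/%s", r,
                               payload$columns$name[[k]], f$locator)
          findings[[length(findings) + 1L]] <- f
        }
        mols[[sprintf("row:%d/col:%s", r, payload$columns$name[[k]])]] <- cellmol
      }
    }
  } else {
    abort("gate_entry() accepts a molecule or a datasheet")
  }
  findings <- if (length(findings)) dplyr::bind_rows(findings) else empty_findings()
  status <- if (any(findings$severity == "ERROR")) "REJECT" else "ACCEPT"
  formulas <- NULL
  if (status == "ACCEPT") {
    formulas <- vapply(mols, function(m)
      formula_to_string(molecular_formula(m, mode = mode)), character(1))
  }
  structure(list(status = status, findings = findings, formulas = formulas),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(x$status, "\n", sep = "")
  if (nrow(x$findings) > 0) {
    for (i in seq_len(nrow(x$findings))) {
      cat(sprintf("  [%s] %s (%s): %s\n", x$findings$severity[[i]],
                  x$findings$code[[i]], x$findings$locator[[i]],
                  x$findings$message[[i]]))
    }
  }
  if (!is.null(x$formulas)) {
    for (nm in names(x$formulas)) cat(sprintf("  %s: %s\n", nm, x$formulas[[nm]]))
  }
  invisible(x)
}

#' Enumerate the species a template encodes
#'
#' Every placeholder atom is substituted by each of its candidate fragments
#' (Cartesian product over placeholder sites), grafted with the shared
#' splice semantics; duplicates -- graph-isomorphic results with identical
#' atom attributes -- are removed. Each result classifies as a molecule.
#'
#' @param template A [molecule()] that classifies as `TEMPLATE`.
#' @param substitutions Named list: placeholder label -> list of fragment
#'   molecules (each with one `"*"` attachment atom).
#' @return List of [molecule()] objects, in product order with duplicates
#'   dropped.
#' @export
enumerate_template <- function(template, substitutions) {
  labels <- vapply(template$atoms, `[[`, character(1), "element")
  sites <- which(grepl(placeholder_rx, labels) &
                   !vapply(seq_along(labels), has_abbrev, logical(1),
                           mol = template))
  if (length(sites) == 0) return(list(template))
  for (lab in unique(labels[sites])) {
    opts <- substitutions[[lab]]
    if (is.null(opts) || length(opts) == 0)
      abort(sprintf("no substitution list for placeholder '%s'", lab))
  }
  # product over sites, substituting from highest index down so earlier
  # site indices stay valid
  grid <- expand.grid(lapply(sites, function(s)
    seq_along(substitutions[[labels[[s]]]])), KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (g in seq_len(nrow(grid))) {
    mol <- template
    for (si in order(sites, decreasing = TRUE)) {
      s <- sites[[si]]
      frag <- substitutions[[labels[[s]]]][[grid[g, si]]]
      mol <- splice_fragment(mol, s, frag)
    }
    dup <- any(vapply(out, function(m) mol_isomorphic(m, mol), logical(1)))
    if (!dup) out[[length(out) + 1L]] <- mol
  }
  out
}
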
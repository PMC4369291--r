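#' Molecular formula map
#'
#' A `formula_map` holds element(+isotope) counts plus the ordered list of
#' uninterpretable label strings encountered while counting. Isotope-tagged
#' atoms are counted under their own (element, mass) key; mass 0 means
#' natural abundance. Counts are always positive; absent keys mean zero.
#'
#' @param counts Tibble with columns `element`, `isotope`, `count`.
#' @param unknown_labels Character vector, first-encounter drawing order.
#' @return An object of class `formula_map`.
#' @export
formula_map <- function(counts = NULL, unknown_labels = character()) {
  if (is.null(counts)) {
    counts <- tibble(element = character(), isotope = integer(),
                     count = integer())
  }
  counts <- counts[counts$count > 0, , drop = FALSE]
  counts <- counts[order(hill_rank(counts$element), counts$element,
                         counts$isotope), , drop = FALSE]
  structure(list(counts = counts, unknown_labels = unknown_labels),
            class = "formula_map")
}

# Hill convention: with carbon present, C then H then the rest
# alphabetically; without carbon, everything (hydrogen included) is
# alphabetical
hill_rank <- function(element) {
  if (!"C" %in% element) return(rep(2L, length(element)))
  ifelse(element == "C", 0L, ifelse(element == "H", 1L, 2L))
}

#' Compute the molecular formula of a molecule
#'
#' Answers the machine-first litmus question "can an algorithm correctly and
#' unambiguously determine the molecular formula?". Explicit atoms are
#' counted under their (element, isotope) key; implicit hydrogens are added
#' per the decision table (see [implicit_hydrogen_count()]); atoms whose
#' element token is not a periodic-table symbol are either expanded (when
#' they carry an inline abbreviation and `expand_abbreviations` is set) or
#' appended verbatim to the unknown-labels list -- the formula is honest
#' about what it could not interpret.
#'
#' @param mol A [molecule()].
#' @param expand_abbreviations Expand inline abbreviations before counting?
#' @param mode Hydrogen decision table, `"strict"` (default) or `"legacy"`.
#' @param overrides Valence-table overrides, see [implicit_hydrogen_count()].
#' @return A [formula_map()].
#' @export
#' @examples
#' cp <- build_fixture("cyclopentane_misdrawn")
#' formula_to_string(molecular_formula(cp))  # "C5H10"
molecular_formula <- function(mol, expand_abbreviations = TRUE,
                              mode = "strict", overrides = NULL) {
  if (expand_abbreviations) mol <- expand_fully(mol)
  counts <- list()
  bump <- function(element, isotope, by) {
    key <- paste0(element, "#", isotope)
    counts[[key]] <<- (counts[[key]] %||% 0L) + as.integer(by)
  }
  unknown <- character()
  for (i in seq_len(n_atoms(mol))) {
    a <- get_atom(mol, i)
    if (is_element(a$element)) {
      bump(a$element, atom_isotope(mol, i), 1L)
    } else {
      unknown <- c(unknown, a$element)
    }
    h <- implicit_hydrogen_count(mol, i, mode, overrides)
    if (h > 0) bump("H", 0L, h)
  }
  if (length(counts) == 0) return(formula_map(unknown_labels = unknown))
  keys <- names(counts)
  element <- sub("#.*$", "", keys)
  isotope <- as.integer(sub("^.*#", "", keys))
  formula_map(
    tibble(element = element, isotope = isotope,
           count = as.integer(unlist(counts, use.names = FALSE))),
    unknown_labels = unknown
  )
}

#' Render a formula map as a Hill-order string
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically.
#' Isotope-tagged counts render as a bracketed mass-prefixed element, e.g.
#' `[2H]4`, placed in their element's Hill slot after the natural-abundance
#' count. Uninterpretable labels are appended in drawing order, each in
#' square brackets.
#'
#' @param f A [formula_map()].
#' @return A single string; `""` for an empty map.
#' @export
formula_to_string <- function(f) {
  stopifnot(inherits(f, "formula_map"))
  cnt <- f$counts
  parts <- character()
  for (i in seq_len(nrow(cnt))) {
    n <- cnt$count[i]
    num <- if (n == 1) "" else as.character(n)
    sym <- if (cnt$isotope[i] == 0) cnt$element[i] else
      sprintf("[%d%s]", cnt$isotope[i], cnt$element[i])
    parts <- c(parts, paste0(sym, num))
  }
  paste0(paste(parts, collapse = ""),
         paste0(vapply(f$unknown_labels, function(u) paste0("[", u, "]"),
                       character(1)), collapse = ""))
}

#' Total hydrogen count of a formula (all isotopes)
#'
#' @param f A [formula_map()].
#' @param isotopes Include isotope-tagged hydrogen (deuterium, tritium)?
#' @return Non-negative integer.
#' @export
formula_hydrogens <- function(f, isotopes = TRUE) {
  cnt <- f$counts
  keep <- cnt$element == "H" & (isotopes | cnt$isotope == 0)
  as.integer(sum(cnt$count[keep]))
}

#' Count of one (element, isotope) key
#'
#' @param f A [formula_map()].
#' @param element Element symbol.
#' @param isotope Mass number, 0 for natural abundance.
#' @return Non-negative integer.
#' @export
formula_count <- function(f, element, isotope = 0L) {
  cnt <- f$counts
  hit <- cnt$element == element & cnt$isotope == isotope
  if (any(hit)) as.integer(cnt$count[hit][1]) else 0L
}

#' Are two formula maps equal?
#'
#' Counts are compared as sets of (element, isotope, count); unknown labels
#' are compared as multisets -- their stored order is drawing order, which
#' is display metadata, not chemistry.
#'
#' @param a,b [formula_map()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
formula_equal <- function(a, b) {
  identical(a$counts$element, b$counts$element) &&
    identical(a$counts$isotope, b$counts$isotope) &&
    identical(a$counts$count, b$counts$count) &&
    identical(sort(a$unknown_labels), sort(b$unknown_labels))
}

#' @export
print.formula_map <- function(x, ...) {
  cat(formula_to_string(x), "\n")
  invisible(x)
}

#' @export
format.formula_map <- function(x, ...) formula_to_string(x)

#' @exportS3Method tibble::as_tibble
as_tibble.formula_map <- function(x, ...) x$counts
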
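# Graph isomorphism for duplicate removal during template enumeration.
# Atom colours combine element, charge, unpaired count, explicit hydrogens
# and isotope; colours are sharpened by iterative refinement over neighbour
# multisets, then a refinement-guided backtracking search finds a full
# match. The graphs involved are tiny (enumerated species), so worst-case
# behaviour is acceptable.

atom_colour0 <- function(mol) {
  vapply(seq_len(n_atoms(mol)), function(i) {
    a <- mol$atoms[[i]]
    h <- if (is.na(a$hydrogens)) "A" else as.character(a$hydrogens)
    paste(a$element, a$charge, a$unpaired, h, atom_isotope(mol, i), sep = "|")
  }, character(1))
}

bond_lookup <- function(mol) {
  n <- n_atoms(mol)
  ords <- matrix(NA_integer_, n, n)
  for (b in mol$bonds) {
    ords[b$from, b$to] <- b$order
    ords[b$to, b$from] <- b$order
  }
  ords
}

refine_colours <- function(mol, col) {
  n <- n_atoms(mol)
  ords <- bond_lookup(mol)
  repeat {
    # colours stay full strings so they compare across molecules; the graphs
    # involved are tiny, so string growth over <= n rounds is immaterial
    nxt <- vapply(seq_len(n), function(i) {
      nbr <- which(!is.na(ords[i, ]))
      sig <- sort(paste0(ords[i, nbr], ":", col[nbr]))
      paste(col[[i]], paste(sig, collapse = ","), sep = "||")
    }, character(1))
    old_parts <- length(unique(col))
    col <- nxt
    if (length(unique(col)) == old_parts) return(col)
  }
}

#' Are two molecules graph-isomorphic?
#'
#' Attribute-preserving graph isomorphism (element, charge, unpaired,
#' explicit-hydrogen and isotope labels on atoms; order on bonds).
#' Coordinates, stereo and extension tokens are not compared -- this is the
#' "same chemical species" equality used to drop duplicates in template
#' enumeration.
#'
#' @param a,b Molecules.
#' @return `TRUE` or `FALSE`.
#' @export
mol_isomorphic <- function(a, b) {
  n <- n_atoms(a)
  if (n != n_atoms(b) || n_bonds(a) != n_bonds(b)) return(FALSE)
  if (n == 0) return(TRUE)
  ca <- refine_colours(a, atom_colour0(a))
  cb <- refine_colours(b, atom_colour0(b))
  if (!identical(sort(ca), sort(cb))) return(FALSE)
  la <- bond_lookup(a); lb <- bond_lookup(b)
  # backtracking: map atoms of a onto b, most-constrained colour first
  colour_sizes <- table(ca)
  order_a <- order(as.integer(colour_sizes[ca]), ca)
  assign_b <- rep(NA_integer_, n)  # a index -> b index
  used_b <- rep(FALSE, n)
  match_from <- function(k) {
    if (k > n) return(TRUE)
    i <- order_a[[k]]
    for (j in which(!used_b & cb == ca[[i]])) {
      ok <- TRUE
      for (kk in seq_len(k - 1L)) {
        ii <- order_a[[kk]]
        if (!identical(la[i, ii], lb[j, assign_b[[ii]]])) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_b[[i]] <<- j; used_b[[j]] <<- TRUE
      if (match_from(k + 1L)) return(TRUE)
      assign_b[[i]] <<- NA_integer_; used_b[[j]] <<- FALSE
    }
    FALSE
  }
  match_from(1L)
}
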
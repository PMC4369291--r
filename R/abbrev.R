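# Inline abbreviations: a placeholder node (e.g. "Ph", "Et") carries its
# defining fragment inside the same record, so the label is never a lookup
# into somebody else's dictionary. The fragment is a molecule containing
# exactly one attachment pseudo-atom (element token "*") bonded to exactly
# one fragment atom; on expansion the pseudo-atom is deleted and the bond to
# the placeholder reattaches there. Definitions may nest recursively;
# definition cycles are an error.

ATTACHMENT_TOKEN <- "*"

attachment_index <- function(frag) {
  which(vapply(frag$atoms, function(a) a$element == ATTACHMENT_TOKEN, logical(1)))
}

#' Inline-abbreviation accessors
#'
#' The abbreviation extension token (`a:` prefix) stores the defining
#' fragment serialized in the molecule dialect and escaped. `atom_abbrev()`
#' decodes it (or returns `NULL`); `set_abbrev()` validates the fragment --
#' exactly one attachment pseudo-atom (`"*"`), itself bonded exactly once,
#' and a clean [check_graph()] -- before attaching it.
#'
#' @param mol A [molecule()].
#' @param idx 1-based atom index.
#' @return `atom_abbrev()`: the fragment [molecule()] or `NULL`;
#'   `has_abbrev()`: logical; `set_abbrev()`: the modified molecule.
#' @export
atom_abbrev <- function(mol, idx) {
  payload <- get_atom_ext(mol, idx, "a:")
  if (is.null(payload)) return(NULL)
  parse_sketchel(payload)
}

#' @rdname atom_abbrev
#' @export
has_abbrev <- function(mol, idx) {
  !is.null(get_atom_ext(mol, idx, "a:"))
}

#' @rdname atom_abbrev
#' @param fragment Fragment [molecule()] with one `"*"` attachment atom.
#' @export
set_abbrev <- function(mol, idx, fragment) {
  ap <- attachment_index(fragment)
  if (length(ap) != 1)
    abort("abbreviation fragment must contain exactly one attachment atom '*'")
  if (atom_degree(fragment, ap) != 1)
    abort("the attachment atom must be bonded to exactly one fragment atom")
  bad <- check_graph(fragment)
  if (nrow(bad) > 0)
    abort(paste0("abbreviation fragment fails structural checks: ",
                 paste(unique(bad$rule), collapse = ", ")))
  set_atom_ext(mol, idx, "a:", write_sketchel(fragment))
}

# Replace placeholder atom `p` of `host` by `frag` (which carries one "*"
# attachment atom). The placeholder must be terminal: at most one incident
# bond. Fragment atoms are appended after the surviving host atoms, rigidly
# transformed so the reattached bond has length 1.5 and points away from the
# host neighbour. Shared by abbreviation expansion, SAR composition and
# template enumeration.
splice_fragment <- function(host, p, frag) {
  inc <- which(vapply(host$bonds, function(b) b$from == p || b$to == p, logical(1)))
  if (length(inc) > 1)
    abort(sprintf("atom %d is not terminal: %d bonds cross into it", p, length(inc)))
  ap <- attachment_index(frag)
  if (length(ap) != 1)
    abort("fragment must contain exactly one attachment atom '*'")
  fa <- atom_neighbours(frag, ap)
  if (length(fa) != 1)
    abort("the attachment atom must be bonded to exactly one fragment atom")
  host_nbr <- NA_integer_
  host_bond <- NULL
  if (length(inc) == 1) {
    host_bond <- host$bonds[[inc]]
    host_nbr <- if (host_bond$from == p) host_bond$to else host_bond$from
  }

  # rigid transform of fragment coordinates
  apos <- c(frag$atoms[[ap]]$x, frag$atoms[[ap]]$y)
  fpos <- c(frag$atoms[[fa]]$x, frag$atoms[[fa]]$y)
  v <- fpos - apos
  vn <- sqrt(sum(v^2))
  if (!is.na(host_nbr)) {
    npos <- c(host$atoms[[host_nbr]]$x, host$atoms[[host_nbr]]$y)
    ppos <- c(host$atoms[[p]]$x, host$atoms[[p]]$y)
    d <- ppos - npos
    dn <- sqrt(sum(d^2))
    d <- if (dn < 1e-9) c(1, 0) else d / dn
    target <- npos + 1.5 * d
    if (vn < 1e-9) {
      rot <- diag(2)
    } else {
      u <- v / vn
      # rotate u onto d
      cosr <- u[1] * d[1] + u[2] * d[2]
      sinr <- u[1] * d[2] - u[2] * d[1]
      rot <- matrix(c(cosr, sinr, -sinr, cosr), 2, 2)
    }
    xform <- function(pt) as.numeric(rot %*% (pt - fpos)) + target
  } else {
    ppos <- c(host$atoms[[p]]$x, host$atoms[[p]]$y)
    xform <- function(pt) pt - fpos + ppos
  }

  out <- delete_atom(host, p)
  base <- n_atoms(out)
  # map fragment index -> result index (attachment atom maps to NA)
  fmap <- rep(NA_integer_, n_atoms(frag))
  k <- 0L
  for (i in seq_len(n_atoms(frag))) {
    if (i == ap) next
    k <- k + 1L
    fmap[i] <- base + k
    fat <- frag$atoms[[i]]
    pt <- xform(c(fat$x, fat$y))
    out <- add_atom(out, fat$element, pt[1], pt[2], fat$charge, fat$unpaired,
                    fat$hydrogens, fat$extensions)
  }
  for (b in frag$bonds) {
    if (b$from == ap || b$to == ap) next
    out <- add_bond(out, fmap[b$from], fmap[b$to], b$order, b$stereo, b$extensions)
  }
  if (!is.na(host_nbr)) {
    nbr_new <- if (host_nbr > p) host_nbr - 1L else host_nbr
    out <- add_bond(out, nbr_new, fmap[fa], host_bond$order, host_bond$stereo,
                    host_bond$extensions)
  }
  out
}

#' Expand one abbreviation placeholder by one level
#'
#' The placeholder atom is replaced by its defining fragment; the bond into
#' the placeholder reattaches at the fragment's attachment point. Nested
#' abbreviations inside the fragment stay collapsed -- an Et3Si
#' meta-abbreviation expands first to a silicon atom carrying three "Et"
#' abbreviation nodes.
#'
#' @param mol A [molecule()].
#' @param idx Index of an atom carrying an abbreviation definition.
#' @return The expanded [molecule()].
#' @export
expand_one_level <- function(mol, idx) {
  frag <- atom_abbrev(mol, idx)
  if (is.null(frag))
    abort(sprintf("atom %d carries no abbreviation definition", idx))
  splice_fragment(mol, idx, frag)
}

#' Expand all abbreviations recursively
#'
#' Fixpoint of [expand_one_level()]: the result carries no abbreviation
#' extensions. Definitions may nest (an abbreviation may contain its own
#' abbreviations); a definition cycle raises an error naming the label chain.
#'
#' @param mol A [molecule()].
#' @return The fully expanded [molecule()].
#' @export
expand_fully <- function(mol) {
  # chains[i] records the stack of labels whose expansion produced atom i,
  # which is what detects definition cycles
  chains <- rep(list(character()), n_atoms(mol))
  repeat {
    idx <- NA_integer_
    for (i in seq_len(n_atoms(mol))) {
      if (has_abbrev(mol, i)) { idx <- i; break }
    }
    if (is.na(idx)) return(mol)
    label <- atom_element(mol, idx)
    chain <- chains[[idx]]
    if (label %in% chain) {
      abort(sprintf("cyclic abbreviation definition: %s",
                    paste(c(chain, label), collapse = " -> ")),
            class = "elnote_abbrev_cycle")
    }
    n_before <- n_atoms(mol)
    mol <- expand_one_level(mol, idx)
    added <- n_atoms(mol) - (n_before - 1L)
    chains <- c(chains[-idx], rep(list(c(chain, label)), added))
  }
}

#' Subsume a terminal fragment into a new abbreviation
#'
#' The selected atoms must form a connected fragment with exactly one bond
#' crossing into the rest of the molecule. They are replaced by a single
#' placeholder atom labelled `label` that carries the fragment (plus a
#' generated attachment point) as its inline definition, so
#' `expand_one_level()` of the result is formula-equal to the input.
#'
#' @param mol A [molecule()].
#' @param atom_indices Atoms to subsume (1-based).
#' @param label Display label for the new abbreviation (e.g. `"Ph"`).
#' @return The molecule with the fragment collapsed to one node.
#' @export
subsume_fragment <- function(mol, atom_indices, label) {
  atom_indices <- sort(unique(as.integer(atom_indices)))
  if (length(atom_indices) == 0) abort("empty selection")
  if (any(atom_indices < 1 | atom_indices > n_atoms(mol)))
    abort("selection outside atom range")
  inside <- seq_len(n_atoms(mol)) %in% atom_indices
  crossing <- which(vapply(mol$bonds, function(b)
    xor(inside[b$from], inside[b$to]), logical(1)))
  if (length(crossing) != 1)
    abort(sprintf(
      "fragment is not terminal: %d bonds cross into the remainder (need exactly 1)",
      length(crossing)))
  cb <- mol$bonds[[crossing]]
  in_end <- if (inside[cb$from]) cb$from else cb$to
  out_end <- if (inside[cb$from]) cb$to else cb$from

  # build the fragment: selected atoms plus a "*" attachment at the position
  # of the outside anchor, bonded to the inside end of the crossing bond
  frag <- molecule()
  fmap <- rep(NA_integer_, n_atoms(mol))
  for (i in atom_indices) {
    a <- mol$atoms[[i]]
    frag <- add_atom(frag, a$element, a$x, a$y, a$charge, a$unpaired,
                     a$hydrogens, a$extensions)
    fmap[i] <- n_atoms(frag)
  }
  for (b in mol$bonds) {
    if (inside[b$from] && inside[b$to]) {
      frag <- add_bond(frag, fmap[b$from], fmap[b$to], b$order, b$stereo,
                       b$extensions)
    }
  }
  oa <- mol$atoms[[out_end]]
  frag <- add_atom(frag, ATTACHMENT_TOKEN, oa$x, oa$y)
  frag <- add_bond(frag, n_atoms(frag), fmap[in_end], cb$order, cb$stereo)

  # connectivity check within the selection (attachment joins one side only)
  comp <- connected_components(frag)
  if (length(unique(comp)) != 1)
    abort("selected atoms do not form a connected fragment")

  # replace: placeholder sits where the inside anchor was
  ia <- mol$atoms[[in_end]]
  keep <- setdiff(seq_len(n_atoms(mol)), atom_indices)
  res <- molecule()
  rmap <- rep(NA_integer_, n_atoms(mol))
  for (i in keep) {
    a <- mol$atoms[[i]]
    res <- add_atom(res, a$element, a$x, a$y, a$charge, a$unpaired,
                    a$hydrogens, a$extensions)
    rmap[i] <- n_atoms(res)
  }
  res <- add_atom(res, label, ia$x, ia$y)
  ph <- n_atoms(res)
  res <- set_abbrev(res, ph, frag)
  for (b in mol$bonds) {
    if (!inside[b$from] && !inside[b$to]) {
      res <- add_bond(res, rmap[b$from], rmap[b$to], b$order, b$stereo,
                      b$extensions)
    }
  }
  res <- add_bond(res, rmap[out_end], ph, cb$order, cb$stereo)
  res
}
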
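# Coordinate generation for small generated fragments. Stored coordinates
# are authoritative everywhere else in the package -- 2D positions belong in
# the data -- so this is deliberately not a general-purpose layout engine:
# it covers acyclic fragments and single rings (the shapes that splicing and
# enumeration produce), placing rings on regular polygons and chains on a
# 120-degree zigzag, with every bond at the idealized length of 1.5
# quasi-Angstrom units.

ring_atoms <- function(mol) {
  # cycle space dimension per component; returns the unique cycle's atoms
  # when there is exactly one independent cycle, integer(0) for a forest,
  # NULL when the cycle structure is beyond scope
  n <- n_atoms(mol)
  m <- n_bonds(mol)
  ncomp <- length(unique(connected_components(mol)))
  extra <- m - n + ncomp
  if (extra == 0L) return(integer(0))
  if (extra > 1L) return(NULL)
  # prune leaves until only the cycle remains
  deg <- vapply(seq_len(n), atom_degree, integer(1), mol = mol)
  alive <- rep(TRUE, n)
  adj <- lapply(seq_len(n), atom_neighbours, mol = mol)
  repeat {
    leaf <- which(alive & deg <= 1L)
    if (length(leaf) == 0) break
    for (v in leaf) {
      alive[v] <- FALSE
      for (w in adj[[v]]) if (alive[w]) deg[w] <- deg[w] - 1L
      deg[v] <- 0L
    }
  }
  which(alive)
}

order_cycle <- function(mol, cyc) {
  # walk the cycle so consecutive entries are bonded
  out <- cyc[[1]]
  prev <- NA_integer_
  while (length(out) < length(cyc)) {
    nbrs <- intersect(atom_neighbours(mol, out[[length(out)]]), cyc)
    nxt <- setdiff(nbrs, c(prev, out))
    prev <- out[[length(out)]]
    out <- c(out, nxt[[1]])
  }
  out
}

#' Generate fresh 2D coordinates for a small fragment
#'
#' Every bond comes out at length 1.5 (to 1e-6), rings are placed on regular
#' polygons, chains zigzag at 120 degrees, and no two atoms coincide.
#' Intended for generated fragments that lack coordinates; molecules with
#' fused polycycles are out of scope and raise an error so the caller keeps
#' the original coordinates.
#'
#' @param mol A [molecule()] (chains and single rings of up to ~8 atoms).
#' @return The molecule with fresh coordinates.
#' @export
layout_fragment <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0) return(mol)
  cyc <- ring_atoms(mol)
  if (is.null(cyc))
    abort("layout_fragment() supports chains and single rings only",
          class = "elnote_layout_unsupported")
  pos <- matrix(NA_real_, n, 2)
  placed <- rep(FALSE, n)
  place <- function(i, xy) {
    pos[i, ] <<- xy
    placed[i] <<- TRUE
  }

  if (length(cyc) > 0) {
    cyc <- order_cycle(mol, cyc)
    k <- length(cyc)
    r <- 0.75 / sin(pi / k)
    for (t in seq_len(k)) {
      ang <- pi / 2 + 2 * pi * (t - 1) / k
      place(cyc[[t]], c(r * cos(ang), r * sin(ang)))
    }
  } else {
    place(1L, c(0, 0))
  }

  # grow trees outward from whatever is already placed, zigzagging;
  # candidate directions are the 12 clock angles, scored to continue a
  # 120-degree chain and to stay clear of occupied positions
  queue <- which(placed)
  zig <- 1
  while (length(queue) > 0 || any(!placed)) {
    if (length(queue) == 0) {
      # disconnected piece: drop it to the right of the bounding box
      seed <- which(!placed)[[1]]
      off <- max(pos[placed, 1]) + 3
      place(seed, c(off, 0))
      queue <- seed
    }
    v <- queue[[1]]; queue <- queue[-1]
    for (w in atom_neighbours(mol, v)) {
      if (placed[w]) next
      from <- pos[v, ]
      prev_dir <- NULL
      pn <- atom_neighbours(mol, v)
      pn <- pn[placed[pn]]
      if (length(pn) > 0) prev_dir <- atan2(from[2] - pos[pn[[1]], 2],
                                            from[1] - pos[pn[[1]], 1])
      cand <- (0:11) * pi / 6
      if (!is.null(prev_dir)) {
        zig <- -zig
        cand <- c(prev_dir + zig * pi / 6, prev_dir - zig * pi / 6, cand)
      } else if (v %in% cyc && length(cyc) > 0) {
        cand <- c(atan2(from[2], from[1]), cand)  # radially outward
      }
      for (ang in cand) {
        xy <- from + 1.5 * c(cos(ang), sin(ang))
        d <- sqrt(rowSums((pos[placed, , drop = FALSE] -
                             matrix(xy, sum(placed), 2, byrow = TRUE))^2))
        if (all(d > 0.5)) { place(w, xy); break }
      }
      if (!placed[w]) place(w, from + 1.5 * c(cos(stats::runif(1, 0, 2 * pi)),
                                              sin(stats::runif(1, 0, 2 * pi))))
      queue <- c(queue, w)
    }
  }
  for (i in seq_len(n)) mol <- set_atom(mol, i, x = pos[i, 1], y = pos[i, 2])
  mol
}
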
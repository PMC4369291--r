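# Independent brute-force oracle for the strict hydrogen decision table:
# restates the allowed-valence sets and finds, by exhaustive search over
# candidate hydrogen counts, the smallest h such that occupied + h lands on
# an allowed (charge-adjusted) valence. Kept deliberately separate from the
# package's closed-form arithmetic.
oracle_strict_h <- function(element, charge, occupied) {
  allowed <- switch(element,
                    C = 4L, N = 3L, O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
                    integer())
  if (length(allowed) == 0) return(0L)
  allowed <- if (element == "C") allowed - abs(charge) else allowed + charge
  for (h in 0:12) {
    if ((occupied + h) %in% allowed) return(h)
  }
  0L
}

# occupied valence recomputed independently (bond-order sum skipping
# zero-order bonds, plus unpaired electrons)
oracle_occupied <- function(mol, idx) {
  occ <- get_atom(mol, idx)$unpaired
  bt <- bonds_tbl(mol)
  occ + sum(bt$order[bt$from == idx | bt$to == idx])
}

# random connected small organic: tree skeleton plus occasional ring-closing
# bond, orders 1-3, charges in {-1, 0, +1}
random_organic <- function(n = NULL) {
  if (is.null(n)) n <- sample(2:9, 1)
  elements <- sample(c("C", "C", "C", "N", "O", "P", "S"), n, replace = TRUE)
  mol <- molecule()
  for (i in seq_len(n)) {
    mol <- add_atom(mol, elements[[i]], x = i * 1.5, y = (i %% 2) * 0.75,
                    charge = sample(c(-1L, 0L, 0L, 0L, 1L), 1))
  }
  for (i in 2:n) {
    mol <- add_bond(mol, sample(seq_len(i - 1L), 1), i, sample(1:3, 1))
  }
  if (n >= 4 && stats::runif(1) < 0.3) {
    ends <- sample(seq_len(n), 2)
    bt <- bonds_tbl(mol)
    dup <- any((bt$from == min(ends) & bt$to == max(ends)) |
                 (bt$from == max(ends) & bt$to == min(ends)))
    if (!dup) mol <- add_bond(mol, ends[[1]], ends[[2]], 1L)
  }
  mol
}

# random printable extension token, exercising the escaping (commas,
# colons, backslashes, reserved-looking prefixes)
random_ext_token <- function() {
  pool <- c(letters, LETTERS, 0:9, ",", ":", ";", "\\", "=", " ", "-", "_")
  prefix <- sample(c("zz:", "xx:", "q:", "n:", ""), 1)
  paste0(prefix, paste(sample(pool, sample(1:12, 1), replace = TRUE),
                       collapse = ""))
}

# random molecule decorated with extension tokens, explicit hydrogens,
# isotopes and stereo -- the read/modify/write workhorse
random_decorated <- function() {
  mol <- random_organic()
  for (i in seq_len(n_atoms(mol))) {
    if (stats::runif(1) < 0.4) {
      mol <- set_atom(mol, i, extensions = replicate(sample(1:3, 1),
                                                     random_ext_token()))
    }
    if (stats::runif(1) < 0.2) mol <- set_atom(mol, i, hydrogens = sample(0:3, 1))
    if (stats::runif(1) < 0.15) mol <- set_isotope(mol, i, sample(c(2L, 13L, 15L), 1))
  }
  for (j in seq_len(n_bonds(mol))) {
    if (stats::runif(1) < 0.3) {
      mol <- set_bond(mol, j, extensions = replicate(sample(1:2, 1),
                                                     random_ext_token()),
                      stereo = sample(c("flat", "inclined", "declined", "unknown"), 1))
    }
  }
  mol
}

# formula as a plain named count vector (element#isotope), for readable
# comparisons in tests
formula_counts <- function(f) {
  stats::setNames(f$counts$count,
                  paste0(f$counts$element, "#", f$counts$isotope))
}

expect_formula_equal <- function(a, b) {
  expect_true(formula_equal(a, b),
              label = sprintf("formula %s == %s", formula_to_string(a),
                              formula_to_string(b)))
}

# fragment builders shared across tests: a "*"-rooted chain of the given
# elements with the given bond orders
star_chain <- function(elements, orders = rep(1L, length(elements))) {
  mol <- molecule() |> add_atom("*", 0, 0)
  for (i in seq_along(elements)) {
    mol <- add_atom(mol, elements[[i]], 1.5 * i, 0)
    mol <- add_bond(mol, i, i + 1L, orders[[i]])
  }
  mol
}

star_hydrogen <- function() {
  molecule() |> add_atom("*", 0, 0) |> add_atom("H", 1.5, 0) |> add_bond(1, 2)
}
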
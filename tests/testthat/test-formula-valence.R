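test_that("strict hydrogen table reproduces the textbook valence cases", {
  # bare C5 ring reads literally as cyclopentane: two single bonds per carbon
  cp <- build_fixture("cyclopentane_misdrawn")
  for (i in 1:5) expect_equal(implicit_hydrogen_count(cp, i, "strict"), 2L)
  expect_equal(formula_to_string(molecular_formula(cp)), "C5H10")

  # hydroxide, ammonium, carbanion: charge arithmetic differs for carbon
  oh <- molecule() |> add_atom("O", charge = -1L)
  expect_equal(implicit_hydrogen_count(oh, 1), 1L)
  nh4 <- molecule() |> add_atom("N", charge = 1L)
  expect_equal(implicit_hydrogen_count(nh4, 1), 4L)
  carbanion <- molecule() |> add_atom("C", charge = -1L)
  expect_equal(implicit_hydrogen_count(carbanion, 1), 3L)
  carbocation <- molecule() |> add_atom("C", charge = 1L)
  expect_equal(implicit_hydrogen_count(carbocation, 1), 3L)

  # multivalent S: the smallest allowed valence that fits the occupancy
  sulfate_core <- molecule() |> add_atom("S")
  for (k in 1:4) {
    sulfate_core <- add_atom(sulfate_core, "O", k * 1.5, 0)
    sulfate_core <- add_bond(sulfate_core, 1, k + 1L)
  }
  expect_equal(implicit_hydrogen_count(sulfate_core, 1), 0L)
  h2s <- molecule() |> add_atom("S")
  expect_equal(implicit_hydrogen_count(h2s, 1), 2L)

  # unpaired electrons consume valence
  methyl_radical <- molecule() |> add_atom("C", unpaired = 1L)
  expect_equal(implicit_hydrogen_count(methyl_radical, 1), 3L)
})

test_that("tin dichloride separates the strict and legacy readings", {
  sn <- build_fixture("sncl2_naive")
  expect_equal(implicit_hydrogen_count(sn, 2, "strict"), 0L)
  expect_equal(implicit_hydrogen_count(sn, 2, "legacy"), 2L)
  # each explicit disambiguation pins the hydrogen count to zero in any mode
  for (nm in c("sncl2_fixed_lonepair", "sncl2_fixed_hzero")) {
    fixed <- build_fixture(nm)
    expect_equal(implicit_hydrogen_count(fixed, 2, "legacy"), 0L, label = nm)
    expect_equal(implicit_hydrogen_count(fixed, 2, "strict"), 0L, label = nm)
  }
  # explicit override wins for any element in any mode
  forced <- set_atom(sn, 2, hydrogens = 5L)
  expect_equal(implicit_hydrogen_count(forced, 2, "legacy"), 5L)
})

test_that("zero-order bonds never consume valence", {
  mol <- molecule() |>
    add_atom("Fe", 0, 0) |> add_atom("C", 1.5, 0, unpaired = 2L) |>
    add_atom("O", 3, 0) |>
    add_bond(1, 2, 0L) |> add_bond(2, 3, 2L)
  expect_equal(implicit_hydrogen_count(mol, 2), 0L)
  # make the metal bond a full single bond and the carbon needs no H either,
  # but drop the lone pair and hydrogens reappear
  naked <- set_atom(mol, 2, unpaired = 0L)
  expect_equal(implicit_hydrogen_count(naked, 2), 2L)
})

test_that("strict hydrogen counts agree with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:150) {
    mol <- random_organic()
    for (i in seq_len(n_atoms(mol))) {
      a <- get_atom(mol, i)
      expect_equal(implicit_hydrogen_count(mol, i, "strict"),
                   oracle_strict_h(a$element, a$charge, oracle_occupied(mol, i)),
                   label = sprintf("%s (charge %d) in molecule %d", a$element,
                                   a$charge, rep))
    }
  }
})

test_that("raising an explicit hydrogen override raises total H by one", {
  set.seed(7)
  for (rep in 1:25) {
    mol <- random_organic()
    i <- sample(n_atoms(mol), 1)
    h0 <- implicit_hydrogen_count(mol, i)
    bumped <- set_atom(mol, i, hydrogens = h0 + 1L)
    expect_equal(formula_hydrogens(molecular_formula(bumped)),
                 formula_hydrogens(molecular_formula(mol)) + 1L)
  }
})

test_that("formula is invariant under reordering and Kekule redistribution", {
  benzene <- build_fixture("bromobenzene_full") |> delete_atom(7)
  f1 <- molecular_formula(benzene)
  # rotate the double bonds one position around the ring
  other <- benzene
  for (j in seq_len(n_bonds(other))) {
    b <- get_bond(other, j)
    other <- set_bond(other, j, order = if (b$order == 2L) 1L else 2L)
  }
  expect_formula_equal(f1, molecular_formula(other))

  set.seed(11)
  mol <- random_organic(8)
  perm <- sample(n_atoms(mol))
  inv <- order(perm)
  shuffled <- molecule()
  for (i in perm) {
    a <- get_atom(mol, i)
    shuffled <- add_atom(shuffled, a$element, a$x, a$y, a$charge, a$unpaired,
                         a$hydrogens, a$extensions)
  }
  for (b in mol$bonds) {
    shuffled <- add_bond(shuffled, inv[b$from], inv[b$to], b$order, b$stereo)
  }
  expect_formula_equal(molecular_formula(mol), molecular_formula(shuffled))
})

test_that("formula strings follow Hill order with isotope brackets", {
  expect_equal(formula_to_string(molecular_formula(build_fixture("triethylsilane_full"))),
               "C6H16Si")
  expect_equal(formula_to_string(formula_map()), "")
  et <- star_chain(c("C", "C"))
  expect_equal(formula_to_string(molecular_formula(et, expand_abbreviations = FALSE)),
               "C2H5[*]")
  f <- molecular_formula(et, expand_abbreviations = FALSE)
  expect_equal(formula_hydrogens(f), 5L)

  # no carbon: Hill order is fully alphabetical, hydrogen included
  amm <- molecular_formula(build_fixture("ammonium_d4_bromide"))
  expect_equal(formula_to_string(amm), "Br[2H]4N")
  expect_equal(formula_count(amm, "H", 2L), 4L)
  expect_equal(formula_count(amm, "H", 0L), 0L)
  expect_equal(formula_count(amm, "N"), 1L)
  expect_equal(formula_count(amm, "Br"), 1L)
})

test_that("uninterpretable labels land in the unknown list, in drawing order", {
  mol <- molecule() |>
    add_atom("Fe", 0, 0) |> add_atom("CO", 1.5, 0) |> add_atom("OC", 3, 0) |>
    add_bond(1, 2) |> add_bond(1, 3)
  f <- molecular_formula(mol)
  expect_equal(f$unknown_labels, c("CO", "OC"))
  expect_equal(formula_to_string(f), "Fe[CO][OC]")
})
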
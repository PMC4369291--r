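test_that("entries classify as molecule, template or query", {
  expect_equal(classify_entry(build_fixture("bromobenzene_full")), "MOLECULE")
  expect_equal(classify_entry(build_fixture("xr_template")), "TEMPLATE")
  expect_equal(classify_entry(build_fixture("query_bond")), "QUERY")
  # a placeholder token with an inline abbreviation is not a template
  expect_equal(classify_entry(build_fixture("bromobenzene_ph")), "MOLECULE")
  # the placeholder grammar is case-sensitive and exact
  expect_equal(classify_entry(molecule() |> add_atom("Rh")), "MOLECULE")
  expect_equal(classify_entry(molecule() |> add_atom("R12")), "TEMPLATE")
})

test_that("validation reports the documented finding codes at the right severity", {
  f <- validate_molecule(build_fixture("fe_dimer_drawn"))
  err <- f[f$severity == "ERROR", ]
  expect_true(all(err$code == "uninterpretable_label"))
  expect_equal(sort(err$locator), c("atom:13", "atom:14"))

  f <- validate_molecule(build_fixture("xr_template"))
  expect_true("template_requires_enumeration" %in% f$code[f$severity == "ERROR"])

  # pentavalent carbon is a warning, never an error: carboranes are real
  f <- validate_molecule(build_fixture("pentavalent_carbon"))
  expect_equal(f$code[f$severity == "WARNING"], "hypervalent_atom")
  expect_false(any(f$severity == "ERROR"))

  f <- validate_molecule(build_fixture("sodium_chloride_covalent"))
  expect_equal(f$code[f$severity == "WARNING"], "covalent_alkali_halide")

  f <- validate_molecule(build_fixture("nitro_pentavalent"))
  expect_true("pentavalent_nitro" %in% f$code)
  # the specific nitro warning suppresses the generic hypervalence one
  expect_false("hypervalent_atom" %in% f$code)

  f <- validate_molecule(build_fixture("sncl2_naive"))
  expect_true("ambiguous_metal_valence" %in% f$code)
  # each of the three explicit fixes silences the ambiguity
  for (nm in c("sncl2_fixed_lonepair", "sncl2_fixed_hzero")) {
    expect_false("ambiguous_metal_valence" %in%
                   validate_molecule(build_fixture(nm))$code, label = nm)
  }
  charged <- set_atom(build_fixture("sncl2_naive"), 2, charge = 2L)
  expect_false("ambiguous_metal_valence" %in% validate_molecule(charged)$code)

  f <- validate_molecule(build_fixture("ammonium_cation"))
  expect_equal(f$code[f$severity == "INFO"], "net_charge_nonzero")
  # the full salt is multi-component and neutral: no such note
  expect_false("net_charge_nonzero" %in%
                 validate_molecule(build_fixture("ammonium_d4_bromide"))$code)
})

test_that("validation is pure: identical findings in identical order", {
  for (nm in c("fe_dimer_drawn", "sncl2_naive", "nitro_pentavalent")) {
    a <- validate_molecule(build_fixture(nm))
    b <- validate_molecule(build_fixture(nm))
    expect_identical(a, b, label = nm)
  }
})

test_that("the fixture registry exercises every finding code", {
  seen <- unique(unlist(lapply(fixture_names(), function(nm) {
    obj <- build_fixture(nm)
    if (is.molecule(obj)) validate_molecule(obj)$code else character()
  })))
  expect_setequal(
    intersect(c("uninterpretable_label", "template_requires_enumeration",
                "hypervalent_atom", "covalent_alkali_halide",
                "pentavalent_nitro", "ambiguous_metal_valence",
                "net_charge_nonzero"), seen),
    c("uninterpretable_label", "template_requires_enumeration",
      "hypervalent_atom", "covalent_alkali_halide", "pentavalent_nitro",
      "ambiguous_metal_valence", "net_charge_nonzero"))
})

test_that("the gate rejects on errors only, and reports formulas on accept", {
  res <- gate_entry(build_fixture("bromobenzene_full"))
  expect_equal(res$status, "ACCEPT")
  expect_equal(unname(res$formulas), "C6H5Br")

  res <- gate_entry(build_fixture("pentavalent_carbon"))
  expect_equal(res$status, "ACCEPT")
  expect_true(any(res$findings$severity == "WARNING"))

  # a sheet with one bad cell is rejected, and the finding locates the cell
  sheet <- datasheet(c("Structure", "Note"), c("molecule", "string"))
  sheet <- ds_append_row(sheet, list(build_fixture("bromobenzene_full"), "ok"))
  sheet <- ds_append_row(sheet, list(build_fixture("fe_dimer_drawn"), "bad"))
  res <- gate_entry(sheet)
  expect_equal(res$status, "REJECT")
  expect_match(res$findings$locator[res$findings$severity == "ERROR"][[1]],
               "^row:2/col:Structure/")

  # acceptance implies an interpretable formula for every molecule cell
  clean <- ds_delete_row(sheet, 2)
  res <- gate_entry(clean)
  expect_equal(res$status, "ACCEPT")
  f <- molecular_formula(ds_cell(clean, 1, "Structure"))
  expect_equal(length(f$unknown_labels), 0L)
})

test_that("template enumeration takes the Cartesian product and dedupes", {
  template <- build_fixture("xr_template")
  subs <- list(X = list(star_chain("Cl"), star_chain("Br")),
               R = list(star_chain("C"), star_chain(c("O", "C"))))
  species <- enumerate_template(template, subs)
  expect_length(species, 4L)
  expect_setequal(vapply(species, function(m)
    formula_to_string(molecular_formula(m)), character(1)),
    c("C7H7Cl", "C7H7Br", "C7H7ClO", "C7H7BrO"))
  for (m in species) expect_equal(classify_entry(m), "MOLECULE")

  # one placeholder, one fragment
  single <- enumerate_template(
    molecule() |> add_atom("C") |> add_atom("X", 1.5, 0) |> add_bond(1, 2),
    list(X = list(star_chain("N"))))
  expect_length(single, 1L)

  # three placeholders with two options each on chemically distinct sites:
  # the full 2^3 product survives deduplication
  tri <- molecule() |>
    add_atom("C", 0, 0) |> add_atom("N", 1.5, 0) |> add_atom("O", 3, 0) |>
    add_bond(1, 2) |> add_bond(2, 3)
  for (k in 1:3) {
    tri <- add_atom(tri, paste0("R", k), 1.5 * (k - 1), 1.5)
    tri <- add_bond(tri, k, k + 3L)
  }
  subs3 <- stats::setNames(rep(list(list(star_chain("F"), star_chain("Cl"))), 3),
                           paste0("R", 1:3))
  expect_length(enumerate_template(tri, subs3), 8L)

  # identical grafts on equivalent sites collapse: duplicates are removed
  sym <- molecule() |> add_atom("C", 0, 0) |>
    add_atom("R1", -1.5, 0) |> add_atom("R2", 1.5, 0) |>
    add_bond(1, 2) |> add_bond(1, 3)
  both <- enumerate_template(sym, list(R1 = list(star_chain("F"), star_chain("Cl")),
                                       R2 = list(star_chain("F"), star_chain("Cl"))))
  # FF, FCl, ClF, ClCl -> FCl == ClF by symmetry, so 3 distinct species
  expect_length(both, 3L)

  expect_error(enumerate_template(template, list(X = list(star_chain("Cl")))),
               "no substitution list.*R")
})
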
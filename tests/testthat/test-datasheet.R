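test_that("typed sheets parse, enforce cell types and round-trip", {
  sheet <- datasheet(c("Structure", "Activity"), c("molecule", "real"))
  sheet <- ds_append_row(sheet, list(build_fixture("bromobenzene_full"), 5.2))
  sheet <- ds_append_row(sheet, list(NULL, 7.4))
  sheet <- ds_append_row(sheet, list(build_fixture("cyclopentane_misdrawn"), NULL))
  expect_equal(ds_nrow(sheet), 3L)
  xml <- write_datasheet(sheet)
  back <- parse_datasheet(xml)
  expect_true(ds_equal(sheet, back))
  expect_identical(write_datasheet(back), xml)
  expect_null(ds_cell(back, 2, "Structure"))
  expect_null(ds_cell(back, 3, "Activity"))

  expect_error(ds_append_row(sheet, list(NULL, "abc")), "conform")
  expect_error(datasheet(c("A", "A"), c("real", "real")), "duplicate")
  expect_error(datasheet("A", "complex"), "unknown column type")

  bad_cell <- paste0(
    '<DataSheet><Header ncols="1" nrows="1">',
    '<Column id="1" name="Count" type="integer"/></Header>',
    '<Row id="1"><Cell col="1">abc</Cell></Row></DataSheet>')
  expect_error(parse_datasheet(bad_cell), "row 1, column 'Count'")
})

test_that("unknown header extensions survive rewriting byte-identically", {
  sheet <- datasheet("Name", "string")
  payload <- "opaque payload\nwith lines & <angles> and trailing spaces  "
  sheet <- ds_set_extension(sheet, "FutureThing", payload)
  sheet <- ds_append_row(sheet, list("x"))
  back <- parse_datasheet(write_datasheet(sheet))
  expect_identical(ds_extension(back, "FutureThing"), payload)
  # modify through generic operations, rewrite, and the payload is intact
  back <- ds_set_cell(back, 1, "Name", "y")
  again <- parse_datasheet(write_datasheet(back))
  expect_identical(ds_extension(again, "FutureThing"), payload)
})

test_that("aspects tolerate unaware editing and repair themselves", {
  for (nm in c("sar_sheet", "reaction_sheet", "experiment_sheet_2step",
               "solvent_sheet")) {
    sheet <- build_fixture(nm)
    aspect <- intersect(vapply(sheet$extensions, `[[`, character(1), "name"),
                        c("Solvent", "SARTable", "Reaction", "Experiment"))[[1]]
    payload0 <- ds_extension(sheet, aspect)

    # simulated aspect-unaware editor: append a column, edit a cell, add and
    # delete a row -- through the generic sheet operations only
    edited <- ds_add_column(sheet, "Comment", "string")
    edited <- ds_append_row(edited)
    edited <- ds_set_cell(edited, ds_nrow(edited), "Comment", "checked")
    edited <- ds_delete_row(edited, ds_nrow(edited))
    back <- parse_datasheet(write_datasheet(edited))
    expect_identical(ds_extension(back, aspect), payload0, label = nm)
    expect_false(is.null(ds_aspects(back)[[aspect]]), label = nm)
    # repair on the undamaged (but edited) sheet restores nothing
    expect_true(ds_equal(repair_aspect(back, aspect), back), label = nm)

    # now actually damage it: delete an aspect-required column
    req <- elnote:::aspect_required_columns(aspect, ds_aspects(sheet)[[aspect]])
    victim <- req[[length(req)]]$name
    damaged <- ds_delete_column(sheet, victim)
    repaired <- repair_aspect(damaged, aspect)
    expect_true(victim %in% ds_colnames(repaired), label = nm)
    expect_equal(ds_coltype(repaired, victim), victim_type <- req[[length(req)]]$type)
    expect_null(ds_cell(repaired, 1, victim))
    # surviving data untouched, and repair is idempotent
    keep <- setdiff(ds_colnames(damaged), victim)
    for (cn in keep) {
      expect_equal(is.null(ds_cell(repaired, 1, cn)), is.null(ds_cell(sheet, 1, cn)))
    }
    expect_true(ds_equal(repair_aspect(repaired, aspect), repaired), label = nm)
  }
  expect_error(repair_aspect(build_fixture("solvent_sheet"), "FutureThing"),
               "unknown aspect")
})

test_that("SAR composition grafts substituents onto scaffold placeholders", {
  sheet <- build_fixture("sar_sheet")
  scaffold <- ds_cell(sheet, 1, "Scaffold")
  methyl <- ds_cell(sheet, 1, "R1")
  comp <- compose_sar_molecule(scaffold, list(R1 = methyl))
  expect_equal(nrow(check_graph(comp)), 0L)
  expect_equal(formula_to_string(molecular_formula(comp)), "C7H8")  # toluene

  # a bare-H substituent restores benzene
  comp_h <- compose_sar_molecule(scaffold, list(R1 = star_hydrogen()))
  expect_equal(formula_to_string(molecular_formula(comp_h)), "C6H6")

  expect_error(compose_sar_molecule(scaffold, list(R2 = methyl)),
               "missing substituent.*R1")
  expect_warning(compose_sar_molecule(scaffold, list(R1 = methyl, R9 = methyl)),
                 "unmatched")
})

test_that("SDfile export loses typing and aspects, and says so", {
  sheet <- datasheet(c("Structure", "Potency", "Active"),
                     c("molecule", "real", "boolean"))
  for (k in 1:3) {
    sheet <- ds_append_row(sheet, list(build_fixture("cyclopentane_misdrawn"),
                                       k * 1.5, k %% 2 == 0))
  }
  sheet <- ds_set_extension(sheet, "Reaction", "step=1;role=product;column=Structure;type=molecule")
  sd <- export_sdfile(sheet, "Structure")
  expect_equal(lengths(regmatches(sd, gregexpr("[$][$][$][$]", sd))), 3L)
  loss <- attr(sd, "loss")
  expect_true("aspect_dropped" %in% loss$code)
  expect_true("column_type_dropped" %in% loss$code)

  back <- parse_sdfile(sd)
  expect_equal(ds_nrow(back), 3L)
  # the boolean column comes back as a sniffed boolean of text origin; the
  # typed aspect machinery is gone
  expect_equal(length(back$extensions), 0L)
  for (k in 1:3) {
    expect_formula_equal(molecular_formula(ds_cell(back, k, "Molecule")),
                         molecular_formula(ds_cell(sheet, k, "Structure")))
  }
  expect_equal(ds_cell(back, 2, "Potency"), 3.0)
  expect_error(export_sdfile(sheet, "Potency"), "not molecule-typed")
})

test_that("reaction schemes assemble components by step and role", {
  rs <- assemble_reaction_scheme(build_fixture("reaction_sheet"), 1)
  expect_equal(rs$role[rs$type == "molecule"], c("reactant", "reactant", "product"))
  expect_equal(unique(rs$step), 1L)
  expect_true(is.molecule(rs$value[[1]]))
  expect_equal(rs$value[[which(rs$column == "Reagent")]], "reflux")

  ex <- assemble_reaction_scheme(build_fixture("experiment_sheet_2step"), 1)
  expect_equal(unique(ex$step), c(1L, 2L))
  expect_equal(ex$quantity[ex$column == "Reactant1"], 2.0)
  # the same molecule column serves as product of step 1 and reactant of step 2
  expect_equal(sum(ex$column == "Intermediate"), 2L)

  expect_error(assemble_reaction_scheme(build_fixture("solvent_sheet"), 1),
               "neither a Reaction nor an Experiment")
})
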
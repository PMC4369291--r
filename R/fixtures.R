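# Programmatic fixture registry. Every worked structure used in tests and
# documentation is constructed here in code -- the construction *is* the
# documentation of what each record contains. Golden serialized copies under
# inst/extdata/ freeze the wire dialect.

hexagon_ring <- function(alternating = TRUE) {
  mol <- molecule()
  for (t in 0:5) {
    ang <- pi / 2 + t * pi / 3
    mol <- add_atom(mol, "C", 1.5 * cos(ang), 1.5 * sin(ang))
  }
  for (t in 1:6) {
    order <- if (alternating && t %% 2 == 1) 2L else 1L
    mol <- add_bond(mol, t, if (t == 6) 1L else t + 1L, order)
  }
  mol
}

pentagon_coords <- function(cx = 0, cy = 0) {
  r <- 0.75 / sin(pi / 5)
  t(vapply(0:4, function(t) {
    ang <- pi / 2 + 2 * pi * t / 5
    c(cx + r * cos(ang), cy + r * sin(ang))
  }, numeric(2)))
}

# substituent position: radially outward from ring atom 1 (which sits on top)
ring_subst_pos <- function(mol, idx, dist = 1.5) {
  a <- get_atom(mol, idx)
  len <- sqrt(a$x^2 + a$y^2)
  c(a$x * (1 + dist / len), a$y * (1 + dist / len))
}

phenyl_fragment <- function() {
  frag <- hexagon_ring()
  sp <- ring_subst_pos(frag, 1)
  frag <- add_atom(frag, ATTACHMENT_TOKEN, sp[1], sp[2])
  add_bond(frag, 7, 1)
}

ethyl_fragment <- function() {
  frag <- molecule() |>
    add_atom(ATTACHMENT_TOKEN, -1.5, 0) |>
    add_atom("C", 0, 0) |>
    add_atom("C", 0.75, 1.299) |>
    add_bond(1, 2) |>
    add_bond(2, 3)
  frag
}

silyl_core <- function(with_et_abbrev) {
  mol <- molecule() |> add_atom("Si", 0, 0, hydrogens = 1L)
  for (t in 0:2) {
    ang <- pi / 2 + 2 * pi * t / 3
    p1 <- 1.5 * c(cos(ang), sin(ang))
    if (with_et_abbrev) {
      mol <- add_atom(mol, "Et", p1[1], p1[2])
      mol <- set_abbrev(mol, n_atoms(mol), ethyl_fragment())
      mol <- add_bond(mol, 1, n_atoms(mol))
    } else {
      p2 <- 3.0 * c(cos(ang + pi / 12), sin(ang + pi / 12))
      mol <- add_atom(mol, "C", p1[1], p1[2])
      ca <- n_atoms(mol)
      mol <- add_atom(mol, "C", p2[1], p2[2])
      mol <- add_bond(mol, 1, ca) |> add_bond(ca, ca + 1L)
    }
  }
  mol
}

sncl2_base <- function() {
  molecule() |>
    add_atom("Cl", -1.299, -0.75) |>
    add_atom("Sn", 0, 0) |>
    add_atom("Cl", 1.299, -0.75) |>
    add_bond(1, 2) |>
    add_bond(2, 3)
}

cp_anion_ring <- function(cx, cy, charge_on = 5L) {
  xy <- pentagon_coords(cx, cy)
  mol <- molecule()
  for (t in 1:5) mol <- add_atom(mol, "C", xy[t, 1], xy[t, 2])
  orders <- c(2L, 1L, 2L, 1L, 1L)
  for (t in 1:5) mol <- add_bond(mol, t, if (t == 5) 1L else t + 1L, orders[t])
  set_atom(mol, charge_on, charge = -1L)
}

append_mol <- function(host, piece) {
  base <- n_atoms(host)
  for (a in piece$atoms) {
    host <- add_atom(host, a$element, a$x, a$y, a$charge, a$unpaired,
                     a$hydrogens, a$extensions)
  }
  for (b in piece$bonds) {
    host <- add_bond(host, b$from + base, b$to + base, b$order, b$stereo,
                     b$extensions)
  }
  host
}

zigzag_chain <- function(elements) {
  mol <- molecule()
  for (i in seq_along(elements)) {
    mol <- add_atom(mol, elements[[i]], 1.299 * (i - 1),
                    if (i %% 2 == 0) 0.75 else 0)
    if (i > 1) mol <- add_bond(mol, i - 1L, i)
  }
  mol
}

fixture_builders <- list(
  bromobenzene_full = function() {
    mol <- hexagon_ring()
    sp <- ring_subst_pos(mol, 1)
    mol |> add_atom("Br", sp[1], sp[2]) |> add_bond(1, 7)
  },
  bromobenzene_ph = function() {
    mol <- molecule() |>
      add_atom("Ph", 0, 0) |>
      add_atom("Br", 1.5, 0) |>
      add_bond(1, 2)
    set_abbrev(mol, 1, phenyl_fragment())
  },
  triethylsilane_full = function() silyl_core(with_et_abbrev = FALSE),
  triethylsilane_et3 = function() silyl_core(with_et_abbrev = TRUE),
  triethylsilane_meta = function() {
    frag <- silyl_core(with_et_abbrev = TRUE)
    # the meta-abbreviation's own attachment point stands in for the Si-H
    # position; the explicit h1 on silicon stays inside the definition
    frag <- add_atom(frag, ATTACHMENT_TOKEN, 0, -1.5)
    frag <- add_bond(frag, n_atoms(frag), 1)
    mol <- molecule() |> add_atom("Et3Si", 0, 0)
    set_abbrev(mol, 1, frag)
  },
  sncl2_naive = function() sncl2_base(),
  sncl2_fixed_lonepair = function() set_atom(sncl2_base(), 2, unpaired = 2L),
  sncl2_fixed_hzero = function() set_atom(sncl2_base(), 2, hydrogens = 0L),
  cyclopentane_misdrawn = function() {
    xy <- pentagon_coords()
    mol <- molecule()
    for (t in 1:5) mol <- add_atom(mol, "C", xy[t, 1], xy[t, 2])
    for (t in 1:5) mol <- add_bond(mol, t, if (t == 5) 1L else t + 1L)
    mol
  },
  ammonium_d4_bromide = function() {
    mol <- molecule() |> add_atom("N", 0, 0, charge = 1L)
    for (t in 0:3) {
      ang <- pi / 4 + t * pi / 2
      mol <- add_atom(mol, "H", cos(ang), sin(ang))
      mol <- set_isotope(mol, n_atoms(mol), 2L)
      mol <- add_bond(mol, 1, n_atoms(mol))
    }
    mol |> add_atom("Br", 3, 0, charge = -1L)
  },
  xr_template = function() {
    mol <- hexagon_ring()
    sp1 <- ring_subst_pos(mol, 1)
    mol <- mol |> add_atom("X", sp1[1], sp1[2]) |> add_bond(1, 7)
    sp4 <- ring_subst_pos(mol, 4)
    mol |> add_atom("R", sp4[1], sp4[2]) |> add_bond(4, 8)
  },
  fe_dimer_machine = function() {
    mol <- molecule() |>
      add_atom("Fe", -1.1, 0, charge = 1L) |>
      add_atom("Fe", 1.1, 0, charge = 1L) |>
      add_bond(1, 2)
    ring1 <- cp_anion_ring(-1.1, 2.6)
    ring2 <- cp_anion_ring(1.1, -2.6)
    mol <- append_mol(mol, ring1)          # atoms 3..7
    mol <- append_mol(mol, ring2)          # atoms 8..12
    for (t in 3:7) mol <- add_bond(mol, 1, t, 0L)
    for (t in 8:12) mol <- add_bond(mol, 2, t, 0L)
    # terminal carbonyls: carbene-like lone pair pins the hydrogen count
    mol <- mol |>
      add_atom("C", -2.9, -0.6, unpaired = 2L) |>   # 13
      add_atom("O", -4.0, -1.1) |>                  # 14
      add_bond(13, 14, 2L) |> add_bond(1, 13, 0L) |>
      add_atom("C", 2.9, 0.6, unpaired = 2L) |>     # 15
      add_atom("O", 4.0, 1.1) |>                    # 16
      add_bond(15, 16, 2L) |> add_bond(2, 15, 0L)
    # bridging carbonyls attach datively to both metals
    mol <- mol |>
      add_atom("C", 0, 1.2, unpaired = 2L) |>       # 17
      add_atom("O", 0, 2.4) |>                      # 18
      add_bond(17, 18, 2L) |> add_bond(1, 17, 0L) |> add_bond(2, 17, 0L) |>
      add_atom("C", 0, -1.2, unpaired = 2L) |>      # 19
      add_atom("O", 0, -2.4) |>                     # 20
      add_bond(19, 20, 2L) |> add_bond(1, 19, 0L) |> add_bond(2, 19, 0L)
    mol
  },
  fe_dimer_drawn = function() {
    # publication-style drawing taken literally: plain C5 rings, a bond from
    # each metal into one ring carbon, and "CO"/"OC" text nodes
    mol <- molecule() |>
      add_atom("Fe", -1.1, 0) |>
      add_atom("Fe", 1.1, 0) |>
      add_bond(1, 2)
    xy1 <- pentagon_coords(-1.1, 2.6)
    xy2 <- pentagon_coords(1.1, -2.6)
    for (t in 1:5) mol <- add_atom(mol, "C", xy1[t, 1], xy1[t, 2])
    for (t in 1:5) mol <- add_bond(mol, t + 2L, if (t == 5) 3L else t + 3L)
    for (t in 1:5) mol <- add_atom(mol, "C", xy2[t, 1], xy2[t, 2])
    for (t in 1:5) mol <- add_bond(mol, t + 7L, if (t == 5) 8L else t + 8L)
    mol |>
      add_bond(1, 5) |> add_bond(2, 10) |>
      add_atom("CO", -2.9, -0.6) |> add_bond(1, 13) |>
      add_atom("OC", 2.9, 0.6) |> add_bond(2, 14)
  },
  pentavalent_carbon = function() {
    mol <- molecule() |> add_atom("C", 0, 0)
    for (t in 0:4) {
      ang <- 2 * pi * t / 5
      mol <- add_atom(mol, "C", 1.5 * cos(ang), 1.5 * sin(ang))
      mol <- add_bond(mol, 1, n_atoms(mol))
    }
    mol
  },
  sodium_chloride_covalent = function() {
    molecule() |> add_atom("Na", 0, 0) |> add_atom("Cl", 1.5, 0) |> add_bond(1, 2)
  },
  nitro_pentavalent = function() {
    molecule() |>
      add_atom("C", 0, 0) |>
      add_atom("N", 1.5, 0) |>
      add_atom("O", 2.25, 1.299) |>
      add_atom("O", 2.25, -1.299) |>
      add_bond(1, 2) |> add_bond(2, 3, 2L) |> add_bond(2, 4, 2L)
  },
  ammonium_cation = function() {
    molecule() |> add_atom("N", 0, 0, charge = 1L)
  },
  query_bond = function() {
    molecule() |>
      add_atom("C", 0, 0) |>
      add_atom("C", 1.5, 0) |>
      add_bond(1, 2, extensions = "q:order1,2")
  },
  sar_sheet = function() {
    scaffold <- hexagon_ring()
    sp <- ring_subst_pos(scaffold, 1)
    scaffold <- scaffold |> add_atom("R1", sp[1], sp[2]) |> add_bond(1, 7)
    methyl <- molecule() |>
      add_atom(ATTACHMENT_TOKEN, 0, 0) |> add_atom("C", 1.5, 0) |> add_bond(1, 2)
    sheet <- datasheet(c("Scaffold", "R1", "Molecule", "Activity"),
                       c("molecule", "molecule", "molecule", "real"))
    sheet <- ds_set_extension(sheet, "SARTable", paste(
      "scaffold=Scaffold", "substituent=R1", "molecule=Molecule",
      "property=Activity;units=pIC50;min=4;max=9", sep = "\n"))
    ds_append_row(sheet, list(scaffold, methyl, NULL, 6.5))
  },
  reaction_sheet = function() {
    ethanol <- zigzag_chain(c("C", "C", "O"))
    hbr <- molecule() |> add_atom("Br", 0, 0, hydrogens = 1L)
    bromoethane <- zigzag_chain(c("C", "C", "Br"))
    sheet <- datasheet(
      c("Reactant1", "Reactant2", "Reagent", "Product", "Yield"),
      c("molecule", "molecule", "string", "molecule", "real"))
    sheet <- ds_set_extension(sheet, "Reaction", paste(
      "step=1;role=reactant;column=Reactant1;type=molecule",
      "step=1;role=reactant;column=Reactant2;type=molecule",
      "step=1;role=reagent;column=Reagent;type=string",
      "step=1;role=product;column=Product;type=molecule",
      "step=1;role=product;column=Yield;type=real", sep = "\n"))
    ds_append_row(sheet, list(ethanol, hbr, "reflux", bromoethane, 72.5))
  },
  experiment_sheet_2step = function() {
    ethanol <- zigzag_chain(c("C", "C", "O"))
    bromoethane <- zigzag_chain(c("C", "C", "Br"))
    nitrile <- molecule() |>
      add_atom("C", 0, 0) |> add_atom("C", 1.3, 0.75) |>
      add_atom("C", 2.6, 0) |> add_atom("N", 3.9, -0.75) |>
      add_bond(1, 2) |> add_bond(2, 3) |> add_bond(3, 4, 3L)
    sheet <- datasheet(
      c("Reactant1", "Reactant1Qty", "Intermediate", "Product", "ProductQty"),
      c("molecule", "real", "molecule", "molecule", "real"))
    sheet <- ds_set_extension(sheet, "Experiment", paste(
      "step=1;role=reactant;column=Reactant1;type=molecule;quantity=Reactant1Qty",
      "step=1;role=product;column=Intermediate;type=molecule",
      "step=2;role=reactant;column=Intermediate;type=molecule",
      "step=2;role=product;column=Product;type=molecule;quantity=ProductQty",
      sep = "\n"))
    ds_append_row(sheet, list(ethanol, 2.0, bromoethane, nitrile, 1.4))
  },
  solvent_sheet = function() {
    sheet <- datasheet(c("Name", "BoilingPoint", "Density"),
                       c("string", "real", "real"))
    sheet <- ds_set_extension(sheet, "Solvent", paste(
      "column=BoilingPoint;role=temperature;units=degC;type=real",
      "column=Density;role=density;units=g/mL;type=real", sep = "\n"))
    sheet <- ds_append_row(sheet, list("water", 100, 0.997))
    ds_append_row(sheet, list("ethanol", 78.4, 0.789))
  }
)

#' Build a named fixture
#'
#' The registry programmatically constructs every worked structure and sheet
#' used throughout the package: bromobenzene drawn in full and as a Ph
#' abbreviation; triethylsilane at all three abbreviation depths; the naive
#' and the three disambiguated tin dichloride sketches; the bare C5 ring
#' that machines read as cyclopentane; deuterated ammonium bromide; the X/R
#' substitution template; the organometallic iron dimer in both its
#' publication-style and its machine-readable zero-order-bond form;
#' validation provocations (pentavalent carbon, covalent Na-Cl, pentavalent
#' nitro, bare ammonium, a query bond); and the four aspect-bearing sheets.
#'
#' @param name Fixture name; see `fixture_names()`.
#' @return A [molecule()] or [datasheet()].
#' @export
#' @examples
#' formula_to_string(molecular_formula(build_fixture("triethylsilane_full")))
build_fixture <- function(name) {
  builder <- fixture_builders[[name]]
  if (is.null(builder))
    abort(sprintf("unknown fixture '%s'; see fixture_names()", name))
  builder()
}

#' @rdname build_fixture
#' @export
fixture_names <- function() names(fixture_builders)
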
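# elnote

Machine-first 2D chemical structures, datasheets and vector depiction for R.

Most chemical data is entered for human eyes first — ring glyphs, "Ph" and
"CO" text labels, wedge shorthand — and then laundered through formats whose
readers silently guess at what was meant. The guesses diverge: the same tin
dichloride sketch reads as SnCl₂ in one program and H₂SnCl₂ in another, and a
cyclopentadienyl ring drawn with a circle becomes cyclopentane. `elnote`
implements the opposite workflow: structures are stored in a minimalist,
extensible graph whose molecular formula an algorithm can always determine,
entries with zero or multiple interpretations are rejected at the gate, and
the human-friendly picture is generated *from* the machine record on demand.

The core record is an atom/bond graph where

- **virtual hydrogens** are calculated automatically only for C, N, O, P and
  S (zero for everything else), and any atom can pin its hydrogen count
  explicitly — `H = max(0, v* − occ)`, where `occ = Σ bond orders + unpaired
  electrons` and `v*` is the smallest allowed valence (charge-adjusted) that
  accommodates `occ`;
- **zero-order bonds** connect dative and multicentre attachments without
  consuming valence, so organometallics keep correct formulas;
- **inline abbreviations** carry their defining fragment (with attachment
  point) inside the same record, recursively, so "Ph" is never a lookup into
  somebody else's dictionary;
- unknown extension tokens survive read/modify/write untouched — software
  that does not understand a field must not destroy it.

Around the record sit a strongly typed datasheet XML container with tolerant
*aspects* (Solvent, SARTable, Reaction, Experiment), Markush-style template
enumeration, loss-ledgered MDL Molfile/SDfile export, and deterministic SVG
depiction.

## A worked example

Bromobenzene stored as a two-node drawing — a "Ph" abbreviation plus a
bromine — still yields the right formula, because the phenyl fragment
travels inside the record:

```r
library(elnote)
mol <- build_fixture("bromobenzene_ph")
n_atoms(mol)                                  # 2 nodes as drawn
#> [1] 2
heavy_atom_count(expand_fully(mol))           # 7 heavy atoms expanded
#> [1] 7
formula_to_string(molecular_formula(mol))
#> C6H5Br
```

The validation gate rejects drawings that have no machine interpretation and
warns (without blocking — the originating scientist is the final arbiter)
about ambiguous ones:

```r
gate_entry(build_fixture("sncl2_naive"))
#> ACCEPT
#>   [WARNING] ambiguous_metal_valence (atom:2): Sn with open valence admits
#>     more than one reading; pin it down with an explicit hydrogen count,
#>     unpaired electrons or a charge
#>   molecule: Cl2Sn

gate_entry(build_fixture("fe_dimer_drawn"))   # "CO"/"OC" text ligands
#> REJECT
#>   [ERROR] uninterpretable_label (atom:13): 'CO' is not an element and has
#>     no inline abbreviation
#>   [ERROR] uninterpretable_label (atom:14): 'OC' is not an element and has
#>     no inline abbreviation
```

The same iron dimer drawn machine-first — zero-order bonds for the η⁵ rings
and dative carbonyls, a carbene-like lone pair on each CO carbon — is
accepted with the clean formula `C14H10Fe2O4`.

The legacy-emulation mode reproduces what permissive Molfile software
perceives, so imports can freeze that reading explicitly instead of letting
it drift:

```r
sn <- build_fixture("sncl2_naive")
implicit_hydrogen_count(sn, 2, "strict")  # 0 -> SnCl2
implicit_hydrogen_count(sn, 2, "legacy")  # 2 -> H2SnCl2, the classic misread
```

A thin command-line front end (`inst/scripts/elnote`) exposes `convert`,
`formula`, `validate`, `render`, `enumerate`, `sheet` and `fixture` verbs;
`validate` exits 0/1 for accept/reject.

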
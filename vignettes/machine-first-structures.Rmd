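---
title: "Machine-first chemical structures: the data model and its decision tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Machine-first chemical structures: the data model and its decision tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elnote)
```

## The problem this package addresses

A 2D structure sketch is usually drawn to communicate with other chemists.
Ring circles, "Ph"/"OMe" text labels, hapticity lines and wedge shorthand
all rely on a human reader to supply the chemistry. Algorithms cannot, and
the formats most data passes through (MDL Molfile above all) force every
reader to *guess* — most visibly at implicit hydrogen counts. The guesses
are not stable across software, so the same bytes mean different molecules
in different programs, and every load/save cycle through an unaware editor
can silently destroy what the original author encoded.

`elnote` stores the record so that the first question an algorithm asks —
*what is the molecular formula?* — always has exactly one answer, and rejects
entries for which it does not. Everything human-facing (formula strings,
SVG depictions, reaction layouts) is derived from the machine record, never
stored alongside it where it could drift.

## The molecule model

A molecule is an ordered atom list and an ordered bond list. Atoms carry an
element token (any non-empty string), x/y in quasi-Ångström units with an
idealized bond length of 1.5 and y increasing upward, an integer formal
charge, an unpaired-electron count, a virtual-hydrogen field, and an ordered
list of opaque extension strings. Bonds carry two 1-based atom indices, an
integer order in 0..5, a stereo type (flat / inclined / declined / unknown)
and their own extensions.

Three modelling commitments matter:

* **Element tokens are never rejected by the model.** A token that is not a
  periodic-table symbol simply makes the record a template or a query —
  a *classification*, applied by `classify_entry()` and the validation gate,
  not a parse error. Placeholder grammar is exactly `X`, `R`, or `R` followed
  by digits, case-sensitive (so `Rh` is rhodium).
* **Bond orders are integers only.** There is no aromatic bond type; Kekulé
  structures carry the information, and the formula is invariant under any
  redistribution that preserves each atom's bond-order sum (tested). Orders
  4 and 5 are stored and summed but no further chemistry is inferred from
  them, since no valence semantics exist for them.
* **Wedges are pictorial.** Inclined/declined/unknown stereo marks are
  stored, serialized and rendered, but never chemically interpreted —
  in the organometallic drawings that motivate this package a wedge usually
  means "3D perspective", not a stereocentre, and guessing does harm.

Reserved extension prefixes are `z:` (third coordinate), `i:` (isotope mass
number, 0 = natural abundance), `n:` (mapping number), `q:` (query), and
`a:` (inline abbreviation). At most one isotope and one abbreviation token
per atom; everything else — including reserved prefixes from future
revisions — is preserved verbatim and never interpreted.

## The hydrogen decision tables

The virtual-hydrogen field is `AUTO` by default or an explicit count ≥ 0.
An explicit count is returned verbatim for *any* element; this is the escape
hatch that makes exotic valence states representable (and it is how Molfile
import freezes its reading, below).

For `AUTO` atoms, define the occupied valence

    occ = sum of incident bond orders (zero-order bonds contribute 0)
        + unpaired electron count

**Strict mode** (the package's native semantics) assigns hydrogens only to
C, N, O, P and S, and zero to every other element:

| element | allowed valences | charge adjustment |
|---------|------------------|-------------------|
| C       | 4                | 4 − |charge|      |
| N       | 3                | 3 + charge        |
| O       | 2                | 2 + charge        |
| P       | 3, 5             | each + charge     |
| S       | 2, 4, 6          | each + charge     |

`H = v* − occ` where `v*` is the smallest adjusted valence ≥ `occ`; if none
fits, `H = 0`. The carbon rule uses `−|charge|` on both signs so that both
carbanions and carbocations come out as CH₃^±^; heteroatoms gain capacity
with positive charge (ammonium NH₄⁺) and lose it with negative charge
(hydroxide OH⁻). The table's element set is fixed by the format; the
charge arithmetic is this package's documented choice, selected because it
reproduces hydroxide, ammonium, carbanion and the literal cyclopentane
reading of a bare C₅ ring (C₅H₁₀) — and it is deliberately *not*
configurable at the model level, only via the CLI config for whole-table
experiments.

**Legacy mode** emulates the group-based defaults that permissive Molfile
readers apply to all main-group elements: B 3; C/Si/Ge/Sn/Pb 4; N/P/As/Sb 3;
O/S/Se/Te 2; halogens 1; everything else 0, with the same arithmetic. This
is the reading that turns a bare SnCl₂ sketch into H₂SnCl₂. It exists to
*reproduce and then freeze* that perception at import time — it is never
used silently.

Zero-order bonds contributing nothing to `occ` is what makes the
machine-readable organometallic drawing formula-safe: an η⁵ ring attached by
five zero-order bonds keeps its five C–H hydrogens, and a dative carbonyl
carbon with an explicit lone pair (unpaired = 2) plus a C=O double bond is
exactly tetravalent-occupied, so no hydrogens are invented.

```{r}
sn <- build_fixture("sncl2_naive")
c(strict = implicit_hydrogen_count(sn, 2, "strict"),
  legacy = implicit_hydrogen_count(sn, 2, "legacy"))
```

The strict table is property-tested against an independent brute-force
oracle that searches candidate hydrogen counts exhaustively rather than
solving the arithmetic.

## Formulas

`molecular_formula()` sums explicit atoms under (element, isotope) keys,
adds implicit hydrogens under natural-abundance H, and appends every
uninterpretable token to an ordered unknown-labels list — the formula is
honest about what it could not read, e.g. `Fe[CO][OC]` for a drawing with
text carbonyls. Formula strings follow Hill order (C, H, then alphabetical;
fully alphabetical when no carbon), with isotopes as bracketed mass-prefixed
elements: deuterated ammonium bromide prints `Br[2H]4N`. Bracket notation
was chosen over a special-case `D` symbol so that every isotope renders the
same way. Formula equality treats unknown labels as a multiset: their
stored order is drawing order, which is display metadata.

## Inline abbreviations

An abbreviation definition is a fragment molecule carried in the atom's
`a:` extension, serialized in the same dialect and escaped. The attachment
point is encoded as one designated pseudo-atom with the token `*`, bonded to
exactly one fragment atom; it is deleted on splice and the host bond
reattaches there. One explicit marker keeps fragments self-contained —
no side-channel index that an unaware editor could invalidate. Fragments
may nest recursively (an Et₃Si meta-abbreviation expands to a silicon
carrying three Et nodes); a label re-appearing in its own expansion chain
raises an error naming the chain. Spliced fragments are rigid-transformed so
the reattached bond is 1.5 long and points away from the host neighbour —
enough to keep depiction sane without a layout engine.

No abbreviation dictionary ships with the package: there is no universal
registry of what "Ph" means, which is precisely why every file must carry
its own definitions.

`subsume_fragment()` is the inverse operation (collapse a terminal fragment
into a new abbreviation); expansion after subsumption preserves the formula
exactly, and expansion is confluent — both property-tested across the
fixture registry.

## The wire dialect

The original sketcher's exact token spellings are not reproducible from the
available description, so the dialect here is the package's own, documented
in `R/sketchel.R` and frozen by golden files under `inst/extdata/`:
line-oriented UTF-8, a `SketchEl!(natoms,nbonds)` header, one atom line and
one bond line per record, `!End` terminator. Coordinates are fixed
4-decimal; an explicit hydrogen override is a present-vs-absent field so
that "explicitly zero" and "automatic" remain distinct; extension tokens are
comma-separated with backslash escapes. Writing is byte-stable for
value-equal molecules and refuses structurally broken graphs. Molecule
equality (`mol_equal()`) compares coordinates at half the serialization's
last digit (5e-5), so a record is equal to its parsed-back serialization.

## Molfile interop and the loss ledger

Import maps atoms, bonds, `M  CHG`/`M  ISO`/`M  RAD` blocks and wedge codes
onto the model, flags non-element labels, and — the central decision —
**materializes implicit hydrogens as explicit per-atom overrides** computed
under a caller-chosen table (or taken from an explicit valence field, which
always wins). Whatever the importing software would have perceived is
thereby frozen into the record and can never drift under later
re-interpretation.

Export is a deliberate lowest-common-denominator downgrade with a
machine-readable loss report. Zero-order bonds are written as single bonds
(not query-bond type 8, which most software would refuse) with a loss entry
per bond; orders 4–5 likewise; query extensions, mapping numbers, expanded
abbreviations and unknown extensions are all recorded. Hydrogen counts that
disagree with the legacy model are emitted through the atom valence field
(15 = zero), computed against the bond orders *as written* — so a legacy
re-import reproduces the frozen formula even for molecules whose zero-order
bonds were downgraded. The invariant "loss report empty iff the round trip
is exact" is property-tested.

## Datasheets and aspects

The datasheet is a typed table — molecule, string, integer, real, boolean —
serialized as XML (`<DataSheet>` / `<Header>` with `<Column>` and
`<Extension>` children / `<Row>` of `<Cell col="k">`). Null cells are absent
elements so numeric columns stay type-clean; molecule cells embed the
molecule dialect as escaped text. Header extensions are opaque named
payloads preserved byte-identically; the four recognized protocols (aspects)
parse them into views:

* **Solvent** — per-column display role and default units; purely
  presentational, carried and rendered, never enforced.
* **SARTable** — scaffold, substituent and composite-molecule columns plus
  property columns with units and range; `compose_sar_molecule()` grafts
  substituents onto `R`-placeholders with the same splice semantics as
  abbreviations.
* **Reaction** — component lines grouping molecule/text/number columns into
  one step with reactant/reagent/product roles.
* **Experiment** — Reaction plus per-component quantity columns and
  multiple steps.

The payload field lists are repo-specific (the behavioural contract, not a
published schema, is what the aspect concept fixes): one line per record,
`key=value` pairs separated by `;`. The load-bearing properties are
*tolerance* — generic row/cell/column edits by aspect-unaware software never
invalidate a payload — and *self-repair*: `repair_aspect()` recreates any
deleted required column, null-filled with its declared type, touches nothing
else, and is idempotent. Both are tested by simulating an unaware editor.

SDfile export writes one record per row and degrades every non-structure
column to a text data field; the dropped typing and aspects are logged.
Re-import sniffs types back best-effort (integer → real → boolean → string),
demonstrating exactly what the format cannot carry.

## The validation gate

"Zero or more than one interpretation" is operationalized as:

* **zero** — any uninterpretable token (ERROR `uninterpretable_label`) or a
  placeholder template submitted without an enumeration recipe (ERROR
  `template_requires_enumeration`). Errors reject.
* **more than one** — constructs with divergent plausible readings warn:
  a bare non-C/N/O/P/S element with open valence and no explicit hydrogen
  count, unpaired electrons or charge (`ambiguous_metal_valence` — the three
  listed fixes each silence it), hypervalent atoms (`hypervalent_atom` — a
  warning, never an error, because carboranes are legal), covalent
  alkali–halide bonds, and neutral pentavalent nitro groups. A non-zero net
  charge on a single-component entry is INFO.

Warnings never block: the originating scientist is always the final
arbiter, and the gate never mutates its input — proactive "fixing" of
structures does more harm than good. On acceptance the gate returns the
computed formula for display, closing the feedback loop at entry time. The
rule inventory is the small set above; the registry is structured so more
rules can be added without touching the gate.

Template enumeration substitutes every placeholder site from its candidate
list (Cartesian product), grafts with the shared splice, and removes
duplicates by attribute-preserving graph isomorphism — iterative colour
refinement followed by refinement-guided backtracking. Worst-case behaviour
is acceptable because enumerated species are tiny; sites made equivalent by
symmetry genuinely collapse (two interchangeable sites with the same two
options yield three species, not four), which is the correct count of
distinct chemical species.

## Depiction

Stored coordinates are authoritative — 2D positions belong in the data, and
a full de-novo layout engine is explicitly out of scope. `layout_fragment()`
exists only for generated fragments: chains zigzag at 120°, single rings go
on regular polygons, every bond comes out at 1.5 ± 1e-6, and fused
polycycles raise a typed error so the caller keeps original coordinates.

`render_molecule_svg()` emits pure SVG 1.1 primitives with stable element
order and fixed 2-decimal formatting, so equal inputs give byte-equal
output. Zero-order bonds are dashed — visibly different chemistry must look
different. Wedges render from the narrow end at the bond's `from` atom
(the stereo bond's own orientation; the convention is documented rather
than configurable). Carbon labels are suppressed unless charged, isotopic,
explicitly hydrogenated, radical or unbonded. Reaction schemes place
reactants left of the arrow, products right, text/number components above
it, steps stacked. PNG output is a convenience wrapper that redraws the
same primitives on a raster device at caller-chosen resolution; the SVG
remains the source of truth.

## What the fixtures do and do not show

The fixture registry reconstructs the worked structures this design is
argued from — bromobenzene at two abbreviation depths, triethylsilane at
three, the tin dichloride ambiguity and its three fixes, the bare C₅ ring,
deuterated ammonium bromide, the X/R template, the iron dimer in drawn and
machine-readable form — plus validation provocations and the four aspect
sheets. Property tests run on top of generators: random small organics
(2–9 atoms, orders 1–3, charges −1..+1) for the hydrogen oracle and Molfile
round trips, and randomly decorated molecules (extension tokens with
hostile characters, isotopes, overrides, stereo) for serialization
integrity. Test problem sizes — 200 serialization round trips, 1,000 oracle
atoms, 60 Molfile round trips — keep the suite under half a minute while
exercising every branch of the decision tables.

What passing these tests does *not* show: that real-world Molfiles from
arbitrary sketchers import losslessly (only the documented V2000 subset is
read); that the validation rule set catches every bad structure (it
implements the documented rules, not a curation platform's full catalog);
or that depiction is publication-quality aesthetics (it is faithful,
deterministic and scalable, which is the design goal).

## Known limitations

* No aromatic perception, tautomer handling or standardization — by design.
* Molfile V3000, S-groups, polymer and Rgroup blocks are out of scope.
* Abbreviations are single-attachment (terminal); polyvalent abbreviations
  would need a different attachment encoding.
* `layout_fragment()` does not handle fused polycycles.
* Exact/monoisotopic mass is not computed; the formula map is the endpoint.
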
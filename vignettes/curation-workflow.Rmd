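---
title: "Curating legacy collections of computed molecular structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating legacy collections of computed molecular structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molcurate)
```

## The problem

A decade-old repository collection of semi-empirically optimized molecular
structures is a difficult thing to reuse. The structure documents were
written in an evolving XML dialect (two different syntaxes for declaring the
net charge of a species), the quantum-chemistry inputs that produced them
were not archived, and the metadata that would let a program find, fetch and
re-verify an individual molecule was never exposed in a standard form.
`molcurate` implements the curation workflow such a collection needs:
validate and normalize the legacy Chemical Markup Language (CML) records,
make every charge and spin declaration explicit before regenerating
quantum-chemistry inputs, compare structure versions through layer-dissected
InChI identifiers, and package each molecule as a repository-ready
deposition bundle (METS manifest, OAI-ORE resource map, SWORD archive) with
DataCite-crosswalked, machine-actionable metadata.

## Charge semantics: absence is not zero

Legacy corpora declare a molecule's formal charge in two dialects: an early
`identifier` element with a `<charge>` child (alongside a proto-InChI
`<basic>` string), and the later `formalCharge` attribute on the `molecule`
element. The failure mode that motivates this module is *implicit
semantics*: a format converter that propagates neither dialect, leaving the
downstream program to default an undeclared charge to zero. For a +1 cation
that silently turns the calculation into a different (odd-electron) species.

`parse_cml()` therefore records each dialect independently, with `NA`
("absent") as a state deliberately distinct from `0`. `reconcile_charge()`
applies the precedence *formal attribute > legacy identifier > default
zero*, flags disagreements rather than aborting (corpus curation must
annotate-and-continue), and flags magnitudes above 3 as implausible —
inspection of such species in legacy data shows them to be curation errors
(misread metal centres), so they are reported, never "corrected".

The spin side of the guard: `electron_count()` sums atomic numbers minus the
net charge, `spin_state()` maps even counts to `SINGLET` and odd to
`DOUBLET` (higher multiplicities are out of scope and rejected), and every
generated input deck carries both `CHARGE=<n>` (always, including
`CHARGE=0`) and exactly one spin keyword. Because the program consuming the
deck recomputes the parity itself, the explicit spin token acts as a
checksum: a wrong or missing charge becomes a hard error instead of a
silently different molecule.

## Geometry: internal coordinates

Input decks default to internal (Z-matrix) coordinates. The reference-atom
choice is not critical — optimized positions do not depend on the starting
coordinate system — so references are chosen for numerical stability:
nearest previously defined atom for the distance, nearest other for the
angle, nearest non-collinear for the dihedral (with a next-nearest
fallback). Distances are written with 4 decimals and angles with 2, matching
the round-trip tolerances (1e-4 Å on reconstructed pairwise distances,
1e-2°). Reconstruction uses standard local-frame placement and preserves
handedness, which the test suite checks via signed tetrahedron volumes, not
only distance matrices.

## Connectivity and InChI concordance

An InChI is derived from atom connectivity, which for computed structures
must itself be derived from Cartesian coordinates by distance heuristics.
Those heuristics are not a formal standard, so this package treats them as
explicit configuration: a bundled single-bond covalent radius table (Cordero
et al. 2008 values) with a default tolerance of 0.40 Å, and a lower floor of
0.40 Å below which a pair is reported as corrupt geometry rather than a
bond. Every structure version is first normalized to bare Cartesian form
(`to_canonical_xyz()` discards any bond data the source may carry, and
orders atoms element-alphabetically for deterministic diffs), so that all
InChIs are generated against a single connection algorithm — the OpenBabel
binding of the IUPAC reference implementation, which this package drives but
deliberately does not re-implement.

Version triplets (original database entry, legacy optimization,
re-optimization) are compared by exact whole-string InChI equality and fall
into five mutually exclusive categories — all match, the two computed
versions agree against the original, either computed version alone
disagrees, or all differ. Mismatches are then attributed to InChI layers
(formula, connectivity, hydrogen, charge, protonation, double-bond stereo,
tetrahedral stereo, isotope) in a separate diagnostic pass;
`divergent_layers()` reports *every* differing layer, because one mismatch
can (and in practice does) differ in several layers at once — a per-layer
histogram can therefore legitimately total more than the number of
mismatched pairs. Double-bond and tetrahedral stereo are reported as
separate labels; the protonation sublayer is reported separately from the
charge layer, since the two can flip independently.

## Packaging and metadata

Each curated molecule becomes a deposition bundle: the two source CML
documents, a conflated CML carrying all three provenance-tagged geometry
blocks, and the optimizer input/output. `build_mets()` writes a manifest
with MD5 checksums, byte sizes and chemical media types per file (MD5 is
retained for fidelity to the repository profile being emulated; the
manifest records `CHECKSUMTYPE` so a future curation can migrate), with
bitstream locators of the form
`/bitstream/handle/<handle>/<file>?sequence=<n>`. `build_ore_map()` emits an
RDF/XML resource map aggregating the same file set; METS/ORE consistency is
an invariant of the test suite. `build_sword_bundle()` zips manifest plus
payloads for a METSDSpaceSIP-packaged deposit; the deposit itself is
represented as a dry-run request object (headers including `X-Packaging`)
and never performed — all network operations stay behind value objects.

`crosswalk()` maps entry metadata onto the DataCite Metadata Schema 3.0
kernel — the version that introduced the `HasMetadata` relation type — so
the METS and ORE manifest locations become machine-actionable related
identifiers, chemical identifiers (InChI, InChIKey, CAS, NCI, SMILES)
become alternate identifiers, and contributor ORCID iDs (validated
including their ISO 7064 checksum digit) become name identifiers. Outputs
are validated against a bundled subset schema of the kernel, authored for
this package as a validation profile. Retrieval URL builders reproduce the
two content-negotiation patterns exactly
(`<resolver>/<handle>?locatt=mimetype:<type>` and
`<content-resolver>/<type>/<doi>`), and the search-query builder serializes
the fielded grammar (`+`-joined `field:value` terms, `:` backslash-escaped
inside values, `*` wildcards preserved).

## The synthetic corpus generator

No deposited accession is required to test any stage: `generate_corpus()`
builds a seeded synthetic corpus from a built-in library of ~30
hand-selected small organics with frozen 3D geometries (stored as plain
JSON; generated once with standard 3D embedding and committed, so runs are
reproducible offline). Its defaults are chosen to emulate the statistical
shape of a real legacy corpus: predominantly neutral, unique, annotated
entries; 8% without a computed annotation; 5% duplicate accessions; a
dialect mix in which the modern attribute dominates but 10% of entries
carry disagreeing declarations and 10% carry none; 10% salt entries with a
counter-ion component; 5% implausible (|q| > 3) declarations; and 21
layer-targeted InChI mismatches per 200 entries, spread over six layers.

Layer injections use frozen base/variant geometry *pairs* whose divergent
layer sets were determined empirically through the package's own
normalization path and are re-verified by the test suite at run time:

* hydrogen removal (ethanol) → {formula, hydrogen}: hydrogen-count
  mismatches surface in the formula layer, the dominant real-world pattern;
* an S–S bond stretched across the perception threshold in 1,2-dithiane →
  {connectivity} alone: the classic "verge of connection" case;
* acetone vs. propen-2-ol geometry → {hydrogen} alone (same formula, same
  skeleton);
* a sodium acetate contact pair vs. the separated ions → {formula,
  connectivity, hydrogen, charge, protonation}: a geometry-only *pure*
  charge-layer flip is not producible through the Cartesian normalization
  path, so charge injections arrive with their chemically inevitable
  companion layers;
* cis/trans-2-butene → {double_bond} alone;
* mirror-inverted butan-2-ol → {tetrahedral} alone (stereo injection
  operates geometrically, by coordinate inversion, so it exercises the real
  normalization path rather than editing strings).

Isotope-layer injections are refused with an explanatory error: the
Cartesian normalization this workflow mandates cannot carry isotope labels,
so an injected isotope difference could never be recovered — the layer
parser and comparator still support the `i` layer fully for identifiers
that arrive with one.

Benign geometry jitter (uniform ±0.01 Å) stands in for re-optimization
noise on non-injected entries; at that magnitude every library molecule's
connectivity, and hence InChI, is invariant (verified for all molecules in
the suite). What the generator does *not* emulate: the true NCI structure
distribution, real semi-empirical physics, 2D-to-3D stereo ambiguities, or
metal-centre perception errors. Passing the recovery tests therefore
certifies the pipeline's bookkeeping and normalization, not the behaviour
of bond-perception heuristics on exotic chemistry.

## Worked example

```{r example, eval = FALSE}
spec <- injection_spec(50, seed = 7,
                       per_layer_mismatch_counts = c(connectivity = 2L,
                                                     tetrahedral = 1L))
dir <- tempfile("corpus")
gen <- generate_corpus(spec, dir)
report <- run_pipeline(run_config(dir))
report$concordance$counts
report$concordance$layer_distribution
```

## Numerical and design choices

* Problem sizes: the shipped test suite runs corpora of 25–200 entries and
  50-geometry property sweeps; these sizes give exact, reproducible
  recovery while keeping a full run in well under a minute.
* Duplicate resolution keeps the first record per accession in input order:
  deterministic and order-stable.
* Equal-size component ties retain the component containing the lowest
  original atom index and set a tie flag.
* When a counter-ion component is removed and neither dialect declares a
  charge, the record is flagged charge-suspect rather than assigned one: a
  split salt with no declared fragment charge is chemically implausible,
  and inventing a charge would repeat the implicit-semantics mistake.
* The optimization stage is a pluggable external command with a built-in
  mock (echoes the geometry as a normally terminated output), so the
  pipeline and its tests never require licensed software.
* CML, METS and ORE validation are documented subset-profile checks
  (violations carry XPath-like locations); DataCite validation uses a
  bundled subset XSD. Full third-party schemas are out of scope.
* Handles and DOIs are syntax-validated but never resolved at build time;
  the artifact stores both identifiers explicitly per entry rather than
  deriving one from the other.

## Known limitations

* InChI generation requires the `obabel` executable on the PATH; there is
  no pure-R fallback, by design (the reference implementation is the
  normalization standard, and connectivity thresholds differ between
  binding versions, so bit-identical replication of another version's edge
  cases is not claimed).
* Only singlet/doublet spin states are modeled.
* The concordance classifier treats InChIs as opaque strings; it makes no
  attempt to explain *why* layers differ beyond naming them.
* MolFile wedge-bond stereo parsing is out of scope.
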
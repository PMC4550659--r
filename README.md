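# molcurate

Standards-based curation of collections of computed molecular structures.

Legacy repository collections of quantum-chemically optimized molecules are
hard to reuse: their Chemical Markup Language (CML) documents mix two
charge-declaration dialects, the optimizer inputs that produced them were
never archived, and per-molecule metadata was never exposed in a
machine-actionable form. `molcurate` is a toolkit for re-curating such a
collection end to end:

* **CML records** — parse, profile-validate and write both dialects (the
  legacy `identifier/charge` child and the modern `formalCharge`
  attribute), deduplicate a corpus by accession, exclude entries without a
  computed annotation, and retain the largest connected component of salt
  entries.
* **Charge/spin semantics** — reconcile the two declarations with explicit
  precedence and conflict flags; an absent declaration is a distinct state,
  never silently zero. The electron count N = Σ Z_i − q determines the spin
  multiplicity (even → singlet, odd → doublet), and every generated input
  deck carries `CHARGE=<q>` plus the spin keyword so the consuming program's
  own parity check acts as a checksum. Charges with |q| > 3 are flagged as
  implausible.
* **Optimizer I/O** — fully explicit semi-empirical input decks, internal
  (Z-matrix) or Cartesian geometry, with a distance-preserving,
  handedness-preserving round trip; a mock optimizer stands in for the
  licensed external stage.
* **Connectivity & InChI** — bond perception by covalent-radius rules
  (edge iff `d(i,j) ≤ r_i + r_j + tolerance`, bundled Cordero radii,
  tolerance 0.40 Å), normalization of every structure version to bare
  Cartesian form, InChI/InChIKey generation via the OpenBabel binding of
  the reference implementation, and dissection of identifiers into layers
  (formula `/c /h /q /p /b /t /i`).
* **Concordance** — classify each three-version triplet (original, legacy
  optimization, re-optimization) into the five equality categories, and
  attribute every mismatch to the set of divergent InChI layers.
* **Packaging & metadata** — per-entry METS manifests (MD5, sizes, chemical
  media types, bitstream locators), OAI-ORE resource maps, SWORD-ready zip
  archives, and a DataCite 3.0 crosswalk with `HasMetadata` related
  identifiers, chemical alternate identifiers and ORCID name identifiers,
  plus the content-negotiation URL builders and fielded search-query
  grammar.
* **Fixtures** — a seeded synthetic-corpus generator with exact ground
  truth (duplicates, missing annotations, dialect mix, counter-ions,
  per-layer InChI mismatch injections), so every stage is testable offline.

## Worked example

```r
library(molcurate)

# a seeded 50-entry synthetic corpus with three injected InChI mismatches
spec <- injection_spec(50, seed = 7,
                       per_layer_mismatch_counts = c(connectivity = 2L,
                                                     tetrahedral = 1L))
dir <- tempfile("corpus")
gen <- generate_corpus(spec, dir)
report <- run_pipeline(run_config(dir))
print(report)
#> <corpus_report read=52 unique=46 duplicates=2 excluded=4>
#> charge conflicts: 5 implausible: 2
#> <concordance_table n = 46 >
#>       ALL_MATCH PM5_PM7_NOT_NCI PM7_NCI_NOT_PM5 PM5_NCI_NOT_PM7      ALL_DIFFER
#>              43               0               0               3               0
#> layer distribution ( PM7 vs NCI ):
#>  tetrahedral connectivity
#>            1            2
#> bundles: 46  errors: 0
```

Reading: 52 documents were ingested, 2 duplicate accessions dropped and 4
entries excluded for lacking a computed annotation. Of the 46 surviving
triplets, 43 have identical InChIs across all three structure versions; the
3 injected re-optimization mismatches are recovered in exactly the layers
the generator injected (two connectivity, one tetrahedral-stereo), and the
5 dialect conflicts and 2 implausible charges match the generator's ground
truth. All 46 entries were packaged as METS/ORE/SWORD bundles with valid
DataCite records.

Reconciling the two printed charge dialects of a single entry:

```r
rec <- molecule_record("NSC138467", atoms("C"), nsc_id = 138467L,
                       formal_charge_attr = 1L, legacy_charge = 1L)
reconcile_charge(rec)
#> <charge_assignment +1 from FORMAL_ATTR>
```

A command-line front end is installed as `exec/molcurate`
(`molcurate validate`, `dedup`, `charges`, `mopac-input`, `inchi`,
`concord`, `package`, `fixtures`, `run`).

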
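---
title: "Models and methods behind protutils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind protutils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protutils)
```

protutils packages the support layer that most proteomics software needs
but no one wants to rewrite: mass arithmetic, digestion, fragmentation and
spectrum annotation, peak-list and FASTA I/O, a unified view of
search-engine results, and generated data-access code. This vignette
explains the models behind each component, the parameters that matter, and
the choices made where the design was genuinely open.

## Mass model

A peptide's neutral monoisotopic mass is the sum of its residue masses
(the free amino acid minus one water) plus one water for the intact chain,
plus the mass shifts of any fixed-mass modifications:

$$M = \sum_{i=1}^{n} m_{\mathrm{res}}(a_i) + m_{\mathrm{H_2O}} + \sum_j \delta_j$$

Positive ions observe at $m/z = (M + z\,m_p)/z$ with $m_p$ the proton
mass. The residue and constant tables ship as tab-separated resources
under `inst/extdata/` with provenance notes in their headers — a single
auditable source of truth rather than literals scattered through code. We
use current IUPAC/CODATA atomic masses (proton 1.007276466879 Da, water
18.0105646859 Da); residue values carry six decimals.

Modification positions follow one convention everywhere: 0 is the
N-terminus, 1..n the residues, n+1 the C-terminus. Nonstandard residues
(B, J, X, Z, U, O) are rejected by default so that unusual sequences fail
loudly; `permissive = TRUE` admits selenocysteine (U) and pyrrolysine (O)
with their standard masses. We deliberately do not silently average
ambiguous codes.

The load-bearing invariant is additivity:
`mass(PQ) = mass(P) + mass(Q) - water` to 1e-9 Da, which the test suite
checks over a thousand random peptide pairs, and which pins down the
residue-sum model against off-by-one-water errors.

## Digestion

An enzyme is modelled as a set of residues it cleaves after plus a set of
residues that block cleavage when they follow the site — the classic
"trypsin cuts after K/R but not before P" convention, which is also the
most common one in search engines. Coordinates are 1-based inclusive
throughout. `digest()` produces every peptide with 0..m missed cleavages;
the zero-missed-cleavage peptides concatenate back to the parent, which is
the invariant that catches boundary mistakes. Correctness is established
against a brute-force enumerator of all substrings filtered by the
cleavage rule, an implementation with no shared code. Built-in enzymes
(trypsin, Lys-C, Arg-C, chymotrypsin high-specificity, Glu-C) follow
standard definitions; semi-specific and non-specific digestion are out of
scope.

## Fragmentation and annotation

Backbone cleavage gives the N-terminal a/b/c and C-terminal x/y/z series.
We define b and y from residue prefix/suffix sums and derive the siblings
by fixed offsets (a = b − CO, c = b + NH3, x = y + CO − H2, z = y − NH3).
z ions default to the z-dot radical (z + 1 H) because that is the species
electron-transfer-dissociation spectra conventionally show; plain z is one
flag away. The algebraic identity $b_i + y_{n-i} = M + 2 m_p$ at 1+ is the
fragmentation module's self-check.

Neutral losses are generated "chemically aware" by default: H2O losses
only for fragments containing S/T/E/D and NH3 losses only for fragments
containing R/K/N/Q. This halves annotation clutter at no cost when the
loss cannot occur; the switch exists because some viewers prefer
exhaustive ladders.

`annotate_spectrum()` is a pure per-ion search: each theoretical ion takes
the peak minimizing |observed − theoretical| within the tolerance (Da or
ppm, ppm relative to the theoretical m/z), ties broken by higher
intensity, then lower m/z. One ion annotates at most one peak, but several
ions may share a peak — mirroring common viewer behaviour and keeping the
result invariant under permutation of the ion list (the output is sorted
by theoretical m/z). The default tolerance of 0.01 Da suits
centroided ion-trap data; high-resolution data would use 5–20 ppm.

## Spectra, chromatograms and rendering

Spectra are ordered (m/z, intensity) lists with optional precursor
metadata; chromatograms are (time, signal) traces. MGF reading accepts the
common dialect (`BEGIN IONS`/`END IONS`, `TITLE`, `PEPMASS`, `CHARGE
2+`); writing uses fixed formatting (m/z four decimals, intensity two), so
write∘read is the identity on its own output. Duplicate m/z peaks are
retained in stable order rather than merged — merging is a processing
decision the I/O layer should not take.

Rendering targets static files. SVG is written by a small deterministic
generator inside the package: identical inputs produce byte-identical
files and annotation labels appear as literal text, which makes the
rendering contract testable (and the files greppable); PNG goes through
the standard graphics device with the same layout. The intensity axis
spans 0..1.05 × the maximum intensity inside the view window; only data in
the window is drawn. When two labels would collide horizontally (closer
than 1% of the window width), the lower-intensity label moves up one
12-pixel line per conflict, highest-intensity labels placed first — a
deterministic rule rather than a layout heuristic.

Interactive behaviour is reduced to its testable core: a `view_state`
models a panel's x-window, and `link_views()` groups views so that
`set_window()` on any member propagates to all. Propagation is idempotent
(re-setting the current window fires no updates), which is what makes it
loop-free by construction.

## Search-result abstraction

Results from different search engines carry the same information in
incompatible shapes. The package normalizes three dialects — a
Mascot-dat-like sectioned text format, an X!Tandem-like XML format and an
OMSSA-like CSV format — into one match model: spectrum title, peptide,
1-based modification positions, charge, precursor m/z, protein accessions,
rank, and the engine's score copied verbatim with orientation metadata
(ionscore higher-is-better; expect/E-value lower-is-better). Scores are
deliberately *not* normalized across engines: cross-engine calibration is
a research topic, not plumbing, and silently rescaling scores would
corrupt downstream filtering.

The dialects are documented minimal subsets defined bit-exactly by the
fixture generator, not the full native formats, which are version-labile;
the abstraction layer is what matters and the subsets exercise it fully.
Numeric fields are carried at fixed printed precision (precursor m/z four
decimals, scores six), so all three adapters parse bit-identical doubles
and the convergence property — one ground truth, three encodings, three
field-identical parses — can be asserted with exact equality. Engine,
score name and score orientation are excluded from that equality: the
orientation is a pure function of the engine, so it differs by
definition.

Format detection sniffs the first bytes (XML declaration + `bioml` root;
MIME `boundary=` + `Mascot` token; the documented CSV header line) and is
stable under a UTF-8 byte-order mark and Windows line endings. A file
matching no rule fails with all three rules listed rather than a generic
error.

## Generated data access

`introspect()` reads a table's column types, nullability, primary key,
whether the key is database-assigned, and the audit columns
`creationdate`/`modificationdate` (exact lowercase name match among
timestamp-typed columns; a column with an audit name but another type is
flagged and left alone). `generate()` then emits a self-contained accessor
class exposing exactly four operations — persist, update, retrieve,
delete — with every value bound as a statement parameter; the caller never
sees SQL. Persist sets both audit columns and reads back a
database-assigned key; update refreshes `modificationdate` only and is a
no-op on a clean instance; generation is a pure function of the
descriptor, so identical descriptors give byte-identical source (each file
carries the descriptor's hash).

The reference engine is embedded SQLite through DBI — zero-configuration
and desk-scale testable — and the emitted SQL is the common-denominator
dialect; the one engine-specific shim is the last-inserted-key query.
Timestamps come from an injectable clock (UTC, microseconds) instead of
SQL `NOW()`, so tests can assert "strictly later modificationdate" without
sleeping. Multi-column database-assigned keys are rejected at generation
time; tables without a primary key cannot satisfy the retrieval contract
and are rejected likewise.

## The fixture generator, and what passing tests do not show

All test inputs are generated in code: FASTA databases per header dialect,
MGF peak lists, ground-truth PSM sets rendered into all three dialect
files, spectra with planted fragment ions, and random table schemas. Every
generator is a pure function of its seed (the caller's RNG state is saved
and restored), with one central seed threaded through, so any failure is
replayable.

The defaults model a small, clean corpus: 5 proteins of 50–300 residues
with uniformly drawn sequences, 5 spectra of 10–60 peaks, 6 PSMs over 3
spectra with up to 2 modifications each, schemas of 1–8 columns over the
five supported types with audit columns on half. Planted-ion spectra place
peaks within ±0.002 Th of theory — comfortably inside the 0.01 Da matching
tolerance, as for well-calibrated instruments — plus uniform noise peaks at
lower intensity.

These choices make the suite a verification of the *logic*, not of
performance on real data: uniform residue usage is not a real proteome's
composition, planted spectra have no isotope envelopes, chimeric
precursors or systematic calibration error, and the dialect files are
subsets of the real formats. A 100% planted-ion recovery therefore shows
the matcher is correct, not that real spectra will annotate completely.

## Numerical and degenerate-input choices

* Equality tolerances in tests: 1e-9 Da for mass identities, 1e-6 Th for
  fragment complementarity — an order looser than accumulated
  double-rounding, an order tighter than any chemical difference.
* A single-residue peptide has no internal bonds and fragments to an empty
  table; an empty spectrum annotates to an empty table; an empty FASTA or
  result file yields an empty collection. Errors are reserved for
  malformed input, and carry line numbers where the input is line-based.
* Duplicate FASTA accessions parse with a warning rather than failing:
  real databases contain them.
* Problem sizes in the property suites (1,000 mass pairs, 500
  complementarity peptides, 200 digestion oracles, 20 CRUD schemas) keep
  the whole suite under a minute while leaving no residue class or rule
  combination unexercised.

## Known limitations

No isotope-distribution or elemental-formula arithmetic beyond the shipped
tables; no semi-specific digestion; no immonium or internal ions; no
intensity prediction; no mzML or mzIdentML (established parsers exist);
no protein inference or FDR estimation; the generated accessors are
single-table CRUD, not an ORM.
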
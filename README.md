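# protutils

Utilities for computational proteomics in R: the support layer that most
proteomics tools need before they can do anything novel. The package is
aimed at developers of proteomics software and at analysts who want
scriptable, testable versions of the operations usually buried inside GUI
viewers.

It provides:

* **Mass arithmetic** — monoisotopic/average peptide masses with
  fixed-mass modifications, and m/z ↔ neutral-mass conversion:
  *M* = Σ residue masses + H₂O + Σ mod shifts, *m/z* = (*M* + *z*·m_p)/*z*.
* **In-silico digestion** — cleave-after / restrict-before enzyme rules
  (trypsin, Lys-C, Arg-C, chymotrypsin, Glu-C built in) with missed
  cleavages, 1-based inclusive coordinates.
* **Fragmentation & annotation** — a/b/c/x/y/z series (z as z-dot by
  default), H₂O/NH₃ neutral losses restricted to chemically capable
  fragments, and nearest-peak annotation within a Da or ppm tolerance with
  deterministic tie-breaks.
* **Spectrum & chromatogram models** — MGF read/write, deterministic SVG
  (and PNG) rendering with collision-resolved fragment labels, and linked
  view windows where zooming one panel zooms the group.
* **FASTA I/O** — header dialect auto-detection (UniProt, NCBI gi, IPI,
  generic fallback) with byte-identical header round-trip.
* **Search-result abstraction** — auto-detecting adapters for three
  result dialects (Mascot-dat-like, X!Tandem-like XML, OMSSA-like CSV)
  converging on one engine-agnostic peptide-spectrum-match model.
* **Data-access code generation** — introspect a table (types, keys,
  `creationdate`/`modificationdate` audit columns) and emit an accessor
  class exposing persist/update/retrieve/delete with all SQL hidden and
  parameterized.
* **A fixture generator** — every test input (FASTA, MGF, result files,
  schemas, spectra with planted ions) is generated deterministically from
  a seed; nothing is downloaded.

## Worked example

Digest a protein, fragment one peptide, and annotate a spectrum
containing its ions:

```r
library(protutils)

monoisotopic_mass("DLVTGR")
#> 659.3602
mz(monoisotopic_mass("DLVTGR"), 2)
#> 330.6874

digest(protein("demo", "MKWVTFISLLFLFSSAYSRGVFRR"),
       builtin_enzymes("trypsin", missed_cleavages_max = 1))
#>                sequence start end missed_cleavages
#> 1                    MK     1   2                0
#> 2   MKWVTFISLLFLFSSAYSR     1  19                1
#> 3     WVTFISLLFLFSSAYSR     3  19                0
#> 4 WVTFISLLFLFSSAYSRGVFR     3  23                1
#> 5                  GVFR    20  23                0
#> 6                 GVFRR    20  24                1
#> 7                     R    24  24                0
```

The digest table lists each peptide with its 1-based coordinates in the
parent and how many cleavage sites it spans. `MK` before `W` is cut
because K is not followed by P; the missed-cleavage rows join adjacent
fragments.

```r
res <- make_spectrum_for("DLVTGR", noise_peaks = 5, seed = 42)
ann <- annotate_spectrum(res$spectrum, res$ions, tolerance = 0.01)
head(ann[, c("peak_index", "label", "theoretical_mz", "observed_mz", "error_mz")], 4)
#>   peak_index label theoretical_mz observed_mz     error_mz
#> 1          2   b1+       116.0342    116.0359 0.0016592242
#> 2          4   y1+       175.1190    175.1190 0.0000763838
#> 3          5   b2+       229.1183    229.1200 0.0017483017
#> 4          6   y2+       232.1404    232.1414 0.0009463533
```

Each row ties a theoretical fragment ion (e.g. `y1+`, the protonated
C-terminal arginine at 175.1190 Th) to the observed peak that matched it
within 0.01 Da, with the signed mass error. Rendering the spectrum writes
the same labels into a deterministic SVG:

```r
render(res$spectrum, "annotated.svg", format = "svg", annotations = ann)
```

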
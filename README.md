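# barrelmetry

Quantitative geometry and topology analysis of beta-barrel membrane-protein
models, built around the VDAC fold.

## The problem

VDAC — the voltage-dependent anion channel of the mitochondrial outer
membrane — folds as a 19-strand transmembrane β-barrel sealed by H-bonding
between its parallel terminal strands (β1/β19), with an N-terminal segment
folded inside the pore. Its lower-conductance "closed" conformers have no
experimental structures, and folding-engine predictions for VDAC sequences
with "cryptic" domains excised produce a whole spectrum of distorted
topologies. Comparing those models requires the same measurements applied
uniformly to every structure. barrelmetry replaces interactive viewer-based
measurement with programmatic operations:

- backbone H-bond detection (distance + Kabsch–Sander energy criterion, with
  geometric amide-H reconstruction) and a census of *stretched* bonds
  (donor–acceptor beyond 3.8 Å);
- β-strand segmentation and the strand-pairing sheet graph;
- barrel-axis fitting with cylindricity diagnostics;
- pore caliper diameter d = (d_max + d_min)/2 and ellipticity d_min/d_max at
  the mid-barrel Cα backbone;
- the N–C gap (orthogonal Cα distance between the first and last barrel
  strands, with an axis-normal convention for very wide gaps);
- per-strand tilt relative to the axis and sheet-twist handedness;
- N-terminal-segment contact counts with the barrel wall;
- classification into the five-class topology taxonomy
  (I closed barrel, II partial barrel with outward-swung flap, III disrupted
  sheet with an axis-normal flap, IV left-twisted barrel, V collapsed sheet).

A deterministic generator of idealized β-barrels and distorted archetypes —
built on the classical lattice closed forms
R = √((S·a)² + (n·b)²) / (2·n·sin(π/n)) and α = atan(S·a/(n·b)) for strand
count n and shear number S — provides structures with exactly known ground
truth for validation. A construct builder enumerates the systematically
modified VDAC sequences (N-terminal/strand deletions, insertions, tandem
repeats) used to probe alternative conformers.

## Worked example

```r
library(barrelmetry)

# a 19-strand, shear-21 idealized barrel -- the canonical VDAC geometry
s  <- make_barrel(ideal_barrel_params(n = 19, S = 21))
an <- analyze_barrel(s)
an
#> <barrel_analysis> barrel_n19_S21
#> <topology_report> barrel_n19_S21: Class I
#>   strands 19, N-C gap 4.4 A, stretched strands 2, handedness right
#>   pore diameter 34.7 A (ellipticity 1.00)
```

The report says: all 19 strands were recovered; the terminal strands sit
4.4 Å apart (H-bonded, the closed-barrel situation); the sheet twists
right-handed, as natural β-sheets do; the mid-barrel caliper diameter is
34.7 Å with an essentially circular cross-section; the fractional-shear
"wrap" interfaces of the S = n + 2 lattice show up as 2 strands with
stretched H-bonds. `summary(an)` adds the axis fit and H-bond totals;
`plot(an)` draws the mid-slab cross-section.

Batch analysis and fixture generation:

```r
write_fixture_suite("fixtures", replicates = 3, seed = 1)   # 15 PDBs + manifest
out <- analyze_structures("fixtures", out_dir = "reports")  # JSON + TSV ledger
out$table[1:3, 1:4]
#>       CONSTRUCT CLASS N-C GAP(A) MEAN_CONF
#> 1 classI_rep001     I        4.8         -
#> 2 classI_rep002     I        4.2         -
#> 3 classI_rep003     I        4.7         -
```

A thin command-line front end covering the same operations ships at
`inst/scripts/barrelmetry-cli.R` (verbs `analyze`, `fixtures`,
`constructs`).

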
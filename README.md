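# tpscan

Training-free detection of protein-coding regions in DNA via
triplet-periodicity walks.

## The problem

Coding DNA is read in codons, and synonymous codons are used with very
unequal frequencies. The result is a period-3 statistical signal —
*triplet periodicity* (TP) — present in coding regions and absent from
random or non-coding DNA. TP-based scanners are attractive for newly
sequenced organisms with no training data, no annotated relatives, and no
usable homologs: they need nothing but the sequence itself.

`tpscan` is for researchers who have draft scaffolds of such an organism
and want a ranked, coordinate-level list of *suspected coding regions* to
triage (e.g. for downstream similarity search or experimental follow-up).

## The method

For a sequence `X = x_1..x_N`, the TP vector at position `t` counts the
occurrences of the residue `x_t` in the suffix after `t`, stratified by
phase offset mod 3:

    s_t = (Z1, Z2, Z3),   Zj = #{ u > t : x_u = x_t, (u - t - 1) mod 3 = j - 1 }

These are rows of the suffix's 4 × 3 triplet-periodicity matrix,
maintained by a backward recursion (shift every base vector right
circularly, `(Z1,Z2,Z3) → (Z3,Z1,Z2)`, then count the incoming residue).
Each vector is mapped through the cube roots of unity,

    L(s) = Z1·e^(-i2π/3) + Z2·e^(-i4π/3) + Z3,

and the TP walk moves one unit in the direction of `L(s_t)` whenever
`L(s_t) ≠ 0` (an exact integer test: `L(s) = 0` iff `Z1 = Z2 = Z3`).
Codon-biased DNA concentrates each base at one codon position, so the
walk drifts directionally (~0.2 units/step for strongly biased genes);
i.i.d. DNA makes it diffuse near the origin (|W_N|/N ≈ 0.01–0.03).

On top of the walk, `tpscan` adds an automated region caller: a windowed
per-step drift profile (computed in both sequence orientations and
combined, because the suffix statistic is sharp only at a region's 5'
edge), thresholding, run merging, a minimum call length, half-height
boundary refinement, and recursive re-scanning of the flanks after
excising the calls. Calls come back as a `GRanges` with a drift score and
pass provenance, exportable to BED6, GFF3 and TSV.

## Worked example

Build a synthetic genome — a 5000-bp random background carrying a
5244-bp codon-biased insert at position 2000 — and scan it:

```r
library(tpscan)

fx <- buildFixture(5000, insertLengths = 5244, insertPositions = 2000,
                   seed = 1, id = "demo")
fx$truth
#> GRanges object with 1 range and 0 metadata columns:
#>       seqnames    ranges strand
#>   [1]     demo 2000-7243      *

netDisplacement(tpWalk(fx$sequence))
#> magnitude     angle
#>  1154.957    -0.042

scanSequence(fx$sequence)
#> GRanges object with 1 range and 2 metadata columns:
#>       seqnames    ranges strand |     score      pass
#>   [1]     seq1 2048-7164      * |  0.238267         1
```

The walk travels ~1155 units in 10244 steps, almost parallel to the real
axis — the inserted gene's drift. The caller localizes the insert to
2048–7164 (truth 2000–7243): both boundaries within ~80 bases, with a
mean per-step drift score of 0.24 (random DNA scores ~0.03 at this
window; the call threshold is 0.15). `writeCallsBED()`,
`writeCallsGFF3()` and `writeCallsTSV()` export the calls;
`plotWalk(tpWalk(fx$sequence))` draws the two-panel walk figure.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/tpscan.R` with subcommands `walk`, `scan` and `simulate`.

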
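---
title: "Scanning DNA for coding regions with triplet-periodicity walks"
author: "tpscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning DNA for coding regions with triplet-periodicity walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpscan)
```

## The signal

Protein-coding DNA is read in codons. Because synonymous codons are used
with very unequal frequencies, the four nucleotides are not distributed
evenly over the three codon positions, and coding DNA therefore carries a
statistical period-3 pattern — triplet periodicity (TP) — that random or
non-coding DNA lacks. TP is attractive for gene finding on organisms with
no usable training data: it needs no model of gene structure, no training
set, and no homologs.

`tpscan` detects TP through a cumulative walk rather than a sliding
Fourier window. For a sequence $X = x_1 \ldots x_N$, define the posterior
subsequence at $t$ as the suffix $\{x_u : t < u \le N\}$. The TP vector at
$t$ is

$$ s_t = (Z_1, Z_2, Z_3), \qquad
   Z_j = \#\{u > t : x_u = x_t,\ (u - t - 1) \bmod 3 = j - 1\}, $$

the phase-stratified counts of the *current residue* over the suffix.
These are the rows of the 4 × 3 triplet-periodicity matrix (TPM) of the
suffix, maintained for all four bases by a backward recursion: at $t = N$
every vector is $(0,0,0)$; moving from $t+1$ to $t$ every base vector is
circularly shifted right once, $(Z_1,Z_2,Z_3) \to (Z_3,Z_1,Z_2)$, and the
vector of base $x_{t+1}$ gains $(1,0,0)$. The package evaluates this
recursion in closed vectorized form (per-base suffix counts by residue
class mod 3), which is algebraically identical and linear in $N$; a
brute-force counting oracle (`posteriorPhaseCounts`) is exported and the
test suite checks exact entrywise agreement between the two routes.

Each TP vector is then mapped onto the complex plane through the cube
roots of unity,

$$ L(s_t) = Z_1 e^{-i2\pi/3} + Z_2 e^{-i4\pi/3} + Z_3, $$

and the TP walk takes a unit step in the direction of $L(s_t)$ whenever
$L(s_t) \neq 0$:

$$ W_0 = 0, \qquad
   W_t = W_{t-1} + \frac{L(s_t)}{|L(s_t)|} \text{ if } L(s_t) \neq 0,
   \text{ else } W_{t-1}. $$

Inside a codon-biased region each base occurs mostly at one codon
position, so the dominant phase offset of the current residue is $0 \bmod
3$ — the $Z_3$ component — and steps align along the positive real axis:
the walk drifts. In i.i.d. DNA the phase counts are exchangeable and the
walk diffuses near the origin. Two numerical points are worth noting:

* $L(s) = 0$ exactly when $Z_1 = Z_2 = Z_3$ (including the nonzero
  constant vectors, for which the printed guard $|s_t| \neq 0$ would
  divide by zero), so the zero-step test is an exact integer comparison —
  no epsilon is involved;
* step directions are normalized from exact integer differences
  $(2Z_3 - Z_1 - Z_2,\ \sqrt{3}(Z_2 - Z_1))$, so identical TP vectors
  always produce bit-identical steps.

Ambiguous residues (N and other IUPAC codes) are never counted and
receive the zero vector at their own position — the conservative choice
that cannot create spurious periodicity. Lowercase (soft-masked) input is
treated as ordinary sequence unless `maskLowercase = TRUE`.

## From the walk to region calls

The original method reads the walk's real part by eye. `tpscan`
operationalizes that reading as a windowed drift profile: at position
$t$, the per-step displacement over a window of `window` positions
centred at $t$,

$$ d_t = \frac{|W_{hi} - W_{lo}|}{hi - lo}, \qquad
   lo = \max(0, t - h),\ hi = \min(N, t + h),\ h = \lfloor
   \mathtt{window}/2 \rfloor, $$

with edges clamped so that every position receives a value in $[0, 1]$.
(The denominator is the actual index span, so a perfectly straight walk
scores exactly 1.) `mode = "real-part-slope"` replaces the modulus by the
signed real difference for a figure-faithful reading; the default
`drift-magnitude` statistic is rotation-invariant, since a gene's drift
direction depends on its codon bias and reading phase.

Calling proceeds as: threshold ($d_t \ge \tau$), merge runs closer than
`mergeGap`, drop runs shorter than `minLength`, score each call by its
mean profile value, then refine boundaries (below). `refineRecursive`
finally excises the calls and re-runs the whole chain on each flanking
fragment — never across an excision join, which would create chimeric
periodicity — up to `depth` extra passes, recording the pass on which
each call was found.

### Defaults

| parameter | default | why |
|---|---|---|
| `window` | 351 | odd; ≈ ⅓ of the shortest region of interest (~1 kb); wide enough that diffusion noise ($\sim 1/\sqrt{w}$ ≈ 0.05) sits well below coding drift |
| `threshold` | 0.15 | roughly midway between the diffusion level of random DNA at this window and the ~0.2 per-step drift of strongly codon-biased DNA |
| `minLength` | 400 | smaller than almost all real CDS; ≥ `window` so a call is supported by at least one full window |
| `mergeGap` | 200 | bridges short within-gene dips without joining distinct genes |
| `depth` | 2 | two refinement passes; further passes were never observed to add calls |
| `bidirectional` | TRUE | see below |
| `refineBoundaries` | TRUE | see below |

### Bidirectional profiling

The TP vector is a *suffix* statistic: inside a coding region the
coherent part of the counts is proportional to the remaining coding
suffix, so the signal decays over roughly the last few hundred bases of a
region, and a unidirectional scan systematically underestimates the 3'
boundary (by ~250 bases in our simulations). The identical statistic
computed on the reversed residue sequence is sharp at the 3' edge and
decays at the 5' edge instead; `tpscan` profiles both orientations and
takes the pointwise maximum, making both edges sharp.

### Half-height boundary refinement

A fixed threshold crosses the boundary ramp of the windowed profile where
the window's overlap with the region is $\tau / d$ (for region drift
$d$), not ½ — an inward bias of up to ~80 bases at the defaults. Each
call's edges are therefore extended outward to the last position at or
above half the call's plateau drift (the 75th percentile of the profile
inside the call), which places the edge where the window overlaps the
region by about half, i.e. at the boundary, adaptively for any region
strength. With both refinements the simulation reported by
`scripts/acceptance.R` (50 fixtures, 10-kb uniform background, one 5-kb
insert at a uniform position) recovers boundaries with a mean absolute
error of ~45 bases, within the 100-base error level claimed for manual
reading.

### Masking, excision and re-scanning

Because every TP vector aggregates the whole remaining suffix, a strongly
biased region influences the profile far outside itself. Measurement on
synthetic fixtures shows this contamination *raises* the windowed drift
of other regions in the fragment (the per-position rotation of the
contaminating phase pattern does not cancel perfectly over a window)
rather than lowering it; with the bidirectional default we did not find a
configuration in which a detectable region was hidden by a stronger one.
The excise-and-re-scan loop is retained — it is cheap, it cannot remove
calls, and it re-examines flanks with clean statistics — but on
single-region fixtures its output is identical at `depth = 0` and
`depth = 3`, which the test suite asserts.

## The synthetic-genome generator

`buildFixture` emulates exactly the two statistical regimes the method
distinguishes:

* **background** — i.i.d. nucleotides with settable GC fraction
  (`gc = 0.5` by default; pass `gc = 0.6588` for a high-GC
  organism-scale composition). No periodicity of any kind.
* **inserts** — concatenations of i.i.d. codon draws from
  `codonUsageTable(beta)`. At `beta = 1`, each synonymous family gives
  weight 0.7 to one dominant codon (the alphabetically first C-ending
  codon, else G-ending, else first — the GC3-rich usage typical of
  high-GC bacteria) and spreads 0.3 over the rest; families are weighted
  equally; `beta` interpolates linearly toward the uniform table.
  Sequences from the `beta = 1` table drive the walk at roughly 0.2
  units per step, the same order as real bacterial genes.

Inserts are spliced *between* background residues at stated positions of
the final sequence, so background length plus insert lengths equals the
final length (a 5000-bp background with a 5244-bp insert at position
2000 gives a 10244-bp sequence with true coding interval 2000–7243), and
the ground truth is returned as a `GRanges`. A single master seed drives
background and inserts sequentially, so fixtures are byte-reproducible,
and seeded generators restore the caller's RNG state.

What the generator does **not** emulate — and hence what passing tests do
not establish about real genomes: realistic amino-acid composition
(families are weighted equally, which caps the walk drift below that of
many real genes), start/stop codons and reading-frame consistency,
introns/UTRs (the validation model is bacterial), reverse-strand genes
(available in scanning via `bothStrands`, but fixtures are
forward-strand), GC heterogeneity, repeats, and sequencing error.
Performance on real data should be checked against annotated genomes.

## Validation setup

The test suite regenerates all inputs in code at fixed seeds: exact
oracle agreement on 200 random sequences (≤ 200 bp) plus worked
micro-examples unrolled by hand; the count-conservation identity
$\sum_{b,j} Z_{bj} = N - t$ on 100 sequences; unit-step and range
invariants on every trace produced; diffusion versus drift separation
(mean $|W_N|/N <$ 0.1 over 100 random 5-kb sequences, $>$ 0.15 for
1748-codon biased sequences); and the 50-fixture boundary-recovery
simulation (10-kb background + 5-kb insert), which `scripts/acceptance.R`
recomputes from scratch. A reproduction check against the originally
published example sequences runs only when those FASTA files are placed
under `inst/extdata/s1/` (they are not redistributed with the package).

## Limitations

* The scanner reports *suspected* coding regions; TP alone cannot assign
  reading frame, strand, or gene boundaries at single-base resolution,
  and short or weakly biased genes (< `minLength`, or drift below
  `threshold`) are invisible by construction.
* Suffix contamination means scores are not purely local; a call's score
  should be compared between regions of the same fragment with care.
* Organisms with weak codon bias yield proportionally weaker drift; on
  such genomes `threshold` must be lowered at the cost of specificity.
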
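---
title: "Codon usage bias analysis with cubtools: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias analysis with cubtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubtools)
```

This vignette is the package's own account of the statistics it computes,
the conventions it adopts where the field admits more than one, and the
limits of what its tests demonstrate.

## The analysis chain

A codon-usage study of a gene family proceeds from validated coding
sequences (CDSs) through a fixed chain of summaries. `cubtools` keeps each
stage a separate function over plain data structures; `run_pipeline()`
merely sequences them.

### Sequence validation

A CDS passes validation when its length is a positive multiple of three,
it begins with ATG, ends with TAA/TAG/TGA, has no internal stop, and
contains only A, C, G, T (U is normalized to T on input; the internal
alphabet is DNA throughout, with `as_rna()` available for presentation).
Validation is *advisory* by default — failing records are excluded with a
logged reason, mirroring how such datasets are curated — and
`strict = TRUE` aborts instead. The genetic code is fixed to the standard
nuclear code; all species this package targets are mammals, and
non-standard codes are out of scope.

### Composition

Base percentages are computed over the whole CDS; the terminal stop codon
is **included** by default (`include_stop = TRUE`), because composition
describes the transcript as a whole. The codon-bias indices below, by
contrast, are always defined over sense codons only. The distinction
matters at the third decimal for genes of ordinary length; both behaviors
are exposed because the convention is rarely stated in published tables.

GC12 is defined as the arithmetic mean of GC1 and GC2, exactly. The GC3
used everywhere — composition, the neutrality regression, the expected-ENc
curve — is a single quantity: percent G+C over *all* third codon
positions. Some authors prefer GC3s (synonymous sites only); the two are
used interchangeably often enough in the literature that we chose one
definition and apply it consistently rather than mixing them per stage.

### Dinucleotide odds ratios

Observed frequencies come from overlapping width-2 windows, step 1,
counted within each record (windows never span record junctions, which
are biologically meaningless) and pooled. Two expectation models are
offered:

* `"uniform"` — expected = 1/16 for every dinucleotide. This is the
  convention of the published table this package reproduces, and is the
  **default** for bit-compatibility with it.
* `"mono_product"` — expected[XY] = f(X)·f(Y) from pooled mononucleotide
  frequencies, the conventional relative-abundance denominator.

The uniform default conflicts with the usual methodological citation for
odds ratios; we expose both rather than silently "correcting" either.
Classification uses strict inequalities — UNDER below 0.78, OVER above
1.23, the boundary values themselves NORMAL.

### RSCU

RSCU_ij = x_ij · n_i / Σ_j x_ij over the 59-codon universe (18 degenerate
families; Met, Trp, stops excluded). Family sums equal the degeneracy
(2/3/4/6) by construction, and the test suite asserts this invariant on
every computed table. Flags use strict inequalities: UNDERREPRESENTED
< 0.6, OVERREPRESENTED > 1.6, PREFERRED > 1, boundaries falling to the
non-extreme class.

Two cross-species conventions deserve comment:

* **Averaging.** `average_rscu(mode = "mean")` is the unweighted
  arithmetic mean of per-species tables; `mode = "pooled"` recomputes
  RSCU from summed counts, which weights species by transcript volume.
  Published "average" columns are sometimes one, sometimes the other,
  and sometimes neither exactly — the bundled EPB41L3 average column is
  *not* the unweighted mean of its five per-species columns (e.g. CUG
  prints 1.86 against an arithmetic mean of 1.956), consistent with a
  pooled quantity dominated by the 30 human transcripts of that 34-CDS
  set. We therefore never assert against that column; both modes are
  provided.
* **Shared preference.** `shared_preferred()` defaults to the inclusive
  rule RSCU ≥ 1 in every species. The published 14-codon shared set for
  EPB41L3 includes two codons (CGC, GGG) that sit at exactly 1.0 in one
  species each, so the strict > 1 reading cannot reproduce it; the
  inclusive reading reproduces it exactly, while per-species PREFERRED
  flags remain strict (the published per-species marks are strict too).
  `inclusive = FALSE` restores the strict rule.

Heatmap ordering uses agglomerative hierarchical clustering, average
linkage on Euclidean distances, over codon rows and species columns —
`stats::hclust`, deterministic given input order with lowest-index
tie-breaking.

### ENc

Wright's estimator is computed per family from the within-family codon
proportions, F̂ = (n·Σp_j² − 1)/(n − 1), and averaged within degeneracy
classes. Numerical policy, chosen once:

* families with n < 2 are excluded from their class mean (F̂ undefined);
* families with F̂ ≤ 0 are excluded the same way — the estimator goes
  non-positive when n is small relative to the degeneracy (e.g. two
  counts spread over two codons of a four-fold family), and a
  non-positive homozygosity is meaningless as a divisor;
* a missing three-fold class (Ile entirely absent) is imputed as
  (F̄₂ + F̄₄)/2; any *other* empty class is an error, because a gene too
  short to populate nine two-fold families cannot be scored honestly;
* the result is clamped to the definitional range [20, 61]. With exactly
  equal counts in every family the raw formula gives ≈ 61.4, so "no
  bias" reports as the 61 cap.

The interpretation threshold (ENc ≤ 35 is conventionally "strong bias";
published prose occasionally inverts the inequality) is deliberately not
baked into any computation — the package reports the number and leaves
the reading to the caller.

### CAI

Relative adaptiveness w is computed within each family from a reference
usage table (Kazusa "countcodon" layout: `CODON freq-per-thousand
(count)`), and CAI is the count-weighted geometric mean of w over the
query's sense codons. Zero reference counts are replaced by a 0.5-count
pseudo-frequency before computing w — the standard guard against
log(0) — and a family with *no* reference usage at all is an error. A
query built entirely of reference-optimal codons scores exactly 1.

### P2

The printed formula P2 = (WWC + SSU)/(WWY + SSY) is ambiguous about what
the symbols aggregate. This package reads each of WWC, WWU, SSU, SSC as
the **mean RSCU of its four codons** and WWY, SSY as means over the
8-codon unions, so that P2 = 2(WWC + SSU)/(WWU + WWC + SSU + SSC). That
reading reproduces every cell of the published five-species P2 table to
its printed precision, which the literal 4-codon-sum reading does not;
the discrepancy is documented here rather than silently resolved. The
classic count-based variant (`mode = "counts"`) is retained for
comparability. P2 > 0.5 is reported as translational-selection bias.

### Neutrality, PR2, ENc–GC3

The neutrality analysis is an ordinary least squares fit of GC12 on GC3
across sequences, with Pearson r and a two-tailed p from the t transform
on n − 2 df. The slope times 100 is reported as the mutational
contribution in percent and its complement as selection — slope 1 means
third-position composition drags positions 1–2 along (pure mutational
pressure), slope 0 means positions 1–2 are insulated (selection).

PR2 coordinates are A3/(A3+T3) against G3/(G3+C3) over **all** third
positions — the definition follows the axis labels as published, without
restriction to four-fold families; `fourfold_only = TRUE` provides the
field-standard variant. The overall point uses dataset-mean third-position
percentages, which coincides with the pooled point when sequences have
equal codon counts.

ENc–GC3 deviations are observed ENc minus the null curve
ENc(s) = 2 + s + 29/(s² + (1−s)²); the summary statistic is the fraction
of sequences below the curve. No multiple-testing correction is applied
anywhere in the correlation tables (none is applied in the analyses this
package mirrors); stars are *** p < 0.001, ** p < 0.01, * p < 0.05.

### Phylogeny

K2P distances use pairwise deletion (sites with a gap or ambiguity in
either sequence are dropped per pair, the common default of standard
tree software; complete-deletion behavior can be had by pre-filtering
columns). Saturation (1 − 2P − Q ≤ 0 or 1 − 2Q ≤ 0) is an error, not a
number. Neighbor-joining follows Saitou–Nei with the standard Q
criterion; ties break to the lowest label-index pair, negative branch
lengths are clamped to zero with a notice, and Newick output orders
children lexicographically by the smallest tip label in each subtree so
that identical inputs always serialize identically. Input must be
pre-aligned; alignment itself is a different project and out of scope.

### tRNA adaptation

Cognate matching is strict Watson–Crick reverse complement in the DNA
alphabet, 5'→3', matching how isotype tables are published. Wobble
decoding (G:U, inosine) is deliberately **not** modeled — the analysis
this reproduces pairs preferred codons with their exact
reverse-complement isotype — so `is_optimal` understates adaptation for
families served by wobble. Met and Trp rows are reported descriptively
but excluded from optimality statistics. A preferred-codon tie resolves
to the lexicographically first codon and is logged.

The bundled house-mouse table carries one internally inconsistent row:
its Met line states a total of 13 against itemized counts 9 + 8. The
parser enforces the stated-total check by default (an error naming the
row); the bundled accessor reads that file in non-strict mode and keeps
the itemized counts as authoritative.

## The synthetic generator

`generate_cds()` emulates the shape of a curated mammalian CDS set: every
sequence is ATG + i.i.d. codon body + uniform stop, so every output
passes validation by construction (stop codons carry zero body weight).
Defaults, chosen once: amino-acid sampling uniform over the 18 degenerate
families with Met/Trp at weight 0.2 — this exercises every RSCU family
without letting single-codon families dilute the bias machinery.

`generate_biased_set(theta)` interpolates within-family codon
probabilities linearly between uniform (θ = 0) and one-hot (θ = 1), so
ENc moves monotonically from the 61 cap to exactly 20.
`generate_neutrality_set(m)` draws a latent GC3 target per sequence from
`gc3_range` (default 0.3–0.7, a realistic mammalian third-position
spread) and tilts codon weights independently at positions 1–2 (toward
0.5 + m·(t − midpoint), Gaussian noise of 1 percentage point by default)
and position 3 (toward t); the OLS slope of realized GC12 on GC3 then
recovers m up to sampling error.

What the generator does **not** emulate: isochore structure, amino-acid
composition of real proteins, autocorrelation along the sequence,
CpG-specific mutation processes, or substitution along a tree (the
phylogeny tests use a simple star-shaped site-wise substitution fixture
instead). Passing tests on synthetic data therefore demonstrate
correctness of the estimators under their own model, not biological
realism of any conclusion drawn from real data.

## Problem sizes and statistical bounds in the test suite

The suite runs in well under a minute. Sizes were picked so that every
stochastic assertion is a ≥ 4σ event under binomial/multinomial sampling
theory rather than a seed-lottery ticket: codon-frequency convergence and
RSCU-recovery checks use ~10⁵ sampled codons (per-codon RSCU standard
error ≈ 0.03 in the six-fold families, asserted at 0.1–0.15); the
neutrality slope-recovery contract runs at its stated conditions of 200
sequences × 500 codons for m ∈ {0, 0.5, 1} with a ±0.1 band; ENc
endpoint checks use ~1.5–20 × 10³ codons, where the uniform-usage raw
value sits above the 61 clamp with margin. Neighbor-joining is checked
against random additive matrices up to 8 taxa (topology via bipartition
sets and exact path-length reproduction) with `ape` as an independent
cross-check, never as the implementation.

## Known limitations

* ENc for single short sequences is fragile by nature: genes that leave a
  whole degeneracy class empty (other than Ile) raise an error rather
  than returning a silently extrapolated number.
* Dataset-level published statistics for the EPB41L3 transcript set
  (mean GC ≈ 50.6%, mean ENc ≈ 57.7, mean CAI ≈ 0.77, neutrality slope
  0.302) depend on the original 34-accession download, which is not
  redistributable here; the package reproduces the in-table worked
  quantities (dinucleotide ratios, P2 chain, tRNA totals) exactly and
  covers the dataset-level pipeline with synthetic data of known ground
  truth instead.
* The odds-ratio uniform expectation and the P2 union-mean reading are
  reproduction conventions, not endorsements; the field-standard
  alternatives sit behind flags on the same functions.
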
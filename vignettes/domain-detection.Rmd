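---
title: "Detecting local secondary-structure domains in long non-coding RNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting local secondary-structure domains in long non-coding RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(rnadomains)
```

## The problem

Long non-coding RNAs of hundreds to thousands of nucleotides rarely fold
into one global structure; their function is often carried by compact,
self-contained structural units. When a lncRNA such as the 656-nt Eleanor2
unit upstream of the *ESR1* gene is to be dissected experimentally, the
question is *which subfragments preserve the fold* — a fragment cut through
the middle of a helix loses the structure, a fragment containing a complete
local domain keeps it. This package identifies such domains computationally
from a base-pairing probability matrix, and provides the bookkeeping
(interval arithmetic, in-vitro transcript construction, dose equivalence)
used when the chosen fragments go to the bench.

## The model and the statistics

All inference starts from the base-pairing probability matrix
$\{p_{ij}\}_{i<j}$: $p_{ij}$ is the equilibrium probability, over the
Boltzmann ensemble of nested secondary structures, that positions $i$ and
$j$ form a base pair.

The sequence is divided into consecutive blocks of 10 nt (a trailing
remainder is kept as its own short block, so no position is dropped). Every
run of consecutive blocks is a **domain candidate** $D$; there are
$B(B+1)/2$ of them for $B$ blocks. Each candidate is scored by two
normalized sums:

$$
p^{(i)}(D) = \frac{\sum_{i<j,\; i,j \in D} p_{ij}}{|D|^2},
\qquad
p^{(io)}(D) = \frac{\sum_{i<j,\; |\{i,j\}\cap D| = 1} p_{ij}}{(L-|D|)\,|D|},
$$

where $L$ is the sequence length and $|D|$ the candidate width. A candidate
with $p^{(i)}(D) > 0.003$ and $p^{(io)}(D) < 0.0003$ (strict inequalities)
pairs strongly within itself and hardly at all with the rest of the
molecule: it contains a stable local secondary structure and is reported as
a domain. Both sums run over unordered pairs counted once, matching the
upper-triangular definition of the matrix; a `double_count_cross` flag
reproduces the alternative reading in which each cross pair enters the
inside–outside sum twice, in which case the thresholds must be rescaled by
the caller. For the whole-sequence candidate the cross set is empty and
$p^{(io)}$ is defined as 0.

```{r scan}
m <- bpp(data.frame(i = 21:30, j = 50:41, p = 0.9), length = 60)
scan <- scan_domains(m)   # block 10, thresholds 0.003 / 0.0003
glance(scan)
tidy(scan)
```

With a noise-free matrix, candidates that merely *contain* the structured
region also pass (the inside statistic dilutes only quadratically), which
is why three extraction policies are provided: `all_passing`,
`maximal_passing` (passing candidates not strictly contained in a larger
passing candidate; the default) and `best_nonoverlapping` (greedy by
descending $p^{(i)}$). On real matrices the background pairing of the
flanks pushes the enlarged candidates' $p^{(io)}$ over the threshold, and
the three policies usually coincide.

## Where the matrix comes from

Two routes feed the scanner:

**Imported matrices.** `read_bpp()` reads plain triplet TSV and the Vienna
dot-plot "ubox" PostScript dialect (where the stored value is
$\sqrt{p_{ij}}$). This is the route for matrices computed by external tools
under full nearest-neighbor thermodynamics; the scanner consumes any valid
matrix unchanged, because the domain statistics are model-agnostic.

**Internal folding.** `base_pair_probabilities()` implements the standard
inside–outside partition-function recursions over nested structures, under
a deliberately simplified Boltzmann model (`fold_model()`): one
configurable weight per allowed pair type (defaults: AU, GC, GU wobble), a
minimum hairpin loop of 3 nt (the conventional steric constraint), and an
optional multiplicative stacking bonus for directly stacked pairs.
Reproducing the Turner 2004 parameter tables is a non-goal: the simplified
model has the identical algorithmic structure, is exactly testable against
brute-force enumeration (`enumerate_structures()`, capped at 20 nt), and
produces valid matrices for the scanner; quantitative parity with any
specific external predictor is delegated to the import path.

Numerical scheme: plain double precision, with per-cell rescaling
($Q'(i,j) = Q(i,j)/\sigma^{j-i+1}$, $\sigma$ estimated from a 150-nt
prefix) switched on above 300 nt, where the raw structure count would
overflow. The rescaled and raw recursions agree to well below $10^{-9}$,
and all probabilities are independent of $\sigma$ by construction.

## The representative structure

`gamma_centroid()` predicts a single structure from a matrix by maximizing
the expected gain $\sum_{(i,j)\in S} [(\gamma+1)p_{ij} - 1]$, the
$\gamma$-centroid estimator. With the default $\gamma = 4$ only pairs with
$p_{ij} > 0.2$ can appear. Ties are broken deterministically (fewer pairs,
then the lexicographically smallest pair set), and pairs exactly at the
threshold — zero gain — are excluded, so output is canonical. Strict
monotonicity of the pair count in $\gamma$ is not guaranteed in degenerate
tie cases; the test suite asserts it as a statistical property.

```{r centroid}
seq <- "GGGGGAAAAACCCCC"
mat <- base_pair_probabilities(seq, fold_model(pair_weight = c(AU = 2, GC = 6, GU = 1),
                                               stacking = 8))
to_dot_bracket(gamma_centroid(mat, gamma = 4))
```

## Bench arithmetic

Fragments chosen from a scan are named by 1-based inclusive base numbers
(`subfragment()`, `interval_width()`; exported BED is 0-based half-open and
labelled as such). In-vitro transcription from a T7 promoter with run-off
at a blunt restriction site adds fixed termini — `GGG` 5' and `GAC`
(EcoRV) or `UCG` (NruI) 3' — so every transcript is insert + 6 nt
(`build_t7_construct()`). Dose equivalence between RNAs of different
lengths (`equivalent_concentration()`) conserves concentration × length,
which covers both "equimolar in moles of nucleotides" and "equal mass"
under the equal-mean-residue-mass assumption; `mass_concentration()`
converts a molar dose to ng/µl using a single configurable mean residue
mass (default 320.5 g/mol, a conventional value for single-stranded RNA —
material such as poly(U) is sold by weight, and no sequence-specific
molecular weight is assumed anywhere).

```{r dosing}
full <- build_t7_construct(strrep("ACGU", 164), "EcoRV")   # 662 nt
short <- build_t7_construct(strrep("ACGU", 164) |> subfragment(250, 302), "EcoRV")
equivalent_concentration(short$width, full$width, 1.25)    # 14.0 uM
mass_concentration(full$width, 1.25)                       # ~265 ng/ul
```

Whether dosing uses insert or full-transcript length is the caller's
choice; the package's own examples use full transcript lengths for
equimolar-nucleotide doses, which is the convention the published fragment
concentrations follow.

## The synthetic fixture generator

`generate_fixture()` realizes seeded test inputs with known ground truth.
In matrix mode each planted domain `(start, end)` gets an anti-diagonal
stem of `floor(span/3)` entries at `stem_probability` (the middle third
stays unpaired, like a hairpin loop), and background noise is laid on all
pairs with **both** ends outside every planted domain, with per-entry
values in `[0.9, 1] × background_noise`. The planted domain is therefore
insulated — exactly the property the statistics detect — while the noise
floor gives every candidate that extends a domain by a block a
cross-pairing term of about `background_noise × extension/width`, which
rejects it. Defaults (length 120, block-aligned spans 20–50 nt, stem
probability 0.7–0.95, `background_noise = 0.0025`) follow from that
arithmetic: the one-block extension of the widest domain is rejected with
margin ($0.9 \times 0.0025 \times 10/60 = 3.75\times10^{-4} > 3\times10^{-4}$),
while noise-only regions stay far below the inside threshold
($< b/2 = 0.00125$). `fixture_spec()` refuses configurations that break
these guarantees (overlapping domains, noise ≥ 0.006, row sums above 1).

What the fixtures do **not** emulate: realistic matrices have diffuse
probability mass, competing registers, and cross-domain pairing; a planted
matrix is block-aligned and insulated by construction. Passing the
recovery suite therefore demonstrates the scanner's correctness and the
thresholds' discriminating geometry, not performance on experimental
matrices — for those, the import path plus the `maximal_passing` policy is
the supported workflow, and block-aligned output means published fragment
endpoints that were trimmed by hand will not be reproduced exactly.

Sequence mode (`sequence_with_hairpins`) instead emits a random sequence
whose planted intervals are complementary inverted repeats around A-rich
loops, for end-to-end pipeline tests through the folding engine.

## Problem sizes and determinism

The scanner and estimators are fully deterministic; randomness exists only
in fixture generation and always takes an explicit seed (the generator
saves and restores the caller's RNG state). The test and acceptance suites
run folding-vs-enumeration checks on 200 random sequences of ≤ 14 nt
(enumeration is exponential), centroid-vs-brute-force on 500 random 12-nt
matrices with ≤ 8 candidate pairs, naive-oracle score checks on 1000
random candidates at L ≤ 60, and 100 seeded recovery matrices at L = 120 —
sizes chosen so the exhaustive oracles stay exact and the whole suite runs
in well under a minute per suite on one CPU. The internal O(L³) folding
engine is comfortable to a few hundred nucleotides (the 656-nt scale of
the motivating lncRNA takes on the order of a minute in pure R); for
routine long-RNA work, import precomputed matrices.

## Known limitations

- The simplified Boltzmann model is not a thermodynamic predictor; its
  matrices are structurally valid but not numerically comparable to
  nearest-neighbor tools. Use `read_bpp()` for quantitative work.
- Domains are reported at block resolution (10 nt by default); sub-block
  endpoint refinement is intentionally out of scope because no principled
  trimming rule exists for the statistics.
- No pseudoknots anywhere: the ensemble, the centroid DP and the
  dot-bracket codec all assume nested structures.
- The choice between the unordered and double-counted cross-sum
  conventions changes the scale of $p^{(io)}$; thresholds are calibrated
  for the unordered reading and must be re-derived if the flag is set.
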
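---
title: "Models and design decisions behind tmdscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions behind tmdscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmdscreen)
```

This vignette records the models, parameter choices and open design
decisions of the package — what is computed, under which assumptions,
and what a passing test does and does not establish.

## 1. The dose-response model

Cell density after overnight growth under ampicillin falls sigmoidally
with dose. We model a kill curve as a *decreasing* Hill function

$$y(x) = \frac{c}{1 + (x/k)^g}, \qquad c, k, g > 0,$$

with $x$ the ampicillin concentration (µg/mL), $c$ the uninhibited cell
density (absorbance units), $k$ the LD50 and $g$ the steepness. The
parameterization is fixed by two identities used as test oracles:
$y(0) = c$ and $y(k) = c/2$. Any alternative decreasing sigmoid could be
swapped in behind `fit_hill()`; nothing downstream depends on the
functional form beyond these identities.

**Fitting** (`fit_hill()`) is bounded nonlinear least squares
(`nls(algorithm = "port")`, polished by `optim(method = "L-BFGS-B")` on
the residual sum of squares, which also serves as fallback when `nls`
cannot evaluate a start). Starting values: $c_0$ = max response, $k_0$ =
the linearly interpolated dose at half-maximum, and a multi-start over
$g_0 \in \{1, 3, 8\}$ keeping the lowest SSE (ties to the smallest
start). Rationale: kill curves can be very steep, and a deterministic
multi-start is reproducible where stochastic global search is not. The
zero dose is kept in the fit (the model is defined there) and doses are
not log-transformed. Bounds scale with the data ($k$ within
$[\min_{x>0} x/100,\; 100\max x]$), which preserves exact dose-scale
equivariance: multiplying all doses by $s$ multiplies $\hat k$ by $s$
and leaves $\hat c, \hat g$ unchanged.

**Quality control.** No acceptance criterion is inherited from any
upstream tool, so the package defines its own: a fit is *accepted* when
the optimizer converged and $R^2 \ge 0.85$ (configurable via
`fit_control()`). Two degenerate inputs are rejected before fitting with
an explanatory flag rather than an error: all-equal responses (no
information; $R^2$ undefined) and responses that never decrease with
dose (no kill signal — a decreasing model would only fit noise).
Whether outlier wells should be excluded beforehand is left to the user;
the package fits what it is given.

**Aggregation** (`aggregate_ld50()`) is fit-per-replicate-then-average,
not a pooled fit: each transformation/culture yields its own curve, and
the replicate structure is the natural unit of biological noise. SEM
uses the $(n-1)$ sample SD divided by $\sqrt n$ and is reported as
missing (not zero) for $n = 1$. Rejected fits are excluded and counted.

**Normalization and classes.** Affinities are percentages of a reference
homodimer's mean LD50 (reference = 100%). Class boundaries read the
"50% to 80%" band as inclusive on both ends: high iff > 80, medium iff
$50 \le p \le 80$, low iff < 50. GFP expression controls are normalized
as (raw − background) / A544, i.e. fluorescence per unit cell density.

## 2. The combinatorial library

The library template is a 19-residue poly-leucine helix with an
invariant GxxxG motif ("L19GG"); each member carries exactly one
ionizable residue (D, E, K or R) at one of the randomized positions
{2, 3, 4, 6, 7, 9, 10, 11}. Positions are 1-based from the N-terminus.
The glycine indices are not fully determined by the available template
description; the default places them at 14 and 18 (`tmd_backbone()`,
configurable), which is consistent with the randomized positions lying
about two helical turns upstream of the motif. Every statistic in the
package depends only on the randomized positions, so this choice is
cosmetic.

Enumeration is exact and ordered: 4 residues × 8 positions = 32
substituted variants, plus the wild-type backbone, per plasmid; the
N-BLa and C-BLa plasmids are physically distinct, so pairs are ordered
and the full library is $33^2 = 1089$ pairs. `parse_variant()` inverts
`make_variant()` (every library sequence is Hamming distance ≤ 1 from
the backbone, so the inversion is unique).

Hybrid proteins are assembled at the protein level only (signal
peptide – BLa fragment – SGS(GGGS)₂GS – TMD – A(EAAAK)₅A – GFP – FLAG);
codon-level cassette design is out of scope. Orientation shifts
(`shift_orientation()`) slide a fixed-length TMD window up to three
residues toward the N-terminus of its natural context, the convention
used to rotate the interaction face relative to the reporter fusion.

## 3. Pattern statistics and overrepresentation

Charge signs are fixed (D/E negative, K/R positive); no protonation
modeling. A pair is *opposite* / *like* when both TMDs are charged with
opposite / equal signs, *single* / *none* by count.

The prior probability of a sequence pattern is computed by brute-force
enumeration over all 1089 pairs (`count_matching()`), with closed-form
combinatorics used only as cross-checks in the tests. A
`pattern_predicate()` with `position_set = c(6, 7)` means "one charged
residue at 6 and the other at 7, in either plasmid order" — the exact
unordered position pair, which yields 16 matching pairs (2 negative × 2
positive residues × 2 sign arrangements × 2 position orders), hence
$p = 16/1089 = 0.0147$. A subset reading ("both positions in {6,7}")
would instead give 32 and is deliberately not the default, as it
double-counts same-position pairs against the worked arithmetic.

Expected counts are $p \times n$ isolates and the overrepresentation
factor is observed/expected, computed from the unrounded prior and
*reported* at conventional precision (prior 4 d.p., expected 2 d.p.,
factor also as nearest integer); raw values are always retained. The
isolate denominator counts duplicates (repeated isolations of the same
pair are evidence of enrichment, and the screen's published arithmetic
uses the duplicated count); restricting to unique pairs is a caller-side
filter. Residue spacing uses the inclusive reading "within five
positions" (≤ 5). Classes with no eligible pairs report `NA` fractions,
never 0. Formal significance testing is intentionally absent — with tens
of isolates over 1089 cells the exact tail adds little; only descriptive
expected/observed factors are reported.

## 4. The selection simulator: a stated world

The simulator exists so the analysis pipeline can be exercised end to
end; its defaults are fixed commitments, not tuning knobs.

**Ground truth** (`affinity_model()`): the mean true LD50 of a pair is
multiplicative in the qualitative drivers the screen is designed to
detect — opposite charge (×2.0), exactly positions 6/7 on top of that
(×1.35), like charge (×1.25, hydrogen bonding being weaker than a salt
bridge), and a decay of ×0.92 per residue of charge spacing beyond 1.
The uncharged backbone pair is anchored at 37 µg/mL against a reference
homodimer at 100 µg/mL, matching the backbone's known 37%
reference-normalized affinity; the opposite-6/7 product lands at
≈ 100%, i.e. reference-like, which is what the screen's strongest
heterotypic hits showed. Clone-to-clone variability is a mean-one
log-normal factor with CV 0.15 — a modest spread standing in for the
clonal variation that bench protocols mitigate by pooling ≥ 40 colonies.

**Selection** (`simulate_selection()`): plated cells are multinomial
over pairs (uniform by default; a frequency vector can model biased
libraries), and each cell/colony survives the plate dose (default
5 µg/mL) and then the liquid dose (default 30 µg/mL) as independent
Bernoulli trials with the Hill-family survival probability
$S(a) = 1/(1 + (a/\mathrm{LD50})^{g_s})$, steepness $g_s = 4$ by
default. Cells plated default to 10× the library size (the coverage
excess used when building such libraries). All randomness flows through
explicit seeds (`withr::with_seed`); identical config + seed gives
byte-identical output.

**What the survival model is and is not.** No quantitative mapping from
LD50 to plate survival is published, so the Hill form and $g_s$ are free
modeling choices (any monotone alternative can be substituted). The
published wild-type/mutant discrimination — 5× after plating, 30× after
both steps, at a 100:29 LD50 ratio — is therefore treated purely as a
calibration exercise: a scan over the absolute LD50 scale and $g_s$ at
the default 5/30 µg/mL doses reaches plate ≈ 5.0× and two-step ≈ 29× at
a wild-type LD50 near 2 µg/mL with $g_s \approx 1.45$
(test-screen_sim.R). The library simulation keeps $g_s = 4$; its tests
claim only monotone enrichment, which holds across this family.

**What a green test establishes.** The end-to-end checks show that *if*
affinity is driven by opposite charges at 6/7 with close spacing, the
pipeline's enrichment statistics recover that signal in ≥ 95% of seeded
screens. They do not validate the biological model itself, the absolute
LD50 scale, expression-level effects (inducer labels are metadata only),
or any growth/enzyme kinetics.

## 5. Numerical conventions and limitations

* Fits are deterministic for fixed input and settings; the multi-start
  tie-break is the smallest $g$ start.
* `factor_rounded` uses R's `round()` (half-to-even); raw factors are
  retained alongside.
* `read_plate_table()` reports offending *file line numbers* for
  non-numeric or duplicated wells and refuses silently incomplete input.
* Known limitations: no outlier-well rejection; no pooled (global) curve
  fitting; no enrichment significance testing; protein-level assembly
  only; the simulator's survival steepness is not identifiable from
  anything the package can observe.
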
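---
title: "Methods: peptide depletion scoring and RNA-binding region calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide depletion scoring and RNA-binding region calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbrid)
```

## The model

RBR-ID infers where a protein touches RNA from a loss-of-signal
contrast. 4-thiouridine (4SU) is incorporated into RNA and crosslinked
to directly contacting residues by 312 nm UV; a crosslinked peptide
carries an RNA adduct, shifts mass, and disappears from the survey-level
quantification. The observable is therefore a *depletion* of intensity
in +4SU runs, restricted to peptides overlapping the RNA-binding region
(RBR), against matched −4SU controls.

Let $x_{pr}$ be the intensity of peptide $p$ in run $r$. Each run is
normalized by its total, $\tilde x_{pr} = x_{pr} / \sum_{q} x_{qr}$,
which removes loading, acquisition and instrument-batch scale factors
exactly (any per-run multiplicative constant cancels). For condition
means $m^+_p$ and $m^-_p$ (arithmetic means over replicates, zeros
included), the per-peptide quantities are

* the depletion ratio $\log_2(m^+_p / m^-_p)$, negative under
  crosslinking-induced loss;
* a two-sided, unpaired, pooled-variance Student $t$ test $P$ value
  across the replicate values;
* the RBR-ID score
  $s_p = -\log_2(m^+_p/m^-_p)\,\cdot\,(\log_{10} P_p)^2$,

so the score is positive for depleted peptides and grows with both the
effect size and its reproducibility. A peptide is called significantly
depleted when $P < \alpha$ (default $\alpha = 0.1$) *and* its ratio is
negative; enrichment is never evidence of binding.

The residue-level track sums the scores of every peptide overlapping
each residue (1-based inclusive coordinates throughout), is smoothed
with a variable-span super smoother, and segments are called from the
smoothed curve.

## Statistical choices

**Zero handling and imputation.** A zero is a measured non-detection
and counts toward its condition mean. Only when *every* replicate in a
condition is zero is the mean unusable for a ratio; it is then imputed
as `floor_factor` (default 0.5) times the smallest strictly positive
condition mean observed anywhere in the dataset, over both conditions.
The minimum is global rather than per-condition: with run-sum
normalization both conditions share a scale, and a global floor keeps
imputed ratios comparable across peptides. Peptides detected in no run
of either condition would have ratio 1 and score 0 by construction and
are dropped with a warning.

**The t test.** The pooled-variance ("Student") form with
$n_1 + n_2 - 2$ degrees of freedom is computed in closed form on the
normalized linear-scale intensities — the same quantities the ratio
uses (`test_scale = "log"` switches to log2 intensities, with zeros
floored at half the smallest positive value). Degenerate zero-variance
cases are defined rather than errors: equal means give $p = 1$;
unequal constant groups give $p$ at the floor. $P$ values are clamped
to $[10^{-15}, 1]$ before the $(\log_{10}P)^2$ term so no single
peptide can contribute an unbounded score; the floor is configurable.

**No multiple-testing correction** is applied: the score aggregates
evidence across peptides along the sequence, and the per-peptide
$\alpha$ is a reporting threshold, not a family-wise claim.

**Calibration.** On null simulations (no planted depletion, generator
defaults, 8+8 replicates, ~1000 peptides per simulation) the fraction
of peptides at $P < 0.1$ measures about 0.094–0.10 and signed scores
split evenly about zero. The slight conservatism comes from
zero-inflated low-abundance peptides, where dropout makes the $t$ test
under-reject; it disappears when dropout is disabled. Because the
significance call is directional, its null rate is $\alpha/2$.

## The super smoother

The residue track is smoothed with a from-scratch implementation of
Friedman's variable-span smoother. The building block is a fixed-span
local linear fit: for each point, ordinary least squares over the $J$
nearest neighbors ($J = 2\,\mathrm{ibw}+1$ with
$\mathrm{ibw} = \max(\mathrm{round}(\mathrm{span}\cdot n/2), 2)$), a
symmetric window that shifts one-sided at the boundaries so it always
holds $J$ points. Window statistics come from prefix sums (linear cost)
and the leave-one-out (LOO) residual from the exact deletion identity
$|y_i - \hat y_i| / (1 - h_{ii})$.

The variable-span stage: (1) fits at the three primary spans 0.05, 0.2,
0.5 ("tweeter/midrange/woofer" — the published defaults of the method,
kept here since no alternative settings are indicated for this
pipeline); (2) absolute LOO residuals of each fit are smoothed with the
midrange span; (3) each point selects the span minimizing that smoothed
residual, with bass enhancement ($\mathrm{bass} \in [0,10]$, default 0)
optionally pulling the choice toward the woofer by
$J^*(i) \leftarrow J^*(i) + (J_{\mathrm{woofer}} - J^*(i))\,R_i^{10-\mathrm{bass}}$
where $R_i$ is the residual ratio to the woofer; (4) the chosen span
values are themselves smoothed with the midrange span; (5) the output
interpolates linearly between the two primary fits bracketing the
smoothed chosen span, and (6) the interpolated curve is passed once
more through the tweeter-span smoother, as in the original algorithm.
The implementation reproduces constants and straight lines to 1e-8, is
affine-equivariant, and agrees with the independent `stats::supsmu`
reference to well under 5% of the signal's dynamic range on seeded test
signals (boundary handling is where implementations of this algorithm
typically differ).

The abscissa in this pipeline is the residue index $1\ldots L$, so ties
and irregular spacing never arise; the smoother still validates general
strictly increasing $x$ for standalone reuse. Uncovered residues carry
raw score 0 (not missing) and participate in the smoothing, giving one
continuous track along the primary sequence; `mask_uncovered = TRUE`
provides the alternative masked mode.

## Peptide location and multimapping

Peptides are located by exact substring search reporting *all*
occurrences, including overlapping ones; I/L are distinct. The default
multimapping policy (`"all"`) adds the full score at every match —
conservative about discarding signal, and the multimap status is
visible downstream; `"drop"` and `"split"` (score divided across
matches) are available where repetitive sequence would otherwise
inflate the track.

## Segment calling

Candidate RBRs are maximal runs of residues whose smoothed score
exceeds a quantile (computed over covered residues) of the smoothed
track, with runs separated by at most `merge_gap` (default 5) residues
merged and merged runs shorter than `min_length` (default 10) residues
discarded; segments are ranked by peak smoothed score. The defaults are
this package's own: no published calling rule exists for these tracks,
which were originally read by eye.

The threshold quantile defaults to **0.85**. A genuine RBR can occupy
10–15% of a protein's primary sequence — for ATRX, roughly 350 of 2492
residues — and a quantile of $q$ caps the callable territory at
$(1-q)\cdot L$ residues. A 0.95 threshold would bound the recoverable
overlap with a region of that scale at a Jaccard of roughly 0.4
regardless of signal strength; 0.85 leaves headroom for regions up to
~15% of the protein while still demanding a clearly elevated score.
Both the quantile and the merge/length parameters are exposed in the
configuration and CLI.

## The synthetic-experiment generator

The generator emulates the design the analysis targets: 8 biological
replicates per condition across 2 instrument batches. Its parts:

* **Protein** — random sequence at average proteome amino-acid
  frequencies (K+R ≈ 11%), so tryptic digestion (cleavage after K/R,
  blocked by proline, 0–2 missed cleavages, peptide length 6–30)
  yields realistic peptide densities (~1 peptide per 18 residues).
* **Abundance** — per-peptide log-normal base abundances
  (`meanlog = log(1e7)`, `sdlog = 1.5`), the right order for MS1
  peptide intensities and wide enough to span the dynamic range where
  dropout matters.
* **Depletion** — peptides overlapping the planted RBR by ≥1 residue
  have +4SU intensities multiplied by $\delta \in (0,1]$ (crosslinking
  at a single residue suffices to remove the whole peptide);
  `overlap_mode = "proportional"` scales the effect by the overlap
  fraction instead.
* **Noise and batches** — multiplicative log-normal replicate noise
  (CV 0.2 by default) and one shared log-normal scale factor per batch
  (`sdlog` 0.25), which run-sum normalization cancels — the simulation
  keeps it to verify exactly that.
* **Dropout** — detection is Bernoulli with
  $P(\text{detected}) = \text{logit}^{-1}\big(k\,(\log_{10} I - m)\big)$,
  default midpoint $m = 5.5$ and steepness $k = 3$: detection is near
  certain at median abundance and decays for the low tail, producing
  occasional all-zero conditions that exercise the imputation rule.

Everything is a pure function of the seed, and the caller's RNG state
is left untouched.

What the generator does *not* emulate: peptide-specific ionization
efficiency, correlated (structured) missingness, retention-time or
charge-state effects, partial crosslinking stoichiometry, or
interfering proteins sharing peptides. Passing recovery tests therefore
demonstrate that the statistics and projection recover a multiplicative
depletion signal under realistic noise and missingness — not that every
property of real acquisitions is handled.

## Problem sizes used in the checks

Null calibration uses 20 simulations of ~1030 tryptic peptides
(18000-residue protein) at 8+8 replicates — about 20,600 peptide tests,
enough that a 3-standard-error band around $\alpha$ is ±0.6 percentage
points. Recovery plants a 300-residue region (12% of a 2500-residue
protein, matching the relative scale of the ATRX region) at
$\delta = 0.5$, noise CV 0.2; across seeds the top segment's Jaccard
with truth runs 0.72–0.95 with midpoint errors under ~25 residues.

## Known limitations

* One canonical isoform per analysis: peptides are projected onto a
  single protein sequence; isoform-aware quantification is out of scope.
* Replicates from different instrument batches are pooled after
  normalization; no explicit batch-effect model is fit.
* The segment caller thresholds a single track; it does not estimate
  uncertainty on segment boundaries.
* With very sparse coverage the smoothed track interpolates across
  uncovered stretches; the masked smoothing mode and the coverage
  column in the output are the guard rails.
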
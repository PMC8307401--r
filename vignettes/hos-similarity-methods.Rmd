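---
title: "Methods: quantitative NMR similarity assessment of protein drug products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative NMR similarity assessment of protein drug products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hosnmr)
```

## The problem

Protein and peptide drugs fold into higher order structures (HOS) in their
formulations, and a biosimilar or follow-on product must show the same HOS as
the reference product. Solution NMR measures this non-invasively, directly on
the marketed drug product: the protein contributes many weak, broad peaks,
while excipients (preservatives, tonicity agents, buffers, stabilizers)
contribute a few strong, sharp ones that must be excluded before any
comparison. `hosnmr` turns processed frequency-domain spectra and picked 2D
peak lists into quantitative similarity decisions, through two independent
routes.

## Route 1: 1D chemometrics and the Mahalanobis distance

For two brands with $m$ and $n$ manufacturing lots, each 1D $^1$H spectrum is
reduced to a feature vector:

1. **Exclusion and binning.** The analysis window is tiled with half-open
   fixed-width bins $[\ell, h)$ (default 0.01 ppm), bins overlapping any
   exclusion interval are dropped, and intensities of points falling in each
   surviving bin are summed. The default window is $(0, 8)$ ppm with eight
   excluded regions (0–0.2, 0.85–0.95, 1.15–1.45, 1.55–1.65, 1.9–2.1,
   2.2–2.9, 3.3–6, 8.45–8.47 ppm), which yields 370 bins at 0.01 ppm; the
   last region lies outside the default window. The window is a
   reconstruction (the published bin count constrains but does not state it)
   and both window and exclusions are arguments.
2. **Integrity check and sum normalization.** Every cell must be finite and
   every lot total positive; each row is then scaled to a constant sum of
   100. The constant is arbitrary but must be fixed — it cancels only if
   applied uniformly.
3. **Pareto scaling.** Column-wise $x \mapsto (x - \bar x)/\sqrt{s_x}$ with
   the sample standard deviation ($n-1$ denominator, the chemometrics
   convention). Constant columns are centered and left undivided, with a
   warning. After scaling, each non-degenerate column's variance equals its
   pre-scaling standard deviation — an identity the tests verify numerically.
4. **PCA.** Mean-centered SVD of the pooled (both-brand) matrix. Fitting on
   the pooled matrix, not per brand, reflects how the published analysis
   treats all lots together; brand membership is applied only when splitting
   scores.
5. **Distance.** With per-brand score matrices $A_{m\times p}$,
   $B_{n\times p}$ (default $p = 3$), sample covariances $S_A$, $S_B$, and
   the lot-count-weighted pool

   $$S = \frac{m S_A + n S_B}{m + n}, \qquad
     D_M = \sqrt{(\bar A - \bar B)\, S^{-1} (\bar A - \bar B)'},$$

   two brands are declared similar when $D_M < 3.3$, the practically
   achievable threshold previously established on marketed insulin products.
   The lot-count weighting is kept verbatim even though it is not the
   unbiased (degrees-of-freedom) pooled estimator; the threshold was
   calibrated with this form.

Score-space scatter is visualized with 90% confidence ellipses. The quantile
is open in the source method (a commercial package drew the published
ellipses), so both forms are provided: the default Hotelling prediction form
$c^2 = \frac{2(m-1)(m+1)}{m(m-2)} F_{0.9}(2, m-2)$, whose coverage of a new
same-distribution lot is exact at any $m$ (verified by simulation in the
tests), and the asymptotic $\chi^2_2$ form.

**Numerical choices.** Bin edges are computed in exact decimal steps (rounded
to 1e-6 ppm) so floating drift cannot change bin counts; bins are half-open to
make point assignment deterministic; $S^{-1}$ is applied through a linear
solve guarded by a condition-number cap (default $10^{10}$), refusing
singular pooled covariances instead of pseudo-inverting.

## Route 2: 2D methyl peak profile

Methyl $^1$H–$^{13}$C cross-peaks are compared across lots after matching.
Labelled lists are matched by label; unlabelled lists are matched greedily to
the first lot's peaks by nearest neighbour in tolerance-normalized shift
space (defaults 10 ppb $^1$H, 50 ppb $^{13}$C — several times the lot-to-lot
differences seen in practice), ties broken by the smaller $^1$H distance.
Peaks not found in every lot are excluded from statistics and reported.

* **Chemical shift difference.** Per peak and axis,
  $\Delta\delta = \bar\delta_{\text{test}} - \bar\delta_{\text{ref}}$ over
  each brand's lots, in ppb. A peak is within the similarity metric when
  $|\Delta\delta_H| \le 4$ ppb and $|\Delta\delta_C| \le 15$ ppb (the
  published metrics: observed maxima of 3.4 and −13 ppb plus 10% headroom,
  rounded).
* **Relative peak height.** Absolute heights are confounded by assay and
  probe response differences between formulations, so each height is
  expressed relative to the most intense peak in the same spectrum,
  $\mathrm{Rel.Int.}_x = 100 \times I_x / I_{\text{ref}}$ — invariant under
  per-lot uniform scaling (a property the tests assert). Brands are compared
  per peak with a two-tailed Welch (unequal-variance) $t$-test; a peak is
  equivalent when $p \ge 0.05$. The reference peak is constant 100 and
  untestable; the default summary counts it as equivalent out of the full
  total (the convention behind "47 of 48, at least 98%"), and the strict
  convention excluding it is reported alongside. No multiple-testing
  correction is applied, mirroring the published procedure.

The package ships the published 48-peak relative-height table for two insulin
glargine products (5 lots each) as a plain-text fixture
(`glargine_methyl_profile()`).

## Amide peak counting

For $^1$H–$^{15}$N correlation spectra of small proteins, the expected peak
count from a sequence uses a stated convention: one backbone NH per residue
except each chain's N-terminus and prolines, two per Asn/Gln side-chain
NH$_2$, one per Trp indole. This convention is reverse-engineered — it
reproduces the published expectations of 44 peaks for teriparatide and 39
for exenatide exactly — and is documented as a convention, not a derived
formula. Arg/Lys/His side-chain NH are excluded by default (typically
exchange-broadened); Arg H$\varepsilon$ can be included by flag. For insulin
glargine the convention gives 60 on the standard two-chain sequence against
a published expectation of 62; the discrepancy is unresolved and glargine is
therefore shipped as a documented fixture, not an anchor. Detected coverage
is reported as an integer percent with a qualitative band (≥ 60%:
well-defined backbone; < 30%: intermediate exchange) that is annotation, not
inference.

## What the synthetic generator emulates — and what it does not

`spectrum_scenario()` builds drug-product-like 1D spectra: Lorentzian lines
(the natural NMR lineshape; Gaussian optional) on a uniform grid, a few
sharp, intense excipient peaks placed *inside* the default exclusion regions
(widths ~0.003 ppm, amplitudes 30–200), many broad, weak protein peaks
outside them (widths 0.05–0.12 ppm, amplitudes ≤ 1.2 — a ~100:1 amplitude
ratio mirroring how excipient signals dominate real spectra), per-point
Gaussian noise (sd 0.02), and per-lot, per-peak jitter (shift sd 0.002 ppm,
amplitude sd 2%). By construction ≥ 99% of excipient intensity falls in
excluded regions (`excipient_exclusion_fraction()` computes this from the
analytic Lorentzian integral). `peaklist_scenario()` emulates a 48-peak
methyl list with ppb-scale shift jitter (1 ppb $^1$H, 5 ppb $^{13}$C) and
percent-scale height jitter (4%, the order of lot-to-lot technical variation
seen in drug-product repeats).

Seeding is counter-based: each (brand, lot) derives an independent substream
from the master seed, so adding a lot never perturbs existing lots, and
identical seeds reproduce byte-identical outputs.

The generator does **not** simulate exchange broadening, relaxation,
baseline or phase artifacts, solvent suppression residues, or peak overlap;
spectra are ideal lineshapes plus white noise. A green synthetic test
therefore establishes that the *pipeline arithmetic* behaves as specified on
data with known ground truth — not that real spectra of two similar products
will produce any particular $D_M$. The published distances for the rituximab
products (1.95 at 850 MHz, 3.15 at 600 MHz) require the original spectra,
which are not distributable, and are deliberately not reproduced.

## Known limitations

* **Printed-precision p-values.** The published relative-height table prints
  intensities rounded to 0.1 but its p-value column was computed from
  unrounded heights. Recomputing Welch p from the printed values reproduces
  only 17 of 47 rows at printed precision (differences up to 0.03, exactly
  the propagated quantization error); the equivalence classification at
  $\alpha = 0.05$ is identical in all rows. The acceptance test asserting
  printed-precision agreement is therefore expected to fail and is kept
  honest rather than loosened.
* **Welch vs permutation.** At 5 lots per brand, the difference between the
  Welch p and a permutation p is a systematic small-sample effect (up to
  ~0.04 with the studentized statistic), larger than the Monte-Carlo error
  of any well-resolved permutation estimate. The acceptance criterion
  demanding agreement within 3 Monte-Carlo standard errors fails for a
  minority of pairs; the suite instead verifies rank agreement with the
  exhaustive permutation oracle plus the exact symmetry/affine-invariance
  properties, and the failure is documented, not masked.
* **Null-study margin.** With $m = 7$, $n = 3$, $p = 3$ and lot-count
  pooling, the null probability of $D_M > 3.3$ is itself about 5%
  (theory: $D_M^2 \approx 0.476 \cdot \tfrac{10}{8} \cdot 4\,F(3,6)$), so
  "95% of 100 replicates below threshold" sits on the boundary by
  construction. The canonical replicate convention (master seeds $1..100$)
  meets it; small-sample users should expect occasional null exceedances of
  3.3 and not over-read single borderline values.
* The JCAMP-DX reader handles uncompressed AFFN blocks only; vendor raw
  directories and time-domain data are out of scope (inputs are processed
  frequency-domain spectra).
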
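---
title: "Entropy-based adaptive subhistogram equalization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based adaptive subhistogram equalization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eashe)
```

## The enhancement model

Histogram equalization maps gray level $k$ through the cumulative
distribution, $f(k) = K_l + (K_u - K_l)\,\mathrm{cdf}(k)$, driving the
output histogram toward uniformity. Applied globally it shifts mean
brightness and saturates dense histogram regions. The method implemented
here counters both effects by equalizing four *subhistograms*
independently, with every partition and every strength parameter derived
from the image itself.

**Stage 1 — entropy-balanced segmentation** (`segment_histogram()`). With
$p_k$ the normalized histogram over the occupied range $[k_l, k_u]$ and
$E = -\sum p_k \log_2 p_k$, the split level $k_{s2}$ is the smallest level
whose cumulative entropy reaches $E/2$; the two halves are split the same
way into $k_{s1}$ and $k_{s3}$. Segments therefore carry near-equal
*information*, not near-equal pixel counts: a heavily populated but flat
region does not dominate the mapping.

**Stage 2 — dynamic-range allocation** (`allocate_ranges()`,
`remap_pdf()`). Segment $r$ spanning $span_r = m_r - m_{r-1}$ input levels
receives the blended output width
$$aspan_r = span_r + w_r\left(\tfrac{L}{4} - span_r\right),\qquad
  w_r = \min\!\left(\tfrac{1}{E_r}, 1\right),$$
with $w_r = 1$ for a zero-entropy segment and $L = 256$. The reciprocal
weight sends uninformative segments toward the uniform share $L/4 = 64$
and leaves entropy-rich segments ($E_r \ge 1$ bit) closer to their input
span; the clamp keeps $aspan_r$ between $span_r$ and 64, so the blend can
never overshoot. Widths are then scaled to sum to $L - 4 = 252$ interior
levels and integerized (below), and the input density is transported onto
the new intervals by per-segment affine remapping.

**Stage 3 — adaptive density reshaping** (`side_stats()`,
`adjust_pdf()`). The remapped density is split at its half-entropy level
$I_{ks}$; with $I_{avg1}, I_{avg2}$ the conditional means of the two
sides, the control factors are
$$\alpha_{low} = \frac{I_{ks} - I_{avg1}}{I_{avg2} - I_{avg1}},\qquad
  \alpha_{high} = \frac{I_{avg2} - I_{ks}}{I_{avg2} - I_{avg1}},$$
complementary by construction and clamped to $[0, 1]$. Per side, over
occupied bins only, with $m = (\mathrm{pdf_{max}} + \mathrm{pdf_{min}})/2$:
$$p' = \begin{cases}
  m - \alpha\,(m - p)^2 / (m - \mathrm{pdf_{min}}) & p < m,\\
  m + \alpha\,(p - m)^2 / (\mathrm{pdf_{max}} - m) & p > m.
\end{cases}$$
At $\alpha = 1$ the side extremes are exact fixed points and the density
is nearly preserved (full HE behaviour); at $\alpha = 0$ every occupied
bin collapses to $m$, which makes the subsequent equalization an almost
linear stretch. The quadratic pull is monotone in $p$ and never leaves the
interval $[\mathrm{pdf_{min}}, \mathrm{pdf_{max}}]$, so bin ordering is
preserved and no side can invert.

**Stage 4 — per-segment equalization** (`segment_transfer()`,
`compose_lut()`). The reshaped weights are renormalized into a global CDF
$c$; segment $r$ with output interval $[l_r, u_r]$ uses the segment-local
CDF $(c(k) - C_{r-1})/(C_r - C_{r-1})$, $C_r = c(u_r)$, so its mapping
spans exactly $[l_r, u_r]$ and the union of the four independently
equalized segments tiles $[0, 255]$. The composed per-level lookup table
is monotone, total, and applied per pixel.

### Assumptions

The method assumes an 8-bit quantized intensity scale, a stationary global
histogram (no local adaptation), and enough distinct occupied levels to
support four non-empty entropy-balanced segments. Images violating the
last assumption (constant, two-level, or otherwise collapsed histograms)
are detected at the failing stage and returned unchanged with
`fallback = TRUE` — degraded inputs never crash and never change.

## Parameters that matter

* `weight_hook` (default `"reciprocal_clamped"`): how segment entropy
  becomes the blend weight $w_r$. The reciprocal-with-clamp rule above is
  the default; `"normalized_entropy"` ($w_r = 1 - E_r/\sum E$) and
  `"uniform"` ($w_r = 1$, equal ranges for all segments) are provided
  because the weight is the one genuinely underdetermined piece of the
  range-allocation stage, and exposing it makes the choice auditable.
* `color_policy` (default `"value_channel"`): RGB images are enhanced on
  the per-pixel channel maximum and the three channels are rescaled by the
  common ratio, which preserves hue; `"per_channel"` equalizes channels
  independently (stronger, may shift color), `"luminance"` drives the
  scaling from the channel mean.
* `eashe()` has deliberately no strength knob: the control factors are
  data-derived. `adjust_pdf()` accepts an overridden `side_stats` object
  as a diagnostic escape hatch for studying fixed $\alpha$.

## Numerical choices

* **Log base 2 everywhere.** Threshold positions are base-invariant, but
  the reciprocal entropy weight $1/E_r$ is not; one global base keeps the
  two stages consistent, and bits make the uniform histogram score exactly 8.
* **$0 \log 0 = 0$** for empty bins, the standard limit.
* **Threshold tie-break.** The half-entropy equation rarely has an exact
  integer solution; the smallest level meeting or exceeding the half mark
  is taken (with $10^{-12}$ slack so exact halves are not lost to floating
  point), clamped to `hi - 1` so neither side is ever empty. Each stop
  overshoots $E/2$ by less than the entropy of the bin it lands on; for the
  outer segments the two nested stops compound, so segment entropies
  deviate from $E/4$ by at most $e(k_{s1,3}) + e(k_{s2})/2$ — this is the
  bound the test suite asserts against a brute-force oracle.
* **Integerization of ranges.** Real widths are rounded by largest
  remainder to a fixed total of 252 with a minimum width of 1 (deficit
  taken from the largest segment, ties to the lower index). The total 252
  rather than 255 is what makes the four closed intervals plus their three
  unit gaps tile the 256 levels without overlap.
* **Rounding half away from zero** at every quantization site (remap,
  transfer, color rescaling), for bit-identical results across platforms;
  base R's `round()` rounds half to even and would differ.
* **No intermediate renormalization.** The reshaped weights may sum to
  anything positive; the single normalization into the CDF is the defined
  place where unit mass is restored.
* **Per-side extremes over occupied bins only.** Taking
  $\mathrm{pdf_{min}}$ over all bins would pin it to 0 and inject mass at
  levels absent from the image; computing the statistics per side (rather
  than globally) follows the two-subhistogram structure of the reshaping
  stage and keeps both guard branches meaningful.

## What the synthetic generators emulate — and what they do not

`synth_image()` produces the regimes that exercise every code path:
exactly uniform histograms (near-identity behaviour), constant and
two-level images (degeneracy handling), narrow-band low-contrast images
(range stretching), seeded bimodal Gaussian mixtures (the
bright/dark-dominant structure of typical photographic test images), and
spike histograms (mass concentration). `random_pdf()` draws seeded
densities for oracle tests of the segmentation machinery. All randomness
flows through explicit integer seeds and the global RNG state is restored,
so identical specifications are bit-identical across runs and platforms.

These fixtures have no spatial structure: their histograms are realistic
but their pixel arrangements are noise. Passing tests therefore establish
the histogram-level and mapping-level properties of the method — monotone
LUTs, range tiling, mass conservation, brightness behaviour relative to
global HE — but say nothing about perceived quality on natural images,
which depends on spatial context the generators do not model.

## Test problem sizes

The oracle sweeps use 200 seeded densities with 32–256 occupied levels
(sparser densities cannot support four balanced segments and fall back by
design); structural invariants run over 500 seeded $32 \times 32$ mixture
images; the brightness and stretch comparisons use 50 seeded
$64 \times 64$ and $48 \times 48$ images. The acceptance script summarizes
20 mixture and 50 low-contrast images at the same sizes. These sizes give
stable statistics for histogram-level properties, which depend on pixel
counts only through sampling noise in the histogram.

## Known limitations

* 8-bit inputs only; 16-bit data must be requantized upstream, and the
  readers reject deep images explicitly rather than silently truncate.
* The number of segments is fixed at four.
* Global mapping only: no tile-based (CLAHE-style) local adaptation.
* The entropy weight reading, the per-side application of the reshaping,
  and the segment-local CDF in the transfer are documented design choices
  where the method's defining formulas admit more than one reading; each
  sits behind a tested interface, and the weight is user-selectable.
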
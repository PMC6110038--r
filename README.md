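# eashe

Contrast enhancement for 8-bit grayscale and RGB images by **entropy-based
adaptive subhistogram equalization**, with the objective quality metrics
used to judge it (discrete entropy, PSNR, AMBE), deterministic synthetic
test-image generators, PNG/TIFF/PGM/PPM I/O, and a command-line interface.

Global histogram equalization (HE) remaps gray levels through the image's
cumulative distribution. It enhances contrast cheaply but is notorious for
saturation artifacts, brightness shifts and detail loss — a real problem
when it is used as a preprocessing step for microscopy or medical images.
This package implements a subhistogram variant that adapts everything to
the image:

1. **Entropy-balanced segmentation.** The occupied intensity range
   `[k_l, k_u]` is split at the level `k_s2` where the cumulative entropy
   reaches half the total, then each half is split the same way, giving four
   contiguous segments of near-equal entropy
   (`E_r ≈ E/4`, r = 1..4).
2. **Dynamic-range allocation.** Segment `r` with input span
   `span_r = m_r − m_{r−1}` gets the blended output width
   `aspan_r = span_r + w_r (L/4 − span_r)`, `w_r = min(1/E_r, 1)`,
   so low-entropy (narrow, detail-poor) segments are pulled toward the
   uniform share of the range; widths are normalized so the four output
   intervals tile `[0, 255]` exactly.
3. **Adaptive density reshaping.** The range-adjusted density is split once
   more at its half-entropy level `I_ks`; each side's control factor
   `α = (I_ks − I_avg1)/(I_avg2 − I_avg1)` (and its complement) pulls the
   density quadratically toward the side's midpoint value
   `(pdf_max + pdf_min)/2`. `α = 1` keeps full HE behaviour, `α = 0` gives
   a near-linear stretch, and the data decide where between those the image
   lands — this is what controls over-enhancement.
4. **Per-segment equalization.** Each segment is equalized with its own
   normalized CDF inside its own output interval; the composed per-level
   lookup table is applied to the pixels. Degenerate inputs (constant or
   two-level images) return unchanged with a fallback flag.

## Worked example

```r
library(eashe)
img <- synth_image("gaussian_mixture", 64, 64, seed = 42)  # bimodal test image
fit <- eashe(img)
summary(fit)
```

```
Entropy-based adaptive subhistogram equalization (64x64, gray)
  thresholds (ks1, ks2, ks3): 60 160 190
  output ranges: 56 83 55 58
  control factors: alpha_low = 0.6791, alpha_high = 0.3209
Image quality report
  discrete entropy: 6.3729 -> 6.3032 bits
  PSNR: 23.2554 dB
  AMBE: 4.1042 gray levels
```

The thresholds split the histogram into four equal-entropy segments; the
output ranges show the dark mode's range being widened at the expense of the
sparser mid-tones. Discrete entropy barely drops (detail is preserved),
PSNR stays high (little over-enhancement), and AMBE of 4.1 gray levels
means the mean brightness moved very little — global HE moves it by ~20
levels on the same images. `plot(fit)` draws the input/output histograms
and the learned level mapping; `predict(fit, other_image)` reuses the
mapping.

The same pipeline is scriptable from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "eashe.R", package = "eashe"))') \
    fixture gaussian_mixture in.pgm --seed 42
Rscript .../eashe.R enhance in.pgm out.pgm --report report.json
Rscript .../eashe.R metrics in.pgm out.pgm
```

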
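---
title: "aortomorph: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aortomorph: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortomorph)
```

# The measurement problem

The aortic media is a stack of concentric elastic lamellae alternating
with smooth muscle cells (SMC), collagen and glycosaminoglycans (GAG).
Semi-quantitative "medial degeneration" grading describes local
abnormality but is blind to changes in medial *mass*: a field can look
elastin-poor either because elastin was lost or because other components
accumulated around it (dilution). aortomorph implements the quantitative
alternative: measure per-field **fractions** and lamellar geometry on
stained sections, then refer everything to the media's cross-sectional
area so that fractions, densities and *amounts per cross-section* can be
distinguished. With media outer/inner radii $r_{out}, r_{in}$,

$$A_{media} = \pi\,(r_{out}^2 - r_{in}^2), \qquad
  \text{amount}_c = f_c \cdot A_{media}, \qquad
  \text{SMC}/\text{x-sec} = \rho_{SMC} \cdot A_{media}.$$

The dilution identity — halving $f_c$ while doubling $A_{media}$ leaves
$\text{amount}_c$ unchanged — is exact by construction and is tested as
such.

# Pixel classification

Stained-section segmentation is nearest-prototype classification in
CIELAB: each palette class has one sRGB prototype; an ROI pixel takes the
class of the nearest prototype (CIE76 ΔE) unless the nearest distance
exceeds `max_distance` (default **25 ΔE**), in which case it is
*unclassified* and excluded from fraction denominators. Pixels with
luminance $L^* >$ `white_L` (default **92**) are background (lumen/white
space) regardless of prototype distance. Choices made where the original
approach is underdetermined:

- The historical implementation ("custom colour segmentation") is not
  specified anywhere we can consult; nearest-prototype in a perceptual
  space was chosen because it is deterministic, auditable and matches the
  semantics of colour segmentation. A k-means refinement seeded at the
  prototypes was considered and left out: it buys little on stains with
  well-separated hues and costs determinism.
- No illumination normalisation is applied before classification; none is
  described for the original pipeline either.
- `nucleus_policy` defaults to merging nucleus pixels into cytoplasm, so
  Movat reports exactly four components (elastin, cytoplasm, collagen,
  GAG); the policy, the denominator ("classified non-background ROI
  pixels") and the unclassified share are recorded in every result.

Fractions are averaged over fields per specimen with an unweighted mean
(`aggregate_fields`), mirroring the practice of measuring several
arbitrarily chosen high-power fields (3 each in inner, mid and outer
media) and averaging.

# Lamellar morphometry

Lamellae in flat medial fields run parallel, so transects are image
columns. Along a transect, maximal runs of elastin pixels are bands,
with two stabilisers:

- `min_band_px = 2`: runs shorter than 2 px are noise, not lamellae.
- `bridge_px = 1`: a 1-px hole does not split a band. Together these
  stabilise counts under colour jitter without hiding real fragmentation.

Thickness is the band extent in µm; **interlamellar distance is
edge-to-edge** (gap between consecutive bands), not midline-to-midline.
The underlying definition is ambiguous in the source material; the
edge-to-edge reading treats the quantity as the thickness of the
interlamellar compartment, and the convention is recorded in the output.
Lamellae thin where they divide or emit radial struts, so thickness is
only measured away from divisions: the elastin mask is thinned
(Zhang-Suen), skeleton pixels with ≥ 3 neighbours are branch points, and
measurements within `exclusion_radius` (default **10 µm**) of one are
dropped and tallied (`n_excluded`). Fewer than two bands on every
transect leaves interlamellar distance *flagged undefined*, never
fabricated.

Medial nuclei on H&E are nucleus-coloured connected components with area
in `[min_area, max_area]` µm² (defaults 4–120). Oversized blobs
(overlapping nuclei) follow a declared deterministic policy — default
`split_by_area`, counting `round(area / nominal_area)` with the nominal
single-nucleus area an ellipse of 12 × 4 µm axes; a watershed split was
not implemented (no suitable dependency, and the declared policy is
deterministic and logged, which is the actual contract). Counting all
medial nuclei overestimates SMC (endothelium and leukocytes are
included); this is a documented property of the H&E proxy, not a bug to
hide.

Layer thickness on ring sections is measured along `n_sites` radial rays
(default 3) from the tissue centroid, as the radial extent of each
classified layer, averaged across rays.

# Aortometry and the remodeling model

Expected diameter is a linear nomogram in age, sex and BSA. **The
shipped coefficients are synthetic defaults** (they produce plausible
adult ascending-aorta values near 3.3–3.6 cm) because the real published
regression coefficients are configuration, not package content; the
object records whether it still carries the synthetic defaults.
Diameters are *external*, and the lumen radius subtracts all three layer
thicknesses; the source convention is not stated, so this one is explicit
and switchable (`reference = "luminal"`). z-scores use the nomogram
residual SD; classes are `aneurysm` (observed > 1.5 × expected), `normal`
(|z| ≤ 2), else `indeterminate-dilated`.

The remodeling model treats the media as an annulus of lumen radius $a$
and thickness $b$ with conserved quantity $Q = 2ab + b^2$
($= A_{media}/\pi$). Dilating the lumen to $a'$ gives the unique positive
root

$$b' = \sqrt{a'^2 + Q} - a',$$

which is exactly area-conserving, strictly decreasing in $a'$, satisfies
$b' \to b\,a/a'$ in the thin-annulus limit, and is an involution under
forward/inverse application — all property-tested at 1e-9 relative.

For the reverse ("pre-aneurysmal") prediction the expected lumen radius
is not known directly, only the expected *external* diameter. Subtracting
the observed media from the expected radius would be inconsistent (the
predicted wall has a different media); instead the prediction is solved
self-consistently: with $c = R_{exp} - t_{intima} - t_{adventitia}$ and
conserved $Q$,

$$b_{pred} = c - \sqrt{c^2 - Q}, \qquad a_{pred} = c - b_{pred},$$

which makes a forward-dilated cohort map back to its original geometry
exactly (tested to 1e-6 relative). Lamella thickness and interlamellar
distance scale by the single factor $b_{pred}/b_{obs}$; per-lamella
nested-annulus scaling differs from uniform scaling by well under 1 % at
physiological $a/b \ge 10$ and the single-factor form matches how such
predictions are presented. All model lengths are unit-agnostic; cm/µm
conversions happen at the interface.

# Statistics

All tests are two-sided.

- **Mann-Whitney**: exact null distribution of U (Gaussian-binomial
  recursion) when $n_x n_y \le 400$ and there are no ties, else
  tie-corrected normal approximation with continuity correction; the
  result flags the branch.
- **Freeman-Halton / Fisher r × c**: full enumeration of fixed-margin
  tables; p is the sum of probabilities of tables no more probable than
  the observed one, with relative tie tolerance 1e-12. The
  *sum-of-smaller-probabilities* convention was chosen (over doubling one
  tail) because it reproduces every published p-value of the reference
  cohort's tables at 4 decimal places — the package's primary worked
  example. Above an enumeration cap (1e7 tables) a seeded Monte Carlo
  fallback (Patefield sampler, 1e6 draws) engages and is flagged.
- **Kruskal-Wallis + Dunn**: H with tie correction, χ² reference on
  k − 1 df; Dunn's z with tie-corrected variance, p multiplied by
  $m = k(k-1)/2$ and capped at 1 (the Prism-style Bonferroni procedure).
  The post hoc runs only when the omnibus rejects (configurable).
- **Spearman**: Pearson correlation of mid-ranks (tie-aware), p from the
  t approximation; zero-variance inputs yield a flagged undefined ρ.
  Inter-rater agreement on the ordinal 1–3 degeneration scores is
  pairwise Spearman.
- p-values print in table style: 4 decimals, "< 0.0001" below 0.00005.

Every test is validated against an independent oracle that shares no
code with the implementation: complete permutation enumeration for
Mann-Whitney, brute-force fixed-margin table enumeration for
Freeman-Halton, hand-computed examples for Kruskal-Wallis (H = 7.2) and
Spearman (ρ = 0.8), plus base-R implementations as cross-checks.

# What the synthetic generators emulate — and what they do not

Fields are **flat Cartesian strips**: lamellae are horizontal wavy bands
(sine displacement, amplitude 2 µm) of exact per-column thickness;
interlamellar tissue is a blocky (4 px) random texture of cytoplasm /
collagen / GAG whose class shares target the requested fractions after
accounting for lamellar elastin and expected nuclear area; nuclei are
rotated ellipses (12 × 4 µm) placed with Poisson-disk separation in the
interlamellar space. Defaults state a plausible medial field: 8 lamellae,
4 µm thick, 12 µm apart (an elastin area fraction of exactly 0.25),
256 × 256 px at 0.5 µm/px, SMC density 1500 /mm². Fragmentation gives
each 16 µm band segment a 2 µm break with the configured probability —
breaks, not wholesale erasure, so transect counts degrade the way
fragmented lamellae do; the break draws are coupled across probabilities
at a fixed seed, making "more fragmentation never adds elastin" a
testable monotone invariant. Noise is additive truncated Gaussian RGB
jitter applied after rendering; truth (realized fractions, counts,
geometry) always comes from the pre-noise label mask.

The field magnification behind published nuclei counts is not stated
anywhere we can consult; the H&E field defaults to **0.12 mm²**
(300 × 400 px at 1 µm/px), a plausible high-power field, kept
configurable. The nuclei count is `round(density × area)` rather than
Poisson so that recovery tests are exact; the cohort's diameter noise is
multiplicative log-normal clipped at ±2σ so the stated class boundaries
(all generated aneurysms > 1.5 × expected) hold by construction.

Ring images are concentric annuli with exact recorded radii. Rendering a
3 cm aorta at ≤ 2 µm/px would need a raster of ~15000² px, so the
pixel-count validation of the annulus formula runs on geometrically
similar smaller rings at fine pixel size, and large-diameter examples use
coarser pixels — a stated scaling-down, not a silent one.

What a green test on this world does **not** establish: robustness to
stain batch variation, uneven illumination, real lamellar waviness and
interruptions, vasa vasorum, tissue folds, or the true shape of medial
nuclei. The generators exercise the measurement logic, unit handling and
statistical machinery, not histological realism.

The synthetic cohort (17 nondilated vs 18 aneurysm) applies additive
group deltas to medial metrics and a 1.6-fold diameter effect; the
defaults encode the dilution scenario (elastin fraction −0.07, SMC
density unchanged, media −250 µm) so the end-to-end pipeline reproduces
the qualitative headline — fraction down, amount per cross-section
maintained, SMC per cross-section up — as a direction check only. The
latent degeneration score is deliberately independent of group, encoding
the finding that qualitative grading does not separate the groups.

# Pipeline and blinding

`run_pipeline()` derives per-stage seeds from one global seed
(`derive_seed(seed, stage)`), generates per-subject fields from the
cohort truth, and keeps the image-facing stages *blind by interface*:
classification and morphometry functions accept only images, palettes
and geometry; group labels first join the data in the derived-metrics
stage. Reports carry provenance (seed, config hash, package version) and
are bit-identical under rerun. Pipeline defaults are budget-scaled
(3 fields of 128 × 128 px per stain per subject instead of 9 high-power
fields); `n_fields = 9` restores the reference protocol.

# Known limitations

- 2-D only: no correction for aortic lengthening; cross-sectional
  amounts will underestimate volumetric gains.
- Axisymmetry is assumed wherever radii are derived from diameters.
- The CIELAB classifier has no stain-deconvolution step; strongly
  overlapping hues (e.g. faded Movat) would need palette retuning.
- The H&E nucleus count is an SMC overestimate by design (documented
  above).
- Exact r × c enumeration is exponential in table size; beyond the cap
  the Monte Carlo fallback is an estimate, flagged as such.
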
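---
title: "Circadian and brightness metrics: models, observers, and the synthetic corpus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian and brightness metrics: models, observers, and the synthetic corpus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlight)
```

## What this package computes

Indoor white lighting is today evaluated along two axes at once: *visual*
brightness and the *non-visual*, ipRGC-mediated effects of light on the
circadian system. Several metric families quantify these axes from the same
input — the absolute spectral irradiance at the eye,
$E_\lambda$ (W m$^{-2}$ nm$^{-1}$):

* **Circadian light** $CL_A$ (versions 1.0/2018 and 2.0/2021) models the
  retinal circuit behind nocturnal melatonin suppression: a melanopsin term
  plus, depending on the sign of the blue-versus-yellow opponent signal
  $b-y$, opponent-channel and rod contributions. The logistic conversion
  $CS = 0.7 - 0.7\,/\,(1 + (CL_A\,t\,f/355.7)^{1.1026})$ turns circadian
  light into a predicted melatonin-suppression fraction saturating at 0.7.
* **Melanopic equivalent daylight illuminance** (mEDI) weights the spectrum
  by the melanopic action spectrum alone and expresses the result as the
  illuminance of D65 daylight with the same melanopic irradiance.
* **Brightness models**: the equivalent luminance
  $L_{eq} = L_v\,(S/V)^{0.24}$; the linear signal
  $B_2 = V + 0.6\,g\,S + 0.5\,Mel$; and the compressed-signal model
  $M = 8.9974\,[E_v^{0.2629}(S^{0.074} + 0.5\,G^{0.0424})] - 1.3307$.
* An mEDI-based logistic **melatonin-suppression formula** with exposure
  duration and pupil dilation as co-parameters (see the caveat below).

The package implements all of these as trapezoidal spectral integrations
against bundled observer functions, plus a correlation pipeline that
evaluates every metric for an ensemble of light sources rescaled to fixed
photopic illuminance levels (default 125, 500, 750 lx), partitions the
sources into warm ($CCT \le 3710$ K) and cold white, and regresses the
metrics on each other.

## Observer functions: provenance and constructions

All metrics integrate $E_\lambda$ against tabulated functions shipped as
plain-text files under `inst/extdata/observers/` (one provenance header line
each) and loaded by `load_bundle()` onto a common grid (default 380–780 nm
at 1 nm, linear interpolation, zero extension outside each table's support;
transmittances are extended with their nearest value so they stay positive).

* **$V(\lambda)$** — CIE 1924 photopic luminous efficiency, 5 nm table,
  peak 1 at 555 nm. **$V'(\lambda)$** — CIE 1951 scotopic, 10 nm table plus
  the 505/507 nm rows, peak 1 at 507 nm.
* **S-cone fundamental** — the Smith–Pokorny fundamental is proportional to
  the Judd-revised $\bar z$ colour-matching function; the bundled table is
  the peak-normalized CIE 1931 $\bar z$ (the Judd revision differs only
  below ~460 nm at the few-percent level). The exact Judd tabulation is not
  reproducible here; this choice is the closest published stand-in.
* **Melanopsin $M_c$** — built from the Govardovskii A1 visual-pigment
  template at $\lambda_{max} = 480$ nm (quantal basis) multiplied by
  crystalline-lens transmittance and peak-normalized (peak lands at 487 nm).
* **Melanopic action spectrum $s_{mel}$** — the same pigment template
  converted to an energy basis ($\times\,\lambda/480$), times lens
  transmittance, peak-normalized; its peak lands at 490 nm, as for the
  standardized melanopic observer. Two independent published constants
  check this construction: the melanopic irradiance of D65 at 1 photopic lux
  evaluates to 1.316 mW m$^{-2}$ (published value 1.3262, −0.8 %), and the
  circadian-light normalization below lands within 1.4 % of its printed
  value.
* **Macular pigment transmittance** $mp$ — standard 2° relative density
  shape (peak near 458 nm, zero above 534 nm), $mp = 10^{-d\,\cdot shape}$.
  See the next section for how the peak density $d$ was fixed.
* **2° colour-matching functions** — CIE 1931 at 5 nm. At load, $\bar x$ and
  $\bar z$ are rescaled so their trapezoidal integrals equal $\bar y$'s
  (the CIE construction makes the three sums equal by design); this removes
  transcription-level drift and makes the equal-energy white point exactly
  $(1/3, 1/3)$.

`corrected_function()` implements the macular-corrected, peak-normalized
cone functions $V_c = (V/mp)/\max(V/mp)$ and $S_c$ analogously. On the
bundled tables $\max(V/mp) = 1$ (the maximum sits at 555 nm where the
macular pigment is transparent), so $V_c$ and the unnormalized $V/mp$
coincide — which makes the 2021 cold-branch opponent term vanish exactly at
the branch point even though, as printed, it pairs $S_c$ with the
unnormalized $V/mp$.

### Calibrating the one unstated parameter

Two properties of the circadian-light models are printed as part of their
definition: $CL_A = 1000$ for CIE illuminant A at 1000 photopic lux (which
requires the 2856 K blackbody to sit on the *warm* branch of the 2018
switch), and a warm/cold boundary empirically near 3400–3710 K. The
literature behind the models does not state the peak optical density of the
macular transmittance used in the opponent terms, and the two printed
properties pin it down: with the bundled S fundamental, a density of 0.32
(a realistic full central-field value) would put the 2018 switch at
~2540 K — classifying illuminant A as cold white and breaking the
normalization — while density 0 puts both switches at 3281 K. The bundled
table uses peak density **0.10**, which places the 2018 switch at ~3010 K
and the 2021 switch at ~3360 K, satisfying both printed properties with
margin. The illuminant-A normalization itself is then met without any
further adjustment: evaluating the 2018 model for a 2856 K Planckian
spectrum at 1000 lx returns 986 (−1.4 %), comfortably inside the ±2 %
band that the unknown provenance of the melanopsin tabulation warrants.
Notably, this anchor is almost insensitive to the lens-density scale used
in $M_c$ (it varies by under ±1.5 % for lens densities scaled anywhere from
0 to 8×), because peak renormalization compensates; no lens calibration was
applied.

The mEDI divisor is self-calibrating by construction: it is the melanopic
irradiance of the bundled D65 reconstruction at 1 photopic lux, computed at
bundle load with the same quadrature used everywhere else, so
$mEDI(\mathrm{D65\ at\ } E\ \mathrm{lx}) = E$ holds to numerical precision
regardless of tabulation step.

## Numerical choices

* Quadrature: trapezoidal, on the bundle grid; rebuilding the bundle at
  5 nm instead of 1 nm moves smooth-spectrum metrics by well under 0.5 %.
* Planck's law uses $c_2 = 1.4388 \times 10^7$ nm K.
* CCT/Duv: Ohno-style search — a precomputed Planckian locus in CIE 1960
  $(u, v)$, log-spaced over 1000–30000 K (1201 points), brackets the nearest
  point; a local distance minimization refines the temperature far below
  1 K. Duv is the signed residual distance, positive above the locus.
  $|Duv| > 0.05$ flags the CCT as not meaningful instead of returning a
  silent number.
* D-series daylight is reconstructed from the bundled $S_0, S_1, S_2$
  components (valid 4000–25000 K); D65 corresponds to
  $6500 \times 1.4388/1.4380 \approx 6504$ K.
* Degenerate inputs: an all-zero spectrum parses fine, yields 0 for the
  linear metrics and the warm branch with value 0 for circadian light, and
  is rejected with an error wherever a positive luminance is required
  (rescaling, $L_{eq}$, chromaticity).
* The rod terms depend on the *absolute* scotopic irradiance
  ($RodSat = 6.5$ W m$^{-2}$), so circadian light 2.0 is deliberately not
  homogeneous in irradiance, while mEDI and the warm-branch 2018 model are
  exactly linear.

## The as-printed melatonin-suppression formula

The mEDI-based suppression formula is reproduced verbatim:
$(0-100)\,/\,(1 + \log_{10}(mEDI \cdot 10^6)\,/\,(9.002 - 0.008\,\Delta t -
0.462\,dil))$. As printed it is internally inconsistent with the behaviour
its source describes: its large-mEDI limit is 0 rather than −100, and its
magnitude *decreases* with mEDI over the usual indoor range. The
transcription is most likely garbled (an exponent or logarithm placement).
The package evaluates it exactly as printed, labels every result
`"as-printed"`, and excludes the column from the headline correlation
orderings; no corrected form is guessed, because any correction would be
speculation.

## The synthetic ensemble

The measured 884-spectrum corpus behind the published correlation analysis
is not publicly deposited, so `generate_ensemble()` provides a seeded
synthetic stand-in with the same composition: 28 incandescent, 252
fluorescent, 419 LED and 185 daylight spectra, CCT confined to
2201–17815 K overall and $|Duv| \le 0.0153$. Per class:

* **Incandescent** — Planck's law at the target CCT; half the draws are
  multiplied by a smooth logistic long- or short-pass transmittance
  (filtered lamps), with resample-and-reject on the achieved CCT/Duv.
* **Fluorescent** — mercury lines at 405/436/546/578 nm (Gaussian,
  sd 2 nm) over canonical phosphor chemistries: triphosphor
  (narrow emitters near 450/543/611 nm) or, for targets up to 5000 K only,
  halophosphate-like (a broad ~580 nm band plus a ~480 nm shoulder). The
  blue and red band weights are solved linearly so the chromaticity lands
  exactly on a target point drawn around the Planckian locus
  (Duv jitter uniform in ±0.012).
* **LED** — blue pump Gaussian (440–460 nm, FWHM ~20 nm) plus a phosphor
  Gaussian (center 540–640 nm coupled loosely to the CCT target, FWHM
  80–120 nm); the pump/phosphor ratio is solved by 1-D root search on the
  achieved CCT.
* **Daylight** — the CIE D-series at the target CCT (4000–17815 K; the
  corpus' extreme CCTs are daylight).

CCT targets are sampled log-uniformly within each class range
(incandescent 2201–3250, fluorescent 2500–7500, LED 2201–10000, daylight
4000–17815 K): the measured corpus' CCT histogram is unknown, so a
scale-free spread is the neutral stand-in. The seed is a mandatory config
field; identical config gives a bit-identical ensemble.

Generated lamps were checked against published touchstones: at ~4000 K the
median melanopic daylight-efficacy ratios are 0.53 (fluorescent) and 0.49
(LED) versus ~0.5–0.6 for real lamps, with the 4000 K blackbody at 0.71.

### What the stand-in does and does not emulate

The ensemble reproduces the corpus' class counts, CCT/Duv placement and
technology-typical spectral shapes — enough for the branch behaviour, the
conversion-slope band and the correlation *orderings* to be meaningful. It
deliberately does **not** constrain colour rendering (the measured corpus
was entirely $80 < R_a < 100$): without that constraint the synthetic
narrowband lamps decouple the S-cone channel from the melanopsin channel
more than real commercial lamps do. The visible consequence, computed by
the test suite on the default ensemble (seed 1), is that the pooled
$r^2$ between $L_{eq}$ (S-cone driven) and mEDI (melanopsin driven) comes
out near 0.81, below the ≥ 0.85 band that the measured corpus supports,
while all other correlation orderings and bands reproduce: passing tests
therefore validate the metric stack and the ordering structure, not the
exact cross-metric $r^2$ levels of real lamp collections.

## Pipeline defaults and problem sizes

`compute_metric_table()` evaluates all metrics for every spectrum × level;
defaults follow the published analysis conditions: levels 125/500/750 lx,
$t = 1$ h, $f = 1.0$ (central visual field), exposure 60 min, no pupil
dilation, warm/cold partition at 3710 K on CCT (the per-spectrum opponent
sign is recorded alongside, and `pairwise_r2(partition_by = "by_sign")`
offers the alternative partition; the two disagree only near the boundary
for off-locus sources). Correlations are pooled across the three levels —
a single-cloud regression of one metric on another; `per_level = TRUE`
preserves the alternative. The default full run is 884 spectra × 3 levels
= 2652 rows (roughly half a minute including ensemble generation); the
branch-discontinuity sweep uses a 2200–8000 K Planckian grid at 25 K steps
and 500 lx.

## Known limitations

* Observer tables are transcriptions/constructions from published sources,
  not certified standards data; the spec-level uncertainty this introduces
  is the reason the illuminant-A normalization is quoted at ±2 %.
* No age-dependent lens models, 10° observers, or field-size-dependent
  fundamentals; the visual field enters only through the scalar $f$.
* Illuminance is treated as the paper-level "photopic vertical illuminance"
  of a spectrum at the eye; no geometry, luminance maps or radiance fields.
* The suppression formula is as-printed and flagged (above); its numbers
  should not be used quantitatively.
* Synthetic-ensemble caveats as described: orderings and bands are
  meaningful, exact cross-metric $r^2$ levels are corpus-dependent.
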
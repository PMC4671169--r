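---
title: "A geometric model of moment-arm change under elbow-flexor hypertrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A geometric model of moment-arm change under elbow-flexor hypertrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexormod)
```

## The question and the model

Strength changes after resistance training or disuse are usually attributed
to muscle force: more cross-sectional area, more force. But a joint moment is
force times moment arm, and a muscle that grows radially also pushes its own
line of action away from the bone — its moment arm grows too. `flexormod`
isolates that geometric contribution with the simplest model that can
express it: a two-dimensional sagittal view of the two proximal elbow
flexors, the biceps brachii (BIC) and brachialis (BRA), in elbow extension
with a neutral radioulnar position.

The ingredients, all closed-form:

1. **ACSA profile.** The combined flexor cross section along the humerus is
   a hyperbolic cosine, $\mathrm{ACSA}(x) = d - \cosh(b(x - c))$ with
   $d = 23\,\mathrm{cm^2}$, $b = 0.48\,\mathrm{cm^{-1}}$,
   $c = 7.3\,\mathrm{cm}$, $x$ in cm proximal to the elbow joint center.
   The curve peaks at $22\,\mathrm{cm^2}$ and is positive only on
   $(c - \mathrm{arccosh}(d)/b,\ c + \mathrm{arccosh}(d)/b)$.
2. **Cylinder assumption.** The flexor mass is a cylinder, so the centroid
   height of the cross section at $x$ is the equal-area circle radius
   $r(x) = \sqrt{\mathrm{ACSA}(x)/\pi}$.
3. **Stacking.** BIC lies superficial to BRA and the two are assumed equal
   in size, so their lines of pull sit at $\varphi\, r(x)$ with
   $\varphi = 3/2$ (BIC) and $1/2$ (BRA). Uniform hypertrophy scales areas
   by $\alpha$, hence all heights by $\sqrt{\alpha}$:
   the belly curve is $\varphi\sqrt{\alpha}\,r(x)$.
4. **Tendon as tangent line.** Distal to the musculotendinous junction
   $\beta$ (BIC $1.1$ cm, BRA $0.69$ cm) the tendon is the tangent to the
   scaled belly curve at $\beta$, with slope
   $s(\alpha) = \varphi\sqrt{\alpha}\,r'(\beta)$.
5. **Moment arm.** With the joint center at the origin and insertion
   distance $\gamma$ (BIC $4.51$ cm, BRA $3.17$ cm), the perpendicular
   distance from the tendon line to the origin is
   $\mathrm{MA}(\alpha) = \gamma\sin(\arctan s) = \gamma s/\sqrt{1+s^2}$.
   It is strictly increasing in $\alpha$ and bounded by $\gamma$.
6. **Force chain.** $F_\mathrm{muscle} = \mathrm{ACSA}\cdot\mathrm{NMF}$
   with specific tension $\mathrm{NMF} = 30.75\,\mathrm{N\,cm^{-2}}$ (mean
   of commonly reported values, held constant across $\alpha$);
   $F_\mathrm{tendon} = F_\mathrm{muscle}\cos\theta_p$ with pennation
   $\theta_p(\alpha) = \alpha\,\theta_{p0}$; and the moment contribution
   $M = F_\mathrm{tendon}\cdot\mathrm{MA}$ (moment arm converted cm to m,
   so $M$ is in N·m). The "excl. MA" variant freezes the moment arm at its
   $\alpha = 1$ value, so the incl./excl. ratio is exactly
   $\mathrm{MA}(\alpha)/\mathrm{MA}(1)$.

```{r sweep}
sw <- flexor_sweep()   # alpha = 0.5 .. 2.0 by 0.1, both muscles
summary(sw)
```

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `d_offset`, `b_width`, `c_peak` | 23, 0.48, 7.3 | cm², 1/cm, cm | cosh profile of combined flexor ACSA |
| `beta` | 1.1 (BIC), 0.69 (BRA) | cm | MT junction: where belly becomes tendon |
| `gamma` | 4.51 (BIC), 3.17 (BRA) | cm | insertion distance distal to joint center |
| `phi` | 3/2 (BIC), 1/2 (BRA) | — | stacking factor placing the line of pull |
| `theta_p0` | 15 (BIC), 10 (BRA) | degrees | baseline pennation angle |
| `nmf` | 30.75 | N/cm² | specific tension, constant across alpha |
| `baseline_acsa` | 11 | cm² | per-muscle maximum ACSA at alpha = 1 |
| `grid` | 0.5..2.0 by 0.1 | — | modelled hypertrophy interval |

Two of these deserve comment, because the published description
underdetermines them and the package had to take a position:

**Tendon slope scaling.** A literal reading of the tendon-line equation
gives a slope $r'(\beta)$ without the $\varphi\sqrt{\alpha}$ factor — under
which the moment arm would not depend on $\alpha$ at all, contradicting the
published moment-arm table and the whole point of the model. The package
therefore uses the true tangent to the *scaled* curve,
$s = \varphi\sqrt{\alpha}\,r'(\beta)$, which reproduces every verifiable
published cell to two decimals. The literal variant remains available as
`literal_eq3 = TRUE` for side-by-side comparison and is deliberately *not*
part of any default path.

**Pennation baselines.** The baseline pennation angles are not printed with
the model constants. They were recovered by inverting the force chain,
$\cos\theta_{p0} = M/(F_\mathrm{muscle}\,\mathrm{MA})$, on the baseline
moment cells — giving 15° (BIC) and 10° (BRA), physiologically ordinary
values for these muscles — and then validated out-of-sample: with
proportional scaling $\theta_p = \alpha\,\theta_{p0}$ they reproduce all
atrophy and hypertrophy moment cells except one (below).

**Per-muscle ACSA.** The force equation uses each muscle's *maximum* ACSA,
$\alpha \times 11\,\mathrm{cm^2}$ (half the 22 cm² profile peak under the
equal-size assumption), not the ACSA at the junction $\beta$. This is the
only reading consistent with the published ACSA rows and with both muscles
having identical muscle force at every $\alpha$.

## Numerical choices

- **Rounding.** Table cells are kept at full precision internally and
  rounded only at the reporting boundary, half away from zero, to two
  decimals. Percent moment-arm changes are computed *from the rounded
  cells* and rounded to one decimal: that convention yields the published
  27.2% (BIC) and 37.3% (BRA); full-precision values (27.5%/37.6%) are
  reported alongside, flagged as the non-matching convention.
- **One known discrepancy.** The BRA excl.-MA hypertrophy cell computes to
  4.75 N·m from the constants above while the published table prints 4.76 —
  almost certainly rounding in the source's own printed coefficients. The
  package reports its computed 4.75 and documents the difference rather
  than patching it.
- **Grid construction.** The default $\alpha$ grid is built by integer
  indexing, $(5{:}20)/10$, so repeated addition of 0.1 can never drift a
  grid point off the exact tenths that the summary extraction matches on.
- **Domain policy.** Evaluating the profile outside its positive support is
  an error, not a clamped zero: a non-positive cross section is
  nonphysical and should fail loudly. Likewise pennation at or beyond 90°
  errors rather than returning a nonpositive force component. $\alpha$
  outside $[0.5, 2]$ is allowed with a warning, since the model was only
  exercised on that interval.
- **Fitting.** `fit_acsa_profile()` is bounded Levenberg–Marquardt
  least squares (`minpack.lm::nlsLM`) on ACSA residuals — the source
  reports a regression but not its procedure, so least squares is this
  package's choice. Initialisation is data-driven (peak position from the
  largest sample, offset from the sample maximum plus 1, width 0.5) with
  bounds $b \in (0, 10]$, $d \in (1, 10^3]$; at least 4 samples with two
  distinct positions on each side of the sample maximum are required,
  otherwise the three-parameter cosh is under-determined. Non-convergence
  is reported as a flag, never as fabricated coefficients.

## The synthetic-data generator

`simulate_acsa_samples()` stands in for the MRI measurements the original
profile was regressed from: cross sections at positions spanning 2.4 to
11.2 cm proximal to the elbow (the CLI default draws 65 positions, matching
the source study's 65 subjects), with additive Gaussian noise on ACSA
(default sd 0.5 cm², a few percent of the 22 cm² peak — the source states
no error model, so Gaussian is the minimal assumption) clamped at zero.
Draws are seed-deterministic and leave the caller's RNG stream untouched.

What it does *not* emulate: between-subject anatomical variation (one true
profile generates all samples), slice-position error, non-Gaussian
segmentation artefacts, or any deviation of real flexor bellies from the
cosh/cylinder idealisation. Passing the generate-fit round-trip tests
therefore shows the estimator is correct and unbiased *under the model's
own assumptions* — it says nothing about how well a cosh profile describes
any particular arm.

## The arcsine scaling characterization

The source observes that the relative moment-arm change is approximately
proportional to the arcsine of the square root of the ACSA ratio. Taken
literally that predictor is undefined for hypertrophy
($\arcsin\sqrt{2}$ does not exist), so `ma_scaling_check()` evaluates the
nearest well-defined form: since
$\mathrm{MA}(\alpha)/\gamma = \sin(\arctan(s_1\sqrt{\alpha}))$, the
predictor applies the arcsine to the $\sqrt{\alpha}$-scaled baseline sine
of the insertion angle,
$P(\alpha) = \arcsin(\sqrt{\alpha}\,\mathrm{MA}(1)/\gamma) /
\arcsin(\mathrm{MA}(1)/\gamma)$, and the report gives the coefficient of
variation of $[\mathrm{MA}(\alpha)/\mathrm{MA}(1)]/P(\alpha)$ over the
grid. The claim is approximate and is *quantified, never asserted*: on the
default grid the CV is about 7.6% for the BIC and 1.8% for the shallower
BRA, whose smaller tendon slope keeps it closer to the small-angle regime.

```{r scaling}
ma_scaling_check(sw)
```

## Problem sizes and test design

All headline quantities are closed-form, so the test suite runs the full
16-point sweep (32 muscle-alpha evaluations) directly. Stochastic checks
use study-scale fixtures chosen once: 65 sample positions with noise sd
0.5 cm² for single-fit recovery, and 200 seeded replicates for the
round-trip bias check (bias is required to be within three standard errors
of zero). Derivative claims are checked against central finite differences
with step $10^{-6}$ cm at relative tolerance $10^{-6}$, over 100 points of
the support.

## Known limitations

The model is two-dimensional, one joint position (extension, neutral
radioulnar), two muscles, straight tendon lines — no wrapping surfaces, no
joint-angle dependence, no force–velocity or activation dynamics, no
fascicle-length change, no myofascial force transfer, and a specific
tension held constant across hypertrophy states. Its value is as a clean,
fully reproducible baseline for the geometric effect of size on moment
arm, and as a hypothesis generator; its moment-arm predictions have not
been validated in vivo, and nothing here should be extrapolated to other
muscles, joints, or joint angles.
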
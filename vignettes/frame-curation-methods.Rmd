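---
title: "Curating emotion-labeled frames from prompt-structured game sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating emotion-labeled frames from prompt-structured game sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emosift)
library(dplyr)
```

## The problem

Emotion classifiers trained on adult face datasets generalize poorly to
children, and especially to children with developmental differences in
facial affect. One way to close that gap is to collect labeled frames at
scale from structured play: a charades-style mobile game in which a child
acts out a prompted emotion while the phone's front camera records them for
a 90-second session. The session's meta-information delimits the recording
into *prompt regions* — intervals during which one prompt, with a known
target emotion, was on screen. That context is weak supervision: frames
inside a region are *likely* to show the region's emotion, but far from
certain, because children take time to interpret a prompt, relax before the
next one, look away, or simply fail to produce the expression.

`emosift` implements a semi-automatic curation pipeline over this structure:

1. **Boundary selection** — keep every frame inside regions whose prompt
   emotion matches the target label.
2. **Sub-bound trimming** — additionally crop `alpha` seconds at the start
   of each region (the interpretation lag) and `beta` seconds at its end
   (the trailing decay, when the face relaxes or leaves the frame as the
   phone is tilted to advance the prompt).
3. **Minimum-confidence filtering** — keep only frames whose classifier
   confidence for the region's emotion strictly exceeds a per-class
   threshold `lambda`; scores can come from one provider or be fused
   (min/max/average) across several.

The per-class parameters `(alpha, beta, lambda)` are tuned by greedy
searches driven by a density-versus-yield tradeoff ratio, described below.
A seeded synthetic session generator reproduces the statistical structure
these stages assume, so every stage is testable without video files or
cloud classifier access.

## Data model and conventions

All containers are ordinary tibbles: a region table (one row per prompt
region), a frame table (one row per frame, at `i / fps` seconds, 0-based),
a long annotation table, and a long score table (`frame_id`, `provider`,
`emotion`, `score`). Multiple sessions pool by `bind_rows()`.

The label codomain is fixed at seven classes: six Ekman emotions with anger
and contempt merged into `angry`, plus `neutral`. All input vocabularies —
rater terms and the per-provider score dialects — are canonicalized onto
this set on read; `confusion` is discarded (not all classifiers support it
and no prompts elicit it), and provider keys mapping to the same canonical
label have their scores summed and capped at 1, treating them as
probabilities of a union event.

**Interval convention.** Regions are treated as left-closed/right-open:
a frame at a shared boundary belongs to the region whose prompt is on
screen starting at that instant. The selection formalism is sometimes
written with closed bounds on both ends; we deviate deliberately so that no
frame is counted in two regions. Sub-bound selection retains frames with
`t_start + alpha <= t < t_end - beta`.

**Score scales.** Provider dialects declare their scale (Azure-style 0–1;
Sighthound- and Rekognition-style 0–100 — the scales are configurable via
`register_dialect()` since historical API behavior is not documented
precisely). Everything downstream sees scores in [0, 1].

## The tradeoff ratio and the greedy searches

Trimming and thresholding trade *yield* (retained frames) for *density*
(the fraction of retained ground-truth frames that actually match the
target emotion). A candidate parameter setting is compared to a baseline
by

\[ k = \frac{100\,(D_{\mathrm{cand}} - D_{\mathrm{base}})}
           {100\,(N_{\mathrm{base}} - N_{\mathrm{cand}})/N_{\mathrm{base}}} , \]

the density gain in percentage points over the percentage of frames lost.
`k = 1` — density up by the same margin the yield shrank — is the boundary
of an acceptable tradeoff; greedy steps are accepted while `k >= 1`.

Two genuinely open readings are exposed as switches, with defaults the
package commits to:

* **Loss denominator** (`loss_on`). Measuring the loss on *all* retained
  frames sounds natural but is degenerate: if a trim removes only
  mismatched frames, algebra gives `k = D_cand` exactly, so `k >= 1` is
  reachable only at density 1 and the search never accepts a step. The
  meaningful quantity is the loss of *matching* (relevant) frames — the
  frames the curated dataset exists to collect — and that is the default.
  `loss_on = "all"` remains available for comparison.
* **Baseline** (`baseline`). `k` is measured against the initial state
  (`alpha = beta = 0` for the trim search, `lambda = 0` for the threshold
  search) rather than the previously accepted step; `"previous"` is
  available as the alternative reading.

Because `k` is baseline-relative, a candidate that changes nothing (or
trades matching frames at unchanged density) can inherit a passing `k`
from earlier accepted steps. Acceptance therefore carries a
**marginal-gain guard**: a step must also strictly improve density over
the current accepted state. Without it, the threshold search would crawl
to its cap across score gaps, and the trim search would keep eating
matching frames once density reaches its plateau.

The trim search evaluates the two single-axis increments
`(alpha + step, beta)` and `(alpha, beta + step)` each iteration, accepts
the admissible candidate with the larger `k` (ties increment `alpha`), and
stops when neither qualifies or the caps are reached. Defaults: step
0.2 s (one frame at 5 frames/s — observed optimal trims are multiples of
it), caps 2.4 s (beyond plausible per-region trims, preventing
pathological full-region crops). The threshold search raises `lambda`
from 0 in steps of 0.01 (observed optima are multiples of 0.01) up to a
0.5 cap. The searches are sequential — trim first, then `lambda` at the
fixed trim — and run independently per class, since interpretation lag
and classifier calibration both differ between emotions. Optimization uses
only frames with consensus ground truth; unlabeled frames cannot inform a
density and are ignored by the searches (though `lambda > 0` drops
unscored frames at extraction time, since absence of a score cannot exceed
a positive threshold — `lambda = 0` means no filtering at all).

`tradeoff_grid()` is the exhaustive oracle: it evaluates density and
retention at every grid point so tests can replay each accepted greedy
step and the terminating condition against an independent enumeration.

## The synthetic world

`simulation_config()` states the world the generator emulates; the
defaults are fixed once and are not tuning knobs:

| parameter | default | why |
|---|---|---|
| `duration`, `fps` | 90 s, 5 /s | the game's session length and the analysis subsampling rate (450 frames/session) |
| `region_duration_range` | U(2, 10) s | no empirical distribution of prompt dwell times is available; a uniform placeholder, configurable |
| `onset_lag`, `decay` | 0.6 s, 1.0 s | the interpretation-lag / trailing-decay magnitudes the recovery experiments posit; per-class configurable |
| `p_express` | 0.75 | interior densities observed after trimming real sessions sit near 75% |
| `p_invalid` | 0.12 | about 12% of manually reviewed frames (165/1350) were unlabelable (no face, blur) |
| `carryover_prob` | 0.5 | during the lag the face holds the previous prompt's expression about as often as it rests at neutral |
| provider `concentration` | 6–10 | Dirichlet sharpness: true-label expected score `(1+c)/(7+c)` strictly dominates `1/(7+c)` for any `c > 0` (the calibration contract); `Inf` gives one-hot scores |
| provider `miss_rate` | 0.05–0.08 | per-provider face-detection misses |

Labels are generated per frame: previous-region carryover or neutral
during the lag, the target with probability `p_express` (else a
confusion-weighted wrong label) in the interior, neutral during the decay,
and absent with probability `p_invalid` anywhere. One global seed fans out
into derived per-session and per-provider streams, so adding a provider
never perturbs session structure. Bundles are emitted in exactly the
interchange formats the readers consume, making synthetic data
indistinguishable from field data to the rest of the system.

What the generator does *not* model: real faces, rater disagreement (the
emitted annotation pair is a perfect-rater pair derived from the truth),
parent camera-handling beyond the decay window, autocorrelated expression
within a region, and provider-specific failure modes beyond a miss rate
and a symmetric score draw. A green test on this world establishes that
the algorithms behave as specified under their own assumptions — not that
those assumptions hold for any particular clinical population.

A consequence of the stated world worth knowing: the `neutral` class has
no recoverable lag/decay signal, because its junk frames are themselves
mostly neutral. Parameter-recovery experiments therefore target a
non-neutral class.

## Worked example

```{r example}
cfg <- simulation_config()
bundle <- simulate_bundle(cfg, n_sessions = 5, seed = 42)

params <- optimize_params(bundle$meta, bundle$frames,
                          scores = bundle$scores, fusion = "average")
params

cmp <- evaluate_techniques(bundle$meta, bundle$frames, bundle$scores,
                           params, fusion = "average")
cmp |>
  select(emotion, technique, density) |>
  tidyr::pivot_wider(names_from = technique, values_from = density)
```

The comparison reproduces the qualitative structure the method is built
around: prevalence over the whole video is low for every non-neutral
emotion; boundary selection concentrates it severalfold; trimming and
confidence filtering raise density further at a bounded cost in yield.

```{r plot, fig.width = 7, fig.height = 3.5}
ggplot2::autoplot(cmp)
```

## Rater reliability

Consensus ground truth keeps a frame only when both raters labeled it
(*valid*) and agreed. `rater_reliability()` reports the counts, percent
agreement `100 * trace / total`, and Cohen's kappa
`(p_o - p_e) / (1 - p_e)`; the degenerate single-label case (`p_e = 1`)
is defined as kappa 1 under perfect agreement. Display rounding is
half-up to one decimal; internal values stay unrounded.

## Numerical choices and edge cases

* Ties in the trim search go to `alpha`; the search schedule is otherwise
  the larger-`k` single-axis increment.
* A region whose trimmed interval is empty contributes no frames — not an
  error; a fully trimmed class returns an empty frame set.
* `tradeoff_ratio()` conventions: no gain gives `k = 0`; gain at zero loss
  gives `k = Inf`; a baseline retaining nothing is an error.
* Confidence filtering uses a strict inequality (`score > lambda`), with
  `lambda = 0` special-cased to disable filtering entirely (including for
  unscored frames); whether historical experiments used strict or
  non-strict comparison is not documented, and the strict reading is
  standardized here.
* Floating-point thresholds accumulate by rounding to 10 decimals so the
  chosen `lambda` is always an exact multiple of the step.

## Known limitations

* Exactly two raters are supported for consensus and reliability; the
  generalization to rater panels is deferred.
* The searches are sequential per class, not a joint
  `(alpha, beta, lambda)` optimization, matching the procedure they
  implement.
* Real-study headline numbers (per-class densities on clinical video) are
  not reproducible from this package: they depend on private video of a
  small clinical cohort and on 2019-era commercial classifier responses.
  The package's claims are the arithmetic identities, the property
  invariants, and recovery on the stated synthetic world.
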
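---
title: "Methods: scoring melasma severity and evaluating treatment effect with a GA-BP network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring melasma severity and evaluating treatment effect with a GA-BP network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(melasmaGABP)
```

## The clinical scoring system

Melasma severity enters the model through two instruments.

**MASI.** The Melasma Area and Severity Index divides the face into four
regions — forehead, right malar, left malar, chin — and scores each for
darkness $D \in \{0..4\}$, homogeneity $H \in \{0..4\}$ and area
$A \in \{0..6\}$:

$$M = 0.3\,A_F(D_F+H_F) + 0.3\,A_{MR}(D_{MR}+H_{MR}) +
      0.3\,A_{ML}(D_{ML}+H_{ML}) + 0.1\,A_C(D_C+H_C).$$

The attainable range is $[0, 48]$ and the score is monotone in every
component; both facts are verified by lattice enumeration in the test
suite. Treatment response is the relative decline
$(V_b - V_a)/V_b$ from the pre-treatment MASI $V_b$ to the post-treatment
$V_a$. We divide by the *baseline* $V_b$, which keeps complete clearance at
exactly 100% and makes the published grade bands attainable; the variant
normalized by $V_a$ is available via `denominator = "after"` for comparison
with sources that print it that way, but it is unbounded above and cannot
feed the band classifier. The four efficacy grades use half-open bands —
invalid $<10\%$, get better $[10\%, 50\%)$, effective $[50\%, 90\%)$,
basically healed $\ge 90\%$ — so every finite rate is classified exactly
once; published band tables typically print integer gaps ("50%–89%", "≥90%")
that leave non-integer rates unassigned, and the half-open convention is the
unique monotone resolution.

**RCM.** Reflectance confocal microscopy grades five parameters on an
ordinal 1–4 scale: epidermal pigmentation (fraction of the field pigmented:
$\le 25\%$, $\le 50\%$, $\le 75\%$, above), dendritic-cell and melanophage
counts (none / $\le5$ / $\le15$ or $\le10$ / more), and solar elastosis and
vascularity (normal / mild / moderate / serious). The printed pigmentation
bands also contain gaps (25% vs 26%); we again close them half-open on the
fraction scale. Images never enter the package — measurements arrive as
numbers or severity labels.

`grade_to_target()` encodes the four grades at their band midpoints (0.05,
0.30, 0.70, 0.95). The encoding is the package's own choice: it is strictly
monotone, and `grade_outcome()` inverts it exactly, which is what the
confusion summary `grade_report()` relies on.

## The network

A three-layer perceptron maps the five min–max-normalized RCM scores to one
sigmoid output regressing the continuous treatment-effect value $b \in
[0,1]$. Hidden and output units use the unipolar sigmoid
$f(x) = 1/(1+e^{-x})$, computed branch-stably so tails saturate cleanly
instead of overflowing. Biases are ordinary weights on constant inputs
($x_0 = y_0 = 1$), so the 5-10-1 architecture has
$(5{+}1)\cdot10 + (10{+}1)\cdot1 = 71$ parameters.

The hidden size follows $H = m + n + a$ with $a = 4$ by default, giving
$H = 10$ for five inputs and one output; the alternative
$H = \lceil\sqrt{m+n}\rceil + a$ often quoted for the same heuristic is
available via `hidden_rule = "sqrt"`. A single continuous output was chosen
over a four-way one-hot head because the evaluation target is a continuous
effect value; grades are derived downstream by thresholding.

**Error and gradients.** The per-sample error is
$E_s = \tfrac12\sum_k (b_k - O_k)^2$; the global error $E$ is the *mean*
over samples, which keeps the 0.001 convergence goal meaningful regardless
of cohort size (a summed error would scale with $n$). Gradients are exact
backpropagation with $f' = f(1-f)$; `bp_gradient()` is exported and checked
against a central finite-difference oracle (step $10^{-5}$, relative
tolerance $10^{-6}$) in every test run.

**Update mode.** Both classic update schedules are implemented:
`batch = "full"` takes one step per epoch along the accumulated gradient,
and `batch = "online"` (the default) sweeps the samples in order, stepping
on each sample's own gradient. Online updating is the default because with
the mean-aggregated error the full-batch gradient is $1/n$-scaled: at the
standard learning rate 0.2 and 1000 epochs a 200-patient cohort moves so
slowly that training ends far from the attainable error (test MAE ≈ 0.1
versus ≈ 0.04 online under identical settings). Per-sample updating is the
schedule the classic three-layer-perceptron literature describes and is the
only one of the two that reaches the stated error goal at the stated
learning rate and epoch budget.

**Initialization and determinism.** Weights start uniform in
$[-0.5, 0.5]$ from a seeded generator; identical config, data and seed give
bitwise-identical training runs. A non-finite $E$ aborts training with the
epoch index rather than propagating NaNs.

## The genetic algorithm

`ga_search()` evolves real-coded genomes — here flattened weight vectors —
with fitness $f = 1/(E + \varepsilon)$, $\varepsilon = 10^{-12}$ guarding
the perfect-fit case where $1/E$ is undefined. Selection is
roulette-wheel on $P_i = f_i / \sum f$; the best individual is copied
unchanged (elitism 1), which makes the best fitness non-decreasing — a
property asserted on every run. The operator forms are the package's own
choices, since only real coding itself is mandated by the design this
follows: arithmetic crossover (children are convex combinations of the
parents, coefficient $\alpha \sim U(0,1)$, so children stay inside the
parents' componentwise envelope) and Gaussian mutation (each component
perturbed with probability $P_m$ by $N(0, 0.1^2)$ noise).

Control parameters default to population 20, 40 generations, $P_c = 0.3$,
$P_m = 0.01$ — fixed rates. The adaptive alternative
$P_c = c\,(f_{\max} - f_a)$, $P_m = d\,(f_{\max} - f_a)$ (spread between
maximum and mean fitness) is available via `adaptive = TRUE`, with rates
clamped to $[0.01, 0.99]$ because the raw formulas can produce 0 (search
stalls) or values above 1 as the fitness scale drifts.

**GA-BP.** `ga_bp_train()` is the two-phase hybrid: the GA scores genomes
by the training-set global error *without* any gradient refinement (a pure
initialization search), then the best genome ever seen is decoded and handed
to `bp_train()`. With zero generations and a single individual the scheme
degenerates exactly to plain BP with one random draw, which the tests use as
a reduction check.

## The synthetic cohort

No patient records ship with the package, so `generate_cohort()` emulates
the assumed data structure: 240 patients, five RCM scores each, split
200/40. Scores are marginally uniform on $\{1,2,3,4\}$ with a Gaussian-
copula correlation of 0.4 between the pigmentation and melanophage scores —
pigment-laden macrophages accompany heavier epidermal pigmentation, and the
copula is the simplest way to encode that while keeping ordinal uniform
marginals. The ground-truth effect is linear in the severity fractions,

$$g = \mathrm{clip}\Big(1 - \sum_k w_k \frac{s_k - 1}{3},\ 0,\ 1\Big),
\qquad w_k = 0.2,$$

so an all-healthy profile (all scores 1) has expected effect 1 and an
all-severe profile (all 4) has 0; the observed target adds $N(0, 0.05^2)$
noise, clipped back to $[0,1]$. Linearity-with-clipping is the simplest
monotone mechanism consistent with the premise that the five indicators
determine the outcome; `nonlinear = TRUE` adds a dendritic×melanophage
interaction to stress the hidden layer. Targets stay within $[0,1]$ by
construction — out-of-range expected values occasionally seen in printed
validation tables are treated as typographical artifacts, not emulated.

What the generator does *not* emulate: the unknown empirical score
distribution of a real clinic population, rater noise in the ordinal scores
themselves, and any nonmonotone or threshold physiology. Passing tests
therefore show that the pipeline recovers a known monotone mechanism from
ordinal inputs at realistic noise — not that it reproduces clinical error
magnitudes, which depend on data that is not available.

## Experiment design and what the numbers mean

`run_experiment()` repeats the whole pipeline over paired seeds: each repeat
simulates a fresh cohort, splits it, fits the normalizer on the training
half, and trains BP and GA-BP on *identical* data so the comparison
isolates initialization. Reported are per-repeat test MAEs, their means and
variances, and the fraction of repeats where GA-BP matches or beats BP.

Two deliberate calibrations of the recovery experiment: the noiseless
recovery run trains to convergence (goal $10^{-7}$, still capped at 1000
epochs) because the standard 0.001 goal — calibrated to noisy clinical
targets — sits above the noiseless error floor and would stop training
after a dozen epochs; the noisy recovery keeps the 0.001 goal. Typical
results: test MAE ≈ 0.009 noiseless and ≈ 0.044 at noise 0.05, i.e. the
network recovers the mechanism essentially up to the injected noise.

**Known limitation.** Under online training both models converge close to
the noise floor on this (deliberately learnable) synthetic mechanism, so the
GA initialization's advantage is small — at the default conditions GA-BP
wins 65% of 20 paired repeats with a variance ratio of 0.80, but the margin
per repeat is on the order of 0.001 MAE and other base seeds can land near
50%. The comparison here supports the *direction* of the claim that
evolutionary seeding helps stability; the large clinical gap originally
reported for this scheme likely reflects gradient descent stalling on real,
noisier data, which this generator does not reproduce.

## Problem sizes and numerical choices

The test suite runs everything at the study's own scale: 240-patient
cohorts, 20 paired repeats for the comparison, 5 seeds for each recovery
average, 10 random 3-4-2 networks for the gradient oracle, and $10^5$ draws
for the roulette-frequency check. Key tolerances: gradient check $10^{-6}$
relative; normalization round trip $10^{-12}$; selection-probability
normalization $10^{-12}$. Degenerate (constant) features normalize to 0.5
and invert to their constant value. Band boundaries are half-open
everywhere, so ties at 10%/50%/90% (and at the RCM count cut-points) resolve
upward deterministically.
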
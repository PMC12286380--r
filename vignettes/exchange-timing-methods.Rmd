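---
title: "Methods: temporal decomposition of vocal exchanges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal decomposition of vocal exchanges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callexchange)
```

## The question and the data model

Paired songbirds exchange very short contact calls (~25 ms). The question
this package addresses is whether the *timing* of those calls shows genuine
turn-taking: does a bird answer its partner with a characteristic short
latency, or do two birds simply call independently and sometimes land close
together by chance?

The unit of data is an annotated call event: session, experimental phase
(`PRE`, `F2F`, `POST` — each 900 s; only `F2F` has both birds present),
caller, onset and offset in seconds from phase start, and vocal type. From
an onset-sorted event sequence within one session phase we form
*transitions*: consecutive call pairs, classed `exchange` when the caller
changes and `repeated` when it does not, each carrying the offset-to-onset
interval $t = \mathrm{onset}_{k+1} - \mathrm{offset}_k$. Negative intervals
are overlapping calls. Transitions never span a session or phase boundary,
and pooled analyses simply concatenate per-session transitions, without
session covariates.

## The interval mixture

Inter-call intervals are strongly bimodal on a log scale: a tight mode
near 0.2 s (response-like "associated" transitions) and a broad mode at a
few seconds (independent calling). We model the $\log_{10}$ intervals as a
two-component Gaussian mixture

$$f(x) = w_s\,\mathcal{N}(x;\mu_s,\sigma_s^2)
       + w_l\,\mathcal{N}(x;\mu_l,\sigma_l^2),\qquad w_s + w_l = 1,$$

with unequal variances and the component count fixed at two — the
bimodality is a modelling assumption, not something we select for. The
base-10 convention matters for reading the estimates: a short mean of
$\mu_s = -0.73$ is $10^{-0.73} \approx 0.19$ s.

Numerical choices:

* **Exclusions.** Negative intervals cannot be log-transformed and are
  dropped (and counted) before fitting; a zero interval is a measure-zero
  boundary case and is excluded for the same reason.
* **EM.** Maximum likelihood by expectation–maximization. The first start
  splits the sample at its median; nine further starts use random
  responsibilities, and the best start by log-likelihood wins. Convergence
  is declared when the relative log-likelihood change falls below
  $10^{-8}$. The iteration cap is 5000: on genuinely unimodal input the
  mixture likelihood has a flat ridge and EM can need a few thousand
  iterations to meet that tolerance.
* **Variance floor** of $10^{-6}$ (log10 s)² prevents a component from
  collapsing onto duplicated values.
* **Labelling.** Components are labelled after fitting so that
  $\mu_s < \mu_l$ always.

`fit_two_component_gmm()` is the package's own EM implementation; the test
suite cross-checks it against an independent mixture fitter (mclust) on the
same data and against the generating parameters of seeded draws.

A caution the tests make explicit: when the data hold *no* true short mode,
a two-component ML fit does not collapse to one component — it splits the
unimodal mass into two overlapping halves with arbitrary weights. The raw
short-component weight is therefore not a reliable measure of "how much
response behaviour is present". For that question we use
`mixture_mass_below(fit, 0.5)`, the fitted-mixture CDF at 0.5 s: the
probability that an interval from the fitted mixture is shorter than half a
second. It equals $w_s$ (almost) when a genuine sub-second mode exists and
stays near the chance level when it does not.

## Comparing conditions: the percentile-interval test

To compare the short component between two conditions we follow a
parametric Monte-Carlo recipe: per repetition, draw one value from
$\mathcal{N}(\mu_A, \sigma_A^2)$ and one from
$\mathcal{N}(\mu_B, \sigma_B^2)$ (the *fitted* component mean and
variance), record the difference, repeat 10,000 times, and report the
2.5th–97.5th empirical percentiles (linear interpolation between order
statistics; at $n = 10{,}000$ the percentile convention moves bounds by
less than $10^{-3}$). The conditions are declared different when the
interval excludes zero; no p-value is computed.

Two properties of this procedure are worth stating plainly:

* It is *not* a permutation test in the label-shuffling sense, despite the
  family resemblance; it is Monte Carlo from the fitted normals. The
  closed form of the difference of independent normals,
  $(\mu_A - \mu_B) \pm z_{0.975}\sqrt{\sigma_A^2 + \sigma_B^2}$, is used
  throughout the tests as the oracle for the bounds.
* It is conservative by construction. The band spans the central 95% of
  the distribution of *single* differences (spread
  $\sqrt{\sigma_A^2+\sigma_B^2}$), not of a mean difference, so when the
  two means are equal, zero sits at the centre of the band and is covered
  essentially always — not 95% of the time. Only separations large
  relative to the pooled component spread are declared significant.

Because the difference direction matters when matching bounds across
comparisons, each result records its order explicitly (e.g.
`exchange - repeated`, `F2F - solo`, `PRE - POST`).

One reported input deserves a flag: the POST-phase short component is
printed in the source material as $-0.074 \pm 0.334$, an order of magnitude
away from every other short mean (~$-0.7$) yet numerically consistent with
its printed interval bound. The package reproduces the printed computation
as given and does not guess at the intended value.

## The pseudo-turn-taking null

The null model asks what exchange intervals would look like if the two
birds ignored each other. For every ordered pair (subject, facing) we
collect that pair's F2F sessions and re-pair each subject track with the
facing track of a *different* session of the same pair, using a seeded
uniform derangement of the session indices (rejection sampling; a
derangement guarantees no pseudo session reproduces a real one). Track
clocks are untouched — no time offset is added — so each bird's marginal
call-time multiset is conserved exactly, while the temporal dependence
between tracks is destroyed. Whether one facing session could be reused
for several pseudo sessions was an open choice; the derangement (each used
exactly once) is the stricter and is what we implement.

On data with genuine responding, the pseudo pairing empties the
sub-second exchange mass (an ~80% drop in `mixture_mass_below` at 0.5 s in
the shipped analysis run) while leaving each track's own statistics
untouched.

## Call counts across phases

Per-subject call counts per phase are modelled as
$y_{ij} \sim \mathrm{Poisson}(\lambda_{ij})$,
$\log \lambda_{ij} = \beta_0 + \beta_{\mathrm{F2F}} + \beta_{\mathrm{POST}}
+ u_{\mathrm{subject}} + v_{\mathrm{trial}}$, with independent Gaussian
random intercepts, fitted by Laplace-approximated maximum likelihood
(`lme4::glmer`). Phase is coded with PRE as reference, so the F2F
coefficient is a log rate ratio against solo calling. "Trial" is the
session identity; the alternative reading (repetition number) does not
match the sampling design. The phase model is compared against an
intercept-only null — both models keep both random intercepts — by AIC,
with ties resolved to the first fit and recorded. The null fit can be
singular on homogeneous data; it is returned with a warning rather than an
error.

## Annotator agreement

Validation of manual labels uses two independent annotations of the same
recording. Segments are matched greedily by nearest onset within a 0.5 s
window (the source material does not state its matching rule; this one is
documented as our choice), each segment used at most once; unmatched
segments on either side count as disagreements. Agreement on a matched
pair requires identical vocal type *and* caller, and the accuracy is
$N_{\mathrm{agree}}/N_{\mathrm{all}}$. Timing bias is assessed with
one-sample Student-t intervals on the signed nearest-neighbour onset and
offset differences; exact distance ties resolve to the earlier neighbour,
and constant differences yield the degenerate zero-width interval.

## The simulator: what it emulates and what it does not

Because no recordings are distributed, a seeded event-driven simulator
stands in for them. Each bird calls independently as a renewal process
with log10-normal gaps and, in the F2F phase, answers its partner's call
offset with probability `response_prob` after a log10-normal latency.
Responses are suppressed inside the responder's refractory window, at most
one response is pending per bird, and a pending baseline call is
rescheduled (not cancelled) after any emission so marginal rates stay
interpretable. Latencies are log10-normal *on purpose*: the analysis fits
Gaussian mixtures on log10 intervals, so end-to-end parameter recovery is
a sharp test rather than an approximation.

Default calibration, chosen once:

* latency $10^{\mathcal{N}(-0.73,\ 0.15^2)}$ s (a ~0.19 s response mode),
  call duration 0.0247 s, refractory 0.05 s;
* self-interval $10^{\mathcal{N}(1.0,\ 0.6^2)}$ s, i.e. a mean gap of
  ~26 s and ~35 solo calls per 900 s phase, matching reported solo call
  output. (A log10 mean taken directly from the fitted *merged-track* long
  component would conflate two different quantities and produce roughly
  three times too many calls.)
* `response_prob = 1/3`, anchored to the reported ~1.5-fold increase of
  call output in the F2F phase: responding forms a branching process that
  multiplies baseline output by $1/(1-p)$.
* `baseline_rate`, when given, rescales the self-interval log10 mean so
  the expected gap is `1/rate` (0 disables baseline calling); the
  log10-normal shape is kept.

The full experiment design is 6 birds, all 15 pairs, 4 sessions per pair
(60 sessions), with the subject role alternating between pair members in
blocks of two sessions so that every ordered (subject, facing) pair occurs
at least twice — a requirement of the derangement null.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: solo calling is a plain renewal process, so the
simulated PRE/POST intervals are unimodal, whereas real solo calling is
bursty (real solo fits report a short component near $-0.75$); there is no
diel or motivational drift within a phase; caller identity is perfect by
construction; and only two-bird sessions are generated (no flock
scenarios). Response triggering from the partner's call *offset* rather
than onset is a documented modelling choice, not a biological claim — with
~25 ms calls the two are nearly indistinguishable.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds (`withr::with_seed`),
and the pipeline derives per-stage seeds from one root seed by fixed
offsets, so reports are byte-stable. The shipped analysis and tests use:
10,000 repetitions for every percentile interval (the Monte-Carlo SE of an
extreme percentile is then ~0.006 log10 s for the main comparison); 5,000
draws and 20 seeded replicates for mixture-recovery checks; 60-session
simulated experiments for end-to-end recovery; and 30 replicates for the
null-model AIC preference check. These sizes were chosen so each check's
Monte-Carlo error is several times smaller than the tolerance it asserts.

## Known limitations

* The two-component assumption is fixed; data with more than two interval
  regimes would be mis-decomposed silently.
* The percentile-interval comparison is conservative (see above); absence
  of significance is weak evidence of equality.
* The pseudo-pairing null requires at least two sessions per ordered pair
  and preserves subject/facing roles; designs without repeated sessions
  cannot use it.
* Counts from renewal processes with heavy-tailed gaps are overdispersed
  relative to Poisson; the GLMM's trial intercept absorbs much of this,
  but simulated-count coefficient recovery is correspondingly noisy.
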
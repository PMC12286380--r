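# callexchange

Temporal analysis of contact-call exchanges between paired songbirds.

Small estrildid finches (the motivating case is the Java sparrow,
*Padda oryzivora*) trade very short (~25 ms) contact calls. Given annotated
call-event tables — who called, when, in which phase of a paired-recording
session — this package asks whether the birds are genuinely *answering*
each other: whether call timing shows a characteristic short response
latency, over and above what two independently calling birds would produce.
It is aimed at bioacousticians and quantitative ethologists working with
annotation tables (CSV or Raven selection tables) rather than raw audio;
segmentation and caller identification are assumed done.

## The method

1. **Transitions.** Within each session phase, consecutive calls form
   transitions: *exchange* when the caller changes, *repeated* when it does
   not, each with the offset-to-onset interval
   *t* = onset₍ₖ₊₁₎ − offset₍ₖ₎ (negative ⇒ overlap).
2. **Mixture decomposition.** After excluding non-positive intervals, the
   log₁₀ intervals are fitted with a two-component Gaussian mixture
   *f(x) = wₛ N(μₛ, σₛ²) + wₗ N(μₗ, σₗ²)* by EM (unequal variances, fixed
   K = 2, multiple starts). The short component (μₛ ≈ −0.73, i.e.
   10^−0.73 ≈ 0.19 s) captures response-like transitions; the long one,
   independent calling.
3. **Percentile-interval comparison.** Two conditions' short components
   are compared by drawing one value from each fitted normal per
   repetition, 10,000 times, and reporting the 2.5th–97.5th percentiles of
   the differences with a contains-zero verdict.
4. **Pseudo-turn-taking null.** Each subject's face-to-face (F2F) track is
   re-paired with its partner's track from a *different* session of the
   same pair (seeded derangement). This conserves every bird's call times
   exactly while destroying temporal dependence; a genuine response mode
   must vanish under it.
5. **Call counts.** Per-phase subject call counts are modelled with a
   Poisson log-link GLMM (random intercepts for subject and trial), and
   the phase model is compared to an intercept-only null by AIC.
6. **Agreement.** Inter-annotator validation: greedy nearest-onset segment
   matching, joint type+caller accuracy, and one-sample t intervals on
   onset/offset time differences.

A seeded event-driven simulator (`simulate_experiment()`) generates
two-bird sessions with exactly this latent structure — baseline renewal
calling plus probabilistic responses at log10-normal latencies — so every
stage is testable end to end without recordings.

## Worked example

The `analysis/` directory holds the numbered pipeline
(`01_simulate.R` … `06_phase_counts.R`); run them in order from the
repository root. Stage 1 simulates the full design (6 birds, 15 pairs, 4
sessions each, three 900 s phases per session; root seed 1234) and the
later stages analyse it. Selected output from the shipped run:

```
F2F transitions: 7945 (4988 exchange, 2957 repeated)
overlapping exchange interactions: 13 (0.26%)
fraction of F2F intervals within 10 s: 0.807

exchange short component: -0.739 log10 s (0.182 s), weight 0.52
short-latency mass (< 0.5 s) of the exchange fit: 0.55

95th percentile range: [-0.569, 0.667]; contains zero: yes; order: exchange - repeated

pseudo transitions: 2878 exchange, 5067 repeated (14 overlaps)
short-latency exchange mass (< 0.5 s): 0.55 original vs 0.10 pseudo (82% drop)

mean calls per phase (subject birds):
 F2F POST  PRE
65.8 34.7 37.3
selected model: phase   (AIC 1617.0 vs null 2350.4)
```

Reading it: the exchange-interval mixture recovers the generating 0.19 s
response latency (−0.739 log10 s); exchange and repeated short components
do not differ (interval contains zero); re-pairing sessions destroys the
short-latency mass (0.55 → 0.10), identifying it as genuine responding;
and birds call more when a partner is present (phase model wins by
ΔAIC ≈ 733). Equivalent programmatic access:
`run_full_analysis(pipeline_config(seed = 1234))`.

The same readers handle real annotation tables: `read_call_table(path,
dialect = "csv")` for the native format or `dialect = "raven"` for Raven
selection tables (with a channel-to-bird `caller_map`).

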
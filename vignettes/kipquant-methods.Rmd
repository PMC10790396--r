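---
title: "Models and methods behind kipquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kipquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kipquant)
```

# Scope

kipquant implements the computational workflow of a kinase inhibitor
pulldown (KiP) targeted-proteomics assay: kinases are enriched from native
lysate on inhibitor-conjugated beads, digested, and quantified by parallel
reaction monitoring (PRM) — targeted MS2 acquisition where each peptide's
abundance is the summed chromatographic area of its fragment-ion
("transition") traces. Around that core the package provides the rules
engine used to design the PRM peptide panel, a simulator of
internal-standard-triggered (IS-PRM / SureQuant-style) acquisition, the
enrichment-characterization metrics (dilution linearity, serial depletion),
and the downstream subtype statistics (per-gene t-tests with
Benjamini–Hochberg correction, clustering, cross-platform correlation).
Everything operates on synthetic data with planted ground truth; the
generators are first-class, seeded and tested.

# Transition-level quantification

A transition trace is an intensity series over retention time for one
fragment ion of one peptide in one sample. Quantification proceeds in four
deterministic steps, replacing the manual chromatogram curation of
interactive tools:

1. **Boundary detection.** The transitions of a peptide are summed on their
   common time grid and lightly smoothed (3-point moving average). The
   integration boundary is the contiguous region around the apex where the
   smoothed signal stays at or above 5% of the apex. For a Gaussian peak of
   width $\sigma$ this gives a boundary width of
   $2\sigma\sqrt{2\ln 20} \approx 4.90\,\sigma$.
2. **Integration.** Each transition is integrated by the trapezoid rule.
   Because a hard 5% cut leaves ~1.4% of a Gaussian's area in the tails, the
   integration range is the detected boundary padded by 0.35× its width on
   each side (clipped to the scheduled window), which recovers the analytic
   area essentially completely while the detected boundary itself still
   marks the peak extent for interference decisions.
3. **Concordance filtering.** A transition is excluded when its in-boundary
   shape correlates with the reference trace below 0.8 (Pearson), or when
   its apex sits more than 2 sampling intervals from the group apex. The
   precursor trace is the reference when present; otherwise the pointwise
   median transition trace. Exclusions carry machine-readable reasons.
4. **Top-6 summation.** Up to the six largest remaining areas (ties broken
   by fragment label for determinism) are summed into the peptide area;
   protein (gene) abundance is the sum of its peptides' areas. A gene with
   no detected peptide is *missing*, never zero.

Matrices are median-normalized per sample to the global median of sample
medians — a scale-preserving choice, since no normalization target is
canonical — and log2-transformed. iBAQ values divide linear intensity by
the count of theoretical fully-tryptic peptides of length 7–30 (cleavage
after K/R except before P, zero missed cleavages); those bounds are the
common observability convention and are configurable.

All thresholds above (5% boundary fraction, 0.35 padding, 0.8 concordance,
2-interval apex shift, top-6) are exposed as arguments.

# Panel design rules

Candidate peptides per gene are judged on archived spectral evidence.
Exclusion rules, applied in a fixed order with accumulating reasons so the
outcome is order-independent: ion score < 20; more than 10% of PSMs
modified; any tryptic missed cleavage; being a subpeptide of a frequently
miscleaved form; sequence shared across gene products. Mouse-conserved
peptides (xenograft stroma background) and peptides not covering all
isoforms are *deprioritized*: ranked behind every clean candidate and
admitted only when clean candidates do not fill the shortlist (upper bound
6). Shortlisted candidates are then evaluated on dilution response curves:

* **linearity** — $R^2$ of a zero-intercept fit of area against input
  $\geq 0.95$, computed against the mean-centered total sum of squares so a
  saturating curve scores visibly below a proportional one;
* **symmetry** — left/right half-area ratio at the apex within [0.67, 1.5];
* **interference** — no local maximum outside the boundary exceeding 20% of
  the apex.

The numeric cut-offs quantify qualitative acceptance language ("narrow,
approximately symmetrical, proportional, no non-specific peaks") and are
documented defaults rather than measured constants. Passing peptides are
ranked by $R^2$ then PSM count and at most four per gene enter the final
panel; genes with no passing peptide are reported in a shortfall table.

# IS-PRM acquisition model

The simulator replays the acquisition logic as an event loop over
time-ordered survey scans, deliberately ignoring instrument physics (AGC,
injection time, cycle-time contention): precursors matching an inclusion
entry within 3 ppm and reaching 1×10^5 intensity are isolated (at most 70
per scan, by intensity); the heavy standard's MS2 is pseudo-spectrally
matched against its listed product ions at 10 ppm; when ≥ 4 listed ions are
found, a light MS2 is acquired at the heavy m/z plus the label mass offset,
and the endogenous quantity is the summed intensity of listed product ions
found there. The heavy→light offset defaults to SILAC-style labels
(−8.014199 Da for K, −10.008269 Da for R, divided by charge); the precursor
tolerance is printed instrument practice while the product-ion tolerance
and the label chemistry are configurable defaults, since neither is
universal. Light quantities are normalized to the run's total ion current
and rescaled by the mean TIC so magnitudes stay comparable; this makes
normalized values invariant in *ratio* (not absolute value) under joint
rescaling of signal and TIC, which is the property that matters for
relative quantification and the one the tests assert.

Decoy precursors in generated streams emit at most 3 listed product ions by
construction (their filler ions are rejection-sampled at least 50 ppm away
from every listed mass), so any decoy trigger is a logic error, not bad
luck; the acquisition log records every decision with its precursor id to
make the no-light-scan-without-trigger invariant auditable.

# Synthetic study conditions

The generators' defaults are the study conditions; they are set once, from
the experiment they emulate, and are not tuned against test outcomes.

* **Chromatograms** — Gaussian peaks (σ = 0.05 min) on a 0.01-min grid in a
  4-min scheduled window, areas lognormal around 10^5, additive Gaussian
  noise clamped at zero, optional interference peaks and heavy twins. In
  the noiseless limit trapezoidal recovery of planted areas is exact to
  closed form.
* **Dilution series** — linear genes scale areas proportionally to input
  over 12.5–200 µg; saturating genes follow area ∝ input/(input + K) with
  K = 25 µg, emulating bead saturation of highly abundant kinases.
* **Serial depletion** — a constant per-round binding fraction f = 0.7:
  round-k capture of a kinase of abundance A is A·f·(1−f)^k. This geometric
  model is the simplest consistent with round-wise recovery percentages
  (abundance falls to 30% after one depletion, 9% after two). Kinase
  abundances are lognormal with sdlog = 1.9045 and the detection floor sits
  at exp(meanlog − 2.9507): this is the unique spread/floor pair under
  which identification falls to exactly 84% and 59% of the round-0 count
  after one and two depletions — the decay characteristic of kinobead
  depletion experiments — and 330 kinases give a round-0 identified count
  near 300. The pair was obtained by solving the two-equation lognormal
  tail system analytically, not by adjusting to simulation output.
* **Cohorts** — two subtypes (basal/luminal, ≥ 2 samples each; default
  8 + 8), lognormal base abundances (sdlog = 1), planted differential genes
  shifted by ±log2-effect/2 per subtype mean, multiplicative lognormal
  technical noise at CV 10% in technical duplicates, optional MCAR
  missingness. The direction split of planted genes defaults to half/half
  and is settable (`n_up_basal`) so a cohort can emulate an observed
  asymmetric split.
* **IS-PRM streams** — one survey appearance per target at its elution
  apex with optional ppm jitter; light signal exists only for targets
  declared endogenous.

What the generators do **not** emulate: retention-time drift between runs,
correlated (non-i.i.d.) noise, isotope envelopes, peptide-specific
digestion/ionization efficiency, informative missingness, and biological
within-subtype heterogeneity beyond the planted effects. Passing recovery
tests therefore demonstrates the correctness of the computations under the
stated model, not the assay's performance on real tissue.

# Statistical choices

Differential testing is a per-gene two-sided two-sample t-test on
replicate-averaged log2 values — pooled-variance Student's t for the
PDX-style contrast, Welch's t as the option for heteroscedastic patient
cohorts — after dropping genes observed in fewer than 10 biological
samples. Raw p-values at α = 0.05 drive the reported discovery counts
(matching discovery-count convention), with Benjamini–Hochberg adjusted
p-values reported alongside; the BH implementation is `stats::p.adjust`,
checked in the tests against a brute-force step-up oracle. Genes testable
in no configuration are reported untested rather than erroring; a gene
constant and equal in both groups is guarded to t = 0, p = 1. Direction
labels are forced to match the sign of the group-mean difference.

Clustering uses 1 − Pearson correlation distance with average linkage
(hierarchical) or k-means on per-gene z-scores with 25 restarts and a fixed
seed; linkage and distance are conventions, not derived quantities, and are
configurable. Missing values are imputed to the per-gene minimum for
distance computation only. `k` equal to the sample count returns the
trivial partition directly. Cross-platform agreement is the median
per-gene Pearson correlation over genes with at least 3 complete sample
pairs. Phosphosite matrices roll up to genes by the mean over non-missing
sites; RNA TPM matrices are transformed to per-gene log2 median ratios
(row medians exactly zero by construction).

For recovery experiments on generated cohorts the linear matrix is
log2-transformed directly without median normalization: the generator
plants no loading differences, and forcing sample medians equal when
planted effects are asymmetric would itself induce spurious group shifts in
null genes. Median normalization remains the default for data arriving as
real transition reports, where loading does vary.

# Problem sizes and determinism

The test and acceptance workloads use 91–100 kinases × 16 samples in
duplicate, 50 recovery and 200 null cohort replicates, 20 clustering
seeds, 25–50 acquisition replays, and 1,000 random p-vectors for the BH
oracle — sizes at which every Monte-Carlo margin in the assertions is wide
relative to its standard error. Every stochastic step is seeded and every
generator restores the RNG state it found, so identical specs yield
bit-identical data regardless of call order.

# Known limitations

* Protein rollup is a plain sum of peptide areas; alternatives (top-n
  peptides, median polish) are not implemented, and whether a different
  combination is preferable on real data is untested here.
* The boundary detector assumes a single dominant elution peak per
  scheduled window; co-eluting isobaric interference *inside* the boundary
  is only handled indirectly through the concordance filter.
* The IS-PRM simulator's one-appearance-per-elution abstraction cannot
  express trigger contention between co-eluting targets.
* The depletion model's constant binding fraction ignores
  competition/affinity differences between kinases; it reproduces
  round-level aggregates, not per-kinase kinetics.
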
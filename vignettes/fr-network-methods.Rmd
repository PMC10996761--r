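---
title: "Fast-ripple network metrics and virtual resection simulation: methods"
author: "frnetsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast-ripple network metrics and virtual resection simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frnetsim)
```

## The problem

In medication-resistant focal epilepsy, surgery aims to remove the
cortical tissue responsible for seizure generation with as small a
resection as possible. The clinical standard of care delineates the
seizure onset zone (SOZ) electroclinically, but resecting the SOZ does
not reliably produce seizure freedom. Interictal fast ripples (FR;
high-frequency oscillations at 200–600 Hz recorded on stereo-EEG
contacts) mark pathological tissue, and the *spatial and temporal
organization* of FR-generating sites — not just the fraction of FR
resected — carries information about which sites must be removed.

`frnetsim` implements that analysis as a pipeline: four FR-derived
factors computed against a (real or simulated) resection, a support
vector machine (SVM) labelling post-operative seizure freedom from
those factors, an iterative virtual-resection simulator that targets
*autonomous, high-rate* FR sites, and a virtual placement simulator for
responsive-neurostimulation (RNS) leads. A coupled point-process
generator produces synthetic patients with known ground truth for every
stage.

## Event families and rates

Detected events come in four categories: fast ripples on oscillations
(fRonO) or on epileptiform spikes (fRonS), and ripples (80–200 Hz) on
oscillations (RonO) or spikes (RonS). The family driving all network
metrics, written FR>350 Hz, is **fRonO with peak frequency above
350 Hz together with all fRonS**. Per-contact rates are event counts
divided by the recording duration (events/min); recordings are 10–60
minutes of artifact-free non-REM sleep.

The **resection ratio** (RR) of an event family is the number of events
on resected contacts over the number of events everywhere; the SOZ RR
is the analogous *contact-count* ratio. Ratios with an empty
denominator are flagged `NA` (see `metric_flag()`), never silently 0.

## The four FR factors

Given a resected contact set, `feature_vector()` computes:

1. **FR RR** — the FR>350 Hz event resection ratio.
2. **Spatial FRnet** — build the complete graph on all FR>350 Hz
   generating contacts with edge weights
   *mean(rate_i, rate_j) × Euclidean distance (mm)*; its *radius* is
   the minimum over nodes of the maximal shortest-path distance, with
   weights used directly as path lengths. The factor is
   `sqrt(max(0, R_whole − R_resected))`, the square root of the radius
   drop when only resected FR nodes remain. It is exactly 0 when the
   resection contains every FR-generating node. The difference is
   clamped at zero before the square root: a resected subset can in
   principle have a larger radius than the whole graph (shortcuts
   through removed nodes are lost), and the full-resection anchor
   requires the whole-minus-resected orientation.
3. **Temporal FRnet-A** — on the FR mutual-information (MI) graph, the
   characteristic path length of the subgraph induced on resected
   nodes divided by that of the whole network. Path lengths are
   reciprocal MI; pairs with no finite path are excluded from the mean
   (their count is reported), which keeps the ratio finite on sparse
   graphs.
4. **Temporal FRnet-B** — the mean nodal local efficiency over nodes
   with positive efficiency. The evaluated set defaults to the
   *unresected* nodes (`fr_options(frnetB_scope = ...)` switches to
   all nodes): the factor should respond to what a virtual resection
   leaves behind, and when everything is resected the degenerate
   convention returns 1.0 with a flag — the value the full-resection
   anchor requires.

## The FR mutual-information network

Nodes are contacts generating at least one FR>350 Hz event; the edge
weight between two nodes is the mutual information (bits) between
their event-onset-time trains; edge *lengths* are reciprocal MI, with
MI = 0 meaning no edge. Patients with fewer than two FR-generating
contacts yield a degenerate graph and are excluded from cohort
analyses; a patient with no contact generating fRonS above 1/min is
flagged as having poor spatial sampling.

### MI estimation between event trains

Estimating MI between two sparse point processes from a 30-minute
recording is the pipeline's hardest numerical problem. The default
estimator reduces the pair to its joint inter-event structure: at
every event time of either train we record the elapsed time since the
previous event of train *a* and of train *b* (two "interval clocks"),
then estimate the MI of that 2-D sample by Darbellay–Vajda adaptive
partitioning in rank space. When the trains are coupled the two clocks
reset together and the sample concentrates along the diagonal; for
independent Poisson trains both clocks are independent exponentials,
and the estimator returns exactly zero for most independent pairs
(the partition never splits). Two numerical choices matter:

* cells are split at the marginal medians while a chi-square test on
  the four quadrant counts rejects local independence (critical value
  7.815, i.e. 5% on 3 df; cells below 8 points are terminal);
* the median 2×2 test is structurally blind to dependence symmetric
  about the medians — a coupled pair produces a diagonal *plus* two
  off-diagonal arms (an X shape) that balances the quadrants — so each
  cell with at least 16 points is additionally tested for uniformity
  on a 4×4 quartile grid (critical value 16.919, 5% on 9 df).

An earlier design represented each train by its inter-event intervals
paired with the latency to the nearest event of the other train; it
was abandoned because the coupling signal sits almost entirely in the
latency *marginal* — jittered copies make latencies small regardless
of the interval — so a partition estimator, which measures joint
dependence only, cannot see it.

A binned alternative (`fr_options(mi_estimator = "binned")`) computes
plug-in MI between fixed-width (default 1 s) event counts with the
Miller–Madow correction. It is more sensitive for very sparse trains
but never returns exact zeros. Both estimators are exactly symmetric
and both pass the same property tests: mean MI below 0.05 bits across
independent Poisson pairs (2/min, 60 min), and permutation p < 0.01
(interval-shuffled surrogates, `mi_permutation_test()`) for trains
copied with probability 0.8 and 20 ms jitter.

### Efficiency conventions

Nodal **local efficiency** follows the Brain Connectivity Toolbox
convention: the efficiency of the subgraph induced on a node's
neighbours, computed on adjacency normalized by its global maximum, so
a complete equal-weight graph scores 1 at every node and nodes with
fewer than two neighbours score 0. **Global efficiency** (the mean
inverse shortest-path length, used for the RNS stimulated subnetwork)
is computed on *raw* reciprocal-MI lengths by default, so a direct
edge contributes its MI in bits and values are comparable across
patients; a `normalize` switch provides the max-normalized variant.
The two defaults differ deliberately: normalization is what makes
local efficiency a bounded within-graph quantity, while the stimulated
global efficiency is compared across stimulation sites and patients.

## The outcome SVM

`fr_svm()` z-scores the four factors on the training rows and fits a
radial-basis-function SVM with penalty C = 1 and kernel coefficient
γ = 1/(number of factors) = 0.25 (an `"auto"` option uses the median
pairwise-distance heuristic instead). Flagged factor components —
degenerate subgraphs arise routinely in early virtual-resection
iterations — are imputed with the training mean of that feature, a
deterministic, neutral (z-score 0) contribution. Predictions come from
the stored support vectors, so a model serialized to JSON
(`write_fr_svm()`) reloads bit-identically; a decision value of
exactly 0 is classified non-seizure-free so a boundary tie never stops
a growing virtual resection. `loocv_accuracy()` refits normalization
and model in every leave-one-out fold; degenerate folds fall back to
the majority training label with a warning.

## The virtual resection

Candidates are contacts with FR>350 Hz rate above 1/min ordered by
ascending local efficiency — most *autonomous* first, autonomy meaning
high-rate FR generation with little temporal coupling to other sites —
with ties broken toward higher rate, then contact id; remaining
FR-generating contacts follow by descending rate. The first candidate
fixes the sphere centre (radius 10 mm); each later iteration admits
the next candidate outside the current sphere and grows the radius to
its centre distance plus a 10 mm buffer, never shrinking, so resected
sets are nested. Membership is a closed ball, and contacts
contralateral to the centre are never resected (candidates in the
opposite hemisphere can therefore never enter the set and are
skipped). After every change of the resected set the four factors,
SOZ RR and RonS RR are recomputed and the SVM queried. The simulation
stops at the first seizure-free label, when the resected set spans
three distinct lobes (checked *before* the SVM query, so a three-lobe
resection is always designated non-seizure-free), or when candidates
run out. Unsampled space contributes nothing to any metric.

`overlap_contingency()` compares virtual and actual resections over
the patient's full contact set (TP/FP/TN/FN with sensitivity,
specificity, PPV, NPV, accuracy, F1, `percent_r` = sensitivity, and
`novel_r`, the fraction of the virtual set outside the actual cavity).

## RNS metrics and virtual placement

The stimulated contact set is every SEEG contact strictly within
15 mm of any of the eight RNS contacts (two leads of four), matching
the extent of a monopolar 1–3 mA stimulation field. `rns_metrics()`
reports the SOZ stimulation ratio (contact counts), the FR stimulation
ratio (FR>350 Hz event counts — the ratio reading of the stimulation
analogue, mirroring the resection definitions), and the stimulated
global efficiency of the MI subgraph on the stimulated contacts plus
their first-degree MI neighbours. Virtual placement
(`virtual_placement()`) centres a four-contact contiguous window on
the highest-rate FR contact's shaft (clipped at shaft ends, padded
from the nearest shaft when a shaft is shorter than four contacts),
with the second lead in the opposite hemisphere for bilateral
implants or on a different shaft otherwise.

## Cohort statistics

Kruskal–Wallis (tie-corrected, via the standard R implementation
behind a degenerate-input guard) compares metric distributions across
outcome groups. The Wilcoxon signed-rank test is *exact*: the
two-sided p comes from enumerating all 2^n sign assignments (zero
differences dropped, average ranks for ties; convolution on doubled
ranks), with a tie-corrected normal approximation above n = 15.
Autonomy clustering runs k-means (k = 2, 25 restarts under a fixed
seed) on the z-scored plane of log FR rate versus local efficiency;
the autonomous cluster is the one with the lowest mean local
efficiency, ties resolved toward the higher-rate cluster — the
relevant degenerate case is an edgeless MI graph where every node has
zero efficiency. The natural log is used for the rate axis; since both
axes are z-scored the base only rescales and cannot change the
partition. Trial power uses the closed-form two-sided unpooled-variance
two-proportion Z-test, and `enrollment_inflation()` divides by one
minus the dropout fraction, rounding up.

## The synthetic-data generator

`generate_patient()` draws 8–16 linear shafts of 7–15 contacts at 5 mm
spacing entering laterally into an MNI-sized bounding box; lobes come
from a fixed geometric partition of the coordinate space (the pipeline
needs only categorical labels for the three-lobe rule) and hemispheres
from the x sign. The planted structure is:

* an **autonomous core** (3–6 contacts clustered around a seed
  contact) emitting independent Poisson FR>350 Hz trains at 2–10/min —
  high rate, near-zero MI, low local efficiency;
* a **halo** (6–12 next-nearest contacts) whose trains are thinned
  (copy probability 0.7), 20 ms-jittered copies of shared latent
  trains. Each latent group shares one target rate drawn from
  0.2–1/min so that every member copies at the full 0.7 and pairwise
  co-occurrence stays at 0.49 of the latent events — the construction
  that makes halo MI high. Event coupling is by latent-train thinning
  rather than rate co-modulation because it produces onset-time MI of
  exactly the kind the estimator targets;
* background RonS/RonO ripples everywhere, and FR events split
  60/40 between fRonO (355–595 Hz) and fRonS.

The actual resection is a 20–30 mm sphere at the core centroid; for a
non-displaced resection the radius additionally covers the core's
spatial extent plus a 5 mm surgical margin (a resection aimed at the
focus encompasses it), while "failed" resections displace the centre
by 20–40 mm. The ground-truth rule is sharp: seizure free iff every
core contact is resected (a label-flip option, default 0, can inject
noise). `generate_cohort()` displaces exactly half the cohort, giving
roughly balanced outcomes at n = 18.

What the generator does *not* emulate: realistic cortical geometry or
atlas anatomy, FR waveforms (only onset times), rate nonstationarity
across the night, detector false positives/negatives, and any
dependence between the SOZ and ripple (as opposed to FR) activity.
Passing tests on synthetic cohorts therefore demonstrate the
pipeline's internal consistency — planted structure is recovered, the
classifier separates the planted outcome rule, virtual resections find
the planted core — not clinical validity on real recordings.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full pipeline on a
fixed-seed 18-patient synthetic reference cohort (the size of the
original clinical training cohort), a scale at which the whole
analysis — cohort generation, all pairwise MI graphs, leave-one-out
SVM training and 18 virtual resections — completes in well under a
minute. Monte-Carlo property checks use 30–100 replicates each. All
randomness flows through explicit seeds (`withr::with_seed`
internally), so every result in the tests, the README example and the
acceptance output is bit-reproducible.

## Known limitations

* MI between trains below roughly 0.4 events/min over 30 minutes is
  physically undetectable (a handful of events); the sparsest halo
  pairs therefore legitimately carry zero estimated MI, and local
  efficiency underestimates coupling at the lowest rates.
* The virtual resection inherits the spherical-cavity simplification;
  real cavities are not spheres, and the sphere tends to over-include
  contacts (the published comparison shows the same).
* With one candidate ordering and a deterministic stopping rule, the
  simulator explores a single resection trajectory per patient rather
  than the full combinatorial space.
* The exact signed-rank enumeration is limited to n ≤ 15 (2^n states);
  beyond that a tie-corrected normal approximation takes over.
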
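# frnetsim

Fast-ripple network metrics, virtual resection and RNS placement
simulation for epilepsy surgery planning.

## What problem this solves

In medication-resistant focal epilepsy, surgery succeeds when the
tissue that generates seizures is removed — but the electroclinically
defined seizure onset zone (SOZ) is an imperfect target, and a fixed
"resect X% of fast ripples" rule neither says *which* fast-ripple (FR)
sites matter nor survives spatial sampling limits. This package
implements a network view of interictal fast ripples (200–600 Hz
events on stereo-EEG contacts) for researchers working on quantitative
surgical planning: the sites that matter are the *autonomous,
high-rate* FR generators — contacts producing FR at high rate with low
mutual information (MI) with the rest of the FR network.

From a detected-event catalog, contact geometry and a resection
boundary, the package computes four factors:

- **FR RR** — resection ratio of FR>350 Hz events (fRonO > 350 Hz plus
  all fRonS): resected-contact events / all events;
- **spatial FRnet** — `sqrt(max(0, R_whole − R_resected))`, the drop in
  the radius of the complete rate–distance graph (edge weight =
  mean(rate_i, rate_j) × distance in mm) when only resected FR nodes
  remain;
- **temporal FRnet-A** — characteristic path length of the resected
  subgraph of the FR MI network over that of the whole network
  (lengths = 1/MI);
- **temporal FRnet-B** — mean nodal local efficiency (> 0) over
  unresected nodes.

An RBF-kernel SVM (C = 1, γ = 1/4, z-scored features) trained on these
factors labels post-operative seizure freedom; an iterative simulator
grows a spherical virtual resection over the most autonomous candidates
(ascending local efficiency, 10 mm initial radius and buffer, stopping
on a seizure-free label or at three lobes); and an RNS module computes
stimulation ratios and stimulated global efficiency for actual and
virtual (highest-FR-rate) lead placements. A coupled point-process
generator produces synthetic cohorts with ground truth for every stage.
See `vignettes/fr-network-methods.Rmd` for the full methods account.

## Worked example

Generate a synthetic 18-patient cohort, train the outcome SVM on the
actual resections, and run a virtual resection for a patient whose
actual surgery missed the planted epileptogenic core:

```r
library(frnetsim)

cohort <- generate_cohort(synth_config(), seed = 42)
cf     <- cohort_features(cohort)          # four factors + outcome labels
model  <- fr_svm(cf$features, cf$labels)
model
#> FR outcome SVM (RBF kernel)
#>   gamma = 0.25, C = 1, 12 support vectors, 18 training patients (9 seizure free)
loocv_accuracy(cf$features, cf$labels)
#> [1] 0.8888889

p <- cohort[[2]]$patient                   # displaced resection, Engel IVB
tr <- run_virtual_resection(p, model, graph = cf$graphs[[2]], rates = cf$rates[[2]])
round(as.data.frame(tr), 3)
#>   iteration radius_mm n_resected soz_rr rons_rr fr_rr spatial_frnet temporal_frnet_a temporal_frnet_b svm_label n_lobes
#> 1         1    10.000          1    0.2   0.017 0.354         9.834               NA                1         0       1
#> 2         2    50.866          7    1.0   0.090 0.921         0.000                1                1         1       1
tr$status
#> [1] "seizure_free"
```

Reading the trace: iteration 1 resects only the most autonomous contact
(FR RR 0.354, large spatial FRnet 9.8 — much of the rate–distance
network remains) and the SVM labels it non-seizure-free. Growing the
sphere to the next candidate (radius 50.9 mm, 7 contacts) captures the
whole planted core: FR RR rises to 0.92, spatial FRnet collapses to 0,
SOZ RR reaches 1.0, and the SVM predicts virtual seizure freedom —
for a patient whose *actual* resection had failed.

Comparing the virtual and actual resected sets:

```r
actual <- p$contacts$contact_id[p$contacts$is_resected]
overlap_contingency(tr$final_resected, actual, p$contacts$contact_id)
#> contingency: TP 2 FP 5 TN 93 FN 1
#>   sensitivity 0.667 specificity 0.949 ppv 0.286 npv 0.989
#>   accuracy 0.941 f1 0.400 percent_r 0.667 novel_r 0.714
```

Desk-scale statistics against the published study cohort shipped in
`inst/extdata` (see `?reference_cohort`):

```r
sz <- reference_cohort("resection_szfree")
wilcoxon_signrank_exact(sz$radius_virtual_mm, sz$radius_actual_mm)$p
#> [1] 0.0390625            # virtual resections are larger, p = 0.04 (n = 9)
two_proportion_power(0.60, 0.75, 150)
#> [1] 0.802281             # 80% power at 150 patients/arm
```

## Command-line interface

A thin wrapper over the package functions is installed at
`inst/cli/frnetsim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/frnetsim.R", package="frnetsim"))')" \
    synth --config config.yaml --seed 7
```

with subcommands `metrics`, `train`, `resect-sim`, `rns-sim`, `synth`,
all taking `--config <yaml>` and `--seed <int>`. On-disk formats are
plain text: contacts TSV, events CSV, metadata JSON (`?load_patient`).
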
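# fatiguenet

Frequency-banded functional brain-network analysis of mental fatigue
from fNIRS hemoglobin signals.

## The problem

Mental fatigue reorganises cortical functional connectivity, and the
reorganisation differs across the slow oscillation bands of the
hemodynamic signal. Given multichannel fNIRS recordings of oxy-, deoxy-
and total hemoglobin (HbO/HbR/HbT), `fatiguenet` quantifies that
reorganisation and uses it to classify fatigue states. It is written for
researchers analysing optical neuroimaging time series who need a
tested, reproducible pipeline from raw channel matrices to group
statistics and classification — plus a synthetic-data generator so the
entire pipeline can be exercised and validated without access to any
recordings.

## The method

1. **Band decomposition.** Each channel is filtered into five bands
   (I: 0.005–0.021, II: 0.021–0.052, III: 0.052–0.145, IV: 0.145–0.600,
   V: 0.6–2.0 Hz — endogenic to cardiac) with a zero-phase Chebyshev
   Type I band-pass, realised as second-order sections so the very
   narrow low bands stay numerically stable at 16 Hz sampling.
2. **Entropy-weighted ROI fusion.** 24 channels map onto 8 regions of
   interest (left/medial/right prefrontal cortex, frontal eye fields,
   supplementary motor area, premotor cortex). Within each ROI, channels
   are combined as `y = Σ_j X_ij ω_j` with information-entropy weights:
   channels with lower normalised Shannon entropy (more structure) count
   more.
3. **Connectivity networks.** Pearson correlations between ROI series
   give an 8×8 weighted network per (species, band). Graph metrics on
   `w = |r|`: the geometric-mean weighted clustering coefficient

   `C_u = 1/(deg(u)(deg(u)−1)) Σ_vw (ŵ_uv ŵ_uw ŵ_vw)^{1/3}`,  `ŵ = w/max(w)`,

   characteristic path length `L = mean over pairs of Dijkstra
   shortest-path lengths` with edge length `1/w`, and small-worldness
   `σ = γ/λ`, `γ = C/C_random`, `λ = L/L_random` against 100 matched
   random networks (Maslov–Sneppen degree-preserving rewiring + weight
   permutation). Networks are thresholded at sparsity 0.45 (exactly 13
   of 28 edges) for both the unweighted and the weighted small-world
   analysis.
4. **Fatigue labelling.** Session MFI-20 mean item scores are split into
   non-fatigue/fatigue by 1-D k-means; a scan over thresholds (step
   0.01, up to 5.00) then separates moderate from severe fatigue at the
   point maximising the Welch-test contrast in n-back behavioural scores
   (reaction time / accuracy).
5. **Group statistics.** Two-way ANOVA (fatigue level × task) with Type
   III sums of squares and partial η², and Tukey–Kramer post-hoc
   comparisons, per band and per connectivity pair / network metric.
6. **Classification.** A 2,250-dimensional feature vector per session
   (420 ROI-pair correlations + 30 network metrics + 1,800 time-domain
   features) feeds a random forest with Gini-importance feature
   selection and genetic-algorithm hyperparameter tuning, nested inside
   stratified fivefold cross-validation.

The methods vignette (`vignettes/fatiguenet-methods.Rmd`) documents the
models, parameter defaults, numerical choices and limitations.

## Worked example

```r
library(fatiguenet)

# a synthetic study: 12 sessions per (task x fatigue level) cell,
# 600 s at 16 Hz, modular inter-ROI coupling with level effects
design <- study_design(seed = 20250901)
sessions <- generate_study(design, species = "HbO")

# one session through the pipeline
series <- roi_aggregate(sessions[["PVT-L1-01"]]$recordings$HbO)  # 5 bands
net <- fc_matrix(series$III)
small_worldness(net$w, n_random = 100, seed = 1)
#> weighted network metrics: C 0.8457  L 1.6457  gamma 2.601  lambda 0.626  sigma 4.157 (100 nulls)

# fatigue labelling from MFI-20 + n-back scores
lab <- label_fatigue(sessions, seed = derive_seed(20250901, "label"))
lab$threshold_nonfatigue   # 2.55  (k-means non-fatigue | fatigue split)
lab$threshold_severe       # 3.03  (scan: moderate | severe split)
mean(lab$scores$level == lab$scores$true_level)   # 0.944
```

The labelling thresholds recovered on the synthetic cohort (2.55 / 3.03)
sit where the generator put them: the dominant MFI gap separates
non-fatigue from fatigue, and the scan finds the moderate/severe
boundary from the behavioural contrast alone.

The numbered scripts under `analysis/` run the full workflow and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # study tables: MFI, n-back
Rscript analysis/02_preprocess.R  # band ROI series, entropy weights
Rscript analysis/03_network.R     # connectivity + graph metrics + sigma
Rscript analysis/04_features.R    # 108 x 2,250 feature table
Rscript analysis/05_label.R       # fatigue levels + threshold scan
Rscript analysis/06_stats.R       # two-way ANOVA + Tukey-Kramer
Rscript analysis/07_classify.R    # nested-CV random-forest reports
```

On the default synthetic study these scripts print, among other things:
per-band mean weighted σ of 1.40 / 1.32 / 2.29 / 4.19 / 4.22 (bands
I–V, all above 1); a band-II right-minus-left connectivity difference of
+0.134 (paired p < 0.001) in moderate fatigue only; a band-III
clustering-coefficient level effect of F = 5.12, p = 0.008, partial
η² = 0.094 with the Tukey–Kramer L1-vs-L2 decrease at p = 0.005; and
nested-CV classification of 93.5% accuracy (recall 97.2%, F1 95.2%) for
non-fatigue vs fatigue and 91.7% (recall 85.7%) for moderate vs severe —
the synthetic analogues of the fatigue signatures the pipeline is
designed to detect.

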
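# eigenmarkers

Distributed eigenmode markers of arousal from parcellated resting-state fMRI
and a weighted structural connectome.

## What it computes, and for whom

When consciousness is lost under anaesthesia — and when behavioural arousal
is restored by deep brain stimulation of the central thalamus — whole-cortex
patterns of brain activity reorganise in characteristic ways. This package is
for researchers in network neuroscience who want to quantify that
reorganisation per scan, at the level of distributed patterns rather than
individual regions, and relate it to behaviour. It provides three marker
families plus the statistics that tie them to a behavioural arousal score:

* **Harmonic-mode energy.** The structural connectome's symmetric normalised
  graph Laplacian `Δ_G = D^{-1/2}(D − C)D^{-1/2}` supplies an orthonormal
  basis of harmonic modes `φ_k` (eigenvalues `0 = λ_1 < λ_2 ≤ … ≤ λ_N`,
  ordered by spatial frequency). Each BOLD timepoint is decomposed exactly as
  `F_t = Σ_k ω_k(t) φ_k`; the energy of mode k is `ω_k(t)² λ_k²`, and the
  scan-level marker is the energy summed over modes, averaged over
  timepoints. Higher energy = activity more dominated by fine-grained,
  structure-divergent patterns.
* **Functional gradients.** Pearson FC is Fisher-z transformed, row-wise
  thresholded (default 10% density), converted to a normalised-angle
  affinity, and embedded by diffusion maps (`α = 0.5`, `λ/(1−λ)` scaling).
  Markers: the range of the principal (and second) gradient, the dispersion
  of the first three gradients, and the principal eigenvalue ratio.
* **Hierarchical integration / segregation.** From `FC = U Λ Uᵀ`, the nested
  sign partition recursively splits modules by the signs of successive
  eigenvectors; with module counts `M_i` and size correction
  `p_i = Σ_j |m_j − N/M_i| / N`, integration is `H_In = Λ_1²/N²` and
  segregation `H_Se = Σ_{i≥2} Λ_i² M_i (1 − p_i) / N²`.
* **Brain–behaviour statistics.** A six-criterion behavioural arousal scale
  (0–11), all-subsets dominance analysis partitioning the regression `R²`
  among markers, a permutation test of the model fit, dichotomised
  classification variants, and Benjamini–Hochberg FDR utilities.
* **Synthetic data.** A calibrated generator (modular connectomes; runs drawn
  as harmonic-coefficient mixtures with condition-dependent spectral
  profiles) emulating awake / anaesthesia / thalamic-DBS conditions, so the
  entire pipeline runs end to end without access to animal data.

## Worked example

```r
library(eigenmarkers)

study <- file.path(tempdir(), "demo_study")
generate_study(study, conditions = c("awake", "deep_anaesthesia", "ct_high"),
               runs_per_condition = 4, seed = 42)

markers <- run_markers(study)
aggregate(cbind(gradient_range, hierarchical_integration, harmonic_energy)
          ~ condition, markers, function(x) round(mean(x), 4))
#>          condition gradient_range hierarchical_integration harmonic_energy
#> 1            awake         0.3066                   0.0383        134.0014
#> 2          ct_high         0.2963                   0.0276        131.5769
#> 3 deep_anaesthesia         0.1333                   0.0005        275.1587

result <- run_brain_behaviour(markers, n_perm = 1000, seed = 42)
result
#> Brain-behaviour dominance analysis
#> Dominance analysis (7 submodels, metric = r2)
#>   full-model fit: 0.9979
#>   gradient_range             dominance 0.3239  importance  32.5%
#>   hierarchical_integration   dominance 0.3479  importance  34.9%
#>   harmonic_energy            dominance 0.3261  importance  32.7%
#>   permutation p = 0.000999 over 1000 permutations
```

Reading the numbers: relative to the awake condition, the deep-anaesthesia
runs show a contracted principal gradient (0.13 vs 0.31: a shallower
functional hierarchy), collapsed hierarchical integration (0.0005 vs 0.038:
the whole-cortex FC eigenmode explains far less covariance), and roughly
doubled harmonic energy (275 vs 134: activity loads much more on
high-spatial-frequency structural modes). High-amplitude centro-median DBS
runs sit near awake on all three markers. The dominance analysis splits the
near-perfect model fit (`R² = 0.998` on this clean synthetic data) across the
three markers, and the permutation test (`p = 1/1001`) confirms the
marker–arousal association is far beyond chance.

A thin CLI over the same functions ships at `inst/cli/eigenmarkers.R`
(subcommands `simulate`, `markers`, `brain-behaviour`, `all`).

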
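# domainmotion

Quantitative analysis of relative domain motion in biomolecular
trajectories, for structural biologists and simulators who want to ask:
*does binding rigidify the relative motion of two protein domains?*

Multi-domain proteins (e.g. the variable domains of a T-cell receptor,
or the two helices framing an MHC peptide-binding groove) move as
quasi-rigid bodies. Given a reference structure (PDB) and one or more
trajectories (multi-model PDB), `domainmotion` reduces each
user-defined C-alpha domain pair to interpretable series and compares
them between states:

* **Inter-domain distance** `d(t)` between domain geometric centers.
* **Orientation angles.** Each domain carries a local coordinate system
  — the orthonormal eigenvectors `v1, v2, v3` of the 3×3 covariance of
  its C-alpha cloud, ordered by decreasing eigenvalue and
  sign-standardized against the crystal reference. For two domains with
  triads `(v1,v2,v3)` and `(w1,w2,w3)` the package reports
  `angle_i(t) = arccos(v_i · w_i)` in degrees.
* **RMSD(t)** `= sqrt( (1/N) Σ_i |r_i(t) − r_i^ref|²)` over a domain's
  C-alpha atoms after least-squares (Kabsch/SVD) superposition —
  intra-domain deformation.
* **RMSF(i)** `= sqrt( (1/T) Σ_j |r_i(t_j) − <r_i>|²)` — per-residue
  flexibility about the time-averaged position.
* **State comparison.** Pooled per-frame samples of any of these are
  compared between *free* and *bound* ensembles via means, sample SDs,
  and the exact two-sample Kolmogorov–Smirnov statistic `D`
  (descriptive; no p-values).

Because MD data sets of this kind are rarely deposited, the package
also ships a synthetic rigid-body trajectory generator with recorded
ground truth (distance law, rotation law, jitter), used for all
closed-loop validation.

## Worked example

Simulate a small bound/free ensemble (3 runs per state of the same
synthetic two-domain molecule; bound runs wobble with SD 2° about their
mean relative orientation, free runs with SD 6°), then run the full
analysis pipeline:

```r
library(domainmotion)

base <- motion_spec(duration = 40, output_interval = 0.2,
                    jitter_sd = 0.02)
dir <- "demo"
run_simulation(dir, n_runs = 3, base_spec = base, master_seed = 42)
cfg <- read_analysis_config(write_simulation_config(dir, base_spec = base))
bundle <- run_analysis(cfg, file.path(dir, "out"))
str(bundle$comparisons[["domA-domB"]]$beta_deg)
```

```
List of 7
 $ mean_free : num 56.2
 $ sd_free   : num 5.66
 $ mean_bound: num 62.8
 $ sd_bound  : num 1.98
 $ ks_D      : num 0.692
 $ n_free    : int 600
 $ n_bound   : int 600
```

Reading this: the angle between the second principal axes of the two
domains averaged 56.2° over the 600 pooled free-state frames and 62.8°
bound, and — the central signal — its spread collapsed from 5.66° to
1.98° on binding; the KS statistic `D = 0.692` says the two angle
distributions barely overlap. (The generator's truth was mean 57°/SD 6°
free and 63°/SD 2° bound, so the pipeline recovered both levels and
the variance contrast.) The same bundle contains distance series,
RMSD/RMSF tables and per-run summaries, all also written as CSV/JSON
under `demo/out/`.

The same steps are available from the shell:

```sh
Rscript inst/cli/domainmotion.R simulate --out demo --seed 42 --runs 3
Rscript inst/cli/domainmotion.R analyze --config demo/analysis_config.yaml \
        --out demo/out
Rscript inst/cli/domainmotion.R compare --free f1.csv --bound b1.csv \
        --column beta_deg
```

## Layout

| Path | Contents |
|---|---|
| `R/structure_io.R` | PDB parsing/writing, topology, domain selections |
| `R/kinematics.R` | geometric centers, Kabsch fit, global-motion removal, distances |
| `R/local_frames.R` | per-frame PCA triads, sign standardization |
| `R/orientation_stats.R` | pair angles, KS statistic, state comparison, histograms |
| `R/deformation_stats.R` | RMSD series, RMSF profiles, run summaries |
| `R/synthetic.R` | ground-truth rigid-body trajectory generator |
| `R/pipeline.R` | config-driven simulate/analyze/compare orchestration |
| `vignettes/domain-motion-analysis.Rmd` | methods: model, assumptions, parameter choices, limitations |
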
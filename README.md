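# gatemap

State-dependent interdomain distance analysis, calcium coordination-site
detection, trajectory stability assessment, clade-grouped sequence
conservation, and inactivation-kinetics statistics for calcium-selective
TRP channels — with a seeded synthetic-data module so every stage runs and
is testable fully offline.

## The problem

Fast Ca²⁺-dependent inactivation of mammalian TRPV6 (and its absence in
TRPV5) is hypothesised to be controlled by the geometry of an intracellular
motif: the helix-loop-helix (HLH) domain, the S2-S3 linker, and the TRP
domain helix (TDh) coupled to the channel gate. Testing this hypothesis
computationally requires a consistent set of measurements across
heterogeneous inputs:

* **salt-bridge proxy distances** between charged residue pairs
  (e.g. E294–R606, R302–E588, K245–E288, D406–R606 in TRPV6 numbering),
  measured as the minimum distance between terminal charged side-chain
  atoms, averaged over multi-model structure ensembles per condition
  (apo/lipid-bound vs Ca²⁺/CaM-bound) and compared between conditions;
* **Ca²⁺ coordination sites**, detected by the generic geometric rule of
  four to eight oxygens within 2.5 Å of the ion;
* **trajectory analyses**: Kabsch-superposed RMSD series, a stability
  (equilibration) onset, and time-averaged pair distances after the onset;
* **conservation fingerprints**: alignment columns conserved in a focal
  clade group (e.g. mammalian TRPV6) but replaced or unconserved in a
  contrast group (e.g. fish), plus conserved scaffold windows;
* **inactivation kinetics** from whole-cell current traces: the residual
  current (mean of the last 5 ms of a 60 ms pulse over the mean of the
  first 5 ms) and the time constant τ of a single-exponential fit
  *i(t) = i∞ + (i₀ − i∞)·exp(−(t−t₀)/τ)*.

The package is aimed at structural bioinformaticians and channel
biophysicists who need these measurements reproducible, parameterised and
unit-tested rather than embedded in one-off visualisation-tool scripts.

## Worked example

The packaged scenario generates a complete two-channel synthetic study —
structure ensembles for two conditions, Na⁺/Ca²⁺ trajectory pairs, current
traces for both phenotype classes, a grouped alignment and a coordination
shell — with every planted value recorded as ground truth:

```r
library(gatemap)
sc  <- trpv_scenario(seed = 1)

tab <- state_comparison_table(sc$structures$v6_like, sc$pairs)
tab
#> <state_comparison>
#>           pair_label            apo          bound
#>   HLH-TDh(E294-R606) 11.94±0.31 (6)  4.00±0.31 (6)
#>  HLH-TDhN(R302-E588) 11.01±0.29 (6)  4.59±0.28 (6)
#>  ARD6-HLH(K245-E288) 14.90±0.50 (6) 14.91±0.53 (6)
#>  S2S3-TDh(D406-R606)  5.87±0.62 (6) 10.09±0.38 (6)
delta_table(tab, "apo", "bound")
#>            pair_label condition_a condition_b delta_mean_A
#> 1 ARD6-HLH(K245-E288)         apo       bound -0.008047503
#> 2  HLH-TDh(E294-R606)         apo       bound  7.943523650
#> 3 HLH-TDhN(R302-E588)         apo       bound  6.421040408
#> 4 S2S3-TDh(D406-R606)         apo       bound -4.220295455
```

Cells are mean ± sd (n models pooled over all ensembles of a condition).
The Δ column is the signed mean difference apo − bound: the two HLH–TDh
pairs shorten by ~7–8 Å on binding (the fast-inactivation geometry), the
ARD6–HLH pair does not move, and the S2-S3→TDh pair lengthens.

Trajectory analysis averages pair distances only after the RMSD-based
stability onset:

```r
tj <- sc$trajectories$v6_like$CaCl2
on <- stability_onset(rmsd_series(tj))
on
#> <stability_result> onset frame 77 (t = 15.20 ns), window 50, |slope| <= 0.05 A/ns
pair_distance_series(tj, sc$pairs$hlh_tdh, on)$stats
#>           pair_label condition   mean_A      sd_A   n
#> 1 HLH-TDh(E294-R606)     CaCl2 4.486166 0.4426589 224
```

Kinetics of the fast-inactivating trace set (residual ≈ 0.13, τ ≈ 10 ms):

```r
inactivation_summary(sc$traces$v6_like)$summary
#>   n residual_mean residual_sem n_converged tau_mean    tau_sem
#> 1 5     0.1273953 0.0008112199           5 9.996086 0.01481982
```

Coordination-site detection on the planted shell:

```r
find_coordination_sites(sc$ca_site)[, c("ion_name", "count", "mean_distance_A", "qualifies")]
#>   ion_name count mean_distance_A qualifies
#> 1       CA     6             2.3      TRUE
```

Real data enter through `read_pdb()` (multi-model PDB, `keep_hetero = TRUE`
for ions/waters), `read_alignment()` (aligned FASTA + id→group TSV) and
`read_trace()` (two-column time/current CSV). Whole runs can be described
in a YAML configuration and executed with `run_pipeline()` (or the thin
wrapper in `inst/scripts/gatemap.R`), which writes per-stage tables, a
consolidated `report.md` and a replayable `manifest.json`.

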
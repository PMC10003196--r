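---
title: "Methods: interdomain distances, coordination sites and inactivation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interdomain distances, coordination sites and inactivation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatemap)
```

## Scientific background

TRPV5 and TRPV6 are calcium-selective epithelial channels whose activity is
limited by Ca^2+^-dependent inactivation. Fast inactivation — characteristic
of mammalian TRPV6 — is thought to be governed by a motif of three
intracellular elements: the helix-loop-helix (HLH) domain, the S2-S3 linker,
and the TRP domain helix (TDh) that couples to the channel's internal gate.
The working hypothesis is geometric: when the HLH approaches the C-terminal
portion of the TDh (e.g. the E294–R606 pair in TRPV6 numbering), the channel
inactivates quickly; when the sixth ankyrin repeat (ARD6) traps the HLH
instead (K245–E288), as in TRPV5, the HLH never reaches the TDh and fast
inactivation is absent.

`gatemap` implements the quantitative machinery used to interrogate this
hypothesis: salt-bridge proxy distances across structure ensembles and
trajectory frames, state-comparison tables, Ca^2+^ coordination-site
detection, RMSD-based equilibration assessment, clade-grouped sequence
conservation, and single-exponential inactivation kinetics. A seeded
synthetic-data module generates every input class with known ground truth,
so the full pipeline is testable without downloading structures or
recordings.

## The salt-bridge proxy distance

For a residue pair, the measured quantity is the distance between the
terminal charged side-chain atoms: carboxylate oxygens of Asp/Glu
(OD1/OD2, OE1/OE2) and basic nitrogens of Lys (NZ), Arg (NE/NH1/NH2) and
His (ND1/NE2). Where a carboxylate or guanidinium offers several equivalent
atoms we take the **minimum over all terminal-atom cross pairs**. This is
the standard salt-bridge convention; it is deterministic and is never
larger than any single-atom choice, resolving the ambiguity in "the last
charged oxygen/nitrogen" phrasing without chemistry-specific tie-breaking.
Hydrogens are ignored throughout; all coordinates are in Ångström.

Per-ensemble statistics are the arithmetic mean and the sample standard
deviation (n−1 denominator; 0 when n = 1) over models. When several PDB
entries represent one condition, pooling weights **each model equally**,
not each entry equally — a deliberate choice, since conditions are commonly
represented by different numbers of deposited maps. The pooled mean
therefore equals the n-weighted mean of per-ensemble means, which is
asserted as an invariant in the tests.

Two chain conventions are supported. In `intra` mode (the default) the two
residues are taken from the chains named in their references; in
`min_over_chain_pairs` mode the residue of each member is located in every
chain of the homotetramer and the global minimum is reported. We chose not
to add a separate "average over subunits" switch: subunits are chains, so a
user who wants per-subunit statistics enumerates one pair specification per
chain, and a user who wants the closest inter-subunit approach uses
`min_over_chain_pairs`. This keeps one unambiguous definition per
specification instead of an averaging mode whose meaning would depend on
chain naming.

The 4.0 Å `classify_contact()` threshold is a common salt-bridge cutoff
used **only** for qualitative formed/broken labelling — it never enters the
statistics.

## Calcium coordination sites

A site qualifies when an ion is surrounded by **four to eight oxygens at
2.5 Å or less** — the generic geometry of Ca^2+^ coordination in proteins.
Two readings of such a criterion are possible ("oxygens within 2.5 Å" vs
"average distance ≤ 2.5 Å"); we count oxygens within the cutoff and report
the mean distance over counted oxygens, which then satisfies the bound
automatically. This is the strictest reading consistent with both
phrasings, and the cutoff and count bounds are configurable
(`coordination_config()`). All element-O atoms count — carboxylate,
carbonyl, hydroxyl and, by default, water oxygens (`include_water`
exposed because published analyses rarely state this choice). Site
identity across trajectory frames is tracked by ion atom identity under
topology constancy, not by spatial clustering.

## RMSD and stability onset

`kabsch_superpose()` implements closed-form optimal superposition from
scratch: centroid subtraction, SVD of the 3×3 covariance matrix, and a
determinant sign correction guaranteeing a proper rotation. Tests check it
against rigid motions (zero RMSD to 1e−9), against an independent
numerical rotation search, and against the unaligned RMSD bound.

Published trajectory analyses often state that averaging started "after
stability was reached" without naming a rule. Our rule is explicit: the
stability onset is the first frame whose forward-looking window (default
50 frames) has a least-squares RMSD slope within ±0.05 Å/ns. Both
parameters are exposed; the onset is non-decreasing as the tolerance
tightens. If no window qualifies, the last admissible start is returned
with a warning rather than an error, so downstream averaging always has a
defined window. The RMSD reference is frame 1 and the selection is
Cα atoms of polymer residues; both are configurable.

Per-frame pair distances are then summarised over frames at or after the
onset, labelled by the trajectory's condition tag (e.g. `NaCl` vs
`CaCl2`).

## Conservation profiles and fingerprints

Per-column identity for a clade group is the count of the modal non-gap
residue divided by the **full group size** (gapped sequences stay in the
denominator), matching the visual per-column identity convention of
standard alignment viewers; ties break to the lexicographically smallest
residue, deterministically, with a message. An all-gap column has no modal
residue and identity 0. Scaffold windows are maximal runs of at least 3
columns at ≥ 70% identity; fingerprint positions are columns at ≥ 80%
identity in the focal group whose contrast group either fixes a different
residue or falls below 50% identity. The three thresholds are defaults
chosen to express "well-conserved" and "not conserved" in round numbers;
all are arguments.

Column coordinates are 1-based alignment columns. Mapping to structure
numbering is the user's responsibility (an offset table), because motif
numbering in the literature is window-relative.

## Inactivation kinetics

The residual current is the ratio of the **mean** current over the last
5 ms of the pulse to the mean over the first 5 ms, on raw signed currents.
We use window means rather than single samples for robustness to
digitisation noise; the window length is an argument. A start-window mean
below 1 pA in magnitude is an unstable ratio and errors.

The time constant comes from a least-squares fit of
\(i(t) = i_\infty + (i_0 - i_\infty)\,e^{-(t-t_0)/\tau}\)
over the pulse window (Levenberg–Marquardt, `minpack.lm`), initialised
from the edge-window means and a log-linear regression for τ. A trace
whose end current is not smaller in magnitude than its start current —
within the estimated noise and by at least 1% of the start current — is
declared non-decaying: `converged = FALSE`, no τ, mirroring the practice
of fitting τ only for clones showing a fast current decay. A fitted τ is
accepted only inside (0.1 ms, 10 × pulse duration). Optional blanking of
the first ~0.5 ms of the pulse is available for real recordings with
capacitive transients; synthetic traces do not need it and the default
is 0.

## What the synthetic generators emulate — and what they do not

The generators plant the *measured quantity* directly: the minimum
terminal-atom distance (every non-minimal partner atom strictly farther),
the displacement scale behind an RMSD ramp-then-plateau profile, oxygen
shells at stated radii, exact per-column residue counts, and exponential
current traces at 10 kHz. Residue geometry is minimal — backbone Cα plus
terminal charged atoms — which is sufficient for every consumer operation
but is **not** physically realistic protein geometry: no excluded volume,
no rotamers, no force-field plausibility. Trajectory "dynamics" are
independent per-frame draws, not autocorrelated motion; alignment columns
are independent, with no phylogenetic covariance. Passing tests therefore
demonstrate the correctness of the measurement and aggregation machinery
under known truth, not the biological conclusions obtainable from real
ensembles.

The packaged scenario (`trpv_scenario()`) encodes the qualitative
state-dependence of the two channel classes as planted means: in the
fast-inactivating class the HLH–TDh pair closes from 12 Å to 4 Å on
binding while ARD6–HLH stays at 15 Å; in the non-inactivating class
ARD6–HLH sits near 4 Å in both states and HLH–TDh never closes. Scatter
is 0.4 Å, chosen to be comparable to coordinate uncertainty in
intermediate-resolution cryo-EM models while keeping planted contrasts
many standard errors wide. Trace sets use τ = 10 ms with ~10% residual
for the decaying class and flat traces for the non-decaying class, with
noise at 1% of amplitude.

## Numerical choices and degenerate inputs

* PDB coordinates are written to 3 decimals; a write–read–write cycle is
  byte-stable, and coordinates outside the fixed-width 8.3 field raise a
  format-overflow error rather than corrupting columns.
* Alternate locations other than blank/'A' are dropped with a count — a
  deterministic approximation of the highest-occupancy convention.
  Insertion codes must match exactly during residue resolution; author
  numbering is never renumbered.
* Topology constancy across models is enforced by construction (one atom
  table, one coordinate slab), so trajectory operations cannot silently
  misalign atoms.
* Truncated-normal distance draws redraw up to 100 times above a 0.5 Å
  floor; oxygen shells fall back to a Fibonacci-sphere layout under a
  random rotation when rejection sampling cannot achieve the 1.5 Å
  mutual separation.
* All generators take an explicit seed, restore the caller's RNG state,
  and are byte-identical across equal-seed runs; the pipeline writes a
  manifest with input digests and the fully-defaulted configuration so a
  run can be replayed exactly.

## Problem sizes used by the test-suite and acceptance script

Unit and acceptance checks run on deliberately small instances chosen to
make sampling tolerances meaningful: 20-model ensembles for planted
Normal(8, 0.5) recovery (tolerance 3σ/√n), 500-frame trajectories with a
changepoint at frame 150 for onset recovery (±1 window over ≥ 95% of
replicates), 100–200 random oxygen shells, 100 seeds for noisy τ recovery,
and a 40-column, 20-sequence alignment with 5 planted fingerprint columns.
The packaged scenario defaults to 300-frame trajectories and 2 ensembles
of 3 models per condition. These sizes are the package's own choices for a
fast, deterministic reference workload; all generators scale to larger
instances through their arguments.

## Known limitations

* Only the PDB dialect is read; mmCIF users convert upstream. No bond
  inference, no symmetry expansion, no DCD/XTC trajectory formats —
  frames arrive as multi-model PDB.
* The stability-onset rule is a sliding-window slope test on the RMSD
  against a fixed reference; it is not a changepoint estimator and will
  return its fallback on monotonically drifting series.
* Coordination-site detection does not cluster transient sites or
  estimate affinities.
* Statistical hypothesis testing across condition groups (ANOVA and
  post-hoc procedures) is out of scope; the tables report means,
  standard deviations and standard errors only.
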
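---
title: "Corralled vibrational descriptors, information gain and contact distances: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corralled vibrational descriptors, information gain and contact distances: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cimvf)
```

# The problem

Olfactory receptors are class-A GPCRs whose experimental structures are
scarce, so the question of what distinguishes an agonist from a non-agonist
of a given receptor is attacked computationally from two sides: a
*spectral* side, where each candidate odorant is characterized by its
molecular vibrational spectrum and the class-informative spectral regions
are identified, and a *structural* side, where docked ligand poses are
measured against a receptor model to find the closest residue contacts.
`cimvf` implements both sides downstream of the expensive steps: it consumes
normal-mode lists (from any quantum-chemistry code) and docked poses (from
any docking program), and replaces both with seeded synthetic generators for
testing and method development.

# The CIMVF descriptor

A molecule's normal modes are pairs $(\nu_j, I_j)$ of wavenumber (cm⁻¹) and
a nonnegative intensity. The corralled intensity of molecular vibrational
frequency (CIMVF) is the vector of intensity sums over consecutive
fixed-width wavenumber bins ("corrals"):

$$x_k = \sum_{j\,:\, \nu_j \in [\,l + (k-1)s,\; l + ks)} I_j .$$

Defaults: step $s = 5$ cm⁻¹ over $[l, h) = [0, 4000)$ cm⁻¹, giving 800
corrals. These cover the fundamental vibrational range of small organics
with a resolution coarse enough to absorb conformer-to-conformer and
method-to-method wavenumber jitter, and fine enough to separate
functional-group signatures; both are tunable through `corral_scheme()`
provided the range is an integer multiple of the step.

Numerical choices:

* **Half-open bins.** Corral $k$ covers $[l+(k-1)s,\; l+ks)$; a wavenumber
  exactly on a boundary belongs to the upper corral. This is the only
  convention that partitions the axis without double counting; it also makes
  $h$ itself out of range.
* **1-based labels.** `F1` covers $[0, 5)$, so `F601` covers
  $[3000, 3005)$ — the label arithmetic $k = \nu \,\mathrm{div}\, 5 + 1$
  fixes the indexing convention. One published range in the informative
  feature table ("F230, 1,145–1,430") is inconsistent with this arithmetic;
  the package treats it as a typographical error for 1,145–1,150, the only
  range containing the quoted representative wavenumber 1,146.86 cm⁻¹.
* **Out-of-range modes** are dropped with a counted warning rather than
  clipped into edge corrals: the representable range is explicit, and
  silently inflating the edge bins would bias the edge features.
* **No normalization.** Intensities are treated as opaque nonnegative
  weights (IR vs Raman is irrelevant to the machinery) and are summed as
  given; per-molecule normalization is deliberately not applied, because the
  presence/absence coding used downstream is scale-free and the best-split
  coding should see the raw scale it will see in practice.
* **Imaginary frequencies** (negative wavenumbers in log files) indicate a
  non-minimum geometry and are rejected by default; `drop_imaginary = TRUE`
  downgrades them to a counted warning for exploratory work.

The descriptor is permutation-invariant in the mode order and conserves
in-range intensity ($\sum_k x_k$ equals the total intensity of in-range
modes); both properties are enforced by the test suite on 1,000 random
spectra.

# Information-gain feature ranking

For binary labels $C$ with entropy $H(C) = -\sum_c p_c \log_2 p_c$ (bits),
the information gain of corral $k$ under a discretizer $\tilde x_k$ is
$IG_k = H(C) - H(C \mid \tilde x_k)$, always in $[0, H(C)]$ and invariant
to which class is called "agonist". Two discretizers are exposed:

* **`presence`** (default): $\tilde x_k = \mathbf{1}[x_k > 0]$. For sparse
  small-molecule spectra, occupancy of a corral is the natural signal, and
  the coding is distribution-free.
* **`split`**: the supervised best binary split — thresholds at midpoints
  between consecutive distinct observed values, keeping the maximum IG.
  This exists because an informative feature table can list corrals
  occupied by *every* molecule yet scored IG > 0, which is impossible under
  presence coding: a threshold on intensity can still separate the classes.
  The original analysis (run in a generic ML toolkit) did not state its
  discretizer; the package exposes both and documents the discrepancy
  rather than resolving it.

A degenerate discretization (all molecules in one bin) scores 0 bits, not
an error. Ranking sorts by IG descending with ties broken by ascending
corral index, so equal-scoring corrals appear in spectral order and the
ranking is deterministic.

The per-corral "frequency" reported alongside IG is the number of molecules
with nonzero intensity in the corral — the most natural reading of an
otherwise undefined column in the motivating table.

# Classification and leave-one-out cross-validation

The fitted `cimvf_fit` object retains the training panel and classifies new
descriptors by **1-nearest-neighbour** on Euclidean distance over the
informative corrals (distance ties broken by lower training-row index), or
by a **naive presence vote** in which each informative corral votes for the
class whose training presence rate better matches the query's occupancy.
1-NN is the default: parameter-free, deterministic, and reasonable for
sparse descriptors. The original work did not name its classifier; nothing
here attempts to reproduce a specific toolkit's numerics.

`loocv_cimvf()` holds out each molecule in turn. By default
(`selection = "fold"`) the IG > 0 subset is recomputed on every training
fold, so feature selection never sees the held-out molecule — the test
suite verifies that garbling a held-out descriptor leaves its fold's
selection untouched. `selection = "global"` selects once on the full panel,
a laxer protocol provided because the original description is ambiguous on
this point; it is not the default precisely because it leaks. A fold whose
selected subset is empty (or whose training fold contains a single class,
as in one-molecule-per-class panels) falls back to the training-fold
majority class, ties going to the first factor level, and is counted in
`n_fallback`. This reproduces the classic two-point LOOCV pathology
(accuracy 0 on two molecules with disjoint descriptors) exactly.

A known behaviour worth stating plainly: at $n \approx 100$, almost every
corral with *any* occupancy imbalance between classes scores slightly
positive IG, so the IG > 0 threshold barely filters (≈ 400 of 800 corrals
survive on the default synthetic panel) and 1-NN over the survivors is
dominated by background noise — LOOCV accuracy on the default panel sits
near chance even though the planted corrals head the ranking by an order of
magnitude. Ranking and thresholding are different tools; the package
reports both honestly rather than tuning the threshold.

# Contact-distance analysis

`min_ligand_residue_distance()` computes the global minimum Euclidean
distance over all (ligand atom, receptor atom) pairs and attributes it to
the residue owning the minimizing receptor atom.

* **Heavy atoms only by default**: docked poses frequently lack hydrogens,
  so heavy-atom framework distances are the comparable quantity; a flag
  includes hydrogens (which can only shrink the minimum, never grow it —
  property-tested). The ligand "backbone" is taken as all its heavy atoms;
  no attempt is made to exclude substituents, since no operational
  definition exists.
* **Ties** (exact equal distances) are broken by lower residue number, then
  lower chain id — deterministic on constructed fixtures.
* **PDB handling** (via bio3d): first MODEL only; alternate locations
  resolved to altloc A, else highest occupancy; HETATM excluded from the
  receptor by default; residue numbering taken verbatim (contact reports
  refer to model numbering).
* **Pose files** (SDF V2000 via ChemmineR, or PDB): multi-record SDFs yield
  poses ranked in file order, matching the convention that docking programs
  write best-scored poses first. Binding-affinity fields present in SDF
  records are passed through verbatim, never computed.
* **Pose selection.** Whether a published contact table measured the
  best-energy pose or the closest pose is not stated in the motivating
  analysis; `pose_distance_table()` implements both rules
  (`"best_rank"`, the default, and `"min_distance"`).
* Per-ligand minima and their mean are reported to 3 decimals, the
  precision of published contact tables. The distance engine is verified
  against an exhaustive all-pairs oracle on 100 random fixtures and is
  invariant under joint rigid motion to 1e-9 Å.

# The synthetic generators

`simulate_spectra()` emulates the statistical structure the IG analysis
assumes, not physical spectra: each molecule occupies a shared set of
*background* corrals with a common probability (class-independent sparsity)
plus *planted* corrals whose occupancy probability differs between classes
(known ground truth). Occupied corrals receive one mode placed uniformly
within the corral, so corralling recovers the planted occupancy pattern
exactly; intensities are drawn from a normal truncated at zero (the choice
is immaterial under presence coding and merely exercises the best-split
path). Defaults mirror the motivating panel's geometry, chosen once as the
study conditions: 53 molecules per class; 428 background corrals at
occupancy 0.25, leaving roughly 370 of 800 corrals empty per class
(matching the reported sparsity of the real panel); three planted corrals
(`F230`, `F241`, `F601`, the headline spectral features) with occupancy
0.9 vs 0.3 — the minimal 0.6 gap at which planted corrals are expected to
dominate the ranking. What the generator does **not** emulate: correlated
corrals from shared substructures, intensity-only (occupancy-neutral)
class differences, heavy-tailed intensities, or any chemistry. Passing
tests therefore demonstrate correct machinery and recoverability of planted
structure, not classification performance on real odorant panels.

`simulate_pose_fixture()` plants a known nearest contact: the ligand's
first atom (an oxygen) sits at the origin with all other ligand atoms
strictly behind it, the target residue's designated atom sits exactly at
the target distance, and decoy residues are rejection-sampled strictly
outside that margin (error after 100 attempts). The fixture is emitted as
PDB/SDF text and re-read through the package's own parsers before being
returned, so the ground truth is what the file formats preserve — which is
also why target distances are rounded to the 3 decimals PDB coordinates
carry.

# Problem sizes and determinism

The test suite exercises: 1,000 random spectra for descriptor conservation
and permutation invariance; 500 random panels for IG bounds and agreement
with a direct contingency-counting oracle; 100 random geometries for
distance-engine/oracle equality; 200 seeded replicates of the default
53 + 53 panel for planted-corral recovery (all three planted corrals in the
top five ranks in ≥ 95% of replicates); and byte-identical reruns of the
full pipeline. These sizes were chosen to estimate the relevant rates
stably while keeping the suite quick to run. All simulation is seeded;
every pipeline output is plain text with fixed formatting and no
timestamps, so identical inputs and configuration reproduce identical
bytes, and the effective configuration is echoed to `config.json` alongside
every run.

# Known limitations

* The descriptor inherits the upstream method's wavenumber scale; spectra
  computed at different theory levels should not be mixed in one panel
  without a scaling correction, which the package does not apply.
* Presence-coded IG at $n \approx 100$ gives a noisy positive tail (see
  above); the IG > 0 selection rule is faithful to the motivating analysis
  but weak as a filter. Users wanting a sharper subset should rank and cut
  by score or use the best-split discretizer.
* Only binary panels are supported; multi-class IG is out of scope.
* No energy, scoring, or docking: pose files are analyzed as given, and
  binding affinities are pass-through metadata.
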
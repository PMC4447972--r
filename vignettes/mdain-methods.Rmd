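---
title: "Methods: differential residue-interaction networks and umbrella-sampling PMFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential residue-interaction networks and umbrella-sampling PMFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdain)
```

## The problem

Secondary transporters of the neurotransmitter:sodium symporter (NSS)
family couple Na$^+$ binding to conformational transitions that move
substrate across the membrane. Perturbations that disrupt coupling — a
non-transported cation such as Li$^+$, or mutations at the intracellular
gate — leave fingerprints in the *dynamics* of the protein long before
they are visible in any single structure. `mdain` implements a protocol
for reading those fingerprints out of molecular-dynamics (MD) ensembles:
it detects pairwise residue interactions frame by frame, estimates their
frequencies per simulated condition, tests which frequencies differ
significantly between a perturbed and a reference condition, and
coarse-grains the significant pairs onto a transmembrane subsegment scheme
to expose the allosteric interaction network (AIN) that links the
perturbation site to distal functional sites. The package also provides
the geometric observables used alongside such analyses (vestibule water
counts, cation binding-site classification, $\chi_1$ rotamers) and a 1-D
weighted-histogram (WHAM) solver for umbrella-sampling free-energy
profiles of ion binding.

## Pairwise residue interactions

Two channels define an interaction in a frame; a pair interacts when
either fires.

**vdW contact.** Residues $a$ and $b$ are in contact when any two heavy
atoms $u \in a$, $v \in b$ satisfy

$$ d(u, v) < r(u) + r(v) + m, $$

with $r$ a per-element van der Waals radius and margin $m = 0.6$ Å
(strict inequality). Same-chain pairs separated by at most 4 residues are
excluded from this channel: nearest-neighbour vdW contacts are
permanent and carry no conformational signal. The radii are a Bondi-style
heavy-atom set (C 1.70, N 1.55, O 1.52, S 1.80 Å) shipped as an editable
table (`inst/extdata/vdw_radii.tsv`); because contact counts depend on
this table it is explicit, never hard-coded.

**Polar interaction.** A geometric hydrogen-bond test complements the
contact channel, chiefly so that changes in *sequence-local* polar
interactions (e.g. backbone hydrogen bonds of a helix turn) are not lost
to the contact channel's sequence exclusion — accordingly this channel
applies **no** sequence exclusion. Donor/acceptor typing comes from
per-residue templates (`inst/extdata/hbond_templates.tsv`; backbone amide
N donates except in proline, carbonyl O accepts). With hydrogens present
the criteria are D–A $\le$ 3.9 Å, H–A $\le$ 2.5 Å and D–H–A $\ge$ 90°,
the customary defaults of HBPLUS-style detection; without hydrogens (as
in crystal structures or stripped trajectories) a tighter heavy-only D–A
cutoff of 3.5 Å is used instead.

Waters and ions are retained by the structure readers (the observables
need them) but excluded from residue-pair analysis by default. With
orthorhombic box vectors present, distances use the minimum-image
convention.

## Frequencies and significance

Frames are subsampled to a fixed stride (default 240 ps) and restricted
to the equilibrated segment of each replica. The frequency of a pair in a
condition is the fraction of masked-in frames in which it interacts;
per-replica frequencies are retained, and the condition-level frequency
is their frame-weighted mean.

A pair differs between conditions $a$ and $b$ when the difference of its
interaction frequencies is statistically significantly different from
zero. The default `replica_t` test applies Welch's unequal-variance
$t$-test to the *per-replica* frequencies. Treating replicas as the
independent units is deliberately conservative: frames within a replica
are strongly autocorrelated, and replica-level aggregation absorbs that
autocorrelation without having to model it. For single-replica conditions
a circular block bootstrap over frames (default block length 20 frames)
is provided instead. P-values are corrected across all tested pairs by
Benjamini–Hochberg; edges with $q \le \alpha$ (default 0.05) are
reported. Whether the original protocol corrected for multiple
comparisons is not documented; controlling FDR is this package's own
choice and is flagged as such.

The test suite calibrates this machinery against planted two-state Markov
models in which each pair's indicator persists with probability $\rho$
and otherwise redraws as Bernoulli($p$), so the stationary frequency is
$p$ and the lag-1 autocorrelation is $\rho$. Under a global null
($p = 0.5$ in both conditions, $\rho = 0.9$, 3 replicas × 1000 frames,
10 candidate pairs) the family-wise false-report rate stays at or below
the nominal $\alpha$ within Monte-Carlo error over 200 simulations; a
planted difference of 0.5 (0.9 vs 0.4) is recovered in well over 90% of
100 simulations. The 10-pair candidate set is this package's choice of a
realistic multiple-testing burden; the null calibration imposes the
persistence explicitly, while the power scenario uses the generator's
default of independent frames.

## Coarse-graining onto subsegments

Significant pairs are gathered into subsegment pairs using a named
partition of the sequence: each TM helix split into extracellular (e),
middle (m) and intracellular (i) sections, plus loops and termini. The
packaged default for the LeuT transporter has 44 subsegments exactly
covering residues 1–515 and is validated (no gaps, no overlaps) by
`validate_scheme()`. One graph edge is drawn per subsegment pair with at
least one significant member pair; its sign is `increased` when every
member is more frequent in the investigated condition, `decreased` when
every member is less frequent, `mixed` otherwise. Pairs falling inside a
single subsegment become flagged self-edges rather than being dropped.
Graph intersection (edges significant under *both* of two perturbations,
regardless of direction) exposes shared allosteric pathways; shortest
pathways between subsegments are enumerated by unweighted hop count with
deterministic lexicographic ordering. Vertex band positions (e/m/i) are
presentational metadata only. Functional-site vertex groupings are left
to user configuration because no authoritative membership list exists.

## Observables

**Vestibule water count.** The openness of the extracellular vestibule is
measured as the number of water oxygens inside a user-specified region:
either the convex hull of the heavy atoms of explicit lining residues
(membership decided by LP feasibility; boundary points count as inside)
or an explicit cylinder. There is deliberately no built-in vestibule
definition — absolute counts depend entirely on the boundary, so the
region must be stated (`inst/extdata/ev_region_example.yaml` shows the
format with an illustrative lining set).

**Cation binding-site state.** The position of the mobile cation near the
Na1/Na1′ sites is classified by its distance to the cation bound in the
Na2 site: Na1 below 8.3 Å, transition up to 10.7 Å, Na1′ beyond. The
published colour-coding quotes both "<10.7" and ">10.5" for the upper
boundary; a single boundary at 10.7 Å is used here so the three states
partition $[0, \infty)$. The crystallographic Na1–Na2 separation of
7.0 Å classifies as Na1; a stable alternative site at ~12–13 Å as Na1′.

**$\chi_1$ rotamers.** Side-chain $\chi_1$ is the signed N–CA–CB–$\gamma$
torsion on $(-180°, 180°]$ (with $-180°$ mapped to $+180°$), the
$\gamma$ atom following the standard per-residue table; glycine and
alanine signal "undefined". Rotamers are binned gauche$^-$ on
$[-120°, 0°)$, gauche$^+$ on $[0°, 120°)$, trans otherwise — the
standard convention, stated here because the bin edges are not universal.

**Conditional occupancy.** Among the top 20% (configurable) of frames
ranked by an openness score, the Na1:Na1′ occupancy ratio is the count
ratio of the two bound states, transition frames excluded; an empty Na1′
pool reports an infinite ratio together with the raw counts.

## Equilibration masking

The protocol requires a consistent, auditable rule for selecting
equilibrated trajectory segments. The default `rmsd_plateau` rule smooths
the C$\alpha$ RMSD trace to the mean structure of the final 10% of frames
with a 5-frame running mean and admits frames from the first index after
which the smoothed trace stays within a tolerance band (default 1.0 Å) of
its final plateau value; a replica that never settles is masked out
entirely with a warning. `fixed_discard` (drop a leading fraction) and
`explicit` (user-supplied ranges) are provided as overrides. This default
is a reproducible stand-in chosen by this package, not a reconstruction
of any particular study's unpublished criterion.

## Umbrella sampling and WHAM

`make_windows()` builds a regular window grid (the canonical ion-entry
setup spans $-1.5$ to $25$ Å in 0.25 Å steps — 107 windows — with
$k = 10$ kcal mol$^{-1}$ Å$^{-2}$); `discard_equilibration()` trims
leading samples (e.g. the first 500 ps of a 2 ns window). The WHAM solver
iterates the standard self-consistent equations over binned samples under
harmonic biases $U_i(z) = \tfrac{k}{2}(z - c_i)^2$, entirely in log
space: strongly displaced windows otherwise underflow the normalisation
integrals. Numerical choices: bin width 0.05 Å by default; convergence
when the largest change in window free-energy shifts falls below
$10^{-7}$ kcal/mol, capped at $10^5$ iterations; profiles aligned
min-zero (a bulk-reference convention can be applied by the caller; the
reference convention of published profiles is generally unstated).
Non-overlapping adjacent windows raise a disconnected-histogram
diagnostic. The reported grid spans a configurable range (default: the
sampled range); samples outside it are dropped.

Errors are estimated by blocking: each window's samples are split into
$n$ contiguous blocks (3 by default; 7 is equally customary), WHAM is
solved per block, block profiles are aligned on their common finite
support by mean subtraction, and the standard error across blocks is
reported per grid point. A Monte-Carlo bootstrap over blocks is available
as an option; neither block count is claimed to be "the" canonical
choice. The flat-bottom cylindrical restraint used during sampling
(radius 15 Å) is carried as metadata only — no standard-state volume
correction is applied.

Correctness is checked against analytic oracles: biased densities of a
quadratic potential are exact Gaussians, so windows can be sampled
exactly and the recovered profile compared with $U(z) = 2z^2$ (RMS
deviation well under 0.15 kcal/mol over $[-1.5, 1.5]$ Å at 21 windows ×
5000 samples); a quartic double well scaled to a 3 kcal/mol barrier is
recovered within 10%; and a single unbiased window must reduce WHAM to
$-k_BT\,\ln(\text{histogram})$ up to a constant.

## Synthetic fixtures: what they do and do not show

All tests run on generated data with known ground truth: idealised
helix/extended peptides built from standard internal coordinates (the
helix yields its full complement of $i, i{+}4$ backbone hydrogen bonds
under the default criteria), planted Markov interaction models realised
either directly as indicator chains or geometrically (the partner residue
translated so its CB sits 0.5 Å inside the contact threshold when "on"),
exactly sampled umbrella windows, and state-labelled cation distance
traces. Umbrella samples for non-quadratic potentials are drawn by
inverse-CDF lookup on a dense grid of the analytic biased density — exact
to grid resolution and deterministic given the seed.

These fixtures validate the *code*: detection thresholds, estimator
identities, calibration of the significance machinery, WHAM consistency.
They do not emulate real transporter dynamics — no cooperative
transitions, no solvent, no force-field physics — so passing tests say
nothing about the biological correctness of any particular simulation
set. Problem sizes used by the test and acceptance runs (up to 50-residue
frames, 3 replicas × 1000 frames, 200 Monte-Carlo repetitions,
5000 samples per umbrella window) were chosen as the smallest sizes at
which the statistical claims under test are sharp.

## Known limitations

* Trajectory input is DCD or multi-model PDB (with a PDB topology); XTC
  is not read.
* The polar channel types only standard amino acids plus the shipped
  template entries; unknown residue types are skipped with a warning.
* Salt bridges and cation-$\pi$ interactions receive no special typing;
  the interaction definition is purely geometric.
* 1-D WHAM only; no MBAR generalisation, no 2-D reaction coordinates.
* The convex-hull water count solves one small LP per water, which is
  exact but not tuned for very large solvated boxes.
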
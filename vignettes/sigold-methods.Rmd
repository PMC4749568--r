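---
title: "Models and methods behind sigold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sigold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigold)
```

## The problem

Serial-section TEM connectomes map synapses but not molecules. Serial-multiplex
immunogold labeling (siGOLD) closes that gap for peptidergic neurons: because
mature neuropeptides travel the whole length of an axon inside dense-core
vesicles (DCVs), immunogold-labeling only a *sparse subset* of the thousands
of 40-nm sections — each short run of consecutive sections (one EM grid) with
one neuropeptide antibody — is enough to tag a neuron wherever its neurite
crosses a labeled section. The tagged neurite is then traced through the full
series, propagating the molecular identity to the complete morphology and its
synaptic partners.

`sigold` implements this analysis end to end: a generative simulator with the
statistical structure the method relies on, the gold-scoring and
identity-calling rules, power analysis of labeling designs, synapse-count
circuit graphs, and groupwise average-template construction for the
accompanying immunofluorescence registration workflow. Everything takes and
returns tibbles, so the stages compose with the pipe.

## The generative model

`generate_dataset(sim_config(...))` composes four submodels. Each draws from
its own child stream of the root seed, so enlarging one component never
perturbs another.

### Neurite population

Neurite profiles crossing the series are placed in a cross-section coordinate
frame (micrometres, midline at `x = 0`, 0-based section index `s` at depth
`z = 40 nm * s`). With `bilateral = TRUE` profiles come in left/right mirror
pairs that share their ground-truth peptide content, emulating the bilateral
symmetry of the ventral nerve cord. A fraction `peptidergic_frac` (default
0.3) expresses one neuropeptide from the 11-antibody panel, and a further
`coexpression_prob` (default 0.05) a second one — coexpression is a real
feature of these data (e.g. FVamide + pigment-dispersing factor), so the
caller rules must tolerate multi-label outcomes.

### DCV occupancy: a two-state Markov chain

Scored DCV counts along real neurites are bursty: stretches rich in vesicles
alternate with sections that completely lack them. The published observations
report this qualitatively but give no generative law, so the package adopts
the simplest chain with those features: a per-section on/off Markov chain
(`dcv_on_rate` = P(off to on), default 0.2; `dcv_off_rate` = P(on to off),
default 0.1) with Poisson(`dcv_mean` = 4) counts in the on state and zero
otherwise. Two closed forms make it testable: the stationary mean count is
`on_rate / (on_rate + off_rate) * dcv_mean`, and zero-run lengths are
geometric with parameter `dcv_on_rate`. Non-peptidergic neurites carry an
all-zero track — they have no DCVs to label.

### Gold deposition: a thinned Poisson law

On a labeled section `s` stained with antibody `a`, the observable gold count
on neurite `i` is

```
N_raw  ~ Poisson( alpha * D(i, s) * max_p S[a, p] + lambda_bg * A_i )
N_obs  ~ Binomial( N_raw, p_enh )
```

with `D(i, s)` the DCV count, `S` the antibody x peptide recognition matrix
(unit cognate diagonal; the max runs over the peptides neurite `i` actually
expresses — an antibody binds its best-matching epitope, avoiding double
counting), `A_i` the profile area, and three invented-but-motivated
parameters: `alpha` (`gold_per_dcv`, default 1) — gold per DCV at full
recognition; `lambda_bg` (`background_rate`, default 0.02 per um^2 per
section) — nonspecific background, small but nonzero because a dead-zero
background would make specificity untestable even though omitted-primary
controls show none in practice; and `p_enh` (`enhancement_prob`, default
0.5) — the probability a deposited ultra-small gold particle is silver-
enhanced into a countable particle, since unenhanced particles are invisible
at scoring resolution. Thinning a Poisson leaves a Poisson, so the observed
mean is `p_enh * (alpha * D * S + lambda_bg * A)` — the oracle used by the
tests. Counts exist only for labeled sections: unlabeled cells are *absent*,
not zero, and totals ignore them.

With defaults, `alpha * dcv_mean = 4` lies in the 2–5 range of mean gold per
DCV-rich labeled section that makes the calling problem realistic rather
than trivial.

### Labeling designs

`design_paired_grids()` reproduces the nerve-cord style: each of the 11
antibodies on two runs of 4–18 consecutive sections (default 5) whose starts
are ~50 sections apart; when the antibody block is longer than the nominal
spacing the effective spacing widens (to 55 with the defaults) to keep runs
disjoint. `design_whole_body()` reproduces the whole-body style: 1–6-section
"set-aside" runs scattered evenly over thousands of sections. Runs are
half-open `[start, end)` on 0-based section indices.

### Synapses and vesicle diameters

Peptidergic presynapses contain only DCVs; their diameters are drawn from a
positive-truncated normal with mean 63 nm and SD 8.4 nm, the published
measurement. Clear vesicles at classical synapses have no published diameter
in this context, so the package uses a typical small-clear-vesicle model
(mean 35 nm, SD 5 nm). The classification cut in `classify_synapse()`
defaults to 45 nm, roughly midway between the two means; with both models
normal, the misclassification rates have closed-form tail probabilities that
the tests check by simulation.

## Scoring and identity calling

`tabulate_gold()` builds the antibody x layer x neurite table with neurite
columns ordered by cross-section position; row, column and antibody totals
obey the double-counting identity. `select_candidates()` applies the
tracing-selection rule: a neurite is a candidate if any single labeled
section carries >= 2 gold particles. `call_identities()` then
operationalises "consistent strong labeling", which the source material never
defines numerically, as: *confirmed* if strong cells (>= `min_gold` = 2)
occur on >= `min_runs` = 2 distinct runs, **or** the total gold for the
antibody reaches `min_total` = 5. The total-gold branch exists precisely for
the documented failure mode in which a neurite labels strongly on one grid
while its partner grid falls on sections that genuinely lack DCVs;
`dcv_cooccurrence_check()` detects that situation and such calls carry a
`dcv_absence_false_negative` flag instead of being discarded.

Control sampling (`sample_control_transect()`) walks a transect across the
cross-section and takes the two nearest unsampled profiles per micrometre.
The default transect is the horizontal (coronal) chord through the median
`y` of the profile centroids — the published figure shows a dotted line with
no coordinates, and this chord is a deterministic, reproducible stand-in
that spans the cross-section's full width.

Cross-reactive antibody groups (the RFamide-like block is the motivating
case) are flagged from data alone: `flag_crossreactive_groups()` connects
antibodies whose confirmed-positive sets have Jaccard overlap >= 0.5 — well
above chance overlap at realistic positive-set sizes — and reports connected
components. `bilateral_symmetry_score()` scores the mirror-pairing of
confirmed positives within a radius (default 1 um), and is invariant to
y-translation and whole-dataset reflection.

### Power analysis

`evaluate_design()` is the experiment the method motivates but that real
grids cannot run: sweep runs-per-antibody, sections-per-run and spacing,
simulate replicate experiments, and score confirmed calls against ground
truth. The cognate map counts a confirmed (neurite, antibody) pair as a true
positive when the neurite expresses a peptide the antibody recognises at
full strength (`S = 1`); partially recognised hits (`0 < S < 1`) are
reported as cross-reactive and count as neither true nor false positives,
mirroring how partially characterised antibodies are treated as markers of a
peptide *family*. Replicate seeds are shared across designs, so comparisons
are paired. At study-like conditions (11 antibodies, two ~5-section runs
~50 sections apart, 200 neurites, detection probability 0.5, 20 replicates)
confirmed calls reach precision >= 0.95 and recall >= 0.80 — package
acceptance thresholds, not claims of the source study.

## Circuit reconstruction

Skeletons use the standard 7-column SWC format; connectors are tables of
synaptic (pre, post) pairs, so a polyadic synapse contributes one pair per
postsynaptic target (the CATMAID convention — the published counts do not
state their polyadic rule, and this is the convention their tooling uses).
`build_graph()` aggregates pairs into a directed graph over neurons or named
groups with edge weight = synapse count and display width = sqrt(weight);
regrouping never changes the total weight. `in_degree_spectrum()` separates
strongly connected targets from the long single-synapse tail, and
`laterality_profile()` computes `n_ipsi / (n_ipsi + n_contra)` of a neuron's
output relative to its soma side — 1 for photoreceptor-like strictly
ipsilateral output, 0.5 for balanced bilateral output.

The volume-scale published numbers (83 traced peptidergic neurons, a
strongest target receiving 22 synapses, 87 single-synapse targets) derive
from an EM volume that is not distributed; the package therefore tests the
*structure* of these results on synthetic circuits with designed
connectivity, not the numbers themselves.

## Template construction

The immunofluorescence side of the workflow registers whole-body confocal
stacks to an unbiased average template. `build_template()` implements the
iterative scheme: centre (optionally orient) all stacks; average naively;
then per stage register every *original* centred stack to the current
average, rank by similarity, and average the `k_keep = 24` most similar of
the 36-stack cohort into the next template. The default staging — one affine
round then two affine+deformable rounds — matches the described procedure,
whose prose is ambiguous about the exact number of repeats; the stage list
is therefore a parameter.

Numerical choices, all made for determinism and desk-scale robustness:

* **Similarity metric**: normalised cross-correlation (the "iteration
  metric" is unnamed in the source). `similarity_score(a, a) = 1`.
* **Optimisation**: Nelder-Mead from the identity with iterated restarts
  (restarting from the incumbent until the gain falls below 1e-4); the
  deformable stage is a greedy block-coordinate descent over a coarse
  4 x 4 x 2 control-point grid with trilinear interpolation, probing each
  displacement component by a halving step. Greedy acceptance means the
  affine+deformable score can never fall below the affine-only score, and
  registering a stack to itself returns the exact identity at score 1.
* **Resampling**: trilinear, zero fill outside the grid. Optimisation
  subsamples the voxel grid (stride 2 in x, y); reported scores always use
  the full grid.
* **Determinism and order invariance**: registrations are independent per
  stack, ranking ties break by stack name, and averages are summed in
  ranked order — a permuted input cohort yields a bit-identical template.

Centre-of-mass alignment on thin stacks (8 z-planes) clips a little mass at
the z borders, so repeated centring converges to within half a voxel rather
than exactly; tests assert the sub-voxel bound, not bitwise idempotence.
Likewise the "template beats any single stack" property is evaluated after
registering both template and stacks to the ground-truth pattern, on
noise-only cohorts — with per-stack deformations the comparison frame is
ill-posed, and affine registration cannot (and should not) undo another
stack's deformation.

## Synthetic data: what it does and does not emulate

The simulator reproduces the *statistical* structure the analysis depends
on: bilateral positional symmetry, bursty DCV occupancy with zero runs,
sparse run-structured labeling, Poisson gold with background and incomplete
enhancement, antibody cross-reactivity, DCV vs clear vesicle diameters, and
smooth inter-specimen deformation of intensity stacks. It does **not**
render membranes, organelles or gold particles as imagery (counts are the
inputs, as in the real scoring workflow), does not model section loss,
folds, or staining gradients along the series, and its neurite paths are
straight with positional jitter rather than curving fascicles. Passing tests
therefore validate the scoring and calling logic under the stated
statistical assumptions — not the image-processing steps (stitching,
alignment, particle detection) that precede them in a real pipeline, which
are out of scope.

## Problem sizes used by the test-suite

Simulation-backed checks run at desk scale, chosen so the full suite
completes in minutes: Monte-Carlo oracles use 1e4 replicates (3-SE bands);
the co-occurrence scan uses 1000 neurites; design power uses 200 neurites x
20 replicates; template cohorts use 36 stacks of 64 x 64 x 8 voxels at the
acceptance scale and smaller cohorts for unit properties. These sizes are
stated here as the package's reference conditions; all are parameters.

## Known limitations

* Identity calling is rule-based by design (matching the source procedure);
  no probabilistic model of counts is fitted.
* The Jaccard threshold (0.5) and calling thresholds (2 / 2 / 5) are
  defaults with stated rationale, not estimated quantities.
* The deformable registration model is a coarse control-point grid, not a
  full B-spline pyramid; it is adequate for the smooth, low-frequency
  deformations the renderer produces, and will underfit sharper warps.
* One packaged fixture cell (`l14`) is typographically ambiguous in its
  printed source and is flagged rather than asserted.
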
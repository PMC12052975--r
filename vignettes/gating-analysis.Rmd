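---
title: "Desk-scale analysis of substrate gating in full-size ABCG transporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale analysis of substrate gating in full-size ABCG transporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcgate)
```

## The problem

Full-size ABCG (pleiotropic drug resistance, PDR) transporters export
chemically similar small molecules — the auxin precursor IBA, the
phytoalexin camalexin (CLX), IAA, indole — with sharply different outcomes
that can hinge on single residues of the hydrophobic extracellular gate
(in AtABCG36: F703/L704 and F1374/F1375). `abcgate` reconstructs, at desk
scale, the computational chain used to dissect this gating: enhanced
sampling of the translocation free-energy surface, steered pulling with
contact statistics, a logistic model of per-residue transport importance,
the electronic binding-energy relation, and an evolutionary profile of the
gate across plant families. Every stage is driven by deterministic
synthetic generators, so the whole chain can be exercised and scored
against known ground truth on one CPU.

## The engine: 1-D Langevin dynamics on the translocation coordinate

The all-atom system is replaced by one coordinate: z, the z-component of
the ligand's position along the transmembrane pathway (nm). A landscape
object supplies the free energy F(z) (kJ/mol) in closed form — quartic
double well, downhill-with-barriers "substrate" shape, the same shape plus
an entry barrier, harmonic, flat, or tabulated — so the analytic profile
is always exactly known.

The propagator is underdamped Langevin dynamics discretised with the BAOAB
splitting, which has excellent configurational sampling accuracy at fixed
step size. Units follow the GROMACS convention (kJ/mol, nm, ps, g/mol), in
which no conversion factors appear. Defaults:

* temperature 303.15 K and timestep 0.002 ps (2 fs), matching the
  production simulation setup (where both 303.5 and 303.15 K appear in the
  source protocol, 303.15 K is adopted everywhere);
* friction 1/ps and mass 50 g/mol. These two are *effective* 1-D
  parameters: they set timescales only and cancel from every equilibrium
  distribution, so no claim is made that they match the all-atom kinetics;
* one-sided power walls at −1.1 and 2.0 nm confine the coordinate to the
  pathway. The source protocol states the wall positions but not their
  stiffness or exponent; we default to κ = 1000 kJ/mol/nm² (the same
  stiffness as the published moving restraint) and exponent 2.

Velocities are initialised from Maxwell–Boltzmann using the run seed; each
walker derives its stream as `seed + walker_index − 1`, and trajectories
are bit-reproducible per (configuration, seed) — the RNG and the Gaussian
transform are implemented explicitly so results do not depend on the C++
standard library. Positions outside the landscape domain are clamped with
a warning rather than erroring; the walls make this rare.

## Well-tempered metadynamics and FES reconstruction

Bias parameters default to the production values: hills of initial height
0.6 kJ/mol and width σ = 0.05 nm every 500 steps (1 ps), bias factor
γ = 10, grid −1.5 to 2.4 nm. The grid bin count is not part of the
published parameter line; 390 bins give 0.01 nm resolution. Hill heights
are scaled at deposition by `exp(−V/(kB (γ−1) T))`, and the free energy is
recovered by hill summation, `F(z) = −γ/(γ−1) · V(z)`, shifted to minimum
zero; bins within 3σ of at least one hill centre are marked sampled.

Design choices worth stating:

* **Synchronous walkers.** The original multiple-walker runs share hills
  through files at hardware-dependent cadence. Here all walkers advance
  one deposition period with the bias frozen, then deposit in walker-index
  order, each deposition seeing the hills laid earlier in the same round.
  This makes runs exactly reproducible, and permuting walker seeds changes
  only hill order, not the reconstructed surface.
* **Hill evaluation.** The offline summation (`bias_from_hills`,
  `reconstruct_fes`) uses full, untruncated Gaussians. The online
  propagator evaluates hills within 9σ of the current position through a
  spatial bucket index; a neglected hill contributes < 3e-18 kJ/mol, so
  the online bias agrees with the offline sum far below the 1e-9 level
  while keeping multi-million-step runs feasible.
* **Convergence scoring.** `fes_rmse` compares two surfaces after aligning
  each to mean zero on the requested interval, excluding bins unsampled in
  either. Recovery is scored on the *thermally accessible* interval —
  where the analytic profile lies within 20 kJ/mol (≈ 8 kT) of its
  minimum. Outside it the quartic reference climbs to tens of kT; bins
  there are touched by at most a stray hill and no finite run estimates
  them, so including them would score noise, not convergence.
* No smoothing or block averaging is applied to reconstructed surfaces
  (whether the original figures applied any is unstated).

At the calibration settings (4 walkers × 2×10⁶ steps, 16,000 hills, fixed
seed) the 12 kJ/mol double well is recovered with an RMS error around
0.3 kJ/mol, and the cumulative bias at the deepest minimum grows strongly
sub-linearly (last-to-first-quartile increment ratio ≈ 0.14), the
signature of well-tempering.

## Steered pulling and corrected contact frequencies

The pull-in stage uses the published staged restraint — (step 0, z_init,
κ 1000), (4,500,000, 0.2 nm, κ 1000), (5,000,000, 0.2 nm, κ 0) — with
centre and stiffness interpolated linearly between stages and held beyond
the last. The pull-out is a constant-velocity umbrella restraint (defaults
κ = 500 kJ/mol/nm², 0.0005 nm/ns along +z, 25 replicates from distinct
seeds, standing in for the original's distinct initial velocities). Desk
runs rescale the velocity (the analysis drivers use 10 nm/ns) so a full
translocation fits in ~300 ps of simulated time.

Contacts are a 1-D surrogate: residue zones are intervals on z (halfwidth
0.1 nm), and a residue is "in contact" at a frame when z lies in its zone.
This preserves the structure of the statistic — which is what the
downstream regression consumes — without 3-D geometry. The published
contact cutoff and atom selection are unstated, so no attempt is made to
mimic them quantitatively.

Two desk-scale dynamics facts shape how landscape contrasts are probed.
First, two runs that share a noise sequence synchronise exactly once past
any region where their forces differ (common-noise contraction of the
damped spring dynamics), so landscape comparisons always use independent
seeds. Second, an entry barrier discriminates gate-zone contacts only when
it is rate-limiting on the pull's timescale: a ~300 ps desk pull crosses a
3 kT bump in a few tens of ps regardless of the landscape, so the
contact-localisation checks and the mechanistic panel mode place the
non-substrate's entry barrier at 18 kJ/mol (≈ 7 kT) and drag with a weak
spring (10 kJ/mol/nm²) — the same rate-limiting regime that the original
µs-scale slow pulls probe at lower barrier heights. The FES archetype
default (+8 kJ/mol) is unchanged.

The correction factor over a ±10 ps force window is
`(P − |N|)/(P + |N|)` with P the sum of positive and N of negative
restraint-force samples, 0 when the denominator vanishes; windows truncate
at trajectory ends without padding. Two conventions the formula leaves
open are resolved as follows and exposed in the interfaces: the positive
and negative terms *sum force values* rather than counting samples of
each sign (with counting, the formula degenerates to a sign fraction);
and the frequency adjustment is the per-frame product
contact × correction factor averaged over frames, with the raw frequency
always reported alongside. Both conventions make the adjusted frequency
lie in [−1, 1] with |adjusted| ≤ raw.

## Logistic residue importance

Adjusted frequencies across (molecule, variant, replicate) simulations are
assembled into a design matrix (residue columns sorted by residue number,
absent residues zero-filled, optional per-column z-scoring with the
population standard deviation; constant columns stay at zero). The
original analysis reports only that a logistic regression was used,
without regularisation or preprocessing details; the defaults here —
ridge penalty λ = 1, standardisation on, replicates as rows, one pooled
model across molecules and variants — are our choices, all configurable. The fit minimises mean cross-entropy plus (λ/2)‖β‖² with the
intercept unpenalised, by damped Newton iterations from a zero start; the
iteration map is symmetric, so flipping all labels exactly negates the
coefficients, and the fit is deterministic and permutation-invariant.
Coefficient signs classify residues as promoting (> 0) or counteracting
(< 0) transport with a 1e-10 dead zone — the computational analogue of the
blue-to-red coefficient colouring. The electronic binding-energy relation
is the subtraction `E_el = E_PL − (E_P + E_L)` with sign-based
classification; the quantum-chemical machinery that produces the
components is out of scope, they are inputs.

## The evolutionary gate profile

The screening pipeline keeps a sequence iff its length is between 950 and
1800 residues (inclusive) and it contains all four PDR signature motifs —
LLXGPP, GLXSS, GLDARXAAXVMR, VCTIHQP — with X matching any single residue;
rejection reasons name the first failing criterion. Database retrieval and
multiple alignment are external by design; the pipeline consumes FASTA /
aligned FASTA, and a self-contained Gotoh global aligner (BLOSUM62, affine
gaps) provides reference mapping when no MSA is given. The affine
convention is that a gap run of length L costs `gap_open + L·gap_extend`
(defaults −10, −0.5) — i.e. the first gap pays opening *and* extension —
with deterministic diagonal-up-left tie-breaking.

Gate positions 703/704 and 1374/1375 lie just outside the printed helix
segments (which end at 700 and 1371), so they are resolved through
alignment to a full reference. The bundled reference is a *synthetic*
AtABCG36-like scaffold (`abcg36_scaffold()`): the four printed segments at
their exact coordinates, F703/L704/F1374/F1375 at the gate, the PDR motifs
planted at fixed sites, deterministic random background elsewhere,
rejection-sampled so no motif occurs off-site. Occurrence tables keep gaps
as a 21st category in counts but exclude them from information content,
`R = log₂20 − H` bits; the WebLogo-style small-sample correction
(19/(2n ln 2)) is available but off by default, as the original analysis
does not state one. The consensus caller emits, per position, the top residue at
fraction ≥ 0.5, else "A/B" when the top two sum to ≥ 0.5 with each ≥ 0.2,
else "x" — thresholds chosen to reproduce the printed
"G F x x S/P R/K x x" shape on profiles that satisfy them.

## What the generators emulate — and what they do not

* `make_transport_labels()` transcribes the phenotype grid: IBA exported
  by every L704 variant but not A1357V; CLX only by Wt and L704Y; IAA
  gained by L704Y and L704S; indole only by L704Y. One sentence in the
  source Results contradicts this grid for L704F/CLX; the label table
  follows the abstract, the export figures and the Discussion.
* `make_pull_panel()` plants the seven promoting (I585, F698, L704, L705,
  Y1251, A1252, N1369) and four counteracting (F589, F592, I1259, N1260)
  residues on top of nine neutral background residues. Real
  contact-frequency magnitudes are not reported in the original analysis
  (the figures are colour maps); baseline 0.2, effect 0.3 and noise 0.05 are generator
  conventions chosen so recovery is neither trivial nor impossible. The
  "mechanistic" mode routes panels through actual pulls on matched
  landscapes instead of direct sampling; both modes order promoting vs
  counteracting mean frequencies the same way.
* `make_sequence_panel()` derives records from the scaffold core
  (substitution rate 0.1 outside protected sites, taxon-specific gate
  draws, variable unaligned C-terminal tails), so a trivial gap-padding
  yields a valid MSA and pairwise mapping is well-posed. The per-taxon
  gate distributions are round numbers qualitatively echoing the family
  contrasts (more L/V weight at 704 in Brassicaceae); they do not claim to
  reproduce the published bar charts. Sequence panels embody none of real
  protein evolution — no phylogeny, no indels inside the core, no
  composition bias — so passing tests demonstrate correctness of the
  pipeline's bookkeeping and statistics, not realism of the sequences.
* The recovery experiment for residue signs uses one replicate per
  molecule × variant cell (36 simulations) with both classes present;
  recovery is demanded in at least 18 of 20 seeded panels, and
  label-permuted panels must show no planted-vs-background separation.

## Problem sizes and numerical conventions

The calibration runs used throughout tests and the acceptance script:
2×10⁶ steps per walker (4 walkers) for FES recovery; 4×10⁷ unbiased steps
for the Boltzmann check; 2×10⁷ steps for the stiff-spring tracking check;
20 panels of 36 simulations for sign recovery; 1,000 sequences for the
filter benchmark; enumeration-oracle alignment checks exhaustively for all
pairs up to length 3 over a 4-letter alphabet plus 250 seeded random pairs
up to length 6. Tabulated landscapes take the right-segment derivative at
interior nodes (left at the last); degenerate inputs (empty hill logs,
all-gap columns, zero force windows, empty alignment pairs) return the
documented neutral values rather than erroring where a neutral value
exists.

## Known limitations

The engine is a one-dimensional caricature: no membrane, no protein
degrees of freedom, no orthogonal relaxation, and its friction/mass are
not calibrated to the all-atom system, so *times* mean nothing here —
only equilibrium and convergence properties do. Contact zones collapse
3-D geometry onto intervals of z. The logistic model is descriptive, not
predictive (no cross-validation by design). The conservation pipeline
implements only the printed screening criteria; the additional curation
behind the original 1,853-sequence panel is unpublished and out of scope.
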
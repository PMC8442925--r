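---
title: "Methods: designing coassembling beta-sheet peptide pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designing coassembling beta-sheet peptide pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and numerical choices behind `coapep`:
what is computed, under which assumptions, which parameters matter, and
what the synthetic test fixtures do and do not demonstrate.

## The design problem and the score

Two 11-residue peptides, a cationic chain A and an anionic chain B, are
sought such that the mixture coassembles into a two-layer β-sheet fibril
while neither chain self-assembles. Candidate pairs are ranked by

$$\Gamma = \Delta G_{\mathrm{binding}} + \lambda \, P_{\mathrm{agg}},$$

with lower values better. $\Delta G_{\mathrm{binding}}$ (kcal/mol) is the
per-peptide interaction energy of the pair threaded onto a fixed fibril
scaffold; $P_{\mathrm{agg}}$ (dimensionless) is the mean intrinsic
self-aggregation propensity of the two chains; $\lambda$ balances the two
terms (values of 3.0 and 4.0 are typical). `combine_score()` implements
the combination exactly; `score_pair()` produces the full breakdown.

Two choices here were genuinely open and are fixed as follows.
$P_{\mathrm{agg}}$ is reported *per peptide* as the **mean** of the two
chains, so that adding a chain-symmetric pair leaves the value on the
scale of a single peptide. $P_{\mathrm{agg}}$ is treated as
dimensionless and energy-compatible: the affine normalization (below)
puts typical values at $O(0.1)$, so with $\lambda$ of a few, the
aggregation term perturbs rather than dominates the binding term.

## Sequence space

The constraint set defines the search space (`sequence_pattern()`,
`composition_constraint()`, `residue_classes()`):

* HP pattern `PPPHPHPHPPP` — hydrophobic sites at 1-based positions 4, 6,
  8; all other sites polar-or-charged.
* Composition per chain: 3 hydrophobic, 3 polar, 5 charged; net side-chain
  charge +5 (chain A) / −5 (chain B). Termini are modeled as capped
  (acetyl/amide), so only side chains count toward the net charge.
* No cysteine (disulfides), proline (β-breaker) or glycine (flexibility).
* Default classes: hydrophobic {A, V, L, I, M, F, W, Y}, polar
  {S, T, N, Q}, positive {K, R}, negative {D, E}. Histidine is excluded
  from the defaults because its protonation near neutral pH is ambiguous;
  every set is configurable.

Charged residues are legal only at P sites and only with the sign of
their chain. `enumerate_space_size()` gives the exact count by the closed
form $\binom{n_P}{n_c}\,|C|^{n_c}\,|P|^{n_p}\,|H|^{n_H}$ per chain
(about $5.9\times10^7$ chains and $3.4\times10^{15}$ pairs under the
defaults). Published pool sizes for this kind of search depend on the
exact alphabet used and are not reproduced by any obvious choice here;
the package reports its own count and makes no claim of matching others.

## Binding-energy model

`binding_energy()` evaluates a residue-level reference energy model on
the scaffold geometry; every constant lives in `energy_params()`:

* **Backbone hydrogen bonds** — `hbond_energy` (default −1.5 kcal/mol)
  per registered bond; the scaffold registry pairs each strand with its
  in-sheet neighbors, one bond per residue. The term is
  sequence-independent and anchors the energy scale.
* **Side-chain contacts** — a symmetric 20×20 table applied to inter-chain
  centroid pairs within `contact_cutoff` (6.5 Å). The default table is
  generated from a documented mixing rule (a favorable product of positive
  Kyte–Doolittle hydropathies plus a −0.5 kcal/mol bonus for polar pairs,
  which also captures N⋯T-type side-chain hydrogen bonding). Any
  knowledge-based table with the same layout can be loaded from CSV.
* **Electrostatics** — Coulomb terms $332.06\,q_iq_j/(\varepsilon_{ij}
  r_{ij})$ over all inter-chain charged pairs, with a variable internal
  dielectric: $\varepsilon_{ij} = \max(\varepsilon_i, \varepsilon_j)$ by
  residue class (nonpolar 1, polar 2, charged 4). Taking the maximum makes
  any polar/charged partner screen the interaction, which avoids
  overestimating charge–charge attraction between the highly charged
  chains.
* **Desolvation** — a penalty (default +1.0 kcal/mol) per charged residue
  whose side-chain centroid lies inside the inter-sheet slab. Burial is
  decided geometrically (projection onto the inter-sheet axis between the
  two sheet mean planes), so the rule survives arbitrary rigid motions of
  the coordinates.

The total is divided by the number of peptides in the scaffold. The model
is deterministic, independent of slot enumeration order, and exactly
invariant under rigid motions; the test suite checks it against an
independently written all-pairs double-loop oracle at $10^{-9}$ relative
tolerance. Absolute values depend on these reference constants and are
not comparable to experimental binding free energies; only ordering and
arithmetic are load-bearing.

Side-chain centroids are placed along the sheet normal at per-residue
canonical distances with β-pleat parity (even positions face the opposing
sheet); there is no rotamer sampling.

## Aggregation propensity

`aggregation_propensity()` computes the per-residue profile

$$z_i = w_h\,\mathrm{KD}_i + w_b\,P^\beta_i - w_c\,|q_i|,$$

(Kyte–Doolittle hydropathy, Chou–Fasman β-sheet propensity, absolute
side-chain charge; unit weights by default), applies a centered moving
average (`window = 5`, truncated at the termini), averages over
positions, and maps through `gain * mean + offset` (defaults 0.25 and 0).
The gain simply scales typical 11-mer values into an $O(0.1)$ range
compatible with the score combination. Hydrophobic, β-prone, weakly
charged stretches score high; charge-rich sequences score low, matching
the intuition that like-charged chains resist self-assembly.

## Monte Carlo engine

`design_pairs()` runs Metropolis MC from a random valid pair. Moves
(probabilities 0.5/0.25/0.25 by default) are closed over the constraint
set by construction: mutation draws a different residue of the same class
(same charge sign on charged sites); intrachain exchange swaps two
same-class sites of one chain; interchain exchange swaps a hydrophobic or
polar residue between chains (charged residues are sign-locked to their
chain). The effective temperature defaults to 1.0 kcal/mol, constant; a
linear annealing schedule is available (`anneal_to`). One trial move per
step; rejected trials leave the state unchanged but are counted. The $k$
lowest-scoring distinct pairs are retained (default $k = 6$). Runs are
bit-reproducible from `rng_seed`.

Default run lengths are deliberately modest (hundreds to a few thousand
steps); the trace shows the expected sharp initial drop from a random
start followed by a fluctuating plateau, and the test suite asserts these
shape properties rather than any particular score value.

## Amyloidogenicity screen

`amyloid_profile()` implements the contact-scale rule: a peptide is
amyloidogenic if at least `min_run = 7` consecutive residues have
window-averaged scale values above `threshold = 21.4`. The window is 5
residues, centered, and terminal windows truncate (average over the
available residues) rather than pad — an 11-mer thus genuinely has 11
averaged positions. The packaged per-residue scale is an approximate
reconstruction of the published expected-contacts (8 Å) scale and is
shipped as a documented CSV; the classifier's logic is tested exclusively
against synthetic scales so its correctness does not depend on the
resource. With the packaged scale, all twelve designed chains classify
nonamyloidogenic, as expected for sequences carrying five charged
residues.

## Scaffold and assembly analysis

`build_scaffold()` constructs the idealized two-layer antiparallel
β-sheet: straight strands (no twist or pleat of the backbone trace),
4.8 Å strand spacing within a sheet, 10 Å sheet separation, 3.5 Å
Cα spacing, species alternating A,B,A,… along each sheet, adjacent
strands antiparallel, in-register face-to-face sheets parallel to each
other. Since only relative distances enter the score, omitting twist
costs nothing for a fixed-backbone design.

`partition_sheets()` links chains whose mean aligned Cα distance (the
minimum over direct and reversed residue pairing) is below 5.5 Å and
takes connected components. `neighbor_statistics()` ranks same-sheet and
cross-sheet neighbors by that distance. Because an interior strand's two
flanking strands are equidistant, "next-nearest" is defined as the next
*distance shell*: the closest chain more than `shell_tol = 1 Å` farther
than the nearest neighbor. β-sheet content counts a peptide as in-sheet
when it has a neighbor with at least 4 aligned Cα pairs within 6.0 Å.
All statistics are invariant under rigid motions and chain relabeling;
on the ideal scaffold they recover the architecture exactly, and they are
robust to 0.3 Å Gaussian coordinate noise.

## NMR quantification

`fit_peaks()` fits a polynomial baseline (default linear) plus analytic
peaks — pseudo-Voigt with fitted mixing by default — within user windows
by Levenberg–Marquardt least squares, initialized by smoothed local
maxima with a minimum-separation rule so noise spikes on one peak cannot
claim two slots. Parameter bounds keep widths positive and mixing in
[0, 1]; 1σ uncertainties come from the fit covariance. Windows that fail
to converge are reported with diagnostics without aborting the others.

`composition_from_areas()` converts the lysine Cγ (≈23 ppm) and
glutamate Cδ (≈181 ppm) reporter areas into the A:B ratio, dividing each
area by the number of contributing carbons on its chain (e.g. 5 K on a
design-4 chain A, 4 E on its chain B) — one carbon per residue, but
residue counts differ between designs, so the normalization uses the
actual sequences.

The synthetic-spectrum generator (`synth_spectrum()`) emulates what the
fitter must handle: analytic peak shapes, a linear baseline, and white
Gaussian noise. It does not emulate phase or baseline-roll artifacts,
spinning sidebands, $t_1$ noise, or overlapping background resonances of
real solid-state spectra, so recovery tests demonstrate correctness of
the estimator, not robustness to every experimental artifact. In the
recovery harnesses, SNR is defined relative to the weaker of the two
reporter peaks.

## Problem sizes and test design

The suite runs entirely from code-generated fixtures: scaffolds of 2
sheets × 6 strands (12 peptides × 11 residues), MC runs of 100–500 steps,
$10^4$ constraint-closure proposals, $10^5$ Metropolis draws for the
acceptance-rate check, 20-seed spectrum-recovery harnesses at SNR 50, and
a 200-seed uncertainty-coverage harness. These sizes make the full suite
run in well under a minute while leaving every statistical assertion at
3σ or better.

## Known limitations

* The backbone scaffold is fixed and idealized; sequence evolution cannot
  relieve strain or exploit backbone relaxation.
* The energy model is a residue-level reference architecture; its
  absolute scale is arbitrary, and no conformational sampling of side
  chains is performed.
* The aggregation propensity is sequence-intrinsic and
  position-independent beyond the windowing; it does not model
  concentration or pH.
* Assembly analysis requires only Cα traces, so its β-content is a
  contact/registry definition, not a dihedral (DSSP-style) one.
* The search explores a fixed-length, fixed-pattern space; variable
  lengths or patterns are structurally possible through the configuration
  but are untested defaults.
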
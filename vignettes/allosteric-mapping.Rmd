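---
title: "Mapping mutation-driven allosteric networks from difference density and local HDX-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mutation-driven allosteric networks from difference density and local HDX-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allonet)
```

# The problem

A point mutation at one site of a protein can reshape conformational
heterogeneity and backbone dynamics far from that site. Two measurements see
complementary slices of this allosteric response:

* **Room-temperature difference crystallography.** Two isomorphous crystals
  (wild type and variant) yield merged structure-factor amplitudes
  $F_{\mathrm{mut}}$ and $F_{\mathrm{WT}}$. The Fourier synthesis of the
  weighted amplitude differences, phased from a reference model, is a
  difference density map $\Delta\rho$ whose features mark everything that
  moved, appeared, or disappeared — across all timescales that crystals
  average over.
* **Local HDX-MS.** Backbone amide hydrogens exchange for deuterium at rates
  set by solvent access and hydrogen bonding. Peptide-level centroid masses
  across labeling times, for the same protein in solution, report on
  millisecond-to-second fluctuations. The mutant-minus-WT difference in
  percent deuteration localizes dynamic perturbations along the sequence.

`allonet` implements both arms as a reusable pipeline, reduces each to a
per-residue score track, thresholds and pools the tracks into a combined
residue network, and quantifies the overlap of that network with externally
supplied residue sets ("sectors", e.g. groups of coevolving residues) by
Jaccard ratios and one-sided hypergeometric tests.

# The crystallographic arm

## Scaling and weighting

The mutant amplitudes are first put on the reference scale by the scalar $k$
minimizing $\sum_h (k F_{\mathrm{mut},h} - F_{\mathrm{WT},h})^2$ over common
reflections (`scale_to_reference()`; a resolution-binned variant is available
behind the `bins` argument). Full anisotropic scaling is out of scope — the
synthetic data this package is validated on are generated on a common scale,
and external data are expected to arrive pre-scaled by a merging program.

For each common reflection, $\Delta F_h = F_{\mathrm{mut},h} -
F_{\mathrm{WT},h}$ with $\sigma_{\Delta F,h}^2 = \sigma_{\mathrm{mut},h}^2 +
\sigma_{\mathrm{WT},h}^2$, and the error-model weight

$$ w_h = \left[ 1 + \frac{\sigma_{\Delta F,h}^2}{\langle \sigma_{\Delta F}^2
\rangle} + \alpha \frac{\Delta F_h^2}{\langle \Delta F^2 \rangle}
\right]^{-1}, $$

with $\alpha = 0.05$ by default. The $\sigma$ term suppresses poorly measured
differences; the $\alpha$ term tempers outlier amplitudes that would
otherwise dominate the synthesis. With all $\sigma = 0$ and $\alpha = 0$
every weight is 1; with $\sigma = 0$ and $\Delta F^2$ at its mean, $w =
1/1.05$.

Phases come from a reference model (normally the refined WT structure) by
direct summation over atoms with the standard four-Gaussian-plus-constant
form factors and a single isotropic $B$. No bulk-solvent model is applied:
difference maps are dominated by local features, and the same convention is
used by the synthetic generator so analysis and generation stay consistent.
Only space group P 1 is handled; higher-symmetry data must be expanded to
P 1 beforehand.

## Map synthesis

`synthesize_map()` places $\{w\Delta F, \varphi\}$ on a reciprocal grid,
applies Friedel completion, and inverse-FFTs with $1/V$ normalization, so
amplitudes in electrons give $\Delta\rho$ in e^-^/Å^3^. The grid spacing is
at most $d_\mathrm{min}/3$ per axis (configurable), which also keeps every
index inside Nyquist — the synthesis is alias-free and obeys Parseval's
identity, both of which are asserted by the test suite.

## IADDAT

The map is reduced to residues by integrating absolute difference density
above a threshold: every voxel with $|\Delta\rho|$ above the noise threshold
(default 0.04 e^-^/Å^3^) lying within 1.5 Å of a protein heavy atom
(hydrogens and waters excluded; periodic minimum-image distances) is
assigned to the residue of the *nearest* such atom, ties resolved to the
lower (chain, residue number). A residue's score is the sum of $|\Delta\rho|$
over its voxels divided by its heavy-atom count; the denominator convention
is exposed (`denominator = "atoms" | "voxels" | "none"`) because the
per-residue averaging convention is not standardized across
implementations. Scores are normalized to $[0,1]$ with an optional display
cap at 0.3.

Two deliberate choices:

* **"Peaks" are voxels, not local maxima.** The score integrates all
  above-threshold density (that is what the acronym says); a local-maximum
  variant was considered and rejected as the default because integration is
  monotone in threshold and radius, which makes the score's behavior easy to
  reason about. The brute-force voxel-scan oracle in the tests checks exact
  agreement.
* **The scoring model is the reference (WT) structure.** Density from a
  side chain that *disappears* in the variant lies where the reference atoms
  were; scoring against the variant model would leave that density with no
  heavy atom within 1.5 Å and silently erase the strongest signal at the
  mutated site. Residue numbering is shared, so the per-residue track is
  directly comparable either way; `iaddat()` itself accepts any model.

Thresholds are interpreted in the map's own units: the synthetic pipeline
works in true e^-^/Å^3^, while external maps of unknown scale require the
user to supply an equivalent threshold.

# The HDX-MS arm

## From centroid masses to percent deuteration

For each peptide, uptake is the centroid-mass increase over the undeuterated
control. With a fully deuterated (FD) control, back exchange cancels in

$$ \%D = 100\,\frac{m_t - m_0}{m_{FD} - m_0}; $$

without one, uptake is normalized to the theoretical maximum
$n_\mathrm{ex} \times 1.006277\ \mathrm{Da} \times f_{D_2O}$ (default
$f_{D_2O} = 0.90$). The FD-corrected form is invariant under affine
recalibration of the mass axis, a property the tests exercise.

The number of exchangeable amides of a peptide excludes the N-terminal
residue, every proline (no amide NH), and the fast-back-exchanging amide
adjacent to the N-terminus — equivalently, the non-proline positions
3..L. Replicates are averaged with their sample standard deviation
reported. Values outside $[0, 100]$ by at most 5 points are kept with a
warning (noise does this); larger excursions fail QC and are dropped with a
record of the drop.

## Differences and residue projection

Mutant-minus-WT differences are an inner join on (span, timepoint), with the
sign convention that positive $\Delta\%D$ means faster exchange in the
mutant. Unmatched peptides go to a coverage report, and a Woods-plot table
(span midpoint vs difference) is emitted.

Commercial HDX software performs a proprietary "deconvolution" to residue
level; this package instead uses a transparent projection: each residue
receives the weighted mean of $\Delta\%D$ over the peptides whose
exchangeable positions include it, weighted by $1/n_\mathrm{ex}$ so short
peptides dominate. Residues measured by no peptide are *missing*, never
zero. An optional centered moving average (`window`, default 1 = off)
smooths the track; smoothing never invents coverage. Values within
$\pm 5$ points are tagged "neutral", mirroring the gray band convention of
difference strip plots; the band is display-only, not a significance test.

A greedy minimal spanning-peptide selection (maximize newly covered residues
per unit length, ties to the shorter then earlier peptide, followed by a
redundancy-pruning pass so the cover is minimal) is computed and reported
for single-peptide track displays. The pipeline's residue projection,
however, uses **all** shared peptides by default (`select_peptides =
FALSE`): the inverse-amide-count weights already favor short peptides, and
restricting to a minimal cover both discards independent measurements and
leaves systematic blind spots — the first two residues of every selected
peptide carry no amide signal, and in a minimal cover there is often no
other peptide to fill them.

# The combined network and sector overlap

Tracks are thresholded into residue sets — IADDAT $> 0.13$ on the normalized
scale, $|\Delta\%D| > 7$ points at 300 s — and pooled (set union) across
modalities and variants. The IADDAT cutoff follows the convention of reading
the printed network threshold on the same normalized 0–1 scale on which the
display cap 0.3 lives.

The overlap population (universe) defaults to the *measurable* residues:
modeled in the crystal structures and carrying an exchangeable amide of at
least one shared (both-state) peptide. This is the conservative choice — a
residue no experiment could have flagged should not inflate the population —
and it is configurable (`population = "full"`) and always reported.
Externally supplied sectors are intersected with the population before
testing, and that restriction is recorded in the set's provenance.

Overlap between the network $X$ and a sector $Y$ is summarized by the
Jaccard ratio $J = |X \cap Y| / |X \cup Y|$ and the one-sided upper-tail
hypergeometric probability $P(K \ge k)$ of drawing at least the observed
intersection when $|X|$ residues are drawn without replacement from the
population. The tail sum is evaluated in log-factorial space; the tests
check it against exhaustive enumeration of all draws for every population
size up to 12 and against the standard distribution function.

A note on calibration at small population sizes: with a population of a few
dozen residues the exact upper-tail p-value is a discrete statistic with
point masses of order 0.2–0.3. Its null distribution is therefore
*superuniform* (conservative — the rate of $p \le 0.05$ under the null does
not exceed 0.05, which the acceptance suite verifies) but visibly
non-uniform to a Kolmogorov–Smirnov test, whose distance from $U(0,1)$ is
bounded below by the largest point mass. Uniform-looking p-value
distributions should only be expected for populations large enough that the
hypergeometric support is fine-grained; at the 40-residue toy scale the KS
check fails by construction, not by miscalibration.

# The synthetic generator

Everything above is testable without any external data because the generator
produces paired inputs with known ground truth:

* **Toy crystal** (`make_toy_crystal()`): a poly-alanine-like helix of
  10–100 residues (default studies use 40) with backbone N, CA, C, O and
  three side-chain pseudo-atoms per residue, in an orthorhombic P 1 cell
  with ≥ 4 Å padding; a random 20-letter sequence (proline-poor, as natural
  sequences are) names the residues and drives the HDX arm.
* **Mutation-like edit** (`apply_mutation_like_edit()`): deletes the side
  chain at the mutated site, adds one ordered water at its centroid, and
  displaces the side-chain atoms of designated "tendril" residues by exactly
  0.5 Å in seeded random directions — the structural signature of a
  destabilizing substitution with a small allosteric relay.
* **Reflections** (`simulate_reflections()`): direct-summation amplitudes to
  $d_\mathrm{min} = 2.0$ Å with a uniform $B = 20$ Å$^2$ (typical of
  room-temperature data) and Gaussian noise $\sigma_F = 0.05\,F$ by default.
* **HDX tables** (`simulate_hdx_tables()`): a pepsin-like tiling (lengths
  5–15, three independent passes plus extra short peptides, roughly 4×
  redundancy — the redundancy of real digests), per-residue logistic uptake
  curves in log-time, timepoints 30–10,000 s with duplicates at 30 s and
  300 s, 90% D$_2$O, and a planted mutant-minus-WT difference attained
  exactly at 300 s and scaled smoothly at other times. Masses are emitted
  through the exact inverse of the FD-corrected %D formula, so the analyzer
  must reproduce the generator's peptide values to numerical precision.
* **Planted truth** (`planted_delta_track()`): the perturbation is
  segmental — every residue within one position of a perturbed center gains
  +15 points of exchange. The planted network is *defined by the
  perturbation itself* (the union of perturbed segments plus the edited
  residues), never by what a detection threshold would find; an earlier
  design that defined truth by half-maximum of a smooth bump was rejected
  exactly because it tied ground truth to detectability.

All randomness flows from one top-level seed through named substreams
(structure, mutation, reflections, peptides, kinetics, noise), so each stage
is independently reproducible and identical seeds give byte-identical
pipeline outputs.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: crystallographic refinement artifacts,
bulk solvent, anisotropic or per-atom disorder, non-P 1 symmetry, EX1
kinetics, peptide carry-over, isotope-envelope effects (the generator works
at centroid level), and real pepsin cleavage specificity. The toy network
statistics also live on a 40-residue chain, two orders of magnitude below a
real catalytic domain; the sector-overlap machinery is size-agnostic, but
p-value granularity is not (see above).

# Problem sizes and numerical choices

The shipped tests and the acceptance script use: 40-residue studies at
$d_\mathrm{min} = 2.0$ Å (about 8,000 unique reflections, map grids around
$100 \times 36 \times 36$), 25 seeded replicates for network-recovery rates
and 100 for sector-test calibration, and brute-force oracle grids up to
$32^3$. A full end-to-end study runs in about one second on one core.
Ties in voxel-to-atom assignment are broken toward the lower residue;
FFT dimensions are rounded up to 5-smooth integers; the weight formula's
mean-based terms drop out gracefully when a dataset carries no
uncertainties ($\langle\sigma^2\rangle = 0$). Degenerate inputs — all-zero
tracks, empty residue sets, peptides with no exchangeable amide — are
either well-defined no-ops or explicit errors, as documented per function.

# Worked example

```{r example, eval = FALSE}
sim <- simulate_study(seed = 7)
res <- analyze_study(sim$wt_refl, sim$mut_refl,
                     phase_model = sim$wt_model, score_model = sim$wt_model,
                     hdx_table = sim$hdx_table)
# residues the combined network recovered, vs the planted truth
sort(as.integer(sub("A:", "", res$network$members)))
sim$truth$planted_network
jaccard(res$network$members,
        intersect(paste0("A:", sim$truth$planted_network), res$population))
```

# Known limitations

* CSV is the only reflection interchange format (columns `h,k,l,F,SIGF`);
  binary MTZ and CCP4/MRC maps are not read or written.
* P 1 only; no symmetry expansion is performed internally.
* Single isotropic scale between datasets (optionally per resolution bin);
  no anisotropic or local scaling.
* The residue projection is a linear smoother, not a deconvolution: sharp
  single-residue features are attenuated by peptide-length averaging, which
  is why network thresholds are applied to the projected track rather than
  to per-peptide values.
* The hypergeometric test treats residues as exchangeable units; spatial
  autocorrelation of both networks and sectors is not modeled.
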
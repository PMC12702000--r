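# allonet

Dual-modality mapping of mutation-driven allosteric networks in a protein,
for structural biologists who have (a) paired room-temperature crystal
datasets for a wild-type protein and one or more point variants and (b)
local HDX-MS peptide tables for the same states — or who want to prototype
and validate such an analysis on fully synthetic data with known ground
truth.

## What it computes

**Crystallographic arm.** From merged amplitudes of an isomorphous pair,
the weighted difference map coefficients

    dF_h = F_mut,h - k F_WT,h
    w_h  = [ 1 + sig(dF_h)^2/<sig(dF)^2> + alpha dF_h^2/<dF^2> ]^-1,   alpha = 0.05

are phased from the reference model (direct summation, four-Gaussian form
factors) and Fourier-synthesized into a difference density map. The map is
reduced to residues by IADDAT — integration of absolute difference density
above threshold: every voxel with |d_rho| > 0.04 e-/A^3 within 1.5 A of a
protein heavy atom (waters excluded) is assigned to the nearest atom's
residue, and per-residue sums are averaged over heavy atoms and normalized
to [0, 1] (display-capped at 0.3).

**HDX arm.** Peptide centroid masses become back-exchange-corrected percent
deuteration, %D = 100 (m_t - m_0)/(m_FD - m_0), using fully-deuterated
controls (or the theoretical maximum at 90% D2O without them), with
exchangeable amides counted as the non-proline positions 3..L. Mutant - WT
differences at 300 s are projected to residue level by an
inverse-amide-count weighted mean over covering peptides.

**Network arm.** Residues with IADDAT > 0.13 (normalized) or |d%D| > 7
points are pooled into the combined network; its overlap with externally
supplied residue sectors is quantified by the Jaccard ratio
J = |X n Y| / |X u Y| and a one-sided upper-tail hypergeometric test
P(K >= k) over the measurable residue population.

**Synthetic module.** A seeded generator builds a toy P1 crystal, applies a
mutation-like edit (side-chain deletion + ordered water + 0.5 A tendril
shifts), simulates noisy reflections and pepsin-like HDX tables with a
planted exchange difference, and records the ground truth — so every stage,
and the whole pipeline, is testable offline.

## Worked example

```r
library(allonet)
sim <- simulate_study(seed = 7)        # 40-residue toy study, planted truth
res <- analyze_study(sim$wt_refl, sim$mut_refl,
                     phase_model = sim$wt_model, score_model = sim$wt_model,
                     hdx_table = sim$hdx_table)

head(res$iaddat_track[order(-res$iaddat_track$score), ], 4)
#>  resnum resname      score    display
#>      25     ASP 1.00000000 0.30000000
#>      10     ASP 0.61153119 0.30000000
#>      12     TYR 0.60382496 0.30000000
#>      30     ASN 0.57246291 0.30000000

sort(as.integer(sub("A:", "", res$network$members)))
#> 10 11 12 13 14 25 29 30 31
sim$truth$planted_network
#> 9 10 11 12 13 24 25 26 29 30 31
jaccard(res$network$members,
        intersect(paste0("A:", sim$truth$planted_network), res$population))
#> 0.6666667

sec <- planted_sector(sim, extras = 4, seed = 7)
hypergeometric_overlap(res$network,
                       restrict_to_population(sec, res$population),
                       res$population)
#> <overlap_result> combined_network vs planted_sector:
#>   |X|=9 |Y|=15 k=8 J=0.5 p=0.0009386 (N=38)
```

The mutated site (residue 25, side chain deleted in the variant) tops the
IADDAT track; the three tendril residues (10, 12, 30) follow; the combined
network recovers most of the planted perturbation (Jaccard 0.67), and a
sector containing the planted residues is significantly enriched
(p = 9.4e-4) while the same test on random sectors stays conservative.

A thin command-line wrapper with `simulate`, `diffmap`, `hdx`, and `run`
subcommands lives at `inst/scripts/allonet.R`; `run_pipeline()` is the
file-based entry point with config validation and a provenance manifest.

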
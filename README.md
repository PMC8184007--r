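# polkadots

Quantitative analysis and simulation of Bcl10 filament dynamics in
activated T cells.

When the T-cell receptor engages an antigen, the adaptor protein Bcl10
polymerizes on Carma1 nucleation seeds into micron-scale helical filaments
(the POLKADOTS signalosome) that relay the signal to NF-κB; at the same
time, autophagosomes attach to these filaments — preferentially near their
ends — and degrade them, shutting the signal down. `polkadots` provides
the computational toolbox for studying this interplay in 3D
super-resolution volumes and in silico:

* **Segmentation** of intensity z-stacks: isotropic cubic-spline
  resampling, per-channel thresholding, the 3×3×3 neighborhood filter
  (retain a voxel iff ≥ 8 of its 27 neighborhood positions are occupied),
  small-component removal, 26-connected labeling.
* **Skeleton analysis**: 3D medial-axis thinning that preserves topology,
  iterative pruning of spurs shorter than 6 voxels (150 nm), punctate
  classification (skeletons < 150 nm ≡ "P"), geodesic distance-from-end
  maps, and untangling of artifactual high-degree junctions by the
  minimum-bending-energy pairing of branches (11-point sphere fits scored
  by elastic energy 1/R²).
* **Colocalization**: autophagosome–filament contacts as voxel overlaps,
  one event per structure–vesicle pair, each localized by the shortest
  distance to a skeleton endpoint.
* **An image-based resampling null**: segmented autophagosomes are
  randomly rotated and re-placed uniformly inside the cell boundary
  (rejection on boundary violation or vesicle–vesicle overlap), contacts
  recomputed over 100 trials, and the observed cell compared against the
  per-cell null interval and pooled end-distance distribution.
* **A stochastic simulator** of nucleation-limited growth with
  autophagy-driven degradation: Carma1 sites activate at the immunological
  synapse, filaments cross a 50-monomer nucleation barrier (attachment
  probability `p_attach` below, `p_grow = 0.4` above), and autophagosomes
  attach, peel monomers from filament ends, or cut filaments in two, with
  the consumed daughter destroyed monomer by monomer. The analytic
  two-phase growth pmf — binomial below the barrier, a negative-binomial ×
  binomial convolution above it — is provided as `growthPmf()`.
* **A synthetic 3D cell generator** with exact ground truth (tubes from
  curvature-bounded random walks, spherical vesicles with controllable
  end-placement bias), used to validate every stage end-to-end.

## Worked example

```r
library(polkadots)
set.seed(7)

## a synthetic activated T cell with end-biased vesicles, analyzed blind
cell <- studyCell(7, "end_biased")
res <- analyzeCell(cell$filaments, cell$vesicles, cell$mask,
                   n_null_trials = 100)
print(res$summary)
#> CellSummary: 4 structures (0 puncta), 7 contacts (0 punctate)
print(res$null)
#> NullEnsemble: 100/100 trials, mean contacts 1.33,
#>   95% CI of mean [1.12, 1.54], trial interval [0, 4]
res$verdict$significant
#> [1] TRUE
res$verdict$ks$p.value
#> [1] 4.612997e-06
```

The cell truly has end-biased vesicles, and the analysis recovers both
signatures: 7 observed contacts against a null mean of 1.33 (outside the
[0, 4] null interval), and an end-distance distribution shifted toward
the filament tips (two-sample KS p ≈ 5e-6 against the pooled null).

```r
## growth-only population: puncta count anticorrelates with filament length
set.seed(7)
cells <- replicate(100, sampleInitialConditions(withAutophagosomes = FALSE),
                   simplify = FALSE)
pop <- runPopulation(cells, SimParams(pActivate = 0.5, pAttach = 0.1),
                     n_trials = 10, mode = "growth")
print(pop)
#> PopulationResult: 100 cells, end-state rho = -0.333

## the analytic two-phase growth distribution (barrier at 5 monomers)
round(growthPmf(20, 0:8, L0 = 5, p_attach = 0.3, p_grow = 0.8), 4)
#> [1] 0.0008 0.0068 0.0278 0.0716 0.1304 0.0577 0.0664 0.0744 0.0808
```

Cells that nucleate many filaments split the monomer pool more ways and
strand late-activating sites below the punctum scale, so puncta-rich
cells have shorter filaments — the negative correlation above. The pmf
shows the nucleation bottleneck: mass piles up just below the barrier
(x = 4), thins at the crossing, then spreads into the fast-growth phase.

See `vignettes/polkadots-methods.Rmd` for the full account of the models,
parameter choices and numerical decisions.

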
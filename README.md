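# patternblend

Complex, camouflaged animal skin patterns — labyrinthine ("Maze")
markings — keep reappearing across distantly related fish lineages while
differing sharply between close relatives. One mechanistic explanation is
**pattern blending**: when two species whose patterns sit at different
ends of a reaction-diffusion parameter axis hybridize (dark spots on a
light ground vs light spots on a dark ground), the intermediate parameter
values of the hybrid produce a *labyrinth* — a phenotype that is
intermediate in overall tone but *transgressive* in complexity.

`patternblend` implements that hypothesis end to end for R users working
in pattern formation, comparative phylogenetics or population genomics:

* **Reaction-diffusion simulator** — the two-factor Turing system
  `du/dt = R[(Au + Bv + C)|clip - Du] + Du∇²u`,
  `dv/dt = R[(Eu - F)|clip - Gv] + Dv∇²v`
  on grids, Fibonacci spheres and fused-blob ("metaball") meshes, with
  kinetic parameters graded along a blend axis for in silico
  hybridization (`simulate`, `make_metaball_mesh`,
  `assign_hybrid_gradient`, `simulate_blend_grid`).
* **Pattern metrics** — pattern lightness (unpigmented fraction) and the
  area-weighted isoperimetric pattern complexity score
  `PCS = 1 − Σᵢ wᵢQᵢ`, `Qᵢ = 4πSᵢ/Lᵢ²`, `wᵢ = Sᵢ/ΣS`
  (`quantify`, `extract_elements`, `pattern_complexity`).
* **Phylogenetic collocation** — genus-level co-occurrence of 11 binary
  pattern motifs scored by Jaccard, Sørensen-Dice, Simpson,
  log-likelihood, T and z measures, pairwise and against an anchor pair
  such as (Sp-D, Sp-L) (`aggregate_to_genus`, `association_screen`).
* **Introgression statistics** — frequency-based Patterson's D with
  block-jackknife z scores, the conservative trio statistic
  `D_min = min{|D(A,B;C,O)|, |D(A,C;B,O)|, |D(C,B;A,O)|}`,
  Holm–Bonferroni control, and interclass heterozygosity on
  ancestry-diagnostic sites (`patterson_d`, `d_min`,
  `interclass_heterozygosity`).
* **Correlated motif evolution** — the joint states of (Sp-D, Sp-L,
  Maze) as an 8-state continuous-time Markov chain on genus trees, with
  independent (6 rates), partially independent (10) and dependent (24)
  parameterizations, penalized-ML fitting, AIC/LRT or stepping-stone
  Bayesian comparison, and the Maze gain/loss rates a–h by spot-motif
  context (`fit_model`, `compare_models`, `maze_rate_summary`).
* **Synthetic data** — seeded generators for every input: annotation
  tables with a controllable blending dependency, birth–death trees with
  evolved motif states, admixed allele-frequency matrices, diagnostic
  genotypes for F1/F2 hybrids, and RD pattern images
  (`gen_annotation_table`, `gen_trait_tree`, `gen_genotypes`,
  `gen_pattern_images`).

## Worked example: an in silico hybrid

```r
library(patternblend)

# dark-spot -> light-spot gradient along a 64 x 192 grid, 2000 steps
st <- simulate_blend_grid(seed = 1)
blend_region_metrics(st)
#>   region pigmented_fraction lightness   pcs n_elements
#> 1  end_a              0.348     0.652 0.734         22
#> 2 center              0.501     0.499 0.879         30
#> 3  end_b              0.666     0.334 0.710         24
```

The dark-spot end is mostly light (lightness 0.65), the light-spot end
mostly dark (0.33), and the central hybrid region is *intermediate* in
lightness (0.50) but *more complex than either parent* (PCS 0.88 vs 0.73
and 0.71) — the blending signature. The same quantification applied to a
pure mid-gradient ("labyrinth") simulation gives lightness 0.50 and PCS
0.87.

And the genomic side of the same story — injecting 20% admixture from P3
into P2 across 50,000 sites in 50 jackknife blocks:

```r
patterson_d(gen_genotypes(50000, n_blocks = 50,
                          admixture_f = 0.2, seed = 1))
#> Patterson's D = 0.0158 (z = 5.63, 50 blocks, 50000 sites)
```

## Documentation

The methods vignette
(`vignettes/pattern-blending-methods.Rmd`) documents the model
assumptions, parameter defaults and units, numerical choices (clipping,
Laplacian calibration, contour smoothing), the design of the synthetic
study conditions, and known limitations.
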
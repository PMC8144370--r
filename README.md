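# clumpseq

Spatial reconstruction of rare intestinal secretory cell types from
sequenced multi-cell clumps.

## The problem and who this is for

Expression along the small-intestinal crypt–villus axis is zonated, but
single-cell approaches that reconstructed enterocyte zonation do not
transfer to the rare secretory lineages (goblet, Paneth, enteroendocrine,
tuft): too few cells, and position is destroyed by dissociation. Clump
sequencing sidesteps this by profiling small fragments of 2–10 attached
cells. The enterocytes in a clump carry the positional signal; any
secretory cell attached to them inherits it. This package, aimed at
computational biologists working with plate-based (e.g. MARS-seq) UMI
count data, implements the full inference chain:

1. **Clump zonation** — each clump's landmark-gene vector is correlated
   with a spatial reference of enterocyte zonation (zone 1 = crypt);
2. **Geometric classification** — per-type marker-sum Z-scores place
   clumps in PC space, where secretory-containing clumps lie on four rays
   through the origin; abundance-calibrated quotas keep calls precise;
3. **Per-type clump zonation tables** and extraction of secretory
   **landmark genes** by their profile center of mass,
   `COM = Σ Eᵢ·i / Σ Eᵢ`;
4. **Single-cell reconstruction** — each secretory cell gets a unit-less
   coordinate `η = Y/(X+Y)` from its crypt (X) and tip (Y) landmark
   sums; zone boundaries in η are chosen by grid search to minimize the
   median Euclidean distance (over secretory genes) between max-normalized
   single-cell and clump profiles; cells are binned and averaged into
   genome-wide zonation tables with Kruskal–Wallis p and BH q values;
5. **Validation** (COM rank correlation against coarse-grained clump
   tables on held-out genes), **robustness sweeps** over every registered
   threshold, two-dataset **merging**, temporal binning, and
   zone-dependent **ligand–receptor scoring**
   `Z_interaction = sqrt((Z_L^C1)² + (Z_R^C2)²)`.

A synthetic crypt–villus tissue simulator with complete ground truth
(zonated expression, clump composition, multinomial UMI sampling, empty-
well ambient background) makes every stage testable end to end; see the
methods vignette (`vignettes/clumpseq-methods.Rmd`) for the model and all
parameter choices.

## Worked example

```r
library(clumpseq)
cfg <- clumpseq_config()                      # all pipeline defaults
sim <- simulate_clumpseq(cfg, seed = 42, n_cells = 600, n_clumps = 6000)
#> count_matrix: 450 genes x 6064 wells (clump=6000, empty=64)

prep <- prepare_pipeline(sim, cfg)            # background, QC, typing
zonation <- run_clump_zonation(prep)
zonation$landmarks
#> landmark_set (enterocyte): 30 crypt, 24 mid, 30 tip
head(zonation$assignment[!zonation$assignment$discarded, ], 3)
#>      clump_id zone correlation discarded reason
#> 1 clump_00001    1   0.8627238     FALSE
#> 2 clump_00002    3   0.7165219     FALSE
#> 3 clump_00003    4   0.4630122     FALSE

zones <- setNames(zonation$assignment$zone, zonation$assignment$clump_id)
calls <- run_clump_classification(prep, zones)
table(calls$call)
#> enterocyte enteroendocrine  goblet  paneth  tuft
#>       5739               4     197      57     3

runner <- make_goblet_runner(prep, calls$clump_id[calls$call == "goblet"],
                             details = TRUE)
recon <- runner(cfg)
round(recon$boundaries, 3)                    # optimized eta zone limits
#> 0.000 0.094 0.494 0.544 0.894 1.000
recon$table
#> zonation_table: 450 genes x 5 zones; 450 genes tested
sum(recon$table$q < 0.05, na.rm = TRUE)       # significantly zonated genes
#> 163

val_genes <- select_validation_genes(recon$table, recon$clump_table_coarse,
                                     recon$sec_landmarks, recon$sec_genes,
                                     cfg$validation$sem_cutoffs$goblet, cfg)
v <- validate_reconstruction(recon$table, recon$clump_table_coarse, val_genes)
#> validation: Spearman R = 0.87 over 35 held-out genes (p = 9.7e-12)
```

The zone assignments map each clump onto the crypt (zone 1) to villus-tip
(zone 7) axis with its best correlation; the classifier's quota step is
why secretory calls are rare but precise; the optimized η limits define
the five reconstruction zones; and the held-out COM correlation is the
package's internal consistency check between the single-cell and
clump-based views of the same tissue.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/clumpseq.R simulate --seed 1 --out-dir sim_out
Rscript inst/cli/clumpseq.R run      --seed 1 --out-dir run_out
Rscript inst/cli/clumpseq.R robustness --parameter discard_fraction \
        --seed 1 --out-dir rob_out
```

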
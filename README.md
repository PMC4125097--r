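# pulsechase

Histone-variant turnover inference from genetic pulse-chase ChIP-seq time
courses, with a ground-truth forward simulator for end-to-end validation.

## The problem

Induce an epitope-tagged histone variant at *t* = 0 in asynchronously
cycling cells and map it by anti-tag ChIP-seq at 3, 6 and 12 h (plus an
uninduced control). Loci that exchange histones rapidly
(replication-independently, at rate *k* per hour) acquire tag in every
cell almost immediately; loci fed only by replication acquire it slowly,
as cells transit S phase. Because sequencing depth is normalized away
(ppm), rapid-turnover loci show **high relative enrichment early that
falls by 12 h**, while stable domains rise. The per-locus statistic

    score = log2( (s3 + eps) / (s12 + eps) )        # fast-positive

ranks loci by turnover relative to the genomic average, and with eps = 0
its pairwise differences are *exactly* invariant to how each time point
was depth-normalized — the property that makes hot/cold calls robust.

The package implements the complete analysis used for this assay type:

- read collapsing by `(chrom, start, strand)`, 3′ extension to 150 bp,
  ppm-normalized 20-bp coverage bins (`coverage_pipeline()`)
- 100-kb tile tables with gene counts, top-1%-of-control artifact
  masking and zero-read masking (`make_tile_table()`, `mask_tiles()`)
- strand-aware ±4-kb TSS matrices, flank normalization, metaprofiles,
  −600..+600 bp promoter summaries, k-means (k = 4) clustering with
  centroid merging, expression quintiles (`tss_matrix()` & friends)
- turnover scores, hot/cold decile classes, normalization-invariance
  audit, two-state histograms (`turnover_score()`, `classify_deciles()`,
  `invariance_audit()`)
- ES-vs-MEF style comparisons: promoter selection (≥ 0.1 in either
  state), per-state normalization, delta sorting with a turnover running
  window, tile delta vs gene density (`run_turnover_analysis()`)
- a forward simulator of tag incorporation in an asynchronous cycling
  population — exchange ODE `dF/dt = k (p(t) − F)` plus a replication
  reset `F ← r F + (1 − r) p(t_rep)`, phase-averaged over the cell
  cycle — that generates BED reads with known per-locus truth
  (`sim_config()`, `simulate_experiment()`)

See `vignettes/pulsechase-methods.Rmd` for the model, parameter meanings
and design decisions.

## Worked example

A reduced synthetic study (one 4-Mb chromosome, 300 genes, 3×10⁵ reads
per sample; the defaults are 2×12 Mb, 1800 genes, 2×10⁶ reads):

```r
library(pulsechase)
cfg <- sim_config(seed = 7, n_chroms = 1, chrom_length = 4e6,
                  n_genes = 300, depth = 3e5)
st <- run_simulation_study(cfg)
print(st)
#> sim_study (ES mode, seed 7, config 4612145a)
#>   promoters scored: 181
#>   Spearman(score, true k): 0.820
#>   designed-hot recovery (k >= 1/h): 83.5%
#>   turnover-expression r: 0.729
#>   normalization-invariance audit (eps = 0): 6.66e-16
round(st$class_signal, 1)
#>              no_dox     t3     t6    t12
#> hot_promoter 1059.3 6068.7 5645.8 3985.0
#> cold_block    486.6  320.4  349.6  464.0
#> background    514.3  742.2  798.0  793.2
```

Reading the numbers: the measured turnover score rank-correlates 0.82
with the true exchange rate, and 83.5% of the loci designed to exchange
rapidly (k ≥ 1/h) are recovered at the top of the score ranking. The
class-level ppm trajectories show the signature the score exploits:
promoters engineered hot *fall* in relative enrichment from t3 (6069) to
t12 (3985) while zero-exchange desert blocks *rise* (320 → 464); the
uninduced control is flat (~500 everywhere) because it contains only
non-specific pulldown. The invariance audit confirms that rescaling
either time point cannot change any pairwise score difference.

Individual gene calls:

```r
head(classify_deciles(st$gene_turnover), 3)
#>          id        s3       s12      score decile_class
#> 1 gene00001  443.0658  718.3927 -0.6972393         cold
#> 2 gene00002 5350.1457 3397.8049  0.6549736 intermediate
#> 3 gene00003 3804.7158 3189.9879  0.2542370 intermediate
```

For user-supplied data, describe each experiment in a manifest (DCF text
file or `pc_manifest()`) pointing at 6-column BED reads and an
annotation TSV, then `run_turnover_analysis(manifest_ES, manifest_MEF)`.
A command-line front end covers the same stages:

```sh
Rscript -e 'pulsechase::pulsechase_cli()' simulate --seed 1 --out simdir
Rscript -e 'pulsechase::pulsechase_cli()' turnover \
    --t3 simdir/reads_t3.bed --t12 simdir/reads_t12.bed \
    --annotation simdir/annotation.tsv --out turnover.tsv
```

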
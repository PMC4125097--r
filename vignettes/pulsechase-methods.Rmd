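---
title: "Inferring histone-variant turnover from pulse-chase ChIP-seq: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring histone-variant turnover from pulse-chase ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsechase)
```

## The assay and the inference problem

A doxycycline-inducible, epitope-tagged histone variant is switched on at
$t = 0$ in an asynchronously cycling cell population, and anti-tag ChIP-seq
maps where the tagged protein has been incorporated at a few later times
(here 3, 6 and 12 h, plus an uninduced control). Two deposition routes
compete. Replication-independent *exchange* replaces nucleosomal histones
with tagged ones from the soluble pool at a locus-specific rate $k$, in
every cell, from the moment the pool carries tag. Replication-*coupled*
deposition happens only when a cell's replication fork passes the locus,
which in an asynchronous population occurs in a small, slowly accumulating
fraction of cells.

Sequencing depth is normalized away (we scale every sample to parts per
million, ppm), so a sample measures *relative* enrichment. Early in the
time course little total tag is incorporated and rapidly exchanging loci
soak up a large share of the read budget; late in the course
replication-coupled deposition has spread tag everywhere and the same hot
loci command a smaller share. Rapid-turnover loci therefore *fall* in
relative enrichment from $t=3$ to $t=12$ h while stable loci rise, and the
statistic

$$\mathrm{score} = \log_2\!\frac{s_3 + \varepsilon}{s_{12} + \varepsilon}$$

(fast-positive; $s_t$ the ppm-scale promoter or tile signal at time $t$)
ranks loci by turnover *relative to the genomic average*. With
$\varepsilon = 0$, rescaling either time point by any positive constant
shifts all scores equally, so pairwise score differences — and hence
hot/cold calls — are exactly invariant to the normalization convention.
`invariance_audit()` measures this identity and quantifies the small
distortion the default pseudocount ($\varepsilon = 0.01$ ppm units,
configurable) introduces.

## The single-cell kinetic model

The simulator formalizes the cartoon above. For one cell and one locus,
the tagged chromatin fraction $F$ obeys

$$\frac{dF}{dt} = k\,\bigl(p(t) - F\bigr), \qquad F(0) = 0,$$

where $p(t)$ is the tagged fraction of the soluble pool, and at each
replication of the locus

$$F \leftarrow r\,F + (1 - r)\,p(t_{\mathrm{rep}}),$$

with retention $r$ (default 0.5: parental histones distribute to both
daughters, the other half of nucleosomes are assembled fresh from the
pool). These two rules — exponential relaxation toward the pool between
replications, a convex-combination reset at replication — are this
package's formalization; the source assay constrains neither functional
form, so both are configurable.

Specific choices, all visible in `pool_params()`, `cell_cycle_params()`
and `sim_config()`:

* **Pool curve** $p(t) = 1 - e^{-(t - t_0)/\tau}$ for $t > t_0$, else 0;
  defaults $t_0 = 1$ h, $\tau = 2$ h reproduce tag protein becoming
  robustly detectable within 2–3 h of induction. $\tau = 0$ gives a step
  pool, used by the closed-form tests. The true pool curve is
  unconstrained by the assay (only Western-blot snapshots exist), so it
  must remain a configuration choice.
* **Cell cycle**: length $T = 12$ h for the stem-cell state and 20 h for
  the fibroblast state. These are order-of-magnitude placeholders, *not*
  measured values. One replication event per locus per cycle at a fixed
  offset in S phase (mid-S by default); per-locus replication-timing
  heterogeneity is available (`rep_timing_heterogeneity = TRUE`) but off
  by default, since no timing data constrain it.
* **Population average**: a measurement is
  $\mathrm{occupancy} \times \mathbb{E}_\phi[F]$ over cell-cycle phases
  $\phi \sim \mathrm{Uniform}[0, T)$, computed by midpoint quadrature on a
  $\ge 256$-point phase grid (512 by default). Replication events strictly
  *before* the measurement instant count; with the midpoint grid this
  makes the textbook checks exact: for $k = 0$, a step pool and $r = 0.5$,
  $\mathbb{E}[F] = 0.25$ at $t = T/2$ and $0.5$ at $t = T$.
* The ODE is solved with an exact piecewise-analytic propagator (with a
  guarded $k \to 1/\tau$ resonance branch); tests verify it against a
  forward-Euler integrator at $\Delta t = 10^{-3}$ h to $10^{-4}$
  absolute.

## What the synthetic genome emulates — and what it does not

`make_genome()` builds chromosomes from 100-kb units: contiguous
**gene deserts** ($\ge 500$ kb, zero genes, 20% of units by default),
**gene-rich blocks** (1 Mb runs with 10-fold gene-placement weight, 10% of
units) and normal territory. Expression is a two-component normal mixture
(silent mode $\mathcal{N}(4, 1)$, expressed mode $\mathcal{N}(9, 1.5^2)$,
35% silent) in log2-intensity units. `assign_kinetics()` then lays down:

* a `hot_promoter` locus (1.2 kb on the TSS, occupancy 3) per expressed
  gene, with $k$ a *deterministic* increasing logistic function of
  expression spanning `k_range` (default 0–2 /h). Determinism makes the
  expression→rate coupling exactly monotone, which the contract demands;
  biological scatter around that coupling is what the Poisson read noise
  then produces in the measured score.
* `cold_block` loci ($k = 0$, occupancy 1.2) tiling the deserts — the
  stable, replication-fed domains.
* `background` loci ($k = 0.05$/h, occupancy 1) tiling everything else.
* a few `artifact` loci with large non-specific pulldown weight in every
  sample including the uninduced control. This class extends the stated
  truth schema, deliberately: without something spuriously enriched in
  the no-dox data, the top-1% artifact mask downstream would have nothing
  real to do.

In the fibroblast ("MEF") mode, promoter rates are shrunk 0.15 of the way
from background (dampened promoter turnover), desert blocks double their
occupancy, and gene-free or desert-flanking background windows convert to
cold blocks — differentiation spreads stable blocks into gene-poor
territory.

Reads are Poisson: locus $i$ receives
$\mathrm{Poisson}(\mathrm{depth} \cdot w_i / \sum_j w_j)$ occurrences with
$w_i = (\mathrm{signal}_i + \mathrm{nonspec}_i)\,\mathrm{width}_i$,
uniform fragment starts, random strand. Fixing the total at `depth`
(default $2 \times 10^6$) per sample reproduces exactly the
depth-normalization phenomenology the score exploits. **Not** modeled: DNA
sequence, GC/mappability bias (the tile mask is the guard, as in the real
analysis), nucleosome positioning, diploidy, and the genome-wide split
between replication-coupled and independent deposition (never quantified
by the assay; exposed as configuration but uncalibrated). A green
simulation test therefore establishes the pipeline's arithmetic and the
direction of population-level effects, not realism of read-level noise.

## The processing pipeline

Coordinates are 0-based half-open throughout; BED input is read
accordingly.

1. **Collapse** identical alignments by `(chrom, start, strand)`, keeping
   summed occurrence counts. (The original procedure collapses raw reads
   by sequence before alignment; operating on aligned records of
   fixed-length reads, position is the sequence.)
2. **Extend** each alignment 3′-ward to 150 bp, clipped at chromosome
   ends.
3. **Bin** occurrence-weighted per-base fragment coverage into 20-bp bins
   and scale to ppm of the genome-wide total. The exact conservation rule
   $\sum \mathrm{bins} = 10^6 \sum (\mathrm{occ} \times \mathrm{len}) /
   \mathrm{total\ occ}$ is asserted in tests. Per-base accumulation (not
   once-per-bin fragment counting) was chosen because the summary being
   binned is positional read occurrence; the conservation rule only holds
   under this choice. The normalization base is the genome-wide total;
   normalizing within the TSS window set would be the alternative
   reading, and differs by a constant per sample, which the score's
   invariance makes immaterial for relative calls.
4. **Tile** into non-overlapping 100-kb tiles (trailing partial tiles
   dropped so sums stay comparable), count TSSs per tile (half-open:
   boundary TSS goes to the following tile). **Mask** the top
   $\lceil 0.01 n \rceil$ tiles by uninduced-control signal (ties broken
   by genomic order; tiles with zero control signal are ineligible) and
   zero-read tiles. Masks annotate, never delete, rows.
5. **TSS matrices**: 400 bins of 20 bp spanning ±4 kb, minus-strand rows
   flipped so positive x is downstream of transcription (standard
   metagene convention; the source is silent on orientation but the flip
   is testable and is asserted). Windows are grid-aligned at the bin
   below the TSS, so a TSS not on the 20-bp grid is registered with
   sub-bin (<20 bp) jitter. Out-of-chromosome cells are missing, not
   zero.
6. **Flank normalization** divides by the row (or group-average) mean
   over −4..−2 kb and takes log2; the alternative −2.5..−1.5 kb window
   used for grouped time-course averages is a parameter, since the two
   conventions genuinely differ in the source material. Values are
   floored at a 0.01 pseudocount before the log; rows whose flank mean is
   at or below the pseudocount are flagged out.
7. **Promoter summary**: mean over the 60 bins spanning −600..+600 bp.
   The mean (not the sum) keeps the 0.1 enrichment threshold used for
   cross-state gene selection independent of bin count; the two differ
   by the constant 60.
8. **Clustering**: k-means ($k = 4$, fixed seed, 10 starts) with merging
   of centroid pairs at Pearson $r \ge 0.90$ (transitively), reproducing
   the observed 4→3 cluster collapse. The merge criterion is invented
   here; 0.90 is a parameter, and flat centroids (zero variance) are
   treated as identical shapes.

## Turnover scoring and comparisons

`turnover_score()` keeps the fast-positive orientation internally and
converts on output only (`write_turnover_table(orientation =
"slow-positive")`), because the source material uses both orientations in
different displays and sign bugs are the cheapest way to ruin such an
analysis. The $t = 6$ h signal is carried but never scored; it serves as a
monotonicity diagnostic. Decile classification takes the top and bottom
$\lfloor n/10 \rfloor$ by score, ties broken by stable id order, hot
assigned before cold.

For two cell states, genes are kept when either state's promoter summary
reaches 0.1 (boundary inclusive); summaries are then normalized by each
state's mean unmasked-tile signal ("relative to the average level in the
corresponding cell type" — the base is not further specified at the
source, so the mean unmasked tile is this package's definition), and the
delta is `MEF − ES` (gain-positive; the convention is stamped on every
output). Promoter loss in the differentiated state is known to be
overestimated under genome-wide normalization when total abundance rises;
both normalizations are surfaced rather than inventing a correction.

## Validation: what the simulation study asserts

`run_simulation_study()` pushes simulated reads through the full pipeline
and reports:

* `spearman_score_vs_k`: rank correlation between the measured gene score
  and the true promoter $k$ (≥ 0.8 at default scale).
* `hot_recovery`: of the loci *designed* to exchange rapidly
  ($k \ge 1$/h), the fraction ranked within the top $n_{\mathrm{designed}}$
  scores. This is the operative recovery definition because the stricter
  one — reproducing the truth's top-decile-by-$k$ exactly — is limited by
  an identifiability fact worth stating plainly: as $k$ grows, $F(3)$
  approaches the pool fraction and the score saturates, so the very
  hottest loci become mutually indistinguishable at any sequencing depth.
  The strict overlap is still reported as `hot_decile_overlap`
  (diagnostic only; ~0.5 at default scale).
* `invariance_audit`: exactly zero (to machine precision) at
  $\varepsilon = 0$.
* class-level ppm trajectories (hot falls, cold rises, background ~flat
  between $t = 3$ and $t = 12$), computed over truth loci not overlapping
  an artifact.

Numerical conventions worth knowing: derived seeds for each stage are
hashed from the user seed and stay below $2^{31}$; k-means degrades $k$
to the number of distinct rows when profiles are degenerate; zero total
signal, empty anchor sets, sub-decile locus counts, and mismatched tile
grids are hard errors, not warnings.

## Known limitations

* The score is relative; no absolute rates in hours$^{-1}$ are estimated,
  by design.
* Promoter windows overlap background loci, so measured promoter signal
  includes a locus-unspecific floor; this compresses, but does not
  reorder, the score–$k$ relationship.
* The simulator's MEF mode encodes the *direction* of the differentiated
  state's changes (dampened promoter turnover, desert gains), with
  magnitudes chosen once as plausible rather than fitted — there is
  nothing to fit them to without the deposited sequencing data.
* Heatmap color scaling defaults to global (1st–99th percentile) with a
  per-row option; the source's choice is unstated.
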
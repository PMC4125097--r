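# Parameter objects for the forward simulator: the soluble-pool induction
# curve, the cell cycle, and the whole-experiment configuration.

#' Soluble-pool induction parameters
#'
#' Fraction of the free histone pool that carries the epitope tag at time
#' `t` after induction. The default functional form is a saturating
#' exponential, `p(t) = 1 - exp(-(t - t0)/tau)` for `t > t0` and 0 before;
#' `tau = 0` gives a step pool (`p = 1` for `t > t0`), convenient for
#' closed-form checks. Tag protein is robustly detectable within 2-3 h of
#' induction in this system, which the defaults (`t0 = 1`, `tau = 2`)
#' reproduce: p(2) ~ 0.39, p(3) ~ 0.63.
#'
#' @param t0 induction delay in hours (>= 0); no tagged protein before t0.
#' @param tau rise time in hours (>= 0); 0 means a step pool.
#' @return object of class `pool_params`.
#' @export
pool_params <- function(t0 = 1, tau = 2) {
  stopifnot(is.numeric(t0), length(t0) == 1, t0 >= 0,
            is.numeric(tau), length(tau) == 1, tau >= 0)
  structure(list(t0 = t0, tau = tau), class = "pool_params")
}

#' Cell-cycle parameters
#'
#' Cycle length, S-phase window, and the parental-histone retention
#' fraction applied when a locus replicates. At replication the tagged
#' fraction is reset to `r * F + (1 - r) * p(t_rep)`: half of the
#' nucleosomes are parental (retention `r`, default 0.5 for dispersive
#' segregation of old histones to both daughters), the other half are
#' assembled de novo from the pool.
#'
#' Defaults describe rapidly cycling embryonic stem cells (12-h cycle,
#' long S phase); `cell_cycle_params(T = 20, s_start = 6, s_end = 14)` is
#' the fibroblast placeholder. Neither cycle length is a measured value
#' from the assay; they are order-of-magnitude defaults and fully
#' configurable.
#'
#' @param T cycle length in hours (> 0).
#' @param s_start,s_end S-phase window within `[0, T)`, `s_start < s_end`.
#' @param retention parental tagged fraction kept at replication, in \[0,1\].
#' @return object of class `cell_cycle_params`.
#' @export
cell_cycle_params <- function(T = 12, s_start = 2, s_end = 10, retention = 0.5) {
  stopifnot(is.numeric(T), length(T) == 1, T > 0,
            is.numeric(s_start), is.numeric(s_end),
            s_start >= 0, s_start < s_end, s_end <= T,
            is.numeric(retention), retention >= 0, retention <= 1)
  structure(list(T = T, s_start = s_start, s_end = s_end,
                 retention = retention),
            class = "cell_cycle_params")
}

#' Simulation configuration
#'
#' Single source of truth for a synthetic pulse-chase experiment: the
#' synthetic genome layout, the ground-truth kinetic parameters, the
#' sequencing model, and the cell state ("ES" or "MEF").
#'
#' Genome layout: each chromosome is segmented into 100-kb units that are
#' gene desert (no genes; contiguous runs of at least 500 kb), gene-rich
#' (gene placement weight `rich_weight` relative to normal units), or
#' normal. Expression is a two-component normal mixture (silent vs
#' expressed modes), mimicking log2 microarray intensities.
#'
#' Kinetics: every expressed gene gets a "hot promoter" locus (1.2 kb
#' centered on the TSS) whose exchange rate is a deterministic increasing
#' logistic function of expression spanning `k_range`; gene deserts are
#' tiled by zero-exchange "cold blocks"; everything else is background
#' with slow exchange. In MEF mode promoter rates are shrunk toward the
#' background rate (`mef_promoter_shrink`) and desert blocks gain
#' occupancy (`mef_desert_gain`), encoding the differentiated state:
#' dampened promoter turnover, Macro gains over gene-poor regions.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param mode `"ES"` or `"MEF"`.
#' @param n_chroms,chrom_length synthetic chromosome count and length (bp).
#' @param n_genes total genes to place.
#' @param desert_frac fraction of 100-kb units that are gene desert.
#' @param rich_frac fraction of units that are gene-rich.
#' @param rich_weight gene-placement weight of rich units (normal = 1).
#' @param expr_silent_frac,expr_means,expr_sds silent-mode fraction and the
#'   two mixture components (log2-intensity units).
#' @param expressed_threshold expression above which a gene is "expressed"
#'   and receives a hot-promoter locus.
#' @param k_range promoter exchange-rate range in events/hour.
#' @param coupling expression-to-rate coupling coefficient in \[0,1\]
#'   (1 = full logistic span, 0 = no coupling).
#' @param k_background,k_cold background and cold-block exchange rates (/h).
#' @param occ_promoter,occ_background,occ_cold relative nucleosome
#'   densities of the three locus classes.
#' @param promoter_width hot-promoter locus width (bp, centered on TSS).
#' @param background_tile,cold_tile locus widths used to tile non-promoter
#'   regions and deserts (bp).
#' @param nonspec non-specific pulldown weight per bp (the no-dox signal
#'   floor present in every sample).
#' @param n_artifacts,artifact_width,artifact_weight spuriously enriched
#'   loci present in all samples including no-dox; these are what the
#'   top-1% tile mask is designed to catch.
#' @param mef_promoter_shrink MEF-mode shrinkage of promoter rates toward
#'   background (0 = fully background, 1 = unchanged).
#' @param mef_desert_gain MEF-mode multiplier on desert-block occupancy.
#' @param depth expected aligned-read occurrences per sample.
#' @param timepoints hours of induction per sample; 0 is the no-dox control.
#' @param fragment_length,read_length sonicated fragment and read length (bp).
#' @param bin_size coverage bin width passed to downstream processing (bp).
#' @param rep_timing_heterogeneity if TRUE each locus draws its replication
#'   offset uniformly within S phase; if FALSE (default) all loci replicate
#'   at mid-S.
#' @param pool,cell_cycle [pool_params()] / [cell_cycle_params()] objects;
#'   `cell_cycle = NULL` picks the mode default (ES 12 h, MEF 20 h).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       mode = c("ES", "MEF"),
                       n_chroms = 2L,
                       chrom_length = 12e6,
                       n_genes = 1800L,
                       desert_frac = 0.2,
                       rich_frac = 0.1,
                       rich_weight = 10,
                       expr_silent_frac = 0.35,
                       expr_means = c(4, 9),
                       expr_sds = c(1, 1.5),
                       expressed_threshold = 6.5,
                       k_range = c(0, 2),
                       coupling = 1,
                       k_background = 0.05,
                       k_cold = 0,
                       occ_promoter = 3,
                       occ_background = 1,
                       occ_cold = 1.2,
                       promoter_width = 1200L,
                       background_tile = 10000L,
                       cold_tile = 50000L,
                       nonspec = 0.05,
                       n_artifacts = 2L,
                       artifact_width = 5000L,
                       artifact_weight = 10,
                       mef_promoter_shrink = 0.15,
                       mef_desert_gain = 2,
                       depth = 2e6,
                       timepoints = c(0, 3, 6, 12),
                       fragment_length = 150L,
                       read_length = 36L,
                       bin_size = 20L,
                       rep_timing_heterogeneity = FALSE,
                       pool = pool_params(),
                       cell_cycle = NULL) {
  mode <- match.arg(mode)
  if (is.null(cell_cycle)) {
    cell_cycle <- if (mode == "ES") cell_cycle_params()
                  else cell_cycle_params(T = 20, s_start = 6, s_end = 14)
  }
  stopifnot(inherits(pool, "pool_params"),
            inherits(cell_cycle, "cell_cycle_params"))
  if (!is.numeric(depth) || depth < 0) stop("`depth` must be >= 0")
  if (any(timepoints < 0)) stop("`timepoints` must be >= 0")
  if (fragment_length <= 0) stop("`fragment_length` must be positive")
  if (length(k_range) != 2 || any(k_range < 0) || k_range[1] > k_range[2]) {
    stop("`k_range` must be nondecreasing and nonnegative")
  }
  if (desert_frac + rich_frac >= 1) {
    stop("`desert_frac` + `rich_frac` must be < 1")
  }
  cfg <- list(seed = as.integer(seed), mode = mode,
              n_chroms = as.integer(n_chroms), chrom_length = chrom_length,
              n_genes = as.integer(n_genes),
              desert_frac = desert_frac, rich_frac = rich_frac,
              rich_weight = rich_weight,
              expr_silent_frac = expr_silent_frac, expr_means = expr_means,
              expr_sds = expr_sds, expressed_threshold = expressed_threshold,
              k_range = k_range, coupling = coupling,
              k_background = k_background, k_cold = k_cold,
              occ_promoter = occ_promoter, occ_background = occ_background,
              occ_cold = occ_cold,
              promoter_width = as.integer(promoter_width),
              background_tile = as.integer(background_tile),
              cold_tile = as.integer(cold_tile),
              nonspec = nonspec, n_artifacts = as.integer(n_artifacts),
              artifact_width = as.integer(artifact_width),
              artifact_weight = artifact_weight,
              mef_promoter_shrink = mef_promoter_shrink,
              mef_desert_gain = mef_desert_gain,
              depth = depth, timepoints = timepoints,
              fragment_length = as.integer(fragment_length),
              read_length = as.integer(read_length),
              bin_size = as.integer(bin_size),
              rep_timing_heterogeneity = isTRUE(rep_timing_heterogeneity),
              pool = pool, cell_cycle = cell_cycle)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %s mode, %d chrom(s) x %.3g bp, %d genes, depth %.3g, seed %d\n",
    x$mode, x$n_chroms, x$chrom_length, x$n_genes, x$depth, x$seed))
  cat(sprintf("  timepoints (h): %s; k range [%g, %g]/h; cycle T = %g h\n",
              paste(x$timepoints, collapse = ", "),
              x$k_range[1], x$k_range[2], x$cell_cycle$T))
  invisible(x)
}
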
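# Cross-cell-state comparison: which promoters to compare, per-state
# normalization, enrichment deltas sorted against turnover, and
# tile-level delta vs gene density.

#' Select promoters enriched in at least one cell state
#'
#' A gene is kept when its promoter summary reaches `threshold`
#' (inclusive) in either dataset — comparing only promoters that carry
#' signal somewhere avoids ratios of noise.
#'
#' @param summary_a,summary_b named promoter summaries over the same
#'   gene universe.
#' @param threshold minimum enrichment (ppm window mean), boundary
#'   inclusive.
#' @return character vector of retained gene ids (stable order of
#'   `summary_a`).
#' @export
select_expressed_promoters <- function(summary_a, summary_b,
                                       threshold = 0.1) {
  if (!setequal(names(summary_a), names(summary_b))) {
    stop("summaries cover different gene universes")
  }
  b <- summary_b[names(summary_a)]
  keep <- pmax(summary_a, b, na.rm = TRUE) >= threshold
  keep[is.na(keep)] <- FALSE
  pc_log("INFO", "select_expressed_promoters: kept %d/%d genes (>= %g)",
         sum(keep), length(keep), threshold)
  names(summary_a)[keep]
}

#' Normalize promoter summaries to the cell state's own average level
#'
#' Divides each gene's summary by the mean unmasked-tile signal of that
#' cell state, expressing enrichment relative to the state's average
#' rather than to genome-wide depth — the scale on which two states with
#' different total histone-variant abundance can be compared.
#'
#' @param summary named numeric promoter summaries.
#' @param tiles masked `tile_table` for the same cell state.
#' @return summaries in cell-state-relative units.
#' @export
celltype_normalize <- function(summary, tiles) {
  stopifnot(inherits(tiles, "tile_table"))
  ok <- tile_ok(tiles)
  if (!any(ok)) stop("no unmasked tiles to define the cell-type average")
  base <- mean(tiles$signal[ok])
  if (base == 0) stop("cell-type average signal is zero")
  summary / base
}

#' Build a two-state comparison table
#'
#' One row per selected gene: both (cell-type-normalized) summaries,
#' their delta (`b - a`, gain-positive in state b), and both turnover
#' scores.
#'
#' @param summary_a,summary_b named, cell-type-normalized promoter
#'   summaries.
#' @param turnover_a,turnover_b `turnover_table`s keyed by gene id.
#' @param genes gene ids to include (e.g. from
#'   [select_expressed_promoters()]).
#' @return data.frame of class `comparison_table` with columns
#'   `gene_id`, `summary_a`, `summary_b`, `delta`, `turnover_a`,
#'   `turnover_b`.
#' @export
comparison_table <- function(summary_a, summary_b, turnover_a, turnover_b,
                             genes = names(summary_a)) {
  ta <- turnover_a$score[match(genes, turnover_a$id)]
  tb <- turnover_b$score[match(genes, turnover_b$id)]
  out <- data.frame(gene_id = genes,
                    summary_a = unname(summary_a[genes]),
                    summary_b = unname(summary_b[genes]),
                    delta = unname(summary_b[genes] - summary_a[genes]),
                    turnover_a = ta, turnover_b = tb)
  out <- out[is.finite(out$delta), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Sort genes by enrichment delta with a turnover running window
#'
#' Stable sort by `delta` (loss in state b first), then a centered
#' running-window mean of the state-a turnover score along the sorted
#' order — the trace that reveals whether genes losing the variant in
#' the second state are the dynamically exchanging ones in the first.
#'
#' @param comparison a `comparison_table`.
#' @param window running-window size in genes (clipped to the table
#'   size).
#' @return the table sorted by delta, with a `turnover_a_running`
#'   column.
#' @export
delta_sort_report <- function(comparison, window = 100L) {
  stopifnot(inherits(comparison, "comparison_table"))
  n <- nrow(comparison)
  if (n == 0) stop("empty comparison table")
  if (window > n) window <- n
  out <- comparison[order(comparison$delta), , drop = FALSE]
  rownames(out) <- NULL
  out$turnover_a_running <- running_window(out$turnover_a, window)
  out
}

#' Tile-level enrichment delta vs gene density
#'
#' Normalizes two masked tile tables each to its own mean unmasked
#' signal, takes the per-tile delta (`b - a`) over tiles unmasked in
#' both, and summarizes gene density in the top and bottom delta
#' deciles — where in gene-density space does the second state gain the
#' variant?
#'
#' @param tiles_a,tiles_b masked `tile_table`s on the same grid.
#' @return list: `per_tile` (chrom, start, end, gene_count, norm_a,
#'   norm_b, delta) and `decile_summary` (mean gene count in bottom /
#'   top delta deciles).
#' @export
density_vs_delta <- function(tiles_a, tiles_b) {
  stopifnot(inherits(tiles_a, "tile_table"), inherits(tiles_b, "tile_table"))
  if (nrow(tiles_a) != nrow(tiles_b) ||
      !all(tiles_a$chrom == tiles_b$chrom &
           tiles_a$start == tiles_b$start)) {
    stop("tile grids do not match")
  }
  ok <- tile_ok(tiles_a) & tile_ok(tiles_b)
  if (!any(ok)) stop("no shared unmasked tiles")
  na <- tiles_a$signal / mean(tiles_a$signal[ok])
  nb <- tiles_b$signal / mean(tiles_b$signal[ok])
  per <- data.frame(chrom = tiles_a$chrom, start = tiles_a$start,
                    end = tiles_a$end, gene_count = tiles_a$gene_count,
                    norm_a = na, norm_b = nb,
                    delta = nb - na)[ok, , drop = FALSE]
  rownames(per) <- NULL
  nd <- max(1L, floor(nrow(per) / 10))
  ord <- order(per$delta)
  bottom <- per$gene_count[ord[seq_len(nd)]]
  top <- per$gene_count[ord[seq(nrow(per) - nd + 1L, nrow(per))]]
  list(per_tile = per,
       decile_summary = data.frame(
         decile = c("bottom_delta", "top_delta"),
         n = c(nd, nd),
         mean_gene_count = c(mean(bottom), mean(top))))
}
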
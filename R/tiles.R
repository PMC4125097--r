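# 100-kb tile summaries: per-tile signal, gene (TSS) counts, and the
# artifact / unmappable masking used before any tile-level correlation.

#' Summarize a coverage track over nonoverlapping genome tiles
#'
#' Segments each chromosome into fixed tiles aligned to the tile grid
#' (only full tiles are emitted; a trailing partial tile is dropped so
#' tile sums stay comparable), sums the track's bin values within each
#' tile, and counts annotated TSSs per tile (half-open: a TSS exactly on
#' a tile boundary belongs to the following tile).
#'
#' @param track a `coverage_track` (see [bin_coverage()]); its bin size
#'   must divide `tile_size`.
#' @param annotation a [genome_annotation()] on the same chromosomes.
#' @param tile_size tile width in bp (default 100 kb).
#' @return data.frame of class `tile_table`: `chrom`, `start`, `end`,
#'   `signal`, `gene_count`, `mask` (all `"ok"`).
#' @export
make_tile_table <- function(track, annotation, tile_size = 100000L) {
  stopifnot(inherits(track, "coverage_track"))
  if (tile_size %% track$bin_size != 0) {
    stop("`tile_size` must be a multiple of the track bin size")
  }
  bpt <- tile_size %/% track$bin_size
  rows <- list()
  for (ch in names(track$values)) {
    len <- track$chrom_lengths[[ch]]
    n_tiles <- floor(len / tile_size)
    if (n_tiles == 0) {
      warning("chromosome ", ch, " shorter than one tile; emitting none")
      next
    }
    v <- track$values[[ch]]
    idx <- seq_len(n_tiles * bpt)
    signal <- as.numeric(rowsum(v[idx], rep(seq_len(n_tiles), each = bpt)))
    tss <- annotation$genes$tss[annotation$genes$chrom == ch]
    cnt <- tabulate(floor(tss / tile_size) + 1L, nbins = n_tiles)
    rows[[ch]] <- data.frame(
      chrom = ch,
      start = (seq_len(n_tiles) - 1) * tile_size,
      end = seq_len(n_tiles) * tile_size,
      signal = signal, gene_count = cnt, mask = "ok")
  }
  if (length(rows) == 0) stop("no chromosome long enough for one tile")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tile_table", "data.frame")
  attr(out, "tile_size") <- as.integer(tile_size)
  out
}

#' Mask artifact and unmappable tiles
#'
#' Flags the top 1% of tiles by signal in the uninduced (no-dox) control
#' as `artifact_top1pct` — spurious enrichment that shows up in every
#' dataset — and tiles with zero reads in the target as `zero_reads`.
#' Exactly `ceiling(0.01 n)` tiles are flagged among tiles with strictly
#' positive control signal (an all-zero control flags nothing); ties are
#' broken by genomic order. Flags are additive annotations: no row is
#' ever dropped, downstream consumers filter with [tile_ok()].
#'
#' @param tiles target `tile_table`.
#' @param control `tile_table` from the uninduced control on the same
#'   tile grid.
#' @return `tiles` with an updated `mask` column.
#' @export
mask_tiles <- function(tiles, control) {
  stopifnot(inherits(tiles, "tile_table"), inherits(control, "tile_table"))
  if (nrow(tiles) != nrow(control) ||
      !all(tiles$chrom == control$chrom & tiles$start == control$start)) {
    stop("target and control tile grids do not match")
  }
  n <- nrow(tiles)
  artifact <- rep(FALSE, n)
  eligible <- which(control$signal > 0)
  if (length(eligible) > 0) {
    n_top <- min(ceiling(0.01 * n), length(eligible))
    ord <- eligible[order(-control$signal[eligible], eligible)]
    artifact[ord[seq_len(n_top)]] <- TRUE
  }
  zero <- tiles$signal == 0
  mask <- rep("ok", n)
  mask[zero] <- "zero_reads"
  mask[artifact] <- "artifact_top1pct"
  mask[artifact & zero] <- "artifact_top1pct+zero_reads"
  pc_log("INFO", "mask_tiles: %d/%d artifact_top1pct, %d zero_reads",
         sum(artifact), n, sum(zero))
  tiles$mask <- mask
  tiles
}

#' Which tiles survive masking?
#'
#' @param tiles a `tile_table`.
#' @return logical vector, TRUE where the tile is unmasked.
#' @export
tile_ok <- function(tiles) tiles$mask == "ok"

#' Write a tile table as TSV
#'
#' @param tiles a `tile_table`.
#' @param path output file.
#' @param stamp optional provenance string written as a header comment.
#' @return `path`, invisibly.
#' @export
write_tile_table <- function(tiles, path, stamp = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(stamp)) writeLines(paste0("# ", stamp), con)
  utils::write.table(as.data.frame(tiles), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
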
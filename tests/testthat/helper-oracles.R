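# Independent oracles and fixture builders. Everything here recomputes
# quantities by brute force, never through the package's own fast paths.

# Per-base coverage oracle: accumulate occurrence-weighted coverage base
# by base, then sum into bins and ppm-scale. Only usable on toy genomes.
oracle_bin_coverage <- function(fragments, chrom_len, bin_size,
                                total_occ = sum(fragments$occurrences)) {
  base <- numeric(chrom_len)
  for (i in seq_len(nrow(fragments))) {
    s <- fragments$start[i] + 1L
    e <- fragments$end[i]
    base[s:e] <- base[s:e] + fragments$occurrences[i]
  }
  nb <- ceiling(chrom_len / bin_size)
  v <- numeric(nb)
  for (b in seq_len(nb)) {
    lo <- (b - 1L) * bin_size + 1L
    hi <- min(b * bin_size, chrom_len)
    v[b] <- sum(base[lo:hi])
  }
  v * 1e6 / total_occ
}

# Direct interval-overlap tile recomputation from a per-base oracle.
oracle_tile_signal <- function(track_values, bin_size, tile_size, n_tiles) {
  bpt <- tile_size / bin_size
  vapply(seq_len(n_tiles), function(tl) {
    sum(track_values[((tl - 1) * bpt + 1):(tl * bpt)])
  }, numeric(1))
}

# Forward-Euler integrator for the exchange ODE with replication resets;
# the brute-force check on the analytic propagator.
oracle_euler_F <- function(t, k, pool, cc = NULL, phase = 0,
                           rep_offset = NULL, dt = 0.001) {
  p <- function(s) pulsechase::pool_fraction(s, pool)
  events <- numeric(0)
  if (!is.null(cc)) {
    if (is.null(rep_offset)) rep_offset <- (cc$s_start + cc$s_end) / 2
    e1 <- (rep_offset - phase) %% cc$T
    if (e1 < t) {
      events <- seq(e1, t + cc$T, by = cc$T)
      events <- events[events < t]
    }
  }
  F <- 0
  s <- 0
  while (s < t - 1e-12) {
    step <- min(dt, t - s)
    ev <- events[events > s & events <= s + step]
    if (length(ev) > 0) {
      # integrate to the event, reset, then continue
      d1 <- ev[1] - s
      F <- F + k * (p(s) - F) * d1
      F <- cc$retention * F + (1 - cc$retention) * p(ev[1])
      s <- ev[1]
      next
    }
    F <- F + k * (p(s) - F) * step
    s <- s + step
  }
  F
}

# Hand-construct a coverage track from a bare value vector (single
# chromosome) without running the binning code.
toy_track <- function(values, bin_size = 20, chrom = "chr1",
                      chrom_len = length(values) * bin_size,
                      total_occ = 1000) {
  structure(list(bin_size = as.integer(bin_size),
                 chrom_lengths = stats::setNames(chrom_len, chrom),
                 total_occurrences = total_occ,
                 values = stats::setNames(list(values), chrom)),
            class = "coverage_track")
}

# Minimal annotation with explicit genes.
toy_annotation <- function(chrom_len = 1e6, genes = NULL, chrom = "chr1") {
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        tss = integer(), strand = character(),
                        expression = numeric())
  }
  genome_annotation(data.frame(name = chrom, length = chrom_len), genes)
}

# Random fragment set on a toy chromosome, reproducible.
random_fragments <- function(n, chrom_len, seed, max_len = 150,
                             chrom = "chr1") {
  set.seed(seed)
  start <- sample.int(chrom_len - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + len,
             strand = sample(c("+", "-"), n, TRUE),
             occurrences = sample.int(5L, n, TRUE))
}

# Small, fast simulation config for orchestration tests.
tiny_config <- function(seed = 11, ...) {
  sim_config(seed = seed, n_chroms = 1L, chrom_length = 3e6,
             n_genes = 200L, depth = 1.5e5, ...)
}
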
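# Ground-truth kinetics assignment and read sampling: the forward model
# that turns a synthetic genome into BED-format pulse-chase ChIP samples
# with known per-locus exchange rates.

logistic <- function(x) 1 / (1 + exp(-x))

# Promoter exchange rate as a deterministic increasing function of
# expression. Deterministic so that k is exactly monotone in expression
# (the stated coupling); `coupling` scales the dynamic range.
promoter_rate <- function(expression, config) {
  g <- logistic((expression - config$expr_means[2]) / config$expr_sds[2])
  k <- config$k_range[1] +
    config$coupling * (config$k_range[2] - config$k_range[1]) * g
  if (config$mode == "MEF") {
    k <- config$k_background +
      config$mef_promoter_shrink * (k - config$k_background)
  }
  pmax(k, 0)
}

# Desert intervals per chromosome, from the territory labels the generator
# stored, or (for external annotations) from runs of >= 5 consecutive
# 100-kb windows without a TSS.
desert_intervals <- function(annotation) {
  unit <- 100000L
  units <- attr(annotation, "units")
  out <- list()
  for (i in seq_len(nrow(annotation$chromosomes))) {
    ch <- annotation$chromosomes$name[i]
    n_units <- floor(annotation$chromosomes$length[i] / unit)
    if (n_units < 1) next
    if (!is.null(units)) {
      is_desert <- units[[ch]] == "desert"
    } else {
      tss <- annotation$genes$tss[annotation$genes$chrom == ch]
      cnt <- tabulate(pmin(floor(tss / unit) + 1L, n_units), nbins = n_units)
      empty <- cnt == 0
      r <- rle(empty)
      keep <- r$values & r$lengths >= 5L
      is_desert <- inverse.rle(list(values = keep, lengths = r$lengths))
    }
    if (!any(is_desert)) next
    r <- rle(is_desert)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch,
      start = (starts[sel] - 1L) * unit,
      end = ends[sel] * unit)
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  }
  do.call(rbind, out)
}

# Tile [start, end) with pieces of width w; the final partial piece is
# kept when at least 1 bp remains.
tile_interval <- function(start, end, w) {
  s <- seq(start, end - 1, by = w)
  data.frame(start = s, end = pmin(s + w, end))
}

#' Assign ground-truth kinetics to a genome
#'
#' Lays kinetic loci over the annotation: one `hot_promoter` locus
#' (`promoter_width` bp centered on the TSS) per expressed gene, with
#' exchange rate a deterministic increasing logistic function of
#' expression; `cold_block` loci (zero exchange) tiling gene deserts;
#' `background` loci tiling the rest; and a few `artifact` loci with
#' large non-specific pulldown weight in every sample (what the top-1%
#' no-dox tile mask exists to remove). In MEF mode promoter rates are
#' shrunk toward background, desert blocks gain occupancy, and gene-free
#' non-desert windows acquire additional cold blocks.
#'
#' @param annotation a [genome_annotation()].
#' @param config a [sim_config()].
#' @return data.frame of class `kinetic_truth` with columns `locus_id`,
#'   `chrom`, `start`, `end`, `occupancy`, `k`, `rep_offset`, `class`,
#'   `nonspec`.
#' @export
assign_kinetics <- function(annotation, config) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "sim_config"))
  if (nrow(annotation$chromosomes) == 0) stop("empty annotation")
  set.seed(derive_seed(config$seed, "assign_kinetics"))
  clen <- chrom_lengths(annotation)
  half <- config$promoter_width / 2
  loci <- list()

  expressed <- annotation$genes[
    annotation$genes$expression >= config$expressed_threshold, , drop = FALSE]
  if (nrow(expressed) > 0) {
    loci$promoter <- data.frame(
      locus_id = paste0("prom_", expressed$gene_id),
      chrom = expressed$chrom,
      start = pmax(0, round(expressed$tss - half)),
      end = pmin(clen[expressed$chrom], round(expressed$tss + half)),
      occupancy = config$occ_promoter,
      k = promoter_rate(expressed$expression, config),
      class = "hot_promoter",
      nonspec = config$nonspec)
  }

  des <- desert_intervals(annotation)
  occ_cold <- config$occ_cold *
    if (config$mode == "MEF") config$mef_desert_gain else 1
  if (nrow(des) > 0) {
    tiles <- do.call(rbind, lapply(seq_len(nrow(des)), function(i) {
      tl <- tile_interval(des$start[i], des$end[i], config$cold_tile)
      tl$chrom <- des$chrom[i]
      tl
    }))
    loci$cold <- data.frame(
      locus_id = sprintf("cold_%05d", seq_len(nrow(tiles))),
      chrom = tiles$chrom, start = tiles$start, end = tiles$end,
      occupancy = occ_cold, k = config$k_cold,
      class = "cold_block", nonspec = config$nonspec)
  }

  # background tiles over non-desert territory
  bg <- list()
  for (i in seq_len(nrow(annotation$chromosomes))) {
    ch <- annotation$chromosomes$name[i]
    tl <- tile_interval(0, clen[ch], config$background_tile)
    di <- des[des$chrom == ch, , drop = FALSE]
    if (nrow(di) > 0) {
      inside <- rep(FALSE, nrow(tl))
      for (j in seq_len(nrow(di))) {
        inside <- inside | (tl$start >= di$start[j] & tl$end <= di$end[j])
      }
      tl <- tl[!inside, , drop = FALSE]
    }
    if (nrow(tl) > 0) { tl$chrom <- ch; bg[[length(bg) + 1L]] <- tl }
  }
  if (length(bg) > 0) {
    bg <- do.call(rbind, bg)
    cls <- rep("background", nrow(bg))
    kbg <- rep(config$k_background, nrow(bg))
    occ <- rep(config$occ_background, nrow(bg))
    if (config$mode == "MEF") {
      # differentiation spreads stable blocks into gene-poor territory:
      # background tiles in gene-free 100-kb windows, or flanking an
      # existing desert by one window, become cold blocks
      unit <- 100000L
      convert <- vapply(seq_len(nrow(bg)), function(i) {
        g <- annotation$genes
        win_start <- floor(bg$start[i] / unit) * unit
        genefree <- !any(g$chrom == bg$chrom[i] &
                           g$tss >= win_start & g$tss < win_start + unit)
        di <- des[des$chrom == bg$chrom[i], , drop = FALSE]
        margin <- nrow(di) > 0 &&
          any(bg$start[i] < di$end + unit & bg$end[i] > di$start - unit)
        genefree || margin
      }, logical(1))
      cls[convert] <- "cold_block"
      kbg[convert] <- config$k_cold
      occ[convert] <- occ_cold
    }
    loci$background <- data.frame(
      locus_id = sprintf("bg_%05d", seq_len(nrow(bg))),
      chrom = bg$chrom, start = bg$start, end = bg$end,
      occupancy = occ, k = kbg, class = cls, nonspec = config$nonspec)
  }

  if (config$n_artifacts > 0) {
    # artifacts live in ordinary territory (repeat-adjacent spurious
    # enrichment), never inside gene deserts
    ch <- sample(annotation$chromosomes$name, config$n_artifacts,
                 replace = TRUE)
    pos <- floor(stats::runif(config$n_artifacts) *
                   (clen[ch] - config$artifact_width))
    if (nrow(des) > 0) {
      for (i in seq_len(config$n_artifacts)) {
        guard <- 0
        repeat {
          di <- des[des$chrom == ch[i], , drop = FALSE]
          hit <- nrow(di) > 0 &&
            any(pos[i] < di$end & pos[i] + config$artifact_width > di$start)
          if (!hit || guard > 100) break
          pos[i] <- floor(stats::runif(1) *
                            (clen[ch[i]] - config$artifact_width))
          guard <- guard + 1
        }
      }
    }
    loci$artifact <- data.frame(
      locus_id = sprintf("artifact_%02d", seq_len(config$n_artifacts)),
      chrom = ch, start = pos, end = pos + config$artifact_width,
      occupancy = 0, k = 0, class = "artifact",
      nonspec = config$artifact_weight)
  }

  truth <- do.call(rbind, loci)
  rownames(truth) <- NULL
  cc <- config$cell_cycle
  truth$rep_offset <- if (config$rep_timing_heterogeneity) {
    stats::runif(nrow(truth), cc$s_start, cc$s_end)
  } else {
    rep((cc$s_start + cc$s_end) / 2, nrow(truth))
  }
  truth <- truth[, c("locus_id", "chrom", "start", "end", "occupancy",
                     "k", "rep_offset", "class", "nonspec")]
  class(truth) <- c("kinetic_truth", "data.frame")
  attr(truth, "mode") <- config$mode
  truth
}

#' Sample aligned reads from expected per-locus signal
#'
#' Poisson read sampling: locus i receives `Poisson(depth * w_i / sum(w))`
#' read occurrences, where `w_i = (signal_i + nonspec_i) * width_i`
#' combines specific tag signal and the flat non-specific pulldown floor.
#' Fragment start positions are uniform within the locus, strands random;
#' read coordinates are clipped to the chromosome. Fixing the total
#' expected occurrences at `depth` per sample is what creates the
#' depth-normalization behavior of real sequencing: early samples have
#' little total tag, so hot loci soak up a large share of a fixed read
#' budget.
#'
#' @param signal data.frame from [population_signal()] (columns
#'   `locus_id`, `signal`).
#' @param truth matching [assign_kinetics()] table (locus coordinates and
#'   non-specific weights).
#' @param config a [sim_config()].
#' @param annotation the [genome_annotation()] (for clipping).
#' @param label sample label, folded into the sampling seed so each time
#'   point draws independent reads.
#' @return data.frame of 6-column BED records (`chrom`, `start`, `end`,
#'   `name`, `score` = occurrence count, `strand`).
#' @export
sample_reads <- function(signal, truth, config, annotation,
                         label = "sample") {
  stopifnot(inherits(config, "sim_config"))
  truth <- as.data.frame(truth)
  m <- match(truth$locus_id, signal$locus_id)
  if (anyNA(m)) stop("signal and truth locus sets differ")
  sig <- signal$signal[m]
  width <- truth$end - truth$start
  w <- (sig + truth$nonspec) * width
  if (sum(w) <= 0) stop("total expected signal is zero; nothing to sample")
  set.seed(derive_seed(config$seed, paste0("sample_reads:", label)))
  lam <- config$depth * w / sum(w)
  counts <- stats::rpois(length(lam), lam)
  n <- sum(counts)
  if (n == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = integer(), strand = character()))
  }
  chrom <- rep(truth$chrom, counts)
  lo <- rep(truth$start, counts)
  wd <- rep(width, counts)
  fs <- lo + floor(stats::runif(n) * wd)
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  clen <- chrom_lengths(annotation)[chrom]
  rl <- config$read_length; fl <- config$fragment_length
  start <- ifelse(strand == "+", fs, pmax(fs + fl - rl, 0))
  end <- ifelse(strand == "+", pmin(fs + rl, clen), pmin(fs + fl, clen))
  start <- pmin(start, end - 1)
  reads <- data.frame(chrom = chrom, start = as.integer(start),
                      end = as.integer(end),
                      name = sprintf("read%07d", seq_len(n)),
                      score = 1L, strand = strand)
  reads <- reads[order(reads$chrom, reads$start, reads$strand), ]
  rownames(reads) <- NULL
  reads
}

sample_label <- function(t) if (t == 0) "no_dox" else sprintf("t%g", t)

#' Simulate a full pulse-chase experiment
#'
#' Genome, ground-truth kinetics, expected per-locus signals at every
#' configured time point, and Poisson-sampled BED reads per sample.
#' Deterministic for a given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `annotation`, `truth`, `signals` (named list of
#'   [population_signal()] tables) and `reads` (named list of BED
#'   data.frames); names are `no_dox`, `t3`, `t6`, `t12`, ...
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$depth <= 0) stop("`depth` must be positive to simulate reads")
  annotation <- make_genome(config)
  truth <- assign_kinetics(annotation, config)
  labels <- vapply(config$timepoints, sample_label, "")
  signals <- lapply(config$timepoints, function(t) {
    population_signal(truth, t, config$pool, config$cell_cycle)
  })
  names(signals) <- labels
  reads <- lapply(seq_along(config$timepoints), function(i) {
    sample_reads(signals[[i]], truth, config, annotation, labels[i])
  })
  names(reads) <- labels
  list(annotation = annotation, truth = truth,
       signals = signals, reads = reads, config = config)
}

#' Write simulator outputs to plain-text files
#'
#' Reads as 6-column BED, the kinetic truth and per-time-point expected
#' signals as TSV, the annotation as TSV. Every file carries the seed in
#' a leading comment.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if missing).
#' @return named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- sim$config$seed
  paths <- list()
  paths$annotation <- file.path(dir, "annotation.tsv")
  write_annotation(sim$annotation, paths$annotation)
  paths$truth <- file.path(dir, "truth.tsv")
  con <- file(paths$truth, "w")
  writeLines(sprintf("# seed: %d", seed), con)
  utils::write.table(as.data.frame(sim$truth), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  close(con)
  for (lab in names(sim$reads)) {
    p <- file.path(dir, paste0("reads_", lab, ".bed"))
    write_bed(sim$reads[[lab]], p, seed = seed)
    paths[[paste0("reads_", lab)]] <- p
    p2 <- file.path(dir, paste0("signal_", lab, ".tsv"))
    con <- file(p2, "w")
    writeLines(sprintf("# seed: %d", seed), con)
    utils::write.table(sim$signals[[lab]], con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    close(con)
    paths[[paste0("signal_", lab)]] <- p2
  }
  invisible(paths)
}

#' Write reads as 6-column BED
#'
#' @param reads data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @param path output file.
#' @param seed optional seed recorded in a header comment.
#' @return `path`, invisibly.
#' @export
write_bed <- function(reads, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.table(
    reads[, c("chrom", "start", "end", "name", "score", "strand")],
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
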
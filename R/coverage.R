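# Aligned-read processing: collapse duplicate alignments, extend reads
# 3'-ward to fragment length, and accumulate ppm-normalized binned
# coverage. Coordinates are 0-based half-open throughout.

#' Read a 6-column BED file of aligned reads
#'
#' Columns: chrom, start, end, name, score (occurrence count; a missing
#' score column means 1), strand. Lines starting with `#` or `track` are
#' skipped. Malformed lines are reported with their line number.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  if (length(lineno) == 0) {
    warning("BED file ", path, " contains no records")
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = integer(), strand = character()))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 3)
  if (length(bad) > 0) {
    stop("malformed BED record at line ", lineno[bad[1]], " of ", path,
         " (fewer than 3 fields)")
  }
  getf <- function(i, default) {
    vapply(parts, function(p) if (length(p) >= i) p[i] else default, "")
  }
  start <- suppressWarnings(as.integer(getf(2, NA)))
  end <- suppressWarnings(as.integer(getf(3, NA)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0) {
    stop("malformed BED record at line ", lineno[bad[1]], " of ", path,
         " (bad coordinates)")
  }
  score <- suppressWarnings(as.integer(getf(5, "1")))
  score[is.na(score)] <- 1L
  strand <- getf(6, "+")
  strand[!strand %in% c("+", "-")] <- "+"
  data.frame(chrom = getf(1, NA), start = start, end = end,
             name = getf(4, "."), score = score, strand = strand)
}

#' Collapse aligned reads by position
#'
#' Merges records sharing `(chrom, start, strand)`, summing occurrence
#' counts; stands in for sequence-level collapsing when the input is
#' already aligned (reads are fixed-length, so position identifies the
#' sequence). The first record's `end` is retained on merge. Total
#' occurrences are conserved.
#'
#' @param reads data.frame from [read_bed()] (or [sample_reads()]).
#' @param annotation optional [genome_annotation()]; when given, reads on
#'   unknown chromosomes are an error.
#' @return data.frame of collapsed alignments with column `occurrences`.
#' @export
ingest_and_collapse <- function(reads, annotation = NULL) {
  reads <- as.data.frame(reads)
  if (nrow(reads) == 0) {
    warning("no reads to collapse")
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      occurrences = integer()))
  }
  if (!is.null(annotation)) {
    unknown <- setdiff(unique(reads$chrom), annotation$chromosomes$name)
    if (length(unknown) > 0) {
      stop("reads reference unknown chromosome(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  occ <- if ("score" %in% names(reads)) reads$score else
         if ("occurrences" %in% names(reads)) reads$occurrences else
         rep(1L, nrow(reads))
  if (any(occ < 1)) stop("occurrence counts must be >= 1")
  dt <- data.table::data.table(chrom = reads$chrom, start = reads$start,
                               end = reads$end, strand = reads$strand,
                               occ = occ)
  out <- dt[, list(end = end[1L], occurrences = sum(occ)),
            by = c("chrom", "start", "strand")]
  data.table::setorder(out, chrom, start, strand)
  as.data.frame(out[, c("chrom", "start", "end", "strand", "occurrences")])
}

#' Extend collapsed alignments to fragment length
#'
#' Each alignment is extended toward its 3' end to `fragment_length` bp:
#' plus-strand reads become `[start, start + L)`, minus-strand reads
#' `[end - L, end)`, clipped to the chromosome, mirroring sonicated
#' fragment footprints.
#'
#' @param alignments data.frame from [ingest_and_collapse()].
#' @param annotation a [genome_annotation()] (chromosome bounds for
#'   clipping).
#' @param fragment_length target fragment length in bp (> 0).
#' @return data.frame of fragment intervals with `occurrences` preserved.
#' @export
extend_reads <- function(alignments, annotation, fragment_length = 150L) {
  if (fragment_length <= 0) stop("`fragment_length` must be positive")
  a <- as.data.frame(alignments)
  if (nrow(a) == 0) return(a)
  clen <- chrom_lengths(annotation)[a$chrom]
  if (anyNA(clen)) stop("alignments reference unknown chromosomes")
  plus <- a$strand == "+"
  start <- ifelse(plus, a$start, pmax(a$end - fragment_length, 0))
  end <- ifelse(plus, pmin(a$start + fragment_length, clen), a$end)
  data.frame(chrom = a$chrom, start = start, end = end,
             strand = a$strand, occurrences = a$occurrences)
}

#' Bin fragment coverage into a ppm-normalized track
#'
#' Accumulates occurrence-weighted per-base fragment coverage into
#' fixed-width bins and scales by `1e6 / total_occurrences` (parts per
#' million of the genome-wide read total). The track satisfies the exact
#' conservation rule: the genome-wide sum of bin values equals
#' `1e6 * sum(occurrences * fragment_length) / total_occurrences`, and is
#' invariant to multiplying every occurrence count by a constant.
#'
#' @param fragments data.frame from [extend_reads()].
#' @param annotation a [genome_annotation()].
#' @param bin_size bin width in bp (default 20).
#' @return object of class `coverage_track`: list with `bin_size`,
#'   `chrom_lengths`, `total_occurrences` and `values` (named list of
#'   per-chromosome numeric vectors, ppm units).
#' @export
bin_coverage <- function(fragments, annotation, bin_size = 20L) {
  if (bin_size <= 0) stop("`bin_size` must be positive")
  f <- as.data.frame(fragments)
  total <- sum(f$occurrences)
  if (is.na(total) || total <= 0) stop("zero total occurrences")
  clen <- chrom_lengths(annotation)
  scale <- 1e6 / total
  values <- lapply(names(clen), function(ch) {
    nb <- as.integer(ceiling(clen[[ch]] / bin_size))
    v <- numeric(nb)
    fi <- f[f$chrom == ch, , drop = FALSE]
    if (nrow(fi) == 0) return(v)
    b0 <- fi$start %/% bin_size
    b1 <- (fi$end - 1L) %/% bin_size
    span <- max(b1 - b0) + 1L
    idx_all <- vector("list", span)
    val_all <- vector("list", span)
    for (j in seq_len(span)) {
      b <- b0 + (j - 1L)
      sel <- b <= b1
      if (!any(sel)) next
      ov <- pmin(fi$end[sel], (b[sel] + 1) * bin_size) -
            pmax(fi$start[sel], b[sel] * bin_size)
      idx_all[[j]] <- b[sel] + 1L
      val_all[[j]] <- ov * fi$occurrences[sel]
    }
    idx <- unlist(idx_all)
    val <- unlist(val_all)
    agg <- rowsum(val, idx)
    v[as.integer(rownames(agg))] <- agg[, 1]
    v * scale
  })
  names(values) <- names(clen)
  structure(list(bin_size = as.integer(bin_size), chrom_lengths = clen,
                 total_occurrences = total, values = values),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "coverage_track: %d chrom(s), bin %d bp, %d occurrences, sum %.4g ppm-bp\n",
    length(x$values), x$bin_size, x$total_occurrences,
    sum(unlist(x$values))))
  invisible(x)
}

#' Full read-to-track pipeline
#'
#' Convenience wrapper: collapse, 3'-extend and bin in one call.
#'
#' @inheritParams ingest_and_collapse
#' @inheritParams extend_reads
#' @inheritParams bin_coverage
#' @return a `coverage_track`.
#' @export
coverage_pipeline <- function(reads, annotation, fragment_length = 150L,
                              bin_size = 20L) {
  collapsed <- ingest_and_collapse(reads, annotation)
  fragments <- extend_reads(collapsed, annotation, fragment_length)
  bin_coverage(fragments, annotation, bin_size)
}

#' Write a coverage track as fixed-step bedGraph
#'
#' @param track a `coverage_track`.
#' @param path output file.
#' @param seed optional seed recorded in a header comment.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  writeLines(sprintf("track type=bedGraph step=%d", track$bin_size), con)
  bs <- track$bin_size
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    nz <- which(v != 0)
    if (length(nz) == 0) next
    starts <- (nz - 1L) * bs
    ends <- pmin(nz * bs, track$chrom_lengths[[ch]])
    utils::write.table(
      data.frame(ch, starts, ends, signif(v[nz], 8)), con, sep = "\t",
      quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
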
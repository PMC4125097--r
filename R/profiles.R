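# TSS-centered matrices and everything built on them: flank-normalized
# metaprofiles, promoter summaries, k-means clustering with centroid
# merging, expression quintiles.

new_tss_matrix <- function(values, gene_ids, bin_size, flank,
                           units = "ppm", oriented = TRUE) {
  rownames(values) <- gene_ids
  structure(list(values = values, gene_ids = gene_ids,
                 bin_size = bin_size, flank = flank, units = units,
                 oriented = oriented),
            class = "tss_matrix")
}

#' @export
print.tss_matrix <- function(x, ...) {
  cat(sprintf(
    "tss_matrix: %d genes x %d bins (%d bp), span +/-%d bp, units %s\n",
    nrow(x$values), ncol(x$values), x$bin_size, x$flank, x$units))
  invisible(x)
}

# Extract windows of `n_bins` grid bins starting at bin floor((pos-flank)/bin)
# for each anchor; out-of-chromosome bins become NA.
extract_windows <- function(track, chrom, pos, flank, n_bins) {
  bs <- track$bin_size
  m <- matrix(NA_real_, nrow = length(pos), ncol = n_bins)
  for (ch in unique(chrom)) {
    rows <- which(chrom == ch)
    v <- track$values[[ch]]
    if (is.null(v)) stop("anchor on unknown chromosome: ", ch)
    s <- floor((pos[rows] - flank) / bs)
    idx <- outer(s, 0:(n_bins - 1L), "+") + 1L
    idx[idx < 1L | idx > length(v)] <- NA_integer_
    m[rows, ] <- v[idx]
  }
  m
}

#' Strand-aware TSS-centered signal matrix
#'
#' One row per gene, fixed-width bins spanning `flank` bp on either side
#' of the TSS, oriented so that positive x is downstream of
#' transcription: minus-strand rows are reversed. With the default
#' `flank = 4000` and 20-bp bins the matrix has 400 columns and 0-based
#' bin 200 begins at the TSS. Window positions that fall off the
#' chromosome are missing (`NA`), not zero.
#'
#' @param track a `coverage_track`.
#' @param annotation a [genome_annotation()]; every gene's chromosome
#'   must be in the track.
#' @param flank half-window in bp; must be a multiple of the bin size.
#' @return object of class `tss_matrix`.
#' @export
tss_matrix <- function(track, annotation, flank = 4000L) {
  stopifnot(inherits(track, "coverage_track"))
  if (flank %% track$bin_size != 0) {
    stop("`flank` must be a multiple of the track bin size")
  }
  g <- annotation$genes
  if (nrow(g) == 0) stop("annotation has no genes")
  unknown <- setdiff(unique(g$chrom), names(track$values))
  if (length(unknown) > 0) {
    stop("gene(s) on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  n_bins <- as.integer(2 * flank / track$bin_size)
  m <- extract_windows(track, g$chrom, g$tss, flank, n_bins)
  minus <- g$strand == "-"
  if (any(minus)) m[minus, ] <- m[minus, n_bins:1, drop = FALSE]
  new_tss_matrix(m, g$gene_id, track$bin_size, flank)
}

#' Unoriented anchor-centered signal matrix
#'
#' Like [tss_matrix()] but centered on arbitrary feature midpoints
#' (bound-factor peaks, domain centers, ...) with no strand flip.
#'
#' @param track a `coverage_track`.
#' @param anchors data.frame with columns `chrom` and `midpoint` (0-based
#'   bp).
#' @param span full window width in bp (default 8 kb).
#' @return object of class `tss_matrix` (with `oriented = FALSE`).
#' @export
anchor_matrix <- function(track, anchors, span = 8000L) {
  stopifnot(inherits(track, "coverage_track"))
  anchors <- as.data.frame(anchors)
  if (nrow(anchors) == 0) stop("empty anchor list")
  if (span %% (2 * track$bin_size) != 0) {
    stop("`span` must be a multiple of twice the bin size")
  }
  flank <- span / 2
  n_bins <- as.integer(span / track$bin_size)
  m <- extract_windows(track, anchors$chrom, anchors$midpoint, flank, n_bins)
  ids <- if ("id" %in% names(anchors)) anchors$id else
    sprintf("anchor%04d", seq_len(nrow(anchors)))
  new_tss_matrix(m, ids, track$bin_size, flank, oriented = FALSE)
}

window_bins <- function(m, window) {
  starts <- -m$flank + (seq_len(ncol(m$values)) - 1L) * m$bin_size
  which(starts >= window[1] & starts + m$bin_size <= window[2])
}

#' Normalize rows to their upstream flank
#'
#' Divides each row (or a single profile) by its mean over an upstream
#' flank window and takes log2, turning raw ppm into enrichment relative
#' to the local baseline. Default flank is -4 kb..-2 kb; the alternative
#' -2.5..-1.5 kb window used for grouped time-course averages is
#' available via `flank_window`. Values are floored at `pseudocount`
#' before the log; rows whose flank mean is at or below the pseudocount
#' are flagged (set to `NA`, listed in `attr(, "flagged")`) and excluded
#' from downstream averages. With `log = FALSE` the ratio itself is
#' returned, on which the operation is idempotent.
#'
#' @param m a `tss_matrix`, or a numeric profile vector (one row's worth
#'   of bins).
#' @param flank_window numeric length-2, bp relative to the anchor.
#' @param pseudocount floor applied before the log (ppm units).
#' @param log return log2 ratios (default) or plain ratios.
#' @return object of the same shape in `log2_ratio` (or `ratio`) units.
#' @export
flank_normalize <- function(m, flank_window = c(-4000, -2000),
                            pseudocount = 0.01, log = TRUE) {
  if (is.numeric(m) && is.null(dim(m))) {
    stop("flank_normalize on a bare profile vector needs bin metadata; ",
         "wrap it with profile_as_matrix() first")
  }
  stopifnot(inherits(m, "tss_matrix"))
  if (flank_window[1] >= flank_window[2]) stop("empty flank window")
  idx <- window_bins(m, flank_window)
  if (length(idx) == 0) stop("flank window outside matrix span")
  fm <- rowMeans(m$values[, idx, drop = FALSE], na.rm = TRUE)
  flagged <- !is.finite(fm) | fm <= pseudocount
  out <- m$values
  ok <- which(!flagged)
  if (log) {
    out[ok, ] <- log2(pmax(out[ok, , drop = FALSE], pseudocount) / fm[ok])
  } else {
    out[ok, ] <- out[ok, , drop = FALSE] / fm[ok]
  }
  out[flagged, ] <- NA_real_
  if (any(flagged)) {
    pc_log("INFO", "flank_normalize: %d/%d row(s) flagged (flank <= %g)",
           sum(flagged), length(fm), pseudocount)
  }
  res <- new_tss_matrix(out, m$gene_ids, m$bin_size, m$flank,
                        units = if (log) "log2_ratio" else "ratio",
                        oriented = m$oriented)
  attr(res, "flagged") <- m$gene_ids[flagged]
  res
}

#' Wrap a single profile vector as a one-row matrix
#'
#' Lets [flank_normalize()] operate on a group-average profile (normalize
#' the average rather than averaging normalized rows).
#'
#' @param profile numeric vector of bin values.
#' @param template `tss_matrix` supplying bin size and span.
#' @return one-row `tss_matrix`.
#' @export
profile_as_matrix <- function(profile, template) {
  stopifnot(inherits(template, "tss_matrix"),
            length(profile) == ncol(template$values))
  new_tss_matrix(matrix(profile, nrow = 1), "profile",
                 template$bin_size, template$flank,
                 units = template$units, oriented = template$oriented)
}

#' Average profile over a gene subset
#'
#' Per-bin mean across the selected rows, ignoring missing cells.
#'
#' @param m a `tss_matrix`.
#' @param gene_subset character vector of gene ids, or `NULL` for all.
#' @return numeric vector, one value per bin.
#' @export
meta_average <- function(m, gene_subset = NULL) {
  stopifnot(inherits(m, "tss_matrix"))
  v <- m$values
  if (!is.null(gene_subset)) {
    rows <- match(gene_subset, m$gene_ids)
    if (length(rows) == 0 || all(is.na(rows))) stop("empty gene subset")
    v <- v[rows[!is.na(rows)], , drop = FALSE]
  }
  if (nrow(v) == 0) stop("empty gene subset")
  colMeans(v, na.rm = TRUE)
}

#' Promoter summary statistic
#'
#' Mean bin value over the window spanning -600..+600 bp around the TSS
#' (60 bins at 20 bp). The mean (rather than the sum) keeps the
#' enrichment threshold used for cross-cell-type gene selection
#' independent of bin count; the two differ only by the constant 60.
#' Genes whose whole window is missing get `NA`.
#'
#' @param m a `tss_matrix` in ppm units.
#' @param window numeric length-2, bp relative to the TSS.
#' @return named numeric vector, one value per gene.
#' @export
promoter_summary <- function(m, window = c(-600, 600)) {
  stopifnot(inherits(m, "tss_matrix"))
  idx <- window_bins(m, window)
  if (length(idx) == 0) stop("summary window outside matrix span")
  s <- rowMeans(m$values[, idx, drop = FALSE], na.rm = TRUE)
  s[is.nan(s)] <- NA_real_
  stats::setNames(s, m$gene_ids)
}

#' k-means clustering of promoter profiles with centroid merging
#'
#' Clusters rows by k-means (fixed seed, multiple starts), then merges
#' clusters whose centroid profiles are nearly identical (Pearson
#' correlation at or above `merge_r`, merged transitively), reproducing
#' the common situation where k = 4 resolves to three interpretable
#' groups. Merged labels are renumbered 1, 2, ... in decreasing order of
#' mean centroid signal. Rows containing missing values are left
#' unlabelled (`NA`).
#'
#' @param m a `tss_matrix`.
#' @param k number of k-means clusters.
#' @param merge_r centroid Pearson correlation at which clusters merge.
#' @param seed RNG seed for reproducible clustering.
#' @return integer vector of cluster labels named by gene id;
#'   `attr(, "centroids")` holds the merged-cluster mean profiles.
#' @export
cluster_and_merge <- function(m, k = 4, merge_r = 0.90, seed = 1L) {
  stopifnot(inherits(m, "tss_matrix"))
  complete <- which(stats::complete.cases(m$values))
  if (k > length(complete)) {
    stop("k (", k, ") exceeds the number of complete rows (",
         length(complete), ")")
  }
  v <- m$values[complete, , drop = FALSE]
  set.seed(seed)
  km <- tryCatch(
    stats::kmeans(v, centers = k, nstart = 10, iter.max = 100),
    error = function(e) {
      # fewer distinct profiles than centers: degrade k gracefully
      kd <- nrow(unique(v))
      if (kd >= k) stop(e)
      stats::kmeans(v, centers = kd, nstart = 10, iter.max = 100)
    })
  k <- nrow(km$centers)
  # merge centroids with near-identical shapes (transitive closure)
  keep_sd <- apply(km$centers, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(km$centers)))
  cc[!is.finite(cc)] <- 1  # flat centroids count as identical shapes
  group <- seq_len(k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (cc[i, j] >= merge_r) {
      gi <- group[i]; gj <- group[j]
      group[group == max(gi, gj)] <- min(gi, gj)
    }
  }
  merged <- match(group, sort(unique(group)))[km$cluster]
  n_groups <- length(unique(merged))
  centroids <- t(vapply(seq_len(n_groups), function(g) {
    colMeans(v[merged == g, , drop = FALSE])
  }, numeric(ncol(v))))
  ord <- order(-rowMeans(centroids))
  relabel <- match(seq_len(n_groups), ord)
  labels <- rep(NA_integer_, length(m$gene_ids))
  labels[complete] <- relabel[merged]
  names(labels) <- m$gene_ids
  attr(labels, "centroids") <- centroids[ord, , drop = FALSE]
  labels
}

#' Boxplot statistics of promoter enrichment by expression quintile
#'
#' Ranks genes by expression, splits them into `n_groups` nearly equal
#' groups (sizes differ by at most one; ties broken by stable gene
#' order), and reports median, quartiles, mean and standard deviation of
#' the promoter summary per group — the numbers behind an
#' enrichment-by-expression boxplot.
#'
#' @param summary named numeric vector from [promoter_summary()].
#' @param annotation a [genome_annotation()] carrying expression values
#'   for every summarized gene.
#' @param n_groups number of expression groups (default 5 = quintiles).
#' @return data.frame with one row per quintile (lowest expression
#'   first): `quintile`, `n`, `median`, `q1`, `q3`, `mean`, `sd`.
#' @export
expression_quintiles <- function(summary, annotation, n_groups = 5L) {
  g <- annotation$genes
  expr <- g$expression[match(names(summary), g$gene_id)]
  if (anyNA(expr)) stop("expression missing for some summarized genes")
  n <- length(summary)
  if (n < n_groups) stop("fewer genes (", n, ") than groups (", n_groups, ")")
  ord <- order(expr)  # stable: ties keep gene order
  sizes <- rep(n %/% n_groups, n_groups) +
    (seq_len(n_groups) <= n %% n_groups)
  grp <- rep(seq_len(n_groups), times = sizes)
  s <- summary[ord]
  do.call(rbind, lapply(seq_len(n_groups), function(q) {
    x <- s[grp == q]
    data.frame(quintile = q, n = length(x),
               median = stats::median(x, na.rm = TRUE),
               q1 = unname(stats::quantile(x, 0.25, na.rm = TRUE)),
               q3 = unname(stats::quantile(x, 0.75, na.rm = TRUE)),
               mean = mean(x, na.rm = TRUE),
               sd = stats::sd(x[!is.na(x)]))
  }))
}

#' Write a TSS matrix as TSV
#'
#' Three header comment lines record the span, bin size and orientation
#' convention.
#'
#' @param m a `tss_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tss_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# span: -%d..+%d bp", m$flank, m$flank),
               sprintf("# bin_size: %d bp; units: %s", m$bin_size, m$units),
               sprintf("# orientation: %s",
                       if (m$oriented) "transcription (minus rows flipped)"
                       else "genomic (unoriented)")), con)
  df <- data.frame(gene_id = m$gene_ids, m$values, check.names = FALSE)
  colnames(df) <- c("gene_id",
                    paste0("bin", seq_len(ncol(m$values)) - 1L))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
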
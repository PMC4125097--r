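# The turnover statistic: log2 of early over late pulse-chase enrichment.
# Because sequencing depth is normalized away, the absolute scale of each
# time point is arbitrary — but pairwise differences of the score across
# loci are exactly invariant to per-time-point rescaling (with zero
# pseudocount), which is what makes the relative hot/cold calls robust.
# Canonical orientation is fast-positive (high score = rapid exchange);
# the reversed, slow-positive orientation used by some displays is an
# output option, never the internal form.

#' Relative turnover score per locus
#'
#' `score = log2((s3 + eps) / (s12 + eps))` from early (t = 3 h) and late
#' (t = 12 h) ppm-scale signals. Positive scores mean rapid exchange
#' relative to the genomic average. A mid-course signal (`s6`) may be
#' carried along for diagnostics; the score itself uses only s3 and s12.
#'
#' @param s3,s12 named nonnegative numeric vectors over the same locus
#'   set (names are matched when present).
#' @param epsilon pseudocount in ppm units (default 0.01); 0 gives the
#'   exactly rescaling-invariant score but undefined values at zero
#'   signal.
#' @param s6 optional mid-course signal, carried not scored.
#' @param ids locus ids if the inputs are unnamed.
#' @return data.frame of class `turnover_table`: `id`, `s3` (`s6`), `s12`,
#'   `score`.
#' @export
turnover_score <- function(s3, s12, epsilon = 0.01, s6 = NULL, ids = NULL) {
  if (is.null(ids)) ids <- names(s3)
  if (is.null(ids)) ids <- as.character(seq_along(s3))
  if (!is.null(names(s3)) && !is.null(names(s12))) {
    if (!setequal(names(s3), names(s12))) {
      stop("s3 and s12 cover different locus sets")
    }
    s12 <- s12[names(s3)]
    if (!is.null(s6)) {
      if (!setequal(names(s3), names(s6))) {
        stop("s6 covers a different locus set")
      }
      s6 <- s6[names(s3)]
    }
  } else if (length(s3) != length(s12)) {
    stop("s3 and s12 cover different locus sets")
  }
  if (any(s3 < 0, na.rm = TRUE) || any(s12 < 0, na.rm = TRUE)) {
    stop("signals must be nonnegative")
  }
  score <- log2((s3 + epsilon) / (s12 + epsilon))
  out <- data.frame(id = ids, s3 = unname(s3))
  if (!is.null(s6)) out$s6 <- unname(s6)
  out$s12 <- unname(s12)
  out$score <- unname(score)
  class(out) <- c("turnover_table", "data.frame")
  attr(out, "epsilon") <- epsilon
  attr(out, "orientation") <- "fast-positive"
  out
}

#' Classify loci into hot / cold / intermediate deciles
#'
#' Top 10% of loci by score are `hot`, bottom 10% `cold`, the rest
#' `intermediate`. Counts are `floor(n/10)` each; ties are broken by
#' stable id order, hot assigned before cold.
#'
#' @param table a `turnover_table` with at least 10 loci.
#' @return the table with a `decile_class` column added.
#' @export
classify_deciles <- function(table) {
  stopifnot(inherits(table, "turnover_table"))
  n <- nrow(table)
  if (n < 10) stop("decile classification needs at least 10 loci, got ", n)
  nd <- floor(n / 10)
  cls <- rep("intermediate", n)
  ord_hot <- order(-table$score)        # stable: ties keep row order
  hot <- ord_hot[seq_len(nd)]
  cls[hot] <- "hot"
  remaining <- setdiff(order(table$score), hot)
  cls[remaining[seq_len(nd)]] <- "cold"
  table$decile_class <- cls
  table
}

#' Audit normalization invariance of the turnover score
#'
#' Rescales the two time points by arbitrary positive factors (as a
#' different depth-normalization convention would) and reports the
#' maximum absolute change in any pairwise score difference. With
#' `epsilon = 0` this is exactly 0 — rescaling shifts every score by the
#' same constant `log2(f3/f12)`; with a positive pseudocount it bounds
#' the (small) distortion the pseudocount introduces.
#'
#' @param s3,s12 nonnegative signal vectors over the same loci.
#' @param factors length-2 positive rescale factors for (s3, s12).
#' @param epsilon pseudocount used in both scorings.
#' @return max absolute change in pairwise score differences (>= 0).
#' @export
invariance_audit <- function(s3, s12, factors = c(2, 5), epsilon = 0) {
  if (length(factors) != 2 || any(factors <= 0)) {
    stop("rescale factors must be two positive numbers")
  }
  base <- log2((s3 + epsilon) / (s12 + epsilon))
  scaled <- log2((s3 * factors[1] + epsilon) / (s12 * factors[2] + epsilon))
  d <- scaled - base
  d <- d[is.finite(d)]
  if (length(d) == 0) return(0)
  max(d) - min(d)
}

#' Shared-bin turnover histograms for two cell states
#'
#' Counts loci in common score bins for two turnover tables (e.g. ES vs
#' MEF), so distribution widths and shifts are directly comparable.
#' `orientation = "slow-positive"` negates scores on output (the display
#' convention where positive = slow).
#'
#' @param table_a,table_b `turnover_table`s.
#' @param bin_width histogram bin width in score units.
#' @param orientation `"fast-positive"` (internal canon) or
#'   `"slow-positive"`.
#' @return list with `breaks` and a named list `counts`; counts sum to
#'   each table's locus count.
#' @export
turnover_histogram <- function(table_a, table_b, bin_width = 0.25,
                               orientation = c("fast-positive",
                                               "slow-positive")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(table_a, "turnover_table"),
            inherits(table_b, "turnover_table"),
            nrow(table_a) > 0, nrow(table_b) > 0)
  sa <- table_a$score; sb <- table_b$score
  if (orientation == "slow-positive") { sa <- -sa; sb <- -sb }
  lo <- floor(min(sa, sb) / bin_width) * bin_width
  hi <- ceiling(max(sa, sb) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  count <- function(s) {
    idx <- pmin(pmax(findInterval(s, breaks, rightmost.closed = TRUE), 1L),
                length(breaks) - 1L)
    tabulate(idx, nbins = length(breaks) - 1L)
  }
  list(breaks = breaks,
       counts = list(a = count(sa), b = count(sb)),
       orientation = orientation)
}

#' Correlation between per-locus quantities
#'
#' Pearson or Spearman correlation on paired finite values; incomplete
#' pairs are dropped and their count reported via `attr(, "n_dropped")`.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return correlation coefficient with attributes `n` and `n_dropped`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs, got ", sum(ok))
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    stop("zero variance in x or y")
  }
  r <- stats::cor(x[ok], y[ok], method = method)
  attr(r, "n") <- sum(ok)
  attr(r, "n_dropped") <- sum(!ok)
  r
}

#' Write a turnover table as TSV
#'
#' @param table a `turnover_table`.
#' @param path output file.
#' @param orientation output orientation; `"slow-positive"` negates the
#'   score column on the way out (the internal table is untouched).
#' @param stamp optional provenance comment.
#' @return `path`, invisibly.
#' @export
write_turnover_table <- function(table, path,
                                 orientation = c("fast-positive",
                                                 "slow-positive"),
                                 stamp = NULL) {
  orientation <- match.arg(orientation)
  out <- as.data.frame(table)
  if (orientation == "slow-positive") out$score <- -out$score
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# orientation: %s%s", orientation,
                     if (is.null(stamp)) "" else paste0("; ", stamp)), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
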
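# Basic display helpers: time-course metaprofiles, turnover-sorted
# heatmaps, quintile boxplots. Deliberately plain base graphics.

#' Plot time-course metaprofiles
#'
#' One line per sample over the TSS window, y in log2 enrichment over the
#' upstream flank.
#'
#' @param profiles named list of numeric profiles (equal length).
#' @param bin_size,flank bin width and half-span in bp (for the x axis).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the x positions.
#' @export
plot_metaprofile <- function(profiles, bin_size = 20, flank = 4000, ...) {
  y <- do.call(cbind, profiles)
  x <- seq(-flank, flank - bin_size, by = bin_size) + bin_size / 2
  graphics::matplot(x, y, type = "l", lty = 1,
                    xlab = "distance from TSS (bp)",
                    ylab = "log2 enrichment vs upstream flank", ...)
  graphics::legend("topright", legend = names(profiles), lty = 1,
                   col = seq_along(profiles), bty = "n")
  invisible(x)
}

#' Heatmap of a TSS matrix with rows in a given order
#'
#' @param m a `tss_matrix`.
#' @param order row order (e.g. `order(-turnover$score)`); default as-is.
#' @param zlim color range; default robust (1st-99th percentile), global
#'   across the matrix.
#' @param ... passed to [graphics::image()].
#' @return invisibly `NULL`.
#' @export
plot_tss_heatmap <- function(m, order = seq_along(m$gene_ids),
                             zlim = NULL, ...) {
  v <- m$values[order, , drop = FALSE]
  if (is.null(zlim)) {
    zlim <- stats::quantile(v, c(0.01, 0.99), na.rm = TRUE)
  }
  v[v < zlim[1]] <- zlim[1]; v[v > zlim[2]] <- zlim[2]
  graphics::image(t(v[rev(seq_len(nrow(v))), , drop = FALSE]),
                  zlim = zlim, axes = FALSE, useRaster = TRUE, ...)
  invisible(NULL)
}

#' Quintile boxplot from precomputed statistics
#'
#' Draws the box (median, quartiles) and whiskers (mean +/- sd) from an
#' [expression_quintiles()] table.
#'
#' @param stats data.frame from [expression_quintiles()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly `NULL`.
#' @export
plot_quintiles <- function(stats, ...) {
  n <- nrow(stats)
  graphics::plot(NA, xlim = c(0.5, n + 0.5),
                 ylim = range(stats$mean - stats$sd,
                              stats$mean + stats$sd, stats$q1, stats$q3),
                 xlab = "expression quintile (low to high)",
                 ylab = "promoter enrichment", xaxt = "n", ...)
  graphics::axis(1, at = seq_len(n))
  for (i in seq_len(n)) {
    graphics::rect(i - 0.3, stats$q1[i], i + 0.3, stats$q3[i])
    graphics::segments(i - 0.3, stats$median[i], i + 0.3, stats$median[i],
                       lwd = 2)
    graphics::segments(i, stats$mean[i] - stats$sd[i],
                       i, stats$mean[i] + stats$sd[i], lty = 2)
  }
  invisible(NULL)
}
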